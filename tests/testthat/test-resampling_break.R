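test_that("subsample_links keeps exactly k links and drops isolated species", {
  set.seed(44)
  net <- rand_net(8, 10)
  i <- n_links(net)
  expect_error(subsample_links(net, 0), "k must be")
  expect_error(subsample_links(net, i + 1), "k must be")

  # k = i -> identical link set
  all <- subsample_links(net, i, seed = 1)
  expect_equal(n_links(all), i)
  expect_setequal(paste(links_of_df(all)$plant_id, links_of_df(all)$animal_id),
                  paste(links_of_df(net)$plant_id, links_of_df(net)$animal_id))

  # k = 1 -> a single 1x1 network
  one <- subsample_links(net, 1, seed = 2)
  expect_equal(dim(one$incidence), c(1L, 1L))

  # star plant with 3 pollinators, k = 2: plant always kept, one pollinator
  # dropped (all three 2-subsets keep the hub)
  star <- make_net(matrix(1, 1, 3))
  for (s in 1:6) {
    sub <- subsample_links(star, 2, seed = s)
    expect_equal(length(sub$plants), 1L)
    expect_equal(length(sub$animals), 2L)
  }

  # deterministic given seed; links always a subset of the original
  s1 <- subsample_links(net, 5, seed = 77)
  s2 <- subsample_links(net, 5, seed = 77)
  expect_identical(s1$incidence, s2$incidence)
  lk <- links_of_df(s1)
  orig <- links_of_df(net)
  expect_true(all(paste(lk$plant_id, lk$animal_id) %in%
                    paste(orig$plant_id, orig$animal_id)))
})

test_that("mixed_network unions a fresh subsample with all nocturnal links", {
  set.seed(50)
  d <- rand_net(10, 12, fill = 0.4)
  # disjoint moth guild: total links exactly d
  nb <- matrix(0L, 3, 4, dimnames = list(sprintf("p%02d", 1:3),
                                         sprintf("moth%d", 1:4)))
  nb[1, 1:2] <- 1L; nb[2, 3] <- 1L; nb[3, 4] <- 1L
  n <- bipartite_network(nb, "nocturnal")
  mx <- mixed_network(d, n, seed = 3)
  expect_equal(n_links(mx), n_links(d))  # d-n diurnal + n disjoint nocturnal

  # nocturnal links fully shared with the diurnal ones: between d-n and d
  sp <- exchangeable_split(d, 6, seed = 9)
  d2 <- sp$diurnal
  shared_n <- subsample_links(d2, 6, seed = 1)
  shared_n$provenance <- "nocturnal"
  mx2 <- mixed_network(d2, shared_n, seed = 4)
  expect_gte(n_links(mx2), n_links(d2) - 6)
  expect_lte(n_links(mx2), n_links(d2))

  expect_error(mixed_network(n, d, seed = 1), "fewer")
})

test_that("exchangeable_split partitions the link set", {
  set.seed(51)
  net <- rand_net(9, 9)
  i <- n_links(net)
  sp <- exchangeable_split(net, 7, seed = 2)
  expect_equal(n_links(sp$diurnal), i - 7)
  expect_equal(n_links(sp$nocturnal), 7)
  dlk <- paste(links_of_df(sp$diurnal)$plant_id, links_of_df(sp$diurnal)$animal_id)
  nlk <- paste(links_of_df(sp$nocturnal)$plant_id, links_of_df(sp$nocturnal)$animal_id)
  expect_length(intersect(dlk, nlk), 0)
  expect_setequal(c(dlk, nlk),
                  paste(links_of_df(net)$plant_id, links_of_df(net)$animal_id))
})

test_that("trajectory builds the level schedule and summaries", {
  g <- generate_community(scenario_config(
    n_plants = 15L, n_diurnal_animals = 30L, diurnal_links = 100L,
    n_moths = 5L, nocturnal_links = 10L, seed = 6))
  d <- build_network(g, "diurnal")
  n <- build_network(g, "nocturnal")
  # d = 100, n = 10 -> levels 10, 20, ..., 90 then the full network
  tr <- trajectory(d, n, step = 0.10, n_reps = 8, seed = 4, r50_reps = 5,
                   n_starts = 2)
  expect_equal(tr$levels, c(seq(10, 90, 10), 100))
  s <- tr$summary
  expect_setequal(unique(s$metric),
                  c("connectance", "web_asymmetry", "connectivity_total",
                    "nodf_total", "Q", "R50_A", "R50_P"))
  expect_true(all(s$lo <= s$mean + 1e-12 & s$mean <= s$hi + 1e-12))
  # the final level is the full network as a point value
  expect_equal(s$lo[s$level_links == 100], s$hi[s$level_links == 100])
  expect_error(trajectory(n, d), "fewer")
  expect_warning(trajectory(d, n, n_reps = 1, r50_reps = 2, n_starts = 1),
                 "degenerate")
})

test_that("connectivity rises along the trajectory in expectation", {
  g <- generate_community(scenario_config(
    n_plants = 15L, n_diurnal_animals = 30L, diurnal_links = 120L,
    n_moths = 5L, nocturnal_links = 10L, seed = 12))
  d <- build_network(g, "diurnal")
  n <- build_network(g, "nocturnal")
  tr <- trajectory(d, n, step = 0.2, n_reps = 30, seed = 8, r50_reps = 5,
                   n_starts = 2)
  s <- tr$summary
  ct <- s[s$metric == "connectivity_total", ]
  ct <- ct[order(ct$level_links), ]
  # monotone non-decreasing within Monte-Carlo error
  expect_true(all(diff(ct$mean) > -0.05))
  # modularity drifts the other way (decreases with sampling depth)
  q <- s[s$metric == "Q", ]
  q <- q[order(q$level_links), ]
  expect_lt(q$mean[nrow(q)], q$mean[1])
})

test_that("break_test CI logic, significance and direction are coherent", {
  g <- generate_community(scenario_config(seed = 31, scenario = "syndrome"))
  d <- build_network(g, "diurnal")
  n <- build_network(g, "nocturnal")
  bt <- break_test(d, n, n_reps = 30, seed = 5, r50_reps = 5, n_starts = 2)
  s <- bt$summary
  expect_setequal(s$metric,
                  c("connectance", "web_asymmetry", "connectivity_total",
                    "nodf_total", "Q", "R50_A", "R50_P"))
  expect_true(all(s$lo <= s$hi))
  expect_identical(s$significant,
                   s$diurnal_full < s$lo | s$diurnal_full > s$hi)
  expect_identical(s$direction == "increase", s$mixed_mean > s$diurnal_full)

  # adding a disjoint moth guild dilutes connectance deterministically
  expect_equal(s$direction[s$metric == "connectance"], "decrease")
})
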