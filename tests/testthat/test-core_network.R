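test_that("read_interactions parses well-formed files and validates input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plant_id,animal_id,period,session_id,individual_id,pollen_grains",
               "p1,a1,diurnal,s1,,",
               "p2,a1,Diurnal,s1,,",
               "p1,m1,nocturnal,n1,i1,4"), path)
  rec <- read_interactions(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$period, c("diurnal", "diurnal", "nocturnal"))
  expect_equal(rec$plant_id, c("p1", "p2", "p1"))  # file order

  # unknown period value -> row-level error
  writeLines(c("plant_id,animal_id,period,session_id",
               "p1,a1,diurnal,s1",
               "p1,a1,Noon,s1"), path)
  expect_error(read_interactions(path), "Noon.*row 2|row 2")

  # missing required column named in the error
  writeLines(c("plant_id,animal_id,session_id", "p1,a1,s1"), path)
  expect_error(read_interactions(path), "period")

  # nocturnal row without pollen_grains
  writeLines(c("plant_id,animal_id,period,session_id,pollen_grains",
               "p1,m1,nocturnal,n1,"), path)
  expect_error(read_interactions(path), "pollen_grains")

  # header only -> empty with a warning
  writeLines("plant_id,animal_id,period,session_id", path)
  expect_warning(rec0 <- read_interactions(path), "no data rows")
  expect_equal(nrow(rec0), 0L)
})

test_that("the nocturnal pollen threshold is inclusive and per individual", {
  rec <- generate_threshold_fixture()
  # 2 grains alone do not score, 3 do (inclusive boundary)
  only2 <- rec[rec$period == "nocturnal" & rec$pollen_grains == 2L, ]
  expect_error(build_network(only2, "nocturnal"), "empty")
  only3 <- rec[rec$period == "nocturnal" & rec$pollen_grains == 3L, ]
  n3 <- build_network(only3, "nocturnal")
  expect_equal(n_links(n3), 1L)

  # full fixture: moth_1 x plant_A survives via the 4-grain individual even
  # though another individual carried only 2; moth_1 x plant_B (0 grains)
  # does not; moth_2 x plant_B survives via the 3-grain individual
  n <- build_network(rec, "nocturnal")
  expect_setequal(n$plants, c("plant_A", "plant_B"))
  expect_setequal(n$animals, c("moth_1", "moth_2"))
  expect_equal(n_links(n), 2L)
  expect_equal(unname(n$incidence["plant_A", "moth_1"]), 1L)
  expect_equal(unname(n$incidence["plant_B", "moth_1"]), 0L)

  # raising the threshold gives a subgraph (monotone filtering)
  n4 <- build_network(rec, "nocturnal", pollen_threshold = 4L)
  expect_true(all(n4$plants %in% n$plants))
  expect_true(all(n4$animals %in% n$animals))
  for (p in n4$plants) for (a in n4$animals)
    if (n4$incidence[p, a] == 1L) expect_equal(unname(n$incidence[p, a]), 1L)
})

test_that("diurnal assembly collapses duplicates to presence/absence", {
  rec <- data.frame(plant_id = c("pX", "pX", "pY"),
                    animal_id = c("a1", "a1", "a1"),
                    period = "diurnal", session_id = c("s1", "s2", "s1"))
  d <- build_network(rec, "diurnal")
  expect_equal(n_links(d), 2L)
  expect_true(all(d$incidence %in% c(0L, 1L)))
})

test_that("combine_networks takes label-keyed unions and flags guild conflicts", {
  d <- make_net(matrix(c(1, 1, 0, 1), 2, 2,
                       dimnames = list(c("pX", "pY"), c("a1", "a2"))))
  n <- make_net(matrix(c(1, 0, 1, 1), 2, 2,
                       dimnames = list(c("pY", "pZ"), c("m1", "m2"))))
  cb <- combine_networks(d, n)
  expect_setequal(cb$plants, c("pX", "pY", "pZ"))
  expect_setequal(cb$animals, c("a1", "a2", "m1", "m2"))
  expect_equal(n_links(cb), n_links(d) + n_links(n))  # disjoint links

  # commutative and idempotent on the link set
  cb2 <- combine_networks(n, d)
  expect_equal(cb$incidence[cb$plants, cb$animals],
               cb2$incidence[cb$plants, cb$animals])
  cb3 <- combine_networks(d, d)
  expect_equal(cb3$incidence[d$plants, d$animals], d$incidence)

  # shared links collapse: i_combined <= i_d + i_n
  shared <- combine_networks(d, make_net(matrix(1, 1, 1,
                   dimnames = list("pX", "a1")), "nocturnal"))
  expect_equal(n_links(shared), n_links(d))

  # guild conflict
  bad <- make_net(matrix(1, 1, 1, dimnames = list("a1", "m1")), "nocturnal")
  expect_error(combine_networks(d, bad), "guild conflict")
})

test_that("network CSV round trip preserves labels and incidence", {
  set.seed(42)
  net <- rand_net(6, 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path, "incidence")
  back <- read_network(path, "incidence", provenance = "synthetic")
  expect_identical(back$plants, net$plants)
  expect_identical(back$animals, net$animals)
  expect_identical(back$incidence, net$incidence)

  write_network(net, path, "edgelist")
  back2 <- read_network(path, "edgelist", provenance = "synthetic")
  expect_equal(back2$incidence[net$plants, net$animals], net$incidence)
})

test_that("bipartite_network enforces its invariants", {
  m <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("p1", "p2"), c("a1", "a2")))
  expect_error(bipartite_network(m, "synthetic"), "without links")
  m2 <- matrix(c(1, 2), 1, 2, dimnames = list("p1", c("a1", "a2")))
  expect_error(bipartite_network(m2, "synthetic"), "only 0 and 1")
})
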