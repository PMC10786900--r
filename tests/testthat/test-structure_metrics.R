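test_that("basic_metrics reproduces the arithmetic definitions", {
  # A = 120, P = 92, i = 1136 (a network of that shape, links arbitrary)
  set.seed(1)
  # construct an incidence with exact dimensions and link count
  B <- matrix(0L, 92, 120,
              dimnames = list(sprintf("p%03d", 1:92), sprintf("a%03d", 1:120)))
  B[cbind(1:92, rep_len(1:120, 92))] <- 1L          # cover all plants
  B[cbind(rep_len(1:92, 120), 1:120)] <- 1L         # cover all animals
  free <- which(B == 0L)
  B[sample(free, 1136 - sum(B))] <- 1L
  net <- bipartite_network(B, "synthetic")
  m <- basic_metrics(net)
  expect_equal(m$i, 1136)
  expect_equal(round(m$connectance, 3), 0.103)
  expect_equal(round(m$web_asymmetry, 3), 0.132)
  expect_equal(round(m$connectivity_A, 3), 9.467)
  expect_equal(round(m$connectivity_P, 3), 12.348)
  expect_equal(round(m$connectivity_total, 3), 5.358)
  expect_equal(m$matrix_size, 11040)

  # A = P -> zero asymmetry; complete matrix -> connectance 1
  sq <- make_net(matrix(1, 3, 3))
  expect_equal(basic_metrics(sq)$web_asymmetry, 0)
  full <- make_net(matrix(1, 3, 4))
  expect_equal(basic_metrics(full)$connectance, 1)
  expect_equal(basic_metrics(full)$i, 12)
})

test_that("percent_change uses the combined-value denominator", {
  expect_equal(round(percent_change(0.132, 0.177), 1), 25.4)
  expect_equal(round(percent_change(37.053, 32.929), 1), -12.5)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "undefined")
})

test_that("nodf matches hand-derived and degenerate cases", {
  stair <- make_net(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(nodf(stair, "rows"), 100)
  expect_equal(nodf(stair, "cols"), 100)
  expect_equal(nodf(stair, "total"), 100)

  # identical rows: every row pair has equal marginals -> 0
  flat <- make_net(matrix(1, 3, 2))
  expect_equal(nodf(flat, "rows"), 0)

  # 2x3 case, all four pairs enumerated by hand: row pair (2,2) ties -> 0;
  # column pairs score 100, 0, 100 -> cols 200/3, total 200/4
  m <- make_net(matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(nodf(m, "rows"), 0)
  expect_equal(nodf(m, "cols"), 200 / 3)
  expect_equal(nodf(m, "total"), 50)

  # single-species guild: axis contributes no pairs, scores 0 with warning
  one <- make_net(matrix(c(1, 1), 1, 2))
  expect_warning(v <- nodf(one, "rows"), "single-species")
  expect_equal(v, 0)
})

test_that("nodf agrees with the brute-force oracle and with vegan", {
  set.seed(7)
  for (r in 1:25) {
    B <- rand_matrix(sample(2:8, 1), sample(2:8, 1))
    net <- make_net(B)
    o <- nodf_oracle(B)
    expect_equal(nodf(net, "total"), o$total, tolerance = 1e-12)
    # vegan sorts first; the pairwise rule is order-free so results agree
    v <- vegan::nestednodf(B, order = TRUE)$statistic
    expect_equal(nodf(net, "total"), unname(v[["NODF"]]), tolerance = 1e-9)
    expect_equal(nodf(net, "rows"), unname(v[["N.rows"]]), tolerance = 1e-9)
    expect_equal(nodf(net, "cols"), unname(v[["N.columns"]]), tolerance = 1e-9)
  }
})

test_that("barber_Q evaluates the modularity formula", {
  # two complete 2x2 blocks as modules: Q = 0.5 by direct evaluation
  B <- matrix(0L, 4, 4, dimnames = list(paste0("p", 1:4), paste0("a", 1:4)))
  B[1:2, 1:2] <- 1L
  B[3:4, 3:4] <- 1L
  net <- bipartite_network(B, "synthetic")
  part <- module_partition(setNames(c(0L, 0L, 1L, 1L), net$plants),
                           setNames(c(0L, 0L, 1L, 1L), net$animals))
  expect_equal(barber_Q(net, part), 0.5)

  # one-module partition always scores 0
  one <- module_partition(setNames(rep(0L, 4), net$plants),
                          setNames(rep(0L, 4), net$animals))
  expect_equal(barber_Q(net, one), 0)

  # coverage error when a species is missing
  bad <- module_partition(setNames(c(0L, 0L, 1L, 1L), net$plants),
                          setNames(c(0L, 0L, 1L), net$animals[1:3]))
  expect_error(barber_Q(net, bad), "cover")

  # matches the independent formula oracle on random nets and partitions
  set.seed(3)
  for (r in 1:20) {
    P <- sample(2:5, 1); A <- sample(2:5, 1)
    B <- rand_matrix(P, A)
    net <- make_net(B)
    g <- sample(0:2, P + A, replace = TRUE)
    part <- module_partition(setNames(g[1:P], net$plants),
                             setNames(g[(P + 1):(P + A)], net$animals))
    # module_partition relabels contiguously; co-membership is preserved
    expect_equal(barber_Q(net, part), q_oracle(B, g), tolerance = 1e-12)
  }
})

test_that("find_modules recovers planted modules and exhaustive optima", {
  B <- matrix(0L, 4, 4, dimnames = list(paste0("p", 1:4), paste0("a", 1:4)))
  B[1:2, 1:2] <- 1L
  B[3:4, 3:4] <- 1L
  net <- bipartite_network(B, "synthetic")
  fm <- find_modules(net, seed = 1)
  expect_equal(fm$Q, 0.5)
  expect_equal(fm$n_modules, 2L)
  # planted co-membership recovered (module ids compared up to permutation)
  expect_equal(fm$plants[["p1"]], fm$plants[["p2"]])
  expect_equal(fm$plants[["p3"]], fm$plants[["p4"]])
  expect_false(fm$plants[["p1"]] == fm$plants[["p3"]])

  # 1x1 network: single module, Q = 0
  tiny <- make_net(matrix(1, 1, 1))
  fm1 <- find_modules(tiny, seed = 1)
  expect_equal(fm1$Q, 0)
  expect_equal(fm1$n_modules, 1L)

  # stability: two seeds agree on Q for a small network at high n_starts,
  # and never fall below the one-module baseline of 0
  set.seed(9)
  for (r in 1:5) {
    net <- rand_net(4, 4)
    q1 <- find_modules(net, seed = 11, n_starts = 30)$Q
    q2 <- find_modules(net, seed = 99, n_starts = 30)$Q
    expect_equal(q1, q2, tolerance = 1e-12)
    expect_gte(q1, 0)
    expect_equal(q1, max_q_exhaustive(net$incidence), tolerance = 1e-9)
  }
})

test_that("connectance increases with links at fixed dimensions", {
  set.seed(21)
  B <- rand_matrix(5, 6)
  B[which(B == 0L)[1]] <- 1L
  net0 <- make_net(B)
  B2 <- B
  B2[which(B2 == 0L)[1]] <- 1L
  net1 <- make_net(B2)
  m0 <- basic_metrics(net0)
  m1 <- basic_metrics(net1)
  expect_equal(m1$A, m0$A)
  expect_equal(m1$P, m0$P)
  expect_gt(m1$connectance, m0$connectance)
})

test_that("network_metrics returns the full fifteen-descriptor row", {
  set.seed(5)
  net <- rand_net(8, 10)
  m <- network_metrics(net, seed = 2, robustness_reps = 20)
  expect_setequal(names(m),
    c("A", "P", "matrix_size", "i", "web_asymmetry", "connectivity_A",
      "connectivity_P", "connectivity_total", "connectance", "nodf_total",
      "nodf_A", "nodf_P", "Q", "n_modules", "R50_A", "R50_P"))
  expect_true(m$Q >= 0 && m$Q <= 1)
  expect_true(m$R50_A > 0 && m$R50_A <= 1)
})
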