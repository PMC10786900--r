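#' Curveball randomization (fixed-fixed null model)
#'
#' Produces a random binary matrix with exactly the observed row and column
#' sums (same number of plants, animals and interactions) by repeated
#' pair-trade steps: two random plants exchange a random subset of their
#' non-shared partners. The curveball procedure samples (asymptotically
#' uniformly) from the set of marginal-preserving matrices.
#'
#' @param net a `bipartite_network`.
#' @param n_trades number of trade attempts; defaults to `5 * (A + P)`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `bipartite_network` with identical marginals and provenance
#'   `"resampled"`.
#' @export
curveball_shuffle <- function(net, n_trades = NULL, seed = 1L) {
  stopifnot(inherits(net, "bipartite_network"))
  if (is.null(n_trades))
    n_trades <- 5L * (length(net$plants) + length(net$animals))
  out <- curveball_cpp(net$incidence, as.integer(n_trades), as.integer(seed))
  bipartite_network(out, "resampled")
}

#' Z-test of a structural metric against a fixed-fixed null distribution
#'
#' Compares the observed NODF or modularity to its distribution over
#' independent curveball randomizations (each replicate an independent chain
#' from the observed matrix, seeded from a replicate-indexed substream). The
#' defaults follow common practice for these metrics: 500 replicates for
#' NODF, 100 for Q (each Q replicate re-runs the modularity search).
#'
#' @param net a `bipartite_network`.
#' @param metric one of `"nodf_total"`, `"nodf_A"`, `"nodf_P"`, `"Q"`.
#' @param n_reps null replicates (>= 2); default 500 (NODF) or 100 (Q).
#' @param seed master seed.
#' @param n_starts modularity-search restarts per replicate (metric `"Q"`).
#' @return an object of class `null_test_result`: `metric`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p` (two-sided normal), `n_null`.
#' @export
null_test <- function(net, metric = c("nodf_total", "nodf_A", "nodf_P", "Q"),
                      n_reps = NULL, seed = 1L, n_starts = 20L) {
  metric <- match.arg(metric)
  if (is.null(n_reps)) n_reps <- if (metric == "Q") 100L else 500L
  stopifnot(n_reps >= 2L)
  eval_metric <- function(x, s) {
    switch(metric,
           nodf_total = unname(nodf_cpp(x$incidence)[["total"]]),
           nodf_A = unname(nodf_cpp(x$incidence)[["cols"]]),
           nodf_P = unname(nodf_cpp(x$incidence)[["rows"]]),
           Q = find_modules(x, seed = s, n_starts = n_starts)$Q)
  }
  observed <- eval_metric(net, substream_seed(seed, "null_observed"))
  nulls <- vapply(seq_len(n_reps), function(r) {
    shuf <- curveball_shuffle(net, seed = substream_seed(seed, "null_shuffle", r))
    eval_metric(shuf, substream_seed(seed, "null_metric", r))
  }, numeric(1))
  null_mean <- mean(nulls)
  null_sd <- sd(nulls)
  if (null_sd == 0) {
    warning("degenerate null distribution (sd = 0)")
    z <- if (observed == null_mean) 0 else sign(observed - null_mean) * Inf
    p <- if (observed == null_mean) 1 else 0
  } else {
    z <- (observed - null_mean) / null_sd
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(metric = metric, observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p = p, n_null = n_reps),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("null test (%s): observed %.4f, null %.4f +/- %.4f, z = %.3f, P = %.4g (n = %d)\n",
              x$metric, x$observed, x$null_mean, x$null_sd, x$z, x$p, x$n_null))
  invisible(x)
}

#' Degree-rank test for preferential attachment of nocturnal moths
#'
#' Tests whether plants visited by nocturnal moths hold better diurnal degree
#' ranks than plants without nocturnal visits. Plants of the combined species
#' pool are ranked by diurnal degree in descending order (rank 1 = most
#' linked; plants absent from the diurnal network have degree 0); ties
#' receive the average rank. A pooled-variance two-sample Student t-test
#' compares the ranks of the two groups (two-sided).
#'
#' @param d a `bipartite_network` (the diurnal network).
#' @param nocturnally_visited character vector of plant labels with at least
#'   one scored nocturnal interaction.
#' @return an object of class `rank_test_result`: `t`, `df`, `p`,
#'   `group_sizes` (visited, not visited), and the rank vectors.
#' @export
attachment_test <- function(d, nocturnally_visited) {
  stopifnot(inherits(d, "bipartite_network"),
            is.character(nocturnally_visited))
  pool <- union(d$plants, nocturnally_visited)
  deg <- setNames(rep(0, length(pool)), pool)
  deg[d$plants] <- rowSums(d$incidence)
  rk <- rank(-deg, ties.method = "average")
  in_group <- names(deg) %in% nocturnally_visited
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need at least 2 plants (sizes ", n1, ", ", n2, ")")
  x <- rk[in_group]
  y <- rk[!in_group]
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {  # every rank tied: no evidence either way
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * pt(-abs(tstat), df)
  structure(list(t = tstat, df = df, p = p, group_sizes = c(n1, n2),
                 ranks_visited = x, ranks_unvisited = y),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("degree-rank t-test: t%d = %.3f, P = %.4g (groups %d vs %d)\n",
              x$df, x$t, x$p, x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}
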