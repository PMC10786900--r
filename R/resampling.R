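#' Uniform random link subsample
#'
#' Retains a uniformly random `k`-subset of the network's links and rebuilds
#' the matrix from the retained link set; species left with zero links are
#' dropped (so A and P shrink). Deterministic given `seed`.
#'
#' @param net a `bipartite_network`.
#' @param k number of links to keep (`1 <= k <= i`).
#' @param seed integer seed.
#' @return a `bipartite_network` with provenance `"resampled"`.
#' @export
subsample_links <- function(net, k, seed = 1L) {
  stopifnot(inherits(net, "bipartite_network"))
  i <- n_links(net)
  if (k < 1L || k > i) stop("k must be in [1, ", i, "], got ", k)
  lk <- links_of(net)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sample.int(i, k)
  out <- net_from_links(lk$plant_id[keep], lk$animal_id[keep], "resampled")
  out
}

# Save/restore R's global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mixed diurnal + nocturnal resampled network
#'
#' The comparison network of the resampling experiment: a fresh uniform
#' `(d - n)`-link subsample of the diurnal network unioned with all `n`
#' nocturnal links (shared links collapse, so the total is at most `d`).
#'
#' @param d_net diurnal `bipartite_network` with `d` links.
#' @param n_net nocturnal `bipartite_network` with `n < d` links.
#' @param seed integer seed for the diurnal subsample.
#' @return a `bipartite_network` with provenance `"resampled"`.
#' @export
mixed_network <- function(d_net, n_net, seed = 1L) {
  d <- n_links(d_net)
  n <- n_links(n_net)
  if (n >= d) stop("nocturnal links (", n, ") must be fewer than diurnal (",
                   d, ")")
  sub <- subsample_links(d_net, d - n, seed = seed)
  lk <- unique(rbind(links_of(sub), links_of(n_net)))
  net_from_links(lk$plant_id, lk$animal_id, "resampled")
}

#' Split a network into an exchangeable diurnal/nocturnal pair
#'
#' Relabels a uniformly random `n`-subset of the links as "nocturnal" and
#' removes them from the diurnal link set (as if those interactions had been
#' observed at night instead). Under this construction the nocturnal links
#' are statistically indistinguishable from the diurnal ones, which provides
#' the exchangeability null for [break_test()].
#'
#' @param net a `bipartite_network`.
#' @param n number of links to relabel.
#' @param seed integer seed.
#' @return list with elements `diurnal` and `nocturnal`
#'   (`bipartite_network`s).
#' @export
exchangeable_split <- function(net, n, seed = 1L) {
  i <- n_links(net)
  stopifnot(n >= 1L, n < i)
  lk <- links_of(net)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- sample.int(i, n)
  list(
    diurnal = net_from_links(lk$plant_id[-pick], lk$animal_id[-pick],
                             "diurnal"),
    nocturnal = net_from_links(lk$plant_id[pick], lk$animal_id[pick],
                               "nocturnal")
  )
}

# The seven monitored metrics of the resampling experiment, evaluated on one
# (sub)network. Q uses a reduced restart count and R50 a reduced replicate
# count inside replicated resampling loops (configurable) to keep runtime
# desk-scale.
monitored_metrics <- function(net, seed, n_starts = 5L, r50_reps = 25L) {
  bm <- basic_metrics(net)
  part <- find_modules(net, seed = substream_seed(seed, "traj_modules"),
                       n_starts = n_starts)
  rp <- robustness_pair(net, n_reps = r50_reps,
                        seed = substream_seed(seed, "traj_r50"))
  c(connectance = bm$connectance,
    web_asymmetry = bm$web_asymmetry,
    connectivity_total = bm$connectivity_total,
    nodf_total = unname(nodf_cpp(net$incidence)[["total"]]),
    Q = part$Q,
    R50_A = unname(rp[["R50_A"]]),
    R50_P = unname(rp[["R50_P"]]))
}

metric_ci <- function(x, method = c("percentile", "normal")) {
  method <- match.arg(method)
  if (length(x) < 2L) return(c(lo = unname(x[1L]), hi = unname(x[1L])))
  if (method == "percentile") {
    q <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    c(lo = q[1L], hi = q[2L])
  } else {
    se <- sd(x) / sqrt(length(x))
    c(lo = mean(x) - 1.96 * se, hi = mean(x) + 1.96 * se)
  }
}

#' Undersampling trajectory of the diurnal network
#'
#' Randomly subsamples the diurnal network at link fractions `step, 2*step,
#' ...` (floored to integer link counts) capped at `d - n`, then appends the
#' full diurnal network as a point value. Each level is replicated and the
#' seven monitored metrics (connectance, web asymmetry, total connectivity,
#' NODF, Q, R50 A, R50 P) are summarized by mean and 95% CI.
#'
#' @param d_net diurnal `bipartite_network` (`d` links).
#' @param n_net nocturnal `bipartite_network` (`n < d` links).
#' @param step level spacing as a fraction of `d` (default 0.10).
#' @param n_reps replicates per level (default 100).
#' @param seed master seed.
#' @param ci `"percentile"` (default) or `"normal"`.
#' @param n_starts,r50_reps per-replicate search effort, see
#'   [find_modules()] and [robustness_pair()].
#' @return object of class `subsample_trajectory`: a tidy data.frame
#'   (`level_links`, `level_frac`, `metric`, `mean`, `lo`, `hi`, `n_reps`)
#'   in `$summary`, plus `d`, `n`, `levels`.
#' @export
trajectory <- function(d_net, n_net, step = 0.10, n_reps = 100L, seed = 1L,
                       ci = c("percentile", "normal"), n_starts = 5L,
                       r50_reps = 25L) {
  ci <- match.arg(ci)
  stopifnot(step > 0, step < 1)
  d <- n_links(d_net)
  n <- n_links(n_net)
  if (n >= d) stop("nocturnal links must be fewer than diurnal links")
  if (n_reps == 1L) warning("n_reps = 1: confidence intervals are degenerate")
  ks <- floor(seq(step, 1, by = step) * d)
  ks <- unique(c(ks[ks < (d - n) & ks >= 1L], d - n))
  rows <- list()
  for (li in seq_along(ks)) {
    k <- ks[li]
    vals <- vapply(seq_len(n_reps), function(r) {
      s <- substream_seed(seed, sprintf("traj_L%d", li), r)
      sub <- subsample_links(d_net, k, seed = s)
      monitored_metrics(sub, seed = s, n_starts = n_starts,
                        r50_reps = r50_reps)
    }, numeric(7))
    for (mname in rownames(vals)) {
      cii <- metric_ci(vals[mname, ], ci)
      rows[[length(rows) + 1L]] <-
        data.frame(level_links = k, level_frac = k / d, metric = mname,
                   mean = mean(vals[mname, ]), lo = cii[["lo"]],
                   hi = cii[["hi"]], n_reps = n_reps)
    }
  }
  # full diurnal network: a point value (full search effort)
  full <- monitored_metrics(d_net, seed = substream_seed(seed, "traj_full"),
                            n_starts = max(n_starts, 20L), r50_reps = 100L)
  for (mname in names(full)) {
    rows[[length(rows) + 1L]] <-
      data.frame(level_links = d, level_frac = 1, metric = mname,
                 mean = unname(full[mname]), lo = unname(full[mname]),
                 hi = unname(full[mname]), n_reps = 1L)
  }
  structure(list(summary = do.call(rbind, rows), d = d, n = n,
                 levels = c(ks, d)),
            class = "subsample_trajectory")
}

#' @export
print.subsample_trajectory <- function(x, ...) {
  cat(sprintf("<subsample_trajectory> d = %d, n = %d, endpoint d-n at %.0f%% of d, %d levels\n",
              x$d, x$n, 100 * (x$d - x$n) / x$d, length(x$levels)))
  invisible(x)
}

#' Break test: nocturnal substitution vs. continued diurnal sampling
#'
#' For each monitored metric, builds the 95% CI over `n_reps` mixed networks
#' (`d - n` diurnal links plus the `n` nocturnal links, see
#' [mixed_network()]) and compares it with the point value of the complete
#' diurnal network. A departure is significant when the full-diurnal value
#' falls outside the CI; direction is the sign of
#' `mixed_mean - diurnal_full_value`.
#'
#' @inheritParams trajectory
#' @param n_reps mixed-network replicates (default 100).
#' @return object of class `break_result`: data.frame in `$summary` with
#'   columns `metric`, `mixed_mean`, `lo`, `hi`, `diurnal_full`,
#'   `significant`, `direction`; plus `d`, `n`, `n_reps`.
#' @export
break_test <- function(d_net, n_net, n_reps = 100L, seed = 1L,
                       ci = c("percentile", "normal"), n_starts = 5L,
                       r50_reps = 25L) {
  ci <- match.arg(ci)
  d <- n_links(d_net)
  n <- n_links(n_net)
  if (n >= d) stop("nocturnal links must be fewer than diurnal links")
  vals <- vapply(seq_len(n_reps), function(r) {
    s <- substream_seed(seed, "break_mixed", r)
    mx <- mixed_network(d_net, n_net, seed = s)
    monitored_metrics(mx, seed = s, n_starts = n_starts, r50_reps = r50_reps)
  }, numeric(7))
  full <- monitored_metrics(d_net, seed = substream_seed(seed, "break_full"),
                            n_starts = max(n_starts, 20L), r50_reps = 100L)
  rows <- lapply(rownames(vals), function(mname) {
    x <- vals[mname, ]
    cii <- metric_ci(x, ci)
    ref <- unname(full[mname])
    dlt <- mean(x) - ref
    data.frame(metric = mname, mixed_mean = mean(x), lo = cii[["lo"]],
               hi = cii[["hi"]], diurnal_full = ref,
               significant = ref < cii[["lo"]] | ref > cii[["hi"]],
               direction = if (dlt > 0) "increase"
                           else if (dlt < 0) "decrease" else "none")
  })
  structure(list(summary = do.call(rbind, rows), d = d, n = n,
                 n_reps = n_reps),
            class = "break_result")
}

#' @export
print.break_result <- function(x, ...) {
  cat(sprintf("<break_result> d = %d, n = %d, %d mixed replicates\n",
              x$d, x$n, x$n_reps))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
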