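#' Simulate random primary-extinction curves
#'
#' Removes the species of one guild one at a time in uniformly random order;
#' after each removal, partner-guild species left with zero links are counted
#' as secondarily extinct. Removals cause no cascades back into their own
#' guild (one-way bipartite secondary extinction).
#'
#' @param net a `bipartite_network`.
#' @param target_guild `"plants"` or `"animals"`: the guild suffering primary
#'   extinctions.
#' @param seed integer seed.
#' @param n_reps number of random removal orders (1 = single run).
#' @return an object of class `extinction_curve`: `target_guild`, `removals`
#'   (0..G), `secondary` (mean cumulative secondary extinctions, with a
#'   leading 0), `secondary_sd`, `n_reps`, `partner_guild_size`.
#' @export
simulate_extinction <- function(net, target_guild = c("plants", "animals"),
                                seed = 1L, n_reps = 1L) {
  target_guild <- match.arg(target_guild)
  stopifnot(inherits(net, "bipartite_network"), n_reps >= 1L)
  B <- if (target_guild == "plants") net$incidence else t(net$incidence)
  runs <- extinction_runs_cpp(B, as.integer(n_reps), as.integer(seed))
  G <- nrow(B)
  structure(list(
    target_guild = target_guild,
    removals = 0:G,
    secondary = c(0, colMeans(runs)),
    secondary_sd = c(0, apply(runs, 2, sd)),
    n_reps = n_reps,
    partner_guild_size = ncol(B)
  ), class = "extinction_curve")
}

#' @export
print.extinction_curve <- function(x, ...) {
  cat(sprintf("<extinction_curve> removing %s (G = %d), %d partner species, %d rep(s)\n",
              x$target_guild, length(x$removals) - 1L, x$partner_guild_size,
              x$n_reps))
  invisible(x)
}

#' R50 robustness from an averaged extinction curve
#'
#' The minimum fraction of random primary extinctions causing at least 50%
#' secondary extinction in the partner guild: the smallest `k/G` such that
#' the mean number of secondary extinctions after `k` removals is
#' `>= 0.5 * initial partner-guild size` (exact step comparison, no
#' interpolation). Always reached at `k = G`, so the value lies in `(0, 1]`.
#'
#' @param curve an `extinction_curve` (averaged over its replicates).
#' @return a fraction in `(0, 1]`.
#' @export
r50 <- function(curve) {
  stopifnot(inherits(curve, "extinction_curve"))
  G <- length(curve$removals) - 1L
  thr <- 0.5 * curve$partner_guild_size
  k <- which(curve$secondary[-1L] >= thr)[1L]
  if (is.na(k)) return(1.0)
  k / G
}

#' R50 for both extinction directions
#'
#' Wraps replicate-averaged extinction curves in both directions. `R50_A`
#' removes animals (pollinators) and counts secondary plant extinctions;
#' `R50_P` removes plants and counts secondary pollinator extinctions. By
#' default R50 is computed on the replicate-averaged curve; set
#' `per_replicate = TRUE` to average per-replicate R50 values instead
#' (sensitivity variant).
#'
#' @param net a `bipartite_network`.
#' @param n_reps extinction replicates per direction (default 100).
#' @param seed master seed (each direction draws a substream).
#' @param per_replicate compute R50 per replicate and average.
#' @return named numeric vector `c(R50_A = ..., R50_P = ...)`.
#' @export
robustness_pair <- function(net, n_reps = 100L, seed = 1L,
                            per_replicate = FALSE) {
  stopifnot(inherits(net, "bipartite_network"))
  one <- function(guild, name) {
    s <- substream_seed(seed, name)
    if (!per_replicate) {
      r50(simulate_extinction(net, guild, seed = s, n_reps = n_reps))
    } else {
      mean(vapply(seq_len(n_reps), function(r) {
        r50(simulate_extinction(net, guild,
                                seed = substream_seed(seed, name, r),
                                n_reps = 1L))
      }, numeric(1)))
    }
  }
  c(R50_A = one("animals", "r50_animals"),
    R50_P = one("plants", "r50_plants"))
}

#' Export an extinction curve as a data.frame
#'
#' @param curve an `extinction_curve`.
#' @return data.frame with columns `removals`, `secondary_mean`,
#'   `secondary_sd`.
#' @export
extinction_curve_df <- function(curve) {
  data.frame(removals = curve$removals,
             secondary_mean = curve$secondary,
             secondary_sd = curve$secondary_sd)
}
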