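#' Size and connectivity descriptors
#'
#' The arithmetic layer of the structural-property table: counts, matrix
#' size, web asymmetry, per-guild and total connectivity, and connectance.
#'
#' @param net a `bipartite_network`.
#' @return a one-row data.frame with columns `A` (animals), `P` (plants),
#'   `matrix_size` (`A*P`), `i` (links), `web_asymmetry` (`(A-P)/(A+P)`),
#'   `connectivity_A` (`i/A`), `connectivity_P` (`i/P`),
#'   `connectivity_total` (`i/(A+P)`) and `connectance` (`i/(A*P)`).
#' @export
#' @examples
#' net <- bipartite_network(
#'   matrix(c(1, 1, 0, 1), 2, 2, dimnames = list(c("p1", "p2"), c("a1", "a2"))),
#'   "synthetic")
#' basic_metrics(net)
basic_metrics <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  A <- length(net$animals)
  P <- length(net$plants)
  i <- n_links(net)
  data.frame(
    A = A, P = P, matrix_size = A * P, i = i,
    web_asymmetry = (A - P) / (A + P),
    connectivity_A = i / A,
    connectivity_P = i / P,
    connectivity_total = i / (A + P),
    connectance = i / (A * P)
  )
}

#' Percentage change when nocturnal pollinators are added
#'
#' Expresses the change from the diurnal value `d` to the combined value `c`
#' relative to the *combined* value: `100 * (c - d) / c`. This is the
#' convention used by the observed-change column of the structural-property
#' table (verified against its printed values).
#'
#' @param d_value metric value in the diurnal network.
#' @param c_value metric value in the combined network (must be non-zero).
#' @return the percentage change.
#' @export
percent_change <- function(d_value, c_value) {
  if (any(c_value == 0))
    stop("percent change undefined when the combined value is 0")
  100 * (c_value - d_value) / c_value
}

#' NODF nestedness
#'
#' Nestedness metric based on Overlap and Decreasing Fill. For each unordered
#' species pair within a guild the paired score is 0 if their marginal totals
#' are equal or the poorer total is 0, and otherwise
#' `100 * shared partners / poorer marginal total`. The guild score is the
#' mean over all pairs of that guild; the total score divides the summed
#' paired scores by `P(P-1)/2 + A(A-1)/2`. No pre-sorting is needed: the
#' pairwise rule is order-free. A guild with a single species contributes no
#' pairs and scores 0 with a warning.
#'
#' @param net a `bipartite_network`.
#' @param axis `"total"`, `"rows"` (plants) or `"cols"` (animals).
#' @return a score in `[0, 100]`.
#' @export
#' @examples
#' stair <- bipartite_network(
#'   matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE,
#'          dimnames = list(paste0("p", 1:3), paste0("a", 1:3))),
#'   "synthetic")
#' nodf(stair)  # 100: perfectly nested staircase
nodf <- function(net, axis = c("total", "rows", "cols")) {
  axis <- match.arg(axis)
  stopifnot(inherits(net, "bipartite_network"))
  v <- nodf_cpp(net$incidence)
  if (axis == "rows" && length(net$plants) < 2L)
    warning("single-species plant guild: NODF rows defined as 0")
  if (axis == "cols" && length(net$animals) < 2L)
    warning("single-species animal guild: NODF cols defined as 0")
  unname(v[[axis]])
}

#' Module partition of a bipartite network
#'
#' @param plants named integer vector: module id per plant.
#' @param animals named integer vector: module id per animal.
#' @param Q Barber modularity of the partition (optional until evaluated).
#' @return an object of class `module_partition`. Module ids are relabelled
#'   to be contiguous from 0.
#' @export
module_partition <- function(plants, animals, Q = NA_real_) {
  stopifnot(!is.null(names(plants)), !is.null(names(animals)))
  ids <- sort(unique(c(plants, animals)))
  plants[] <- match(plants, ids) - 1L
  animals[] <- match(animals, ids) - 1L
  structure(list(plants = plants, animals = animals, Q = Q,
                 n_modules = length(ids)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.4f\n", x$n_modules, x$Q))
  invisible(x)
}

#' Barber bipartite modularity of a given partition
#'
#' `Q = (1/i) * sum over plant p, animal a in the same module of
#' (B[p,a] - k_p * k_a / i)`, where `k` are species degrees and `i` the link
#' count. The one-module partition has `Q = 0`.
#'
#' @param net a `bipartite_network`.
#' @param partition a `module_partition` covering exactly the network's
#'   species.
#' @return the modularity `Q` (at most 1).
#' @export
barber_Q <- function(net, partition) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(partition, "module_partition"))
  if (!setequal(names(partition$plants), net$plants) ||
      !setequal(names(partition$animals), net$animals))
    stop("partition does not cover exactly the network's species")
  barber_q_cpp(net$incidence,
               as.integer(partition$plants[net$plants]),
               as.integer(partition$animals[net$animals]))
}

#' Find modules by multi-start label propagation
#'
#' Maximizes Barber modularity with asynchronous label propagation in random
#' node order, a greedy module-merge pass after convergence, multiple
#' restarts, and perturbation restarts around the incumbent (the search
#' strategy of the DIRTLPAwb+ family). Deterministic given `seed`. The
#' returned Q is never below the one-module baseline of 0.
#'
#' @param net a `bipartite_network`.
#' @param seed integer seed for the optimizer's RNG.
#' @param n_starts number of independent restarts (default 20).
#' @return a `module_partition` with its `Q` and `n_modules`.
#' @export
find_modules <- function(net, seed = 1L, n_starts = 20L) {
  stopifnot(inherits(net, "bipartite_network"), n_starts >= 1L)
  res <- lpa_modules_cpp(net$incidence, as.integer(n_starts),
                         as.integer(seed))
  p <- res$row_modules
  names(p) <- net$plants
  a <- res$col_modules
  names(a) <- net$animals
  out <- module_partition(p, a, Q = res$Q)
  out
}

#' All fifteen structural properties of a network
#'
#' Computes the full descriptor set of the property table: the size /
#' connectivity layer of [basic_metrics()], NODF (total, animals, plants),
#' Barber modularity with its module count, and both R50 robustness values.
#'
#' @param net a `bipartite_network`.
#' @param seed master seed (modularity search and extinction replicates draw
#'   substreams from it).
#' @param n_starts restarts for [find_modules()].
#' @param robustness_reps extinction replicates for [robustness_pair()].
#' @return a one-row data.frame.
#' @export
network_metrics <- function(net, seed = 1L, n_starts = 20L,
                            robustness_reps = 100L) {
  bm <- basic_metrics(net)
  nv <- nodf_cpp(net$incidence)
  part <- find_modules(net, seed = substream_seed(seed, "modules"),
                       n_starts = n_starts)
  rp <- robustness_pair(net, n_reps = robustness_reps,
                        seed = substream_seed(seed, "robustness"))
  cbind(bm,
        data.frame(nodf_total = unname(nv[["total"]]),
                   nodf_A = unname(nv[["cols"]]),
                   nodf_P = unname(nv[["rows"]]),
                   Q = part$Q, n_modules = part$n_modules,
                   R50_A = rp[["R50_A"]], R50_P = rp[["R50_P"]]))
}
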