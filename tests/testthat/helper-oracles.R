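# Independent oracles used to check the package's kernels. These share no
# code with the implementation paths they verify.

# All-pairs NODF by direct application of the overlap / decreasing-fill rule.
nodf_oracle <- function(B) {
  pair_sum <- function(M) {
    n <- nrow(M)
    s <- 0
    np <- 0
    if (n >= 2) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          np <- np + 1
          fi <- sum(M[i, ])
          fj <- sum(M[j, ])
          if (fi == fj || min(fi, fj) == 0) next
          s <- s + 100 * sum(M[i, ] & M[j, ]) / min(fi, fj)
        }
      }
    }
    list(s = s, np = np)
  }
  r <- pair_sum(B)
  cc <- pair_sum(t(B))
  list(rows = if (r$np > 0) r$s / r$np else 0,
       cols = if (cc$np > 0) cc$s / cc$np else 0,
       total = if (r$np + cc$np > 0) (r$s + cc$s) / (r$np + cc$np) else 0)
}

# Barber modularity straight from the definition, membership vector over
# plants then animals.
q_oracle <- function(B, g) {
  P <- nrow(B)
  A <- ncol(B)
  E <- sum(B)
  M <- B - outer(rowSums(B), colSums(B)) / E
  sum(M[outer(g[1:P], g[(P + 1):(P + A)], "==")]) / E
}

# All set partitions of n elements as restricted-growth strings.
rgs_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in 0:(maxlab + 1)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), -1L)
  out
}

# Exhaustive maximum Barber Q over every partition of the species set.
max_q_exhaustive <- function(B) {
  parts <- rgs_partitions(nrow(B) + ncol(B))
  max(vapply(parts, function(g) q_oracle(B, g), numeric(1)))
}

# All permutations of a vector (for exhaustive extinction-order enumeration).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Exact per-step secondary-extinction counts over all removal orders of the
# rows of B. Returns a steps x orders matrix of cumulative counts.
extinction_enumeration <- function(B) {
  G <- nrow(B)
  orders <- all_perms(seq_len(G))
  vapply(orders, function(ord) {
    deg <- colSums(B)
    cums <- numeric(G)
    dead <- 0
    for (s in seq_len(G)) {
      deg <- deg - B[ord[s], ]
      cums[s] <- sum(deg == 0)
    }
    cums
  }, numeric(G))
}

# R50 rule applied to an exact mean curve (independent of the package path).
r50_oracle <- function(mean_curve, partner_guild_size) {
  G <- length(mean_curve)
  k <- which(mean_curve >= 0.5 * partner_guild_size)[1L]
  if (is.na(k)) 1.0 else k / G
}

# Random 0/1 matrix with no empty rows or columns.
rand_matrix <- function(P, A, fill = 0.45) {
  repeat {
    B <- matrix(rbinom(P * A, 1, fill), P, A)
    if (all(rowSums(B) > 0) && all(colSums(B) > 0)) return(B)
  }
}

rand_net <- function(P, A, fill = 0.45, provenance = "synthetic") {
  B <- rand_matrix(P, A, fill)
  dimnames(B) <- list(sprintf("p%02d", seq_len(P)), sprintf("a%02d", seq_len(A)))
  bipartite_network(B, provenance)
}

make_net <- function(B, provenance = "synthetic") {
  if (is.null(rownames(B)))
    dimnames(B) <- list(sprintf("p%d", seq_len(nrow(B))),
                        sprintf("a%d", seq_len(ncol(B))))
  bipartite_network(B, provenance)
}

# Link list of a network derived directly from the incidence matrix
# (independent of the package's internal extractor).
links_of_df <- function(net) {
  idx <- which(net$incidence == 1L, arr.ind = TRUE)
  data.frame(plant_id = net$plants[idx[, 1L]],
             animal_id = net$animals[idx[, 2L]],
             stringsAsFactors = FALSE)
}
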