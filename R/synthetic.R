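#' Scenario configuration for the synthetic-community generator
#'
#' Encodes the statistical world the analysis assumes: a degree-heterogeneous
#' diurnal network, a small nocturnal moth component, per-individual pollen
#' grain counts straddling the scoring threshold, and session-structured
#' sampling. Default sizes mirror the study system: nocturnal networks of
#' roughly 15 moth species and 25 links next to a diurnal network of about
#' 100 animals by 40 plants (desk-scale for replicated resampling runs), 3
#' nocturnal trapping sessions, and overdispersed (negative-binomial) grain
#' counts, since most trapped moths carry few grains.
#'
#' @param n_plants plant pool size.
#' @param n_diurnal_animals diurnal animal pool size.
#' @param n_moths nocturnal moth species count (disjoint from the diurnal
#'   pool: the moth taxa are exclusively night-active).
#' @param diurnal_links,nocturnal_links target qualitative link counts.
#' @param scenario `"random"` (moth links uniform over plants),
#'   `"preferential"` (probability proportional to current diurnal degree) or
#'   `"syndrome"` (probability `assortativity` onto designated
#'   moth-syndrome plants).
#' @param syndrome_plants number of designated phalaenophilous plants
#'   (syndrome scenario); chosen as the plants least attractive to diurnal
#'   visitors.
#' @param assortativity probability a syndrome-scenario moth link lands on a
#'   syndrome plant.
#' @param syndrome_day_discount multiplier on the diurnal attractiveness of
#'   syndrome plants (nocturnal anthesis: such flowers receive few diurnal
#'   visits, though each keeps at least one).
#' @param n_sessions_diurnal,n_sessions_nocturnal session counts for the
#'   incidence structure.
#' @param pollen_mean,pollen_dispersion negative-binomial mean and size for
#'   per-individual grain counts.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_plants = 40L, n_diurnal_animals = 100L,
                            n_moths = 15L, diurnal_links = 300L,
                            nocturnal_links = 25L,
                            scenario = c("random", "preferential",
                                         "syndrome"),
                            syndrome_plants = 8L, assortativity = 0.95,
                            syndrome_day_discount = 0.05,
                            n_sessions_diurnal = 20L,
                            n_sessions_nocturnal = 3L,
                            pollen_mean = 8, pollen_dispersion = 0.8,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(assortativity >= 0, assortativity <= 1,
            diurnal_links <= n_plants * n_diurnal_animals,
            nocturnal_links <= n_plants * n_moths,
            diurnal_links >= max(n_plants, n_diurnal_animals),
            nocturnal_links >= n_moths,
            syndrome_plants >= 1L, syndrome_plants <= n_plants)
  structure(as.list(environment()), class = "scenario_config")
}

# Breadth-first check that the bipartite graph over the realized species is
# connected.
is_connected_net <- function(plants, animals) {
  pl <- unique(plants)
  an <- unique(animals)
  nodes <- c(paste0("P:", pl), paste0("A:", an))
  adj <- split(paste0("A:", animals), paste0("P:", plants))
  adj2 <- split(paste0("P:", plants), paste0("A:", animals))
  adj <- c(adj, adj2)
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  queue <- nodes[1L]
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# Draw `k` distinct (plant, animal) pairs with the given marginal weights,
# resampling collisions so the qualitative link count equals the target.
draw_distinct_pairs <- function(k, p_weights, a_weights, max_tries = 200L) {
  np <- length(p_weights)
  na <- length(a_weights)
  stopifnot(k <= np * na)
  have <- integer(0)
  for (t in seq_len(max_tries)) {
    need <- k - length(have)
    if (need == 0L) break
    p <- sample.int(np, need, replace = TRUE, prob = p_weights)
    a <- sample.int(na, need, replace = TRUE, prob = a_weights)
    have <- unique(c(have, (p - 1L) * na + a))
  }
  if (length(have) < k) stop("could not realize the requested link count")
  cbind(plant = (have - 1L) %/% na + 1L, animal = (have - 1L) %% na + 1L)
}

#' Generate a synthetic plant-pollinator community
#'
#' Emits interaction records with the structure the pipeline assumes.
#' Diurnal links are drawn with lognormal plant and animal attractiveness
#' weights (skewed degree distributions); connectedness of the realized
#' diurnal network is guaranteed by rejection. Nocturnal links are placed
#' per scenario, and each nocturnal link is realized as one or more
#' individual-moth records with negative-binomial grain counts, of which at
#' least one meets the scoring threshold of 3 grains (further individuals
#' may fall below it, exercising the threshold end-to-end). All records
#' carry session ids.
#'
#' @param config a [scenario_config()].
#' @return a data.frame of interaction records (see [read_interactions()])
#'   with attribute `"syndrome_plants"` naming the designated syndrome
#'   plants.
#' @export
generate_community <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  plants <- sprintf("plant_%02d", seq_len(config$n_plants))
  animals <- sprintf("fly_%03d", seq_len(config$n_diurnal_animals))
  moths <- sprintf("moth_%02d", seq_len(config$n_moths))

  # heterogeneous attractiveness -> skewed degree distributions
  pw <- rlnorm(config$n_plants, 0, 1)
  aw <- rlnorm(config$n_diurnal_animals, 0, 1)
  syn_idx <- order(pw)[seq_len(config$syndrome_plants)]  # least attractive
  pw_day <- pw
  if (config$scenario == "syndrome")  # nocturnal anthesis: few diurnal visits
    pw_day[syn_idx] <- pw_day[syn_idx] * config$syndrome_day_discount

  # diurnal network, connected by rejection
  for (try in 1:100) {
    pairs <- draw_distinct_pairs(config$diurnal_links, pw_day, aw)
    if (config$scenario == "syndrome") {
      # even night-syndrome flowers receive some diurnal visits (in the
      # field, most moth-visited plants are also visited by day): guarantee
      # each syndrome plant one diurnal link, swapped in from a plant that
      # can spare one
      for (sp in syn_idx) {
        if (any(pairs[, 1L] == sp)) next
        counts <- table(pairs[, 1L])
        donor_rows <- which(pairs[, 1L] %in%
                              as.integer(names(counts)[counts >= 2L]))
        row <- donor_rows[sample.int(length(donor_rows), 1L)]
        partner <- sample.int(config$n_diurnal_animals, 1L, prob = aw)
        if (!any(pairs[, 1L] == sp & pairs[, 2L] == partner))
          pairs[row, ] <- c(sp, partner)
      }
    }
    # pool species need not all appear; connectivity is required on the
    # realized species only
    if (is_connected_net(pairs[, 1L], pairs[, 2L])) break
    if (try == 100) stop("could not generate a connected diurnal network")
  }
  d_plants <- plants[pairs[, 1L]]
  d_animals <- animals[pairs[, 2L]]

  # each diurnal link observed in >= 1 sessions (geometric revisit count)
  n_occ <- pmin(1L + rpois(nrow(pairs), 0.8), config$n_sessions_diurnal)
  d_rows <- data.frame(
    plant_id = rep(d_plants, n_occ),
    animal_id = rep(d_animals, n_occ),
    period = "diurnal",
    session_id = sprintf("D%02d", unlist(lapply(n_occ, function(k)
      sample.int(config$n_sessions_diurnal, k)))),
    individual_id = NA_character_,
    pollen_grains = NA_integer_
  )

  # nocturnal link placement: moth degrees first (every moth carries at
  # least one scored load; extra loads spread uniformly -- most moths bear
  # pollen of one or two plants), then plants per scenario
  ddeg <- tabulate(pairs[, 1L], nbins = config$n_plants)  # diurnal degree
  n <- config$nocturnal_links
  moth_deg <- rep(1L, config$n_moths)
  for (k in seq_len(n - config$n_moths)) {
    i <- sample.int(config$n_moths, 1L)
    moth_deg[i] <- moth_deg[i] + 1L
  }
  n_plant_idx <- integer(0)
  n_moth_idx <- integer(0)
  if (config$scenario == "syndrome") {
    # planted night module: one dominant night-flowering hub receives every
    # moth's primary load; secondary loads go to a set of satellite
    # syndrome plants, each visited at least twice by hub-sharing moths
    # (so the block stays connected); each link is then redirected to a
    # uniformly random plant with probability 1 - assortativity
    hub <- syn_idx[sample.int(length(syn_idx), 1L)]
    sats <- setdiff(syn_idx, hub)
    extras <- n - config$n_moths
    n_active <- max(1L, min(length(sats), extras %/% 2L))
    active <- if (length(sats) > 0L) sample(sats)[seq_len(n_active)]
              else hub
    queue <- sample(rep_len(active, extras))
    qi <- 0L
    for (m in seq_len(config$n_moths)) {
      used <- hub
      n_plant_idx <- c(n_plant_idx, hub)
      n_moth_idx <- c(n_moth_idx, m)
      for (j in seq_len(moth_deg[m] - 1L)) {
        qi <- qi + 1L
        p <- queue[qi]
        if (p %in% used) {  # same satellite twice for one moth: swap ahead
          alt <- which(!queue[seq(qi, length(queue))] %in% used)[1L]
          if (!is.na(alt)) {
            k2 <- qi + alt - 1L
            tmp <- queue[qi]; queue[qi] <- queue[k2]; queue[k2] <- tmp
            p <- queue[qi]
          } else p <- setdiff(seq_len(config$n_plants), used)[1L]
        }
        used <- c(used, p)
        n_plant_idx <- c(n_plant_idx, p)
        n_moth_idx <- c(n_moth_idx, m)
      }
    }
    # off-syndrome redirection (heterospecific or day-flower pollen)
    for (k in seq_along(n_plant_idx)) {
      if (runif(1) < config$assortativity) next
      m <- n_moth_idx[k]
      used <- n_plant_idx[n_moth_idx == m]
      p <- sample.int(config$n_plants, 1L)
      if (!p %in% used) n_plant_idx[k] <- p
    }
  } else {
    for (m in seq_len(config$n_moths)) {
      used <- integer(0)
      for (j in seq_len(moth_deg[m])) {
        for (t in 1:200) {
          p <- switch(config$scenario,
            random = sample.int(config$n_plants, 1L),
            preferential = sample.int(config$n_plants, 1L,
                                      prob = ddeg + 1e-9))
          if (!p %in% used) break
          if (t == 200) stop("could not realize the nocturnal link count")
        }
        used <- c(used, p)
        n_plant_idx <- c(n_plant_idx, p)
        n_moth_idx <- c(n_moth_idx, m)
      }
    }
  }

  # realize each link as 1-3 individual moths; the first is conditioned to
  # carry >= 3 grains so the link survives scoring
  rnb <- function(k) rnbinom(k, size = config$pollen_dispersion,
                             mu = config$pollen_mean)
  n_rows <- list()
  ind_counter <- 0L
  for (j in seq_len(n)) {
    k_ind <- 1L + rbinom(1L, 2L, 0.3)
    grains <- rnb(k_ind)
    while (grains[1L] < 3L) grains[1L] <- rnb(1L)
    ind_counter <- ind_counter + k_ind
    n_rows[[j]] <- data.frame(
      plant_id = plants[n_plant_idx[j]],
      animal_id = moths[n_moth_idx[j]],
      period = "nocturnal",
      session_id = sprintf("N%02d", sample.int(config$n_sessions_nocturnal,
                                               k_ind, replace = TRUE)),
      individual_id = sprintf("ind_%04d",
                              seq.int(ind_counter - k_ind + 1L, ind_counter)),
      pollen_grains = as.integer(grains)
    )
  }
  out <- rbind(d_rows, do.call(rbind, n_rows))
  rownames(out) <- NULL
  attr(out, "syndrome_plants") <- plants[syn_idx]
  out
}

#' Small fixture exercising the pollen-grain threshold boundary
#'
#' Emits a deterministic record set in which known individual moths carry 0,
#' 1, 2, 3 and 5 grains, so the inclusive >= 3 scoring rule is testable
#' end-to-end, plus two diurnal records.
#'
#' @param seed unused placeholder for interface symmetry (the fixture is
#'   deterministic).
#' @return a data.frame of interaction records.
#' @export
generate_threshold_fixture <- function(seed = 1L) {
  data.frame(
    plant_id = c("plant_A", "plant_A", "plant_B", "plant_B", "plant_B",
                 "plant_A", "plant_C"),
    animal_id = c("moth_1", "moth_1", "moth_1", "moth_2", "moth_2",
                  "bee_1", "bee_1"),
    period = c(rep("nocturnal", 5L), "diurnal", "diurnal"),
    session_id = c("N01", "N01", "N02", "N02", "N03", "D01", "D02"),
    individual_id = c("ind_0001", "ind_0002", "ind_0003", "ind_0004",
                      "ind_0005", NA, NA),
    # moth_1 on plant_A: grains 2 then 4 -> single species-level link;
    # moth_1 on plant_B: 0 -> no link; moth_2 on plant_B: 1 then 3 -> link
    pollen_grains = c(2L, 4L, 0L, 1L, 3L, NA, NA),
    stringsAsFactors = FALSE
  )
}
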