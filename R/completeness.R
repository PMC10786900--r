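#' Session-structured incidence table
#'
#' Builds a binary entity x session presence matrix from interaction
#' records, the input of the Chao 2 estimator. Entities are plant species,
#' animal species, or plant-animal pairs; presence marks any *scored*
#' occurrence in that session (nocturnal records must meet the pollen-grain
#' threshold to be scored).
#'
#' @param records interaction-record data.frame (see [read_interactions()]).
#' @param level `"plants"`, `"animals"` or `"interactions"`.
#' @param period `"diurnal"` or `"nocturnal"` (tables are built per network).
#' @param pollen_threshold scoring threshold for nocturnal records.
#' @return an object of class `incidence_table`: `entities`, `sessions`,
#'   binary `presence` matrix and `m` (session count).
#' @export
incidence_from_records <- function(records,
                                   level = c("plants", "animals",
                                             "interactions"),
                                   period = c("diurnal", "nocturnal"),
                                   pollen_threshold = 3L) {
  level <- match.arg(level)
  period <- match.arg(period)
  records <- validate_records(records)
  rec <- records[records$period == period, , drop = FALSE]
  if (period == "nocturnal")
    rec <- rec[!is.na(rec$pollen_grains) &
                 rec$pollen_grains >= pollen_threshold, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no scored ", period, " records")
  if (any(is.na(rec$session_id) | rec$session_id == ""))
    stop("record(s) missing session_id")
  ent <- switch(level,
                plants = rec$plant_id,
                animals = rec$animal_id,
                interactions = paste(rec$plant_id, rec$animal_id, sep = " -- "))
  entities <- sort(unique(ent))
  sessions <- sort(unique(rec$session_id))
  presence <- matrix(0L, length(entities), length(sessions),
                     dimnames = list(entities, sessions))
  presence[cbind(match(ent, entities), match(rec$session_id, sessions))] <- 1L
  structure(list(entities = entities, sessions = sessions,
                 presence = presence, m = length(sessions)),
            class = "incidence_table")
}

#' Chao 2 asymptotic richness and sampling completeness
#'
#' Non-parametric incidence-based estimator, appropriate for small sample
#' sizes. With `m` sessions, `q1` singletons (entities seen in exactly one
#' session) and `q2` doubletons:
#' `S_est = S_obs + ((m-1)/m) * q1^2 / (2*q2)` when `q2 > 0`, and the
#' bias-corrected `S_est = S_obs + ((m-1)/m) * q1*(q1-1)/2` when `q2 = 0`.
#' Completeness is `100 * S_obs / S_est`.
#'
#' @param table an `incidence_table` with `m >= 2`.
#' @return a list: `S_obs`, `q1`, `q2`, `m`, `S_est`, `completeness_pct`.
#' @export
#' @examples
#' rec <- data.frame(plant_id = c("p1", "p1", "p2"),
#'                   animal_id = c("a1", "a1", "a2"),
#'                   period = "diurnal",
#'                   session_id = c("s1", "s2", "s1"))
#' chao2(incidence_from_records(rec, "interactions", "diurnal"))
chao2 <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  m <- table$m
  if (m < 2L)
    stop("Chao 2 undefined for fewer than 2 sessions (m = ", m, ")")
  freq <- rowSums(table$presence)
  S_obs <- length(freq)
  q1 <- sum(freq == 1L)
  q2 <- sum(freq == 2L)
  corr <- (m - 1) / m
  S_est <- if (q2 > 0L) S_obs + corr * q1^2 / (2 * q2)
           else S_obs + corr * q1 * (q1 - 1) / 2
  list(S_obs = S_obs, q1 = q1, q2 = q2, m = m, S_est = S_est,
       completeness_pct = 100 * S_obs / S_est)
}

#' Completeness report across networks and levels
#'
#' Convenience wrapper producing one row per (period, level) combination
#' present in the records.
#'
#' @param records interaction-record data.frame.
#' @param pollen_threshold scoring threshold for nocturnal records.
#' @return data.frame with columns `network`, `level`, `S_obs`, `q1`, `q2`,
#'   `m`, `S_est`, `completeness_pct`.
#' @export
completeness_report <- function(records, pollen_threshold = 3L) {
  rows <- list()
  for (period in intersect(c("diurnal", "nocturnal"), unique(records$period))) {
    for (level in c("plants", "animals", "interactions")) {
      est <- tryCatch({
        tab <- incidence_from_records(records, level, period, pollen_threshold)
        chao2(tab)
      }, error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <-
        data.frame(network = period, level = level, S_obs = est$S_obs,
                   q1 = est$q1, q2 = est$q2, m = est$m, S_est = est$S_est,
                   completeness_pct = est$completeness_pct)
    }
  }
  do.call(rbind, rows)
}
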