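#' Read long-format interaction records
#'
#' Parses a UTF-8 CSV of plant-animal interaction records. Required columns:
#' `plant_id`, `animal_id`, `period`, `session_id`. Optional columns:
#' `individual_id` (specimen label, used for nocturnal moths) and
#' `pollen_grains` (non-negative integer count per individual; required on
#' every nocturnal row, ignored on diurnal rows).
#'
#' @param path path to the CSV file.
#' @return a data.frame of interaction records, one row per input data row,
#'   in file order, with `period` normalized to lower case.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("plant_id", "animal_id", "period", "session_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"individual_id" %in% names(df))
    df$individual_id <- rep(NA_character_, nrow(df))
  if (!"pollen_grains" %in% names(df))
    df$pollen_grains <- rep(NA_integer_, nrow(df))
  df <- df[, c(required, "individual_id", "pollen_grains")]
  if (nrow(df) == 0L) {
    warning("no data rows in ", path)
    return(validate_records(df))
  }
  df$period <- tolower(trimws(as.character(df$period)))
  bad <- which(!df$period %in% c("diurnal", "nocturnal"))
  if (length(bad) > 0L)
    stop("unknown period value '", df$period[bad[1L]], "' in data row ",
         bad[1L])
  validate_records(df)
}

# Shared invariant checks for interaction-record data frames.
validate_records <- function(df) {
  required <- c("plant_id", "animal_id", "period", "session_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"individual_id" %in% names(df))
    df$individual_id <- rep(NA_character_, nrow(df))
  if (!"pollen_grains" %in% names(df))
    df$pollen_grains <- rep(NA_integer_, nrow(df))
  df$plant_id <- as.character(df$plant_id)
  df$animal_id <- as.character(df$animal_id)
  df$session_id <- as.character(df$session_id)
  df$individual_id <- as.character(df$individual_id)
  df$pollen_grains <- suppressWarnings(as.integer(df$pollen_grains))
  noct <- df$period == "nocturnal"
  if (any(noct & is.na(df$pollen_grains)))
    stop("nocturnal record(s) lacking pollen_grains in data row(s): ",
         paste(utils::head(which(noct & is.na(df$pollen_grains)), 5L),
               collapse = ", "))
  if (any(!is.na(df$pollen_grains) & df$pollen_grains < 0L))
    stop("negative pollen_grains")
  rownames(df) <- NULL
  df
}

#' Write interaction records to CSV
#'
#' @param records interaction-record data.frame (see [read_interactions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assemble a qualitative network from interaction records
#'
#' Diurnal networks: any recorded floral contact creates a link. Nocturnal
#' networks: a plant x moth-species link is scored only if at least one
#' *individual* moth of that species carried `pollen_threshold` or more
#' pollen grains of that plant (default 3, guarding against heterospecific
#' pollen carry-over). All counts collapse to presence/absence.
#'
#' @param records interaction-record data.frame.
#' @param period `"diurnal"` or `"nocturnal"`.
#' @param pollen_threshold minimum grain count for a nocturnal record to be
#'   scored (inclusive).
#' @return a `bipartite_network`.
#' @export
build_network <- function(records, period = c("diurnal", "nocturnal"),
                          pollen_threshold = 3L) {
  period <- match.arg(period)
  records <- validate_records(records)
  rec <- records[records$period == period, , drop = FALSE]
  if (period == "nocturnal")
    rec <- rec[!is.na(rec$pollen_grains) &
                 rec$pollen_grains >= pollen_threshold, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no ", period, " links survive filtering (empty network)")
  net_from_links(rec$plant_id, rec$animal_id, period)
}
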