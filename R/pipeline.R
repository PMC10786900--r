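#' Run configuration for the full pipeline
#'
#' Bundles inputs and replicate counts. Defaults transcribe the analysis
#' protocol: 500 null networks for NODF, 100 for Q, 100 extinction
#' repetitions, 100 resampling replicates, 10% subsampling steps.
#'
#' @param input path to an interaction-record CSV, or `NULL` to generate a
#'   synthetic community from `generator`.
#' @param generator a [scenario_config()] (used when `input` is `NULL`).
#' @param pollen_threshold nocturnal scoring threshold (default 3).
#' @param nodf_null_reps,q_null_reps fixed-fixed null replicates.
#' @param robustness_reps extinction replicates.
#' @param trajectory_reps resampling replicates per level.
#' @param step subsampling step fraction.
#' @param ci confidence-interval method (`"percentile"` or `"normal"`).
#' @param seed master seed; every stochastic stage draws a named substream.
#' @param out_dir output directory for the report bundle.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = scenario_config(),
                       pollen_threshold = 3L, nodf_null_reps = 500L,
                       q_null_reps = 100L, robustness_reps = 100L,
                       trajectory_reps = 100L, step = 0.10,
                       ci = "percentile", seed = 1L, out_dir = "mothnets_run") {
  stopifnot(step > 0, step < 1, nodf_null_reps >= 2L, q_null_reps >= 2L,
            robustness_reps >= 1L, trajectory_reps >= 1L)
  structure(as.list(environment()), class = "run_config")
}

# Tiny stable content hash (polynomial rolling hash over the deparsed
# config) for the manifest; avoids a digest dependency.
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Assembles the diurnal, nocturnal and combined networks, then produces the
#' report bundle under `config$out_dir`: `table1.csv` (the fifteen
#' structural properties for D and C plus observed % change),
#' `null_tests.json`, `attachment.json`, `robustness_curves.csv`,
#' `completeness.csv`, `trajectory.csv`, `break.json`, and `manifest.json`
#' (config hash, seed, stage log). Fails with a stage-named error; artifacts
#' of completed stages are preserved.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory results.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- character(0)
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list()

  records <- stage("input", {
    if (!is.null(config$input)) read_interactions(config$input)
    else generate_community(config$generator)
  })
  stages <- c(stages, "input")

  nets <- stage("assemble", {
    d <- build_network(records, "diurnal",
                       pollen_threshold = config$pollen_threshold)
    n <- build_network(records, "nocturnal",
                       pollen_threshold = config$pollen_threshold)
    list(d = d, n = n, c = combine_networks(d, n))
  })
  res$networks <- nets
  stages <- c(stages, "assemble")

  seed <- config$seed
  tab1 <- stage("metrics", {
    md <- network_metrics(nets$d, seed = substream_seed(seed, "metrics_d"),
                          robustness_reps = config$robustness_reps)
    mc <- network_metrics(nets$c, seed = substream_seed(seed, "metrics_c"),
                          robustness_reps = config$robustness_reps)
    keep <- setdiff(names(md), "n_modules")
    obs <- vapply(keep, function(k) {
      if (mc[[k]] == 0) NA_real_  # change undefined on a zero combined value
      else percent_change(md[[k]], mc[[k]])
    }, numeric(1))
    out <- data.frame(property = keep, D = unlist(md[keep]),
                      C = unlist(mc[keep]), obs_pct_change = obs)
    write.csv(out, file.path(config$out_dir, "table1.csv"),
              row.names = FALSE)
    out
  })
  res$table1 <- tab1
  stages <- c(stages, "metrics")

  res$null_tests <- stage("nulltest", {
    nt <- list(
      null_test(nets$d, "nodf_total", config$nodf_null_reps,
                seed = substream_seed(seed, "null_d_nodf")),
      null_test(nets$c, "nodf_total", config$nodf_null_reps,
                seed = substream_seed(seed, "null_c_nodf")),
      null_test(nets$d, "Q", config$q_null_reps,
                seed = substream_seed(seed, "null_d_q")),
      null_test(nets$c, "Q", config$q_null_reps,
                seed = substream_seed(seed, "null_c_q")))
    names(nt) <- c("diurnal_nodf", "combined_nodf", "diurnal_Q", "combined_Q")
    jsonlite::write_json(lapply(nt, unclass),
                         file.path(config$out_dir, "null_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    nt
  })
  stages <- c(stages, "nulltest")

  res$attachment <- stage("attach", {
    at <- attachment_test(nets$d, nets$n$plants)
    jsonlite::write_json(unclass(at),
                         file.path(config$out_dir, "attachment.json"),
                         auto_unbox = TRUE, digits = NA)
    at
  })
  stages <- c(stages, "attach")

  res$robustness <- stage("robustness", {
    curves <- list()
    for (nm in c("d", "c")) {
      for (guild in c("plants", "animals")) {
        cv <- simulate_extinction(
          nets[[nm]], guild, n_reps = config$robustness_reps,
          seed = substream_seed(seed, paste0("curve_", nm, "_", guild)))
        df <- extinction_curve_df(cv)
        df$network <- nm
        df$target_guild <- guild
        curves[[paste(nm, guild)]] <- df
      }
    }
    all <- do.call(rbind, curves)
    write.csv(all, file.path(config$out_dir, "robustness_curves.csv"),
              row.names = FALSE)
    all
  })
  stages <- c(stages, "robustness")

  res$completeness <- stage("completeness", {
    cp <- completeness_report(records, config$pollen_threshold)
    write.csv(cp, file.path(config$out_dir, "completeness.csv"),
              row.names = FALSE)
    cp
  })
  stages <- c(stages, "completeness")

  res$trajectory <- stage("resample", {
    tr <- trajectory(nets$d, nets$n, step = config$step,
                     n_reps = config$trajectory_reps,
                     seed = substream_seed(seed, "trajectory"),
                     ci = config$ci)
    write.csv(tr$summary, file.path(config$out_dir, "trajectory.csv"),
              row.names = FALSE)
    br <- break_test(nets$d, nets$n, n_reps = config$trajectory_reps,
                     seed = substream_seed(seed, "break"), ci = config$ci)
    jsonlite::write_json(br$summary,
                         file.path(config$out_dir, "break.json"),
                         auto_unbox = TRUE, digits = NA)
    list(trajectory = tr, break_result = br)
  })
  stages <- c(stages, "resample")

  manifest <- list(package = "mothnets",
                   version = as.character(utils::packageVersion("mothnets")),
                   seed = seed, config_hash = config_hash(config),
                   stages = stages, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  say("done: %s", config$out_dir)
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches the subcommands used by the `exec/mothnets` script:
#' `simulate` (write a synthetic community CSV), `assemble` (records ->
#' network CSVs), `metrics`, `nulltest`, `attach`, `robustness`,
#' `completeness`, `resample` (each runnable on saved files) and `report`
#' (the full [run_pipeline()]).
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mothnets <command> [options]",
    "commands: simulate | assemble | metrics | nulltest | attach |",
    "          robustness | completeness | resample | report",
    "common options: --input FILE --out DIR --seed N --threshold N",
    sep = "\n")
  if (length(args) < 1L) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opt <- list(input = NULL, out = "mothnets_run", seed = 1L, threshold = 3L,
              scenario = "random")
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt)) stop("unknown option --", key)
    opt[[key]] <- if (key %in% c("seed", "threshold"))
      as.integer(rest[i + 1L]) else rest[i + 1L]
    i <- i + 2L
  }
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  load_nets <- function() {
    rec <- read_interactions(opt$input)
    d <- build_network(rec, "diurnal", opt$threshold)
    n <- build_network(rec, "nocturnal", opt$threshold)
    list(rec = rec, d = d, n = n, c = combine_networks(d, n))
  }
  switch(cmd,
    simulate = {
      rec <- generate_community(scenario_config(scenario = opt$scenario,
                                                seed = opt$seed))
      write_interactions(rec, file.path(opt$out, "records.csv"))
    },
    assemble = {
      x <- load_nets()
      write_network(x$d, file.path(opt$out, "diurnal_incidence.csv"))
      write_network(x$n, file.path(opt$out, "nocturnal_incidence.csv"))
      write_network(x$c, file.path(opt$out, "combined_incidence.csv"))
    },
    metrics = {
      x <- load_nets()
      md <- network_metrics(x$d, seed = opt$seed)
      mc <- network_metrics(x$c, seed = opt$seed)
      write.csv(rbind(cbind(network = "diurnal", md),
                      cbind(network = "combined", mc)),
                file.path(opt$out, "metrics.csv"), row.names = FALSE)
    },
    nulltest = {
      x <- load_nets()
      nt <- list(nodf = unclass(null_test(x$c, "nodf_total", seed = opt$seed)),
                 Q = unclass(null_test(x$c, "Q", seed = opt$seed)))
      jsonlite::write_json(nt, file.path(opt$out, "null_tests.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    attach = {
      x <- load_nets()
      jsonlite::write_json(unclass(attachment_test(x$d, x$n$plants)),
                           file.path(opt$out, "attachment.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    robustness = {
      x <- load_nets()
      rp <- rbind(robustness_pair(x$d, seed = opt$seed),
                  robustness_pair(x$c, seed = opt$seed))
      write.csv(data.frame(network = c("diurnal", "combined"), rp),
                file.path(opt$out, "robustness.csv"), row.names = FALSE)
    },
    completeness = {
      x <- load_nets()
      write.csv(completeness_report(x$rec, opt$threshold),
                file.path(opt$out, "completeness.csv"), row.names = FALSE)
    },
    resample = {
      x <- load_nets()
      tr <- trajectory(x$d, x$n, seed = opt$seed)
      write.csv(tr$summary, file.path(opt$out, "trajectory.csv"),
                row.names = FALSE)
      br <- break_test(x$d, x$n, seed = opt$seed)
      jsonlite::write_json(br$summary, file.path(opt$out, "break.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    report = {
      cfg <- run_config(input = opt$input,
                        generator = scenario_config(scenario = opt$scenario,
                                                    seed = opt$seed),
                        pollen_threshold = opt$threshold, seed = opt$seed,
                        out_dir = opt$out)
      run_pipeline(cfg)
    },
    {
      cat(usage, "\n")
      return(invisible(1L))
    })
  invisible(0L)
}
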