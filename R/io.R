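session_columns <- c(
  "participant_id", "design", "mode", "phase", "trial", "cycle",
  "raw_tap_ms", "tap_ms", "target_ms"
)

#' Write tap-event sessions to tidy CSV
#'
#' @param taps Tap-event tibble (see [simulate_cohort()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(taps, path) {
  stopifnot(all(session_columns %in% names(taps)))
  readr::write_csv(taps[session_columns], path)
  invisible(path)
}

#' Read tap-event sessions from tidy CSV
#'
#' Validates the schema and reports malformed rows (unparseable or
#' incomplete) with their line numbers; well-formed rows are kept.
#'
#' @param path CSV file written by [write_session_csv()] or following the
#'   same schema: participant_id, design, mode, phase, trial, cycle,
#'   raw_tap_ms, tap_ms, target_ms.
#' @return Tap-event tibble.
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path, call. = FALSE)
  taps <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      design = readr::col_character(),
      mode = readr::col_character(),
      phase = readr::col_character(),
      trial = readr::col_integer(),
      cycle = readr::col_integer(),
      raw_tap_ms = readr::col_double(),
      tap_ms = readr::col_double(),
      target_ms = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(session_columns, names(taps))
  if (length(missing_cols)) {
    stop(
      "session file is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  probs <- readr::problems(taps)
  bad <- !complete.cases(taps[session_columns])
  if (nrow(probs) > 0 || any(bad)) {
    lines <- sort(unique(c(probs$row, which(bad))))
    message(
      "dropped ", sum(bad), " malformed session row(s) at data line(s): ",
      paste(head(lines, 10), collapse = ", ")
    )
    taps <- taps[!bad, , drop = FALSE]
  }
  if (nrow(taps) == 0) stop("session file contains no valid rows", call. = FALSE)
  taps
}

#' Configuration for a full pipeline run
#'
#' @param n_block,n_alternating Cohort sizes (defaults 10 and 13).
#' @param design_template A [task_design()] supplying the paradigm constants.
#' @param params_block_group,params_alt_group Generator parameters per group.
#' @param iqr_k IQR multiplier for outlier rejection (default 1.5).
#' @param balance_m Bootstrap-balanced block size (default 5).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config` object (named list).
#' @export
run_config <- function(n_block = 10, n_alternating = 13,
                       design_template = task_design(),
                       params_block_group = params_block(),
                       params_alt_group = params_alternating(),
                       iqr_k = 1.5, balance_m = 5,
                       seed = 1L, out_dir = tempfile("tapsync_run_")) {
  structure(
    list(
      n_block = n_block, n_alternating = n_alternating,
      design_template = design_template,
      params_block_group = params_block_group,
      params_alt_group = params_alt_group,
      iqr_k = iqr_k, balance_m = balance_m,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

config_snapshot <- function(config) {
  jsonlite::toJSON(
    list(
      n_block = config$n_block,
      n_alternating = config$n_alternating,
      design = unclass(config$design_template),
      params_block_group = unclass(config$params_block_group),
      params_alt_group = unclass(config$params_alt_group),
      iqr_k = config$iqr_k, balance_m = config$balance_m,
      seed = config$seed
    ),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes asynchrony and IRI statistics,
#' applies outlier rejection and bootstrap balancing, and writes condition
#' summaries, regression effect tables, Tukey contrasts, cycle-averaged
#' trends with turning points, DID tables and the power table to
#' `config$out_dir`. A config snapshot (JSON) and a manifest associating
#' every artifact with the snapshot's content hash are written alongside.
#' Two runs with the same config and seed produce identical bundles.
#'
#' @param config A [run_config()].
#' @param taps Optional pre-loaded tap-event tibble; when `NULL` (default) a
#'   cohort is simulated from the config.
#' @param stage Run up to this stage: `"simulate"`, `"metrics"`, or
#'   `"all"` (default).
#' @return Invisibly, a list of the computed objects (taps, summaries,
#'   models, trends, turning points, DID results, power table, paths).
#' @export
run_pipeline <- function(config = run_config(), taps = NULL,
                         stage = c("all", "simulate", "metrics")) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    if (inherits(x, "data.frame")) {
      readr::write_csv(x, path)
    } else {
      writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
    }
    written <<- c(written, name)
    path
  }

  snap_path <- file.path(config$out_dir, "config_snapshot.json")
  writeLines(config_snapshot(config), snap_path)
  written <- c(written, "config_snapshot.json")

  out <- list(config = config)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  out$taps <- step("simulate", {
    if (is.null(taps)) {
      simulate_cohort(
        config$n_block, config$n_alternating,
        config$params_block_group, config$params_alt_group,
        seed = config$seed, design_template = config$design_template
      )
    } else {
      taps
    }
  })
  emit(out$taps, "sessions.csv")
  message("stage simulate: ", nrow(out$taps), " tap events")

  if (stage != "simulate") {
    out$summary_asynchrony <- step("metrics", {
      summarize_conditions(asynchrony(out$taps), "asynchrony_ms")
    })
    out$summary_iri <- step("metrics", {
      summarize_conditions(iri_events(out$taps), "iri_ms")
    })
    emit(out$summary_asynchrony, "summary_asynchrony.csv")
    emit(out$summary_iri, "summary_iri.csv")
    message("stage metrics: condition summaries written")
  }

  if (stage == "all") {
    for (statistic in c("asynchrony", "iri")) {
      prep <- step("preprocess", {
        preprocess_cohort(out$taps, statistic,
          k = config$iqr_k, m = config$balance_m, seed = config$seed
        )
      })
      out[[paste0("prep_", statistic)]] <- prep
      emit(prep$filter_report, paste0("filter_report_", statistic, ".csv"))

      model <- step("regression", fit_ols(regression_input(prep$trial_means)))
      out[[paste0("mlr_", statistic)]] <- model
      emit(effect_table(model), paste0("effects_", statistic, ".csv"))

      cond <- interaction(
        prep$trial_means$mode, prep$trial_means$phase,
        sep = ":"
      )
      tk <- step("tukey", tukey_hsd(prep$trial_means$value_ms, cond))
      emit(tk, paste0("tukey_", statistic, ".csv"))

      trend <- step("trend", cycle_average(out$taps, statistic, by = "design"))
      out[[paste0("trend_", statistic)]] <- trend
      emit(trend, paste0("trend_", statistic, ".csv"))
      tps <- lapply(split(trend, trend$design), function(s) {
        tp <- turning_points(fit_growth_spline(s))
        list(
          primary_s = tp$primary_s, degenerate = tp$degenerate,
          turning_points = tp$turning_points
        )
      })
      out[[paste0("turning_points_", statistic)]] <- tps
      emit(tps, paste0("turning_points_", statistic, ".json"))

      did <- step("did", fit_did(did_observations(prep$trial_means)))
      out[[paste0("did_", statistic)]] <- did
      emit(did_report(did), paste0("did_", statistic, ".csv"))
      message("stage analyze (", statistic, "): done")
    }
    n_total <- config$n_block + config$n_alternating
    if (n_total > 4) {
      out$power <- power_table(n = n_total, predictors = 3)
      emit(out$power, "power.csv")
    } else {
      message("cohort too small for a 3-predictor power analysis; skipping")
    }
  }

  hash <- unname(tools::md5sum(snap_path))
  emit(
    tibble::tibble(file = written, config_md5 = hash),
    "manifest.csv"
  )
  invisible(out)
}
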