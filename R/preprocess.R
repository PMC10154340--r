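#' Tukey-fence outlier rejection within condition cells
#'
#' Within each group, observations outside
#' `[Q1 - k*IQR, Q3 + k*IQR]` are removed (Tukey fences, default `k = 1.5`).
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Groups with fewer than 4 values are passed
#' through untouched with a warning — quartiles are not meaningful there.
#'
#' @param events Tibble holding the statistic and grouping columns.
#' @param value Name of the statistic column.
#' @param by Grouping columns defining the cells the fences are computed in;
#'   default participant x design x mode x phase.
#' @param k Positive IQR multiplier (default 1.5).
#' @return A list with `kept` (filtered tibble), `removed` (rows rejected)
#'   and `report` (per-group tibble: grouping columns, `n_before`,
#'   `n_removed`, `n_after`).
#' @examples
#' x <- tibble::tibble(g = "a", v = c(1:10, 1000))
#' iqr_filter(x, "v", by = "g")$removed
#' @export
iqr_filter <- function(events, value,
                       by = c("participant_id", "design", "mode", "phase"),
                       k = 1.5) {
  stopifnot(k > 0, value %in% names(events), all(by %in% names(events)))
  grouped <- events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(
      .n_group = dplyr::n(),
      .q1 = quantile(.data[[value]], 0.25, type = 7, names = FALSE),
      .q3 = quantile(.data[[value]], 0.75, type = 7, names = FALSE),
      .keep_row = .data$.n_group < 4L |
        (.data[[value]] >= .data$.q1 - k * (.data$.q3 - .data$.q1) &
          .data[[value]] <= .data$.q3 + k * (.data$.q3 - .data$.q1))
    ) |>
    dplyr::ungroup()
  if (any(grouped$.n_group < 4L)) {
    warning("groups with fewer than 4 values passed through unfiltered",
      call. = FALSE
    )
  }
  report <- grouped |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_before = dplyr::n(),
      n_removed = sum(!.data$.keep_row),
      n_after = sum(.data$.keep_row),
      .groups = "drop"
    )
  drop_cols <- c(".n_group", ".q1", ".q3", ".keep_row")
  kept <- grouped[grouped$.keep_row, setdiff(names(grouped), drop_cols)]
  removed <- grouped[!grouped$.keep_row, setdiff(names(grouped), drop_cols)]
  list(kept = kept, removed = removed, report = report)
}

#' Bootstrap-balance condition blocks to a constant size
#'
#' Resamples every block (by default with replacement, i.e. a bootstrap
#' draw) to exactly `m` rows, so downstream model fits see equally sized
#' cells regardless of how many taps survived matching and outlier
#' rejection. Deterministic given `seed`.
#'
#' @param events Tibble to balance.
#' @param by Grouping columns defining a block; default participant x design
#'   x mode x phase x trial (a trial-phase block).
#' @param m Target rows per block (default 5).
#' @param replace Sample with replacement (default TRUE).
#' @param seed Integer seed.
#' @return Tibble with exactly `m` rows per non-empty block.
#' @export
bootstrap_balance <- function(events,
                              by = c(
                                "participant_id", "design", "mode",
                                "phase", "trial"
                              ),
                              m = 5, replace = TRUE, seed = 1L) {
  stopifnot(m >= 1, all(by %in% names(events)))
  if (nrow(events) == 0) stop("no observations to balance", call. = FALSE)
  set.seed(as.integer(seed))
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 0) {
        stop(
          "empty condition block: ",
          paste(unlist(key), collapse = "/"),
          call. = FALSE
        )
      }
      if (!replace && nrow(df) < m) {
        stop("block smaller than m and replace = FALSE", call. = FALSE)
      }
      df[sample.int(nrow(df), m, replace = replace), , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

#' Standard preprocessing for a tap-event cohort
#'
#' The full preparation applied before inference: compute the statistic
#' ((virtual) asynchrony or IRI), reject outliers by Tukey fences within
#' participant x design x mode x phase, bootstrap-balance trial-phase blocks
#' to `m` values, and average to one observation per trial-phase.
#'
#' @param taps Tap-event tibble (see [simulate_cohort()]).
#' @param statistic `"asynchrony"` or `"iri"`.
#' @param k IQR multiplier (default 1.5).
#' @param m Balanced block size (default 5).
#' @param seed Seed for the bootstrap draw.
#' @return A list with `events` (per-tap statistic after filtering and
#'   balancing, column `value_ms`), `trial_means` (one row per participant x
#'   trial x phase: columns `participant_id`, `design`, `mode`, `phase`,
#'   `trial`, `value_ms`) and `filter_report`.
#' @export
preprocess_cohort <- function(taps, statistic = c("asynchrony", "iri"),
                              k = 1.5, m = 5, seed = 1L) {
  statistic <- match.arg(statistic)
  events <- if (statistic == "asynchrony") {
    asynchrony(taps) |> dplyr::rename(value_ms = "asynchrony_ms")
  } else {
    iri_events(taps) |> dplyr::rename(value_ms = "iri_ms")
  }
  filt <- iqr_filter(events, "value_ms", k = k)
  balanced <- bootstrap_balance(filt$kept, m = m, seed = seed)
  trial_means <- balanced |>
    dplyr::group_by(
      .data$participant_id, .data$design, .data$mode,
      .data$phase, .data$trial
    ) |>
    dplyr::summarise(value_ms = mean(.data$value_ms), .groups = "drop")
  list(events = balanced, trial_means = trial_means, filter_report = filt$report)
}
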