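#' Remove a constant device-registration delay from raw tap times
#'
#' Tapping hardware registers responses a fixed latency after the physical
#' tap; subtracting that latency recovers the response onset.
#'
#' @param raw_tap_times Numeric vector of device-clock tap times, ms.
#' @param delay Non-negative delay in ms (default 25).
#' @return Corrected tap times, same order.
#' @examples
#' correct_device_delay(c(1025, 2025), 25)
#' @export
correct_device_delay <- function(raw_tap_times, delay = 25) {
  stopifnot(is.numeric(raw_tap_times), delay >= 0)
  raw_tap_times - delay
}

#' Target times for a mode and phase
#'
#' Synchronized targets are the beat onsets `i * T`; syncopated targets are
#' the inter-beat midpoints `(i + 1/2) * T`. Both sequences continue on the
#' nominal metronome grid through the continuation phase ("extrapolated
#' silent beats"), so a virtual asynchrony is defined after the metronome
#' stops.
#'
#' @param design A [task_design()].
#' @param mode `"synchronized"` or `"syncopated"`.
#' @param phase `"pacing"`, `"continuation"`, or `"all"` (default).
#' @return Numeric vector of target times in ms, one per cycle.
#' @export
target_times <- function(design, mode = c("synchronized", "syncopated"),
                         phase = c("all", "pacing", "continuation")) {
  mode <- match.arg(mode)
  phase <- match.arg(phase)
  stopifnot(inherits(design, "task_design"))
  cycles <- switch(phase,
    all = seq_len(design$total_cycles) - 1L,
    pacing = seq_len(design$pacing_cycles) - 1L,
    continuation = design$pacing_cycles + seq_len(design$continuation_cycles) - 1L
  )
  offset <- if (mode == "synchronized") 0 else design$inter_beat_interval / 2
  cycles * design$inter_beat_interval + offset
}

#' Match taps to targets
#'
#' Pairs each tap with its nearest target within `±window` ms, using each
#' target at most once; pairs are assigned greedily in order of increasing
#' |tap - target|, so when two taps compete for one target the closer tap
#' wins. Ties (exactly equidistant) resolve toward the later target.
#'
#' @param tap_times Numeric vector of tap times, ms.
#' @param targets Numeric vector of target times, ms.
#' @param window Maximum |tap - target| for a match; must be at most half the
#'   target spacing.
#' @return A list with `pairs` (tibble: `tap`, `target`, `target_index`),
#'   `unmatched_taps` (times) and `missed_targets` (indices, 1-based).
#' @export
match_taps <- function(tap_times, targets, window = 500) {
  stopifnot(is.numeric(tap_times), is.numeric(targets), window > 0)
  if (length(targets) >= 2) {
    spacing <- min(diff(sort(targets)))
    if (window > spacing / 2 + 1e-9) {
      stop("matching window (", window, " ms) exceeds half the target spacing",
        call. = FALSE
      )
    }
  }
  if (length(tap_times) == 0 || length(targets) == 0) {
    return(list(
      pairs = tibble::tibble(
        tap = numeric(), target = numeric(),
        target_index = integer()
      ),
      unmatched_taps = tap_times,
      missed_targets = seq_along(targets)
    ))
  }
  cand <- expand.grid(i = seq_along(tap_times), j = seq_along(targets))
  cand$dist <- abs(tap_times[cand$i] - targets[cand$j])
  cand <- cand[cand$dist <= window, , drop = FALSE]
  # break exact-distance ties toward the later target
  cand <- cand[order(cand$dist, -cand$j), , drop = FALSE]
  tap_used <- logical(length(tap_times))
  tgt_used <- logical(length(targets))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]
    j <- cand$j[r]
    if (!tap_used[i] && !tgt_used[j]) {
      tap_used[i] <- TRUE
      tgt_used[j] <- TRUE
      keep[r] <- TRUE
    }
  }
  matched <- cand[keep, , drop = FALSE]
  matched <- matched[order(matched$j), , drop = FALSE]
  list(
    pairs = tibble::tibble(
      tap = tap_times[matched$i],
      target = targets[matched$j],
      target_index = as.integer(matched$j)
    ),
    unmatched_taps = tap_times[!tap_used],
    missed_targets = which(!tgt_used)
  )
}

#' Signed (virtual) asynchrony of tap events
#'
#' Asynchrony is `tap - target` for every tap, in ms, under a uniform sign
#' convention: negative values mean the tap preceded its target
#' (anticipation), positive values that it followed (reaction). For
#' syncopated tapping and for continuation cycles the target is the virtual
#' one (inter-beat midpoint / extrapolated silent beat), so the same formula
#' yields the virtual asynchrony.
#'
#' @param taps A tap-event tibble with columns `tap_ms` and `target_ms`
#'   (e.g. from [simulate_cohort()]); any grouping columns are carried
#'   through.
#' @return The input with an added `asynchrony_ms` column.
#' @export
asynchrony <- function(taps) {
  stopifnot(all(c("tap_ms", "target_ms") %in% names(taps)))
  dplyr::mutate(taps, asynchrony_ms = .data$tap_ms - .data$target_ms)
}

#' Inter-response intervals of a tap sequence
#'
#' `IRI_i = tap_{i+1} - tap_i` for taps on consecutive cycles only: a gap
#' spanning a missed tap is excluded rather than reported as a double-length
#' interval. The interval is labelled with the later tap's cycle and phase,
#' so the first unpaced interval (last paced tap to first continuation tap)
#' belongs to the continuation phase.
#'
#' @param tap_times Strictly increasing tap times, ms.
#' @param cycles Integer cycle index per tap (same length); defaults to
#'   `seq_along(tap_times) - 1`, i.e. no missed taps.
#' @return Tibble with columns `cycle` (of the later tap) and `iri_ms`.
#' @examples
#' iri(c(0, 980, 2010))
#' @export
iri <- function(tap_times, cycles = seq_along(tap_times) - 1L) {
  stopifnot(length(tap_times) == length(cycles))
  if (length(tap_times) < 2) {
    return(tibble::tibble(cycle = integer(), iri_ms = numeric()))
  }
  if (any(diff(tap_times) <= 0)) {
    stop("tap times must be strictly increasing; corrupted session?", call. = FALSE)
  }
  consecutive <- diff(cycles) == 1L
  tibble::tibble(
    cycle = as.integer(cycles[-1][consecutive]),
    iri_ms = diff(tap_times)[consecutive]
  )
}

#' Per-tap IRI table for a cohort of tap events
#'
#' Computes consecutive-cycle inter-response intervals within each
#' participant x trial, preserving the condition labels of the later tap of
#' each interval. Unlike [iri()], which refuses non-monotone input outright,
#' pairs whose interval is non-positive (a gross device error inverted the
#' local tap order) are skipped here: such taps are exactly what downstream
#' outlier rejection handles, and an inverted pair has no meaningful
#' interval.
#'
#' @param taps A tap-event tibble (see [simulate_cohort()]).
#' @return Tibble with columns `participant_id`, `design`, `mode`, `phase`,
#'   `trial`, `cycle`, `iri_ms`.
#' @export
iri_events <- function(taps) {
  stopifnot(all(c("participant_id", "trial", "cycle", "tap_ms") %in% names(taps)))
  taps |>
    dplyr::arrange(.data$participant_id, .data$trial, .data$cycle) |>
    dplyr::group_by(.data$participant_id, .data$design, .data$mode, .data$trial) |>
    dplyr::reframe(
      {
        d <- diff(.data$tap_ms)
        consecutive <- diff(.data$cycle) == 1L & d > 0
        ph <- .data$phase[-1][consecutive]
        cy <- .data$cycle[-1][consecutive]
        tibble::tibble(phase = ph, cycle = cy, iri_ms = d[consecutive])
      }
    ) |>
    dplyr::ungroup()
}

#' Per-condition summary of a timing statistic
#'
#' Mean and SD of a statistic within each condition cell, the tabular
#' counterpart of the per-condition bar plots of tapping studies.
#'
#' @param events Tibble holding the statistic and the grouping columns.
#' @param value Name of the statistic column (e.g. `"asynchrony_ms"`).
#' @param by Character vector of grouping columns
#'   (default `c("design", "mode", "phase")`).
#' @return Tibble with the grouping columns plus `n`, `mean_ms`, `sd_ms`.
#' @export
summarize_conditions <- function(events, value,
                                 by = c("design", "mode", "phase")) {
  stopifnot(value %in% names(events), all(by %in% names(events)))
  out <- events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ms = mean(.data[[value]]),
      sd_ms = sd(.data[[value]]),
      .groups = "drop"
    )
  empty <- out$n == 0
  if (any(empty)) {
    warning("empty condition cells excluded from summary", call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  out
}
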