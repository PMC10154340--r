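#' Define a pacing-continuation tapping task design
#'
#' Encodes the structure of a synchronization/syncopation-continuation
#' finger-tapping experiment: a metronome sounds for `pacing_cycles` beats,
#' then stops, and the participant keeps tapping for `continuation_cycles`
#' further cycles against their internal timekeeper. Trials come in two
#' coordination modes (tapping on the beat, or midway between beats) and are
#' ordered either blocked by mode or alternating mode every trial.
#'
#' All durations are in milliseconds except `rest_duration_s`. Cycle indices
#' are 0-based with the trial onset (first metronome beat) at 0 ms, so cycle
#' `i` has its nominal beat at `i * inter_beat_interval`.
#'
#' @param inter_beat_interval Metronome period T in ms (default 1000, i.e. 1 Hz).
#' @param tone_duration Duration of each metronome tone in ms (default 20).
#' @param pacing_cycles Number of paced cycles per trial (default 15).
#' @param continuation_cycles Number of unpaced cycles per trial (default 12).
#' @param trials_per_mode Trials per coordination mode (default 10).
#' @param rest_duration_s Inter-trial rest in seconds (default 20).
#' @param device_delay Constant response-registration latency of the tapping
#'   device in ms, subtracted from raw tap times (default 25).
#' @param design_kind `"blocked"` or `"alternating"` trial ordering.
#' @param mode_order Which mode a participant starts with:
#'   `"sync_first"` or `"syncopation_first"`.
#'
#' @return An object of class `task_design` (a named list of the above fields
#'   plus `total_cycles`).
#' @examples
#' d <- task_design()
#' d$total_cycles # 27
#' @export
task_design <- function(inter_beat_interval = 1000,
                        tone_duration = 20,
                        pacing_cycles = 15,
                        continuation_cycles = 12,
                        trials_per_mode = 10,
                        rest_duration_s = 20,
                        device_delay = 25,
                        design_kind = c("blocked", "alternating"),
                        mode_order = c("sync_first", "syncopation_first")) {
  design_kind <- match.arg(design_kind)
  mode_order <- match.arg(mode_order)
  stopifnot(
    inter_beat_interval > 0,
    tone_duration >= 0,
    pacing_cycles >= 1, continuation_cycles >= 1, trials_per_mode >= 1,
    rest_duration_s >= 0, device_delay >= 0
  )
  structure(
    list(
      inter_beat_interval = inter_beat_interval,
      tone_duration = tone_duration,
      pacing_cycles = pacing_cycles,
      continuation_cycles = continuation_cycles,
      total_cycles = pacing_cycles + continuation_cycles,
      trials_per_mode = trials_per_mode,
      rest_duration_s = rest_duration_s,
      device_delay = device_delay,
      design_kind = design_kind,
      mode_order = mode_order
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "<task_design> %s, %s: T = %g ms, %d pacing + %d continuation cycles, %d trials/mode\n",
    x$design_kind, x$mode_order, x$inter_beat_interval,
    x$pacing_cycles, x$continuation_cycles, x$trials_per_mode
  ))
  invisible(x)
}

#' Ordered trial schedule for a task design
#'
#' Expands a [task_design()] into the sequence of trials a participant
#' performs. Blocked designs run all trials of the starting mode then all
#' trials of the other mode; alternating designs switch mode every trial.
#'
#' @param design A [task_design()].
#' @return A tibble with columns `trial` (1-based index) and `mode`
#'   (`"synchronized"` / `"syncopated"`).
#' @examples
#' trial_schedule(task_design(design_kind = "alternating"))
#' @export
trial_schedule <- function(design) {
  stopifnot(inherits(design, "task_design"))
  first <- if (design$mode_order == "sync_first") "synchronized" else "syncopated"
  second <- setdiff(c("synchronized", "syncopated"), first)
  n <- design$trials_per_mode
  modes <- switch(design$design_kind,
    blocked = c(rep(first, n), rep(second, n)),
    alternating = rep(c(first, second), n)
  )
  tibble::tibble(trial = seq_along(modes), mode = modes)
}

#' Phase of each cycle in a trial
#'
#' @param design A [task_design()].
#' @return Character vector of length `total_cycles`: `"pacing"` for cycles
#'   `0 .. pacing_cycles-1`, `"continuation"` afterwards.
#' @export
cycle_phases <- function(design) {
  stopifnot(inherits(design, "task_design"))
  c(
    rep("pacing", design$pacing_cycles),
    rep("continuation", design$continuation_cycles)
  )
}

#' Mode order for the i-th participant of a cohort
#'
#' Counterbalancing is deterministic: odd participant indices start with
#' synchronization, even indices with syncopation, so any even-sized cohort
#' is exactly balanced.
#'
#' @param participant_index 1-based participant index.
#' @return `"sync_first"` or `"syncopation_first"`.
#' @export
counterbalanced_mode_order <- function(participant_index) {
  stopifnot(participant_index >= 1)
  ifelse(participant_index %% 2 == 1, "sync_first", "syncopation_first")
}
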