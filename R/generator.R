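#' Parameters of the synthetic tap-event generator
#'
#' The generator uses a two-level scheme. During pacing, taps are anchored to
#' their targets with a constant bias plus independent Gaussian jitter
#' (emulating the negative mean asynchrony of paced tapping). During
#' continuation, taps are produced by accumulating intervals
#' `T + continuation_drift + Normal(0, continuation_timekeeper_sd)` from the
#' last paced tap, so asynchrony performs a random walk with linear drift —
#' the variance inflation and systematic drift characteristic of unpaced
#' tapping. Two degradations emulate an alternating design: a constant
#' `switch_cost_bias` on trials that follow a mode switch, and a linear
#' pacing-bias ramp that begins `anticipatory_drift_onset_s` seconds into the
#' trial (before metronome offset).
#'
#' Defaults are calibrated to the phenomenology of paced/unpaced tapping at
#' 1 Hz: a pacing bias of -35 ms, per-tap jitter of 50 ms, a 25 ms timekeeper
#' SD, and an 8.9 ms/cycle continuation drift (a mean continuation-minus-pacing
#' asynchrony increase of about 49 ms over 12 cycles). Misses and gross
#' outliers are injected at low rates so outlier rejection and missing-data
#' accounting are exercised.
#'
#' @param pacing_bias Mean pacing asynchrony in ms (negative = anticipation).
#' @param pacing_sd SD of per-tap pacing jitter, ms.
#' @param continuation_timekeeper_sd Per-interval SD of the internal
#'   timekeeper during continuation, ms.
#' @param continuation_drift Systematic interval lengthening per continuation
#'   cycle, ms (positive values lengthen intervals). The first unpaced
#'   interval is drift-free (it reproduces the just-heard period), so the
#'   mean continuation-minus-pacing asynchrony increase over 12 continuation
#'   cycles is `5.5 * continuation_drift`.
#' @param anticipatory_drift_onset_s Trial time (s) at which a pacing bias
#'   ramp begins; `Inf` disables it.
#' @param anticipatory_drift_rate Slope of that ramp, ms per cycle.
#' @param switch_cost_bias Extra bias (ms) on trials whose predecessor used
#'   the other tapping mode.
#' @param miss_prob Probability a tap is dropped.
#' @param outlier_prob Probability a tap's deviation from target is scaled by
#'   `outlier_scale` (a gross error).
#' @param outlier_scale Multiplier applied to an outlier tap's deviation.
#' @param participant_bias_sd Between-participant SD of `pacing_bias`, ms
#'   (0 disables participant heterogeneity).
#'
#' @return A `generator_params` object (named list).
#' @seealso [params_block()], [params_alternating()]
#' @export
generator_params <- function(pacing_bias = -35,
                             pacing_sd = 50,
                             continuation_timekeeper_sd = 25,
                             continuation_drift = 8.9,
                             anticipatory_drift_onset_s = Inf,
                             anticipatory_drift_rate = 0,
                             switch_cost_bias = 0,
                             miss_prob = 0.01,
                             outlier_prob = 0.02,
                             outlier_scale = 8,
                             participant_bias_sd = 0) {
  stopifnot(
    pacing_sd >= 0, continuation_timekeeper_sd >= 0,
    miss_prob >= 0, miss_prob <= 1,
    outlier_prob >= 0, outlier_prob <= 1,
    outlier_scale >= 0, participant_bias_sd >= 0,
    anticipatory_drift_onset_s > 0
  )
  structure(
    list(
      pacing_bias = pacing_bias,
      pacing_sd = pacing_sd,
      continuation_timekeeper_sd = continuation_timekeeper_sd,
      continuation_drift = continuation_drift,
      anticipatory_drift_onset_s = anticipatory_drift_onset_s,
      anticipatory_drift_rate = anticipatory_drift_rate,
      switch_cost_bias = switch_cost_bias,
      miss_prob = miss_prob,
      outlier_prob = outlier_prob,
      outlier_scale = outlier_scale,
      participant_bias_sd = participant_bias_sd
    ),
    class = "generator_params"
  )
}

#' Generator presets for the two study-design groups
#'
#' `params_block()` is the plain generator: degradation confined to the
#' continuation phase, so the cycle-averaged trend changes only at metronome
#' offset. `params_alternating()` adds a mode-switch cost of 23 ms and an
#' anticipatory pacing-bias ramp starting 10 s into the trial, emulating the
#' earlier entrainment breakdown seen under trial-by-trial mode switching.
#'
#' @param ... Overrides passed to [generator_params()].
#' @return A `generator_params` object.
#' @export
params_block <- function(...) generator_params(...)

#' @rdname params_block
#' @export
params_alternating <- function(...) {
  args <- list(...)
  defaults <- list(
    switch_cost_bias = 23,
    anticipatory_drift_onset_s = 10,
    anticipatory_drift_rate = 5
  )
  do.call(generator_params, utils::modifyList(defaults, args))
}

#' Zero-noise generator parameters
#'
#' All biases, SDs, drift and corruption rates set to zero: taps land exactly
#' on their targets. Useful for contract tests.
#'
#' @param ... Overrides passed to [generator_params()].
#' @return A `generator_params` object.
#' @export
params_zero_noise <- function(...) {
  args <- utils::modifyList(
    list(
      pacing_bias = 0, pacing_sd = 0, continuation_timekeeper_sd = 0,
      continuation_drift = 0, switch_cost_bias = 0,
      miss_prob = 0, outlier_prob = 0, participant_bias_sd = 0
    ),
    list(...)
  )
  do.call(generator_params, args)
}

#' Metronome beat onsets for a trial
#'
#' Beats sound only during the pacing phase, at `0, T, 2T, ...`.
#'
#' @param design A [task_design()].
#' @return Numeric vector of `pacing_cycles` onset times in ms.
#' @examples
#' make_metronome(task_design(pacing_cycles = 4, inter_beat_interval = 500))
#' @export
make_metronome <- function(design) {
  stopifnot(inherits(design, "task_design"))
  (seq_len(design$pacing_cycles) - 1) * design$inter_beat_interval
}

# Expected systematic deviation must stay well inside half a period or taps
# can no longer be attributed to their cycle.
check_params_feasible <- function(design, params) {
  worst_bias <- abs(params$pacing_bias) + abs(params$switch_cost_bias) +
    2 * params$pacing_sd
  if (worst_bias > design$inter_beat_interval / 2) {
    stop(
      "generator parameters imply expected pacing deviations beyond T/2 (",
      round(worst_bias, 1), " ms > ", design$inter_beat_interval / 2,
      " ms); cycle assignment would break",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Simulate one tapping trial
#'
#' @param design A [task_design()].
#' @param params A [generator_params()].
#' @param mode `"synchronized"` or `"syncopated"`.
#' @param trial_index 1-based trial number.
#' @param after_switch Did the previous trial use the other mode? Adds
#'   `switch_cost_bias` to the pacing bias.
#' @param participant_bias Participant-level bias offset, ms (default 0).
#'
#' @return A tibble of tap events with columns `trial`, `cycle`, `mode`,
#'   `phase`, `target_ms`, `tap_ms`, `raw_tap_ms`. Missed taps are absent.
#' @export
simulate_trial <- function(design, params, mode = c("synchronized", "syncopated"),
                           trial_index = 1L, after_switch = FALSE,
                           participant_bias = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "task_design"), inherits(params, "generator_params"))
  check_params_feasible(design, params)

  ibi <- design$inter_beat_interval
  n_pace <- design$pacing_cycles
  n_cont <- design$continuation_cycles
  cycles <- seq_len(n_pace + n_cont) - 1L
  offset <- if (mode == "synchronized") 0 else ibi / 2
  targets <- cycles * ibi + offset

  bias <- params$pacing_bias + participant_bias +
    if (after_switch) params$switch_cost_bias else 0
  # anticipatory ramp: extra bias on pacing cycles at/after the onset time
  onset_cycle <- params$anticipatory_drift_onset_s * 1000 / ibi
  ramp <- params$anticipatory_drift_rate * pmax(0, cycles[seq_len(n_pace)] - onset_cycle)

  pace_taps <- targets[seq_len(n_pace)] + bias + ramp +
    rnorm(n_pace, 0, params$pacing_sd)

  # The first unpaced interval still reproduces the just-heard period; the
  # timekeeper's systematic drift accrues from the second unpaced interval
  # on, so the cycle-averaged trend changes slope exactly at continuation
  # onset (the first unpaced tap's cycle).
  drift <- params$continuation_drift * c(0, rep(1, max(0, n_cont - 1)))
  intervals <- ibi + drift +
    rnorm(n_cont, 0, params$continuation_timekeeper_sd)
  cont_taps <- pace_taps[n_pace] + cumsum(intervals)

  taps <- c(pace_taps, cont_taps)

  is_outlier <- runif(length(taps)) < params$outlier_prob
  taps[is_outlier] <- targets[is_outlier] +
    (taps[is_outlier] - targets[is_outlier]) * params$outlier_scale

  keep <- runif(length(taps)) >= params$miss_prob

  tibble::tibble(
    trial = as.integer(trial_index),
    cycle = cycles,
    mode = mode,
    phase = cycle_phases(design),
    target_ms = targets,
    tap_ms = taps,
    raw_tap_ms = taps + design$device_delay
  )[keep, ]
}

#' Simulate a full session for one participant
#'
#' Runs every trial of the design's [trial_schedule()], applying the
#' mode-switch cost on trials whose predecessor used the other mode.
#'
#' @param design A [task_design()].
#' @param params A [generator_params()].
#' @param participant_id Identifier recorded in the output.
#' @param seed Integer seed for this session.
#' @return A tidy tibble of tap events with columns `participant_id`,
#'   `design`, `mode`, `phase`, `trial`, `cycle`, `raw_tap_ms`, `tap_ms`,
#'   `target_ms`.
#' @export
simulate_session <- function(design, params, participant_id = "P01", seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  set.seed(as.integer(seed))
  sched <- trial_schedule(design)
  p_bias <- if (params$participant_bias_sd > 0) {
    rnorm(1, 0, params$participant_bias_sd)
  } else {
    0
  }
  trials <- lapply(seq_len(nrow(sched)), function(j) {
    after_switch <- j > 1 && sched$mode[j] != sched$mode[j - 1]
    simulate_trial(design, params,
      mode = sched$mode[j], trial_index = sched$trial[j],
      after_switch = after_switch, participant_bias = p_bias
    )
  })
  out <- dplyr::bind_rows(trials)
  tibble::tibble(
    participant_id = participant_id,
    design = design$design_kind,
    mode = out$mode,
    phase = out$phase,
    trial = out$trial,
    cycle = out$cycle,
    raw_tap_ms = out$raw_tap_ms,
    tap_ms = out$tap_ms,
    target_ms = out$target_ms
  )
}

# Fixed master-seed -> participant sub-seed splitting rule. Indexed by the
# participant's global position so adding participants never reshuffles
# earlier ones. Kept below 2^31 - 1.
participant_seed <- function(master_seed, index) {
  (as.numeric(master_seed) * 10007 + 7919 * index) %% (2^31 - 1)
}

#' Simulate a cohort of block- and alternating-design participants
#'
#' Mirrors the study structure: `n_block` participants perform the task with
#' trials blocked by mode, `n_alternating` with modes alternating every
#' trial. Mode order is counterbalanced within each group by participant
#' index. Each participant gets a sub-seed derived deterministically from the
#' master seed, so output is bit-reproducible and extending the cohort never
#' changes earlier participants.
#'
#' @param n_block,n_alternating Group sizes (the study used 10 and 13).
#' @param params_block_group,params_alt_group [generator_params()] for each
#'   group; defaults [params_block()] and [params_alternating()].
#' @param seed Master integer seed.
#' @param design_template A [task_design()] supplying everything except
#'   `design_kind`/`mode_order` (default [task_design()]).
#' @return A tidy tap-event tibble (one row per registered tap) covering all
#'   participants; see [simulate_session()] for columns.
#' @examples
#' taps <- simulate_cohort(2, 2, seed = 1)
#' dplyr::count(taps, design, mode, phase)
#' @export
simulate_cohort <- function(n_block = 10, n_alternating = 13,
                            params_block_group = params_block(),
                            params_alt_group = params_alternating(),
                            seed = 1L,
                            design_template = task_design()) {
  stopifnot(n_block >= 0, n_alternating >= 0, n_block + n_alternating >= 1)
  groups <- list(
    list(kind = "blocked", n = n_block, params = params_block_group, prefix = "B"),
    list(kind = "alternating", n = n_alternating, params = params_alt_group, prefix = "A")
  )
  sessions <- list()
  idx <- 0L
  for (g in groups) {
    if (g$n == 0) next
    for (i in seq_len(g$n)) {
      idx <- idx + 1L
      d <- design_template
      d$design_kind <- g$kind
      d$mode_order <- counterbalanced_mode_order(i)
      sessions[[idx]] <- simulate_session(
        d, g$params,
        participant_id = sprintf("%s%02d", g$prefix, i),
        seed = participant_seed(seed, idx)
      )
    }
  }
  dplyr::bind_rows(sessions)
}
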