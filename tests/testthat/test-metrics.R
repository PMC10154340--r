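test_that("device-delay correction subtracts the constant latency", {
  expect_equal(correct_device_delay(c(1025, 2025), 25), c(1000, 2000))
  expect_equal(correct_device_delay(c(3, 1, 2), 0), c(3, 1, 2))
  expect_equal(correct_device_delay(100, 25), 75)
})

test_that("target times follow the metronome grid, extrapolated through continuation", {
  d <- task_design(pacing_cycles = 3, continuation_cycles = 2)
  expect_equal(target_times(d, "synchronized"), c(0, 1000, 2000, 3000, 4000))
  expect_equal(target_times(d, "syncopated"), c(500, 1500, 2500, 3500, 4500))
  # continuation targets continue the same arithmetic sequence
  expect_equal(target_times(d, "synchronized", "continuation"), c(3000, 4000))
  expect_equal(
    target_times(d, "syncopated", "all"),
    c(target_times(d, "syncopated", "pacing"), target_times(d, "syncopated", "continuation"))
  )
})

test_that("exact taps match perfectly and absences are reported", {
  targets <- c(0, 1000, 2000, 3000)
  m <- match_taps(targets, targets)
  expect_equal(m$pairs$tap, targets)
  expect_length(m$unmatched_taps, 0)
  expect_length(m$missed_targets, 0)

  m2 <- match_taps(c(10, 2020, 2980), targets)
  expect_equal(m2$missed_targets, 2L)
  expect_equal(m2$pairs$target_index, c(1L, 3L, 4L))
})

test_that("competing taps resolve to the closer one, matching exhaustive assignment", {
  targets <- c(0, 1000, 2000)
  cases <- list(
    list(taps = c(940, 1030)), # both nearest target 2
    list(taps = c(960, 1100, 2050)),
    list(taps = c(-100, 80, 1010)),
    list(taps = c(450, 520)) # straddling a midpoint
  )
  for (case in cases) {
    got <- match_taps(case$taps, targets, window = 500)
    oracle <- brute_force_match(case$taps, targets, window = 500)
    matched <- !is.na(oracle)
    expect_equal(got$pairs$tap, case$taps[matched])
    expect_equal(got$pairs$target_index, oracle[matched])
  }
})

test_that("window wider than half the target spacing is refused", {
  expect_error(match_taps(0, c(0, 1000), window = 600), "window")
})

test_that("asynchrony uses tap - target with anticipation negative", {
  taps <- zero_noise_cohort()
  a <- asynchrony(taps)
  expect_equal(a$asynchrony_ms, rep(0, nrow(a)))

  shifted <- dplyr::mutate(taps, tap_ms = tap_ms - 30)
  expect_equal(asynchrony(shifted)$asynchrony_ms, rep(-30, nrow(taps)))
  late <- dplyr::mutate(taps, tap_ms = tap_ms + 50)
  expect_equal(asynchrony(late)$asynchrony_ms, rep(50, nrow(taps)))
})

test_that("asynchrony is equivariant under constant time shifts", {
  taps <- simulate_cohort(1, 0, seed = 2)
  base <- asynchrony(taps)$asynchrony_ms
  for (c_shift in c(-17.5, 3, 120)) {
    shifted <- dplyr::mutate(taps, tap_ms = tap_ms + c_shift)
    expect_equal(asynchrony(shifted)$asynchrony_ms, base + c_shift)
  }
})

test_that("zero-noise syncopated tapping has identically zero virtual asynchrony", {
  taps <- zero_noise_cohort(design = task_design(mode_order = "syncopation_first"))
  sync_taps <- taps[taps$mode == "syncopated", ]
  expect_gt(nrow(sync_taps), 0)
  expect_equal(asynchrony(sync_taps)$asynchrony_ms, rep(0, nrow(sync_taps)))
})

test_that("inter-response intervals are successive differences on consecutive cycles", {
  expect_equal(iri(c(0, 1000, 2000))$iri_ms, c(1000, 1000))
  expect_equal(iri(c(0, 980, 2010))$iri_ms, c(980, 1030))
  # cycle 2 missing: the c1 -> c3 gap is excluded
  r <- iri(c(0, 1000, 3010), cycles = c(0L, 1L, 3L))
  expect_equal(r$iri_ms, 1000)
  expect_equal(r$cycle, 1L)
  expect_error(iri(c(0, 2000, 1000)), "strictly increasing")
  expect_equal(nrow(iri(numeric(0))), 0)
})

test_that("mean IRI of strictly periodic taps equals the period exactly", {
  taps <- zero_noise_cohort()
  ev <- iri_events(taps)
  expect_equal(mean(ev$iri_ms), 1000)
  expect_equal(unique(ev$iri_ms), 1000)
  # interval spanning continuation onset belongs to continuation
  first_unpaced <- ev[ev$cycle == 15, ]
  expect_equal(unique(first_unpaced$phase), "continuation")
})

test_that("continuation IRI variance recovers the timekeeper variance", {
  p <- generator_params(
    pacing_sd = 0, pacing_bias = 0, continuation_drift = 0,
    continuation_timekeeper_sd = 30, miss_prob = 0, outlier_prob = 0
  )
  taps <- simulate_cohort(10, 0, params_block_group = p, seed = 9)
  cont <- iri_events(taps)
  cont <- cont[cont$phase == "continuation" & cont$cycle > 15, ]
  n <- nrow(cont)
  # sample variance of N(0, 900): SE ~ 900 * sqrt(2/(n-1))
  expect_lt(abs(var(cont$iri_ms) - 900), 3 * 900 * sqrt(2 / (n - 1)))
})

test_that("condition summaries report mean and SD per cell", {
  ev <- tibble::tibble(
    design = "blocked", mode = "synchronized",
    phase = rep(c("pacing", "continuation"), each = 2),
    x = c(7, 7, -1, 1)
  )
  s <- summarize_conditions(ev, "x")
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_ms[s$phase == "pacing"], 7)
  expect_equal(s$sd_ms[s$phase == "pacing"], 0)
  expect_equal(s$mean_ms[s$phase == "continuation"], 0)
})

test_that("a zero-noise biased generator yields condition mean exactly the bias", {
  taps <- zero_noise_cohort(pacing_bias = -30)
  s <- summarize_conditions(asynchrony(taps), "asynchrony_ms")
  expect_equal(s$mean_ms[s$phase == "pacing"], rep(-30, sum(s$phase == "pacing")))
  expect_equal(s$sd_ms[s$phase == "pacing"], rep(0, sum(s$phase == "pacing")))
})
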