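# Small designs and cohorts used across tests. Everything is generated in
# code; no fixture files.

tiny_design <- function(...) {
  task_design(
    pacing_cycles = 5, continuation_cycles = 4, trials_per_mode = 2,
    ...
  )
}

zero_noise_cohort <- function(n_block = 1, n_alternating = 0, seed = 1,
                              design = task_design(), ...) {
  p <- params_zero_noise(...)
  simulate_cohort(n_block, n_alternating,
    params_block_group = p, params_alt_group = p,
    seed = seed, design_template = design
  )
}

# Brute-force minimal-total-distance assignment of taps to targets within a
# window; independent oracle for match_taps on tiny inputs.
brute_force_match <- function(taps, targets, window) {
  best <- NULL
  best_cost <- Inf
  best_n <- -1L
  k <- length(taps)
  # enumerate all injective partial assignments tap -> target
  assignments <- list(integer(0))
  for (i in seq_len(k)) {
    new <- list()
    for (a in assignments) {
      new[[length(new) + 1]] <- c(a, NA_integer_) # tap i unmatched
      for (j in setdiff(seq_along(targets), a[!is.na(a)])) {
        if (abs(taps[i] - targets[j]) <= window) {
          new[[length(new) + 1]] <- c(a, j)
        }
      }
    }
    assignments <- new
  }
  for (a in assignments) {
    matched <- !is.na(a)
    n <- sum(matched)
    cost <- sum(abs(taps[matched] - targets[a[matched]]))
    # maximise matches, then minimise total distance
    if (n > best_n || (n == best_n && cost < best_cost)) {
      best <- a
      best_n <- n
      best_cost <- cost
    }
  }
  best
}
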