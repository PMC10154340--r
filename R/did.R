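#' Observations for the difference-in-differences estimator
#'
#' Recodes trial-phase means into the two-group, two-period layout of a DID
#' analysis of study design: the block design is the control group
#' (`group = 0`), the alternating design the manipulated group
#' (`group = 1`); pacing is the pre period (`time = 0`), continuation the
#' post period (`time = 1`). Tapping mode is deliberately not a covariate:
#' it is balanced over time within every participant, so it cannot confound
#' the design contrast.
#'
#' @param trial_means Tibble with columns `design`, `phase`, `value_ms`
#'   (e.g. `preprocess_cohort()$trial_means`).
#' @return Tibble with columns `outcome`, `group` (0/1), `time` (0/1).
#' @export
did_observations <- function(trial_means) {
  stopifnot(all(c("design", "phase", "value_ms") %in% names(trial_means)))
  tibble::tibble(
    outcome = trial_means$value_ms,
    group = as.integer(trial_means$design == "alternating"),
    time = as.integer(trial_means$phase == "continuation")
  )
}

check_did_cells <- function(observations) {
  cells <- expand.grid(group = 0:1, time = 0:1)
  for (r in seq_len(nrow(cells))) {
    if (!any(observations$group == cells$group[r] &
      observations$time == cells$time[r])) {
      stop(
        "empty DID cell: group=", cells$group[r], " (",
        ifelse(cells$group[r] == 1, "alternating", "block"),
        "), time=", cells$time[r], " (",
        ifelse(cells$time[r] == 1, "continuation", "pacing"), ")",
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Design matrix for the DID regression
#'
#' Canonical two-period, two-group coding: intercept, time dummy, group
#' dummy, and their interaction. The returned `mapping` records how these
#' columns correspond to the conventional report row labels
#' (Constant / Block / Alternating / Block x Alternating): the time dummy
#' carries the control (block) group's temporal change, the group dummy the
#' alternating group's offset, and the interaction the causal DID effect.
#'
#' @param observations Tibble from [did_observations()].
#' @return List with `X` (n x 4 matrix), `y` (outcomes) and `mapping`
#'   (named character vector, column -> report label).
#' @export
build_did_matrix <- function(observations) {
  stopifnot(all(c("outcome", "group", "time") %in% names(observations)))
  check_did_cells(observations)
  X <- cbind(
    intercept = 1,
    time = observations$time,
    group = observations$group,
    time_x_group = observations$time * observations$group
  )
  list(
    X = X,
    y = observations$outcome,
    mapping = c(
      intercept = "Constant", time = "Block",
      group = "Alternating", time_x_group = "Block x Alternating"
    )
  )
}

#' Fit the difference-in-differences model by OLS
#'
#' Estimates `Y = b0 + b1*time + b2*group + b3*time*group + e`. Under
#' parallel trends — both design groups would have followed the same
#' pacing-to-continuation change absent the manipulation — `b3` is the
#' causal effect of the alternating design on the outcome. Parallel trends
#' is an identifying assumption and is documented, not tested. Standard
#' errors are conventional OLS; note that trial-level observations within a
#' participant are not independent, so these SEs are anti-conservative.
#'
#' @param observations Tibble from [did_observations()].
#' @return A `did_result`: list with `coefficients` (tibble `term`, `label`,
#'   `estimate`, `se`, `t`, `p`), `r_squared`, `f_overall`, `n`,
#'   `residual_kurtosis`, `residual_skewness`, and the underlying `fit`.
#'   On a balanced noiseless 2x2 table the interaction estimate equals the
#'   difference-of-differences of the four cell means exactly.
#' @export
fit_did <- function(observations) {
  m <- build_did_matrix(observations)
  dat <- data.frame(outcome = m$y, time = observations$time, group = observations$group)
  fit <- lm(outcome ~ time * group, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  res <- residuals(fit)
  m2 <- mean(res^2)
  skew <- if (m2 > 0) mean(res^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean(res^4) / m2^2 else NA_real_
  fstat <- sm$fstatistic
  terms <- c("intercept", "time", "group", "time_x_group")
  structure(
    list(
      coefficients = tibble::tibble(
        term = terms,
        label = unname(m$mapping[terms]),
        estimate = unname(co[, 1]),
        se = unname(co[, 2]),
        t = unname(co[, 3]),
        p = unname(co[, 4])
      ),
      r_squared = sm$r.squared,
      f_overall = if (!is.null(fstat)) {
        list(
          statistic = unname(fstat[1]), df1 = unname(fstat[2]),
          df2 = unname(fstat[3])
        )
      },
      n = nrow(dat),
      residual_kurtosis = kurt,
      residual_skewness = skew,
      fit = fit
    ),
    class = "did_result"
  )
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf(
    "<did_result> n = %d, R^2 = %.3f, residual kurtosis %.2f / skewness %.2f\n",
    x$n, x$r_squared, x$residual_kurtosis, x$residual_skewness
  ))
  print(x$coefficients)
  invisible(x)
}

#' Tabular DID report
#'
#' Four coefficient rows under the conventional labels plus the observation
#' count, ready to write as CSV. When the fit is noiseless the standard
#' errors are zero and the rows are flagged degenerate.
#'
#' @param result A `did_result` from [fit_did()].
#' @return Tibble with columns `row`, `beta`, `se`, `t`, `p`, `degenerate`.
#' @export
did_report <- function(result) {
  stopifnot(inherits(result, "did_result"))
  co <- result$coefficients
  tibble::tibble(
    row = c(co$label, "Obs"),
    beta = c(co$estimate, NA_real_),
    se = c(co$se, NA_real_),
    t = c(co$t, NA_real_),
    p = c(co$p, NA_real_),
    degenerate = c(co$se <= 1e-10 * pmax(1, abs(co$estimate)), NA)
  ) |>
    dplyr::mutate(beta = ifelse(.data$row == "Obs", result$n, .data$beta))
}
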