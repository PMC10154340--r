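#' Cycle-averaged temporal trend of a timing statistic
#'
#' Averages a per-tap statistic by cycle position: first across trials
#' within each participant, then across participants within each grouping
#' cell (participants-then-grand-mean). The grid time of cycle `i` is
#' `i * T` seconds (0-based, 1 Hz default), so with the default design the
#' continuation phase starts at 15 s.
#'
#' @param taps Tap-event tibble (see [simulate_cohort()]).
#' @param statistic `"asynchrony"` or `"iri"`.
#' @param by Grouping columns (default `"design"`; use
#'   `c("design", "mode")` for per-mode trends).
#' @param filter_outliers Reject gross errors by the Tukey-fence rule before
#'   averaging (default TRUE); a handful of device glitches would otherwise
#'   dominate a cycle mean. Fences are computed within participant x design
#'   x mode x phase x cycle cells — including the cycle position keeps a
#'   systematic within-phase drift (the very signal the growth model fits)
#'   out of the outlier criterion.
#' @param k IQR multiplier for that filter (default 1.5).
#' @return Tibble with the grouping columns plus `cycle`, `time_s`,
#'   `value_ms`, `n_participants`. Cycles with no data in a cell are absent.
#' @export
cycle_average <- function(taps, statistic = c("asynchrony", "iri"),
                          by = "design", filter_outliers = TRUE, k = 1.5) {
  statistic <- match.arg(statistic)
  events <- if (statistic == "asynchrony") {
    asynchrony(taps) |> dplyr::rename(value_ms = "asynchrony_ms")
  } else {
    iri_events(taps) |> dplyr::rename(value_ms = "iri_ms")
  }
  stopifnot(all(by %in% names(events)))
  if (filter_outliers) {
    events <- iqr_filter(events, "value_ms",
      by = c("participant_id", "design", "mode", "phase", "cycle"), k = k
    )$kept
  }
  ibi_s <- infer_period_s(taps)
  per_participant <- events |>
    dplyr::group_by(
      dplyr::across(dplyr::all_of(c(by, "participant_id", "cycle")))
    ) |>
    dplyr::summarise(value_ms = mean(.data$value_ms), .groups = "drop")
  per_participant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "cycle")))) |>
    dplyr::summarise(
      value_ms = mean(.data$value_ms),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(time_s = .data$cycle * ibi_s, .before = "value_ms") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "cycle"))))
}

# Nominal period in seconds from the target grid (median spacing per trial).
infer_period_s <- function(taps) {
  one <- taps[taps$participant_id == taps$participant_id[1] &
    taps$trial == taps$trial[1], ]
  if (nrow(one) < 2) {
    return(1)
  }
  median(diff(sort(one$target_ms)) / diff(sort(one$cycle))) / 1000
}

#' Fit a cubic-spline growth-curve model to a cycle series
#'
#' Fits a cubic smoothing spline to the cycle-averaged trend. By default the
#' smoothing level is chosen by generalized cross-validation; `smoothing = 0`
#' requests exact natural-cubic interpolation of the points, and a positive
#' `smoothing` is passed through as the `spar` smoothing parameter. The fit
#' has a continuous second derivative, which is what the turning-point
#' estimator interrogates.
#'
#' @param series A tibble with `time_s` and `value_ms` columns (one grouping
#'   cell of [cycle_average()]), or numeric vectors via `time_s`/`value_ms`.
#' @param smoothing `NULL` (GCV), `0` (interpolation), or a `spar` value in
#'   (0, 1.5].
#' @return A `growth_spline` object with `predict(object, t, deriv)` support.
#' @export
fit_growth_spline <- function(series, smoothing = NULL) {
  stopifnot(all(c("time_s", "value_ms") %in% names(series)))
  ok <- is.finite(series$time_s) & is.finite(series$value_ms)
  x <- series$time_s[ok]
  y <- series$value_ms[ok]
  if (length(x) < 5) {
    stop("need at least 5 non-missing points to fit a growth spline",
      call. = FALSE
    )
  }
  if (is.unsorted(x, strictly = TRUE)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  if (!is.null(smoothing) && smoothing == 0) {
    fun <- stats::splinefun(x, y, method = "natural")
    engine <- list(kind = "interpolating", fun = fun)
  } else {
    fit <- if (is.null(smoothing)) {
      # GCV on short series can degenerate to spar < 0 (rougher than the
      # unpenalized fit, i.e. interpolation of the noise); restrict the
      # search to non-negative smoothing
      smooth.spline(x, y,
        cv = FALSE, all.knots = TRUE,
        control.spar = list(low = 0)
      )
    } else {
      smooth.spline(x, y, spar = smoothing, all.knots = TRUE)
    }
    engine <- list(kind = "smoothing", fit = fit)
  }
  structure(
    list(engine = engine, range = range(x), x = x, y = y),
    class = "growth_spline"
  )
}

#' Evaluate a growth spline or one of its derivatives
#'
#' @param object A `growth_spline`.
#' @param t Times (s) at which to evaluate; default the fitted grid.
#' @param deriv Derivative order 0, 1 or 2.
#' @param ... Unused.
#' @return Numeric vector of values.
#' @export
predict.growth_spline <- function(object, t = object$x, deriv = 0, ...) {
  stopifnot(deriv %in% 0:2)
  if (object$engine$kind == "interpolating") {
    object$engine$fun(t, deriv = deriv)
  } else {
    predict(object$engine$fit, x = t, deriv = deriv)$y
  }
}

#' @export
print.growth_spline <- function(x, ...) {
  cat(sprintf(
    "<growth_spline> %s fit on %d points over [%g, %g] s\n",
    x$engine$kind, length(x$x), x$range[1], x$range[2]
  ))
  invisible(x)
}

#' Turning points of a growth-curve fit
#'
#' Evaluates the model's second derivative on a dense grid and reports the
#' local maxima of (signed) curvature: times where the trend accelerates
#' most sharply, interpreted as the onset of a behavioral change. The global
#' maximum is the primary turning point; secondary local maxima above
#' `rel_threshold` of the global maximum are also reported. A near-constant
#' second derivative (e.g. a linear or purely quadratic trend) yields a
#' degenerate "no turning point" result.
#'
#' @param model A `growth_spline` from [fit_growth_spline()].
#' @param grid_step Spacing of the evaluation grid in seconds (default 0.1).
#' @param rel_threshold Secondary maxima must reach this fraction of the
#'   global maximum curvature (default 0.5).
#' @return A `turning_points` object: list with `turning_points` (tibble
#'   `time_s`, `curvature`, ordered by decreasing curvature), `primary_s`
#'   (numeric, `NA` if degenerate), `degenerate` (flag) and `grid` (tibble
#'   `time_s`, `value_ms`, `second_deriv`).
#' @export
turning_points <- function(model, grid_step = 0.1, rel_threshold = 0.5) {
  stopifnot(inherits(model, "growth_spline"), grid_step > 0)
  t <- seq(model$range[1], model$range[2], by = grid_step)
  d2 <- predict(model, t, deriv = 2)
  value <- predict(model, t, deriv = 0)
  grid <- tibble::tibble(time_s = t, value_ms = value, second_deriv = d2)

  # Degenerate when curvature is essentially constant (linear or purely
  # quadratic trends). Judged over the central 80% of the span: natural
  # boundary conditions force the second derivative toward zero at the ends
  # even when the true curvature is a nonzero constant.
  central <- d2[t >= model$range[1] + 0.1 * diff(model$range) &
    t <= model$range[2] - 0.1 * diff(model$range)]
  y_scale <- max(1, max(abs(model$y)))
  flat <- diff(range(central)) <=
    max(1e-8 * y_scale, 0.1 * max(abs(central), 1e-12))
  if (flat) {
    return(structure(
      list(
        turning_points = tibble::tibble(time_s = numeric(), curvature = numeric()),
        primary_s = NA_real_, degenerate = TRUE, grid = grid
      ),
      class = "turning_points"
    ))
  }

  n <- length(d2)
  interior <- which(d2[2:(n - 1)] > d2[1:(n - 2)] & d2[2:(n - 1)] >= d2[3:n]) + 1L
  # boundary points count when the curve falls away from them
  if (d2[1] > d2[2]) interior <- c(1L, interior)
  if (d2[n] > d2[n - 1]) interior <- c(interior, n)
  cand <- tibble::tibble(time_s = t[interior], curvature = d2[interior])
  global_max <- max(cand$curvature)
  cand <- cand[cand$curvature >= rel_threshold * global_max & cand$curvature > 0, ]
  cand <- cand[order(-cand$curvature), ]
  structure(
    list(
      turning_points = cand,
      primary_s = if (nrow(cand)) cand$time_s[1] else NA_real_,
      degenerate = FALSE,
      grid = grid
    ),
    class = "turning_points"
  )
}

#' @export
print.turning_points <- function(x, ...) {
  if (x$degenerate || !nrow(x$turning_points)) {
    cat("<turning_points> no turning point (near-constant curvature)\n")
  } else {
    cat(sprintf(
      "<turning_points> primary at %.1f s; %d supra-threshold maxima\n",
      x$primary_s, nrow(x$turning_points)
    ))
  }
  invisible(x)
}
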