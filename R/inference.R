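#' Build the regression input for a timing outcome
#'
#' Assembles the model frame and formula for the multiple linear regression
#' of a timing statistic on tapping mode, maintenance phase and study
#' design. Factors are dummy coded with reference levels synchronized,
#' pacing and blocked; by default all two-way interactions enter the model.
#'
#' @param trial_means Tibble with one observation per trial-phase (columns
#'   `mode`, `phase`, `design`, `value_ms`), e.g.
#'   `preprocess_cohort()$trial_means`.
#' @param interactions Include all two-way interactions (default TRUE)?
#' @return A `regression_input` object: list with `data` (model frame) and
#'   `formula`.
#' @export
regression_input <- function(trial_means, interactions = TRUE) {
  needed <- c("mode", "phase", "design", "value_ms")
  stopifnot(all(needed %in% names(trial_means)))
  data <- trial_means |>
    dplyr::mutate(
      mode = factor(.data$mode, levels = c("synchronized", "syncopated")),
      phase = factor(.data$phase, levels = c("pacing", "continuation")),
      design = factor(.data$design, levels = c("blocked", "alternating"))
    )
  if (any(is.na(data$mode) | is.na(data$phase) | is.na(data$design))) {
    stop("unrecognized mode/phase/design labels", call. = FALSE)
  }
  # factors with a single observed level (e.g. a one-design cohort) carry no
  # information and would make the fit rank deficient
  varying <- c("mode", "phase", "design")[vapply(
    data[c("mode", "phase", "design")],
    function(f) length(unique(f)) > 1, logical(1)
  )]
  rhs <- if (length(varying) == 0) {
    "1"
  } else if (interactions && length(varying) > 1) {
    paste0("(", paste(varying, collapse = " + "), ")^2")
  } else {
    paste(varying, collapse = " + ")
  }
  structure(
    list(data = data, formula = as.formula(paste("value_ms ~", rhs))),
    class = "regression_input"
  )
}

#' Fit the timing regression by ordinary least squares
#'
#' @param input A [regression_input()], or any list with `data` and
#'   `formula` elements.
#' @return A `tapsync_mlr` object: list with the underlying `lm` fit,
#'   `coefficients` (tibble: term, estimate, se, t, p), `r_squared`,
#'   `f_overall` (statistic, df1, df2, p) and `n`.
#' @export
fit_ols <- function(input) {
  stopifnot(is.list(input), !is.null(input$data), !is.null(input$formula))
  fit <- lm(input$formula, data = input$data)
  if (anyNA(coef(fit))) {
    stop(
      "design matrix is rank deficient; collinear columns: ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
      call. = FALSE
    )
  }
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  structure(
    list(
      fit = fit,
      coefficients = tibble::tibble(
        term = rownames(co),
        estimate = unname(co[, 1]), se = unname(co[, 2]),
        t = unname(co[, 3]), p = unname(co[, 4])
      ),
      r_squared = sm$r.squared,
      f_overall = if (!is.null(fstat)) {
        list(
          statistic = unname(fstat[1]),
          df1 = unname(fstat[2]), df2 = unname(fstat[3]),
          p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
        )
      },
      n = nrow(input$data)
    ),
    class = "tapsync_mlr"
  )
}

#' @export
print.tapsync_mlr <- function(x, ...) {
  cat(sprintf(
    "<tapsync_mlr> n = %d, R^2 = %.3f, F(%g, %g) = %.2f\n",
    x$n, x$r_squared, x$f_overall$df1, x$f_overall$df2, x$f_overall$statistic
  ))
  print(x$coefficients)
  invisible(x)
}

#' Per-effect F tests and partial eta-squared
#'
#' Type-III (marginal) F tests: each term's sum of squares is its marginal
#' contribution under sum-to-zero contrasts, so main effects are testable in
#' the presence of interactions. Partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param model A `tapsync_mlr` from [fit_ols()].
#' @return Tibble with columns `term`, `df`, `sum_sq`, `f`, `p`,
#'   `partial_eta_sq`.
#' @export
effect_table <- function(model) {
  stopifnot(inherits(model, "tapsync_mlr"))
  fit <- model$fit
  # refit under sum contrasts so Type-III marginal SS are meaningful
  dat <- fit$model
  fac <- names(dat)[vapply(dat, is.factor, logical(1))]
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  fit3 <- lm(stats::formula(fit), data = dat, contrasts = contr)
  tab <- car::Anova(fit3, type = 3)
  tab <- tab[!rownames(tab) %in% c("(Intercept)"), , drop = FALSE]
  ss_err <- tab["Residuals", "Sum Sq"]
  eff <- tab[rownames(tab) != "Residuals", , drop = FALSE]
  tibble::tibble(
    term = rownames(eff),
    df = eff$Df,
    sum_sq = eff$`Sum Sq`,
    f = eff$`F value`,
    p = eff$`Pr(>F)`,
    partial_eta_sq = eff$`Sum Sq` / (eff$`Sum Sq` + ss_err)
  )
}

#' Tukey honestly-significant-difference pairwise contrasts
#'
#' All pairwise mean differences between groups with studentized-range
#' critical values, the standard post-hoc family for a one-way layout.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (coerced to factor), same length.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble with columns `contrast`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(
    length(values) == length(groups),
    nlevels(groups) >= 2,
    all(table(groups) >= 2),
    alpha > 0, alpha < 1
  )
  df <- data.frame(y = values, g = groups)
  tk <- TukeyHSD(aov(y ~ g, data = df), conf.level = 1 - alpha)$g
  tibble::tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
}

#' Post-hoc power of a multiple-regression F test
#'
#' Power of the overall F test of a regression with `predictors` predictors
#' at sample size `n`, for effect size Cohen's f: the probability that a
#' noncentral F variate with `df1 = predictors`,
#' `df2 = n - predictors - 1` and noncentrality `f^2 * n` exceeds the
#' central-F critical value at level `alpha`.
#'
#' @param effect_size_f Cohen's f (>= 0). Conventional benchmarks used in
#'   power analyses of this design are 0.14 (small), 0.39 (medium) and
#'   0.59 (large).
#' @param n Sample size; must exceed `predictors + 1`.
#' @param predictors Number of predictors (default 3).
#' @param alpha Significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @examples
#' posthoc_power(0.39, n = 23, predictors = 3)
#' @export
posthoc_power <- function(effect_size_f, n, predictors = 3, alpha = 0.05) {
  stopifnot(effect_size_f >= 0, alpha > 0, alpha < 1, predictors >= 1)
  if (n <= predictors + 1) {
    stop("n must exceed predictors + 1 for a residual df", call. = FALSE)
  }
  df1 <- predictors
  df2 <- n - predictors - 1
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = effect_size_f^2 * n, lower.tail = FALSE)
}

#' Power table over the conventional effect-size benchmarks
#'
#' @param n Sample size (default 23).
#' @param predictors Number of predictors (default 3).
#' @param alpha Significance level (default 0.05).
#' @param f Named vector of Cohen's f values
#'   (default small/medium/large = 0.14/0.39/0.59).
#' @return Tibble with columns `label`, `cohens_f`, `power`.
#' @export
power_table <- function(n = 23, predictors = 3, alpha = 0.05,
                        f = c(small = 0.14, medium = 0.39, large = 0.59)) {
  tibble::tibble(
    label = names(f),
    cohens_f = unname(f),
    power = vapply(f, posthoc_power,
      numeric(1),
      n = n, predictors = predictors, alpha = alpha
    )
  )
}
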