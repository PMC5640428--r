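#' Reversal potential and conductance from an IV curve
#'
#' Ordinary least-squares regression of peak IPSC amplitude on holding
#' potential, `amplitude = m V + b`.  The intercept of the fitted line with
#' the voltage axis, `-b / m`, is the reversal potential (for GABA-evoked
#' currents, E_GABA, set chiefly by intracellular chloride); the slope `m` is
#' the synaptic conductance in input units (pA/mV; the source literature
#' labels these values pS, which is echoed, not converted).
#'
#' @param points Data frame with columns `holding_potential` (mV) and
#'   `peak_amplitude` (pA).
#' @param absolute Regress on absolute amplitudes instead of signed ones;
#'   default FALSE (signed).
#' @return An `iv_fit` object with elements `e_rev`, `conductance`,
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @export
#' @examples
#' pts <- simulate_iv_curve(e_rev = -40, conductance = 2,
#'                          potentials = seq(-80, -40, 10), noise_sd = 0)
#' fit_iv_reversal(pts)
fit_iv_reversal <- function(points, absolute = FALSE) {
  assert_columns(points, c("holding_potential", "peak_amplitude"),
                 what = "IV point table")
  if (nrow(points) < 3) {
    abort("at least 3 IV points are required",
          class = "baitprey_validation_error")
  }
  if (length(unique(points$holding_potential)) < 2) {
    abort("at least 2 distinct holding potentials are required",
          class = "baitprey_validation_error")
  }
  y <- points$peak_amplitude
  if (absolute) y <- abs(y)
  fit <- lm(y ~ holding_potential, data = points)
  m <- unname(coef(fit)[[2]])
  b <- unname(coef(fit)[[1]])
  if (abs(m) < sqrt(.Machine$double.eps) * max(1, abs(b))) {
    abort("zero slope: the IV curve has no reversal",
          class = "baitprey_validation_error")
  }
  structure(list(
    e_rev = -b / m,
    conductance = m,
    # suppressWarnings: summary.lm warns on exactly collinear (noiseless) data
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = nrow(points),
    fit = fit
  ), class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf(
    "<iv_fit: E_rev = %.2f mV, conductance = %.3f pA/mV, R^2 = %.3f, n = %d>\n",
    x$e_rev, x$conductance, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_iv_reversal
#' @param x,object An `iv_fit` object.
#' @param ... Unused.
#' @method tidy iv_fit
#' @export
tidy.iv_fit <- function(x, ...) {
  tibble(term = c("e_rev", "conductance"),
         estimate = c(x$e_rev, x$conductance))
}

#' @rdname fit_iv_reversal
#' @method glance iv_fit
#' @export
glance.iv_fit <- function(x, ...) {
  tibble(e_rev = x$e_rev, conductance = x$conductance,
         r_squared = x$r_squared, n = x$n)
}

#' @rdname fit_iv_reversal
#' @method autoplot iv_fit
#' @export
autoplot.iv_fit <- function(object, ...) {
  df <- data.frame(
    holding_potential = object$fit$model$holding_potential,
    peak_amplitude = object$fit$model$y
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$holding_potential,
                                   y = .data$peak_amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$e_rev, linetype = "dotted") +
    ggplot2::labs(x = "holding potential (mV)", y = "peak amplitude (pA)",
                  title = sprintf("IV regression: E_rev = %.1f mV",
                                  object$e_rev)) +
    ggplot2::theme_minimal()
}

#' Pooled two-sample t test from printed group summaries
#'
#' Recomputes a Student (pooled-variance) two-tailed t test from the
#' `(mean, SEM, n)` triples that papers print.  Standard deviations are
#' recovered as `sd = sem * sqrt(n)`, the pooled variance is
#' `((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`, and
#' `t = (mean1 - mean2) / (s sqrt(1/n1 + 1/n2))` with `df = n1 + n2 - 2`.
#' The pooled (not Welch) form is used because printed degrees of freedom of
#' the form `n1 + n2 - 2` identify it.
#'
#' @param mean1,sem1,n1 Summary of group 1 (`sem1 > 0`, `n1 >= 2`).
#' @param mean2,sem2,n2 Summary of group 2.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
#' @examples
#' # whole-cell E_GABA, control vs PACSIN1 shRNA
#' pooled_t_from_summary(-28.62, 3.07, 9, -37.86, 1.73, 11)
pooled_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  for (nm in c("n1", "n2")) {
    n <- get(nm)
    if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
      abort(sprintf("`%s` must be an integer >= 2", nm),
            class = "baitprey_validation_error")
    }
  }
  if (sem1 <= 0 || sem2 <= 0) {
    abort("SEMs must be positive", class = "baitprey_validation_error")
  }
  sd1 <- sem1 * sqrt(n1)
  sd2 <- sem2 * sqrt(n2)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(s2 * (1 / n1 + 1 / n2))
  tibble(t = t, df = as.integer(df), p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Pooled two-sample t test from raw samples via their summaries
#'
#' Convenience wrapper: summarises two raw vectors to `(mean, sem, n)` and
#' calls [pooled_t_from_summary()]; equal to `t.test(..., var.equal = TRUE)`.
#'
#' @param x,y Numeric sample vectors of length >= 2.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
pooled_t_from_raw <- function(x, y) {
  pooled_t_from_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x),
                        mean(y), stats::sd(y) / sqrt(length(y)), length(y))
}
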