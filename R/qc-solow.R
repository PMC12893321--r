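#' Fit the coverage-saturation (Solow growth) model
#'
#' Models genome coverage `y` as a saturating function of the sequencing
#' data amount `x`,
#' \deqn{y = a - e^{-bx + c},}
#' where `a` is the maximal genome coverage (a fraction), and `b` and `c` are
#' rate and offset constants. Used to decide how much raw data to sequence:
#' beyond the tipping point the marginal coverage gain per unit of data falls
#' below a chosen tolerance.
#'
#' Fitting is by Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]);
#' the residual sum-of-squares trace across iterations is returned and is
#' non-increasing (only improving steps are accepted).
#'
#' @param amounts numeric vector of data amounts (e.g. Gb); at least 3
#'   distinct values.
#' @param coverages numeric vector of genome coverages in \[0, 1\], same
#'   length as `amounts`.
#' @param gain_tolerance marginal gain (coverage per data unit) defining the
#'   tipping point (default 0.005).
#' @return An object of class `solow_fit`: list with `a`, `b`, `c`,
#'   `residual` (final sum of squared errors), `rss_trace`,
#'   `tipping_point`, and `fitted` (function of x).
#' @export
fit_solow <- function(amounts, coverages, gain_tolerance = 0.005) {
  x <- as.numeric(amounts); y <- as.numeric(coverages)
  if (length(x) != length(y)) stop_hylopop("`amounts` and `coverages` must have equal length")
  if (length(unique(x)) < 3L) stop_hylopop("need >= 3 distinct data amounts")
  if (any(y < 0 | y > 1)) stop_hylopop("coverages must be fractions in [0, 1]")
  if (stats::sd(y) < 1e-12)
    stop_hylopop(sprintf("degenerate fit: coverage is constant at %.3g", y[1]))

  # linearised start values: log(a0 - y) = -b x + c
  a0 <- min(1, max(y) + 0.5 * (1 - max(y)) + 1e-6)
  ly <- log(pmax(a0 - y, 1e-9))
  lf <- stats::lm(ly ~ x)
  start <- c(a = a0, b = max(1e-4, -unname(stats::coef(lf)[2])),
             c = unname(stats::coef(lf)[1]))

  resid_fn <- function(par) y - (par[1] - exp(-par[2] * x + par[3]))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(1e-9, -Inf, -Inf),
                            upper = c(1, Inf, Inf),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (fit$info %in% c(0, 5))
    stop_hylopop(sprintf(
      "Solow fit did not converge (last residual sum of squares %.6g)",
      tail(fit$rsstrace, 1)))
  par <- fit$par
  a <- par[[1]]; b <- par[[2]]; cc <- par[[3]]
  # marginal gain y'(x) = b exp(-b x + c); tipping point where it reaches tol
  tipping <- if (b > 0 && b > gain_tolerance)
    (cc + log(b / gain_tolerance)) / b else NA_real_
  structure(list(a = a, b = b, c = cc,
                 residual = sum(resid_fn(par)^2),
                 rss_trace = fit$rsstrace,
                 tipping_point = tipping,
                 gain_tolerance = gain_tolerance,
                 fitted = function(x) a - exp(-b * x + cc)),
            class = "solow_fit")
}

#' @export
print.solow_fit <- function(x, ...) {
  cat(sprintf(
    "Solow coverage model: y = %.4f - exp(-%.4f x + %.4f)\n  SSE %.3g, tipping point at x = %.2f (gain < %.3g per unit)\n",
    x$a, x$b, x$c, x$residual, x$tipping_point, x$gain_tolerance))
  invisible(x)
}

#' @export
predict.solow_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  object$fitted(x)
}
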