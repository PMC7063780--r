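#' Fit a logistic decay to residual-substrate data
#'
#' Least-squares fit of the decreasing four-parameter logistic
#' `f(t) = A + (B - A) / (1 + exp(k (t - t0)))` to a residual cellulose
#' (or other substrate) time series.  `B` is the initial plateau, `A` the
#' floor, `t0` the inflection time and `k` the steepness; the maximum
#' solubilization rate is the magnitude of the first derivative at the
#' inflection, `k (B - A) / 4`, attained at `t = t0`.
#'
#' Fitting uses Levenberg-Marquardt least squares from multiple
#' deterministic data-driven starts (initial/final values for `B`/`A`, the
#' steepest finite-difference location for `t0`, its slope for `k`, each
#' varied over a small grid), keeping the converged fit with the lowest
#' residual sum of squares.
#'
#' @param time sampling times, h (strictly increasing, >= 6 points).
#' @param value residual substrate, g glucose equivalents/L.
#' @param n_starts maximum number of starting points tried (default 10).
#' @return Object of class `"logistic_decay"` with elements `converged`,
#'   `coefficients` (named: A, B, k, t0), `rss`, `data`, and `message`.
#'   On failure `converged` is `FALSE` and the coefficients are `NA` (no
#'   number is fabricated).
#' @examples
#' t <- seq(0, 120, by = 10)
#' y <- 10 + (130 - 10) / (1 + exp(0.05 * (t - 60)))
#' fit <- fit_logistic_decay(t, y)
#' coef(fit)
#' max_solubilization_rate(fit)
#' @export
fit_logistic_decay <- function(time, value, n_starts = 10) {
  stopifnot(length(time) == length(value))
  if (length(time) < 6) stop("need at least 6 time points")
  o <- order(time)
  time <- time[o]; value <- value[o]
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(value < 0)) stop("residual substrate must be >= 0")

  B0 <- max(value[1], max(value) * 0.99)
  A0 <- max(min(value), 0)
  slopes <- diff(value) / diff(time)
  imin <- which.min(slopes)
  t00 <- (time[imin] + time[imin + 1]) / 2
  span <- max(B0 - A0, 1e-8)
  k0 <- max(-4 * slopes[imin] / span, 1e-6)
  tr <- diff(range(time))
  starts <- expand.grid(kf = c(1, 0.5, 2, 0.25, 4),
                        dt = c(0, -0.15, 0.15) * tr)
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]

  df <- data.frame(time = time, value = value)
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    st <- list(A = A0, B = B0, k = k0 * starts$kf[r],
               t0 = t00 + starts$dt[r])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ A + (B - A) / (1 + exp(k * (time - t0))),
        data = df, start = st,
        lower = c(A = 0, B = 1e-12, k = 1e-9, t0 = min(time) - 2 * tr),
        upper = c(A = Inf, B = Inf, k = Inf, t0 = max(time) + 2 * tr),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    if (cf[["B"]] <= cf[["A"]] || cf[["k"]] <= 0) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(rss = rss, coef = cf)
  }
  if (is.null(best)) {
    out <- list(converged = FALSE,
                coefficients = c(A = NA_real_, B = NA_real_, k = NA_real_,
                                 t0 = NA_real_),
                rss = NA_real_, data = df,
                message = "no start converged to a valid decreasing logistic")
  } else {
    out <- list(converged = TRUE,
                coefficients = best$coef[c("A", "B", "k", "t0")],
                rss = best$rss, data = df, message = "ok")
  }
  class(out) <- "logistic_decay"
  out
}

#' @export
coef.logistic_decay <- function(object, ...) object$coefficients

#' @export
print.logistic_decay <- function(x, ...) {
  if (!x$converged) {
    cat("Logistic decay fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat("Logistic decay fit: f(t) = A + (B - A)/(1 + exp(k (t - t0)))\n")
  cat(sprintf("  A = %.4g, B = %.4g g gluc eq/L; k = %.4g 1/h; t0 = %.4g h\n",
              cf["A"], cf["B"], cf["k"], cf["t0"]))
  cat(sprintf("  max rate = %.4g g gluc eq/L/h at t = %.4g h (RSS %.4g)\n",
              max_solubilization_rate(x), cf["t0"], x$rss))
  invisible(x)
}

#' @export
summary.logistic_decay <- function(object, ...) {
  out <- list(coefficients = object$coefficients, rss = object$rss,
              max_rate = if (object$converged)
                max_solubilization_rate(object) else NA_real_,
              n = nrow(object$data), converged = object$converged)
  class(out) <- "summary.logistic_decay"
  out
}

#' @export
print.summary.logistic_decay <- function(x, ...) {
  cat("Logistic decay fit on", x$n, "points\n")
  print(round(c(x$coefficients, rss = x$rss, max_rate = x$max_rate), 6))
  invisible(x)
}

#' @export
predict.logistic_decay <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  t <- if (is.null(newdata)) object$data$time
       else if (is.data.frame(newdata)) newdata$time else newdata
  cf <- object$coefficients
  cf[["A"]] + (cf[["B"]] - cf[["A"]]) / (1 + exp(cf[["k"]] * (t - cf[["t0"]])))
}

#' @export
fitted.logistic_decay <- function(object, ...) predict(object)

#' @export
residuals.logistic_decay <- function(object, ...) {
  object$data$value - fitted(object)
}

#' @export
plot.logistic_decay <- function(x, ...) {
  plot(x$data$time, x$data$value, xlab = "time (h)",
       ylab = "residual substrate (g gluc eq/L)", ...)
  if (x$converged) {
    tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
    lines(tt, predict(x, tt))
    abline(v = x$coefficients[["t0"]], lty = 2)
  }
  invisible(x)
}

#' Solubilization rate curve of a fitted logistic decay
#'
#' The rate of substrate consumption, `-f'(t) = (B - A) k e / (1 + e)^2`
#' with `e = exp(k (t - t0))`, in g glucose equivalents/L/h.
#'
#' @param fit a converged [fit_logistic_decay()] object.
#' @param t times at which to evaluate the rate, h.
#' @return Numeric vector of rates (positive during depletion).
#' @export
solubilization_rate <- function(fit, t) {
  stopifnot(inherits(fit, "logistic_decay"))
  if (!fit$converged) stop("fit did not converge")
  cf <- fit$coefficients
  e <- exp(cf[["k"]] * (t - cf[["t0"]]))
  (cf[["B"]] - cf[["A"]]) * cf[["k"]] * e / (1 + e)^2
}

#' Maximum solubilization rate of a fitted logistic decay
#'
#' Analytic maximum of the rate curve, `k (B - A) / 4`, attained at the
#' inflection time `t0`.
#'
#' @param fit a converged [fit_logistic_decay()] object.
#' @return Maximum rate, g glucose equivalents/L/h.
#' @export
max_solubilization_rate <- function(fit) {
  stopifnot(inherits(fit, "logistic_decay"))
  if (!fit$converged) stop("fit did not converge")
  cf <- fit$coefficients
  cf[["k"]] * (cf[["B"]] - cf[["A"]]) / 4
}

#' Extent of substrate solubilization
#'
#' Difference between the first and the last residual-substrate value of a
#' time-ordered series (g glucose equivalents/L).  Computed on the averaged
#' replicate series when replicate runs are averaged upstream.
#'
#' @param time sampling times, h.
#' @param value residual substrate, g glucose equivalents/L.
#' @return Solubilized substrate, g glucose equivalents/L.
#' @export
solubilization_extent <- function(time, value) {
  stopifnot(length(time) == length(value), length(value) >= 1)
  o <- order(time)
  value[o][1] - value[o][length(value)]
}

#' Timing of maximum solubilization rate versus peak cell density
#'
#' Compares the inflection time of the solubilization fit (where the rate is
#' maximal) with the time of maximum pellet nitrogen (the cell proxy), and
#' flags whether the rate peak precedes the cell peak.
#'
#' @param fit a converged [fit_logistic_decay()] object.
#' @param time_n,pellet_n pellet nitrogen time series (h, g/L).
#' @return List with `t_rate_max`, `t_cell_max`, and logical
#'   `rate_precedes_cells`.
#' @export
rate_vs_growth_timing <- function(fit, time_n, pellet_n) {
  stopifnot(inherits(fit, "logistic_decay"),
            length(time_n) == length(pellet_n))
  if (!fit$converged) stop("fit did not converge")
  t_rate <- fit$coefficients[["t0"]]
  t_cell <- time_n[which.max(pellet_n)]
  list(t_rate_max = t_rate, t_cell_max = t_cell,
       rate_precedes_cells = t_rate < t_cell)
}

#' Convert between cellulose mass and glucose equivalents
#'
#' Hydration of the anhydroglucose unit: multiply cellulose (g/L) by 180/162
#' to express it as glucose equivalents, and the inverse to go back.
#'
#' @param x concentration, g/L.
#' @return Converted concentration, g/L.
#' @export
glucose_equivalents <- function(x) x * 180 / 162

#' @rdname glucose_equivalents
#' @export
cellulose_from_glucose_eq <- function(x) x * 162 / 180
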