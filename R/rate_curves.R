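#' Four-parameter logistic value
#'
#' The sigmoid `y = (A1 - A2) / (1 + (t/x0)^p) + A2` used to smooth
#' cumulative time courses before differentiation. `A1` is the initial
#' value at t = 0, `A2` the final asymptote, `x0` the mid-range time and
#' `p` the slope factor. The model is undefined at t = 0 for non-integer
#' `p`; times at or below zero are evaluated at `t = 1e-6` h.
#'
#' @param t Time(s), h.
#' @param A1,A2,x0,p Logistic parameters.
#' @return Fitted value(s).
#' @export
logistic4p <- function(t, A1, A2, x0, p) {
  t <- pmax(t, 1e-6)
  (A1 - A2) / (1 + (t / x0)^p) + A2
}

#' Fit a four-parameter logistic curve
#'
#' Levenberg-Marquardt least squares of [logistic4p()] on a cumulative time
#' course (sugar consumed, cell mass, lipid titer, organic acid...). The
#' default initializer is deterministic: `A1 = y[1]`, `A2 = y[n]`, `x0` at
#' the time the data cross half-range, `p = 4`. Constant series yield a
#' degenerate fit (`A1 = A2`, flagged) without invoking the optimizer.
#'
#' @param t Times, h (values at or below 0 are shifted to 1e-6).
#' @param y Observations, same length as `t`, at least 5 points.
#' @param init Optional named list overriding initial values of
#'   `A1, A2, x0, p`.
#' @param max_iter Maximum optimizer iterations.
#' @return Object of class `logistic_fit` with fields `A1, A2, x0, p`,
#'   `rss`, `converged`, `degenerate`, `n_iter`.
#' @export
fitLogistic <- function(t, y, init = NULL, max_iter = 500) {
  stopifnot(length(t) == length(y), length(t) >= 5, !anyNA(t), !anyNA(y))
  t <- pmax(t, 1e-6)
  newFit <- function(A1, A2, x0, p, rss, converged, degenerate, n_iter) {
    structure(list(A1 = A1, A2 = A2, x0 = x0, p = p, rss = rss,
                   converged = converged, degenerate = degenerate,
                   n_iter = n_iter),
              class = "logistic_fit")
  }
  if (diff(range(y)) < 1e-12 * max(1, abs(mean(y)))) {
    return(newFit(y[1], y[1], max(t) / 2, 4, 0, TRUE, TRUE, 0L))
  }
  mid <- (y[1] + y[length(y)]) / 2
  start <- list(A1 = y[1], A2 = y[length(y)],
                x0 = max(t[which.min(abs(y - mid))], 1e-3), p = 4)
  if (!is.null(init)) start <- modifyList(start, as.list(init))
  par0 <- unlist(start[c("A1", "A2", "x0", "p")])
  resid_fn <- function(par) {
    y - (par[1] - par[2]) / (1 + (t / abs(par[3]))^par[4]) - par[2]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-10, ptol = 1e-12)
    ),
    error = function(e) e
  )
  ok <- !inherits(fit, "error") && fit$info %in% 1:4
  if (!ok) {
    best <- if (inherits(fit, "error")) par0 else fit$par
    rss <- sum(resid_fn(best)^2)
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    cnd <- structure(
      class = c("logistic_fit_error", "error", "condition"),
      list(message = paste0("logistic fit did not converge: ", msg),
           call = sys.call(-1),
           best = newFit(best[1], best[2], abs(best[3]), best[4],
                         rss, FALSE, FALSE,
                         if (inherits(fit, "error")) 0L else fit$niter))
    )
    stop(cnd)
  }
  newFit(fit$par[[1]], fit$par[[2]], abs(fit$par[[3]]), fit$par[[4]],
         fit$deviance, TRUE, FALSE, fit$niter)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> A1 = %.4g, A2 = %.4g, x0 = %.4g h, p = %.4g (rss %.3g%s)\n",
    x$A1, x$A2, x$x0, x$p, x$rss,
    if (x$degenerate) ", degenerate" else if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, t, ...) {
  logistic4p(t, object$A1, object$A2, object$x0, object$p)
}

#' Analytic volumetric rate from a logistic fit
#'
#' The absolute time derivative of the fitted 4PL curve,
#' `|dy/dt| = |A1 - A2| * p * (t/x0)^p / (t * (1 + (t/x0)^p)^2)`,
#' i.e. the volumetric consumption or production rate Q in g/(L h) when the
#' fit was made on a cumulative concentration course.
#'
#' @param fit A [fitLogistic()] result.
#' @param t Time(s), h; strictly positive.
#' @return Rate(s), same units as `y` per hour.
#' @export
derivativeRate <- function(fit, t) {
  if (any(t <= 0)) stop("derivative rate requires t > 0")
  r <- (t / fit$x0)^fit$p
  abs(fit$A1 - fit$A2) * fit$p * r / (t * (1 + r)^2)
}

#' Rate curve with peak and threshold metrics
#'
#' Evaluates the analytic derivative of a logistic fit on a fine grid and
#' extracts the peak rate, the plateau interval over which the rate stays
#' within `plateau_fraction` of the peak, and the time after the peak at
#' which the rate first falls below a threshold.
#'
#' @param fit A [fitLogistic()] result.
#' @param t_max End of the evaluation grid, h.
#' @param step Grid step, h (<= 0.1).
#' @param plateau_fraction Fraction of the peak defining the peak interval.
#' @param threshold Rate threshold for the flattening time, g/(L h).
#' @param sign Whether the fitted course was consumption or production
#'   (metadata only; rates are reported as magnitudes).
#' @return Object of class `rate_curve` with `grid`, `rates`, `peak_rate`,
#'   `peak_time`, `peak_interval` (h), `subthreshold_time` (h or `NA` if
#'   the rate never falls below the threshold on the grid).
#' @export
rateCurve <- function(fit, t_max, step = 0.05, plateau_fraction = 0.99,
                      threshold = 0.1, sign = c("consumption", "production")) {
  sign <- match.arg(sign)
  stopifnot(step <= 0.1, t_max > step)
  grid <- seq(step, t_max, by = step)
  rates <- derivativeRate(fit, grid)
  ipk <- which.max(rates)
  peak <- rates[ipk]
  in_plateau <- rates >= plateau_fraction * peak
  # maximal contiguous run containing the argmax
  lo <- ipk; while (lo > 1 && in_plateau[lo - 1]) lo <- lo - 1
  hi <- ipk; while (hi < length(grid) && in_plateau[hi + 1]) hi <- hi + 1
  below <- which(rates < threshold & seq_along(grid) > ipk)
  structure(
    list(fit = fit, sign = sign, grid = grid, rates = rates,
         peak_rate = peak, peak_time = grid[ipk],
         peak_interval = c(grid[lo], grid[hi]),
         subthreshold_time = if (length(below)) grid[below[1]] else NA_real_,
         plateau_fraction = plateau_fraction, threshold = threshold),
    class = "rate_curve"
  )
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf(
    "<rate_curve> (%s) peak %.3g g/(L h) at %.1f h [plateau %.1f-%.1f h]%s\n",
    x$sign, x$peak_rate, x$peak_time, x$peak_interval[1], x$peak_interval[2],
    if (is.na(x$subthreshold_time)) "" else
      sprintf("; < %.2g g/(L h) after %.1f h", x$threshold, x$subthreshold_time)))
  invisible(x)
}

#' Peak and threshold metrics of a rate curve
#'
#' @param curve A [rateCurve()].
#' @return List with `peak_rate`, `peak_interval`, `subthreshold_time`.
#' @export
peakMetrics <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  curve[c("peak_rate", "peak_interval", "subthreshold_time")]
}

#' Cumulative consumed-sugar course of a record
#'
#' Pulse feeds put a sawtooth on the measured sugar concentration that
#' breaks the logistic shape, so consumption curves are fitted on the
#' cumulative consumed concentration
#' `consumed(t) = applied(<t)/Vbar + S(0) - S(t)`
#' (applied sugar before `t` on the mean-volume basis, plus the
#' concentration drop). This is the required preprocessing before
#' [fitLogistic()] on pulsed records; for production series (cell mass,
#' lipid, acid) the measured concentrations are already cumulative.
#'
#' @param rec A `cultivation_record`.
#' @return `data.frame` with columns `t_h` and `consumed_gL`.
#' @export
cumulativeConsumption <- function(rec) {
  s <- rec$samples
  vbar <- mean(.volumeAt(rec, s$t_h))
  e <- rec$events
  applied_before <- vapply(s$t_h, function(ti) {
    if (!nrow(e)) return(0)
    m <- sum(e$sugar_mass_g[e$kind == "pulse" & e$t_start_h < ti - 1e-9],
             na.rm = TRUE)
    cont <- e[e$kind == "continuous", , drop = FALSE]
    if (nrow(cont)) {
      frac <- pmin(pmax((ti - cont$t_start_h) /
                          (cont$t_end_h - cont$t_start_h), 0), 1)
      m <- m + sum(frac * cont$sugar_mass_g)
    }
    m
  }, numeric(1))
  data.frame(t_h = s$t_h,
             consumed_gL = applied_before / vbar + s$sugar_gL[1] - s$sugar_gL)
}
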