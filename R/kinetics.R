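#' Cultivation phase windows
#'
#' @param t_start,t_end Window bounds, h (`t_end > t_start`).
#' @param label Window label.
#' @return Object of class `phase_window`.
#' @export
phaseWindow <- function(t_start, t_end, label = sprintf("%g-%g h", t_start, t_end)) {
  stopifnot(t_end > t_start)
  structure(list(t_start = t_start, t_end = t_end, label = label),
            class = "phase_window")
}

#' Default phase windows of a two-phase fed-batch cultivation
#'
#' Daily windows plus the nitrogen-metabolization phase (0-72 h), the
#' nitrogen-limitation phase (72 h to end) and the total window. Growth is
#' nitrogen-fuelled in the first phase; once ammonium is exhausted (around
#' 70 h) lipid accumulation dominates.
#'
#' @param t_end End of cultivation, h.
#' @param daily Include daily windows?
#' @return List of [phaseWindow()]s.
#' @export
defaultPhases <- function(t_end = 142, daily = FALSE) {
  w <- list()
  if (daily) {
    b <- seq(0, 24 * floor(t_end / 24), by = 24)
    if (max(b) < t_end) b <- c(b, t_end)
    for (i in seq_len(length(b) - 1)) {
      w[[length(w) + 1]] <- phaseWindow(b[i], b[i + 1])
    }
  }
  w$n_metabolization <- phaseWindow(0, 72, "N-metabolization")
  w$n_limitation <- phaseWindow(72, t_end, "N-limitation")
  w$total <- phaseWindow(0, t_end, "Total")
  w
}

# nearest sample index to time t, within tolerance (h)
.nearestSample <- function(rec, t, tol = 2) {
  d <- abs(rec$samples$t_h - t)
  i <- which.min(d)
  if (d[i] > tol) {
    stop("no sample within ", tol, " h of t = ", t, " h")
  }
  i
}

# concentration-basis sugar consumption over [t0, t1): concentration drop
# plus feed additions expressed on the initial-volume basis. Feeds at t0
# count (samples are drawn before feeding), feeds at t1 do not.
.concConsumed <- function(rec, t0, t1, tol = 2) {
  i0 <- .nearestSample(rec, t0, tol)
  i1 <- .nearestSample(rec, t1, tol)
  s <- rec$samples
  t0s <- s$t_h[i0]; t1s <- s$t_h[i1]
  e <- rec$events
  fed <- 0
  if (nrow(e)) {
    p <- e$kind == "pulse" & e$t_start_h >= t0s - 1e-9 & e$t_start_h < t1s - 1e-9
    fed <- sum(e$sugar_mass_g[p], na.rm = TRUE)
    cont <- e[e$kind == "continuous", , drop = FALSE]
    if (nrow(cont)) {
      ov <- pmax(pmin(cont$t_end_h, t1s) - pmax(cont$t_start_h, t0s), 0)
      fed <- fed + sum(ov / (cont$t_end_h - cont$t_start_h) * cont$sugar_mass_g)
    }
  }
  s$sugar_gL[i0] - s$sugar_gL[i1] + fed / rec$initial_volume
}

# mass-basis sugar consumption over [t0, t1): dissolved mass change plus
# feeds minus withdrawals, using the tracked volume.
.massConsumed <- function(rec, t0, t1, tol = 2) {
  i0 <- .nearestSample(rec, t0, tol)
  i1 <- .nearestSample(rec, t1, tol)
  s <- rec$samples
  t0s <- s$t_h[i0]; t1s <- s$t_h[i1]
  e <- rec$events
  fed <- 0; withdrawn <- 0
  if (nrow(e)) {
    p <- e$kind == "pulse" & e$t_start_h >= t0s - 1e-9 & e$t_start_h < t1s - 1e-9
    fed <- sum(e$sugar_mass_g[p], na.rm = TRUE)
    cont <- e[e$kind == "continuous", , drop = FALSE]
    if (nrow(cont)) {
      ov <- pmax(pmin(cont$t_end_h, t1s) - pmax(cont$t_start_h, t0s), 0)
      fed <- fed + sum(ov / (cont$t_end_h - cont$t_start_h) * cont$sugar_mass_g)
    }
    w <- e$kind == "sample_withdrawal" & e$t_start_h > t0s & e$t_start_h < t1s - 1e-9
    if (any(w)) {
      withdrawn <- sum(sugarConcAt(rec, e$t_start_h[w]) *
                         abs(e$volume_delta_L[w]))
    }
  }
  s$sugar_gL[i0] * .volumeAt(rec, t0s) + fed - withdrawn -
    s$sugar_gL[i1] * .volumeAt(rec, t1s)
}

#' Phase-resolved yields and volumetric rates
#'
#' For each phase window: cell mass yield `Y_xs` (g CDW per g sugar
#' consumed), lipid yield `Y_ps` (g lipid per g sugar), volumetric
#' consumption rate `Q_s` and lipid production rate `Q_p` (g/(L h)).
#' Window endpoints snap to the nearest sample within `tol` hours.
#'
#' Two accounting bases are offered. The `"concentration"` basis works on
#' measured concentrations with feeds expressed on the initial volume and
#' ignores volume drift from feeding and sampling — the convention the
#' published summary tables of such processes follow. The `"mass"` basis
#' corrects every term by the tracked volume (feeds, withdrawals,
#' dilution), for records where volume change is substantial.
#'
#' Windows in which no sugar was consumed are retained with `NA` yields and
#' the `undefined_yield` flag set.
#'
#' @param rec A `cultivation_record`.
#' @param windows List of [phaseWindow()]s (default [defaultPhases()] at
#'   the record's final sample time).
#' @param basis `"concentration"` (default) or `"mass"`.
#' @param tol Endpoint snap tolerance, h.
#' @return `data.frame` with one row per window: `phase`, `t_start_h`,
#'   `t_end_h`, `dX_gL`, `dP_gL`, `dS_gL` (consumed, basis-equivalent
#'   concentration), `Y_xs`, `Y_ps`, `Q_s`, `Q_p`, `undefined_yield`.
#' @export
phaseYields <- function(rec, windows = NULL,
                        basis = c("concentration", "mass"), tol = 2) {
  basis <- match.arg(basis)
  if (is.null(windows)) windows <- defaultPhases(max(rec$samples$t_h))
  if (inherits(windows, "phase_window")) windows <- list(windows)
  s <- rec$samples
  titer <- lipidTiter(rec)
  rows <- lapply(windows, function(w) {
    i0 <- .nearestSample(rec, w$t_start, tol)
    i1 <- .nearestSample(rec, w$t_end, tol)
    dt <- s$t_h[i1] - s$t_h[i0]
    if (basis == "concentration") {
      dS <- .concConsumed(rec, w$t_start, w$t_end, tol)
      dX <- s$cdw_gL[i1] - s$cdw_gL[i0]
      dP <- titer[i1] - titer[i0]
      vbar <- rec$initial_volume
    } else {
      v0 <- .volumeAt(rec, s$t_h[i0]); v1 <- .volumeAt(rec, s$t_h[i1])
      vbar <- (v0 + v1) / 2
      dS <- .massConsumed(rec, w$t_start, w$t_end, tol) / vbar
      dX <- (s$cdw_gL[i1] * v1 - s$cdw_gL[i0] * v0) / vbar
      dP <- (titer[i1] * v1 - titer[i0] * v0) / vbar
    }
    undef <- dS <= 0
    data.frame(
      phase = w$label, t_start_h = s$t_h[i0], t_end_h = s$t_h[i1],
      dX_gL = dX, dP_gL = dP, dS_gL = dS,
      Y_xs = if (undef) NA_real_ else dX / dS,
      Y_ps = if (undef) NA_real_ else dP / dS,
      Q_s = dS / dt, Q_p = dP / dt,
      undefined_yield = undef
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Sugar utilization percentage
#'
#' Share of the applied sugar actually metabolized by the yeast,
#' `100 * metabolized / applied`. Measurement noise can push the ratio
#' marginally over 100 %; such values are capped at 100 with the
#' `"capped"` attribute set.
#'
#' @param total_metabolized Metabolized sugar mass, g.
#' @param total_applied Applied sugar mass, g; must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
utilization <- function(total_metabolized, total_applied) {
  if (total_applied <= 0) stop("applied sugar must be positive")
  if (total_metabolized < 0 || total_metabolized > total_applied * 1.02) {
    stop("metabolized sugar outside [0, 1.02 * applied]: inconsistent record")
  }
  pct <- 100 * total_metabolized / total_applied
  capped <- pct > 100
  pct <- min(pct, 100)
  attr(pct, "capped") <- capped
  pct
}

#' Percent change between two process outcomes
#'
#' `100 * (new - reference) / base`, where the base is either the reference
#' value ("x % less/more than the reference") or the new value ("the
#' improvement amounts to x % of the new level"). Published comparisons of
#' feeding strategies use both conventions, so the base is explicit.
#'
#' @param reference Reference value.
#' @param new New value.
#' @param base `"reference"` or `"new"`; the denominator. Must be non-zero.
#' @return Signed percentage.
#' @export
percentChange <- function(reference, new, base = c("reference", "new")) {
  base <- match.arg(base)
  denom <- if (base == "reference") reference else new
  if (any(denom == 0)) stop("zero base value")
  100 * (new - reference) / denom
}

#' Compare feeding strategies across cultivation records
#'
#' Assembles, per record, the totals a strategy comparison table reports:
#' applied and metabolized sugar, utilization, final CDW / lipid content /
#' lipid titer / organic-acid concentration, total volumetric rates and
#' yields over the whole record, total CO2 and CO2 per CDW.
#'
#' @param records List of `cultivation_record`s (at least one).
#' @param basis Accounting basis passed to [phaseYields()].
#' @return List with `summary` (one row per record) and, when two or more
#'   records are given, `changes`: pairwise percent changes of key outcomes
#'   of each record vs the first (reference) record, on the reference base.
#' @export
compareStrategies <- function(records, basis = "concentration") {
  stopifnot(length(records) >= 1)
  rows <- lapply(records, function(rec) {
    s <- rec$samples
    n <- nrow(s)
    applied <- appliedSugar(rec)
    metab <- metabolizedSugar(rec)
    tot <- phaseYields(rec, phaseWindow(s$t_h[1], s$t_h[n], "Total"),
                       basis = basis)
    dt <- s$t_h[n] - s$t_h[1]
    data.frame(
      label = rec$label,
      total_applied_g = applied,
      total_metabolized_g = metab,
      pct_used = as.numeric(utilization(metab, applied)),
      final_cdw_gL = s$cdw_gL[n],
      final_lipid_pct = s$fame_pct_cdw[n],
      final_lipid_titer_gL = lipidTiter(rec)[n],
      final_acid_gL = s$acid_gL[n],
      Q_s = tot$Q_s,
      Q_x = (s$cdw_gL[n] - s$cdw_gL[1]) / dt,
      Q_p = tot$Q_p,
      Y_xs = tot$Y_xs,
      Y_ps = tot$Y_ps,
      total_co2_g = s$co2_cum_g[n],
      co2_per_cdw = s$co2_cum_g[n] /
        (s$cdw_gL[n] * rec$initial_volume)
    )
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  out <- list(summary = summary)
  if (length(records) >= 2) {
    ref <- summary[1, ]
    fields <- c("total_applied_g", "total_metabolized_g", "final_cdw_gL",
                "final_lipid_titer_gL", "final_acid_gL", "Q_s", "Q_x", "Q_p")
    ch <- lapply(seq(2, nrow(summary)), function(i) {
      data.frame(label = summary$label[i], field = fields,
                 pct_change = vapply(fields, function(f) {
                   percentChange(ref[[f]], summary[[f]][i], "reference")
                 }, numeric(1)))
    })
    changes <- do.call(rbind, ch)
    rownames(changes) <- NULL
    out$changes <- changes
  }
  out
}

#' Normalize a series to its maximum
#'
#' @param x Numeric vector with a positive maximum.
#' @return `x / max(x)`, `NA`s preserved.
#' @export
normalizeToMax <- function(x) {
  m <- max(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("series has no positive maximum")
  x / m
}
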