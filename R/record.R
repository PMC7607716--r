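#' Cultivation record: time series plus feed/sampling events
#'
#' The universal input of all analysis stages: time-stamped samples of a
#' fed-batch cultivation (sugar, ammonium, cell dry weight, lipid content as
#' % FAME/CDW, organic acid, cumulative CO2) together with the feed and
#' sample-withdrawal events that shaped the broth volume and sugar supply.
#'
#' Sample columns: `t_h, sugar_gL, sugar_sd, nh4_gL, cdw_gL, cdw_sd,
#' fame_pct_cdw, fame_sd, acid_gL, acid_sd, co2_cum_g`. Only `t_h` is
#' mandatory; missing measurements are `NA`, never silent zeros. The lipid
#' titer (g/L) is always the derived product `cdw_gL * fame_pct_cdw / 100`,
#' not an independent column.
#'
#' Event columns: `t_start_h, t_end_h, kind, sugar_mass_g, volume_delta_L,
#' pump_rate_g_per_h` with `kind` one of `"pulse"`, `"continuous"`,
#' `"sample_withdrawal"` and `t_end_h = NA` for instantaneous events.
#' Time is hours from inoculation; events attribute to intervals closed on
#' the left and open on the right.
#'
#' @param label Short name of the cultivation.
#' @param samples `data.frame` of time-point samples (see Details).
#' @param events `data.frame` of feed/withdrawal events, may be empty.
#' @param sugar_species,acid_species [chemSpecies()] objects for the carbon
#'   source and the organic-acid by-product.
#' @param initial_volume Working volume at inoculation, L.
#' @param initial_cn_ratio Optional initial carbon-to-nitrogen mass ratio of
#'   the medium (g C per g N).
#' @return Object of class `cultivation_record`.
#' @export
cultivationRecord <- function(label, samples, events = emptyEvents(),
                              sugar_species = speciesRegistry()$glucose,
                              acid_species = speciesRegistry()$gluconic_acid,
                              initial_volume = 1.2,
                              initial_cn_ratio = NA_real_) {
  samples <- as.data.frame(samples)
  events <- as.data.frame(events)
  for (col in .SAMPLE_COLS) {
    if (is.null(samples[[col]])) samples[[col]] <- NA_real_
    samples[[col]] <- as.numeric(samples[[col]])
  }
  samples <- samples[.SAMPLE_COLS]
  for (col in .EVENT_COLS) {
    if (is.null(events[[col]])) {
      events[[col]] <- if (col == "kind") character(0) else NA_real_
    }
    if (col != "kind") events[[col]] <- as.numeric(events[[col]])
  }
  events <- events[.EVENT_COLS]
  rec <- structure(
    list(label = label, samples = samples, events = events,
         sugar_species = sugar_species, acid_species = acid_species,
         initial_volume = initial_volume, initial_cn_ratio = initial_cn_ratio),
    class = "cultivation_record"
  )
  validateRecord(rec)
  rec
}

.SAMPLE_COLS <- c("t_h", "sugar_gL", "sugar_sd", "nh4_gL", "cdw_gL", "cdw_sd",
                  "fame_pct_cdw", "fame_sd", "acid_gL", "acid_sd", "co2_cum_g")
.EVENT_COLS <- c("t_start_h", "t_end_h", "kind", "sugar_mass_g",
                 "volume_delta_L", "pump_rate_g_per_h")

#' @rdname cultivationRecord
#' @export
emptyEvents <- function() {
  data.frame(t_start_h = numeric(0), t_end_h = numeric(0),
             kind = character(0), sugar_mass_g = numeric(0),
             volume_delta_L = numeric(0), pump_rate_g_per_h = numeric(0))
}

#' Validate a cultivation record
#'
#' Checks monotone time, non-negative concentrations, lipid fraction bounds,
#' event-kind consistency and non-overlap of continuous segments. Errors
#' name the offending row.
#'
#' @param rec A `cultivation_record`.
#' @return `rec`, invisibly, if valid.
#' @export
validateRecord <- function(rec) {
  s <- rec$samples
  if (nrow(s) == 0) stop("record has no samples")
  if (any(s$t_h < 0)) stop("negative sample time at row ",
                           which(s$t_h < 0)[1])
  if (any(diff(s$t_h) <= 0)) {
    stop("sample times not strictly increasing at row ",
         which(diff(s$t_h) <= 0)[1] + 1)
  }
  for (col in c("sugar_gL", "nh4_gL", "cdw_gL", "acid_gL", "co2_cum_g")) {
    bad <- which(!is.na(s[[col]]) & s[[col]] < 0)
    if (length(bad)) stop("negative ", col, " at row ", bad[1])
  }
  bad <- which(!is.na(s$fame_pct_cdw) &
                 (s$fame_pct_cdw < 0 | s$fame_pct_cdw > 100))
  if (length(bad)) stop("fame_pct_cdw outside [0, 100] at row ", bad[1])
  if (rec$initial_volume <= 0) stop("initial_volume must be positive")

  e <- rec$events
  if (nrow(e)) {
    if (!all(e$kind %in% c("pulse", "continuous", "sample_withdrawal"))) {
      stop("unknown event kind")
    }
    if (any(e$sugar_mass_g < 0, na.rm = TRUE)) stop("negative event sugar mass")
    w <- e$kind == "sample_withdrawal"
    if (any(w & e$volume_delta_L >= 0)) {
      stop("sample_withdrawal events must have negative volume_delta_L")
    }
    cont <- e[e$kind == "continuous", , drop = FALSE]
    if (nrow(cont)) {
      if (any(is.na(cont$t_end_h)) || any(cont$t_end_h <= cont$t_start_h)) {
        stop("continuous segments need t_end_h > t_start_h")
      }
      cont <- cont[order(cont$t_start_h), ]
      if (nrow(cont) > 1 &&
          any(cont$t_start_h[-1] < cont$t_end_h[-nrow(cont)] - 1e-9)) {
        stop("continuous segments overlap")
      }
    }
  }
  # volume trajectory must stay positive
  tt <- sort(unique(c(s$t_h, e$t_start_h, e$t_end_h[!is.na(e$t_end_h)])))
  if (any(.volumeAt(rec, tt) <= 0)) stop("implied volume trajectory reaches zero")
  invisible(rec)
}

#' @export
print.cultivation_record <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<cultivation_record> '%s' on %s\n", x$label, x$sugar_species$name))
  cat(sprintf("  %d samples over %.1f-%.1f h; %d events; V0 = %.2f L\n",
              nrow(s), min(s$t_h), max(s$t_h), nrow(x$events), x$initial_volume))
  invisible(x)
}

#' Read a cultivation record from CSV files
#'
#' Reads the two CSV dialects used throughout the package: a time-series
#' file with columns `t_h, sugar_gL, sugar_sd, nh4_gL, cdw_gL, cdw_sd,
#' fame_pct_cdw, fame_sd, acid_gL, acid_sd, co2_cum_g` (header mandatory,
#' "." decimal separator; missing optional columns become `NA` fields) and
#' an events file with columns `t_start_h, t_end_h, kind, sugar_mass_g,
#' volume_delta_L, pump_rate_g_per_h` (empty `t_end_h` for pulses).
#'
#' @param timeseries_file Path to the time-series CSV.
#' @param events_file Optional path to the events CSV.
#' @param ... Passed to [cultivationRecord()] (label, species, volume...).
#' @return A `cultivation_record`.
#' @export
readRecord <- function(timeseries_file, events_file = NULL, ...) {
  samples <- read.csv(timeseries_file, stringsAsFactors = FALSE)
  if (!"t_h" %in% names(samples)) stop("time-series file lacks a t_h column")
  events <- if (!is.null(events_file)) {
    read.csv(events_file, stringsAsFactors = FALSE)
  } else {
    emptyEvents()
  }
  cultivationRecord(samples = samples, events = events, ...)
}

#' Write a cultivation record to CSV files
#'
#' Inverse of [readRecord()]; `readRecord(writeRecord(...))` round-trips.
#'
#' @param rec A `cultivation_record`.
#' @param timeseries_file,events_file Output paths.
#' @return `rec`, invisibly.
#' @export
writeRecord <- function(rec, timeseries_file, events_file = NULL) {
  write.csv(rec$samples, timeseries_file, row.names = FALSE, na = "")
  if (!is.null(events_file)) {
    write.csv(rec$events, events_file, row.names = FALSE, na = "")
  }
  invisible(rec)
}

.volumeAt <- function(rec, t) {
  e <- rec$events
  vapply(t, function(ti) {
    v <- rec$initial_volume
    if (nrow(e)) {
      inst <- e$kind != "continuous"
      v <- v + sum(e$volume_delta_L[inst & e$t_start_h <= ti])
      cont <- e[e$kind == "continuous", , drop = FALSE]
      if (nrow(cont)) {
        frac <- pmin(pmax((ti - cont$t_start_h) /
                            (cont$t_end_h - cont$t_start_h), 0), 1)
        v <- v + sum(frac * cont$volume_delta_L)
      }
    }
    v
  }, numeric(1))
}

#' Culture volume at time t
#'
#' Initial volume plus the signed volume changes of all events up to `t`;
#' continuous segments contribute pro-rata. Piecewise linear between
#' instantaneous events.
#'
#' @param rec A `cultivation_record`.
#' @param t Time(s) in h, within `[0, max(sample time)]`.
#' @return Volume(s) in L.
#' @export
volumeAt <- function(rec, t) {
  tmax <- max(c(rec$samples$t_h, rec$events$t_end_h,
                rec$events$t_start_h), na.rm = TRUE)
  if (any(t < 0 | t > tmax + 1e-9)) stop("t outside the record's time range")
  .volumeAt(rec, t)
}

#' Interpolated sugar concentration at time t
#'
#' Linear interpolation between samples. Note that at a pulse-feed time the
#' measured sample reflects the pre-feed broth (samples are drawn before
#' feeding).
#'
#' @inheritParams volumeAt
#' @return Concentration(s) in g/L.
#' @export
sugarConcAt <- function(rec, t) {
  s <- rec$samples[!is.na(rec$samples$sugar_gL), ]
  if (nrow(s) < 2) stop("need at least two sugar measurements to interpolate")
  approx(s$t_h, s$sugar_gL, xout = t, rule = 2)$y
}

#' Total sugar mass applied to a cultivation
#'
#' Initial dissolved mass (first sugar concentration times initial volume)
#' plus all feed sugar masses. Continuous segments extending beyond the last
#' sample contribute pro-rata up to the record end.
#'
#' @param rec A `cultivation_record`.
#' @return Mass in g.
#' @export
appliedSugar <- function(rec) {
  s0 <- rec$samples$sugar_gL[1]
  if (is.na(s0)) stop("initial sugar concentration missing")
  total <- s0 * rec$initial_volume
  e <- rec$events
  if (nrow(e)) {
    t_end <- max(rec$samples$t_h)
    total <- total + sum(e$sugar_mass_g[e$kind == "pulse"], na.rm = TRUE)
    cont <- e[e$kind == "continuous", , drop = FALSE]
    if (nrow(cont)) {
      frac <- pmin(pmax((t_end - cont$t_start_h) /
                          (cont$t_end_h - cont$t_start_h), 0), 1)
      total <- total + sum(frac * cont$sugar_mass_g)
    }
  }
  total
}

#' Total sugar mass metabolized over a cultivation
#'
#' Total applied sugar minus the residual dissolved mass at the final sample
#' (final concentration times final volume) minus sugar removed with sample
#' withdrawals (interpolated concentration at the withdrawal time times the
#' withdrawn volume).
#'
#' @param rec A `cultivation_record`.
#' @return Mass in g; never exceeds the total applied.
#' @export
metabolizedSugar <- function(rec) {
  s <- rec$samples
  if (nrow(s) < 2) stop("need at least two samples")
  s_final <- s$sugar_gL[nrow(s)]
  if (is.na(s_final)) stop("final sugar concentration missing")
  t_final <- s$t_h[nrow(s)]
  residual <- s_final * .volumeAt(rec, t_final)
  e <- rec$events
  withdrawn <- 0
  w <- e[e$kind == "sample_withdrawal", , drop = FALSE]
  if (nrow(w)) {
    withdrawn <- sum(sugarConcAt(rec, w$t_start_h) * abs(w$volume_delta_L))
  }
  appliedSugar(rec) - residual - withdrawn
}

#' Lipid titer time series of a record
#'
#' The derived quantity `cdw_gL * fame_pct_cdw / 100`, g/L.
#'
#' @param rec A `cultivation_record`.
#' @return Numeric vector aligned with the record's samples.
#' @export
lipidTiter <- function(rec) {
  rec$samples$cdw_gL * rec$samples$fame_pct_cdw / 100
}
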