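#' Feed solution composition
#'
#' An aqueous sugar feed characterized by its sugar concentration, its
#' density, and the derived sugar mass fraction (g sugar per g feed). A
#' typical feed mixes equal volumes of a 500 g/L sugar stock with salt and
#' trace-element solutions, giving ~250 g sugar per litre of feed.
#'
#' @param sugar_conc Sugar concentration of the feed, g/L.
#' @param density Feed density, g/L; >= 1000 for aqueous sugar feeds.
#' @param species [chemSpecies()] of the sugar.
#' @return Object of class `feed_solution` with the additional field
#'   `sugar_mass_fraction = sugar_conc / density`.
#' @export
feedSolution <- function(sugar_conc, density,
                         species = speciesRegistry()$glucose) {
  stopifnot(sugar_conc > 0, density >= 1000, sugar_conc < density)
  structure(
    list(sugar_species = species, sugar_conc = sugar_conc, density = density,
         sugar_mass_fraction = sugar_conc / density),
    class = "feed_solution"
  )
}

#' Feed plan: pulses and/or continuous segments
#'
#' @param label Plan label.
#' @param pulses `data.frame` with columns `t_h`, `sugar_mass_g`,
#'   `volume_L` (the volume each pulse adds).
#' @param segments `data.frame` with columns `t_start_h`, `t_end_h`,
#'   `pump_rate_g_per_h` (g feed/h) plus a `solution` ([feedSolution()])
#'   shared by all segments; per-segment dilution rates `D` (1/h) are
#'   stored alongside when computed.
#' @param solution Optional [feedSolution()] for continuous segments.
#' @return Object of class `feed_plan`.
#' @export
feedPlan <- function(label, pulses = NULL, segments = NULL, solution = NULL) {
  if (is.null(pulses)) {
    pulses <- data.frame(t_h = numeric(0), sugar_mass_g = numeric(0),
                         volume_L = numeric(0))
  }
  if (is.null(segments)) {
    segments <- data.frame(t_start_h = numeric(0), t_end_h = numeric(0),
                           pump_rate_g_per_h = numeric(0), D = numeric(0))
  }
  stopifnot(all(pulses$sugar_mass_g >= 0), all(pulses$volume_L >= 0))
  if (nrow(segments)) {
    stopifnot(!is.null(solution), all(segments$t_end_h > segments$t_start_h),
              all(segments$pump_rate_g_per_h >= 0))
    segments <- segments[order(segments$t_start_h), ]
    if (nrow(segments) > 1 &&
        any(segments$t_start_h[-1] < segments$t_end_h[-nrow(segments)] - 1e-9)) {
      stop("continuous segments overlap")
    }
    if (is.null(segments$D)) segments$D <- NA_real_
  }
  structure(list(label = label, pulses = pulses, segments = segments,
                 solution = solution),
            class = "feed_plan")
}

#' @export
print.feed_plan <- function(x, ...) {
  cat(sprintf("<feed_plan> '%s': %d pulse(s), %d continuous segment(s)\n",
              x$label, nrow(x$pulses), nrow(x$segments)))
  if (nrow(x$pulses)) {
    cat(sprintf("  pulses: %s g at %s h\n",
                paste(round(x$pulses$sugar_mass_g, 1), collapse = ", "),
                paste(x$pulses$t_h, collapse = ", ")))
  }
  invisible(x)
}

#' Sugar mass for a restock-to-target pulse
#'
#' The high-sugar-excess standard strategy: after measuring the current
#' sugar concentration, feed enough sugar to restore a fixed target
#' concentration (e.g. 90 g/L glucose or 60 g/L xylose).
#'
#' @param current_conc Measured concentration before feeding, g/L.
#' @param target_conc Restock target, g/L; must not be below `current_conc`.
#' @param volume Broth volume at feeding, L.
#' @return Sugar mass in g: `(target_conc - current_conc) * volume`. The
#'   volume the pulse itself adds depends on the stock concentration and is
#'   accounted separately (see [planEvents()]).
#' @export
restockPulse <- function(current_conc, target_conc, volume) {
  stopifnot(volume > 0, current_conc >= 0)
  if (any(target_conc < current_conc)) {
    stop("target concentration below current concentration: no negative feed")
  }
  (target_conc - current_conc) * volume
}

#' Average consumption profile from cultivation records
#'
#' Builds the piecewise-constant daily mean consumption-rate profile used
#' to size a calculated feed strategy: for each interval between breaks,
#' the concentration-basis sugar consumption rate is averaged over the
#' supplied records.
#'
#' @param records List of `cultivation_record`s.
#' @param breaks Interval boundaries, h (default daily up to the shortest
#'   record).
#' @return Object of class `consumption_profile`: `data.frame` with columns
#'   `t_start_h`, `t_end_h`, `rate_gLh`, `sd_gLh`, `n_runs`.
#' @export
consumptionProfile <- function(records, breaks = NULL) {
  stopifnot(length(records) >= 1)
  if (is.null(breaks)) {
    tmax <- min(vapply(records, function(r) max(r$samples$t_h), numeric(1)))
    breaks <- seq(0, 24 * floor(tmax / 24), by = 24)
  }
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  n <- length(breaks) - 1
  rates <- matrix(NA_real_, nrow = n, ncol = length(records))
  for (j in seq_along(records)) {
    for (i in seq_len(n)) {
      rates[i, j] <- .concConsumed(records[[j]], breaks[i], breaks[i + 1]) /
        (breaks[i + 1] - breaks[i])
    }
  }
  structure(
    data.frame(t_start_h = breaks[-length(breaks)], t_end_h = breaks[-1],
               rate_gLh = rowMeans(rates),
               sd_gLh = apply(rates, 1, sd),
               n_runs = length(records)),
    class = c("consumption_profile", "data.frame")
  )
}

#' As consumptionProfile, from explicit rates
#'
#' @param breaks Interval boundaries, h.
#' @param rates Mean consumption rates per interval, g/(L h).
#' @param sd Optional rate standard deviations.
#' @param n_runs Number of runs the rates were averaged over.
#' @return A `consumption_profile`.
#' @export
profileFromRates <- function(breaks, rates, sd = NA_real_, n_runs = 1L) {
  stopifnot(length(rates) == length(breaks) - 1, all(rates >= 0),
            all(diff(breaks) > 0))
  structure(
    data.frame(t_start_h = breaks[-length(breaks)], t_end_h = breaks[-1],
               rate_gLh = rates, sd_gLh = sd, n_runs = n_runs),
    class = c("consumption_profile", "data.frame")
  )
}

# integral of a piecewise-constant profile over [t0, t1)
.profileIntegral <- function(profile, t0, t1) {
  if (t1 <= t0) return(0)
  if (t0 < min(profile$t_start_h) - 1e-9 || t1 > max(profile$t_end_h) + 1e-9) {
    stop("profile does not cover the planning horizon [", t0, ", ", t1, "]")
  }
  ov <- pmin(profile$t_end_h, t1) - pmax(profile$t_start_h, t0)
  sum(pmax(ov, 0) * profile$rate_gLh)
}

#' Calculated feed strategy: reduced-excess pulse plan
#'
#' Sizes daily pulse feeds from an average consumption profile so that the
#' predicted sugar concentration never falls below a target excess at its
#' lowest point (~10 g/L in the reduced-sugar strategy): each pulse
#' replaces the consumption predicted until the next feed, topped up if the
#' predicted pre-feed concentration would undershoot the floor.
#'
#' @param profile A [consumptionProfile()].
#' @param min_excess Target minimum concentration, g/L.
#' @param volume Broth volume used to convert concentrations to masses, L.
#' @param feed_times Pulse times, h.
#' @param start_conc Concentration at the first feed time, g/L (default:
#'   `min_excess`, i.e. the batch phase is assumed to have run the sugar
#'   down to the floor).
#' @param horizon End of the planning horizon, h (default: end of profile).
#' @param stock_conc Stock concentration converting pulse mass to added
#'   volume, g/L.
#' @return A [feedPlan()] of pulses; deterministic given the profile.
#' @export
planCfs <- function(profile, min_excess, volume, feed_times,
                    start_conc = min_excess, horizon = max(profile$t_end_h),
                    stock_conc = 500) {
  stopifnot(min_excess > 0, volume > 0, length(feed_times) >= 1,
            all(diff(feed_times) > 0))
  bounds <- c(feed_times, horizon)
  conc <- start_conc
  masses <- numeric(length(feed_times))
  for (i in seq_along(feed_times)) {
    cons <- .profileIntegral(profile, bounds[i], bounds[i + 1])
    need <- cons + max(0, min_excess - conc)
    masses[i] <- need * volume
    conc <- conc + need - cons # predicted concentration at the next feed
  }
  feedPlan(
    label = sprintf("cfs_%ggL_floor", min_excess),
    pulses = data.frame(t_h = feed_times, sugar_mass_g = masses,
                        volume_L = masses / stock_conc)
  )
}

#' Continuous-feed pump rates and dilution rates
#'
#' Converts a daily sugar demand into the pump mass rate of feed solution
#' and the dilution rate: `pump_rate = demand / 24 / sugar_mass_fraction`
#' (g feed/h), volumetric inflow `F = pump_rate / density` (L/h), and
#' `D = F / volume` (1/h).
#'
#' @param daily_sugar_demand Sugar demand per segment day, g/day (vector).
#' @param solution A [feedSolution()].
#' @param volume Broth volume at segment start, L.
#' @return `data.frame` with columns `demand_g_per_day`,
#'   `pump_rate_g_per_h`, `inflow_L_per_h`, `D_per_h`. Homogeneous of
#'   degree one in the demand.
#' @export
continuousRates <- function(daily_sugar_demand, solution, volume) {
  stopifnot(inherits(solution, "feed_solution"), volume > 0,
            all(daily_sugar_demand >= 0))
  if (solution$sugar_mass_fraction <= 0) stop("feed solution carries no sugar")
  pump <- daily_sugar_demand / 24 / solution$sugar_mass_fraction
  inflow <- pump / solution$density
  data.frame(demand_g_per_day = daily_sugar_demand,
             pump_rate_g_per_h = pump,
             inflow_L_per_h = inflow,
             D_per_h = inflow / volume)
}

#' Build a continuous feed plan from daily demands
#'
#' @inheritParams continuousRates
#' @param t_start Start of the continuous fed-batch phase, h.
#' @param label Plan label.
#' @return A [feedPlan()] with one segment per day.
#' @export
planContinuous <- function(daily_sugar_demand, solution, volume,
                           t_start = 48, label = "continuous") {
  rates <- continuousRates(daily_sugar_demand, solution, volume)
  n <- length(daily_sugar_demand)
  segments <- data.frame(
    t_start_h = t_start + 24 * (seq_len(n) - 1),
    t_end_h = t_start + 24 * seq_len(n),
    pump_rate_g_per_h = rates$pump_rate_g_per_h,
    D = rates$D_per_h
  )
  feedPlan(label, segments = segments, solution = solution)
}

#' Summarize a feed plan
#'
#' @param plan A [feedPlan()].
#' @param batch_sugar Sugar mass supplied with the initial batch medium, g.
#' @return List with `total_applied_g` (batch + pulses + sugar delivered by
#'   continuous segments) and `per_feed_g` (mass per pulse/segment).
#' @export
summarizePlan <- function(plan, batch_sugar = 0) {
  stopifnot(inherits(plan, "feed_plan"), batch_sugar >= 0)
  pulse_m <- plan$pulses$sugar_mass_g
  seg_m <- if (nrow(plan$segments)) {
    plan$segments$pump_rate_g_per_h *
      (plan$segments$t_end_h - plan$segments$t_start_h) *
      plan$solution$sugar_mass_fraction
  } else {
    numeric(0)
  }
  list(total_applied_g = batch_sugar + sum(pulse_m) + sum(seg_m),
       per_feed_g = c(pulse_m, seg_m))
}

#' Convert a feed plan into the events-CSV representation
#'
#' @param plan A [feedPlan()].
#' @param stock_conc Fallback stock concentration (g/L) for pulses without
#'   an explicit volume.
#' @return `data.frame` in the events dialect of [cultivationRecord()].
#' @export
planEvents <- function(plan, stock_conc = 500) {
  stopifnot(inherits(plan, "feed_plan"))
  out <- list()
  if (nrow(plan$pulses)) {
    vol <- plan$pulses$volume_L
    if (is.null(vol) || all(is.na(vol))) vol <- plan$pulses$sugar_mass_g / stock_conc
    out$pulses <- data.frame(
      t_start_h = plan$pulses$t_h, t_end_h = NA_real_, kind = "pulse",
      sugar_mass_g = plan$pulses$sugar_mass_g, volume_delta_L = vol,
      pump_rate_g_per_h = NA_real_)
  }
  if (nrow(plan$segments)) {
    s <- plan$segments
    dur <- s$t_end_h - s$t_start_h
    out$segments <- data.frame(
      t_start_h = s$t_start_h, t_end_h = s$t_end_h, kind = "continuous",
      sugar_mass_g = s$pump_rate_g_per_h * dur * plan$solution$sugar_mass_fraction,
      volume_delta_L = s$pump_rate_g_per_h * dur / plan$solution$density,
      pump_rate_g_per_h = s$pump_rate_g_per_h)
  }
  if (!length(out)) return(emptyEvents())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
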