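#' Approximate process carbon balance
#'
#' Distributes the total applied substrate carbon over the process sinks at
#' the final sampling time: CO2 (from the cumulative exhaust-gas signal),
#' lipid-free cell mass (empirical yeast formula C6H10O3N, after
#' subtracting the lipid content, which is intracellular and therefore
#' weighed with the CDW), lipids (configurable carbon fraction, default
#' 0.77), the organic acid, residual dissolved sugar, optionally the carbon
#' removed with daily sample withdrawals, and an unaccounted remainder that
#' makes the fractions sum to one exactly.
#'
#' @param rec A `cultivation_record`.
#' @param species Species registry, see [speciesRegistry()]; the lipid
#'   carbon fraction is configured there.
#' @param v_basis Volume basis converting final concentrations to masses:
#'   `"initial"` (the working volume at inoculation — the basis consistent
#'   with concentration-basis summary tables), `"end"` (volume at the final
#'   sample from the tracked events), or `"tracked"` (end volume, with the
#'   sampled-out sink enabled).
#' @param include_sampled_out Include carbon removed in sample withdrawals
#'   as its own sink (forced on by `v_basis = "tracked"`).
#' @return Object of class `carbon_balance`: `data.frame` `sinks` with
#'   carbon mass (g) and fraction per sink, `total_carbon_applied_g`, the
#'   basis used, and an `overshoot` flag when the unaccounted remainder is
#'   negative.
#' @export
carbonBalance <- function(rec, species = speciesRegistry(),
                          v_basis = c("initial", "end", "tracked"),
                          include_sampled_out = FALSE) {
  v_basis <- match.arg(v_basis)
  if (v_basis == "tracked") include_sampled_out <- TRUE
  s <- rec$samples
  n <- nrow(s)
  for (col in c("cdw_gL", "fame_pct_cdw", "acid_gL", "sugar_gL")) {
    if (is.na(s[[col]][n])) stop("final sample lacks ", col)
  }
  V <- switch(v_basis,
              initial = rec$initial_volume,
              .volumeAt(rec, s$t_h[n]))
  fc_s <- rec$sugar_species$carbon_mass_fraction
  fc_a <- rec$acid_species$carbon_mass_fraction
  fc_x <- species$biomass$carbon_mass_fraction
  fc_l <- species$lipid$carbon_mass_fraction
  fc_co2 <- species$co2$carbon_mass_fraction

  applied_c <- fc_s * appliedSugar(rec)
  lip_frac <- s$fame_pct_cdw[n] / 100
  sink <- c(
    co2 = if (is.na(s$co2_cum_g[n])) NA_real_ else fc_co2 * s$co2_cum_g[n],
    lipid_free_biomass = fc_x * s$cdw_gL[n] * (1 - lip_frac) * V,
    lipid = fc_l * s$cdw_gL[n] * lip_frac * V,
    organic_acid = fc_a * s$acid_gL[n] * V,
    residual_sugar = fc_s * s$sugar_gL[n] * V
  )
  if (include_sampled_out) {
    e <- rec$events
    w <- e[e$kind == "sample_withdrawal", , drop = FALSE]
    out_c <- 0
    if (nrow(w)) {
      conc_c <- function(col) approx(s$t_h, s[[col]], xout = w$t_start_h,
                                     rule = 2)$y
      cdw_w <- conc_c("cdw_gL")
      lf_w <- conc_c("fame_pct_cdw") / 100
      out_c <- sum(abs(w$volume_delta_L) *
                     (fc_x * cdw_w * (1 - lf_w) + fc_l * cdw_w * lf_w +
                        fc_a * conc_c("acid_gL") + fc_s * conc_c("sugar_gL")))
    }
    sink <- c(sink, sampled_out = out_c)
  }
  unaccounted <- applied_c - sum(sink, na.rm = TRUE)
  sink <- c(sink, unaccounted = unaccounted)
  sinks <- data.frame(sink = names(sink), carbon_g = unname(sink),
                      fraction = unname(sink) / applied_c)
  structure(
    list(sinks = sinks, total_carbon_applied_g = applied_c,
         volume_basis = v_basis, volume_L = V,
         co2_absent = is.na(s$co2_cum_g[n]),
         overshoot = !is.na(unaccounted) && unaccounted < 0),
    class = "carbon_balance"
  )
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat(sprintf("<carbon_balance> %.2f g substrate carbon (%s-volume basis)\n",
              x$total_carbon_applied_g, x$volume_basis))
  with(x$sinks, for (i in seq_along(sink)) {
    cat(sprintf("  %-20s %7.2f g  %6.2f %%\n", sink[i], carbon_g[i],
                100 * fraction[i]))
  })
  if (x$overshoot) cat("  (closure overshoots: negative unaccounted remainder)\n")
  invisible(x)
}

#' Fraction of substrate carbon emitted as CO2
#'
#' The volume-independent headline of the carbon balance: carbon in the
#' cumulative CO2 divided by carbon in the applied sugar.
#'
#' @param co2_mass Cumulative CO2 mass, g.
#' @param sugar_mass Total applied sugar mass, g.
#' @param sugar [chemSpecies()] of the sugar.
#' @param species Species registry.
#' @return Percentage of applied carbon.
#' @export
co2CarbonPct <- function(co2_mass, sugar_mass,
                         sugar = speciesRegistry()$glucose,
                         species = speciesRegistry()) {
  100 * carbonMass(species$co2, co2_mass) / carbonMass(sugar, sugar_mass)
}

#' CO2 produced per cell dry mass
#'
#' @param rec A `cultivation_record` with a cumulative CO2 signal.
#' @param v_basis Volume basis for the total cell dry mass.
#' @return g CO2 per g CDW.
#' @export
co2PerCdw <- function(rec, v_basis = c("initial", "end")) {
  v_basis <- match.arg(v_basis)
  s <- rec$samples
  n <- nrow(s)
  if (is.na(s$co2_cum_g[n])) stop("cumulative CO2 missing")
  if (is.na(s$cdw_gL[n]) || s$cdw_gL[n] <= 0) stop("final CDW missing or zero")
  V <- if (v_basis == "initial") rec$initial_volume else .volumeAt(rec, s$t_h[n])
  s$co2_cum_g[n] / (s$cdw_gL[n] * V)
}
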