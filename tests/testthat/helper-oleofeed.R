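# Shared fixtures, built in code.

# noise-free simulation parameters
nfParams <- function(preset = "glucose", ...) {
  simParams(preset, noise_sd = c(conc = 0, cdw = 0, co2 = 0), ...)
}

# the continuous-feed plans matching the published schedules (glucose: 89 g
# over 4 days from 48 h; xylose: 101 g), feed ~250 g sugar/L, implied
# densities from the printed pump rates
gluSolution <- function() feedSolution(250, 1081)
xylSolution <- function() feedSolution(250, 1070)

gluContinuousPlan <- function() {
  planContinuous(c(24, 24, 24, 17), gluSolution(), 1.2, t_start = 48)
}
xylContinuousPlan <- function() {
  planContinuous(c(31, 23.5, 23.5, 23), xylSolution(), 1.2, t_start = 48)
}

# a small hand-built record: linear sugar decline, one pulse, one withdrawal
toyRecord <- function() {
  samples <- data.frame(
    t_h = c(0, 24, 48, 72, 96, 120, 144),
    sugar_gL = c(60, 40, 55, 35, 15, 10, 5),
    nh4_gL = c(1.2, 0.8, 0.3, 0, 0, 0, 0),
    cdw_gL = c(0.5, 5, 12, 18, 20, 21, 22),
    fame_pct_cdw = c(5, 6, 8, 15, 22, 27, 30),
    acid_gL = c(0, 0.5, 1.5, 3, 5, 7, 9),
    co2_cum_g = c(0, 8, 30, 55, 70, 82, 92)
  )
  events <- data.frame(
    t_start_h = c(24, 72),
    t_end_h = NA_real_,
    kind = c("pulse", "sample_withdrawal"),
    sugar_mass_g = c(42, 0),
    volume_delta_L = c(0.084, -0.015),
    pump_rate_g_per_h = NA_real_
  )
  cultivationRecord("toy", samples, events)
}

extdataPath <- function(file) {
  system.file("extdata", file, package = "oleofeed", mustWork = TRUE)
}
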