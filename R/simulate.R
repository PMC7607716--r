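#' Simulation parameters for the fed-batch bioreactor model
#'
#' A minimal Monod-plus-switch model of an oleaginous yeast fed-batch
#' cultivation. Growth follows dual Monod kinetics on sugar and ammonium;
#' lipid synthesis switches on as ammonium is exhausted (nitrogen
#' limitation with carbon excess); organic-acid formation scales with the
#' dissolved sugar excess; CO2 is emitted so that carbon closes exactly
#' (consumed sugar carbon not fixed into cell mass, lipid or acid leaves as
#' CO2). The model is a deliberately simple stand-in that reproduces the
#' qualitative physiology of such processes — biphasic growth/lipogenesis,
#' excess-dependent acid formation, carbon closure — not a mechanistic
#' metabolic model.
#'
#' Rate equations, with `S` sugar, `N` ammonium, `Xf` lipid-free cell mass,
#' `L` lipid, `A` organic acid (all g/L):
#' \deqn{\mu = \mu_{max} \frac{S}{K_s+S} \frac{N}{K_N+N}, \quad
#'       dX_f/dt = \mu X_f, \quad dN/dt = -\mu X_f / Y_{xn}}
#' \deqn{f_N = \max(0, 1 - N/n_{switch}), \quad
#'       dL/dt = q_{lip} f_N \frac{S}{K_{lip}+S} X_f, \quad
#'       dA/dt = q_{acid} \frac{S}{K_{acid}+S} X_f}
#' \deqn{\sigma = \mu X_f/Y_{xs} + (dL/dt)/Y_{ls} + (dA/dt)/Y_{as} + m_s X_f,
#'       \quad dS/dt = -\sigma}
#'
#' Two presets ship, `"glucose"` and `"xylose"`, tuned so that headline
#' magnitudes resemble typical Saitozyma podzolica fed-batch runs (final
#' CDW ~25-27 g/L, lipid fraction ~0.27-0.30 at ~142 h, ammonium exhausted
#' near 70 h, gluconic acid ~10 g/L at ~10 g/L sugar excess vs ~20 g/L at
#' high excess, xylonic acid < 1 g/L).
#'
#' @param preset `"glucose"` or `"xylose"`.
#' @param ... Named overrides of any parameter field.
#' @return Object of class `sim_params`: a list with fields `mu_max` (1/h),
#'   `Ks`, `K_N`, `K_lip`, `K_acid`, `n_switch` (g/L), `Y_xn`, `Y_xs`,
#'   `Y_ls`, `Y_as` (g/g), `q_lip_max`, `q_acid_max` (g/(g h)), `m_s`
#'   (g/(g h)), `S0`, `N0`, `X0` (g/L), `V0` (L), `dt` (h),
#'   `sampling_times` (h), `sample_volume_L` (L withdrawn per sampling),
#'   `noise_sd` (named relative sds: conc, cdw, co2), `seed` (integer).
#' @export
simParams <- function(preset = c("glucose", "xylose"), ...) {
  preset <- match.arg(preset)
  p <- list(
    mu_max = 0.085, Ks = 0.5, K_N = 0.04,
    Y_xn = 17.8, Y_xs = 0.40,
    q_lip_max = 0.0062, K_lip = 1, n_switch = 0.15, Y_ls = 0.27,
    q_acid_max = 0.018, K_acid = 15, Y_as = 1.05,
    m_s = 0.010,
    S0 = 59.2, N0 = 1.29, X0 = 0.4, V0 = 1.2,
    dt = 0.01, sampling_times = c(0, 24, 46, 70, 94, 118, 142),
    sample_volume_L = 0.017,
    noise_sd = c(conc = 0.05, cdw = 0.03, co2 = 0.02),
    seed = 1L,
    sugar = "glucose", acid = "gluconic_acid"
  )
  if (preset == "xylose") {
    p$mu_max <- 0.078
    p$Y_xs <- 0.38
    p$q_lip_max <- 0.0068
    p$q_acid_max <- 0.0015
    p$Y_as <- 1.00
    p$S0 <- 40.8
    p$sugar <- "xylose"; p$acid <- "xylonic_acid"
  }
  p <- modifyList(p, list(...))
  stopifnot(p$dt <= 0.1, p$mu_max > 0, p$Y_xs > 0, p$Y_xs < 1.2,
            p$Y_ls > 0, p$Y_ls < 1.2, p$Y_as > 0, p$Y_as < 1.2)
  structure(p, class = "sim_params")
}

#' Initial simulation state
#'
#' @param params A [simParams()] object.
#' @return Object of class `sim_state`: time `t` (h), volume `V` (L),
#'   concentrations `S`, `N`, `Xf`, `L`, `A` (g/L), cumulative CO2 mass
#'   `CO2` (g) and cumulative consumed sugar mass `consumed` (g).
#' @export
initialState <- function(params) {
  structure(
    list(t = 0, V = params$V0, S = params$S0, N = params$N0,
         Xf = params$X0, L = 0, A = 0, CO2 = 0, consumed = 0),
    class = "sim_state"
  )
}

# Carbon fractions used for the closure-by-construction CO2 term.
.simCarbon <- function(params) {
  reg <- speciesRegistry()
  list(
    s = reg[[params$sugar]]$carbon_mass_fraction,
    x = reg$biomass$carbon_mass_fraction,
    l = reg$lipid$carbon_mass_fraction,
    a = reg[[params$acid]]$carbon_mass_fraction,
    co2 = reg$co2$carbon_mass_fraction
  )
}

# Per-litre derivatives of (S, N, Xf, L, A, CO2_C, consumed); CO2_C is
# carbon, converted to CO2 mass outside. CO2_C is a fixed linear
# combination of the other derivatives, so RK4 preserves carbon closure to
# machine precision.
.simDeriv <- function(y, p, fc) {
  S <- max(y[1], 0); N <- max(y[2], 0)
  Xf <- y[3]
  mu <- p$mu_max * S / (p$Ks + S) * N / (p$K_N + N)
  dXf <- mu * Xf
  dN <- -dXf / p$Y_xn
  fN <- max(0, 1 - N / p$n_switch)
  dL <- p$q_lip_max * fN * S / (p$K_lip + S) * Xf
  dA <- p$q_acid_max * S / (p$K_acid + S) * Xf
  sigma <- dXf / p$Y_xs + dL / p$Y_ls + dA / p$Y_as + p$m_s * Xf *
    S / (p$Ks + S)
  dCO2C <- fc$s * sigma - fc$x * dXf - fc$l * dL - fc$a * dA
  c(-sigma, dN, dXf, dL, dA, dCO2C, sigma)
}

#' Advance the bioreactor state by one integration step
#'
#' Fourth-order Runge-Kutta step of the rate equations at constant volume
#' (feeds and withdrawals are separate events, see [applyFeed()]). Sugar
#' consumption is Monod-limited so concentrations remain non-negative for
#' any step size at which the scheme is stable; a residual negative
#' undershoot is clipped at zero.
#'
#' @param state A `sim_state`.
#' @param params A [simParams()] object.
#' @param dt Step size in h.
#' @return The advanced `sim_state`.
#' @export
stepState <- function(state, params, dt) {
  stopifnot(dt > 0)
  fc <- .simCarbon(params)
  y <- c(state$S, state$N, state$Xf, state$L, state$A, 0, 0)
  k1 <- .simDeriv(y, params, fc)
  k2 <- .simDeriv(y + dt / 2 * k1, params, fc)
  k3 <- .simDeriv(y + dt / 2 * k2, params, fc)
  k4 <- .simDeriv(y + dt * k3, params, fc)
  y2 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  state$S <- max(y2[1], 0)
  state$N <- max(y2[2], 0)
  state$Xf <- y2[3]; state$L <- y2[4]; state$A <- y2[5]
  state$CO2 <- state$CO2 + y2[6] * state$V * (44.009 / 12.011)
  state$consumed <- state$consumed + y2[7] * state$V
  state$t <- state$t + dt
  state
}

#' Apply a feed or withdrawal event to a simulation state
#'
#' Pulse (or per-step continuous chunk): sugar mass dissolves into the
#' enlarged volume, all other concentrations are diluted by `V/(V+dV)`.
#' Sample withdrawal: volume shrinks, concentrations unchanged.
#'
#' @param state A `sim_state`.
#' @param sugar_mass Sugar mass added, g.
#' @param volume_delta Signed volume change, L.
#' @param kind `"pulse"`, `"continuous"` or `"sample_withdrawal"`.
#' @return The updated `sim_state`.
#' @export
applyFeed <- function(state, sugar_mass = 0, volume_delta = 0,
                      kind = "pulse") {
  V2 <- state$V + volume_delta
  if (V2 <= 0) stop("event would make the volume non-positive")
  if (kind == "sample_withdrawal") {
    if (volume_delta >= 0) stop("withdrawal must remove volume")
    state$V <- V2
    return(state)
  }
  dil <- state$V / V2
  state$S <- (state$S * state$V + sugar_mass) / V2
  state$N <- state$N * dil
  state$Xf <- state$Xf * dil
  state$L <- state$L * dil
  state$A <- state$A * dil
  state$V <- V2
  state
}

#' Simulate a fed-batch cultivation
#'
#' Integrates the bioreactor model over the sampling horizon, applying feed
#' events from a plan and/or closed-loop restock-to-target pulses, sampling
#' withdrawals at each sampling time, and multiplicative Gaussian
#' observation noise. Event times are rounded to the integration grid.
#' Repeated runs with equal parameters (including `seed`) are identical.
#'
#' @param params A [simParams()] object.
#' @param plan Optional feed events: a `data.frame` in the events-CSV
#'   dialect (see [cultivationRecord()]) or a [feedPlan()] object.
#' @param restock_target Optional concentration target, g/L: at each
#'   `restock_times` point a pulse restores the sugar concentration to this
#'   target (the high-sugar-excess standard strategy).
#' @param restock_times Times of closed-loop restocks, h.
#' @param pulse_stock_conc Stock solution concentration used to convert
#'   pulse masses to added volume, g/L.
#' @param label Label of the resulting record.
#' @return A `cultivation_record` with noisy observations. The noise-free
#'   states and true cumulative consumption are attached as attribute
#'   `"truth"` (a `data.frame` at the sampling times) together with
#'   `"true_totals"` (applied/consumed/withdrawn-carbon bookkeeping).
#' @export
simulateCultivation <- function(params, plan = NULL, restock_target = NULL,
                                restock_times = c(24, 46, 70, 94, 118),
                                pulse_stock_conc = 500, label = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(plan, "feed_plan")) plan <- planEvents(plan, pulse_stock_conc)
  if (is.null(plan)) plan <- emptyEvents()
  fc <- .simCarbon(params)
  dt <- params$dt
  st <- params$sampling_times
  horizon <- max(st)
  n_steps <- round(horizon / dt)

  pulses <- plan[plan$kind == "pulse", , drop = FALSE]
  cont <- plan[plan$kind == "continuous", , drop = FALSE]
  # grid indices (1-based step boundaries) of samples, pulses, restocks
  idx_of <- function(t) as.integer(round(t / dt)) + 1L
  sample_idx <- idx_of(st)
  pulse_mass <- pulse_dv <- numeric(n_steps + 1)
  if (nrow(pulses)) {
    ip <- idx_of(pulses$t_start_h)
    for (j in seq_len(nrow(pulses))) {
      pulse_mass[ip[j]] <- pulse_mass[ip[j]] + pulses$sugar_mass_g[j]
      pulse_dv[ip[j]] <- pulse_dv[ip[j]] + pulses$volume_delta_L[j]
    }
  }
  restock_idx <- if (!is.null(restock_target)) idx_of(restock_times) else integer(0)
  # per-step continuous inflow (sugar mass, volume), first-order in dt
  cont_dm <- cont_dv <- numeric(n_steps)
  if (nrow(cont)) {
    for (j in seq_len(nrow(cont))) {
      steps <- seq.int(idx_of(cont$t_start_h[j]),
                       min(idx_of(cont$t_end_h[j]) - 1L, n_steps))
      dur <- cont$t_end_h[j] - cont$t_start_h[j]
      cont_dm[steps] <- cont_dm[steps] + cont$sugar_mass_g[j] / dur * dt
      cont_dv[steps] <- cont_dv[steps] + cont$volume_delta_L[j] / dur * dt
    }
  }

  # state: y = (S, N, Xf, L, A) g/L; V, CO2 (g), consumed (g) as scalars
  y <- c(params$S0, params$N0, params$X0, 0, 0)
  V <- params$V0
  CO2 <- 0; consumed <- 0; max_sigma <- 0
  applied <- y[1] * V
  withdrawn_c <- 0; withdrawn_sugar <- 0
  truth <- matrix(NA_real_, length(st), 9,
                  dimnames = list(NULL, c("t", "V", "S", "N", "Xf", "L", "A",
                                          "CO2", "consumed")))
  ev_t <- ev_kind <- ev_mass <- ev_dv <- list()
  k <- 0L
  add_event <- function(t, kind, mass, dv) {
    k <<- k + 1L
    ev_t[[k]] <<- t; ev_kind[[k]] <<- kind
    ev_mass[[k]] <<- mass; ev_dv[[k]] <<- dv
  }
  dilute <- function(mass, dv) {
    V2 <- V + dv
    y <<- c((y[1] * V + mass) / V2, y[-1] * V / V2)
    V <<- V2
  }
  co2_factor <- 44.009 / 12.011

  for (i in seq_len(n_steps + 1)) {
    t_now <- (i - 1) * dt
    hit <- match(i, sample_idx)
    # 1) sample observation (pre-feed, pre-withdrawal)
    if (!is.na(hit)) {
      truth[hit, ] <- c(t_now, V, y, CO2, consumed)
      # 2) sampling withdrawal (not at t = 0, not after the final sample)
      if (hit > 1L && hit < length(st)) {
        dv <- params$sample_volume_L
        withdrawn_c <- withdrawn_c +
          dv * (fc$s * y[1] + fc$x * y[3] + fc$l * y[4] + fc$a * y[5])
        withdrawn_sugar <- withdrawn_sugar + dv * y[1]
        V <- V - dv
        if (V <= 0) stop("withdrawal would empty the reactor")
        add_event(t_now, "sample_withdrawal", 0, -dv)
      }
    }
    # 3) planned pulses
    if (pulse_mass[i] > 0 || pulse_dv[i] > 0) {
      dilute(pulse_mass[i], pulse_dv[i])
      applied <- applied + pulse_mass[i]
      add_event(t_now, "pulse", pulse_mass[i], pulse_dv[i])
    }
    # 4) closed-loop restock to target
    if (i %in% restock_idx) {
      m <- max(0, (restock_target - y[1]) * V)
      if (m > 0) {
        dilute(m, m / pulse_stock_conc)
        applied <- applied + m
        add_event(t_now, "pulse", m, m / pulse_stock_conc)
      }
    }
    if (i > n_steps) break
    # 5) continuous inflow over [t_now, t_now + dt), as a per-step chunk
    if (cont_dm[i] > 0 || cont_dv[i] > 0) {
      dilute(cont_dm[i], cont_dv[i])
      applied <- applied + cont_dm[i]
    }
    # 6) integrate biology: RK4 at constant volume
    y7 <- c(y, 0, 0)
    k1 <- .simDeriv(y7, params, fc)
    k2 <- .simDeriv(y7 + dt / 2 * k1, params, fc)
    k3 <- .simDeriv(y7 + dt / 2 * k2, params, fc)
    k4 <- .simDeriv(y7 + dt * k3, params, fc)
    y7 <- y7 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y <- pmax(y7[1:5], 0)
    CO2 <- CO2 + y7[6] * V * co2_factor
    consumed <- consumed + y7[7] * V
    if (y7[7] / dt > max_sigma) max_sigma <- y7[7] / dt
  }

  truth <- as.data.frame(truth)
  events <- if (k) data.frame(
    t_start_h = unlist(ev_t), t_end_h = NA_real_, kind = unlist(ev_kind),
    sugar_mass_g = unlist(ev_mass), volume_delta_L = unlist(ev_dv),
    pump_rate_g_per_h = NA_real_) else emptyEvents()
  events <- list(events)
  # continuous segments enter the record as single events
  if (nrow(cont)) {
    events[[length(events) + 1]] <- cont
  }
  events <- if (length(events)) do.call(rbind, events) else emptyEvents()
  events <- events[order(events$t_start_h), ]
  rownames(events) <- NULL

  # observations: multiplicative Gaussian noise, seeded
  set.seed(params$seed)
  ns <- params$noise_sd
  rel <- function(x, sdr) x * (1 + rnorm(length(x), 0, sdr))
  cdw_true <- truth$Xf + truth$L
  fame_true <- ifelse(cdw_true > 0, 100 * truth$L / cdw_true, 0)
  nh4_obs <- pmax(rel(truth$N, ns[["conc"]]), 0)
  nh4_obs[nh4_obs < 0.01] <- 0 # below-detection
  samples <- data.frame(
    t_h = truth$t,
    sugar_gL = pmax(rel(truth$S, ns[["conc"]]), 0),
    sugar_sd = truth$S * ns[["conc"]],
    nh4_gL = nh4_obs,
    cdw_gL = pmax(rel(cdw_true, ns[["cdw"]]), 0),
    cdw_sd = cdw_true * ns[["cdw"]],
    fame_pct_cdw = pmin(pmax(rel(fame_true, ns[["cdw"]]), 0), 100),
    fame_sd = fame_true * ns[["cdw"]],
    acid_gL = pmax(rel(truth$A, ns[["conc"]]), 0),
    acid_sd = truth$A * ns[["conc"]],
    co2_cum_g = pmax(rel(truth$CO2, ns[["co2"]]), 0)
  )
  reg <- speciesRegistry()
  rec <- cultivationRecord(
    label = label %||% paste0("sim_", params$sugar),
    samples = samples, events = events,
    sugar_species = reg[[params$sugar]], acid_species = reg[[params$acid]],
    initial_volume = params$V0
  )
  attr(rec, "truth") <- truth
  attr(rec, "true_totals") <- list(
    applied_sugar_g = applied, consumed_sugar_g = truth$consumed[nrow(truth)],
    withdrawn_carbon_g = withdrawn_c, withdrawn_sugar_g = withdrawn_sugar
  )
  # true peak volumetric consumption rate, g/(L h), per-step average
  attr(rec, "true_peak_sigma") <- max_sigma
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Carbon closure error of a simulated record
#'
#' Compares total applied sugar carbon against the carbon found in all
#' sinks (cell mass, lipid, acid, residual sugar, CO2, withdrawn broth) at
#' the final sampling time, using the simulator's noise-free truth.
#'
#' @param rec A record produced by [simulateCultivation()].
#' @return Relative closure error (dimensionless; 0 is perfect).
#' @export
carbonClosureError <- function(rec) {
  truth <- attr(rec, "truth")
  tot <- attr(rec, "true_totals")
  if (is.null(truth)) stop("record carries no simulation truth")
  reg <- speciesRegistry()
  fcs <- rec$sugar_species$carbon_mass_fraction
  fca <- rec$acid_species$carbon_mass_fraction
  fin <- truth[nrow(truth), ]
  ini <- truth[1, ]
  sinks <- fin$V * (reg$biomass$carbon_mass_fraction * fin$Xf +
                      reg$lipid$carbon_mass_fraction * fin$L +
                      fca * fin$A + fcs * fin$S) +
    reg$co2$carbon_mass_fraction * fin$CO2 + tot$withdrawn_carbon_g
  # sources: applied sugar carbon plus the carbon of the inoculum biomass
  applied_c <- fcs * tot$applied_sugar_g +
    ini$V * (reg$biomass$carbon_mass_fraction * ini$Xf +
               reg$lipid$carbon_mass_fraction * ini$L + fca * ini$A)
  (applied_c - sinks) / applied_c
}
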