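# Two-compartment drug transport on the frozen tumor + IFF state: the
# extracellular concentration s1 (per IF volume) is advected by the Darcy
# flux, diffuses, exchanges with the intracellular concentration s2 (per cell
# volume) across the cell membrane, and exchanges with the vasculature
# (diffusive wall flux + convective extravasation) and lymphatics.  The
# conserved variables are the tissue densities m1 = phi_f s1, m2 = phi_c s2.

#' Plasma drug concentration for an injection schedule
#'
#' Bolus: exponential decay `exp(-t/tau)` normalized to 1 at t = 0.
#' Infusion: constant 1 on `[0, T]`, zero afterwards.
#' @param t time s (>= 0); @param schedule `"bolus"` or `"infusion"`;
#' @param tau bolus decay time s; @param T_inf infusion duration s.
#' @return plasma concentration (normalized), vectorized over `t`.
#' @export
plasma_concentration <- function(t, schedule = c("bolus", "infusion"),
                                 tau = 3600, T_inf = 24 * 3600) {
  schedule <- match.arg(schedule)
  if (any(t < 0)) stop("negative time")
  if (schedule == "bolus") exp(-t / tau) else as.numeric(t <= T_inf)
}

#' Transmembrane exchange coefficient gamma(phi_c)
#'
#' Built from the single-cell volume and surface and the fraction of the cell
#' surface in contact with the IF: `gamma = phi_c f A_c / V_c` (1/um); the
#' exchange flux is `Gamma_12 = gamma (k12 s1 - k21 s2)` per mixture volume.
#' @param phi_c cell volume fraction; @param params parameters.
#' @export
gamma_exchange <- function(phi_c, params = default_parameters()) {
  dg <- params$drug
  phi_c * dg$contact_fraction * dg$cell_surface / dg$cell_volume
}

#' Transmembrane exchange rate
#' @param s1 extracellular concentration; @param s2 intracellular; @param
#'   phi_c cell fraction; @param params parameters.
#' @return Gamma_12 (concentration per second per mixture volume); zero at the
#'   steady-state ratio `s2/s1 = k12/k21`.
#' @export
exchange_rate <- function(s1, s2, phi_c, params = default_parameters()) {
  gamma_exchange(phi_c, params) * (params$drug$k12 * s1 - params$drug$k21 * s2)
}

#' Maturity-dependent diffusive wall permeability for drug
#'
#' Same interpolation as the hydraulic permeability (resistance proportional
#' to wall thickness, bounded above by the leaky tumor value) with the
#' drug-specific endpoint constants.
#' @param w wall maturity um; @param r radius um; @param params parameters.
#' @return permeability um/s.
#' @export
diffusive_wall_permeability <- function(w, r, params = default_parameters()) {
  .wall_permeability(w, r, params$drug$lambda_diff_tumor,
                     params$drug$lambda_diff_normal,
                     params$iff$wall_thickness_coef)
}

#' Create a drug state on a frozen tumor + IFF solution
#'
#' Precomputes the per-cell exchange coefficients (vascular diffusive wall
#' conductance, convective in/out rates from the IFF source decomposition,
#' lymphatic uptake) so that time stepping is cheap.
#'
#' @param net network with flow; @param state continuum state; @param grid
#'   grid; @param iff `iff_solution`; @param params parameters.
#' @return list of class `drug_state`: s1, s2 arrays (start at 0), phi_f,
#'   phi_c, exchange coefficient fields and bookkeeping of cumulative
#'   vascular/lymphatic mass fluxes.
#' @export
drug_state <- function(net, state, grid, iff, params = default_parameters()) {
  cl <- phase_closure(state)
  phi_c <- cl$phi
  phi_f <- cl$phi_f
  V <- cell_volume(grid)
  samp <- iff$sampling
  diffw <- zero_field(grid)
  if (nrow(samp)) {
    segs <- net$segments
    row <- match(samp$seg, segs$id)
    lamd <- diffusive_wall_permeability(segs$w[row], segs$r[row], params)
    wt <- cic_weights(grid, samp)
    coefs <- wt$w * samp$a[wt$point] * lamd[wt$point] / V
    t <- tapply(coefs, wt$cell, sum)
    diffw[as.integer(names(t))] <- t
  }
  structure(list(
    grid = grid, s1 = zero_field(grid), s2 = zero_field(grid),
    phi_f = phi_f, phi_c = phi_c,
    Adiff = assemble_diffusion(grid, params$drug$D_s * phi_f),
    diffw = diffw,                       # diffusive wall conductance (1/s)
    Qin = iff$sources$Qin_v,             # convective extravasation (1/s)
    Qoutv = iff$sources$Qout_v,          # uptake into vessels (1/s)
    QoutL = pmax(iff$sources$Qout_L, 0), # lymphatic uptake (1/s)
    u = iff$u,
    influx = 0, efflux = 0, t = 0), class = "drug_state")
}

# stable time step for the split scheme
drug_dt <- function(ds, params) {
  h <- ds$grid$h
  vmax <- max(abs(unlist(ds$u[c("ux", "uy", "uz")])), 1e-12)
  dt_adv <- params$numerics$cfl * h / vmax
  dt_diff <- params$numerics$cfl * h^2 / (2 * 3 * params$drug$D_s)
  gmax <- max(gamma_exchange(ds$phi_c, params) * params$drug$k12 /
                pmax(ds$phi_f, 0.05), 1e-12)
  wmax <- max(ds$diffw / pmax(ds$phi_f, 0.05),
              (ds$Qin + ds$Qoutv + ds$QoutL) / pmax(ds$phi_f, 0.05), 1e-12)
  min(dt_adv, dt_diff, 0.5 / gmax, 0.5 / wmax)
}

#' Advance the drug state by one operator-split step
#'
#' Sub-steps, each conservative: (a) upwind advection of `phi_f s1` by the IF
#' flux (skipped in convection-off mode); (b) diffusion of s1 through the
#' fluid fraction; (c) exact transmembrane exchange (closed-form 2x2 linear
#' update, mass-preserving to round-off); (d) vascular and lymphatic
#' exchange: diffusive wall flux `lam S (s_B - s1)`, convective extravasation
#' carrying `s_B`, and fluid uptake removing `s1`.
#'
#' @param ds drug state; @param dt step s; @param sB plasma concentration over
#'   the step; @param params parameters; @param convection logical.
#' @return updated drug state (with `influx`/`efflux` accumulators).
#' @export
drug_step <- function(ds, dt, sB, params = default_parameters(),
                      convection = TRUE) {
  grid <- ds$grid
  V <- cell_volume(grid)
  phi_f <- pmax(ds$phi_f, 1e-6)
  m1 <- ds$phi_f * ds$s1
  # (a) advection of m1 with the Darcy flux
  if (convection) {
    vmax <- max(abs(unlist(ds$u[c("ux", "uy", "uz")])), 0)
    if (vmax * dt / grid$h > 1) stop("CFL violation in drug advection")
    m1 <- m1 + .advect_flux_s(grid, ds$s1, ds$u, dt)
  }
  s1 <- m1 / phi_f
  # (b) diffusion of s1 with conductance D phi_f on faces (operator cached)
  m1 <- m1 - dt * array(as.numeric(ds$Adiff %*% as.vector(s1)),
                        dim = grid$dims)
  s1 <- m1 / phi_f
  if (min(s1) < -1e-8 * max(abs(s1), 1))
    stop("negative concentration beyond tolerance: reduce dt")
  s1[s1 < 0] <- 0
  # (c) exact transmembrane exchange of the linear 2x2 system
  s2 <- ds$s2
  gam <- gamma_exchange(ds$phi_c, params)
  a <- gam * params$drug$k12 / phi_f      # 1/s
  b <- gam * params$drug$k21 / pmax(ds$phi_c, 1e-6)
  lam <- a + b
  act <- lam > 0 & ds$phi_c > 1e-6
  if (any(act)) {
    E <- exp(-lam[act] * dt)
    # equilibrium split of the conserved density m = phi_f s1 + phi_c s2
    s1a <- s1[act]; s2a <- s2[act]
    weq1 <- b[act] / lam[act]             # fraction of "rate space"
    # ds1/dt = -a s1 + b' s2 with b' = b phi_c/phi_f ... solve in (s1, s2):
    # d s1/dt = -(gam k12/phi_f) s1 + (gam k21/phi_f) s2
    # d s2/dt =  (gam k12/phi_c) s1 - (gam k21/phi_c) s2
    a11 <- -gam[act] * params$drug$k12 / phi_f[act]
    a12 <- gam[act] * params$drug$k21 / phi_f[act]
    a21 <- gam[act] * params$drug$k12 / pmax(ds$phi_c[act], 1e-6)
    a22 <- -gam[act] * params$drug$k21 / pmax(ds$phi_c[act], 1e-6)
    tr <- a11 + a22                       # second eigenvalue (det = 0)
    Et <- exp(tr * dt)
    # eigen decomposition: eigenvalue 0 with equilibrium vector, tr with
    # difference vector
    denom <- tr
    w1 <- (a11 * s1a + a12 * s2a) / denom # component along decaying mode
    w2 <- (a21 * s1a + a22 * s2a) / denom
    s1[act] <- s1a + w1 * (Et - 1)
    s2[act] <- s2a + w2 * (Et - 1)
  }
  # (d) vascular + lymphatic exchange, exact exponential per cell (linear in s1)
  sink <- (ds$diffw + ds$Qoutv + ds$QoutL) / phi_f          # 1/s
  src <- (ds$diffw + ds$Qin) * sB / phi_f                   # conc/s
  act2 <- sink > 0
  s1n <- s1
  s1n[act2] <- s1[act2] * exp(-sink[act2] * dt) +
    src[act2] / sink[act2] * (1 - exp(-sink[act2] * dt))
  s1n[!act2] <- s1[!act2] + dt * src[!act2]
  # mass bookkeeping (um^3-normalized concentration mass per volume)
  dm <- ds$phi_f * (s1n - s1)
  ds$influx <- ds$influx + sum(pmax(dm, 0)) * V
  ds$efflux <- ds$efflux + sum(pmax(-dm, 0)) * V
  ds$s1 <- s1n
  ds$s2 <- s2
  ds$t <- ds$t + dt
  ds
}

# conservative upwind advection increment for m1 = phi_f s1 with face flux u
.advect_flux_s <- function(grid, s1, u, dt) {
  d <- grid$dims; h <- grid$h
  inc <- zero_field(grid)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    U <- u[[c("ux", "uy", "uz")[ax]]]
    fdim <- d; fdim[ax] <- d[ax] + 1L
    ixin <- list(seq_len(fdim[1]), seq_len(fdim[2]), seq_len(fdim[3]))
    ixin[[ax]] <- 1L + seq_len(d[ax] - 1L)
    ixlo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixlo[[ax]] <- seq_len(d[ax] - 1L)
    ixhi <- ixlo; ixhi[[ax]] <- 1L + seq_len(d[ax] - 1L)
    slo <- do.call(`[`, c(list(s1), ixlo, list(drop = FALSE)))
    shi <- do.call(`[`, c(list(s1), ixhi, list(drop = FALSE)))
    uf <- do.call(`[`, c(list(U), ixin, list(drop = FALSE)))
    Fv <- uf * ifelse(uf >= 0, slo, shi)
    F <- array(0, dim = fdim)
    F <- do.call(`[<-`, c(list(F), ixin, list(Fv)))
    ixcl <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixch <- ixcl; ixch[[ax]] <- ixcl[[ax]] + 1L
    Flo <- do.call(`[`, c(list(F), ixcl, list(drop = FALSE)))
    Fhi <- do.call(`[`, c(list(F), ixch, list(drop = FALSE)))
    inc <- inc - dt * (Fhi - Flo) / h
  }
  inc
}

#' Simulate drug transport over an observation window
#'
#' Operator-split integration with automatic stable step size; records ICmax
#' and ICAUC of the intracellular concentration online and optional snapshots.
#'
#' @param ds initial drug state ([drug_state()]); @param params parameters;
#'   @param T_obs observation window s (default 96 h); @param schedule
#'   injection schedule (`"bolus"`/`"infusion"`); @param T_inf infusion
#'   duration s; @param convection logical; @param snapshot_times times (s) at
#'   which to store s1/s2 copies; @param dt_max optional cap on the step.
#' @return list: final state, exposure (`icmax`, `icauc` arrays), snapshots,
#'   times, mass trace.
#' @export
simulate_drug <- function(ds, params = default_parameters(), T_obs = 96 * 3600,
                          schedule = "bolus", T_inf = 24 * 3600,
                          convection = TRUE, snapshot_times = numeric(0),
                          dt_max = Inf) {
  dt0 <- min(drug_dt(ds, params), dt_max)
  icmax <- zero_field(ds$grid)
  icauc <- zero_field(ds$grid)
  snaps <- list()
  trace_t <- c(); trace_mass <- c()
  t <- 0
  snap_idx <- 1L
  while (t < T_obs - 1e-9) {
    dt <- min(dt0, T_obs - t)
    sB <- plasma_concentration(t + dt / 2, schedule, params$drug$tau_bolus,
                               T_inf)
    s2_old <- ds$s2
    ds <- drug_step(ds, dt, sB, params, convection)
    t <- ds$t
    icauc <- icauc + (s2_old + ds$s2) / 2 * dt
    icmax <- pmax(icmax, ds$s2)
    if (snap_idx <= length(snapshot_times) && t >= snapshot_times[snap_idx]) {
      snaps[[length(snaps) + 1L]] <- list(t = t, s1 = ds$s1, s2 = ds$s2)
      snap_idx <- snap_idx + 1L
    }
    trace_t <- c(trace_t, t)
    trace_mass <- c(trace_mass,
                    sum(ds$phi_f * ds$s1 + ds$phi_c * ds$s2) * cell_volume(ds$grid))
  }
  list(state = ds, icmax = icmax, icauc = icauc, snapshots = snaps,
       trace = data.frame(t = trace_t, mass = trace_mass))
}

#' Exposure metrics from a recorded trajectory
#'
#' Per-cell maximum over time (ICmax) and trapezoidal time integral (ICAUC)
#' of the intracellular concentration.
#' @param times numeric vector (s); @param s2_list list of s2 arrays at
#'   `times`.
#' @return list(icmax, icauc).
#' @export
exposure_metrics <- function(times, s2_list) {
  if (!length(times)) stop("empty trajectory")
  icmax <- s2_list[[1]]
  icauc <- s2_list[[1]] * 0
  if (length(times) > 1) for (m in 2:length(times)) {
    icmax <- pmax(icmax, s2_list[[m]])
    icauc <- icauc + (s2_list[[m - 1]] + s2_list[[m]]) / 2 *
      (times[m] - times[m - 1])
  }
  list(icmax = icmax, icauc = icauc)
}

#' Length at which the local Peclet number is one
#'
#' `L = D_s / |u|` per cell; infinite where the IF velocity vanishes
#' (diffusion always wins at any length there).
#' @param grid grid; @param u face velocity; @param D_s diffusivity um^2/s.
#' @return cell array of L (um), `Inf` sentinel where |u| = 0.
#' @export
peclet_unit_length <- function(grid, u, D_s) {
  vm <- velocity_magnitude(grid, u)
  out <- D_s / vm
  out[vm == 0] <- Inf
  out
}
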