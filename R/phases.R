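# Continuum tissue state: volume fractions phi_T (tumor cells), phi_N (normal
# cells), phi_D (necrotic debris), fixed phi_ECM, and the interstitial fluid
# fraction phi_f as the incompressibility remainder.  Cells share one velocity
# field driven by the solid pressure gradient against ECM friction.

#' Create a continuum tissue state
#'
#' @param grid grid; @param theta tumor level set (negative inside); @param
#'   params parameters.  Inside the tumor the cell fraction starts at the
#'   tumor homeostatic value, outside at the normal homeostatic value.
#' @return list of class `continuum_state` with fields `grid`, `theta`,
#'   `phiT`, `phiN`, `phiD`, `phi_ecm` and accessors for `phi` (total cells)
#'   and `phi_f`.
#' @export
continuum_state <- function(grid, theta, params = default_parameters()) {
  Hin <- 1 - smoothed_heaviside(theta, params$numerics$heaviside_width)
  st <- list(grid = grid, theta = theta,
             phiT = Hin * params$tissue$phi_h_tumor,
             phiN = (1 - Hin) * params$tissue$phi_h_normal,
             phiD = zero_field(grid),
             phi_ecm = params$tissue$phi_ecm)
  class(st) <- "continuum_state"
  st
}

#' Total cell fraction and interstitial fluid fraction of a state
#' @param state continuum state.
#' @return list(phi, phi_f); `phi_f = 1 - phi - phi_ecm` (volume closure).
#' @export
phase_closure <- function(state) {
  phi <- state$phiT + state$phiN + state$phiD
  list(phi = phi, phi_f = 1 - phi - state$phi_ecm)
}

#' Solid pressure from the total cell fraction
#'
#' Linear elastic law above the relaxed fraction: `p = E (phi - phi0)` for
#' `phi > phi0`, zero below (cells exert no pressure on each other in the
#' relaxed state).  The package works with the product `mobility x E`, so `E`
#' is kept at 1 and the mobility carries the units.
#' @param phi total cell fraction; @param E elastic modulus (kPa); @param phi0
#'   relaxed fraction.
#' @return pressure array.
#' @export
solid_pressure <- function(phi, E = 1, phi0 = 0.3) {
  E * pmax(phi - phi0, 0)
}

#' Tissue cell velocity from the solid pressure
#'
#' `v = -mu grad p` on faces (porous-medium friction against the rigid ECM).
#' @param grid grid; @param p solid pressure; @param mu mobility (x modulus),
#'   um^2/s.
#' @return list(ux, uy, uz) face velocity, um/s.
#' @export
cell_velocity <- function(grid, p, mu) {
  darcy_velocity(grid, p, mu)
}

#' Per-phase source rates (proliferation, apoptosis, necrosis)
#'
#' Proliferation is gated by oxygen (`c > c_prolif`), capped at the maximal
#' rate, and depends linearly on the density deviation from the homeostatic
#' fraction; at the homeostatic fraction and ample oxygen, proliferation and
#' apoptosis cancel exactly.  Apoptosis removes mass without debris; necrosis
#' (for `c < c_necro`) transfers cell mass to the necrotic phase.
#'
#' @param state continuum state; @param c oxygen field; @param params
#'   parameters.
#' @return list(sT, sN, sD) volumetric rates (1/s).
#' @export
phase_sources <- function(state, c, params = default_parameters()) {
  ts <- params$tissue; ox <- params$oxygen
  phi <- phase_closure(state)$phi
  rate_one <- function(phia, phih, cp, ca, cn) {
    gate <- c > ox$c_prolif
    # linear density dependence, normalized to cancel apoptosis at phi_h
    dens <- pmin(1, pmax(0, ts$pressure_sensitivity * (phih - phi) + ca / max(cp, 1e-300)))
    prol <- cp * phia * dens * gate
    apop <- ca * phia
    necr <- cn * phia * (c < ox$c_necro)
    list(net = prol - apop - necr, necr = necr)
  }
  tum <- rate_one(state$phiT, ts$phi_h_tumor, ts$prolif_tumor, ts$apopt_tumor,
                  ts$necro_tumor)
  nor <- rate_one(state$phiN, ts$phi_h_normal, ts$prolif_normal,
                  ts$apopt_normal, ts$necro_normal)
  list(sT = tum$net, sN = nor$net, sD = tum$necr + nor$necr)
}

# conservative upwind advection of a cell field with face velocity v
.advect_upwind <- function(grid, phi, v, dt) {
  d <- grid$dims; h <- grid$h
  out <- phi
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    U <- v[[c("ux", "uy", "uz")[ax]]]
    fdim <- d; fdim[ax] <- d[ax] + 1L
    # upwind face value of phi
    phf <- array(0, dim = fdim)
    ixin <- list(seq_len(fdim[1]), seq_len(fdim[2]), seq_len(fdim[3]))
    ixin[[ax]] <- 1L + seq_len(d[ax] - 1L)
    ixlo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixlo[[ax]] <- seq_len(d[ax] - 1L)
    ixhi <- ixlo; ixhi[[ax]] <- 1L + seq_len(d[ax] - 1L)
    ulo <- do.call(`[`, c(list(phi), ixlo, list(drop = FALSE)))
    uhi <- do.call(`[`, c(list(phi), ixhi, list(drop = FALSE)))
    uf <- do.call(`[`, c(list(U), ixin, list(drop = FALSE)))
    face_val <- ifelse(uf >= 0, ulo, uhi)
    F <- array(0, dim = fdim)
    F <- do.call(`[<-`, c(list(F), ixin, list(uf * face_val)))
    # divergence of flux
    ixcl <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixch <- ixcl; ixch[[ax]] <- ixcl[[ax]] + 1L
    Flo <- do.call(`[`, c(list(F), ixcl, list(drop = FALSE)))
    Fhi <- do.call(`[`, c(list(F), ixch, list(drop = FALSE)))
    out <- out - dt * (Fhi - Flo) / h
  }
  out
}

#' Advance the volume fractions by one step (improved Euler)
#'
#' Conservative finite-volume advection with the shared cell velocity plus the
#' phase source terms, integrated with the second-order improved (Heun) Euler
#' method.  Errors if the advective CFL number exceeds the configured bound.
#'
#' @param state continuum state; @param c oxygen field; @param v face velocity
#'   (um/s); @param dt time step (s); @param params parameters.
#' @return updated state.
#' @export
advance_phases <- function(state, c, v, dt, params = default_parameters()) {
  grid <- state$grid
  vmax <- max(abs(unlist(v[c("ux", "uy", "uz")])), 0)
  if (vmax * dt / grid$h > params$numerics$cfl)
    stop("CFL violation in phase advection: reduce dt")
  step_once <- function(st) {
    s <- phase_sources(st, c, params)
    st2 <- st
    st2$phiT <- .advect_upwind(grid, st$phiT, v, dt) + dt * s$sT
    st2$phiN <- .advect_upwind(grid, st$phiN, v, dt) + dt * s$sN
    st2$phiD <- .advect_upwind(grid, st$phiD, v, dt) + dt * s$sD
    st2
  }
  # improved Euler: average of one full step and the step evaluated at the
  # predictor state
  pred <- step_once(state)
  corr <- step_once(pred)
  out <- state
  out$phiT <- (state$phiT + corr$phiT) / 2
  out$phiN <- (state$phiN + corr$phiN) / 2
  out$phiD <- (state$phiD + corr$phiD) / 2
  cl <- phase_closure(out)
  if (any(cl$phi_f < -1e-6) || any(out$phiT < -1e-6))
    warning("volume closure violated; consider a smaller dt")
  out
}
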