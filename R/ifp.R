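# Stationary interstitial fluid pressure and flow on a frozen tumor state:
# Darcy medium with tissue-dependent conductivity, Starling vessel sources
# (maturity-dependent wall permeability, osmotic offset), lymphatic sinks
# (absent in the tumor), sparse elliptic solve, source decomposition and the
# vascular decay-length / extravasation-fraction diagnostics.

#' Physiologically normal vessel wall thickness
#'
#' Power-law fit `w(r) = a r^b` (um) to microvascular wall-thickness data
#' (about 1.5 um for a 4 um capillary, about 7 um for a 50 um arteriole);
#' anchors the maturity-dependent permeability interpolation.
#' @param r vessel radius um; @param coef named vector c(a, b).
#' @export
normal_wall_thickness <- function(r, coef = c(a = 0.65, b = 0.6)) {
  coef[["a"]] * r^coef[["b"]]
}

#' Maturity-dependent hydraulic wall permeability
#'
#' The wall's hydraulic resistance grows proportionally to its thickness `w`:
#' at the physiologically normal thickness for the radius the permeability
#' equals the normal-capillary value, and as `w` tends to zero it is bounded
#' above by the leaky tumor-capillary value.
#'
#' @param w wall maturity um (>= 0); @param r radius um; @param params
#'   parameters (uses `iff$lambda_l_tumor`, `iff$lambda_l_normal`,
#'   `iff$wall_thickness_coef`).
#' @return permeability um/(kPa s), monotone non-increasing in `w`.
#' @export
wall_hydraulic_permeability <- function(w, r, params = default_parameters()) {
  .wall_permeability(w, r, params$iff$lambda_l_tumor,
                     params$iff$lambda_l_normal,
                     params$iff$wall_thickness_coef)
}

.wall_permeability <- function(w, r, lam_tumor, lam_normal, coef) {
  if (any(w < 0)) stop("wall maturity must be >= 0")
  wN <- normal_wall_thickness(r, coef)
  lam <- ifelse(w <= 0, lam_tumor, lam_normal * wN / w)
  pmin(lam, lam_tumor)
}

#' Tissue hydraulic conductivity field
#'
#' Smoothly interpolates the normal / tumor coefficients across the tumor
#' interface with the smoothed Heaviside of the level set, and ramps to the
#' necrotic coefficient where the necrotic fraction dominates.
#' @param state continuum state; @param params parameters.
#' @return K array, um^2/(kPa s).
#' @export
tissue_conductivity <- function(state, params = default_parameters()) {
  iff <- params$iff
  Hin <- 1 - smoothed_heaviside(state$theta, params$numerics$heaviside_width)
  K <- iff$K_normal * (1 - Hin) + iff$K_tumor * Hin
  cl <- phase_closure(state)
  wnec <- ifelse(cl$phi > 0, state$phiD / pmax(cl$phi, 1e-12), 0)
  K * (1 - wnec) + iff$K_necrotic * wnec
}

#' Lymphatic surface density field
#'
#' Normal-tissue value outside the tumor, `S_lymph_tumor_frac` times it
#' inside, interpolated with the same smoothed Heaviside as the conductivity.
#' @param state continuum state; @param params parameters.
#' @return S_L array, 1/um.
#' @export
lymphatic_density <- function(state, params = default_parameters()) {
  Hin <- 1 - smoothed_heaviside(state$theta, params$numerics$heaviside_width)
  params$iff$S_lymph_normal *
    ((1 - Hin) + params$iff$S_lymph_tumor_frac * Hin)
}

# per-sample wall permeability and effective (osmosis-corrected) blood pressure
.sample_wall_terms <- function(net, state, grid, sampling, params) {
  segs <- net$segments
  row <- match(sampling$seg, segs$id)
  lam <- .wall_permeability(segs$w[row], segs$r[row],
                            params$iff$lambda_l_tumor,
                            params$iff$lambda_l_normal,
                            params$iff$wall_thickness_coef)
  theta_s <- interp_field(grid, state$theta, sampling)
  sigma <- ifelse(theta_s < 0, params$iff$sigma_tumor, params$iff$sigma_normal)
  dpi <- params$iff$pi_vessel - params$iff$pi_interstitial
  peff <- sampling$pblood - sigma * dpi
  list(lambda = lam, peff = peff)
}

#' Assemble and solve the interstitial fluid pressure
#'
#' Solves `div(K grad p) + Q(p) = 0` where the source is the Starling
#' transvascular exchange deposited from the surface sampling (linear in `p`)
#' minus the lymphatic sink `lambda_L S_L (p - p_L)`.  Zero-flux box
#' boundaries; the lymphatics anchor the far field.
#'
#' @param net vessel network with a flow solution; @param state continuum
#'   state; @param grid grid; @param params parameters; @param seed sampling
#'   seed; @param sampling optional precomputed [sample_surfaces()] result.
#' @param dirichlet optional Dirichlet specification forwarded to the solver.
#' @return list of class `iff_solution`: p (kPa), u (face fluxes um/s),
#'   sources (class `source_field`: Q, Qin_v, Qout_v, Qout_L in 1/s),
#'   sampling, K, and the per-sample terms.
#' @export
assemble_and_solve_ifp <- function(net, state, grid,
                                   params = default_parameters(), seed = 1L,
                                   sampling = NULL, dirichlet = NULL) {
  if (is.null(sampling))
    sampling <- sample_surfaces(net, grid, params$iff$sample_density,
                                seed = derive_seed(seed, "ifp-sampling"))
  K <- tissue_conductivity(state, params)
  SL <- lymphatic_density(state, params)
  lymph_coef <- params$iff$lambda_lymph * SL      # 1/(kPa s)
  V <- cell_volume(grid)
  diag_add <- lymph_coef
  rhs <- lymph_coef * params$iff$p_lymph
  wt <- NULL
  if (nrow(sampling)) {
    terms <- .sample_wall_terms(net, state, grid, sampling, params)
    wt <- cic_weights(grid, sampling)
    coefs <- wt$w * sampling$a[wt$point] * terms$lambda[wt$point] / V
    add <- function(A, idx, val) { t <- tapply(val, idx, sum)
      A[as.integer(names(t))] <- A[as.integer(names(t))] + t; A }
    diag_add <- add(diag_add, wt$cell, coefs)
    rhs <- add(rhs, wt$cell, coefs * terms$peff[wt$point])
  } else terms <- list(lambda = numeric(0), peff = numeric(0))
  if (all(diag_add == 0) && is.null(dirichlet))
    stop("singular IFP system: no lymphatic or vascular sink anchors the pressure")
  p <- solve_reaction_diffusion(grid, K, diag_add, rhs, dirichlet = dirichlet,
                                tol = params$numerics$solver_tol * 100)
  u <- darcy_velocity(grid, p, K)
  sources <- source_decomposition(grid, p, sampling, terms, lymph_coef,
                                  params)
  structure(list(p = p, u = u, sources = sources, sampling = sampling, K = K,
                 wall_terms = terms, lymph_coef = lymph_coef),
            class = "iff_solution")
}

#' Decompose the fluid source term by channel and sign
#'
#' Splits the per-sample Starling fluxes at the solved pressure into vessel
#' extravasation `Qin_v` (blood to interstitium), vessel uptake `Qout_v`
#' (back-flow into low-pressure vessels) and lymphatic uptake `Qout_L`, so
#' that `Q = Qin_v - Qout_v - Qout_L` cell-wise.
#'
#' @param grid grid; @param p solved IFP; @param sampling surface sampling;
#'   @param terms per-sample wall terms; @param lymph_coef cell array of
#'   `lambda_L S_L`; @param params parameters.
#' @return list of class `source_field` with Q, Qin_v, Qout_v, Qout_L (1/s).
#' @export
source_decomposition <- function(grid, p, sampling, terms, lymph_coef,
                                 params = default_parameters()) {
  V <- cell_volume(grid)
  Qin <- zero_field(grid); Qoutv <- zero_field(grid)
  if (nrow(sampling)) {
    wt <- cic_weights(grid, sampling)
    pv <- as.vector(p)[wt$cell]
    flux <- wt$w * sampling$a[wt$point] * terms$lambda[wt$point] *
      (terms$peff[wt$point] - pv) / V
    add <- function(A, idx, val) { t <- tapply(val, idx, sum)
      A[as.integer(names(t))] <- A[as.integer(names(t))] + t; A }
    Qin <- add(Qin, wt$cell[flux > 0], flux[flux > 0])
    Qoutv <- add(Qoutv, wt$cell[flux < 0], -flux[flux < 0])
  }
  QoutL <- lymph_coef * (p - params$iff$p_lymph)
  structure(list(Q = Qin - Qoutv - QoutL, Qin_v = Qin, Qout_v = Qoutv,
                 Qout_L = QoutL), class = "source_field")
}

#' Axial decay length of blood pressure toward the interstitial pressure
#'
#' For a leaky vessel the blood pressure relaxes toward the effective
#' interstitial pressure over `lambda = sqrt(axial conductance per length /
#' wall conductance per length)`; sealed walls recover plain Poiseuille flow
#' (`lambda -> Inf`).
#'
#' @param r radius um; @param eta blood viscosity kPa s; @param lambda_l wall
#'   permeability um/(kPa s).
#' @return decay length um.
#' @export
vessel_pressure_decay_length <- function(r, eta, lambda_l) {
  k_ax <- pi * r^4 / (8 * eta)       # um^4/(kPa s) per unit length
  c_wall <- lambda_l * 2 * pi * r    # um^2/(kPa s) per unit length... per length
  ifelse(c_wall <= 0, Inf, sqrt(k_ax / c_wall))
}

#' Fraction of tumor blood flow lost to the interstitium
#'
#' `r_Gamma = (integral of Qin_v over the tumor) / (blood inflow across the
#' tumor boundary)`; the inflow sums segment flows over vessels whose level
#' set changes sign between the endpoints and whose flow is directed inward.
#'
#' @param net network with flow solution; @param state continuum state; @param
#'   grid grid; @param sources source field.
#' @return list(r_gamma, extravasation um^3/s, inflow um^3/s).
#' @export
extravasation_ratio <- function(net, state, grid, sources) {
  if (all(state$theta > 0)) stop("empty tumor region")
  tumor <- state$theta < 0
  extrav <- sum(sources$Qin_v[tumor]) * cell_volume(grid)
  segs <- net$segments
  inflow <- 0
  for (m in seq_len(nrow(segs))) {
    s <- segs[m, ]
    p1 <- site_position(net$lat, node_site(net, s$n1))
    p2 <- site_position(net$lat, node_site(net, s$n2))
    th1 <- interp_field(grid, state$theta, data.frame(x = p1[1], y = p1[2], z = p1[3]))
    th2 <- interp_field(grid, state$theta, data.frame(x = p2[1], y = p2[2], z = p2[3]))
    if (sign(th1) == sign(th2)) next
    P1 <- net$nodes$press[match(s$n1, net$nodes$id)]
    P2 <- net$nodes$press[match(s$n2, net$nodes$id)]
    # flow direction: from higher to lower pressure; inward if downstream end
    # is the one inside the tumor
    downstream_inside <- (P1 > P2 && th2 < 0) || (P2 > P1 && th1 < 0)
    if (downstream_inside) inflow <- inflow + abs(s$q)
  }
  if (inflow == 0) return(list(r_gamma = NA_real_, extravasation = extrav,
                               inflow = 0))
  list(r_gamma = extrav / inflow, extravasation = extrav, inflow = inflow)
}
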