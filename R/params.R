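# Model parameters.  Units throughout: length um, time s (rates per s unless a
# field is explicitly "per h"), pressure kPa.  Remodeling operates in 1 h steps.

#' Default model parameters
#'
#' Returns the full parameter set of the simulator: vessel lattice and network
#' construction controls, hemodynamics constants, vascular remodeling rates,
#' continuum tissue model constants, interstitial-fluid-flow coefficients and
#' drug (Doxorubicin-like) transport constants.  Values follow the published
#' parameterization logic for a dense, compartmentalized solid tumor: cellular
#' uptake/release ratio of 100 observed in cell cultures, interstitial drug
#' diffusivity of 16 um^2/s, proliferation once per day, a 10 day normal-cell
#' lifetime, necrotic die-off within 48 h, homeostatic cell fractions 0.6
#' (tumor) and 0.4 (normal), a lymphatic channel every 100 um, and a lymphatic
#' pressure of -0.5 kPa.  See the methods vignette for the provenance and
#' sensitivity of every entry.
#'
#' @param desk logical; if TRUE (default) the network/growth extents are scaled
#'   to desk size (small triangular-lattice networks, 2 mm class domains).  With
#'   FALSE the full-scale base configuration (25x31x31 construction lattice, two
#'   up-scaling steps, 8 mm continuum box) is returned.
#' @return a named list of parameter groups (`lattice`, `builder`, `blood`,
#'   `remodel`, `tissue`, `oxygen`, `gf`, `iff`, `drug`, `numerics`).
#' @export
default_parameters <- function(desk = TRUE) {
  p <- list(
    lattice = list(
      kind = if (desk) "tri" else "fcc",
      spacing = 80,              # construction lattice constant ~ inter-capillary distance (um)
      extent = if (desk) c(12L, 14L, 1L) else c(25L, 31L, 31L)
    ),
    builder = list(
      n_roots = if (desk) 10L else 40L,
      upscale_steps = if (desk) 1L else 2L,
      r_capillary = 4,           # um
      r_arterial_terminal = 3.5, # um
      r_venous_terminal = 5,     # um
      murray_alpha = 3,
      p_single = 0.5,            # probability of a single-bond element (vs Y element)
      plateau_window = if (desk) 20L else 50L, # sweeps in the plateau moving average
      plateau_tol = if (desk) 0.05 else 0.01,  # relative change deemed flat
      max_remodel_sweeps = if (desk) 100L else 400L
    ),
    blood = list(
      plasma_viscosity = 1.2e-6, # kPa s
      hematocrit = 0.45,         # human average, constant network-wide
      root_pressure_model = "logistic-fallback"
    ),
    remodel = list(
      dt = 1,                    # h, vessel network step
      sprout_rate = 0.2,         # per h per candidate site (p = rate*dt <= 1)
      sprout_extension_speed = 5,    # um/h
      sprout_max_life = 100,     # h
      sprout_min_separation = 20, # um, to the next branching point
      r_sprout = 4,              # um, initial sprout radius
      sprout_tumor_time_max = 24, # h, sites inside tumor longer than this stop sprouting
      dilation_rate = 0.4,       # um/h
      r_max = 25,                # um, maximum dilation radius
      switch_delay = 24,         # h, circumferential-growth switch delay
      f_collapse = 1.5e-4,       # kPa, critical wall shear stress
      t_unstable = 20,           # h, unstable-vessel survival time (collapse rate = 1/t)
      w_degrade_rate = 0.05,     # um/h wall degradation
      w_collapse = 0.05          # um, wall maturity below which collapse is possible
    ),
    tissue = list(
      phi_ecm = 0.2,
      phi_relaxed = 0.3,         # cell fraction of the fully relaxed state
      phi_h_tumor = 0.6,
      phi_h_normal = 0.4,
      mobility_E = 1000 / 3600,  # cell mobility x elastic modulus, um^2/s
      prolif_tumor = 1 / 86400,  # 1/s, once per day
      prolif_normal = 1 / 86400,
      apopt_tumor = 0,
      apopt_normal = 1 / (10 * 86400), # 10 day lifetime
      necro_tumor = 1 / (48 * 3600),   # die-off within 48 h
      necro_normal = 1 / (48 * 3600),
      pressure_sensitivity = 10  # slope of the linear density dependence
    ),
    oxygen = list(
      D = 2000,                  # um^2/s effective diffusivity
      cons_tumor = 0.2,          # 1/s, sets a ~100 um penetration depth sqrt(D/alpha)
      cons_normal = 0.1,         # tumor consumes twice the normal rate
      cons_necrotic = 0,
      wall_perm = 8,             # um/s, calibrated so normal tissue stays above ~0.5
      c_prolif = 0.3,            # proliferation stops below this
      c_necro = 0.03             # necrosis below this
    ),
    gf = list(
      R_g = 200                  # um, growth factor diffusion radius
    ),
    iff = list(
      K_normal = 190,            # um^2/(kPa s) tissue conductivity
      K_tumor = 250,
      K_necrotic = 500,
      p_lymph = -0.5,            # kPa
      S_lymph_normal = 0.0188,   # 1/um, grid of channels every 100 um, radius 10 um
      S_lymph_tumor_frac = 0,    # tumor is left without lymphatics
      lambda_lymph = 0.0225,     # um/(kPa s), same order as normal capillary walls
      sigma_normal = 0.91,       # osmotic reflection coefficients
      sigma_tumor = 0.82,
      pi_vessel = 2.7,           # kPa plasma oncotic pressure
      pi_interstitial = 1.33,    # kPa
      lambda_l_tumor = 1.4,      # um/(kPa s) hydraulic permeability, leaky tumor capillary
      lambda_l_normal = 0.0225,  # um/(kPa s) normal capillary
      sample_density = 0.015,    # surface samples per um^2 of vessel surface
      wall_thickness_coef = c(a = 0.65, b = 0.6) # w_N(r) = a * r^b (um)
    ),
    drug = list(
      D_s = 16,                  # um^2/s interstitial diffusion coefficient
      k12 = 0.04,                # um/s membrane uptake (fast: minutes)
      k21 = 4e-4,                # um/s release (slow: hours); k12/k21 = 100
      lambda_diff_tumor = 0.17,  # um/s diffusive wall permeability, leaky tumor capillary
      lambda_diff_normal = 0.17 * (0.0225 / 1.4), # equal tumor/normal ratio as hydraulic
      cell_volume = 2100,        # um^3 single cell
      cell_surface = 800,        # um^2 single cell
      contact_fraction = 0.2,    # fraction of the cell surface wetted by IF
      tau_bolus = 3600,          # s, bolus plasma decay time (1 h)
      mol_mass_ratio_heavy = 1000 # case (i): heavy particles, D scaled by ratio^(-1/3)
    ),
    numerics = list(
      h = 30,                    # um grid spacing
      box = if (desk) 2000 else 8000, # um lateral continuum box size
      solver_tol = 1e-10,
      cfl = 0.8,
      heaviside_width = 30,      # um, = h
      field_refresh_cap = 3600   # s, cap on oxygen/GF refresh cadence
    )
  )
  class(p) <- "tumorperf_params"
  p
}

#' Validate a parameter set
#'
#' Checks unit/range invariants: non-negative rates and permeabilities,
#' reflection coefficients in [0,1], Murray exponent in [2.7, 3], per-step event
#' probabilities `rate * dt <= 1`, equality of the diffusive and hydraulic
#' tumor/normal wall-permeability ratios, and presence of every required field.
#'
#' @param p parameter list as returned by [default_parameters()].
#' @return `p` invisibly; stops with an informative message on violation.
#' @export
validate_parameters <- function(p) {
  need <- c("lattice", "builder", "blood", "remodel", "tissue", "oxygen",
            "gf", "iff", "drug", "numerics")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter group(s): ", paste(miss, collapse = ", "))
  r <- p$remodel
  for (nm in c("sprout_rate")) {
    if (r[[nm]] * r$dt > 1)
      stop("per-step probability ", nm, " * dt = ", r[[nm]] * r$dt, " exceeds 1")
  }
  if (r$dt / r$t_unstable > 1) stop("collapse probability dt/t_unstable exceeds 1")
  if (p$builder$murray_alpha < 2.7 || p$builder$murray_alpha > 3)
    stop("Murray exponent must lie in [2.7, 3]")
  if (any(unlist(p$iff[c("K_normal", "K_tumor", "K_necrotic", "S_lymph_normal",
                         "lambda_lymph", "lambda_l_tumor", "lambda_l_normal")]) < 0))
    stop("negative permeability/conductivity")
  if (p$iff$sigma_normal < 0 || p$iff$sigma_normal > 1 ||
      p$iff$sigma_tumor < 0 || p$iff$sigma_tumor > 1)
    stop("reflection coefficients must lie in [0,1]")
  ratio_h <- p$iff$lambda_l_tumor / p$iff$lambda_l_normal
  ratio_d <- p$drug$lambda_diff_tumor / p$drug$lambda_diff_normal
  if (abs(ratio_h - ratio_d) / ratio_h > 1e-6)
    stop("diffusive and hydraulic tumor/normal permeability ratios must be equal")
  if (p$drug$k12 < 0 || p$drug$k21 <= 0) stop("drug exchange rates must be positive")
  invisible(p)
}

#' Read and write parameter files (YAML)
#'
#' `write_parameters()` serializes a parameter set to YAML;
#' `load_validate_config()` reads one back, overlays it on the defaults (so a
#' config may specify only the values it changes), and runs
#' [validate_parameters()] so unit/range violations are rejected at load time
#' with the offending field named.
#'
#' @param p parameter list; @param path file path; @param desk passed to
#'   [default_parameters()] for the defaults underlying a partial config.
#' @return `load_validate_config` returns the validated parameter list.
#' @export
write_parameters <- function(p, path) {
  p2 <- unclass(p)
  p2$iff$wall_thickness_coef <- as.list(p$iff$wall_thickness_coef)
  yaml::write_yaml(p2, path, precision = 15)
  invisible(path)
}

#' @rdname write_parameters
#' @export
load_validate_config <- function(path, desk = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  p <- default_parameters(desk)
  for (grp in names(raw)) {
    if (grp == "case") { p$case <- raw$case; next }
    if (!grp %in% names(p)) stop("unknown parameter group: ", grp)
    for (nm in names(raw[[grp]])) {
      if (!nm %in% names(p[[grp]]))
        stop("unknown parameter: ", grp, "$", nm)
      val <- raw[[grp]][[nm]]
      if (nm == "wall_thickness_coef") val <- unlist(val)
      if (nm == "extent") val <- as.integer(unlist(val))
      p[[grp]][[nm]] <- val
    }
  }
  validate_parameters(p)
  p
}

#' Apply a variation case to a parameter set
#'
#' Multiplicative parameter deltas for the studied variations of the base case:
#' \describe{
#'   \item{`base`}{no change.}
#'   \item{`i`}{heavier drug particles: `D_s` and the diffusive wall
#'     permeabilities scaled by `(m/m0)^(-1/3)` with mass ratio 1000.}
#'   \item{`ii-a`, `ii-b`}{prolonged infusion schedule, 24 h / 96 h (affects the
#'     injection schedule, not the constants; recorded in `$case`).}
#'   \item{`iii`}{interstitial convection switched off for the drug.}
#'   \item{`iv-a`, `iv-b`, `iv-c`}{tumor vascular permeability bound scaled by
#'     10, 1/100, 1/1000 (hydraulic and diffusive alike).}
#'   \item{`v`}{tissue conductivity, lymphatic permeability and `D_s` scaled
#'     together by 10.}
#'   \item{`vi`}{normal lymphatic permeability scaled by 10.}
#'   \item{`vii-a`, `vii-b`}{tumor lymphatics at 0.1 / 1.0 of the normal
#'     density.}
#' }
#' @param p parameter list.
#' @param case case id string.
#' @return modified parameter list with attribute fields `$case` set.
#' @export
case_variation <- function(p, case = "base") {
  p$case <- list(id = case, convection = TRUE,
                 schedule = "bolus", infusion_T = NA_real_)
  scale_wall <- function(p, f) {
    p$iff$lambda_l_tumor <- p$iff$lambda_l_tumor * f
    p$drug$lambda_diff_tumor <- p$drug$lambda_diff_tumor * f
    p
  }
  switch(case,
    "base" = p,
    "i" = {
      f <- p$drug$mol_mass_ratio_heavy^(-1 / 3)
      p$drug$D_s <- p$drug$D_s * f
      p$drug$lambda_diff_tumor <- p$drug$lambda_diff_tumor * f
      p$drug$lambda_diff_normal <- p$drug$lambda_diff_normal * f
      p
    },
    "ii-a" = { p$case$schedule <- "infusion"; p$case$infusion_T <- 24 * 3600; p },
    "ii-b" = { p$case$schedule <- "infusion"; p$case$infusion_T <- 96 * 3600; p },
    "iii" = { p$case$convection <- FALSE; p },
    "iv-a" = scale_wall(p, 10),
    "iv-b" = scale_wall(p, 1 / 100),
    "iv-c" = scale_wall(p, 1 / 1000),
    "v" = {
      for (nm in c("K_normal", "K_tumor", "K_necrotic", "lambda_lymph"))
        p$iff[[nm]] <- p$iff[[nm]] * 10
      p$drug$D_s <- p$drug$D_s * 10
      p
    },
    "vi" = { p$iff$lambda_lymph <- p$iff$lambda_lymph * 10; p },
    "vii-a" = { p$iff$S_lymph_tumor_frac <- 0.1; p },
    "vii-b" = { p$iff$S_lymph_tumor_frac <- 1.0; p },
    stop("unknown case id: ", case)
  )
}
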