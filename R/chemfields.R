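# Quasi-stationary chemical fields: oxygen (diffusion-consumption with
# trans-wall influx from perfused vessels, normalized so the blood value is 1)
# and the growth factor (Green's-function superposition of linearly decaying
# kernels from hypoxic tumor sites, capped at 1).

#' Stationary oxygen field
#'
#' Solves `D lap c - alpha(x) c + sum_s gamma a_s/V (c_B - c) delta_s = 0`
#' with zero-flux box boundaries.  The consumption rate is the
#' fraction-weighted mix of the tumor/normal/necrotic rates; `c_B = 1` in
#' perfused vessels and 0 in unperfused ones (which therefore contribute no
#' oxygen).
#'
#' @param grid grid; @param net vessel network with perfusion flags; @param
#'   state continuum state (for the consumption mix); @param params
#'   parameters; @param seed sampling seed.
#' @return list(c = oxygen array in [0,1], sampling).
#' @export
oxygen_field <- function(grid, net, state, params = default_parameters(),
                         seed = 1L) {
  ox <- params$oxygen
  alpha <- ox$cons_tumor * state$phiT + ox$cons_normal * state$phiN +
    ox$cons_necrotic * state$phiD
  sampling <- sample_surfaces(net, grid, params$iff$sample_density,
                              seed = derive_seed(seed, "o2-sampling"),
                              perfused_only = TRUE)
  V <- cell_volume(grid)
  diag_add <- zero_field(grid); rhs <- zero_field(grid)
  if (nrow(sampling)) {
    w <- cic_weights(grid, sampling)
    coefs <- w$w * sampling$a[w$point] * ox$wall_perm / V
    t1 <- tapply(coefs, w$cell, sum)
    diag_add[as.integer(names(t1))] <- diag_add[as.integer(names(t1))] + t1
    rhs_c <- coefs * 1                      # blood oxygen level normalized to 1
    t2 <- tapply(rhs_c, w$cell, sum)
    rhs[as.integer(names(t2))] <- rhs[as.integer(names(t2))] + t2
  }
  if (all(diag_add == 0) && all(alpha == 0))
    stop("singular oxygen system: no vessel sources and no consumption")
  c <- solve_reaction_diffusion(grid, ox$D, alpha + diag_add, rhs,
                                tol = params$numerics$solver_tol * 100)
  c[c < 0] <- 0; c[c > 1] <- 1
  list(c = c, sampling = sampling)
}

#' Growth factor field from hypoxic tumor sites
#'
#' Every source cell (tumor cells present, oxygen below the proliferation
#' threshold) adds a linearly decaying kernel `max(0, 1 - d/R_g)`; the sum is
#' capped at 1.
#'
#' @param grid grid; @param source_mask logical array of source cells; @param
#'   params parameters.
#' @return g array in [0, 1].
#' @export
growth_factor_field <- function(grid, source_mask, params = default_parameters()) {
  Rg <- params$gf$R_g
  g <- zero_field(grid)
  src <- which(source_mask, arr.ind = TRUE)
  if (!nrow(src)) return(g)
  cc <- cell_centers(grid)
  d <- grid$dims
  win <- ceiling(Rg / grid$h)
  for (m in seq_len(nrow(src))) {
    i0 <- src[m, 1]; j0 <- src[m, 2]; k0 <- src[m, 3]
    ir <- max(1, i0 - win):min(d[1], i0 + win)
    jr <- max(1, j0 - win):min(d[2], j0 + win)
    kr <- if (d[3] == 1L) 1L else max(1, k0 - win):min(d[3], k0 + win)
    dx <- cc$x[ir] - cc$x[i0]; dy <- cc$y[jr] - cc$y[j0]; dz <- cc$z[kr] - cc$z[k0]
    dist <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
    g[ir, jr, kr] <- g[ir, jr, kr] + pmax(0, 1 - dist / Rg)
  }
  pmin(g, 1)
}

#' Hypoxic tumor source mask for growth factor production
#' @param state continuum state; @param c oxygen; @param params parameters.
#' @return logical array.
#' @export
gf_source_mask <- function(state, c, params = default_parameters()) {
  state$phiT > 0.01 & c < params$oxygen$c_prolif
}

#' Interpolate a cell field at arbitrary positions (multilinear)
#' @param grid grid; @param field cell array; @param pts data.frame x,y,z.
#' @return numeric vector of interpolated values.
#' @export
interp_field <- function(grid, field, pts) {
  w <- cic_weights(grid, pts)
  acc <- numeric(nrow(pts))
  fv <- as.vector(field)
  contrib <- w$w * fv[w$cell]
  t <- tapply(contrib, w$point, sum)
  acc[as.integer(names(t))] <- t
  acc
}
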