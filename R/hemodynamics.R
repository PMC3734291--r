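# Blood flow on the vessel graph: Poiseuille conductances with the Pries
# in-vivo viscosity law, Kirchhoff nodal-pressure solve, wall shear stress and
# radius-dependent root boundary pressures.

#' In-vivo relative blood viscosity (Pries law)
#'
#' Relative apparent viscosity of blood in microvessels as a function of lumen
#' diameter and discharge hematocrit, from the in-vivo parameterization of
#' Pries and co-workers.  Multiply by the plasma viscosity to obtain the
#' dynamic viscosity.  Exhibits the Fahraeus-Lindqvist minimum at small
#' diameters.
#'
#' @param r vessel radius, um (> 0).
#' @param h discharge hematocrit in [0, 1).
#' @return dimensionless relative viscosity (vectorized over `r`).
#' @export
relative_viscosity <- function(r, h = 0.45) {
  if (any(r <= 0)) stop("radius must be > 0")
  if (any(h < 0 | h >= 1)) stop("hematocrit must lie in [0, 1)")
  d <- 2 * r
  eta45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  wall <- (d / (d - 1.1))^2
  hterm <- (eta45 - 1) * ((1 - h)^cc - 1) / ((1 - 0.45)^cc - 1)
  (1 + hterm * wall) * wall
}

#' Poiseuille conductance of a cylindrical segment
#'
#' `g = pi r^4 / (8 eta l)` in um^3 s^-1 kPa^-1, so that `q = g * dp`.
#' @param r radius um; @param l length um; @param eta dynamic viscosity kPa s.
#' @export
conductance <- function(r, l, eta) {
  if (any(r <= 0) || any(eta <= 0)) stop("radius and viscosity must be > 0")
  if (any(l <= 0)) stop("zero or negative segment length")
  pi * r^4 / (8 * eta * l)
}

#' Wall shear stress of pipe flow
#'
#' `f = r |dp| / (2 l)` (kPa): the wall traction of Poiseuille flow driven by
#' the end-to-end pressure difference `dp` over length `l`.
#' @param r radius um; @param dp pressure difference kPa; @param l length um.
#' @export
wall_shear_stress <- function(r, dp, l) {
  if (any(r <= 0) || any(l <= 0)) stop("radius and length must be > 0")
  r * abs(dp) / (2 * l)
}

#' Root boundary pressure as a function of vessel radius
#'
#' Pressure (kPa) prescribed at arterial and venous tree roots.  The package
#' uses a documented logistic fit to microvascular pressure-radius data
#' (arterial pressures rise with radius toward systemic levels, venous
#' pressures fall toward central-venous levels; the arterial curve lies above
#' the venous curve for every radius).  The model tag is
#' `"logistic-fallback"` in [default_parameters()].
#'
#' @param r radius um; @param kind `"arterial"` or `"venous"`.
#' @return pressure kPa (vectorized over `r`).
#' @export
root_pressure <- function(r, kind = c("arterial", "venous")) {
  kind <- match.arg(kind)
  if (any(r <= 0)) stop("radius must be > 0")
  if (kind == "arterial") 3.0 + 6.6 / (1 + (12 / r)^1.4)
  else 0.3 + 2.2 / (1 + (r / 8)^1.2)
}

#' Solve nodal blood pressures and segment flows (Kirchhoff balance)
#'
#' Builds the sparse conductance Laplacian of the vessel graph, applies the
#' prescribed pressures at root nodes as Dirichlet conditions and solves for
#' the remaining nodal pressures.  Segment flows, shear stresses and perfusion
#' flags are then computed from the pressure drops.  Every connected component
#' must contain at least one root node.
#'
#' @param net `vessel_network` with root nodes carrying pressures (use
#'   [place_roots()] / [root_pressure()]).
#' @param params parameter list ([default_parameters()]), for plasma viscosity.
#' @param q_tol flows below this (um^3/s) count as unperfused.
#' @return list with the updated network (`net`: absolute `q`, `f`, perfused
#'   flags), `pressure` (named by node id), `q_signed` (positive from n1 to
#'   n2), `eta` per segment, and `residual`.
#' @export
solve_nodal_pressures <- function(net, params = default_parameters(),
                                  q_tol = 1e-9) {
  segs <- net$segments
  if (!nrow(segs)) stop("empty network")
  # nodes without any incident segment carry no flow and would make the
  # system singular; drop them from the solve (and the network)
  used <- unique(c(segs$n1, segs$n2))
  net$nodes <- net$nodes[net$nodes$id %in% used, , drop = FALSE]
  nodes <- net$nodes
  nid <- nodes$id
  i1 <- match(segs$n1, nid); i2 <- match(segs$n2, nid)
  len <- segs$nbonds * net$lat$spacing
  eta <- params$blood$plasma_viscosity * relative_viscosity(segs$r, segs$hema)
  g <- conductance(segs$r, len, eta)
  n <- length(nid)
  fixed <- nodes$bc != "none" & !is.na(nodes$press)
  # components without any boundary node are singular
  gr <- igraph::graph_from_edgelist(cbind(i1, i2), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  bad <- setdiff(unique(comp), unique(comp[fixed]))
  # isolated root-free single nodes without segments cannot occur (nodes are
  # only created with segments or as roots); still guard:
  bad <- bad[bad %in% comp[c(i1, i2)]]
  if (length(bad))
    stop("singular system: connected component(s) without boundary node: ",
         paste(bad, collapse = ", "))
  L <- Matrix::sparseMatrix(i = c(i1, i2, i1, i2), j = c(i1, i2, i2, i1),
                            x = c(g, g, -g, -g), dims = c(n, n))
  p <- numeric(n)
  p[fixed] <- nodes$press[fixed]
  free <- which(!fixed)
  if (length(free)) {
    A <- L[free, free, drop = FALSE]
    b <- -L[free, which(fixed), drop = FALSE] %*% p[fixed]
    p[free] <- as.numeric(Matrix::solve(A, b))
  }
  q_signed <- g * (p[i1] - p[i2])
  resid <- max(0, {
    net_flow <- numeric(n)
    for (s in seq_along(q_signed)) {
      net_flow[i1[s]] <- net_flow[i1[s]] - q_signed[s]
      net_flow[i2[s]] <- net_flow[i2[s]] + q_signed[s]
    }
    if (length(free)) max(abs(net_flow[free])) / max(abs(q_signed), 1e-300) else 0
  })
  net$nodes$press <- p
  net$segments$q <- abs(q_signed)
  net$segments$f <- wall_shear_stress(segs$r, p[i1] - p[i2], len)
  net$segments$perfused <- abs(q_signed) > q_tol
  list(net = net, pressure = setNames(p, nid), q_signed = q_signed,
       eta = eta, residual = resid)
}
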