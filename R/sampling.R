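# Vessel-surface sampling: exchange fluxes between the vessel network and the
# continuum are represented by smoothed delta functions at points drawn
# uniformly from the lateral surfaces of the cylindrical segments, deposited
# onto grid cells with a multilinear (cloud-in-cell) kernel that partitions
# unity exactly.

#' Uniformly sample vessel segment surfaces
#'
#' Per segment, `ceiling(density * 2 pi r l)` points are drawn uniformly on the
#' cylinder surface; each carries the equal area weight `a_s = area / n` and
#' the blood pressure interpolated linearly between the segment end nodes.
#'
#' @param net vessel network (with nodal pressures if blood pressure is
#'   needed); @param grid continuum grid; @param density samples per um^2 of
#'   surface; @param seed RNG seed; @param perfused_only sample only perfused
#'   segments (default TRUE).
#' @return data.frame of class `surface_sampling`: columns x, y, z (um), seg
#'   (segment id), a (um^2), pblood (kPa), plus attribute `area` per segment.
#' @export
sample_surfaces <- function(net, grid, density = 0.015, seed = 1L,
                            perfused_only = TRUE) {
  set.seed(seed)
  segs <- net$segments
  if (perfused_only && nrow(segs)) segs <- segs[segs$perfused, , drop = FALSE]
  out <- list(); areas <- numeric(0)
  if (nrow(segs)) for (m in seq_len(nrow(segs))) {
    s <- segs[m, ]
    p1 <- as.numeric(site_position(net$lat, node_site(net, s$n1)))
    p2 <- as.numeric(site_position(net$lat, node_site(net, s$n2)))
    L <- sqrt(sum((p2 - p1)^2))
    area <- 2 * pi * s$r * L
    n <- max(1L, ceiling(density * area))
    t <- runif(n)
    phi <- runif(n, 0, 2 * pi)
    axis <- (p2 - p1) / L
    # orthonormal frame perpendicular to the axis
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    base <- outer(t, p2 - p1) + matrix(p1, n, 3, byrow = TRUE)
    pos <- base + s$r * (outer(cos(phi), e1) + outer(sin(phi), e2))
    P1 <- net$nodes$press[match(s$n1, net$nodes$id)]
    P2 <- net$nodes$press[match(s$n2, net$nodes$id)]
    pb <- if (is.na(P1) || is.na(P2)) rep(NA_real_, n) else P1 + t * (P2 - P1)
    out[[length(out) + 1L]] <- data.frame(
      x = pos[, 1], y = pos[, 2], z = pos[, 3], seg = s$id, a = area / n,
      t = t, pblood = pb)
    areas[as.character(s$id)] <- area
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               seg = integer(0), a = numeric(0), t = numeric(0),
               pblood = numeric(0))
  attr(res, "area") <- areas
  class(res) <- c("surface_sampling", class(res))
  res
}

#' Cloud-in-cell deposition weights of points onto grid cells
#'
#' Multilinear kernel of support 2h per axis; weights per point sum to exactly
#' one (partition of unity).  Points outside the box are clamped to it.
#'
#' @param grid grid; @param pts matrix/data.frame with columns x, y, z.
#' @return data.frame(point, cell, w) with flattened cell indices.
#' @export
cic_weights <- function(grid, pts) {
  d <- grid$dims; h <- grid$h
  n <- nrow(pts)
  if (!n) return(data.frame(point = integer(0), cell = integer(0),
                            w = numeric(0)))
  xyz <- cbind(pts$x, pts$y, pts$z)
  res <- vector("list", 8)
  # fractional cell coordinate relative to cell centers
  fc <- sweep(sweep(xyz, 2, grid$origin), 2, rep(h, 3), "/") + 0.5
  lo <- floor(fc)
  fr <- fc - lo
  m <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- pmin(pmax(lo[, 1] + dx, 1), d[1])
    cj <- pmin(pmax(lo[, 2] + dy, 1), d[2])
    ck <- pmin(pmax(lo[, 3] + dz, 1), d[3])
    wx <- ifelse(dx == 1, fr[, 1], 1 - fr[, 1])
    wy <- ifelse(dy == 1, fr[, 2], 1 - fr[, 2])
    wz <- ifelse(dz == 1, fr[, 3], 1 - fr[, 3])
    m <- m + 1L
    res[[m]] <- data.frame(point = seq_len(n),
                           cell = flat_index(grid, ci, cj, ck),
                           w = wx * wy * wz)
  }
  out <- do.call(rbind, res)
  out[out$w > 0, , drop = FALSE]
}

#' Deposit weighted point values onto a cell field
#' @param grid grid; @param pts sampling points; @param values per-point
#'   values to deposit (default 1).
#' @return cell array of deposited sums.
#' @export
deposit_points <- function(grid, pts, values = 1) {
  w <- cic_weights(grid, pts)
  if (length(values) == 1) values <- rep(values, nrow(pts))
  acc <- numeric(prod(grid$dims))
  contrib <- w$w * values[w$point]
  t <- tapply(contrib, w$cell, sum)
  acc[as.integer(names(t))] <- t
  array(acc, dim = grid$dims)
}

#' Vessel volume fraction field
#'
#' Deposits each segment's cylinder volume onto the grid from axis samples;
#' used for distance-to-vessel profiles and plots.
#' @param net network; @param grid grid; @param samples_per_cell axial
#'   sampling resolution; @param seed RNG seed.
#' @return cell array of the vessel volume fraction.
#' @export
vessel_volume_fraction <- function(net, grid, samples_per_cell = 4,
                                   seed = 1L) {
  set.seed(seed)
  segs <- net$segments
  if (!nrow(segs)) return(zero_field(grid))
  out <- list()
  for (m in seq_len(nrow(segs))) {
    s <- segs[m, ]
    p1 <- as.numeric(site_position(net$lat, node_site(net, s$n1)))
    p2 <- as.numeric(site_position(net$lat, node_site(net, s$n2)))
    L <- sqrt(sum((p2 - p1)^2))
    n <- max(2L, ceiling(samples_per_cell * L / grid$h))
    t <- (seq_len(n) - 0.5) / n
    vol <- pi * s$r^2 * L
    out[[m]] <- data.frame(x = p1[1] + t * (p2[1] - p1[1]),
                           y = p1[2] + t * (p2[2] - p1[2]),
                           z = p1[3] + t * (p2[3] - p1[3]),
                           v = vol / n)
  }
  pts <- do.call(rbind, out)
  deposit_points(grid, pts, pts$v) / cell_volume(grid)
}
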