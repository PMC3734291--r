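# Level-set representation of the tumor interface.  theta < 0 inside the
# tumor.  Advection is first-order upwind with the cell-interpolated tissue
# velocity; reinitialization is geometric: the zero contour is reconstructed
# from sign changes with linear interpolation and theta is reset to the exact
# signed distance to that point set, which preserves the contour to sub-cell
# accuracy and restores |grad theta| = 1.

#' Initialize a spherical (circular in slab mode) tumor level set
#' @param grid grid; @param radius um; @param center um (default origin).
#' @return theta array (signed distance, negative inside).
#' @export
levelset_sphere <- function(grid, radius, center = c(0, 0, 0)) {
  cc <- cell_centers(grid)
  d <- grid$dims
  x <- array(cc$x, dim = d)
  y <- array(rep(cc$y, each = d[1]), dim = d)
  z <- array(rep(cc$z, each = d[1] * d[2]), dim = d)
  r2 <- (x - center[1])^2 + (y - center[2])^2
  if (d[3] > 1L) r2 <- r2 + (z - center[3])^2
  sqrt(r2) - radius
}

#' Advect the level set with a face velocity field (upwind)
#'
#' @param grid grid; @param theta level set; @param v list(ux,uy,uz) face
#'   velocity (um/s); @param dt time step (s).  Errors if the CFL number
#'   `max|v| dt / h` exceeds 1.
#' @return advected theta.
#' @export
advect_levelset <- function(grid, theta, v, dt) {
  d <- grid$dims; h <- grid$h
  vmax <- max(abs(unlist(v[c("ux", "uy", "uz")])), 0)
  if (vmax * dt / h > 1) stop("CFL violation in level-set advection")
  out <- theta
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    U <- v[[c("ux", "uy", "uz")[ax]]]
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixhi <- ix; ixhi[[ax]] <- 1L + seq_len(d[ax])
    vc <- (do.call(`[`, c(list(U), ix, list(drop = FALSE))) +
           do.call(`[`, c(list(U), ixhi, list(drop = FALSE)))) / 2
    # one-sided differences with edge replication
    shift <- function(A, s) {
      ixs <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ixs[[ax]] <- pmin(pmax(ixs[[ax]] + s, 1L), d[ax])
      do.call(`[`, c(list(A), ixs, list(drop = FALSE)))
    }
    dminus <- (theta - shift(theta, -1L)) / h
    dplus <- (shift(theta, 1L) - theta) / h
    out <- out - dt * (pmax(vc, 0) * dminus + pmin(vc, 0) * dplus)
  }
  out
}

# interface points: zero crossings of theta along grid edges (linear interp)
interface_points <- function(grid, theta) {
  d <- grid$dims
  cc <- cell_centers(grid)
  pts <- matrix(numeric(0), ncol = 3)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixlo <- ix; ixlo[[ax]] <- seq_len(d[ax] - 1L)
    ixhi <- ix; ixhi[[ax]] <- 1L + seq_len(d[ax] - 1L)
    a <- do.call(`[`, c(list(theta), ixlo, list(drop = FALSE)))
    b <- do.call(`[`, c(list(theta), ixhi, list(drop = FALSE)))
    cross <- which((a < 0 & b >= 0) | (a >= 0 & b < 0), arr.ind = TRUE)
    if (!nrow(cross)) next
    av <- a[cross]; bv <- b[cross]
    t <- av / (av - bv)
    p <- cbind(cc$x[cross[, 1]], cc$y[cross[, 2]], cc$z[cross[, 3]])
    p[, ax] <- p[, ax] + t * grid$h
    pts <- rbind(pts, p)
  }
  pts
}

#' Geometric reinitialization of the level set
#'
#' Restores the signed-distance property exactly with respect to the linearly
#' reconstructed zero contour.
#' @param grid grid; @param theta level set.
#' @return redistanced theta (same zero contour to sub-cell accuracy).
#' @export
redistance_levelset <- function(grid, theta) {
  pts <- interface_points(grid, theta)
  if (!nrow(pts)) return(theta)
  cc <- cell_centers(grid)
  d <- grid$dims
  x <- array(cc$x, dim = d)
  y <- array(rep(cc$y, each = d[1]), dim = d)
  z <- array(rep(cc$z, each = d[1] * d[2]), dim = d)
  n <- prod(d)
  P <- cbind(as.vector(x), as.vector(y), as.vector(z))
  dist <- rep(Inf, n)
  chunk <- 500L
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(P[, 1], block[, 1], "-")^2 + outer(P[, 2], block[, 2], "-")^2 +
      outer(P[, 3], block[, 3], "-")^2
    dist <- pmin(dist, sqrt(apply(d2, 1, min)))
  }
  array(sign(theta) * dist, dim = d)
}

#' Norm of the level-set gradient (central differences)
#' @param grid grid; @param theta level set.
#' @return array of |grad theta|.
#' @export
levelset_gradient_norm <- function(grid, theta) {
  d <- grid$dims
  sq <- zero_field(grid)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    shift <- function(A, s) {
      ixs <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ixs[[ax]] <- pmin(pmax(ixs[[ax]] + s, 1L), d[ax])
      do.call(`[`, c(list(A), ixs, list(drop = FALSE)))
    }
    # central differences in the interior, one-sided at the box faces (the
    # clamped span is h there, not 2h)
    span <- array(2 * grid$h, dim = d)
    ix1 <- slice.index(span, ax)
    span[ix1 == 1L | ix1 == d[ax]] <- grid$h
    g <- (shift(theta, 1L) - shift(theta, -1L)) / span
    sq <- sq + g^2
  }
  sqrt(sq)
}

#' Zero-contour radius of a (near-)spherical level set
#'
#' Mean distance of the reconstructed interface points from `center`; used to
#' audit contour preservation under advection/redistancing.
#' @param grid grid; @param theta level set; @param center um.
#' @export
levelset_radius <- function(grid, theta, center = c(0, 0, 0)) {
  pts <- interface_points(grid, theta)
  if (!nrow(pts)) return(NA_real_)
  dd <- sweep(pts, 2, center)
  if (grid$dims[3] == 1L) dd[, 3] <- 0
  mean(sqrt(rowSums(dd^2)))
}
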