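# Staggered finite-difference grid: cell-centered scalars (3D arrays, the
# third extent may be 1 for slab/2D runs) and face-centered velocities/fluxes.

#' Create a uniform staggered grid
#'
#' @param dims integer triple of cell counts (use `c(nx, ny, 1)` for slab/2D).
#' @param h grid spacing, um (default 30, about two to three tissue cells).
#' @param origin position of the low corner of the box, um; defaults to
#'   centering the box at the coordinate origin.
#' @return object of class `continuum_grid`.
#' @export
continuum_grid <- function(dims, h = 30, origin = NULL) {
  dims <- as.integer(dims)
  if (length(dims) == 2) dims <- c(dims, 1L)
  if (any(dims < 1L) || h <= 0) stop("invalid grid")
  if (is.null(origin)) origin <- -dims * h / 2
  structure(list(dims = dims, h = h, origin = as.numeric(origin)),
            class = "continuum_grid")
}

#' @export
print.continuum_grid <- function(x, ...) {
  cat(sprintf("<continuum_grid %s, h = %g um>\n",
              paste(x$dims, collapse = "x"), x$h))
  invisible(x)
}

#' Cell-center coordinates along each axis
#' @param grid grid.
#' @return list(x, y, z) numeric vectors.
#' @export
cell_centers <- function(grid) {
  setNames(lapply(1:3, function(d)
    grid$origin[d] + (seq_len(grid$dims[d]) - 0.5) * grid$h),
    c("x", "y", "z"))
}

# zero field (3D array)
zero_field <- function(grid) array(0, dim = grid$dims)

# flattened index (column-major, matches as.vector of the array)
flat_index <- function(grid, i, j, k) {
  d <- grid$dims
  i + d[1] * ((j - 1) + d[2] * (k - 1))
}

#' Cell volume (um^3)
#' @param grid grid.
#' @export
cell_volume <- function(grid) grid$h^3

#' Smoothed Heaviside step of width `eps`
#'
#' `0` for `x <= -eps`, `1` for `x >= eps`, sinusoidal ramp in between; used to
#' interpolate tissue coefficients across the tumor interface.
#' @param x numeric; @param eps half-width (um).
#' @export
smoothed_heaviside <- function(x, eps) {
  y <- 0.5 * (1 + x / eps + sin(pi * x / eps) / pi)
  y[x <= -eps] <- 0
  y[x >= eps] <- 1
  y
}

# Face-harmonic mean of a cell field along axis d; returns array with one
# extra layer along d (boundary faces get value 0 => zero-flux by default).
face_harmonic <- function(grid, K, d) {
  dm <- grid$dims
  fdim <- dm; fdim[d] <- dm[d] + 1L
  Kf <- array(0, dim = fdim)
  idx1 <- slice.index(Kf, d)
  inner <- idx1 > 1 & idx1 <= dm[d]
  lo <- K; hi <- K
  # K of cell below / above an interior face
  take <- function(A, d, rng) {
    ix <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    ix[[d]] <- rng
    do.call(`[`, c(list(A), ix, list(drop = FALSE)))
  }
  a <- take(K, d, seq_len(dm[d] - 1L))
  b <- take(K, d, 1L + seq_len(dm[d] - 1L))
  hm <- 2 * a * b / pmax(a + b, .Machine$double.xmin)
  hm[a + b == 0] <- 0
  ix <- list(seq_len(fdim[1]), seq_len(fdim[2]), seq_len(fdim[3]))
  ix[[d]] <- 1L + seq_len(dm[d] - 1L)
  Kf <- do.call(`[<-`, c(list(Kf), ix, list(hm)))
  Kf
}

#' Assemble the sparse operator of `-div(K grad u)` with zero-flux boundaries
#'
#' Seven-point (five-point in slab mode) finite-volume discretization with
#' harmonic face averaging of the cell conductivity `K`.  The returned matrix
#' is symmetric positive semi-definite; add a positive diagonal (sinks or
#' Dirichlet penalties) before solving.
#'
#' @param grid grid; @param K cell conductivity array (scalar allowed).
#' @return sparse `dgCMatrix` of size ncell x ncell.
#' @export
assemble_diffusion <- function(grid, K) {
  d <- grid$dims; h <- grid$h
  if (length(K) == 1) K <- array(K, dim = d)
  n <- prod(d)
  ii <- jj <- xx <- list()
  m <- 0L
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    Kf <- face_harmonic(grid, K, ax)
    # interior faces connect cell (.. i ..) and (.. i+1 ..)
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                 k = seq_len(d[3])))
    sel <- idx[, ax] < d[ax]
    lowc <- idx[sel, , drop = FALSE]
    highc <- lowc; highc[, ax] <- highc[, ax] + 1L
    fidx <- lowc; fidx[, ax] <- fidx[, ax] + 1L    # interior face index
    fdim <- d; fdim[ax] <- d[ax] + 1L
    kf <- Kf[fidx[, 1] + fdim[1] * ((fidx[, 2] - 1) + fdim[2] * (fidx[, 3] - 1))]
    g <- kf / h^2
    a <- flat_index(grid, lowc[, 1], lowc[, 2], lowc[, 3])
    b <- flat_index(grid, highc[, 1], highc[, 2], highc[, 3])
    m <- m + 1L
    ii[[m]] <- c(a, b, a, b); jj[[m]] <- c(a, b, b, a)
    xx[[m]] <- c(g, g, -g, -g)
  }
  if (m == 0L) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(n, n)))
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

#' Solve a linear reaction-diffusion system `-div(K grad u) + a u = b`
#'
#' Sparse symmetric solve with zero-flux boundaries (optionally Dirichlet on a
#' mask).  Errors if the system has no anchoring (pure Neumann with `a = 0`).
#'
#' @param grid grid; @param K conductivity; @param a cell sink coefficients
#'   (array or scalar, >= 0); @param b right-hand side; @param dirichlet
#'   optional list(mask = logical array, value = array) of fixed cells.
#' @param tol relative residual tolerance for the post-solve audit.
#' @return solution array.
#' @export
solve_reaction_diffusion <- function(grid, K, a, b, dirichlet = NULL,
                                     tol = 1e-8) {
  n <- prod(grid$dims)
  A <- assemble_diffusion(grid, K)
  av <- if (length(a) == 1) rep(a, n) else as.vector(a)
  bv <- if (length(b) == 1) rep(b, n) else as.vector(b)
  fixed <- rep(FALSE, n)
  fixval <- numeric(n)
  if (!is.null(dirichlet)) {
    fixed <- as.vector(dirichlet$mask)
    fixval <- if (length(dirichlet$value) == 1) rep(dirichlet$value, n)
              else as.vector(dirichlet$value)
  }
  if (!any(fixed) && all(av <= 0))
    stop("singular system: no sinks and no Dirichlet anchor (pure Neumann)")
  M <- A + Matrix::Diagonal(n, av)
  u <- numeric(n)
  u[fixed] <- fixval[fixed]
  free <- which(!fixed)
  if (length(free)) {
    Af <- M[free, free, drop = FALSE]
    rhs <- bv[free] - as.numeric(M[free, fixed, drop = FALSE] %*% u[fixed])
    u[free] <- as.numeric(Matrix::solve(Af, rhs))
    res <- sqrt(sum((as.numeric(Af %*% u[free]) - rhs)^2)) /
      max(sqrt(sum(rhs^2)), .Machine$double.xmin)
    if (is.finite(res) && res > tol)
      warning("linear solve residual ", format(res))
  }
  array(u, dim = grid$dims)
}

#' Face-centered Darcy flux from a cell pressure field
#'
#' `u = -K grad p` evaluated on interior faces (zero on boundary faces:
#' zero-flux box).
#' @param grid grid; @param p pressure array; @param K cell conductivity.
#' @return list(ux, uy, uz) of face arrays (dimension +1 along own axis).
#' @export
darcy_velocity <- function(grid, p, K) {
  d <- grid$dims
  if (length(K) == 1) K <- array(K, dim = d)
  out <- list()
  nm <- c("ux", "uy", "uz")
  for (ax in 1:3) {
    fdim <- d; fdim[ax] <- d[ax] + 1L
    u <- array(0, dim = fdim)
    if (d[ax] > 1L) {
      Kf <- face_harmonic(grid, K, ax)
      take <- function(A, rng) {
        ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        ix[[ax]] <- rng
        do.call(`[`, c(list(A), ix, list(drop = FALSE)))
      }
      dp <- (take(p, 1L + seq_len(d[ax] - 1L)) - take(p, seq_len(d[ax] - 1L))) / grid$h
      ix <- list(seq_len(fdim[1]), seq_len(fdim[2]), seq_len(fdim[3]))
      ix[[ax]] <- 1L + seq_len(d[ax] - 1L)
      kf <- do.call(`[`, c(list(Kf), ix, list(drop = FALSE)))
      u <- do.call(`[<-`, c(list(u), ix, list(-kf * dp)))
    }
    out[[nm[ax]]] <- u
  }
  out
}

#' Discrete divergence of a face flux field (per cell, 1/s if u is um/s / h)
#' @param grid grid; @param u list(ux, uy, uz) of face arrays.
#' @return cell array of `div u`.
#' @export
divergence <- function(grid, u) {
  d <- grid$dims
  out <- zero_field(grid)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    U <- u[[c("ux", "uy", "uz")[ax]]]
    take <- function(rng) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[ax]] <- rng
      dim_f <- d; dim_f[ax] <- d[ax] + 1L
      ix2 <- ix; ix2[[ax]] <- rng
      do.call(`[`, c(list(U), ix2, list(drop = FALSE)))
    }
    out <- out + (take(1L + seq_len(d[ax])) - take(seq_len(d[ax]))) / grid$h
  }
  out
}

#' Magnitude of a face velocity field interpolated to cell centers
#' @param grid grid; @param u list(ux, uy, uz).
#' @return cell array of |u|.
#' @export
velocity_magnitude <- function(grid, u) {
  d <- grid$dims
  sq <- zero_field(grid)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    U <- u[[c("ux", "uy", "uz")[ax]]]
    ixlo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixhi <- ixlo
    ixhi[[ax]] <- 1L + seq_len(d[ax])
    lo <- do.call(`[`, c(list(U), ixlo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(U), ixhi, list(drop = FALSE)))
    sq <- sq + ((lo + hi) / 2)^2
  }
  sqrt(sq)
}
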