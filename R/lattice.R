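# Vessel lattices.  Sites are addressed by integer triples; geometry (positions,
# bond lengths, angles) is always derived from the indices, never stored.
#
# "fcc": sites are integer triples (i,j,k) with even coordinate sum inside the
#   extent box; the 12 nearest neighbors differ by permutations of (+-1,+-1,0),
#   giving the 60 degree branching angles of the face-centered-cubic lattice.
#   Physical position = index * spacing / sqrt(2), so bonded sites are exactly
#   `spacing` apart.
# "tri": the 2D analogue (triangular lattice, 6 neighbors, 60 degree angles)
#   embedded in the z = 0 plane; used for desk-scale slab simulations.

.fcc_offsets <- function() {
  m <- rbind(
    c( 1,  1, 0), c( 1, -1, 0), c(-1,  1, 0), c(-1, -1, 0),
    c( 1, 0,  1), c( 1, 0, -1), c(-1, 0,  1), c(-1, 0, -1),
    c( 0,  1, 1), c( 0,  1, -1), c( 0, -1, 1), c( 0, -1, -1))
  storage.mode(m) <- "integer"
  m
}

.tri_offsets <- function() {
  m <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(1, -1, 0), c(-1, 1, 0))
  storage.mode(m) <- "integer"
  m
}

#' Build a vessel lattice
#'
#' @param extent integer triple, number of index units per axis (>= 2 for the
#'   axes in use; the third component is ignored for `kind = "tri"`).
#' @param spacing bond length in um (> 0).
#' @param kind `"fcc"` (3D, 12 neighbors) or `"tri"` (2D triangular slab,
#'   6 neighbors).
#' @param origin physical position of index (0,0,0), um.
#' @return an object of class `vessel_lattice`.
#' @export
build_lattice <- function(extent, spacing, kind = c("fcc", "tri"),
                          origin = c(0, 0, 0)) {
  kind <- match.arg(kind)
  extent <- as.integer(round(extent))
  if (length(extent) == 2) extent <- c(extent, 1L)
  ndim <- if (kind == "tri") 2L else 3L
  if (any(extent[seq_len(ndim)] < 2L)) stop("extent components must be >= 2")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  structure(list(kind = kind, spacing = spacing, extent = extent,
                 origin = as.numeric(origin),
                 offsets = if (kind == "fcc") .fcc_offsets() else .tri_offsets()),
            class = "vessel_lattice")
}

#' @export
print.vessel_lattice <- function(x, ...) {
  cat(sprintf("<vessel_lattice %s %s, spacing %g um>\n", x$kind,
              paste(x$extent, collapse = "x"), x$spacing))
  invisible(x)
}

#' Physical positions of lattice sites
#'
#' @param lat lattice.
#' @param idx integer matrix (n x 3) of site indices.
#' @return numeric matrix (n x 3) of positions in um.
#' @export
site_position <- function(lat, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  if (lat$kind == "fcc") {
    pos <- idx * lat$spacing / sqrt(2)
  } else {
    pos <- cbind((idx[, 1] + idx[, 2] / 2) * lat$spacing,
                 idx[, 2] * sqrt(3) / 2 * lat$spacing,
                 idx[, 3] * 0)
  }
  sweep(pos, 2, lat$origin, "+")
}

#' Test whether index triples are lattice sites inside the extent
#' @param lat lattice; @param idx integer matrix (n x 3).
#' @return logical vector.
#' @export
site_valid <- function(lat, idx) {
  idx <- matrix(as.integer(idx), ncol = 3)
  inside <- idx[, 1] >= 0L & idx[, 1] < lat$extent[1] &
            idx[, 2] >= 0L & idx[, 2] < lat$extent[2]
  if (lat$kind == "fcc") {
    inside & idx[, 3] >= 0L & idx[, 3] < lat$extent[3] &
      (rowSums(idx) %% 2L == 0L)
  } else {
    inside & idx[, 3] == 0L
  }
}

#' Nearest-neighbor sites of one lattice site
#' @param lat lattice; @param site integer triple.
#' @return integer matrix of valid neighbor sites (rows).
#' @export
site_neighbors <- function(lat, site) {
  nb <- sweep(lat$offsets, 2, as.integer(site), "+")
  nb[site_valid(lat, nb), , drop = FALSE]
}

#' Boundary sites of a lattice in traversal order
#'
#' Sites with at least one in-use index coordinate on the extent boundary,
#' ordered by angle around the lattice center so that root placement can
#' alternate along a perimeter walk.
#' @param lat lattice.
#' @return integer matrix (n x 3).
#' @export
boundary_sites <- function(lat) {
  ex <- lat$extent
  if (lat$kind == "tri") {
    g <- as.matrix(expand.grid(i = 0:(ex[1] - 1L), j = 0:(ex[2] - 1L), k = 0L))
  } else {
    g <- as.matrix(expand.grid(i = 0:(ex[1] - 1L), j = 0:(ex[2] - 1L),
                               k = 0:(ex[3] - 1L)))
    g <- g[rowSums(g) %% 2L == 0L, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  ndim <- if (lat$kind == "tri") 2L else 3L
  on_b <- rep(FALSE, nrow(g))
  for (d in seq_len(ndim))
    on_b <- on_b | g[, d] == 0L | g[, d] == ex[d] - 1L
  b <- g[on_b, , drop = FALSE]
  pos <- site_position(lat, b)
  ctr <- colMeans(pos)
  ang <- atan2(pos[, 2] - ctr[2], pos[, 1] - ctr[1])
  b[order(ang, pos[, 3]), , drop = FALSE]
}

# canonical key of a lattice bond (undirected), used for occupancy maps
bond_key <- function(a, b) {
  ka <- paste(a, collapse = ",")
  kb <- paste(b, collapse = ",")
  if (ka < kb) paste(ka, kb, sep = "|") else paste(kb, ka, sep = "|")
}

site_key <- function(s) paste(s, collapse = ",")

#' Angles realized between lattice bonds
#'
#' All distinct angles (degrees) between pairs of bond directions sharing a
#' site.  For both supported lattices the set contains 60 degrees, the
#' parent/child branching angle of the model.
#' @param lat lattice.
#' @return sorted numeric vector of angles in degrees.
#' @export
bond_angles <- function(lat) {
  off <- lat$offsets
  pos <- site_position(lat, off) - matrix(site_position(lat, matrix(0L, 1, 3)),
                                          nrow(off), 3, byrow = TRUE)
  n <- nrow(pos)
  angs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cosv <- sum(pos[i, ] * pos[j, ]) / sqrt(sum(pos[i, ]^2) * sum(pos[j, ]^2))
    angs <- c(angs, acos(pmin(1, pmax(-1, cosv))) * 180 / pi)
  }
  sort(unique(round(angs, 6)))
}
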