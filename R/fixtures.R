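# Deterministic desk-scale fixtures exercising every solver without running
# the full growth simulation: a single perfused vessel in a tissue block, an
# arteriovenous pair bridged by capillaries, a frozen spherical tumor (level
# set + degenerate dilated central vessels + intact periphery, mimicking a
# late growth state), and a homogeneous lymphatic slab for closed-form
# pressure-decay checks.

#' Generate a named test fixture
#'
#' @param kind one of `"single-vessel-block"`, `"AV-pair-capillary-bridge"`,
#'   `"frozen-spherical-tumor"`, `"homogeneous-lymphatic-slab"`.
#' @param size grid cells per axis (slab mode, third dimension 1 unless
#'   `three_d`); @param seed RNG seed; @param params parameters; @param
#'   three_d logical, build a thin 3D block instead of a slab.
#' @return list with `net`, `grid`, `state` and kind-specific extras.
#' @export
make_fixture <- function(kind, size = 32L, seed = 1L,
                         params = default_parameters(), three_d = FALSE) {
  h <- params$numerics$h
  nz <- if (three_d) max(4L, size %/% 4L) else 1L
  grid <- continuum_grid(c(size, size, nz), h)
  box <- size * h
  switch(kind,
    "single-vessel-block" = {
      # one straight vessel through the block center along x
      nb <- max(2L, floor(box / params$lattice$spacing) - 1L)
      lat <- build_lattice(c(nb + 2L, 3L, 1L), params$lattice$spacing, "tri",
                           origin = c(-box / 2, 0, 0))
      net <- vessel_network(lat)
      net <- net_add_node(net, c(0L, 0L, 0L), "arterial-root")$net
      net <- net_add_node(net, c(nb, 0L, 0L), "venous-root")$net
      for (m in seq_len(nb))
        net <- net_add_segment(net, c(m - 1L, 0L, 0L), c(m, 0L, 0L),
                               r = 10)$net
      net$nodes$press[net$nodes$bc == "arterial-root"] <- root_pressure(10, "arterial")
      net$nodes$press[net$nodes$bc == "venous-root"] <- root_pressure(10, "venous")
      sol <- solve_nodal_pressures(net, params)
      theta <- array(box, dim = grid$dims)    # no tumor
      state <- continuum_state(grid, theta, params)
      list(net = sol$net, grid = grid, state = state, flow = sol)
    },
    "AV-pair-capillary-bridge" = {
      # arterial and venous chain joined by two capillary bridges
      lat <- build_lattice(c(8L, 6L, 1L), params$lattice$spacing, "tri",
                           origin = c(-3.5 * params$lattice$spacing,
                                      -2 * params$lattice$spacing, 0))
      net <- vessel_network(lat)
      net <- net_add_node(net, c(0L, 0L, 0L), "arterial-root")$net
      net <- net_add_node(net, c(0L, 3L, 0L), "venous-root")$net
      for (m in 0:3) {  # arterial chain along +x at j=0, venous at j=3
        net <- net_add_segment(net, c(m, 0L, 0L), c(m + 1L, 0L, 0L), r = 6)$net
        net <- net_add_segment(net, c(m, 3L, 0L), c(m + 1L, 3L, 0L), r = 8)$net
      }
      # capillary bridges at x = 2 and x = 4 (three bonds each through j=1,2)
      for (x0 in c(2L, 4L)) for (j in 0:2)
        net <- net_add_segment(net, c(x0 - 0L, j, 0L), c(x0 - 0L, j + 1L, 0L),
                               r = params$builder$r_capillary, cap = TRUE)$net
      net$nodes$press[net$nodes$bc == "arterial-root"] <- root_pressure(6, "arterial")
      net$nodes$press[net$nodes$bc == "venous-root"] <- root_pressure(8, "venous")
      sol <- solve_nodal_pressures(net, params)
      theta <- array(box, dim = grid$dims)
      state <- continuum_state(grid, theta, params)
      list(net = sol$net, grid = grid, state = state, flow = sol)
    },
    "frozen-spherical-tumor" = {
      # theta sphere + parallel vessels: central ones degenerate and dilated,
      # peripheral ones intact; mimics the late compartmentalized state
      R <- box / 4
      theta <- levelset_sphere(grid, R)
      state <- continuum_state(grid, theta, params)
      # necrotic core
      core <- theta < -R / 2
      state$phiD[core] <- state$phiT[core] * 0.8
      state$phiT[core] <- state$phiT[core] * 0.2
      sp <- params$lattice$spacing
      nb <- max(2L, floor(0.9 * box / sp))
      nlines <- 7L
      yspan <- (2 * nlines - 1) * sqrt(3) / 2 * sp
      lat <- build_lattice(c(nb + 2L, 2L * nlines + 2L, 1L), sp, "tri",
                           origin = c(-nb * sp / 2 - yspan / 4, -yspan / 2, 0))
      net <- vessel_network(lat)
      set.seed(seed)
      for (ln in seq_len(nlines)) {
        j <- 2L * (ln - 1L) + 1L
        # alternate flow direction so neighbors have different pressures
        akind <- if (ln %% 2L) "arterial-root" else "venous-root"
        vkind <- if (ln %% 2L) "venous-root" else "arterial-root"
        net <- net_add_node(net, c(0L, j, 0L), akind)$net
        net <- net_add_node(net, c(nb, j, 0L), vkind)$net
        for (m in seq_len(nb))
          net <- net_add_segment(net, c(m - 1L, j, 0L), c(m, j, 0L), r = 8)$net
      }
      # degenerate + dilate vessels inside the tumor; reduce central density
      keep <- rep(TRUE, nrow(net$segments))
      for (m in seq_len(nrow(net$segments))) {
        s <- net$segments[m, ]
        mid <- (site_position(lat, node_site(net, s$n1)) +
                site_position(lat, node_site(net, s$n2))) / 2
        d <- sqrt(sum(mid[1:2]^2))
        if (d < R) {
          net$segments$w[m] <- 0
          net$segments$r[m] <- params$remodel$r_max
          net$segments$tumor[m] <- TRUE
          if (d < R / 2 && runif(1) < 0.5) keep[m] <- FALSE  # regressed
        }
      }
      net <- net_remove_segments(net, net$segments$id[!keep])
      net <- drop_rootless_components(net)
      for (b in c("arterial-root", "venous-root")) {
        k <- sub("-root", "", b)
        sel <- net$nodes$bc == b
        net$nodes$press[sel] <- root_pressure(8, k)
      }
      sol <- solve_nodal_pressures(net, params)
      list(net = sol$net, grid = grid, state = state, flow = sol, R = R)
    },
    "homogeneous-lymphatic-slab" = {
      # uniform normal tissue with lymphatics only; no vessels
      theta <- array(box, dim = grid$dims)
      state <- continuum_state(grid, theta, params)
      lat <- build_lattice(c(3L, 3L, 1L), params$lattice$spacing, "tri")
      net <- vessel_network(lat)
      list(net = net, grid = grid, state = state)
    },
    stop("unknown fixture kind: ", kind)
  )
}
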