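test_that("relative viscosity: plasma limit, hematocrit monotonicity, F-L minimum", {
  # H = 0 reduces to the wall-layer factor of the in-vivo law
  for (r in c(3, 5, 10, 40)) {
    d <- 2 * r
    expect_equal(relative_viscosity(r, 0), (d / (d - 1.1))^2, tolerance = 1e-12)
  }
  # monotone increasing in hematocrit at fixed radius
  hs <- seq(0, 0.8, by = 0.05)
  for (r in c(4, 10, 50)) expect_true(all(diff(relative_viscosity(r, hs)) > 0))
  # Fahraeus-Lindqvist effect: an interior minimum over diameter at H = 0.45
  # (the in-vivo parameterization puts it near d ~ 48 um; frozen from a scan
  # of the published formula)
  ds <- seq(3, 300, by = 0.5)
  ev <- relative_viscosity(ds / 2, 0.45)
  expect_equal(ds[which.min(ev)], 48.5, tolerance = 0.05)
  expect_lt(min(ev), ev[1])          # smaller than capillary-scale viscosity
  expect_lt(min(ev), ev[length(ev)]) # and than the large-vessel limit
  expect_error(relative_viscosity(-1, 0.45), "radius")
  expect_error(relative_viscosity(10, 1.2), "hematocrit")
})

test_that("Poiseuille conductance follows pi r^4 / (8 eta l)", {
  expect_equal(conductance(10, 100, 4e-6), pi * 1e4 / (8 * 4e-6 * 100),
               tolerance = 1e-12)
  expect_equal(conductance(20, 100, 4e-6) / conductance(10, 100, 4e-6), 16)
  expect_error(conductance(10, 0, 4e-6), "length")
})

test_that("wall shear stress r |dp| / (2 l), zero at zero drop, linear in dp", {
  expect_equal(wall_shear_stress(10, 0, 100), 0)
  expect_equal(wall_shear_stress(10, 1, 100), 0.05)
  dps <- seq(0.1, 2, by = 0.1)
  expect_equal(wall_shear_stress(10, dps, 100) / dps,
               rep(0.05, length(dps)), tolerance = 1e-12)
})

test_that("root pressures: arterial above venous, monotone, continuous", {
  r <- c(5, 20, 50)
  expect_true(all(root_pressure(r, "arterial") > root_pressure(r, "venous")))
  rg <- seq(2, 100, by = 0.1)
  pa <- root_pressure(rg, "arterial"); pv <- root_pressure(rg, "venous")
  expect_true(all(diff(pa) > 0))
  expect_true(all(diff(pv) < 0))
  expect_true(all(pa > pv))
  expect_lt(max(abs(diff(pa))), 0.05)    # no jumps on a fine grid
  expect_lt(max(abs(diff(pv))), 0.05)
})

test_that("Kirchhoff solve: series midpoint, Y junction, uniform pressure", {
  # two identical segments in series, ends at 10 and 2 kPa -> middle 6 kPa
  net <- chain_network(2, p_in = 10, p_out = 2)
  sol <- solve_nodal_pressures(net)
  mid <- setdiff(sol$net$nodes$id, sol$net$nodes$id[sol$net$nodes$bc != "none"])
  expect_equal(unname(sol$pressure[as.character(mid)]), 6, tolerance = 1e-10)
  # Y junction: parent at 9 kPa, two identical children to 0, equal
  # conductances -> junction at 3 kPa (hand-solved three-resistor network)
  lat <- build_lattice(c(6, 6, 1), 100, "tri")
  y <- vessel_network(lat)
  y <- net_add_node(y, c(0L, 2L, 0L), "arterial-root", 9)$net
  y <- net_add_node(y, c(2L, 1L, 0L), "venous-root", 0)$net
  y <- net_add_node(y, c(1L, 3L, 0L), "venous-root", 0)$net
  y <- net_add_segment(y, c(0L, 2L, 0L), c(1L, 2L, 0L), r = 5)$net
  y <- net_add_segment(y, c(1L, 2L, 0L), c(2L, 1L, 0L), r = 5)$net
  y <- net_add_segment(y, c(1L, 2L, 0L), c(1L, 3L, 0L), r = 5)$net
  soly <- solve_nodal_pressures(y)
  j <- setdiff(soly$net$nodes$id, soly$net$nodes$id[soly$net$nodes$bc != "none"])
  expect_equal(unname(soly$pressure[as.character(j)]), 3, tolerance = 1e-10)
  # uniform boundary pressure everywhere -> all flows zero
  net0 <- chain_network(3, p_in = 5, p_out = 5)
  sol0 <- solve_nodal_pressures(net0)
  expect_true(all(abs(sol0$q_signed) < 1e-9))
  expect_false(any(sol0$net$segments$perfused))
})

test_that("component without boundary node raises a singular-system error", {
  lat <- build_lattice(c(8, 8, 1), 100, "tri")
  net <- vessel_network(lat)
  net <- net_add_node(net, c(0L, 0L, 0L), "arterial-root", 9)$net
  net <- net_add_segment(net, c(0L, 0L, 0L), c(1L, 0L, 0L), r = 5)$net
  net <- net_add_segment(net, c(4L, 4L, 0L), c(5L, 4L, 0L), r = 5)$net
  expect_error(solve_nodal_pressures(net), "component")
})

test_that("global conservation and boundary-offset invariance", {
  res <- test_network()
  sol <- res$flow
  net <- sol$net
  roots <- net$nodes$id[net$nodes$bc != "none"]
  net_node_flow <- function(sol, net, ids) {
    tot <- 0
    i1 <- match(net$segments$n1, net$nodes$id)
    i2 <- match(net$segments$n2, net$nodes$id)
    for (id in ids) {
      m1 <- which(net$segments$n1 == id); m2 <- which(net$segments$n2 == id)
      tot <- tot + sum(-sol$q_signed[m1]) + sum(sol$q_signed[m2])
    }
    tot
  }
  art <- net$nodes$id[net$nodes$bc == "arterial-root"]
  ven <- net$nodes$id[net$nodes$bc == "venous-root"]
  inflow <- -net_node_flow(sol, net, art)
  outflow <- net_node_flow(sol, net, ven)
  expect_equal(inflow, outflow, tolerance = 1e-8)
  # uniform offset of all boundary pressures leaves the flows unchanged
  net2 <- net
  sel <- net2$nodes$bc != "none"
  net2$nodes$press[sel] <- net2$nodes$press[sel] + 2.5
  sol2 <- solve_nodal_pressures(net2, test_params())
  expect_equal(sol2$q_signed, sol$q_signed, tolerance = 1e-7)
})

test_that("sparse Kirchhoff solve matches a dense direct solve (oracle)", {
  set.seed(5)
  net <- chain_network(4, p_in = 12, p_out = 1)
  # add a few extra branches for a non-trivial (< 50 node) network
  for (m in 1:4) {
    nb <- site_neighbors(net$lat, c(m, 0L, 0L))
    for (k in seq_len(nrow(nb))) {
      res <- tryCatch(net_add_segment(net, c(m, 0L, 0L), nb[k, ],
                                      r = runif(1, 3, 8)),
                      error = function(e) NULL)
      if (!is.null(res) && runif(1) < 0.5) net <- res$net
    }
  }
  net <- drop_rootless_components(net)
  p <- default_parameters()
  sol <- solve_nodal_pressures(net, p)
  # dense oracle assembled independently
  nid <- sol$net$nodes$id
  n <- length(nid)
  L <- matrix(0, n, n)
  segs <- sol$net$segments
  for (m in seq_len(nrow(segs))) {
    i <- match(segs$n1[m], nid); j <- match(segs$n2[m], nid)
    eta <- p$blood$plasma_viscosity * relative_viscosity(segs$r[m], segs$hema[m])
    g <- pi * segs$r[m]^4 / (8 * eta * segs$nbonds[m] * net$lat$spacing)
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
  }
  fixed <- sol$net$nodes$bc != "none"
  pvec <- numeric(n); pvec[fixed] <- sol$net$nodes$press[fixed]
  free <- !fixed
  pvec[free] <- solve(L[free, free], -L[free, fixed] %*% pvec[fixed])
  expect_equal(unname(sol$pressure), pvec, tolerance = 1e-9)
})
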