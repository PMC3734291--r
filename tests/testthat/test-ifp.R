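test_that("wall hydraulic permeability: anchors and monotonicity", {
  p <- default_parameters()
  r <- 6
  wN <- normal_wall_thickness(r, p$iff$wall_thickness_coef)
  expect_equal(wall_hydraulic_permeability(wN, r, p), p$iff$lambda_l_normal)
  expect_equal(wall_hydraulic_permeability(0, r, p), p$iff$lambda_l_tumor)
  ws <- seq(0, 2 * wN, length.out = 50)
  lam <- wall_hydraulic_permeability(ws, r, p)
  expect_true(all(diff(lam) <= 1e-15))
  expect_true(all(lam <= p$iff$lambda_l_tumor + 1e-15))
  expect_error(wall_hydraulic_permeability(-0.1, r, p), "maturity")
})

test_that("surface sampling: Monte-Carlo area convergence and kernel unity", {
  p <- default_parameters()
  fx <- single_vessel_fixture()
  g <- fx$grid
  net <- fx$net
  s <- sample_surfaces(net, g, density = 0.2, seed = 3)
  per_seg <- tapply(s$a, s$seg, sum)
  segs <- net$segments
  for (id in names(per_seg)) {
    sr <- segs[segs$id == as.integer(id), ]
    area <- 2 * pi * sr$r * sr$nbonds * net$lat$spacing
    expect_equal(unname(per_seg[[id]]), area, tolerance = 0.01)
  }
  # empty network samples to an empty frame
  empty <- vessel_network(build_lattice(c(3, 3, 1), 80, "tri"))
  expect_equal(nrow(sample_surfaces(empty, g, 0.1, 1)), 0)
  # CIC deposition: weights per point sum to one
  w <- cic_weights(g, s)
  sums <- tapply(w$w, w$point, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, nrow(s)), tolerance = 1e-12)
})

test_that("IFP equilibrium: effective blood pressure at lymphatic level", {
  # when the osmosis-corrected vessel pressure equals the lymphatic pressure
  # everywhere, the solution is that constant and all flow vanishes
  p <- test_params()
  fx <- single_vessel_fixture()
  net <- fx$net
  dpi <- p$iff$pi_vessel - p$iff$pi_interstitial
  net$nodes$press[] <- p$iff$p_lymph + p$iff$sigma_normal * dpi
  iff <- assemble_and_solve_ifp(net, fx$state, fx$grid, p, seed = 2)
  expect_equal(max(abs(iff$p - p$iff$p_lymph)), 0, tolerance = 1e-8)
  expect_lt(max(abs(unlist(iff$u))), 1e-10)
})

test_that("lymphatics-only slab: pressure decays with the screened length", {
  p <- test_params()
  g <- continuum_grid(c(72, 4, 1), 30)
  K <- p$iff$K_normal
  aL <- p$iff$lambda_lymph * p$iff$S_lymph_normal
  mask <- array(FALSE, g$dims); mask[1, , ] <- TRUE
  p0 <- 1
  u <- solve_reaction_diffusion(g, K, aL, aL * p$iff$p_lymph,
                                dirichlet = list(mask = mask, value = p0))
  lam_theory <- sqrt(K / aL)
  prof <- u[2:40, 2, 1] - p$iff$p_lymph
  x <- (2:40 - 1) * g$h
  fit <- lm(log(prof) ~ x)
  expect_equal(-1 / unname(coef(fit)[2]), lam_theory, tolerance = 0.05)
})

test_that("Darcy velocity: trivial fields and exact conservation", {
  g <- continuum_grid(c(16, 16, 1), 30)
  u0 <- darcy_velocity(g, array(2, g$dims), 100)
  expect_true(all(abs(unlist(u0)) == 0))
  x <- array(rep(cell_centers(g)$x, 16), g$dims)
  u1 <- darcy_velocity(g, 0.003 * x, 100)
  expect_equal(as.vector(u1$ux[2:16, , ]),
               rep(-100 * 0.003, 15 * 16), tolerance = 1e-12)
  # cell-wise conservation on a solved fixture: div u = Q exactly
  iff <- frozen_iff()
  fx <- frozen_fixture()
  divu <- divergence(fx$grid, iff$u)
  expect_lt(max(abs(divu - iff$sources$Q)),
            1e-10 * max(abs(iff$sources$Q)))
})

test_that("source decomposition: identity, signs, tumor lymphatics absent", {
  p <- test_params()
  iff <- frozen_iff()
  fx <- frozen_fixture()
  src <- iff$sources
  expect_equal(src$Q, src$Qin_v - src$Qout_v - src$Qout_L, tolerance = 1e-14)
  expect_true(all(src$Qin_v >= 0))
  expect_true(all(src$Qout_v >= 0))
  # no lymphatics inside the tumor: the lymphatic channel vanishes there
  core <- fx$state$theta < -2 * p$numerics$heaviside_width
  expect_equal(max(abs(src$Qout_L[core])), 0, tolerance = 1e-12)
  # leaky low-pressure vessels absorb fluid somewhere inside the tumor
  expect_gt(sum(src$Qout_v[fx$state$theta < 0] > 0), 0)
})

test_that("frozen tumor: IFP plateau, boundary drop, rim velocity peak", {
  iff <- frozen_iff()
  fx <- frozen_fixture()
  prof <- theta_profile(iff$p, fx$state$theta, 100)
  inner <- prof$mean[prof$theta < -200]
  outer <- prof$mean[prof$theta > 200]
  expect_gt(min(inner, na.rm = TRUE), max(outer, na.rm = TRUE))
  # plateau: interior variation much smaller than the boundary drop
  drop <- max(inner, na.rm = TRUE) - min(outer, na.rm = TRUE)
  expect_lt(diff(range(inner, na.rm = TRUE)), drop)
  # outward velocity peaks near the rim, not deep inside or far outside
  vm <- velocity_magnitude(fx$grid, iff$u)
  pv <- theta_profile(vm, fx$state$theta, 100)
  pk <- pv$theta[which.max(pv$mean)]
  expect_lt(abs(pk), 300)
})

test_that("IFP linearity: scaling all driving pressures scales p and u", {
  p <- test_params()
  fx <- frozen_fixture()
  iff1 <- frozen_iff()
  s <- 2.5
  p2 <- p
  p2$iff$p_lymph <- p$iff$p_lymph * s
  p2$iff$pi_vessel <- p$iff$pi_vessel * s
  p2$iff$pi_interstitial <- p$iff$pi_interstitial * s
  net2 <- fx$net
  net2$nodes$press <- net2$nodes$press * s
  iff2 <- assemble_and_solve_ifp(net2, fx$state, fx$grid, p2, seed = 3)
  expect_equal(iff2$p, iff1$p * s, tolerance = 1e-6)
  expect_equal(iff2$u$ux, iff1$u$ux * s, tolerance = 1e-6)
})

test_that("raising tumor wall permeability raises total influx (ohmic chain)", {
  p <- test_params()
  fx <- frozen_fixture()
  influx <- sapply(c(0.2, 1, 5), function(f) {
    pf <- p; pf$iff$lambda_l_tumor <- pf$iff$lambda_l_tumor * f
    pf$drug$lambda_diff_tumor <- pf$drug$lambda_diff_tumor * f
    iff <- assemble_and_solve_ifp(fx$net, fx$state, fx$grid, pf, seed = 3)
    sum(iff$sources$Qin_v[fx$state$theta < 0])
  })
  expect_true(all(diff(influx) > 0))
  # decreasing tissue conductivity with fixed walls lowers the influx
  influxK <- sapply(c(0.1, 1), function(f) {
    pf <- p
    for (nm in c("K_normal", "K_tumor", "K_necrotic"))
      pf$iff[[nm]] <- pf$iff[[nm]] * f
    iff <- assemble_and_solve_ifp(fx$net, fx$state, fx$grid, pf, seed = 3)
    sum(iff$sources$Qin_v[fx$state$theta < 0])
  })
  expect_lt(influxK[1], influxK[2])
})

test_that("sparse IFP solve agrees with a dense direct solve (oracle)", {
  p <- test_params()
  g <- continuum_grid(c(9, 8, 1), 30)
  set.seed(21)
  K <- array(runif(prod(g$dims), 100, 300), g$dims)
  a <- array(runif(prod(g$dims), 1e-5, 1e-3), g$dims)
  b <- array(rnorm(prod(g$dims), 0, 1e-4), g$dims)
  u <- solve_reaction_diffusion(g, K, a, b)
  # dense oracle with harmonic face conductivities, assembled independently
  n <- prod(g$dims)
  A <- matrix(0, n, n)
  id <- function(i, j) i + g$dims[1] * (j - 1)
  for (i in 1:g$dims[1]) for (j in 1:g$dims[2]) {
    m <- id(i, j)
    A[m, m] <- a[i, j, 1]
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > g$dims[1] || nb[2] < 1 || nb[2] > g$dims[2])
        next
      kh <- 2 * K[i, j, 1] * K[nb[1], nb[2], 1] /
        (K[i, j, 1] + K[nb[1], nb[2], 1])
      A[m, m] <- A[m, m] + kh / g$h^2
      A[m, id(nb[1], nb[2])] <- A[m, id(nb[1], nb[2])] - kh / g$h^2
    }
  }
  expect_equal(as.vector(u), solve(A, as.vector(b)), tolerance = 1e-8)
})

test_that("vessel pressure decay length: limits, scaling, BVP oracle", {
  p <- default_parameters()
  eta <- 4e-6
  # sealed walls recover plain Poiseuille flow (infinite decay length)
  expect_equal(vessel_pressure_decay_length(10, eta, 0), Inf)
  # quadrupling the wall conductance halves the length
  l1 <- vessel_pressure_decay_length(10, eta, 0.1)
  l4 <- vessel_pressure_decay_length(10, eta, 0.4)
  expect_equal(l1 / l4, 2, tolerance = 1e-12)
  # finite-difference two-point boundary problem as independent oracle:
  # (k_ax p')' = c_w (p - p_inf), p(0) = 1, p(L) -> far end sealed
  r <- 8; lam_l <- 0.5
  k_ax <- pi * r^4 / (8 * eta)
  c_w <- lam_l * 2 * pi * r
  lam_theory <- sqrt(k_ax / c_w)
  L <- 6 * lam_theory
  nfd <- 600
  hx <- L / nfd
  A <- matrix(0, nfd, nfd); rhs <- numeric(nfd)
  for (m in 1:nfd) {
    A[m, m] <- 2 * k_ax / hx^2 + c_w
    if (m > 1) A[m, m - 1] <- -k_ax / hx^2
    if (m < nfd) A[m, m + 1] <- -k_ax / hx^2
  }
  A[1, 1] <- A[1, 1] + 2 * k_ax / hx^2   # strong Dirichlet p=1 ghost at x=0
  rhs[1] <- 2 * k_ax / hx^2 * 1
  A[nfd, nfd] <- A[nfd, nfd] - k_ax / hx^2  # sealed far end (Neumann)
  pr <- solve(A, rhs)
  x <- (1:nfd - 0.5) * hx
  sel <- x < 2 * lam_theory
  fit <- lm(log(pr[sel]) ~ x[sel])
  expect_equal(-1 / unname(coef(fit)[2]), lam_theory, tolerance = 0.02)
})

test_that("extravasation fraction: sealed walls give zero; quadrature oracle", {
  p <- test_params()
  fx <- frozen_fixture()
  # sealed walls: no extravasation at all
  ps <- p
  ps$iff$lambda_l_tumor <- 1e-300
  ps$iff$lambda_l_normal <- 1e-300
  ps$drug$lambda_diff_tumor <- 1e-300
  ps$drug$lambda_diff_normal <- 1e-300 * (0.0225 / 1.4)
  iff0 <- assemble_and_solve_ifp(fx$net, fx$state, fx$grid, ps, seed = 3)
  ex0 <- extravasation_ratio(fx$net, fx$state, fx$grid, iff0$sources)
  expect_equal(ex0$r_gamma, 0, tolerance = 1e-12)
  # base case: r_gamma equals the direct per-sample quadrature
  iff <- frozen_iff()
  ex <- extravasation_ratio(fx$net, fx$state, fx$grid, iff$sources)
  samp <- iff$sampling
  terms <- iff$wall_terms
  w <- cic_weights(fx$grid, samp)
  pv <- as.vector(iff$p)[w$cell]
  flux <- w$w * samp$a[w$point] * terms$lambda[w$point] *
    (terms$peff[w$point] - pv)
  tumor_cell <- as.vector(fx$state$theta < 0)[w$cell]
  direct <- sum(pmax(flux, 0)[tumor_cell])
  expect_equal(ex$extravasation, direct, tolerance = 1e-10)
  expect_gt(ex$r_gamma, 0)
  expect_lt(ex$r_gamma, 0.05)   # a small fraction of tumor blood flow
  # empty tumor region is an error
  healthy <- fx$state; healthy$theta <- abs(healthy$theta) + 1
  expect_error(extravasation_ratio(fx$net, healthy, fx$grid, iff$sources),
               "empty tumor")
})
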