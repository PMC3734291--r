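test_that("plasma concentration: bolus normalization and infusion window", {
  expect_equal(plasma_concentration(0, "bolus"), 1)
  expect_equal(plasma_concentration(3600, "bolus", tau = 3600), exp(-1))
  expect_equal(plasma_concentration(25 * 3600, "infusion",
                                    T_inf = 24 * 3600), 0)
  expect_equal(plasma_concentration(12 * 3600, "infusion",
                                    T_inf = 24 * 3600), 1)
  expect_error(plasma_concentration(-1, "bolus"), "negative")
})

test_that("transmembrane exchange vanishes at the steady-state ratio", {
  p <- default_parameters()
  ratio <- p$drug$k12 / p$drug$k21
  expect_equal(ratio, 100)
  expect_equal(exchange_rate(1, ratio, 0.5, p), 0, tolerance = 1e-15)
  expect_equal(exchange_rate(0, 0, 0.5, p), 0)
  expect_gt(exchange_rate(1, 0, 0.5, p), 0)
})

test_that("isolated two-compartment system relaxes to ratio 100 with the
           eigenvalue of the rate matrix (matrix-exponential oracle)", {
  p <- default_parameters()
  phi_f <- 0.4; phi_c <- 0.4
  gam <- gamma_exchange(phi_c, p)
  a11 <- -gam * p$drug$k12 / phi_f; a12 <- gam * p$drug$k21 / phi_f
  a21 <- gam * p$drug$k12 / phi_c; a22 <- -gam * p$drug$k21 / phi_c
  M <- matrix(c(a11, a21, a12, a22), 2)
  ev <- eigen(M)$values
  lam <- min(ev)                          # the decaying mode (other is 0)
  # oracle: dense matrix exponential by scaling-and-squaring
  expm2 <- function(M, t, k = 16) {
    X <- diag(2) + M * t / 2^k
    S <- M * t / 2^k
    term <- S
    for (j in 2:10) { term <- term %*% S / j; X <- X + term }
    for (j in 1:k) X <- X %*% X
    X
  }
  x0 <- c(1, 0)
  tend <- 25 / abs(lam)    # deep into the steady state
  xT <- expm2(M, tend) %*% x0
  expect_equal(xT[2] / xT[1], 100, tolerance = 1e-3)
  # package integration path reproduces the oracle trajectory
  g <- continuum_grid(c(2, 2, 1), 30)
  ds <- list(grid = g, s1 = array(1, g$dims), s2 = array(0, g$dims),
             phi_f = array(phi_f, g$dims), phi_c = array(phi_c, g$dims),
             Adiff = assemble_diffusion(g, 0),
             diffw = array(0, g$dims), Qin = array(0, g$dims),
             Qoutv = array(0, g$dims), QoutL = array(0, g$dims),
             u = list(ux = array(0, c(3, 2, 1)), uy = array(0, c(2, 3, 1)),
                      uz = array(0, c(2, 2, 2))),
             influx = 0, efflux = 0, t = 0)
  class(ds) <- "drug_state"
  nstep <- 200
  for (m in 1:nstep) ds <- drug_step(ds, tend / nstep, 0, p)
  expect_equal(ds$s2[1, 1, 1] / ds$s1[1, 1, 1], 100, tolerance = 1e-3)
  xmid <- expm2(M, tend / 2) %*% x0
  ds2 <- ds; ds2$s1[] <- 1; ds2$s2[] <- 0; ds2$t <- 0
  for (m in 1:(nstep / 2)) ds2 <- drug_step(ds2, tend / nstep, 0, p)
  expect_equal(ds2$s1[1, 1, 1], xmid[1], tolerance = 1e-6)
  expect_equal(ds2$s2[1, 1, 1], xmid[2], tolerance = 1e-6)
})

test_that("diffusive wall permeability mirrors the hydraulic interpolation", {
  p <- default_parameters()
  r <- 8
  wN <- normal_wall_thickness(r, p$iff$wall_thickness_coef)
  expect_equal(diffusive_wall_permeability(wN, r, p),
               p$drug$lambda_diff_normal)
  expect_equal(diffusive_wall_permeability(0, r, p), p$drug$lambda_diff_tumor)
  # tumor/normal ratio equals the hydraulic ratio by construction
  expect_equal(p$drug$lambda_diff_tumor / p$drug$lambda_diff_normal,
               p$iff$lambda_l_tumor / p$iff$lambda_l_normal,
               tolerance = 1e-9)
})

test_that("sealed box without vascular exchange conserves drug mass exactly", {
  p <- test_params()
  g <- continuum_grid(c(12, 12, 1), 30)
  set.seed(31)
  phi_f <- array(runif(prod(g$dims), 0.3, 0.5), g$dims)
  phi_c <- 1 - 0.2 - phi_f
  ds <- list(grid = g,
             s1 = array(runif(prod(g$dims)), g$dims),
             s2 = array(runif(prod(g$dims)), g$dims),
             phi_f = phi_f, phi_c = phi_c,
             Adiff = assemble_diffusion(g, p$drug$D_s * phi_f),
             diffw = array(0, g$dims), Qin = array(0, g$dims),
             Qoutv = array(0, g$dims), QoutL = array(0, g$dims),
             u = list(ux = array(0.01 * rnorm(13 * 12), c(13, 12, 1)),
                      uy = array(0.01 * rnorm(12 * 13), c(12, 13, 1)),
                      uz = array(0, c(12, 12, 2))),
             influx = 0, efflux = 0, t = 0)
  # boundary faces sealed
  ds$u$ux[c(1, 13), , ] <- 0; ds$u$uy[, c(1, 13), ] <- 0
  class(ds) <- "drug_state"
  m0 <- sum(ds$phi_f * ds$s1 + ds$phi_c * ds$s2)
  for (m in 1:50) ds <- drug_step(ds, 5, 0, p)
  m1 <- sum(ds$phi_f * ds$s1 + ds$phi_c * ds$s2)
  expect_equal(m1, m0, tolerance = 1e-12)
  # positivity is preserved under the split scheme
  expect_true(all(ds$s1 >= 0))
  expect_true(all(ds$s2 >= 0))
})

test_that("vascular mass audit: total change equals influx minus efflux", {
  p <- test_params()
  fx <- single_vessel_fixture()
  iff <- assemble_and_solve_ifp(fx$net, fx$state, fx$grid, p, seed = 3)
  ds <- drug_state(fx$net, fx$state, fx$grid, iff, p)
  res <- simulate_drug(ds, p, T_obs = 2 * 3600, schedule = "bolus")
  st <- res$state
  mass <- sum(st$phi_f * st$s1 + st$phi_c * st$s2) * cell_volume(fx$grid)
  expect_equal(mass, st$influx - st$efflux, tolerance = 1e-8)
})

test_that("uniform s1 equal to plasma with no cells and no flow stays put", {
  p <- test_params()
  g <- continuum_grid(c(8, 8, 1), 30)
  phi_f <- array(0.8, g$dims)
  ds <- list(grid = g, s1 = array(1, g$dims), s2 = array(0, g$dims),
             phi_f = phi_f, phi_c = array(0, g$dims),
             Adiff = assemble_diffusion(g, p$drug$D_s * phi_f),
             diffw = array(0.01, g$dims), Qin = array(0, g$dims),
             Qoutv = array(0, g$dims), QoutL = array(0, g$dims),
             u = list(ux = array(0, c(9, 8, 1)), uy = array(0, c(8, 9, 1)),
                      uz = array(0, c(8, 8, 2))),
             influx = 0, efflux = 0, t = 0)
  class(ds) <- "drug_state"
  ds2 <- drug_step(ds, 10, sB = 1, p)   # diffusive wall term vanishes
  expect_equal(ds2$s1, ds$s1, tolerance = 1e-12)
})

test_that("exposure metrics: constants, exponential AUC, bound by max times T", {
  g <- continuum_grid(c(4, 4, 1), 30)
  times <- seq(0, 10 * 3600, by = 600)
  const <- lapply(times, function(t) array(0.7, g$dims))
  em <- exposure_metrics(times, const)
  expect_equal(max(abs(em$icmax - 0.7)), 0)
  expect_equal(em$icauc[1, 1, 1], 0.7 * 10 * 3600, tolerance = 1e-12)
  tau <- 3600
  decay <- lapply(times, function(t) array(exp(-t / tau), g$dims))
  em2 <- exposure_metrics(times, decay)
  # trapezoidal integral of e^{-t/tau} over [0, 10 tau] ~ tau
  expect_equal(em2$icauc[1, 1, 1], tau, tolerance = 0.01)
  expect_error(exposure_metrics(numeric(0), list()), "empty")
  # general bound on any trajectory
  set.seed(3)
  rnd <- lapply(times, function(t) array(runif(16), g$dims))
  em3 <- exposure_metrics(times, rnd)
  expect_true(all(em3$icauc <= em3$icmax * max(times) + 1e-9))
})

test_that("Peclet unit length: sentinel, linear scaling, heavy-drug shrink", {
  p <- default_parameters()
  g <- continuum_grid(c(8, 8, 1), 30)
  u0 <- list(ux = array(0, c(9, 8, 1)), uy = array(0, c(8, 9, 1)),
             uz = array(0, c(8, 8, 2)))
  L0 <- peclet_unit_length(g, u0, p$drug$D_s)
  expect_true(all(is.infinite(L0)))
  u1 <- list(ux = array(0.1, c(9, 8, 1)), uy = array(0, c(8, 9, 1)),
             uz = array(0, c(8, 8, 2)))
  u1$ux[c(1, 9), , ] <- 0.1
  L1 <- peclet_unit_length(g, u1, p$drug$D_s)
  L2 <- peclet_unit_length(g, u1, 2 * p$drug$D_s)
  expect_equal(L2, 2 * L1, tolerance = 1e-12)
  # heavy particles (case i): D scales by (m/m0)^(-1/3), so does L
  ph <- case_variation(p, "i")
  f <- p$drug$mol_mass_ratio_heavy^(-1 / 3)
  expect_equal(ph$drug$D_s, p$drug$D_s * f)
  Lh <- peclet_unit_length(g, u1, ph$drug$D_s)
  expect_equal(Lh, L1 * f, tolerance = 1e-12)
})

test_that("convection-off retains more late drug in the tumor periphery", {
  p <- test_params()
  fx <- frozen_fixture()
  iff <- frozen_iff()
  run <- function(conv) {
    ds <- drug_state(fx$net, fx$state, fx$grid, iff, p)
    simulate_drug(ds, p, T_obs = 12 * 3600, schedule = "bolus",
                  convection = conv, dt_max = 20)
  }
  on <- run(TRUE)
  off <- run(FALSE)
  peri <- fx$state$theta > -150 & fx$state$theta < 0
  s_on <- mean(on$state$phi_f * on$state$s1 + on$state$phi_c * on$state$s2)
  peri_on <- mean((on$state$phi_f * on$state$s1 +
                   on$state$phi_c * on$state$s2)[peri])
  peri_off <- mean((off$state$phi_f * off$state$s1 +
                    off$state$phi_c * off$state$s2)[peri])
  expect_gt(peri_off, peri_on)
  assign("drug_on", on, envir = .tp_cache)
})

test_that("early concentrations fall off exponentially with vessel distance", {
  p <- test_params()
  fx <- single_vessel_fixture()
  iff <- assemble_and_solve_ifp(fx$net, fx$state, fx$grid, p, seed = 3)
  ds <- drug_state(fx$net, fx$state, fx$grid, iff, p)
  res <- simulate_drug(ds, p, T_obs = 2 * 3600, schedule = "bolus")
  st <- res$state
  sbar <- st$phi_f * st$s1 + st$phi_c * st$s2
  phiv <- vessel_volume_fraction(fx$net, fx$grid)
  prof <- distance_to_vessel_profile(fx$grid, sbar, phiv, threshold = 0.001,
                                     bin_width = 30)
  expect_true(prof$fit$ok)
  expect_gt(prof$fit$l, 10)
  expect_lt(prof$fit$l, 500)
})
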