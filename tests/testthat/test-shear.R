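ff <- default_forcefield()

test_that("a single swap exchanges the extremal x velocities exactly", {
  set.seed(1)
  n <- 400
  L <- 10
  sys <- raw_system(matrix(runif(3 * n, 0, L), ncol = 3),
                    matrix(rnorm(3 * n), ncol = 3),
                    rep(5L, n), box = L)
  proto <- shear_protocol(1, n_slabs = 10)
  p0 <- colSums(sys$vel)
  ke0 <- sum(sys$vel^2) / 2
  out <- swap_momenta(sys, proto)
  expect_identical(colSums(out$system$vel), p0)        # exact conservation
  expect_identical(sum(out$system$vel^2) / 2, ke0)
  expect_equal(out$ledger$count, 1L)
  # ledger grew by |vmax_top - vmin_bottom|
  slabw <- L / 10
  isl <- pmin(floor(sys$pos[, 3] / slabw) + 1L, 10L)
  expected <- max(sys$vel[isl == 10, 1]) - min(sys$vel[isl == 1, 1])
  expect_equal(out$ledger$px, abs(expected))
})

test_that("constructed extremal velocities transfer the documented momentum", {
  pos <- rbind(c(1, 1, 0.1), c(1, 1, 9.9), c(5, 5, 5))
  sys <- raw_system(pos, vel = rbind(c(-2, 0, 0), c(3, 0, 0), c(1, 0, 0)),
                    box = 10)
  out <- swap_momenta(sys, shear_protocol(1, n_slabs = 10))
  expect_equal(out$ledger$px, 5)  # |3 - (-2)|
  expect_equal(out$system$vel[1, 1], 3)
  expect_equal(out$system$vel[2, 1], -2)
})

test_that("an empty driven slab skips the swap with a warning", {
  pos <- rbind(c(1, 1, 5), c(2, 2, 5))   # nothing in the driven slabs
  sys <- raw_system(pos, vel = rbind(c(1, 0, 0), c(-1, 0, 0)), box = 10)
  expect_warning(out <- swap_momenta(sys, shear_protocol(1, n_slabs = 10)),
                 "skipped")
  expect_equal(out$ledger$count, 0L)
  expect_equal(out$ledger$skipped, 1L)
  expect_identical(out$system$vel, sys$vel)
})

test_that("momentum flux follows Px / (2 t Lx Ly)", {
  expect_equal(momentum_flux(18, elapsed = 1, Lx = 30), 0.01)
  expect_equal(momentum_flux(0, elapsed = 1, Lx = 30), 0)
  expect_equal(momentum_flux(18, elapsed = 1, Lx = 60, Ly = 30),
               momentum_flux(18, elapsed = 1, Lx = 30) / 2)
  expect_error(momentum_flux(18, elapsed = 0, Lx = 30), "positive")
  lg <- new_swap_ledger(px = 18, count = 3L, elapsed = 2)
  expect_equal(momentum_flux(lg, Lx = 30), 0.005)
})

test_that("velocity profiles recover constructed linear flows", {
  set.seed(2)
  L <- 20
  n <- 8000
  pos <- matrix(runif(3 * n, 0, L), ncol = 3)
  vel <- matrix(0, n, 3)
  vel[, 1] <- 0.073 * (pos[, 3] - L / 2)
  sys <- raw_system(pos, vel, box = L)
  prof <- velocity_profile(sys, n_slabs = 20)
  expect_equal(sum(prof$n), n)
  fit <- shear_rate(prof)
  expect_equal(fit$gamma_dot, 0.073, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999)
  # flat flow gives a flat zero profile
  sys0 <- raw_system(pos, matrix(0, n, 3), box = L)
  prof0 <- velocity_profile(sys0, n_slabs = 10)
  expect_equal(prof0$mean_vx, rep(0, 10))
  # tidy/glance expose the fit
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(glance(fit)$gamma_dot, 0.073, tolerance = 1e-3)
})

test_that("shear_rate needs at least three interior slabs", {
  prof <- tibble::tibble(slab = 1:4, z = 1:4, mean_vx = c(0, 1, 2, 3),
                         n = rep(5, 4))
  expect_error(shear_rate(prof), "interior slabs")
})

test_that("swaps during a run conserve momentum and drive a gradient", {
  st <- build_system(system_spec(8, n_lipids = 0, seed = 21))
  p0 <- colSums(st$system$vel)
  proto <- shear_protocol(3, n_slabs = 16)
  warm <- run_dpd(st$system, NULL, ff, n_steps = 2000, shear = proto,
                  energy_every = 0, engine_seed = 21)
  meas <- run_dpd(warm$system, NULL, ff, n_steps = 3000, shear = proto,
                  energy_every = 0, profile_every = 2, engine_seed = 22)
  expect_lt(max(abs(colSums(meas$system$vel) - p0)), 1e-8)
  expect_gt(meas$ledger$count, 0)
  expect_gt(meas$ledger$px, 0)
  fit <- shear_rate(meas$profile)
  expect_gt(fit$gamma_dot, 0)
  # flux-gradient consistency: effective viscosity is positive and finite
  eta <- momentum_flux(meas$ledger, Lx = 8) / fit$gamma_dot
  expect_gt(eta, 0)
  expect_lt(eta, 10)
})

test_that("the midplane geometry drives opposite gradients in the two halves", {
  st <- build_system(system_spec(8, n_lipids = 0, seed = 31))
  proto <- shear_protocol(3, n_slabs = 16, geometry = "midplane")
  warm <- run_dpd(st$system, NULL, ff, n_steps = 2000, shear = proto,
                  energy_every = 0, engine_seed = 31)
  meas <- run_dpd(warm$system, NULL, ff, n_steps = 3000, shear = proto,
                  energy_every = 0, profile_every = 2, engine_seed = 32)
  prof <- meas$profile
  lo <- prof[prof$slab %in% 2:8, ]
  hi <- prof[prof$slab %in% 10:16, ]
  s1 <- coef(lm(mean_vx ~ z, lo))[["z"]]
  s2 <- coef(lm(mean_vx ~ z, hi))[["z"]]
  expect_lt(s1 * s2, 0)
})
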