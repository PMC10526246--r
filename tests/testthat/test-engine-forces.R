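ff <- default_forcefield()

test_that("weight function is linear inside the cut-off and zero beyond", {
  expect_equal(weight_function(0, 1), 1)
  expect_equal(weight_function(1, 1), 0)
  expect_equal(weight_function(0.5, 1), 0.5)
  expect_equal(weight_function(2.5, 2), 0)
  expect_error(weight_function(-1))
})

test_that("conservative pair force has magnitude a_ij w(r) along the axis", {
  sys <- raw_system(rbind(c(1, 1, 1), c(1.5, 1, 1)), box = 5,
                    species = c(5L, 5L))
  f <- dpd_forces(sys, NULL, ff, dissipative = FALSE, random = FALSE)
  expect_equal(f$forces[1, ], c(-12.5, 0, 0))  # 25 * (1 - 0.5), repulsive
  expect_equal(f$forces[2, ], c(12.5, 0, 0))
  expect_equal(f$pe_pair, 0.5 * 25 * 0.5^2)
  # beyond the cut-off every term vanishes
  sys2 <- raw_system(rbind(c(1, 1, 1), c(2.2, 1, 1)), box = 5)
  f2 <- dpd_forces(sys2, NULL, ff)
  expect_equal(max(abs(f2$forces)), 0)
  expect_equal(f2$pe_pair, 0)
})

test_that("dissipative term vanishes at zero relative velocity and damps motion", {
  sys <- raw_system(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                    vel = rbind(c(0.3, 0, 0), c(0.3, 0, 0)), box = 5)
  f <- dpd_forces(sys, NULL, ff, conservative = FALSE, random = FALSE)
  expect_equal(max(abs(f$forces)), 0)
  sys2 <- raw_system(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                     vel = rbind(c(0.4, 0, 0), c(-0.4, 0, 0)), box = 5)
  f2 <- dpd_forces(sys2, NULL, ff, conservative = FALSE, random = FALSE)
  # -gamma w^2 (v_ij . e) = -4.5 * 0.25 * 0.8 opposing the approach... separation
  expect_equal(f2$forces[1, 1], -4.5 * 0.25 * 0.8)
  expect_equal(f2$forces[1, ] + f2$forces[2, ], c(0, 0, 0))
})

test_that("deterministic pair terms match an R brute-force oracle", {
  sys <- random_fluid(80, L = 5, seed = 11)
  got <- dpd_forces(sys, NULL, ff, random = FALSE)
  ref <- brute_pair_forces_R(sys, ff)
  expect_lt(max(abs(got$forces - ref$forces)), 1e-10)
  expect_equal(got$pe_pair, ref$pe_pair, tolerance = 1e-12)
})

test_that("cell-list and all-pairs paths agree including the random term", {
  for (seed in 1:3) {
    sys <- random_fluid(150, L = 6, seed = seed)
    a <- dpd_forces(sys, NULL, ff, engine_seed = 5, step = seed)
    b <- dpd_forces(sys, NULL, ff, engine_seed = 5, step = seed, brute = TRUE)
    expect_lt(max(abs(a$forces - b$forces)), 1e-10)
    # Newton's third law holds over the whole system
    expect_lt(max(abs(colSums(a$forces))), 1e-9)
  }
})

test_that("bond force is harmonic about rs", {
  topo <- dpdshear:::new_dpd_topology(
    tibble::tibble(chain = 1L, type = 1L, first = 1L, nh = 1L, nt = 1L,
                   length = 2L),
    matrix(c(1L, 2L), 1, 2), matrix(integer(0), 0, 3), 2L)
  at <- function(r) {
    sys <- raw_system(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box = 8,
                      species = c(1L, 2L))
    dpd_forces(sys, topo, ff, conservative = FALSE, dissipative = FALSE,
               random = FALSE)
  }
  expect_equal(max(abs(at(0.7)$forces)), 0)       # equilibrium
  expect_equal(at(0.35)$forces[1, 1], -60)        # 120*(1-0.5), pushed apart
  expect_equal(at(1.4)$forces[1, 1], 120)         # pulled together
  expect_equal(at(1.4)$forces[2, 1], -120)
})

test_that("angle forces are the exact gradient of ktheta (theta - theta0)^2", {
  topo <- dpdshear:::new_dpd_topology(
    tibble::tibble(chain = 1L, type = 1L, first = 1L, nh = 1L, nt = 2L,
                   length = 3L),
    matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE),
    matrix(c(1L, 2L, 3L), 1, 3), 3L)
  angle_only <- function(pos) {
    sys <- raw_system(pos, box = 20, species = c(1L, 1L, 2L))
    ffb <- default_forcefield(ks = 0)  # isolate the bending term
    dpd_forces(sys, topo, ffb, conservative = FALSE, dissipative = FALSE,
               random = FALSE)
  }
  straight <- angle_only(rbind(c(5, 5, 5), c(5.7, 5, 5), c(6.4, 5, 5)))
  expect_lt(max(abs(straight$forces)), 1e-8)
  expect_equal(straight$pe_angle, 0, tolerance = 1e-12)
  bent <- angle_only(rbind(c(5, 5.7, 5), c(5, 5, 5), c(5.7, 5, 5)))
  expect_equal(bent$pe_angle, 6 * (pi / 2)^2, tolerance = 1e-10)
  # finite-difference oracle on a random triple
  set.seed(4)
  pos <- matrix(5 + rnorm(9, sd = 0.5), 3, 3)
  f <- angle_only(pos)$forces
  h <- 1e-6
  for (b in 1:3) {
    for (d in 1:3) {
      pp <- pos; pp[b, d] <- pp[b, d] + h
      pm <- pos; pm[b, d] <- pm[b, d] - h
      grad <- (angle_only(pp)$pe_angle - angle_only(pm)$pe_angle) / (2 * h)
      expect_equal(f[b, d], -grad, tolerance = 1e-5)
    }
  }
  # translation invariance: forces sum to zero; and zero net torque
  expect_lt(max(abs(colSums(f))), 1e-10)
  tq <- colSums(t(vapply(1:3, function(b) {
    c(pos[b, 2] * f[b, 3] - pos[b, 3] * f[b, 2],
      pos[b, 3] * f[b, 1] - pos[b, 1] * f[b, 3],
      pos[b, 1] * f[b, 2] - pos[b, 2] * f[b, 1])
  }, numeric(3))))
  expect_lt(max(abs(tq)), 1e-9)
})

test_that("random force variance scales as 1/dt and noise is variance-matched", {
  sys <- raw_system(rbind(c(1, 1, 1), c(1.5, 1, 1)), box = 5)
  sample_force <- function(dt, gaussian = FALSE, n = 4000) {
    ffd <- default_forcefield(dt = dt)
    vapply(seq_len(n), function(s) {
      dpd_forces(sys, NULL, ffd, engine_seed = 77, step = s,
                 conservative = FALSE, dissipative = FALSE,
                 gaussian_noise = gaussian)$forces[1, 1]
    }, numeric(1))
  }
  f1 <- sample_force(0.01)
  f2 <- sample_force(0.04)
  # var = sigma^2 w^2 / dt = 9 * 0.25 / dt
  expect_equal(var(f1), 9 * 0.25 / 0.01, tolerance = 0.1)
  expect_equal(var(f1) / var(f2), 4, tolerance = 0.15)
  expect_equal(mean(f1), 0, tolerance = 0.5)
  fg <- sample_force(0.01, gaussian = TRUE)
  expect_equal(var(fg), 9 * 0.25 / 0.01, tolerance = 0.1)
})

test_that("non-finite states are rejected with a diagnostic", {
  sys <- raw_system(rbind(c(1, 1, 1), c(NaN, 1, 1)), box = 5)
  expect_error(dpd_forces(sys, NULL, ff), "non-finite")
})
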