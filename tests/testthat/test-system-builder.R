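test_that("bead counts follow density * volume and the chain arithmetic", {
  ff <- default_forcefield()
  spec <- system_spec(30, n_lipids = 2400,
                      lipid_I = lipid_spec("H1", "T1", 3, 2),
                      lipid_II = lipid_spec("H2", "T2", 3, 4), seed = 7)
  st <- build_system(spec, ff)
  expect_equal(nrow(st$system$pos), 81000)  # 3 * 30^3
  tab <- table(factor(dpdshear:::.species_levels[st$system$species],
                      levels = dpdshear:::.species_levels))
  expect_equal(unname(tab[["H1"]] + tab[["T1"]]), 1200 * 5)
  expect_equal(unname(tab[["H2"]] + tab[["T2"]]), 1200 * 7)
  expect_equal(unname(tab[["W"]]), 81000 - 14400)
  expect_equal(sum(tab), 81000)  # conservation
})

test_that("building is deterministic for a fixed seed", {
  spec <- dilute_pair_spec(box = 8, seed = 42)
  a <- build_system(spec)
  b <- build_system(spec)
  expect_identical(a$system$pos, b$system$pos)
  expect_identical(a$system$vel, b$system$vel)
  spec2 <- dilute_pair_spec(box = 8, seed = 43)
  expect_false(identical(build_system(spec2)$system$pos, a$system$pos))
})

test_that("initial velocities are thermal with zero net momentum", {
  st <- build_system(system_spec(10, n_lipids = 0, seed = 3))
  sys <- st$system
  expect_gte(nrow(sys$vel), 3000)
  expect_lt(abs(compute_temperature(sys) - 1), 0.05)
  expect_lt(max(abs(colSums(sys$vel))), 1e-9)
  expect_true(all(abs(apply(sys$vel, 2, var) - 1) < 0.1))
})

test_that("topology has the right bond/angle structure", {
  ff <- default_forcefield()
  spec <- dilute_pair_spec(box = 10, nt1 = 2, nt2 = 5, seed = 5)
  st <- build_system(spec, ff)
  topo <- st$topology
  ch <- topo$chains
  expect_equal(nrow(topo$bonds), sum(ch$length - 1L))
  expect_equal(nrow(topo$angles), sum(pmax(ch$length - 2L, 0L)))
  # no bond crosses chains: both ends inside the same chain's index run
  owner <- integer(topo$n_beads)
  for (k in seq_len(nrow(ch))) {
    owner[seq(ch$first[k], length.out = ch$length[k])] <- k
  }
  expect_true(all(owner[topo$bonds[, 1]] == owner[topo$bonds[, 2]]))
  expect_true(all(owner[topo$bonds[, 1]] > 0))  # no water in bonds
  # bonds start near their equilibrium length
  d <- st$system$pos[topo$bonds[, 1], ] - st$system$pos[topo$bonds[, 2], ]
  d <- min_image(d, spec$box_length)
  expect_lt(max(sqrt(rowSums(d^2))), 1.5 * ff$rs)
})

test_that("junction-spanning angles can be switched off", {
  spec <- dilute_pair_spec(box = 10, nt1 = 4, nt2 = 4, seed = 1)
  with_j <- build_system(spec, angles_span_junction = TRUE)$topology
  without <- build_system(spec, angles_span_junction = FALSE)$topology
  n <- spec$n_lipids
  # nh = 3, nt = 4: full chain has 5 triples; 2 of them straddle the junction
  expect_equal(nrow(with_j$angles), n * 5L)
  expect_equal(nrow(without$angles), n * 3L)
})

test_that("infeasible systems are rejected", {
  expect_error(build_system(system_spec(3, n_lipids = 50, seed = 1)),
               "exceed")
  expect_error(build_system(system_spec(1.5, n_lipids = 0, seed = 1)),
               "box_length")
})

test_that("concentration is chains per volume", {
  expect_equal(concentration(system_spec(30, n_lipids = 1200, seed = 1)),
               1200 / 27000)
  expect_equal(concentration(system_spec(30, n_lipids = 2400, seed = 1)),
               2400 / 27000, tolerance = 1e-12)
  expect_equal(concentration(system_spec(30, n_lipids = 0, seed = 1)), 0)
  expect_equal(n_lipids_for_phi(1200 / 27000, 30), 1200L)
})

test_that("fixture geometries have their defining features", {
  # membrane area density ~1.3 chains per rc^2 per leaflet keeps the leaflet
  # contact graph connected
  spec <- system_spec(12, n_lipids = 2L * round(1.33 * 144),
                      lipid_I = lipid_spec("H1", "T1", 3, 4),
                      lipid_II = lipid_spec("H2", "T2", 3, 4), seed = 9)
  bil <- make_fixture("flat_bilayer", spec)
  prof <- density_profile(bil$system, axis = "z", n_bins = 32)
  peak_at <- function(sp) {
    p <- prof[prof$species == sp, ]
    p$pos[which.max(p$density)]
  }
  # tails peak between the two head layers
  expect_gt(peak_at("H1"), peak_at("T1"))
  expect_lt(peak_at("H2"), peak_at("T2"))
  expect_true(peak_at("T1") >= peak_at("T2"))

  perf <- make_fixture("perforated_bilayer", spec, hole_radius = 3)
  m <- density_map_2d(perf$system, plane = "xy", n_bins = 12)
  expect_gt(dpdshear:::largest_empty_patch(m$count, 12), 3)
  m0 <- density_map_2d(bil$system, plane = "xy", n_bins = 12)
  expect_lt(dpdshear:::largest_empty_patch(m0$count, 12),
            dpdshear:::largest_empty_patch(m$count, 12))

  vspec <- system_spec(18, n_lipids = 200,
                       lipid_I = lipid_spec("H1", "T1", 3, 4),
                       lipid_II = lipid_spec("H2", "T2", 3, 4), seed = 9)
  ves <- make_fixture("vesicle_shell", vspec, bead_spacing = 0.35)
  ctr <- vspec$box_length / 2
  wat <- ves$system$pos[dpdshear:::.species_levels[ves$system$species] == "W", ]
  r <- sqrt(rowSums(sweep(wat, 2, ctr)^2))
  expect_gt(sum(r < 1.8), 0)  # water strictly inside the shell core
})

test_that("multi-seed selection picks the lowest-energy candidate", {
  spec <- system_spec(6, n_lipids = 6,
                      lipid_I = lipid_spec("H1", "T1", 3, 2),
                      lipid_II = lipid_spec("H2", "T2", 3, 2), seed = 1)
  sel <- select_initial_state(spec, seeds = 1:2, n_steps = 50)
  expect_equal(sel$seed, sel$energies$seed[which.min(sel$energies$total)])
  expect_s3_class(sel$state$system, "dpd_system")
})
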