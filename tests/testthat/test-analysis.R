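ff <- default_forcefield()

test_that("density profiles integrate exactly to per-species bead counts", {
  st <- build_system(dilute_pair_spec(box = 8, seed = 14))
  sys <- st$system
  prof <- density_profile(sys, axis = "z", n_bins = 16)
  bw <- attr(prof, "bin_width")
  counts <- tapply(prof$count, prof$species, sum)
  truth <- table(factor(dpdshear:::.species_levels[sys$species],
                        levels = dpdshear:::.species_levels))
  for (sp in names(truth)) {
    expect_equal(unname(counts[[sp]]), unname(truth[[sp]]))
    p <- prof[prof$species == sp, ]
    expect_equal(sum(p$density) * bw * sys$box^2, unname(truth[[sp]]))
  }
  # uniform water sits near the bulk density in every bin
  wat <- density_profile(build_system(system_spec(10, n_lipids = 0,
                                                  seed = 2))$system,
                         n_bins = 10, species = "W")
  expect_true(all(abs(wat$density - 3) < 3 * sqrt(3 / (10 * 100)) * 3))
  # an absent species yields an all-zero profile
  none <- density_profile(build_system(system_spec(6, n_lipids = 0,
                                                   seed = 1))$system,
                          species = "H1")
  expect_equal(sum(none$density), 0)
})

test_that("2D occupancy maps are near-uniform for bulk water", {
  sys <- build_system(system_spec(10, n_lipids = 0, seed = 5))$system
  m <- density_map_2d(sys, plane = "xy", n_bins = 5, species = "W")
  expect_equal(sum(m$count), nrow(sys$pos))
  expect_lt(max(abs(m$count - mean(m$count))) / mean(m$count), 0.5)
  expect_equal(dpdshear:::largest_empty_patch(m$count, 5), 0)
})

test_that("gyration tensor matches the double-sum form and hand cases", {
  expect_equal(gyration_tensor(matrix(c(1, 2, 3), 1, 3))$eigenvalues,
               c(0, 0, 0))
  two <- gyration_tensor(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(two$tensor[1, 1], 1)  # d^2/4 with d = 2
  expect_equal(sum(abs(two$tensor)) - two$tensor[1, 1], 0)
  set.seed(9)
  for (k in 1:5) {
    pos <- matrix(rnorm(3 * 12), 12, 3)
    g <- gyration_tensor(pos)
    expect_lt(max(abs(g$tensor - gyration_double_sum(pos))), 1e-12)
  }
})

test_that("shape factor hits its limiting values and stays in [0, 1]", {
  expect_equal(shape_factor(c(1, 1, 1)), 0)    # sphere
  expect_equal(shape_factor(c(1, 0, 0)), 1)    # rod
  expect_equal(shape_factor(c(0, 0, 0)), 0)    # degenerate, by convention
  # a thin uniform ring in a plane evaluates to 1/4
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ring <- cbind(cos(th), sin(th), 0)
  expect_equal(shape_factor(gyration_tensor(ring)), 0.25, tolerance = 1e-6)
  set.seed(3)
  for (k in 1:20) {
    ev <- sort(abs(rnorm(3)), decreasing = TRUE)
    d <- shape_factor(ev)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("shape factor is invariant under rigid rotation and translation", {
  set.seed(6)
  pos <- matrix(rnorm(3 * 9), 9, 3)
  d0 <- shape_factor(gyration_tensor(pos))
  for (k in 1:10) {
    r <- random_rotation()
    moved <- pos %*% t(r) + matrix(rnorm(3), 9, 3, byrow = TRUE)
    expect_equal(shape_factor(gyration_tensor(moved)), d0, tolerance = 1e-10)
  }
})

test_that("chain unwrapping restores bonded contiguity across the boundary", {
  L <- 10
  pos <- rbind(c(9.6, 5, 5), c(0.3, 5, 5), c(1.0, 5, 5))
  u <- unwrap_chain(pos, L)
  expect_equal(diff(u[, 1]), c(0.7, 0.7))
  # straight chains through the boundary still read as rods
  expect_equal(shape_factor(gyration_tensor(u)), 1)
})

test_that("per-chain shape factors label chains by species", {
  spec <- dilute_pair_spec(box = 8, seed = 4)
  st <- build_system(spec, ff)
  sf <- chain_shape_factors(st$system, st$topology)
  expect_equal(nrow(sf), spec$n_lipids)
  expect_true(all(sf$delta >= 0 & sf$delta <= 1))
  ser <- mean_shape_factor(list(st$system), st$topology)
  expect_equal(nrow(ser), 2)
  # perfectly straight chains give a constant series of 1
  topo <- dpdshear:::build_topology(2L, 0L, lipid_spec("H1", "T1", 2, 2),
                                    lipid_spec("H2", "T2", 2, 2), 8L)
  pos <- rbind(cbind(1:4 * 0.5, 1, 1), cbind(1:4 * 0.5, 3, 3))
  sys <- raw_system(pos, box = 10, species = rep(c(1L, 1L, 2L, 2L), 2))
  ser1 <- mean_shape_factor(list(sys), topo)
  expect_equal(ser1$mean_delta, 1)
})

test_that("stable_mean averages the trailing window, weighted by chains", {
  ser <- tibble::tibble(time = rep(c(10, 20, 30), each = 2),
                        type = rep(1:2, 3),
                        mean_delta = c(0.5, 0.4, 0.8, 0.7, 0.9, 0.8),
                        n_chains = rep(c(10, 20), 3))
  class(ser) <- c("dpd_shape_series", class(ser))
  sm <- stable_mean(ser, fraction = 1 / 3)
  expect_equal(sm$mean_delta[sm$type == 1], 0.9)
  expect_equal(sm$mean_delta[sm$type == 2], 0.8)
  pooled <- stable_mean(ser, fraction = 1 / 3, by_type = FALSE)
  expect_equal(pooled$mean_delta, (0.9 * 10 + 0.8 * 20) / 30)
})

test_that("mixing counts respond exactly to constructed head translocations", {
  spec <- system_spec(16, n_lipids = 80,
                      lipid_I = lipid_spec("H1", "T1", 3, 3),
                      lipid_II = lipid_spec("H2", "T2", 3, 3), seed = 2)
  bil <- make_fixture("flat_bilayer", spec)
  m0 <- mixing_counts(bil$system, bil$topology)
  expect_equal(m0$n_typeI_right, 40)
  expect_equal(m0$n_typeII_left, 40)
  expect_equal(m0$normal, "z")
  # move k type-I head beads across the midplane
  k <- 7
  sys <- bil$system
  ch <- bil$topology$chains
  movers <- ch$first[ch$type == 1L][1:k]
  sys$pos[movers, 3] <- m0$midplane - 1
  m1 <- mixing_counts(sys, bil$topology)
  expect_equal(m1$n_typeI_right, 40 - k)
  expect_equal(m1$n_typeII_left, 40)
  # mirror through the midplane: counts swap symmetrically
  mir <- bil$system
  mir$pos[, 3] <- (2 * m0$midplane - mir$pos[, 3]) %% mir$box
  m2 <- mixing_counts(mir, bil$topology)
  expect_equal(m2$n_typeI_right, 0)
  expect_equal(m2$n_typeII_left, 0)
  # complements: right + left = totals each frame
  expect_equal(m0$n_typeI, 40)
  expect_equal(m0$n_typeII, 40)
})

test_that("clustering matches a brute-force minimum-image oracle", {
  set.seed(13)
  for (k in 1:3) {
    n <- 120
    L <- 6
    # clumpy point set: several gaussian blobs, some crossing the boundary
    ctrs <- matrix(runif(3 * 6, 0, L), ncol = 3)
    pos <- (ctrs[sample(6, n, TRUE), ] + matrix(rnorm(3 * n, 0, 0.4),
                                                ncol = 3)) %% L
    sys <- raw_system(pos, box = L)
    got <- cluster_beads(sys, subset = seq_len(n), cutoff = 0.8)
    ref <- brute_clusters_R(pos, L, 0.8)
    expect_equal(relabel_by_first_occurrence(got$labels),
                 relabel_by_first_occurrence(unname(ref)))
  }
})

test_that("clusters report periodic spanning and separation correctly", {
  L <- 10
  # a line of beads threading the box along x spans x only
  line <- cbind(seq(0, L - 0.5, by = 0.5), 5, 5)
  got <- cluster_beads(raw_system(line, box = L), subset = seq_len(nrow(line)),
                       cutoff = 0.6)
  expect_equal(nrow(got$clusters), 1)
  expect_true(got$clusters$spans_x[1])
  expect_false(got$clusters$spans_y[1])
  expect_false(got$clusters$spans_z[1])
  # two distant blobs are two clusters; one straddling the boundary is one
  two <- rbind(cbind(1 + runif(10, 0, 0.5), 1, 1),
               cbind(6 + runif(10, 0, 0.5), 6, 6))
  g2 <- cluster_beads(raw_system(two, box = L), subset = 1:20, cutoff = 1)
  expect_equal(nrow(g2$clusters), 2)
  straddle <- cbind(c(9.7, 9.95, 0.2, 0.45), 2, 2)
  g3 <- cluster_beads(raw_system(straddle, box = L), subset = 1:4, cutoff = 0.5)
  expect_equal(nrow(g3$clusters), 1)
  expect_false(g3$clusters$spans_x[1])
})

test_that("the classifier is deterministic and permutation-invariant", {
  spec <- system_spec(14, n_lipids = 120,
                      lipid_I = lipid_spec("H1", "T1", 3, 4),
                      lipid_II = lipid_spec("H2", "T2", 3, 4), seed = 8)
  mic <- make_fixture("spherical_micelle", spec)
  lab1 <- classify_phase(mic$system, mic$topology)$label
  expect_equal(lab1, "micelle")
  # shuffle bead order (species travel with their beads)
  set.seed(1)
  perm <- sample(nrow(mic$system$pos))
  shuffled <- dpdshear:::new_dpd_system(mic$system$pos[perm, ],
                                        mic$system$vel[perm, ],
                                        mic$system$species[perm],
                                        mic$system$box, 0)
  expect_equal(classify_phase(shuffled)$label, lab1)
})

test_that("stage segmentation finds constructed changepoints", {
  set.seed(10)
  t1 <- seq(0, 800, by = 4)
  t2 <- seq(804, 1800, by = 4)
  t3 <- seq(1804, 3000, by = 4)
  e <- c(5000 - 3 * t1, 2600 - 0.35 * (t2 - 800),
         rep(2250, length(t3))) + rnorm(length(t1) + length(t2) + length(t3), 0, 6)
  st <- segment_stages(tibble::tibble(time = c(t1, t2, t3), total = e))
  expect_equal(nrow(st), 3)
  expect_equal(st$label, c("initial", "adjustment", "stable"))
  expect_lt(abs(st$t_end[1] - 800), 120)
  expect_lt(abs(st$t_end[2] - 1800), 160)
  # pure two-segment series yields exactly two stages
  e2 <- c(4000 - 4 * t1, rep(4000 - 4 * 800, length(t2))) +
    rnorm(length(t1) + length(t2), 0, 4)
  st2 <- segment_stages(tibble::tibble(time = c(t1, t2), total = e2))
  expect_equal(nrow(st2), 2)
  expect_lt(abs(st2$t_end[1] - 800), 120)
  # constant series is a single stage
  stc <- segment_stages(tibble::tibble(time = t1, total = rep(100, length(t1))))
  expect_equal(nrow(stc), 1)
})
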