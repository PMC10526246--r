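# shared fixtures and independent oracles

# bare particle system from raw matrices
raw_system <- function(pos, vel = NULL, species = NULL, box, time = 0) {
  pos <- rbind(pos)
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  if (is.null(species)) species <- rep(5L, nrow(pos))  # water
  dpdshear:::new_dpd_system(pos, rbind(vel), species, box, time)
}

random_fluid <- function(n, L, seed = 1, kBT = 1) {
  set.seed(seed)
  raw_system(matrix(runif(3 * n, 0, L), ncol = 3),
             matrix(rnorm(3 * n, 0, sqrt(kBT)), ncol = 3),
             sample.int(5, n, replace = TRUE), box = L)
}

min_image <- function(d, L) d - L * round(d / L)

# O(N^2) reference for the deterministic pair terms (conservative +
# dissipative), independent of the C++ path
brute_pair_forces_R <- function(sys, ff) {
  n <- nrow(sys$pos)
  f <- matrix(0, n, 3)
  pe <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min_image(sys$pos[i, ] - sys$pos[j, ], sys$box)
      r <- sqrt(sum(d^2))
      if (r >= ff$rc || r < 1e-12) next
      e <- d / r
      w <- 1 - r / ff$rc
      a <- ff$aij[sys$species[i], sys$species[j]]
      vr <- sum((sys$vel[i, ] - sys$vel[j, ]) * e)
      fm <- a * w - ff$gamma * w^2 * vr
      f[i, ] <- f[i, ] + fm * e
      f[j, ] <- f[j, ] - fm * e
      pe <- pe + 0.5 * a * ff$rc * w^2
    }
  }
  list(forces = f, pe_pair = pe)
}

# double-sum form of the gyration tensor:
# G_ab = 1/(2 N^2) sum_i sum_j (r_ia - r_ja)(r_ib - r_jb)
gyration_double_sum <- function(pos) {
  n <- nrow(pos)
  g <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- pos[i, ] - pos[j, ]
      g <- g + outer(d, d)
    }
  }
  g / (2 * n^2)
}

# igraph-based connected components under minimum-image distances
brute_clusters_R <- function(pos, L, cutoff) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min_image(pos[i, ] - pos[j, ], L)
      if (sum(d^2) <= cutoff^2) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# canonicalise cluster labelings for comparison
relabel_by_first_occurrence <- function(labels) {
  match(labels, unique(labels))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

dilute_pair_spec <- function(box = 12, nt1 = 6, nt2 = 8, seed = 1) {
  system_spec(box, n_lipids = n_lipids_for_phi(1200 / 27000, box),
              lipid_I = lipid_spec("H1", "T1", 3, nt1),
              lipid_II = lipid_spec("H2", "T2", 3, nt2), seed = seed)
}
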