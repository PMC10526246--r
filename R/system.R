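#' System specification for a two-species lipid solution
#'
#' Declares everything needed to build a seeded initial configuration: a
#' cubic box of side `box_length` (in rc) filled to bead density `density`
#' (rc^-3) with `n_lipids` amphiphilic chains split between two species, the
#' remainder water.
#'
#' @param box_length Cubic box side L in rc; must exceed `2 * rc`.
#' @param density Bead number density rho in rc^-3 (default 3).
#' @param n_lipids Total number of lipid chains.
#' @param lipid_I,lipid_II [lipid_spec()] for the two species.
#' @param split Fraction of chains that are type I (default 0.5).
#' @param seed Integer seed controlling placement and initial velocities.
#' @return An object of class `dpd_system_spec`.
#' @examples
#' spec <- system_spec(box_length = 12, n_lipids = 76,
#'                     lipid_I = lipid_spec("H1", "T1", 3, 6),
#'                     lipid_II = lipid_spec("H2", "T2", 3, 8), seed = 1)
#' concentration(spec)
#' @export
system_spec <- function(box_length, density = 3, n_lipids = 0,
                        lipid_I = lipid_spec("H1", "T1"),
                        lipid_II = lipid_spec("H2", "T2"),
                        split = 0.5, seed = 1L) {
  stopifnot(box_length > 0, density > 0, n_lipids >= 0,
            split >= 0, split <= 1)
  structure(list(box_length = box_length, density = density,
                 n_lipids = as.integer(n_lipids),
                 lipid_I = lipid_I, lipid_II = lipid_II,
                 split = split, seed = as.integer(seed)),
            class = "dpd_system_spec")
}

#' Lipid chain concentration
#'
#' Ratio of lipid chain count to box volume, `phi = n / L^3`, in rc^-3.
#' The two study conditions are `phi = 1200/27000 = 0.0444` (dilute) and
#' `2400/27000 = 0.0889` (dense); values are reported unrounded.
#'
#' @param spec A [system_spec()].
#' @return `phi` in rc^-3.
#' @export
concentration <- function(spec) {
  stopifnot(inherits(spec, "dpd_system_spec"))
  spec$n_lipids / spec$box_length^3
}

#' Number of lipid chains matching a target concentration
#'
#' Rounds `phi * L^3` to the nearest even integer so the two species can be
#' split equally.
#'
#' @param phi Target chain concentration in rc^-3.
#' @param box_length Box side in rc.
#' @return Even integer chain count.
#' @export
n_lipids_for_phi <- function(phi, box_length) {
  2L * as.integer(round(phi * box_length^3 / 2))
}

new_dpd_system <- function(pos, vel, species, box, time = 0) {
  structure(list(pos = pos, vel = vel, species = as.integer(species),
                 box = box, time = time),
            class = "dpd_system")
}

#' @export
print.dpd_system <- function(x, ...) {
  tab <- table(factor(.species_levels[x$species], levels = .species_levels))
  cat(sprintf("<dpd_system> %d beads in %g^3 box at t = %g tau\n",
              nrow(x$pos), x$box, x$time))
  print(tab)
  invisible(x)
}

#' @export
as_tibble.dpd_system <- function(x, ...) {
  tibble(bead = seq_len(nrow(x$pos)),
         species = .species_levels[x$species],
         x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
         vx = x$vel[, 1], vy = x$vel[, 2], vz = x$vel[, 3])
}

new_dpd_topology <- function(chains, bonds, angles, n_beads) {
  structure(list(chains = chains, bonds = bonds, angles = angles,
                 n_beads = as.integer(n_beads)),
            class = "dpd_topology")
}

#' @export
print.dpd_topology <- function(x, ...) {
  cat(sprintf("<dpd_topology> %d chains, %d bonds, %d angles over %d beads\n",
              nrow(x$chains), nrow(x$bonds), nrow(x$angles), x$n_beads))
  invisible(x)
}

# bead indices (1-based) of one chain
chain_indices <- function(topo, chain) {
  with(topo$chains[chain, ], seq(first, length.out = length))
}

# chain topology tables for n1 type-I + n2 type-II chains laid out head-block
# first, starting at bead 1; angles optionally skip triples straddling the
# head-tail junction
build_topology <- function(n1, n2, lipid_I, lipid_II, n_beads,
                           angles_span_junction = TRUE) {
  nlen1 <- lipid_I$nh + lipid_I$nt
  nlen2 <- lipid_II$nh + lipid_II$nt
  first <- c(if (n1 > 0) (seq_len(n1) - 1L) * nlen1 + 1L else integer(0),
             if (n2 > 0) n1 * nlen1 + (seq_len(n2) - 1L) * nlen2 + 1L else integer(0))
  chains <- tibble(
    chain = seq_len(n1 + n2),
    type = rep(c(1L, 2L), c(n1, n2)),
    first = as.integer(first),
    nh = rep(c(lipid_I$nh, lipid_II$nh), c(n1, n2)),
    nt = rep(c(lipid_I$nt, lipid_II$nt), c(n1, n2)),
    length = rep(c(nlen1, nlen2), c(n1, n2)))
  bonds <- do.call(rbind, lapply(seq_len(nrow(chains)), function(k) {
    i <- seq(chains$first[k], length.out = chains$length[k])
    cbind(i[-length(i)], i[-1])
  }))
  angles <- do.call(rbind, lapply(seq_len(nrow(chains)), function(k) {
    len <- chains$length[k]
    if (len < 3) return(NULL)
    i <- seq(chains$first[k], length.out = len)
    tri <- cbind(i[1:(len - 2)], i[2:(len - 1)], i[3:len])
    if (!angles_span_junction) {
      nh <- chains$nh[k]
      # keep triples entirely within the head block or the tail block
      keep <- (tri[, 3] - chains$first[k] + 1L) <= nh |
              (tri[, 1] - chains$first[k] + 1L) > nh
      tri <- tri[keep, , drop = FALSE]
    }
    tri
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(0), 0, 3)
  new_dpd_topology(chains, bonds, angles, n_beads)
}

# near-linear random walk of `len` beads with bond length b, wrapped into the box
random_chain <- function(len, b, L) {
  p <- matrix(0, len, 3)
  p[1, ] <- runif(3, 0, L)
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  for (m in seq_len(len - 1)) {
    dir <- dir + 0.25 * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    p[m + 1, ] <- p[m, ] + b * dir
  }
  p %% L
}

# Maxwell-Boltzmann velocities at kBT with the net momentum removed
mb_velocities <- function(n, kBT) {
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  sweep(v, 2, colMeans(v))
}

#' Build a seeded initial configuration
#'
#' Places `n_lipids` chains as near-linear random walks with bond length
#' `ff$rs`, fills the remaining beads with uniformly random water up to
#' `round(density * L^3)` total, and draws Maxwell-Boltzmann velocities at
#' `kBT` with the net momentum removed. Soft DPD potentials tolerate
#' overlaps, so no overlap rejection is applied (standard DPD practice).
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [system_spec()].
#' @param ff A [default_forcefield()] (supplies `rs` and `kBT`).
#' @param angles_span_junction Place bending triples across the head-tail
#'   junction (default TRUE).
#' @return A list with elements `system` (a `dpd_system`) and `topology`
#'   (a `dpd_topology`).
#' @examples
#' st <- build_system(system_spec(5, n_lipids = 4, seed = 1),
#'                    default_forcefield())
#' st$system
#' @export
build_system <- function(spec, ff = default_forcefield(),
                         angles_span_junction = TRUE) {
  stopifnot(inherits(spec, "dpd_system_spec"))
  L <- spec$box_length
  if (L <= 2 * ff$rc) abort("box_length must exceed 2*rc")
  N <- as.integer(round(spec$density * L^3))
  n1 <- as.integer(round(spec$n_lipids * spec$split))
  n2 <- spec$n_lipids - n1
  nlip <- n1 * (spec$lipid_I$nh + spec$lipid_I$nt) +
          n2 * (spec$lipid_II$nh + spec$lipid_II$nt)
  if (nlip > N) abort(sprintf("lipid beads (%d) exceed total bead count (%d)", nlip, N))
  topo <- build_topology(n1, n2, spec$lipid_I, spec$lipid_II, N,
                         angles_span_junction)
  set.seed(spec$seed)
  pos <- matrix(0, N, 3)
  species <- integer(N)
  for (k in seq_len(nrow(topo$chains))) {
    idx <- chain_indices(topo, k)
    pos[idx, ] <- random_chain(length(idx), ff$rs, L)
    lp <- if (topo$chains$type[k] == 1L) spec$lipid_I else spec$lipid_II
    species[idx] <- c(rep(species_index(lp$species_head), lp$nh),
                      rep(species_index(lp$species_tail), lp$nt))
  }
  if (N > nlip) {
    wat <- seq(nlip + 1L, N)
    pos[wat, ] <- matrix(runif(3 * length(wat), 0, L), ncol = 3)
    species[wat] <- species_index("W")
  }
  vel <- mb_velocities(N, ff$kBT)
  list(system = new_dpd_system(pos, vel, species, L),
       topology = topo)
}

#' Pick the lowest-energy candidate among several seeded starts
#'
#' Builds one configuration per seed, relaxes each for a short burn-in, and
#' returns the candidate with the lowest final total energy, together with
#' the energy table. A light-weight analogue of selecting an initial state
#' by comparing system energies across candidate states.
#'
#' @param spec A [system_spec()]; its `seed` field is overridden per candidate.
#' @param ff Force field.
#' @param seeds Integer vector of candidate seeds.
#' @param n_steps Burn-in steps per candidate.
#' @return List with `state` (the winning `(system, topology)` pair, relaxed),
#'   `seed`, and `energies` (tibble of final energies per seed).
#' @export
select_initial_state <- function(spec, ff = default_forcefield(),
                                 seeds = 1:3, n_steps = 500) {
  runs <- lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    st <- build_system(sp, ff)
    run_dpd(st$system, st$topology, ff, n_steps = n_steps,
            energy_every = n_steps, engine_seed = s)
  })
  etot <- vapply(runs, function(r) tail(r$energy$total, 1), numeric(1))
  best <- which.min(etot)
  list(state = list(system = runs[[best]]$system,
                    topology = runs[[best]]$topology),
       seed = seeds[best],
       energies = tibble(seed = seeds, total = etot))
}

# ---- idealized geometry fixtures -------------------------------------------

# points roughly evenly spread on a sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# uniform water outside a keep-out predicate; deterministic given the RNG state
fill_water <- function(n, L, excluded = NULL) {
  if (n <= 0) return(matrix(0, 0, 3))
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(runif(3 * max(2 * (n - nrow(out)), 64), 0, L), ncol = 3)
    if (!is.null(excluded)) cand <- cand[!excluded(cand), , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Idealized aggregate geometries for analysis tests
#'
#' Deterministic constructions of the five aggregate morphologies the phase
#' classifier distinguishes: a flat bilayer spanning the x-y plane
#' (`flat_bilayer`), the same membrane with a circular pore
#' (`perforated_bilayer`), a spherical micelle with tails buried inside
#' (`spherical_micelle`), a bilayer vesicle enclosing water
#' (`vesicle_shell`), and a stack of bilayer discs along the y axis with
#' alternating head/tail layers (`stacked_discs`). Water fills the remainder
#' of the box, excluded from the aggregate interior so that enclosed water
#' occurs only where the geometry dictates it.
#'
#' @param kind One of `"flat_bilayer"`, `"perforated_bilayer"`,
#'   `"spherical_micelle"`, `"vesicle_shell"`, `"stacked_discs"`.
#' @param spec A [system_spec()]; `n_lipids` chains are split over the two
#'   species according to the geometry (bilayers put type I in the upper /
#'   right leaflet and type II in the lower / left one). For a contiguous
#'   membrane the caller should supply a realistic area density, about
#'   1.3 chains per rc^2 per leaflet (`n_lipids ~ 2.6 * L^2`);
#'   `stacked_discs` derives its chain count from that density directly and
#'   ignores `n_lipids`.
#' @param bead_spacing Intra-chain bead spacing in rc.
#' @param hole_radius Pore radius for `perforated_bilayer`, in rc.
#' @param disc_radius In-plane radius for `stacked_discs`; default `0.3 * L`.
#' @param n_discs Number of stacked discs; default fills the box period.
#' @param shell_radius Mid-shell radius for `vesicle_shell`; default `L / 4`.
#' @return A list `(system, topology)` as from [build_system()]; velocities
#'   are zero.
#' @export
make_fixture <- function(kind, spec, bead_spacing = 0.45,
                         hole_radius = 3, disc_radius = NULL, n_discs = NULL,
                         shell_radius = NULL) {
  stopifnot(inherits(spec, "dpd_system_spec"))
  kind <- match.arg(kind, c("flat_bilayer", "perforated_bilayer",
                            "spherical_micelle", "vesicle_shell",
                            "stacked_discs"))
  L <- spec$box_length
  b <- bead_spacing
  set.seed(spec$seed)
  n1 <- as.integer(round(spec$n_lipids * spec$split))
  n2 <- spec$n_lipids - n1
  len1 <- spec$lipid_I$nh + spec$lipid_I$nt
  len2 <- spec$lipid_II$nh + spec$lipid_II$nt

  # chain builder: bead positions from head outer end toward tail end
  chain_line <- function(origin, dir, len, spacing = b) {
    origin <- rbind(origin)[rep(1, len), , drop = FALSE]
    origin + outer((seq_len(len) - 1) * spacing, dir)
  }

  place <- switch(kind,
    flat_bilayer = ,
    perforated_bilayer = {
      z0 <- L / 2
      grid_xy <- function(n) {
        k <- ceiling(sqrt(n))
        g <- (expand.grid(x = seq_len(k), y = seq_len(k)) - 0.5) * (L / k)
        as.matrix(g[seq_len(n), , drop = FALSE])
      }
      up <- grid_xy(n1)
      lo <- grid_xy(n2)
      ch <- c(
        lapply(seq_len(n1), function(i)
          chain_line(c(up[i, 1], up[i, 2], z0 + len1 * b), c(0, 0, -1), len1)),
        lapply(seq_len(n2), function(i)
          chain_line(c(lo[i, 1], lo[i, 2], z0 - len2 * b), c(0, 0, 1), len2)))
      if (kind == "perforated_bilayer") {
        cent <- vapply(ch, function(p) p[1, 1:2], numeric(2))
        r2 <- (cent[1, ] - L / 2)^2 + (cent[2, ] - L / 2)^2
        keep <- r2 > hole_radius^2
        ch <- ch[keep]
        n1 <- sum(keep[seq_len(n1)])
        n2 <- length(ch) - n1
      }
      half <- max(len1, len2) * b + 0.5
      list(chains = ch,
           excluded = function(p) abs(p[, 3] - z0) < half)
    },
    spherical_micelle = {
      n <- n1 + n2
      dirs <- fibonacci_sphere(n)
      rhead1 <- len1 * b + 0.3
      rhead2 <- len2 * b + 0.3
      ch <- lapply(seq_len(n), function(i) {
        len <- if (i <= n1) len1 else len2
        rh <- if (i <= n1) rhead1 else rhead2
        ctr <- c(L / 2, L / 2, L / 2)
        chain_line(ctr + rh * dirs[i, ], -dirs[i, ], len)
      })
      rmax <- max(rhead1, rhead2) + 0.5
      list(chains = ch,
           excluded = function(p) {
             rowSums(sweep(p, 2, c(L, L, L) / 2)^2) < rmax^2
           })
    },
    vesicle_shell = {
      # mid-shell radius must leave an interior water core inside the inner
      # leaflet and clear water outside the outer one
      rmid <- if (is.null(shell_radius)) max(L / 4, len2 * b + 2.5) else shell_radius
      ctr <- c(L / 2, L / 2, L / 2)
      # outer leaflet type I (heads outward), inner leaflet type II (heads inward)
      r_out <- rmid + len1 * b
      r_in <- rmid - len2 * b
      if (r_in < 1 || r_out + 1.5 > L / 2) {
        abort("vesicle_shell: box too small for the shell radius and chain length; increase box_length or reduce bead_spacing")
      }
      d1 <- fibonacci_sphere(n1)
      d2 <- fibonacci_sphere(n2)
      ch <- c(
        lapply(seq_len(n1), function(i)
          chain_line(ctr + r_out * d1[i, ], -d1[i, ], len1)),
        lapply(seq_len(n2), function(i)
          chain_line(ctr + r_in * d2[i, ], d2[i, ], len2)))
      list(chains = ch,
           excluded = function(p) {
             r <- sqrt(rowSums(sweep(p, 2, ctr)^2))
             r > r_in - 0.7 & r < r_out + 0.7
           })
    },
    stacked_discs = {
      R <- if (is.null(disc_radius)) 0.3 * L else disc_radius
      halfchain <- max(len1, len2) * b
      nd <- if (is.null(n_discs)) max(2L, floor(L / (2 * halfchain + 0.8))) else n_discs
      period <- L / nd
      # size the chains so adjacent discs' head faces sit 0.7 rc apart and
      # the two leaflets' tail ends meet 0.6 rc apart inside each disc
      half <- (period - 0.7) / 2
      bd <- (2 * half - 0.6) / (len1 + len2 - 2)
      # leaflet population from membrane area density (~1.3 chains per rc^2)
      # so neighbouring chains sit within the interaction range
      per_leaf <- ceiling(1.3 * pi * R^2)
      # sunflower points in the disc cross-section (x-z plane)
      sunflower <- function(n, R) {
        i <- seq_len(n) - 0.5
        r <- R * sqrt(i / n)
        th <- pi * (1 + sqrt(5)) * i
        cbind(r * cos(th), r * sin(th))
      }
      pts <- sunflower(per_leaf, R)
      ch <- list()
      ty <- integer(0)
      for (d in seq_len(nd)) {
        yc <- (d - 0.5) * period
        for (i in seq_len(per_leaf)) {
          # +y leaflet type I, -y leaflet type II
          ch <- c(ch,
            list(chain_line(c(L / 2 + pts[i, 1], yc + half, L / 2 + pts[i, 2]),
                            c(0, -1, 0), len1, spacing = bd)),
            list(chain_line(c(L / 2 + pts[i, 1], yc - half, L / 2 + pts[i, 2]),
                            c(0, 1, 0), len2, spacing = bd)))
          ty <- c(ty, 1L, 2L)
        }
      }
      n1 <- sum(ty == 1L)
      n2 <- sum(ty == 2L)
      # reorder: type I chains first to match build_topology's layout
      ch <- c(ch[ty == 1L], ch[ty == 2L])
      list(chains = ch,
           excluded = function(p) {
             (p[, 1] - L / 2)^2 + (p[, 3] - L / 2)^2 < (R + 0.7)^2
           })
    })

  chains <- place$chains
  nlip <- n1 * len1 + n2 * len2
  stopifnot(length(chains) == n1 + n2)
  N <- max(as.integer(round(spec$density * L^3)), nlip)
  topo <- build_topology(n1, n2, spec$lipid_I, spec$lipid_II, N)
  pos <- matrix(0, N, 3)
  species <- integer(N)
  for (k in seq_len(n1 + n2)) {
    idx <- chain_indices(topo, k)
    pos[idx, ] <- chains[[k]] %% L
    lp <- if (k <= n1) spec$lipid_I else spec$lipid_II
    species[idx] <- c(rep(species_index(lp$species_head), lp$nh),
                      rep(species_index(lp$species_tail), lp$nt))
  }
  if (N > nlip) {
    wat <- seq(nlip + 1L, N)
    pos[wat, ] <- fill_water(length(wat), L, place$excluded)
    species[wat] <- species_index("W")
  }
  list(system = new_dpd_system(pos, matrix(0, N, 3), species, L),
       topology = topo)
}
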