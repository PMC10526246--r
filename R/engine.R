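#' DPD weight function
#'
#' Linear soft-repulsion weight `w(r) = 1 - r/rc` inside the cut-off and 0
#' beyond it. The conservative force uses `w`, the dissipative force `w^2`,
#' and the random force `w`.
#'
#' @param r Distance(s), rc units.
#' @param rc Cut-off radius.
#' @return Dimensionless weight(s).
#' @export
weight_function <- function(r, rc = 1) {
  stopifnot(all(r >= 0))
  ifelse(r < rc, 1 - r / rc, 0)
}

#' Instantaneous kinetic temperature
#'
#' `kBT = 2 KE / (3 N)` in reduced units (all masses 1). The three
#' zero-momentum constraints are ignored in the denominator, the usual DPD
#' convention; the bias is O(1/N).
#'
#' @param sys A `dpd_system`.
#' @return Temperature in units of kBT.
#' @export
compute_temperature <- function(sys) {
  stopifnot(inherits(sys, "dpd_system"))
  n <- nrow(sys$vel)
  stopifnot(n >= 2)
  2 * (0.5 * sum(sys$vel^2)) / (3 * n)
}

topo_matrices <- function(topo) {
  list(bonds = matrix(as.integer(topo$bonds - 1L), ncol = 2),
       angles = matrix(as.integer(topo$angles - 1L), ncol = 3))
}

#' Evaluate DPD, bond and angle forces on a configuration
#'
#' One force evaluation, mainly a testing and inspection surface: per-bead
#' total forces plus the pair, bond and angle potential energies. Individual
#' force channels can be switched off, the O(N^2) all-pairs path can be
#' forced instead of the cell list, and the pair noise can be made Gaussian.
#'
#' @param sys A `dpd_system`.
#' @param topo A `dpd_topology` (use an empty one for pure fluids).
#' @param ff Force field.
#' @param engine_seed,step Noise counter inputs; the random term is a pure
#'   function of `(engine_seed, step, i, j)`.
#' @param brute Use the all-pairs reference path instead of the cell list.
#' @param conservative,dissipative,random Include the respective pair term.
#' @param gaussian_noise Draw pair noise from a unit Gaussian instead of the
#'   default variance-matched uniform.
#' @return List with `forces` (N x 3 matrix), `pe_pair`, `pe_bond`, `pe_angle`.
#' @export
dpd_forces <- function(sys, topo = NULL, ff = default_forcefield(),
                       engine_seed = 1, step = 0, brute = FALSE,
                       conservative = TRUE, dissipative = TRUE, random = TRUE,
                       gaussian_noise = FALSE) {
  stopifnot(inherits(sys, "dpd_system"))
  if (!all(is.finite(sys$pos)) || !all(is.finite(sys$vel))) {
    abort("non-finite positions or velocities")
  }
  if (is.null(topo)) {
    topo <- new_dpd_topology(tibble(), matrix(integer(0), 0, 2),
                             matrix(integer(0), 0, 3), nrow(sys$pos))
  }
  tm <- topo_matrices(topo)
  forces_cpp(sys$pos, sys$vel, as.integer(sys$species - 1L),
             ff$aij, ff$gamma, ff$sigma, ff$rc,
             tm$bonds, ff$ks, ff$rs, tm$angles, ff$ktheta, ff$theta0,
             sys$box, ff$dt, engine_seed, step,
             gaussian = gaussian_noise, brute = brute,
             with_cons = conservative, with_diss = dissipative,
             with_rand = random)
}

energy_tibble <- function(m) {
  colnames(m) <- c("step", "time", "kinetic", "pe_pair", "pe_bond",
                   "pe_angle", "total", "kBT")
  as_tibble(as.data.frame(m))
}

#' Run the DPD integrator
#'
#' Advances the system `n_steps` of length `ff$dt` with the Groot-Warren
#' modified velocity-Verlet scheme (`lambda = 0.5` velocity prediction for
#' the dissipative force), cell-list pair search, periodic wrapping, and
#' optional Muller-Plathe momentum swaps every `shear$swap_every` steps.
#' Deterministic for fixed inputs and `engine_seed`.
#'
#' @param sys A `dpd_system`.
#' @param topo A `dpd_topology` (or NULL for a pure fluid).
#' @param ff Force field.
#' @param n_steps Number of time steps (>= 0).
#' @param shear Optional [shear_protocol()].
#' @param energy_every Record an energy row every this many steps (0 = never).
#' @param frame_every Store a full snapshot every this many steps (0 = never).
#' @param profile_every Accumulate the slab velocity profile every this many
#'   steps (0 = never); slabs follow `shear` or default to 20.
#' @param engine_seed Seed of the counter-based pair-noise stream.
#' @param gaussian_noise Gaussian instead of uniform pair noise.
#' @param lambda Velocity-prediction factor of the integrator.
#' @return An object of class `dpd_run`: list with the advanced `system`,
#'   `topology`, `energy` (tibble), `frames` (list of `dpd_system`),
#'   `ledger` (swap bookkeeping), `profile` (slab velocity tibble or NULL),
#'   `ff`, and `shear`.
#' @examples
#' st <- build_system(system_spec(5, n_lipids = 0, seed = 1), default_forcefield())
#' r <- run_dpd(st$system, NULL, n_steps = 10, energy_every = 5)
#' r$energy
#' @export
run_dpd <- function(sys, topo = NULL, ff = default_forcefield(), n_steps,
                    shear = NULL, energy_every = 100, frame_every = 0,
                    profile_every = 0, engine_seed = 1,
                    gaussian_noise = FALSE, lambda = 0.5) {
  stopifnot(inherits(sys, "dpd_system"), n_steps >= 0)
  if (is.null(topo)) {
    topo <- new_dpd_topology(tibble(), matrix(integer(0), 0, 2),
                             matrix(integer(0), 0, 3), nrow(sys$pos))
  }
  n_slabs <- if (!is.null(shear)) shear$n_slabs else 20L
  if (n_steps == 0) {
    return(structure(list(system = sys, topology = topo,
                          energy = energy_tibble(matrix(0, 0, 8)),
                          frames = list(), ledger = new_swap_ledger(),
                          profile = NULL, ff = ff, shear = shear),
                     class = "dpd_run"))
  }
  tm <- topo_matrices(topo)
  step0 <- round(sys$time / ff$dt)
  elig <- rep(TRUE, 5)
  swap_every <- 0L
  slab_lo <- 0L
  slab_hi <- -1L
  if (!is.null(shear)) {
    stopifnot(inherits(shear, "dpd_shear_protocol"))
    swap_every <- shear$swap_every
    slab_lo <- shear$slab_lo - 1L
    slab_hi <- shear$slab_hi - 1L
    elig <- .species_levels %in% shear$eligible_species
  }
  out <- run_cpp(sys$pos, sys$vel, as.integer(sys$species - 1L),
                 ff$aij, ff$gamma, ff$sigma, ff$rc,
                 tm$bonds, ff$ks, ff$rs, tm$angles, ff$ktheta, ff$theta0,
                 sys$box, ff$dt, as.integer(n_steps), engine_seed,
                 step0 = step0, time0 = sys$time,
                 swap_every = as.integer(swap_every),
                 n_slabs = as.integer(n_slabs),
                 slab_lo = as.integer(slab_lo), slab_hi = as.integer(slab_hi),
                 eligible = elig,
                 energy_every = as.integer(energy_every),
                 frame_every = as.integer(frame_every),
                 profile_every = as.integer(profile_every),
                 gaussian = gaussian_noise, lambda = lambda)
  newsys <- new_dpd_system(out$pos, out$vel, sys$species, sys$box, out$time)
  frames <- lapply(out$frames, function(f)
    new_dpd_system(f$pos, f$vel, sys$species, sys$box, f$time))
  ledger <- new_swap_ledger(px = out$swap_px, count = out$swap_count,
                            skipped = out$swap_skipped,
                            elapsed = n_steps * ff$dt)
  if (!is.null(shear) && out$swap_skipped > 0) {
    warn(sprintf("%d momentum swaps skipped (empty driven slab)", out$swap_skipped))
  }
  profile <- NULL
  if (profile_every > 0) {
    zmid <- (seq_len(n_slabs) - 0.5) * sys$box / n_slabs
    profile <- tibble(slab = seq_len(n_slabs), z = zmid,
                      mean_vx = ifelse(out$prof_n > 0, out$prof_vx / out$prof_n, 0),
                      n = out$prof_n)
  }
  structure(list(system = newsys, topology = topo,
                 energy = energy_tibble(out$energy), frames = frames,
                 ledger = ledger, profile = profile, ff = ff, shear = shear),
            class = "dpd_run")
}

#' @export
print.dpd_run <- function(x, ...) {
  cat(sprintf("<dpd_run> %d beads advanced to t = %g tau; %d energy rows, %d frames\n",
              nrow(x$system$pos), x$system$time, nrow(x$energy), length(x$frames)))
  if (x$ledger$count > 0) {
    cat(sprintf("  momentum swaps: %d (cumulative |dPx| = %.4g)\n",
                x$ledger$count, x$ledger$px))
  }
  invisible(x)
}

#' @export
tidy.dpd_run <- function(x, ...) x$energy

#' @export
glance.dpd_run <- function(x, ...) {
  tibble(n_beads = nrow(x$system$pos), time = x$system$time,
         kBT = compute_temperature(x$system),
         swaps = x$ledger$count, swap_px = x$ledger$px)
}
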