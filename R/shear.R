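#' Momentum-swap shear protocol
#'
#' Reverse non-equilibrium shear: the box is partitioned into `n_slabs`
#' slabs along z, and every `swap_every` steps the x velocity of the bead
#' with the minimum vx in the bottom driven slab is exchanged with that of
#' the bead with the maximum vx in the top driven slab. With equal masses
#' the exchange conserves total momentum and kinetic energy exactly while
#' imposing an unphysical momentum flux, whose physical return through the
#' fluid sets up a linear vx(z) profile.
#'
#' The driven slabs default to the bottom (`[0, L/n_slabs)`) and top
#' (`[L - L/n_slabs, L)`) of the box, so the counter-gradient sits across
#' the periodic z boundary and the interior carries a single linear profile.
#' Set `geometry = "midplane"` for the textbook choice of driving slabs at
#' z = 0 and z = L/2 (two opposite gradients).
#'
#' @param swap_every Swap interval M in steps; the presets `"weak"` and
#'   `"strong"` correspond to M = 6 and M = 1 at the full 30 rc box.
#' @param n_slabs Number of z slabs (default 20).
#' @param eligible_species Bead labels allowed to swap (default: all, since
#'   all masses are equal).
#' @param geometry `"edges"` (default) or `"midplane"`.
#' @return An object of class `dpd_shear_protocol`.
#' @examples
#' shear_protocol("weak")
#' shear_protocol(12, n_slabs = 10)
#' @export
shear_protocol <- function(swap_every = 6, n_slabs = 20,
                           eligible_species = .species_levels,
                           geometry = c("edges", "midplane")) {
  geometry <- match.arg(geometry)
  if (is.character(swap_every)) {
    swap_every <- switch(match.arg(swap_every, c("weak", "strong")),
                         weak = 6L, strong = 1L)
  }
  stopifnot(swap_every >= 1, n_slabs >= 4)
  slab_hi <- if (geometry == "edges") as.integer(n_slabs) else
    as.integer(n_slabs / 2) + 1L
  structure(list(swap_every = as.integer(swap_every),
                 n_slabs = as.integer(n_slabs),
                 slab_lo = 1L, slab_hi = slab_hi,
                 eligible_species = eligible_species,
                 geometry = geometry),
            class = "dpd_shear_protocol")
}

#' @export
print.dpd_shear_protocol <- function(x, ...) {
  cat(sprintf("<dpd_shear_protocol> swap every %d steps, %d z-slabs, driven slabs %d and %d (%s)\n",
              x$swap_every, x$n_slabs, x$slab_lo, x$slab_hi, x$geometry))
  invisible(x)
}

#' Swap ledger
#'
#' Cumulative bookkeeping of the momentum transferred by swap events:
#' `px` is the running sum of |dPx| per swap, `count` the number of swaps,
#' `elapsed` the simulated time covered.
#'
#' @param px,count,skipped,elapsed Initial values (all zero by default).
#' @return An object of class `dpd_swap_ledger`.
#' @export
new_swap_ledger <- function(px = 0, count = 0L, skipped = 0L, elapsed = 0) {
  structure(list(px = px, count = as.integer(count),
                 skipped = as.integer(skipped), elapsed = elapsed),
            class = "dpd_swap_ledger")
}

#' Perform a single momentum swap
#'
#' One Muller-Plathe exchange on a `dpd_system`: finds the eligible bead
#' with minimum vx in the bottom driven slab and the one with maximum vx in
#' the top driven slab and exchanges their x velocities. Mostly a testing
#' surface; production runs swap inside [run_dpd()].
#'
#' @param sys A `dpd_system`.
#' @param proto A [shear_protocol()].
#' @param ledger A [new_swap_ledger()] to grow.
#' @return List with updated `system` and `ledger`.
#' @export
swap_momenta <- function(sys, proto, ledger = new_swap_ledger()) {
  stopifnot(inherits(sys, "dpd_system"), inherits(proto, "dpd_shear_protocol"))
  slabw <- sys$box / proto$n_slabs
  isl <- pmin(floor(sys$pos[, 3] / slabw) + 1L, proto$n_slabs)
  elig <- .species_levels[sys$species] %in% proto$eligible_species
  lo <- which(isl == proto$slab_lo & elig)
  hi <- which(isl == proto$slab_hi & elig)
  if (length(lo) == 0 || length(hi) == 0) {
    warn("momentum swap skipped: empty driven slab")
    ledger$skipped <- ledger$skipped + 1L
    return(list(system = sys, ledger = ledger))
  }
  imin <- lo[which.min(sys$vel[lo, 1])]
  imax <- hi[which.max(sys$vel[hi, 1])]
  dpx <- abs(sys$vel[imax, 1] - sys$vel[imin, 1])
  tmp <- sys$vel[imin, 1]
  sys$vel[imin, 1] <- sys$vel[imax, 1]
  sys$vel[imax, 1] <- tmp
  ledger$px <- ledger$px + dpx
  ledger$count <- ledger$count + 1L
  list(system = sys, ledger = ledger)
}

#' Imposed momentum flux
#'
#' `j_z(Px) = Px / (2 t Lx Ly)`: the cumulative exchanged momentum divided
#' by twice the elapsed time and the cross-section area (the factor 2
#' because the flux travels both ways round the periodic box).
#'
#' @param ledger A `dpd_swap_ledger` (or a bare number, the cumulative Px).
#' @param elapsed Exchange time t in tau; defaults to `ledger$elapsed`.
#' @param Lx,Ly Box cross-section side lengths in rc.
#' @return Momentum flux in reduced units.
#' @export
momentum_flux <- function(ledger, elapsed = NULL, Lx, Ly = Lx) {
  px <- if (inherits(ledger, "dpd_swap_ledger")) ledger$px else ledger
  if (is.null(elapsed)) elapsed <- ledger$elapsed
  if (elapsed <= 0) abort("elapsed time must be positive")
  px / (2 * elapsed * Lx * Ly)
}

#' Slab velocity profile from trajectory frames
#'
#' Time-averaged mean x velocity per z slab over one or more frames.
#'
#' @param frames A `dpd_system` or list of them.
#' @param n_slabs Number of z slabs.
#' @return A tibble of class `dpd_velocity_profile`: `slab`, `z`
#'   (slab centre), `mean_vx`, `n` (bead-frame samples).
#' @export
velocity_profile <- function(frames, n_slabs = 20) {
  if (inherits(frames, "dpd_system")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  L <- frames[[1]]$box
  slabw <- L / n_slabs
  svx <- numeric(n_slabs)
  sn <- numeric(n_slabs)
  for (f in frames) {
    isl <- pmin(floor(f$pos[, 3] / slabw) + 1L, n_slabs)
    svx <- svx + as.numeric(tapply(f$vel[, 1], factor(isl, levels = seq_len(n_slabs)),
                                   sum, default = 0))
    sn <- sn + as.numeric(tabulate(isl, n_slabs))
  }
  out <- tibble(slab = seq_len(n_slabs), z = (seq_len(n_slabs) - 0.5) * slabw,
                mean_vx = ifelse(sn > 0, svx / sn, 0), n = sn)
  class(out) <- c("dpd_velocity_profile", class(out))
  out
}

#' Shear rate from a velocity profile
#'
#' Least-squares slope of mean vx against z over the interior slabs (the
#' driven slabs, where the unphysical swaps act, are excluded). Returns a
#' fit object carrying the magnitude `gamma_dot`, the signed slope, and the
#' goodness of fit; `tidy()` and `glance()` methods expose the details.
#'
#' @param profile A [velocity_profile()] tibble (columns `z`, `mean_vx`).
#' @param exclude_slabs Slab indices to drop; defaults to the first and last
#'   (the driven slabs in the edge geometry).
#' @return An object of class `dpd_shear_fit`.
#' @export
shear_rate <- function(profile, exclude_slabs = c(1L, max(profile$slab))) {
  interior <- profile[!(profile$slab %in% exclude_slabs) & profile$n > 0, ]
  if (nrow(interior) < 3) abort("need at least 3 interior slabs to fit a gradient")
  fit <- lm(mean_vx ~ z, data = interior)
  r2 <- summary(fit)$r.squared
  structure(list(gamma_dot = abs(coef(fit)[["z"]]),
                 slope = coef(fit)[["z"]],
                 r_squared = r2, fit = fit, n_slabs = nrow(interior)),
            class = "dpd_shear_fit")
}

#' @export
print.dpd_shear_fit <- function(x, ...) {
  cat(sprintf("<dpd_shear_fit> gamma_dot = %.4g / tau (slope %.4g, R^2 = %.4f, %d slabs)\n",
              x$gamma_dot, x$slope, x$r_squared, x$n_slabs))
  invisible(x)
}

#' @export
tidy.dpd_shear_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.dpd_shear_fit <- function(x, ...) {
  tibble(gamma_dot = x$gamma_dot, slope = x$slope,
         r.squared = x$r_squared, n_slabs = x$n_slabs)
}

#' Calibrate the swap interval to a target shear rate
#'
#' The velocity gradient produced by a given swap interval M depends on the
#' box size, so matching a reference shear rate on a reduced box requires
#' retuning M. This runs a short momentum-swap simulation of pure water at
#' the requested box size with a probe interval, measures the resulting
#' gradient, and returns the interval whose predicted gradient (using the
#' inverse proportionality of flux to M) is closest to the target, refined
#' by a confirmation run.
#'
#' @param target_gamma_dot Desired shear rate in 1/tau.
#' @param box_length Box side in rc.
#' @param ff Force field.
#' @param probe_M Swap interval of the probe run.
#' @param n_steps Steps for each measurement (after an equal equilibration).
#' @param n_slabs Slab count.
#' @param seed Build/engine seed.
#' @return List with `swap_every` (integer), `gamma_dot` (measured at the
#'   returned interval) and `probe` (the probe fit).
#' @export
calibrate_swap_interval <- function(target_gamma_dot, box_length,
                                    ff = default_forcefield(), probe_M = 10,
                                    n_steps = 4000, n_slabs = 20, seed = 1) {
  measure <- function(M) {
    st <- build_system(system_spec(box_length, n_lipids = 0, seed = seed), ff)
    proto <- shear_protocol(M, n_slabs = n_slabs)
    warm <- run_dpd(st$system, NULL, ff, n_steps = n_steps, shear = proto,
                    energy_every = 0, engine_seed = seed)
    meas <- run_dpd(warm$system, NULL, ff, n_steps = n_steps, shear = proto,
                    energy_every = 0, profile_every = 2,
                    engine_seed = seed + 1)
    shear_rate(meas$profile)
  }
  probe <- measure(probe_M)
  M_pred <- max(1L, as.integer(round(probe_M * probe$gamma_dot / target_gamma_dot)))
  confirm <- if (M_pred == probe_M) probe else measure(M_pred)
  list(swap_every = M_pred, gamma_dot = confirm$gamma_dot, probe = probe)
}
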