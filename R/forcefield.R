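#' Default DPD force field for the two-species lipid model
#'
#' Returns the complete reduced-unit parameter set used throughout the
#' package: the 5x5 soft-repulsion matrix over bead species
#' (`H1`, `T1`, `H2`, `T2`, `W`), the dissipative/random thermostat pair
#' (`gamma`, `sigma`) satisfying the fluctuation-dissipation relation
#' `sigma^2 = 2 gamma kBT`, harmonic-bond and angle-bending constants, and
#' the integration time step.
#'
#' Repulsions: 25 between identical species and between the two head species;
#' 40 between any head and water; 100 between any tail and water, between a
#' head and any tail, and between the two tail species. All beads have unit
#' mass; `rc = 1` is the unit of length and `kBT = 1` the unit of energy.
#'
#' @param sigma Noise amplitude (reduced units). Default 3.0.
#' @param gamma Dissipation coefficient. Default 4.5.
#' @param kBT Thermostat temperature (unit energy). Default 1.
#' @param rc Interaction cut-off radius (unit length). Default 1.
#' @param ks Bond spring coefficient. Default 120.
#' @param rs Equilibrium bond length in units of `rc`. Default 0.7.
#' @param ktheta Angle-bending constant. Default 6.
#' @param theta0 Equilibrium bond angle (radians). Default `pi` (straight).
#' @param dt Time step in units of tau. Default 0.01.
#' @param aij Optional 5x5 repulsion matrix with dimnames over the species
#'   labels; defaults to [default_interaction_matrix()].
#'
#' @return An object of class `dpd_forcefield`: a named list of the above
#'   parameters.
#' @seealso [validate_forcefield()], [flory_huggins_chi()], [unit_map()]
#' @examples
#' ff <- default_forcefield()
#' ff$sigma^2 - 2 * ff$gamma * ff$kBT  # fluctuation-dissipation: 0
#' @export
default_forcefield <- function(sigma = 3.0, gamma = 4.5, kBT = 1, rc = 1,
                               ks = 120, rs = 0.7, ktheta = 6, theta0 = pi,
                               dt = 0.01, aij = default_interaction_matrix()) {
  ff <- structure(
    list(aij = aij, gamma = gamma, sigma = sigma, kBT = kBT, rc = rc,
         ks = ks, rs = rs, ktheta = ktheta, theta0 = theta0, dt = dt),
    class = "dpd_forcefield")
  ff
}

#' Bead-bead repulsion matrix for the two-species lipid / water system
#'
#' 5x5 symmetric matrix of conservative repulsion strengths `a_ij` over the
#' species `H1`, `T1`, `H2`, `T2`, `W`: 25 on the diagonal and between the
#' two head species, 40 for head-water, 100 for tail-water, head-tail and
#' tail-tail cross pairs.
#'
#' @return A 5x5 numeric matrix with species dimnames.
#' @export
default_interaction_matrix <- function() {
  a <- matrix(100, 5, 5, dimnames = list(.species_levels, .species_levels))
  diag(a) <- 25
  a["H1", "H2"] <- a["H2", "H1"] <- 25
  a["H1", "W"] <- a["W", "H1"] <- 40
  a["H2", "W"] <- a["W", "H2"] <- 40
  a
}

#' Map DPD repulsion to the Flory-Huggins interaction parameter
#'
#' Linear mapping `chi = 0.286 * (a_ij - a_ii)` between the excess soft
#' repulsion of an unlike bead pair and the Flory-Huggins incompatibility
#' parameter, the standard bridge between DPD repulsions and solution
#' thermodynamics at bead density 3 rc^-3.
#'
#' @param a_ij Repulsion strength between the unlike pair.
#' @param a_ii Repulsion strength between identical beads (reference).
#' @return Dimensionless `chi`, vectorised over inputs.
#' @examples
#' flory_huggins_chi(40, 25)   # head-water: 4.29
#' flory_huggins_chi(100, 25)  # tail-water: 21.45
#' @export
flory_huggins_chi <- function(a_ij, a_ii) {
  stopifnot(all(a_ij >= 0), all(a_ii >= 0))
  0.286 * (a_ij - a_ii)
}

#' Sigma implied by the fluctuation-dissipation relation
#'
#' The DPD thermostat requires `sigma^2 = 2 gamma kBT`; this returns the
#' noise amplitude consistent with a given dissipation coefficient.
#'
#' @param gamma Dissipation coefficient.
#' @param kBT Temperature in reduced units.
#' @return `sqrt(2 * gamma * kBT)`.
#' @export
fluctuation_dissipation_sigma <- function(gamma, kBT = 1) {
  sqrt(2 * gamma * kBT)
}

#' Reduced-to-physical unit mapping
#'
#' Carries the physical interpretation of the reduced DPD units: the bead
#' volume and density fix the cut-off length scale, and the time unit tau is
#' calibrated externally (here from experimental in-plane lipid diffusion,
#' giving 1.88 ns). `rc_nm` is stored as the conventional display value
#' 0.5 nm; note that `(rho * V_P)^(1/3)` with the defaults evaluates to
#' 0.448 nm, and the rounded mapping is kept deliberately.
#'
#' @param tau_ns Physical duration of one tau, in nanoseconds.
#' @param rc_nm Physical length of one rc, in nanometres.
#' @param bead_volume_nm3 Volume represented by one DPD bead, nm^3.
#' @param density Bead number density in rc^-3.
#' @return An object of class `dpd_unit_map`.
#' @export
unit_map <- function(tau_ns = 1.88, rc_nm = 0.5, bead_volume_nm3 = 0.03,
                     density = 3) {
  stopifnot(tau_ns > 0, rc_nm > 0, density > 0)
  structure(list(tau_ns = tau_ns, rc_nm = rc_nm,
                 bead_volume_nm3 = bead_volume_nm3, density = density),
            class = "dpd_unit_map")
}

#' Convert a reduced-unit duration to nanoseconds
#'
#' @param u A [unit_map()].
#' @param t_reduced Duration in units of tau (vectorised).
#' @return Duration in nanoseconds.
#' @examples
#' map_to_physical(unit_map(), 0.01)  # one time step: 0.0188 ns
#' @export
map_to_physical <- function(u, t_reduced) {
  stopifnot(inherits(u, "dpd_unit_map"))
  t_reduced * u$tau_ns
}

#' Validate a force-field parameter set
#'
#' Checks the structural invariants of a `dpd_forcefield`: the
#' fluctuation-dissipation relation `sigma^2 = 2 gamma kBT`, symmetry and
#' constant diagonal of the repulsion matrix, a positive time step, and an
#' equilibrium bond length in `(0, rc]`.
#'
#' @param ff A `dpd_forcefield`.
#' @param tol Numeric tolerance for the fluctuation-dissipation identity.
#' @return A character vector of violated invariants; empty when valid.
#' @examples
#' validate_forcefield(default_forcefield())  # character(0)
#' @export
validate_forcefield <- function(ff, tol = 1e-10) {
  stopifnot(inherits(ff, "dpd_forcefield"))
  bad <- character(0)
  if (abs(ff$sigma^2 - 2 * ff$gamma * ff$kBT) > tol) {
    bad <- c(bad, "fluctuation-dissipation")
  }
  a <- ff$aij
  if (!is.matrix(a) || nrow(a) != 5L || ncol(a) != 5L) {
    bad <- c(bad, "aij-shape")
  } else {
    if (max(abs(a - t(a))) > tol) bad <- c(bad, "symmetry")
    if (any(abs(diag(a) - a[1, 1]) > tol)) bad <- c(bad, "diagonal-constant")
  }
  if (!(ff$rs > 0 && ff$rs <= ff$rc)) bad <- c(bad, "bond-length-range")
  if (!(ff$dt > 0)) bad <- c(bad, "time-step-positive")
  if (!(ff$rc > 0)) bad <- c(bad, "cutoff-positive")
  bad
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat("<dpd_forcefield>\n")
  cat(sprintf("  sigma = %g, gamma = %g, kBT = %g (sigma^2 - 2*gamma*kBT = %g)\n",
              x$sigma, x$gamma, x$kBT, x$sigma^2 - 2 * x$gamma * x$kBT))
  cat(sprintf("  rc = %g, dt = %g tau; bonds ks = %g, rs = %g; angles ktheta = %g, theta0 = %g\n",
              x$rc, x$dt, x$ks, x$rs, x$ktheta, x$theta0))
  cat("  aij:\n")
  print(x$aij)
  invisible(x)
}

#' Lipid chain specification
#'
#' An amphiphile with `nh` head beads followed by `nt` tail beads, all
#' connected by harmonic bonds with bending stiffness along the chain.
#'
#' @param species_head,species_tail Bead species labels for the two blocks
#'   (one of `"H1"`, `"H2"` and `"T1"`, `"T2"`).
#' @param nh,nt Head and tail bead counts (each at least 1).
#' @return An object of class `dpd_lipid_spec`.
#' @examples
#' lipid_spec("H1", "T1", nh = 3, nt = 6)
#' @export
lipid_spec <- function(species_head, species_tail, nh = 3, nt = 4) {
  stopifnot(nh >= 1, nt >= 1)
  species_index(c(species_head, species_tail))
  structure(list(species_head = species_head, species_tail = species_tail,
                 nh = as.integer(nh), nt = as.integer(nt)),
            class = "dpd_lipid_spec")
}
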