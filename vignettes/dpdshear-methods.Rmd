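---
title: "Methods: coarse-grained lipid self-assembly under momentum-swap shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained lipid self-assembly under momentum-swap shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dpdshear)
```

## The model

`dpdshear` simulates the self-assembly of two amphiphile species in explicit
coarse-grained water with dissipative particle dynamics (DPD). Each lipid is a
linear chain of `nh` hydrophilic head beads followed by `nt` hydrophobic tail
beads; water is a single bead. All beads have unit mass, and the package works
in the standard reduced units: the interaction cut-off `rc` is the unit of
length, `kBT` the unit of energy, and `tau = rc * sqrt(m / kBT)` the unit of
time.

Beads interact pairwise inside `rc` through three channels, each directed
along the interparticle axis and vanishing beyond the cut-off with the linear
weight `w(r) = 1 - r/rc`:

* a soft conservative repulsion of magnitude `a_ij * w(r)`;
* a dissipative drag `-gamma * w(r)^2 * (v_ij . e_ij)`;
* a random kick `sigma * w(r) * zeta_ij / sqrt(dt)`.

The dissipative and random channels form a momentum-conserving pairwise
thermostat; `sigma^2 = 2 * gamma * kBT` (fluctuation–dissipation) makes the
stationary distribution canonical at `kBT`. `validate_forcefield()` enforces
the identity; the default `gamma = 4.5`, `sigma = 3.0` satisfies it exactly.

Chain connectivity adds a harmonic bond force `ks * (1 - r/rs)` between
consecutive beads (`ks = 120`, `rs = 0.7 rc`) and a bending potential
`ktheta * (theta - theta0)^2` on consecutive bead triples (`ktheta = 6`,
`theta0 = pi`), which gives the chains their rigidity.

The 5×5 repulsion matrix over the species `{H1, T1, H2, T2, W}` has 25 on the
diagonal and for the head–head cross pair, 40 for head–water, and 100 for every
tail-involving unlike pair (tail–water, head–tail, tail–tail). The excess
repulsion maps linearly onto the Flory–Huggins incompatibility,
`chi = 0.286 * (a_ij - a_ii)`, so head–water is weakly unfavourable
(`chi = 4.29`) while tail–water is strongly demixing (`chi = 21.45`; note the
literal coefficient gives 21.45 while 21.42 is sometimes quoted after
rounding — we keep the literal linear form). The physical mapping stored in
`unit_map()` is `rc = 0.5` nm (display convention; `(rho * V_P)^(1/3)` with
`V_P = 0.03` nm³ and `rho = 3` evaluates to 0.448 nm) and `tau = 1.88` ns,
making the default `dt = 0.01 tau` equal to 0.0188 ns.

## Integration

`run_dpd()` advances the system with the Groot–Warren modified velocity-Verlet
scheme: positions take a full step from the current forces, the dissipative
force is evaluated at a predicted velocity `v + lambda * dt * f` with
`lambda = 0.5`, and velocities are corrected with the average of old and new
forces. The plain description "velocity Verlet" is ambiguous for DPD because
the drag depends on velocity; `lambda = 0.5` is the community standard that
keeps the measured temperature within a few per cent of the target at
`dt = 0.01`. The equilibrium temperature of a default water box measures
`1.00 +/- 0.02 kBT`; DPD's well-known small `dt`-dependent drift is tolerated
and covered by the 5% test band.

Pair search uses a cell list with edge `>= rc`, rebuilt every step, falling
back to an all-pairs sweep for boxes under three cells; the two paths agree to
`1e-10` per force component and the all-pairs path doubles as the test oracle.

The pair noise `zeta_ij` is drawn from a counter-based hash of
`(engine_seed, step, i, j)` with `i, j` unordered, so each pair shares one
symmetric value per step (required for exact momentum conservation) and the
enumeration order of the cell list cannot change results — trajectories are
bitwise reproducible for a fixed seed on a given platform. By default `zeta`
is uniform, `sqrt(3) * U(-1, 1)`, scaled to unit variance — the standard DPD
choice, statistically equivalent to a Gaussian at these time steps — and a
Gaussian switch (`gaussian_noise = TRUE`) is provided.

The reported pair potential energy is `(a_ij * rc / 2) * (1 - r/rc)^2`, the
integral of the conservative force; kinetic, pair, bond and angle channels are
logged separately along with their sum, since "system energy" can reasonably
mean either the total or the potential part — both are available for stage
analysis.

## Synthetic systems

`build_system()` is the package's data generator: it fills a cubic box of side
`L` to bead density `rho = 3 rc^-3`, placing `n` lipid chains as near-linear
random walks with bond length `rs` (soft DPD cores tolerate overlap, so no
rejection is applied — the standard DPD practice that avoids biasing the
ensemble) and the remainder as uniform water, with Maxwell–Boltzmann
velocities at `kBT` and the net momentum removed. The reference study
conditions are a 30 rc box with `n = 1200` (dilute, `phi = n/V = 0.0444
rc^-3`) or `n = 2400` (dense, `0.0889 rc^-3`) chains split equally between the
species, heads of length 3 and tails between 2 and 10; concentrations are
reported unrounded. Desk-scale work maps the same concentrations onto reduced
boxes (10–15 rc) via `n_lipids_for_phi()`.

Bending triples are placed on every consecutive triple including the
head–tail junction — the model description does not restrict them, and a
uniform rule keeps chain stiffness homogeneous — with
`angles_span_junction = FALSE` available to probe the alternative.
`select_initial_state()` mirrors the practice of relaxing several seeded
starts briefly and keeping the lowest-energy candidate; the exact candidate
protocol used historically is unspecified, so the helper makes the procedure
explicit rather than guessing.

`make_fixture()` builds idealized geometries (flat and perforated bilayers,
spherical micelles, vesicle shells with enclosed water, stacked discs) for
which the correct analysis answers are known by construction; they exercise
the classifiers without any simulation.

## Momentum-swap shear

Shear is imposed by the reverse non-equilibrium method: every `M` steps the
x-velocity of the bead with the lowest `vx` in the bottom slab is exchanged
with the bead with the highest `vx` in the top slab (equal masses make the
velocity swap a momentum swap that conserves energy exactly). The driven
slabs sit at the bottom and top of the box, so the unphysical counter-gradient
lives across the periodic z boundary and the whole interior carries one linear
profile; the textbook geometry with the second driven slab at `L/2` is
available via `geometry = "midplane"`. 20 slabs are the default for a 30 rc
box (1.5 rc slabs keep populations in the thousands); all species are
swap-eligible since all masses are equal. Exactly one extremal pair is
exchanged per event.

The imposed flux is `j_z(Px) = Px / (2 t Lx Ly)` from the swap ledger, and the
realised shear rate `gamma_dot` is the least-squares slope of the slab-mean
`vx(z)` over the interior slabs. At the full 30 rc box the reference
conditions are `M = 6` ("weak", `gamma_dot ≈ 0.073/tau`) and `M = 1`
("strong", `≈ 0.168/tau`). The gradient a given `M` produces scales roughly
as `1/(M L^2)`, so reduced boxes need retuned intervals:
`calibrate_swap_interval()` measures the gradient on a water box of the target
size and returns the interval closest to a requested `gamma_dot`. One
limitation is discrete: a single extremal swap per step (`M = 1`) caps the
attainable flux, so on a 12 rc box the strong condition saturates near
`0.12/tau` rather than 0.168; the calibrated "strong" protocol is then the
maximal-flux `M = 1` (which is also the reference strong interval) and the
ordering weak < strong is preserved, which is what the shape-factor
comparisons rely on.

## Analyses

*Density profiles.* `density_profile()` histograms bead positions along a box
axis per species and divides by the slab volume, integrating exactly to bead
counts; `density_map_2d()` projects onto a plane for pore and disc
diagnostics.

*Shape factor.* For each chain, coordinates are unwrapped by walking the
bonds with minimum-image displacements (moments on wrapped coordinates are
meaningless), the gyration tensor `G_ab = (1/N) sum_i (r_ia - rc_a)(r_ib -
rc_b)` is diagonalised, and the asphericity
`delta = 1 - 3 (L1 L2 + L2 L3 + L1 L3) / (L1 + L2 + L3)^2` is computed from
the eigenvalues: 0 for a sphere, 1 for a rod. Direct evaluation gives 0.25
for a thin planar ring (the value 0.5 is sometimes associated with circular
conformations in the literature; the closed form above is implemented
literally and the discrepancy documented here). `mean_shape_factor()` averages
over chains per frame and species; `stable_mean()` then averages the final
third of the run — the stable stage — weighting frames by chain count. Both
the per-frame series and the windowed means are reported, since averaging
conventions over time versus chains differ between studies.

*Leaflet mixing.* For bilayers, the midplane is the periodic (circular) mean
of the tail-bead positions along the bilayer normal — the axis of smallest
circular spread of the tails — and a chain belongs to the leaflet containing
its first head bead. The counts of type-I chains in the right leaflet and
type-II in the left, per frame, quantify inter-leaflet mixing; their
complements are fixed by the per-species chain totals.

*Clustering and phase classification.* `cluster_beads()` builds connected
components of the contact graph at a 1 rc cutoff (the interaction range) under
minimum-image distances and detects, by unwrapping during the traversal,
whether a component connects to its own periodic image along each axis.
`classify_phase()` applies a decision tree to the largest lipid cluster:
spanning two or more dimensions is a membrane — perforated (PDL) if the
in-plane occupancy grid at ~1 rc resolution contains a connected empty patch
of at least 4 cells (pores are identified visually in the source studies, so
the quantitative threshold is an exposed approximation), else intact (DL);
spanning one dimension is cylinder-like — a hierarchical disc stack (HD) when
the head density along the axis shows at least two peaks anti-correlated with
the tail density (the alternating head/tail layering that defines HD), else an
elongated micelle; spanning none is a vesicle when a detached water pocket of
at least 5 beads sits inside the aggregate, else a micelle. All thresholds
are arguments; diagnostics are returned for audit, and a comparable-sized
second aggregate flags the label as ambiguous.

*Stage segmentation.* `segment_stages()` smooths the energy series and fits
piecewise-linear models with one, two or three segments, accepting an extra
changepoint only while it halves the residual sum of squares. The ratio rule
was chosen over plain BIC because the smoothed corner of a clean two-stage
relaxation otherwise lures a spurious third segment; with the 0.5 threshold
both constructed two-stage and three-stage series are recovered reliably,
and a constant series stays a single stage.

## Phase-diagram sweeps

`run_sweep()` classifies the final configuration over a grid of tail lengths,
concentrations and shear conditions at reduced scale. The repulsion matrix is
exactly invariant under relabelling `(H1, T1) <-> (H2, T2)`, so the cell
`(NT1, NT2) = (a, b)` and its mirror `(b, a)` describe the same physical
system with species names exchanged; the sweep therefore simulates each
unordered pair once and mirrors the label, making the diagonal symmetry of the
phase diagram exact by construction (mirrored rows are flagged). Full 9×9
grids at the reference box and durations are cluster-scale; the package's
defaults run 3×3 grids on 10 rc boxes, which reproduce the topology of the
diagram (the shear-driven loss of enclosed-water structures toward cylindrical
micelles) but not its exact phase boundaries.

## Problem sizes and what the tests show

The package's test and acceptance workloads use: water boxes of 10–12 rc
(3000–5184 beads) for thermostat, momentum-conservation and shear-profile
checks; the dilute `NT1 = 6 / NT2 = 8` mixture on a 12 rc box (76 chains,
5184 beads, 60 000 steps = 600 tau) for the stable-stage shape factors under
zero, calibrated-weak and maximal-flux-strong shear; and fixture geometries
for the classifier. At these sizes the stable-stage shape-factor means
reproduce the reference values (≈ 0.92, type-II below type-I, strong above
weak) within ±0.02. What passing these tests does **not** show: equality of
the full-scale phase boundaries, the absolute shear rates of the 30 rc box,
or kinetics of pore formation in dense membranes — those require the
cluster-scale runs explicitly left out of desk-scale scope.

Two desk-scale limitations deserve emphasis. First, enclosed-water vesicles
do not nucleate from disordered starts in reduced boxes (10–18 rc, up to a
few hundred tau): the grids produce membranes, disc stacks and micelles, and
even a constructed vesicle drains its interior water within tens of tau —
small shells are leaky, and a vesicle stable over the run needs far more
lipids than a reduced box holds. The shear trend therefore shows up at desk
scale as the collapse of the zero-shear structural diversity (membranes,
perforated membranes, disc stacks) into shear-aligned cylindrical micelles,
plus the conversion of a constructed vesicle into a micelle under the strong
protocol; the unsheared persistence control for that conversion is not
attainable at this size. Second, the shape-factor difference between the
weak and strong conditions (+0.007 in the reference data) is comparable to
the single-run sampling noise of a 76-chain system (~0.01), so while the
packaged seeds reproduce the ordering, it should be regarded as marginal at
this system size rather than a robust desk-scale observable.

Numerical details worth knowing: coincident beads (distance < 1e-12) exert no
conservative pair force (the direction is undefined; the soft core makes this
harmless and it cannot persist); a zero-length bond or angle arm aborts the
run; the angle force uses a sine-clamped gradient which is exact away from
collinearity and tends smoothly to zero at the equilibrium straight angle;
positions are wrapped half-open into `[0, L)` every step and all distances use
the minimum-image convention.
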