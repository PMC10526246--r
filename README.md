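# dpdshear

Dissipative particle dynamics (DPD) simulation and analysis of two-species
lipid self-assembly in water, with reverse non-equilibrium (momentum-swap)
shear — for soft-matter and membrane-biophysics researchers who want a
desk-scale, fully seeded, scriptable version of the classic coarse-grained
amphiphile-under-shear setup in R.

Each lipid is a chain of `nh` hydrophilic head beads and `nt` hydrophobic
tail beads in explicit single-bead water. Beads interact through the
standard DPD triple — soft conservative repulsion `a_ij (1 - r/rc)`,
pairwise dissipative drag `-gamma w(r)^2 (v_ij · e_ij)`, and random kicks
`sigma w(r) zeta_ij / sqrt(dt)` with `sigma^2 = 2 gamma kBT`
(fluctuation–dissipation) — plus harmonic bonds `ks (1 - r/rs)` and angle
bending `ktheta (theta - theta0)^2` along the chains. Shear is imposed by
Müller-Plathe momentum swaps: every `M` steps the extremal x-velocities of
the top and bottom slab are exchanged, transferring momentum flux
`j_z(Px) = Px / (2 t Lx Ly)` which the fluid returns as a linear velocity
gradient `gamma_dot = dvx/dz`. Chain conformation is tracked by the
gyration-tensor shape factor

```
delta = 1 - 3 (L1 L2 + L2 L3 + L1 L3) / (L1 + L2 + L3)^2
```

(0 = sphere, 1 = rod), and aggregates are classified into bilayer (DL),
perforated bilayer (PDL), stacked hierarchical discs (HD), micelle and
vesicle by periodic-aware clustering of the lipid beads.

The integrator core is compiled (Rcpp) with cell-list pair search and a
counter-based noise stream keyed by `(seed, step, i, j)`, so trajectories
are bitwise reproducible and independent of force-evaluation order.

## Worked example

Self-assembly of the dilute two-species mixture (heads of 3 beads, tails of
6 and 8) in a 12 rc box at bead density 3, 600 tau of dynamics, no shear:

```r
library(dpdshear)

ff <- default_forcefield()          # sigma = 3, gamma = 4.5, Table-style a_ij
spec <- system_spec(12, n_lipids = n_lipids_for_phi(1200 / 27000, 12),
                    lipid_I  = lipid_spec("H1", "T1", 3, 6),
                    lipid_II = lipid_spec("H2", "T2", 3, 8), seed = 101)
st  <- build_system(spec, ff)       # 5184 beads: 76 chains + water
run <- run_dpd(st$system, st$topology, ff, n_steps = 60000,
               energy_every = 400, frame_every = 400, engine_seed = 101)

series <- mean_shape_factor(run$frames, st$topology)
stable_mean(series)
#> # A tibble: 2 x 3
#>    type mean_delta n_frames
#>   <int>      <dbl>    <int>
#> 1     1      0.929       50
#> 2     2      0.906       50

classify_phase(run$system, run$topology)$label
#> [1] "micelle"
```

The stable-stage means say the chains are strongly rod-like
(`delta ≈ 0.93` against 1 for a perfect rod), with the longer-tailed
species slightly less extended — the signature of chains packed side-by-side
in an elongated aggregate, which the classifier identifies as a
shear-axis-spanning cylindrical micelle at this reduced box size.
`autoplot(series)` plots the per-species time series; `plot_energy(run)`
shows the relaxation stages that `segment_stages()` delimits.

Shear runs add a protocol, e.g. `run_dpd(..., shear = shear_protocol("weak"))`,
and `velocity_profile()` + `shear_rate()` measure the realised gradient;
`calibrate_swap_interval()` retunes the swap interval for reduced boxes.
`run_config()` drives all of this from a sectioned key-value config file, and
`inst/cli/dpdshear.R` wraps run / sweep / analyze / fixtures for the shell.

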