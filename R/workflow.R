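default_run_config <- function() {
  list(
    system = list(box_length = 12, density = 3, n_lipids = 76,
                  nh1 = 3, nt1 = 6, nh2 = 3, nt2 = 8, split = 0.5),
    forcefield = list(profile = "paper_defaults"),
    shear = list(mode = "none", swap_every = 0, n_slabs = 20),
    run = list(n_steps = 1000, energy_every = 100, frame_every = 0,
               profile_every = 0),
    output = list(dir = ".", format = "xyz", basename = "run"))
}

forcefield_from_config <- function(fc) {
  ff <- default_forcefield()
  if (!is.null(fc$profile) && !identical(fc$profile, "paper_defaults")) {
    abort(sprintf("unknown forcefield profile: %s", fc$profile))
  }
  for (key in intersect(names(fc), c("sigma", "gamma", "kBT", "rc", "ks",
                                     "rs", "ktheta", "theta0", "dt"))) {
    ff[[key]] <- fc[[key]]
  }
  bad <- validate_forcefield(ff)
  if (length(bad)) {
    abort(paste0("invalid forcefield: ", paste(bad, collapse = ", ")))
  }
  ff
}

shear_from_config <- function(sc) {
  mode <- if (is.null(sc$mode)) "none" else sc$mode
  n_slabs <- if (is.null(sc$n_slabs)) 20 else sc$n_slabs
  swap_every <- switch(as.character(mode),
                       none = , zero = 0,
                       weak = 6, strong = 1,
                       custom = sc$swap_every,
                       abort(sprintf("unknown shear mode: %s", mode)))
  if (swap_every == 0) return(NULL)
  shear_protocol(swap_every, n_slabs = n_slabs)
}

spec_from_config <- function(cfg) {
  sc <- cfg$system
  if (is.null(cfg$seed) && is.null(sc$seed)) {
    abort("config is missing required field: [system] seed")
  }
  system_spec(box_length = sc$box_length,
              density = if (is.null(sc$density)) 3 else sc$density,
              n_lipids = sc$n_lipids,
              lipid_I = lipid_spec("H1", "T1",
                                   nh = if (is.null(sc$nh1)) 3 else sc$nh1,
                                   nt = sc$nt1),
              lipid_II = lipid_spec("H2", "T2",
                                    nh = if (is.null(sc$nh2)) 3 else sc$nh2,
                                    nt = sc$nt2),
              split = if (is.null(sc$split)) 0.5 else sc$split,
              seed = sc$seed)
}

#' Run one simulation from a configuration
#'
#' Builds the system from the `[system]` section, runs the engine with the
#' `[forcefield]`, `[shear]` and `[run]` sections, and writes the
#' trajectory, energy table, summary report and a JSON manifest into the
#' `[output]` directory. Reruns with the same config and seed reproduce the
#' outputs exactly.
#'
#' @param config Path to a config file (see [read_run_config()]) or an
#'   equivalent nested list.
#' @param out_dir Optional override of `[output] dir`.
#' @return Invisibly, a list with the `run` object, the `phase` label of
#'   the final state, and output `paths`.
#' @export
run_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  cfg <- modifyList(default_run_config(), cfg)
  spec <- spec_from_config(cfg)
  ff <- forcefield_from_config(cfg$forcefield)
  shear <- shear_from_config(cfg$shear)
  rc <- cfg$run
  st <- build_system(spec, ff)
  run <- run_dpd(st$system, st$topology, ff,
                 n_steps = rc$n_steps, shear = shear,
                 energy_every = rc$energy_every,
                 frame_every = rc$frame_every,
                 profile_every = rc$profile_every,
                 engine_seed = spec$seed)
  dir <- if (is.null(out_dir)) cfg$output$dir else out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, cfg$output$basename)
  fmt <- cfg$output$format
  paths <- list(
    trajectory = paste0(base, if (fmt == "dump") ".dump" else ".xyz"),
    topology = paste0(base, ".topo"),
    energy = paste0(base, "_energy.tsv"),
    report = paste0(base, "_report.txt"),
    manifest = paste0(base, "_manifest.json"))
  frames <- if (length(run$frames)) run$frames else list(run$system)
  write_trajectory(frames, paths$trajectory, format = fmt, dt = ff$dt)
  write_topology(run$topology, paths$topology)
  write_energy_table(run$energy, paths$energy)
  phase <- classify_phase(run$system, run$topology)
  report <- summarize_run(run, phase)
  writeLines(report, paths$report)
  manifest <- list(config = cfg, seed = spec$seed,
                   package = as.character(utils::packageVersion("dpdshear")),
                   n_beads = nrow(run$system$pos),
                   paths = paths, written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(run = run, phase = phase, paths = paths))
}

summarize_run <- function(run, phase = NULL) {
  sys <- run$system
  out <- c(sprintf("beads: %d  box: %g rc  time: %g tau",
                   nrow(sys$pos), sys$box, sys$time),
           sprintf("temperature: %.4f kBT", compute_temperature(sys)))
  if (nrow(run$energy) > 0) {
    out <- c(out, sprintf("final total energy: %.4f", tail(run$energy$total, 1)))
  }
  if (!is.null(phase)) {
    out <- c(out, sprintf("phase: %s%s", phase$label,
                          if (phase$ambiguous) " (ambiguous)" else ""))
  }
  if (run$ledger$count > 0) {
    out <- c(out, sprintf("swaps: %d  cumulative |dPx|: %.4g  flux: %.4g",
                          run$ledger$count, run$ledger$px,
                          momentum_flux(run$ledger, Lx = sys$box)))
  }
  if (!is.null(run$profile)) {
    fit <- tryCatch(shear_rate(run$profile), error = function(e) NULL)
    if (!is.null(fit)) {
      out <- c(out, sprintf("shear rate: %.4g /tau (R^2 = %.3f)",
                            fit$gamma_dot, fit$r_squared))
    }
  }
  out
}

#' Phase-diagram sweep over tail lengths and conditions
#'
#' Runs a reduced-scale self-assembly simulation for every grid cell
#' `(NT1, NT2, phi, shear)` and classifies the final configuration. Because
#' the force field is exactly symmetric under relabelling the two species
#' (with their tail lengths), the sweep simulates each unordered tail pair
#' once and mirrors the label across the diagonal; mirrored rows are
#' flagged. When `out_dir` is given each finished cell is written as a
#' small JSON file and interrupted sweeps resume without recomputation.
#'
#' @param nt1,nt2 Tail-length grids (each within 2..10).
#' @param phi Chain concentrations in rc^-3.
#' @param shear Named numeric vector of swap intervals per condition
#'   (0 = no shear). Use [calibrate_swap_interval()] to map the weak/strong
#'   reference gradients onto a reduced box.
#' @param box_length Box side in rc.
#' @param n_steps Production steps per cell.
#' @param nh Head length for both species.
#' @param seed Base seed; each cell derives a unique seed.
#' @param ff Force field.
#' @param out_dir Optional directory for per-cell results (enables resume).
#' @return Tibble with `nt1`, `nt2`, `phi`, `shear`, `swap_every`, `label`,
#'   `ambiguous`, `seed`, `mirrored`.
#' @export
run_sweep <- function(nt1 = c(2, 6, 10), nt2 = c(2, 6, 10),
                      phi = 1200 / 27000,
                      shear = c(zero = 0, weak = 6, strong = 1),
                      box_length = 10, n_steps = 20000, nh = 3,
                      seed = 1, ff = default_forcefield(), out_dir = NULL) {
  stopifnot(all(nt1 >= 2 & nt1 <= 10), all(nt2 >= 2 & nt2 <= 10))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(nt1 = nt1, nt2 = nt2, phi = phi,
                      shear = names(shear), stringsAsFactors = FALSE)
  if (nrow(grid) == 0) return(tibble())
  cache <- list()
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    a <- grid$nt1[g]; b <- grid$nt2[g]
    lo <- min(a, b); hi <- max(a, b)
    key <- sprintf("nt%d-%d_phi%.5f_%s", lo, hi, grid$phi[g], grid$shear[g])
    cell_seed <- (seed * 7919 + lo * 101 + hi * 13 +
                    match(grid$shear[g], names(shear)) * 3 +
                    round(grid$phi[g] * 1e4)) %% 2147483647
    res <- cache[[key]]
    cell_file <- if (!is.null(out_dir)) file.path(out_dir, paste0(key, ".json"))
    if (is.null(res) && !is.null(cell_file) && file.exists(cell_file)) {
      res <- jsonlite::read_json(cell_file, simplifyVector = TRUE)
    }
    if (is.null(res)) {
      res <- tryCatch({
        n <- n_lipids_for_phi(grid$phi[g], box_length)
        spec <- system_spec(box_length, n_lipids = n,
                            lipid_I = lipid_spec("H1", "T1", nh, lo),
                            lipid_II = lipid_spec("H2", "T2", nh, hi),
                            seed = cell_seed)
        st <- build_system(spec, ff)
        proto <- if (shear[[grid$shear[g]]] > 0) {
          shear_protocol(shear[[grid$shear[g]]])
        } else NULL
        run <- run_dpd(st$system, st$topology, ff, n_steps = n_steps,
                       shear = proto, energy_every = 0,
                       engine_seed = cell_seed)
        ph <- classify_phase(run$system, run$topology)
        list(label = ph$label, ambiguous = ph$ambiguous, seed = cell_seed,
             swap_every = shear[[grid$shear[g]]])
      }, error = function(e) {
        list(label = "error", ambiguous = FALSE, seed = cell_seed,
             swap_every = shear[[grid$shear[g]]], message = conditionMessage(e))
      })
      cache[[key]] <- res
      if (!is.null(cell_file)) {
        jsonlite::write_json(res, cell_file, auto_unbox = TRUE)
      }
    }
    cache[[key]] <- res
    rows[[g]] <- tibble(nt1 = a, nt2 = b, phi = grid$phi[g],
                        shear = grid$shear[g], swap_every = res$swap_every,
                        label = res$label, ambiguous = isTRUE(res$ambiguous),
                        seed = res$seed, mirrored = a > b)
  }
  dplyr::bind_rows(rows)
}

#' Re-analyse a stored trajectory
#'
#' Reads a trajectory (and optional topology sidecar), classifies the final
#' frame, and where the topology allows it computes the shape-factor series
#' with its stable-stage means, plus the slab velocity profile with a
#' shear-rate fit.
#'
#' @param trajectory Path to an extended-XYZ or dump file.
#' @param topology Optional path to a [write_topology()] sidecar.
#' @param n_slabs Slabs for the velocity profile.
#' @param report Optional path: write a plain-text summary there.
#' @return List of class `dpd_report` with elements `frames`, `phase`,
#'   `shape` (series or NULL), `stable` (tibble or NULL), `profile`,
#'   `shear_fit` (or NULL).
#' @export
analyze_trajectory <- function(trajectory, topology = NULL, n_slabs = 20,
                               report = NULL) {
  frames <- read_trajectory(trajectory, partial = TRUE)
  if (length(frames) == 0) abort("no complete frames in trajectory")
  topo <- if (!is.null(topology)) read_topology(topology) else NULL
  last <- frames[[length(frames)]]
  phase <- classify_phase(last, topo)
  shape <- stable <- NULL
  if (!is.null(topo) && nrow(topo$chains) > 0) {
    shape <- mean_shape_factor(frames, topo)
    stable <- stable_mean(shape)
  }
  profile <- velocity_profile(frames, n_slabs)
  fit <- tryCatch(shear_rate(profile), error = function(e) NULL)
  out <- structure(list(frames = frames, phase = phase, shape = shape,
                        stable = stable, profile = profile, shear_fit = fit),
                   class = "dpd_report")
  if (!is.null(report)) {
    lines <- c(sprintf("frames: %d", length(frames)),
               sprintf("phase: %s", phase$label))
    if (!is.null(stable)) {
      lines <- c(lines, sprintf("stable <delta> type %d: %.4f",
                                stable$type, stable$mean_delta))
    }
    if (!is.null(fit)) {
      lines <- c(lines, sprintf("shear rate: %.4g /tau (R^2 = %.3f)",
                                fit$gamma_dot, fit$r_squared))
    }
    writeLines(lines, report)
  }
  out
}

#' @export
print.dpd_report <- function(x, ...) {
  cat(sprintf("<dpd_report> %d frames; phase %s\n", length(x$frames), x$phase$label))
  if (!is.null(x$stable)) print(x$stable)
  if (!is.null(x$shear_fit)) print(x$shear_fit)
  invisible(x)
}
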