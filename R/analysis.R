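axis_index <- function(axis) {
  i <- match(axis, c("x", "y", "z"))
  if (is.na(i)) abort("axis must be one of 'x', 'y', 'z'")
  i
}

lipid_species <- c("H1", "T1", "H2", "T2")
head_species <- c("H1", "H2")
tail_species <- c("T1", "T2")

species_subset_idx <- function(sys, species) {
  if (is.null(species)) return(seq_len(nrow(sys$pos)))
  which(.species_levels[sys$species] %in% species)
}

#' One-dimensional per-species bead density profile
#'
#' Histogram of bead positions along one box axis, converted to number
#' density by the slab volume `L^2 * bin_width`. Densities integrate exactly
#' to the per-species bead counts.
#'
#' @param sys A `dpd_system`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param n_bins Number of bins (>= 2).
#' @param species Character vector of species labels to include (default:
#'   all five).
#' @return A tibble of class `dpd_density_profile` with columns `species`,
#'   `bin`, `pos` (bin centre), `count`, `density` (rc^-3).
#' @export
density_profile <- function(sys, axis = "z", n_bins = 60, species = NULL) {
  stopifnot(inherits(sys, "dpd_system"), n_bins >= 2)
  ai <- axis_index(axis)
  L <- sys$box
  bw <- L / n_bins
  if (is.null(species)) species <- .species_levels
  labs <- .species_levels[sys$species]
  out <- purrr::map_dfr(species, function(sp) {
    sel <- labs == sp
    b <- pmin(floor(sys$pos[sel, ai] / bw) + 1L, n_bins)
    cnt <- tabulate(b, n_bins)
    tibble(species = sp, bin = seq_len(n_bins), pos = (seq_len(n_bins) - 0.5) * bw,
           count = cnt, density = cnt / (bw * L^2))
  })
  attr(out, "axis") <- axis
  attr(out, "bin_width") <- bw
  attr(out, "box") <- L
  class(out) <- c("dpd_density_profile", class(out))
  out
}

plane_axes <- function(plane) {
  switch(plane,
         xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L),
         abort("plane must be one of 'xy', 'xz', 'yz'"))
}

#' Two-dimensional projected occupancy map
#'
#' Projects bead positions onto a box plane and counts them on a regular
#' grid; used for pore and disc diagnostics.
#'
#' @param sys A `dpd_system`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param n_bins Grid resolution per axis (>= 2).
#' @param species Species labels to include (default: the four lipid species).
#' @param subset Optional integer bead indices to restrict to (applied after
#'   the species filter).
#' @return Tibble of class `dpd_density_map` with `i`, `j`, `u`, `v`
#'   (cell centres), `count`, `density` (projected, rc^-2... per cell area
#'   times box depth; `count` is what the diagnostics use).
#' @export
density_map_2d <- function(sys, plane = "xy", n_bins = 30, species = lipid_species,
                           subset = NULL) {
  stopifnot(inherits(sys, "dpd_system"), n_bins >= 2)
  ax <- plane_axes(plane)
  L <- sys$box
  bw <- L / n_bins
  idx <- species_subset_idx(sys, species)
  if (!is.null(subset)) idx <- intersect(idx, subset)
  iu <- pmin(floor(sys$pos[idx, ax[1]] / bw) + 1L, n_bins)
  iv <- pmin(floor(sys$pos[idx, ax[2]] / bw) + 1L, n_bins)
  cnt <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(iu)) cnt[iu[k], iv[k]] <- cnt[iu[k], iv[k]] + 1L
  out <- tibble(i = rep(seq_len(n_bins), n_bins),
                j = rep(seq_len(n_bins), each = n_bins),
                u = (rep(seq_len(n_bins), n_bins) - 0.5) * bw,
                v = (rep(seq_len(n_bins), each = n_bins) - 0.5) * bw,
                count = as.vector(cnt))
  out$density <- out$count / (bw * bw * L)
  attr(out, "plane") <- plane
  attr(out, "n_bins") <- n_bins
  class(out) <- c("dpd_density_map", class(out))
  out
}

# largest connected empty patch (4-connectivity, periodic) of a 2D count grid
largest_empty_patch <- function(counts, n_bins) {
  m <- matrix(counts, n_bins, n_bins)
  empty <- m == 0
  seen <- matrix(FALSE, n_bins, n_bins)
  best <- 0L
  for (s in which(empty & !seen)) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      ci <- (cur - 1L) %% n_bins + 1L
      cj <- (cur - 1L) %/% n_bins + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- (ci - 1L + d[1]) %% n_bins + 1L
        nj <- (cj - 1L + d[2]) %% n_bins + 1L
        k <- ni + (nj - 1L) * n_bins
        if (empty[k] && !seen[k]) {
          seen[k] <- TRUE
          stack <- c(stack, k)
        }
      }
    }
    best <- max(best, size)
  }
  best
}

#' Unwrap a bonded chain across periodic boundaries
#'
#' Walks the beads in order, adding minimum-image displacements, so that
#' consecutive beads are geometrically adjacent. Required before any
#' gyration-tensor computation: moments are meaningless on wrapped
#' coordinates.
#'
#' @param pos n x 3 matrix of wrapped bead positions in chain order.
#' @param L Box side.
#' @return n x 3 matrix of unwrapped positions (first bead unchanged).
#' @export
unwrap_chain <- function(pos, L) {
  if (nrow(pos) < 2) return(pos)
  d <- diff(pos)
  d <- d - L * round(d / L)
  rbind(pos[1, , drop = FALSE],
        sweep(apply(d, 2, cumsum), 2, pos[1, ], "+"))
}

#' Gyration tensor of a bead chain
#'
#' The 3x3 second-moment tensor of bead positions about the chain centroid,
#' `G_ab = (1/N) sum_i (r_ia - rc_a)(r_ib - rc_b)`, with eigenvalues sorted
#' in decreasing order. Positions must be unwrapped (see [unwrap_chain()]).
#'
#' @param pos n x 3 matrix of unwrapped bead positions.
#' @return Object of class `dpd_gyration`: list with `tensor` (3x3),
#'   `eigenvalues` (length 3, decreasing), `n`.
#' @export
gyration_tensor <- function(pos) {
  pos <- rbind(pos)
  n <- nrow(pos)
  if (n == 0) abort("empty chain")
  cen <- sweep(pos, 2, colMeans(pos))
  g <- crossprod(cen) / n
  ev <- sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  structure(list(tensor = g, eigenvalues = ev, n = n), class = "dpd_gyration")
}

#' Shape factor from gyration-tensor eigenvalues
#'
#' `delta = 1 - 3 (L1 L2 + L2 L3 + L1 L3) / (L1 + L2 + L3)^2` on the three
#' eigenvalues `L1 >= L2 >= L3` of the gyration tensor (each an `L^2`
#' moment). `delta = 0` for an isotropic (spherical) mass distribution and
#' 1 for collinear beads (rod); intermediate shapes fall in between (a thin
#' planar ring evaluates to 0.25). A degenerate all-zero tensor returns 0
#' by convention.
#'
#' @param g A `dpd_gyration` object or a numeric vector of 3 eigenvalues.
#' @return `delta` in `[0, 1]`.
#' @examples
#' shape_factor(c(1, 1, 1))  # sphere: 0
#' shape_factor(c(1, 0, 0))  # rod: 1
#' @export
shape_factor <- function(g) {
  ev <- if (inherits(g, "dpd_gyration")) g$eigenvalues else as.numeric(g)
  stopifnot(length(ev) == 3)
  s <- sum(ev)
  if (s <= 0) return(0)
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[1] * ev[3]) / s^2
}

#' Per-chain shape factors of one configuration
#'
#' Unwraps every chain, computes its gyration tensor and shape factor.
#'
#' @param sys A `dpd_system`.
#' @param topo A `dpd_topology`.
#' @return Tibble with `chain`, `type`, `delta`.
#' @export
chain_shape_factors <- function(sys, topo) {
  stopifnot(inherits(sys, "dpd_system"), inherits(topo, "dpd_topology"))
  delta <- vapply(seq_len(nrow(topo$chains)), function(k) {
    idx <- chain_indices(topo, k)
    shape_factor(gyration_tensor(unwrap_chain(sys$pos[idx, , drop = FALSE],
                                              sys$box)))
  }, numeric(1))
  tibble(chain = topo$chains$chain, type = topo$chains$type, delta = delta)
}

#' Shape-factor time series over a trajectory
#'
#' Per-frame mean shape factor for each lipid species.
#'
#' @param frames List of `dpd_system` frames (e.g. `run$frames`).
#' @param topo A `dpd_topology`.
#' @return Tibble of class `dpd_shape_series` with `time`, `type`,
#'   `mean_delta`, `n_chains`.
#' @seealso [stable_mean()] for the stable-stage average.
#' @export
mean_shape_factor <- function(frames, topo) {
  if (inherits(frames, "dpd_run")) frames <- frames$frames
  if (inherits(frames, "dpd_system")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  out <- purrr::map_dfr(frames, function(f) {
    sf <- chain_shape_factors(f, topo)
    sf |>
      dplyr::group_by(.data$type) |>
      dplyr::summarise(mean_delta = mean(.data$delta),
                       n_chains = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(time = f$time, .before = 1)
  })
  class(out) <- c("dpd_shape_series", class(out))
  out
}

#' Stable-stage mean of a shape-factor series
#'
#' Averages the per-frame means over the final fraction of the covered time
#' window (default: the final third, the stable stage), weighting frames by
#' chain count.
#'
#' @param series A [mean_shape_factor()] tibble.
#' @param fraction Trailing fraction of the time window to average over.
#' @param by_type Return one row per species (TRUE) or a single pooled mean.
#' @return Tibble with `type` (if `by_type`) and `mean_delta`, `n_frames`.
#' @export
stable_mean <- function(series, fraction = 1 / 3, by_type = TRUE) {
  t0 <- min(series$time)
  t1 <- max(series$time)
  cut <- t1 - fraction * (t1 - t0)
  st <- dplyr::filter(series, .data$time >= cut)
  grp <- if (by_type) dplyr::group_by(st, .data$type) else st
  dplyr::summarise(grp,
                   mean_delta = sum(.data$mean_delta * .data$n_chains) /
                     sum(.data$n_chains),
                   n_frames = length(unique(.data$time)),
                   .groups = "drop")
}

# periodic (circular) spread of coordinates along one axis: 0 = concentrated
circular_spread <- function(x, L) {
  th <- 2 * pi * x / L
  1 - sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

circular_mean <- function(x, L) {
  th <- 2 * pi * x / L
  (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * L) %% L
}

# bilayer normal: axis along which the tail beads are most concentrated
bilayer_normal <- function(sys) {
  tails <- species_subset_idx(sys, tail_species)
  if (length(tails) == 0) return(NA_integer_)
  which.min(vapply(1:3, function(a) circular_spread(sys$pos[tails, a], sys$box),
                   numeric(1)))
}

#' Leaflet occupancy counts for a bilayer
#'
#' Splits a bilayer at the midplane through the tail-bead centre of mass
#' (periodic circular mean along the bilayer normal) and counts, per lipid
#' species, the chains whose first head bead lies on each side. The
#' right/left naming follows the positive/negative side of the normal axis.
#'
#' @param sys A `dpd_system`.
#' @param topo A `dpd_topology`.
#' @param normal Normal axis (`"x"`, `"y"`, `"z"`) or NULL to auto-detect
#'   as the axis of smallest periodic tail spread.
#' @return Tibble with one row: `time`, `n_typeI_right`, `n_typeII_left`,
#'   `n_typeI`, `n_typeII`, `normal`, `midplane`.
#' @export
mixing_counts <- function(sys, topo, normal = NULL) {
  stopifnot(inherits(sys, "dpd_system"), inherits(topo, "dpd_topology"))
  ai <- if (is.null(normal)) bilayer_normal(sys) else axis_index(normal)
  if (is.na(ai)) abort("no tail beads: cannot identify a bilayer")
  L <- sys$box
  tails <- species_subset_idx(sys, tail_species)
  mid <- circular_mean(sys$pos[tails, ai], L)
  headpos <- sys$pos[topo$chains$first, ai]
  d <- headpos - mid
  d <- d - L * round(d / L)
  right <- d > 0
  t1 <- topo$chains$type == 1L
  tibble(time = sys$time,
         n_typeI_right = sum(right & t1),
         n_typeII_left = sum(!right & !t1),
         n_typeI = sum(t1), n_typeII = sum(!t1),
         normal = c("x", "y", "z")[ai], midplane = mid)
}

#' Periodic-aware clustering of a bead subset
#'
#' Connected components of the contact graph whose edges join beads at
#' minimum-image distance at most `cutoff`. Each component also reports
#' whether it connects to its own periodic image along each axis (the
#' spanning dimensions used by the phase classifier) and its centroid.
#'
#' @param sys A `dpd_system`.
#' @param species Species labels to cluster (default: the four lipid
#'   species); or give explicit `subset` indices.
#' @param subset Optional integer bead indices (overrides `species`).
#' @param cutoff Contact distance in rc (default 1, the interaction range).
#' @return Object of class `dpd_clusters`: list with `clusters` (tibble:
#'   `cluster`, `size`, `spans_x/y/z`, `n_span`, centroid columns), `labels`
#'   (cluster id per selected bead), `indices` (the selected bead indices).
#' @export
cluster_beads <- function(sys, species = lipid_species, subset = NULL,
                          cutoff = 1.0) {
  stopifnot(inherits(sys, "dpd_system"), cutoff > 0)
  idx <- if (!is.null(subset)) subset else species_subset_idx(sys, species)
  if (length(idx) == 0) {
    return(structure(list(clusters = tibble(cluster = integer(0)),
                          labels = integer(0), indices = integer(0)),
                     class = "dpd_clusters"))
  }
  cl <- cluster_cpp(sys$pos[idx, , drop = FALSE], sys$box, cutoff)
  ord <- order(cl$sizes, decreasing = TRUE)
  rank <- match(seq_along(cl$sizes), ord)
  clusters <- tibble(cluster = seq_along(ord),
                     size = cl$sizes[ord],
                     spans_x = cl$spanning[ord, 1],
                     spans_y = cl$spanning[ord, 2],
                     spans_z = cl$spanning[ord, 3],
                     cx = cl$centroid[ord, 1],
                     cy = cl$centroid[ord, 2],
                     cz = cl$centroid[ord, 3])
  clusters$n_span <- clusters$spans_x + clusters$spans_y + clusters$spans_z
  structure(list(clusters = clusters, labels = rank[cl$labels], indices = idx),
            class = "dpd_clusters")
}

#' @export
print.dpd_clusters <- function(x, ...) {
  cat(sprintf("<dpd_clusters> %d clusters over %d beads\n",
              nrow(x$clusters), length(x$indices)))
  print(head(x$clusters, 5))
  invisible(x)
}

#' Classify the aggregate morphology of a configuration
#'
#' Heuristic decision tree on the largest lipid-bead cluster:
#' \itemize{
#'   \item spanning 2 or 3 box dimensions: a membrane; perforated (PDL) if
#'     the in-plane occupancy grid of the membrane contains a connected
#'     empty patch of at least `min_pore_cells` cells, else intact (DL);
#'   \item spanning exactly 1 dimension: cylinder-like; a hierarchical disc
#'     stack (HD) if the head-bead density along the spanning axis shows at
#'     least `min_head_peaks` alternating peaks anti-correlated with the
#'     tail density, else an elongated micelle;
#'   \item spanning 0 dimensions: a vesicle if a detached pocket of at least
#'     `min_enclosed_water` water beads is enclosed near the aggregate,
#'     else a micelle.
#' }
#' Diagnostics are retained for audit. The label is deterministic and
#' invariant under bead reordering.
#'
#' @param sys A `dpd_system`.
#' @param topo A `dpd_topology` (currently unused beyond validation; the
#'   decision tree works on bead species).
#' @param cutoff Contact cutoff for clustering, rc.
#' @param min_pore_cells Minimum empty-patch size (cells of ~1 rc) for PDL.
#' @param min_head_peaks Minimum head-density peaks along the axis for HD.
#' @param min_enclosed_water Minimum detached water-pocket size for vesicle.
#' @return Object of class `dpd_phase`: list with `label` (one of
#'   `"DL"`, `"PDL"`, `"HD"`, `"micelle"`, `"vesicle"`, `"unclassified"`),
#'   `ambiguous` flag, and `diagnostics` tibble.
#' @export
classify_phase <- function(sys, topo = NULL, cutoff = 1.0,
                           min_pore_cells = 4, min_head_peaks = 2,
                           min_enclosed_water = 5) {
  stopifnot(inherits(sys, "dpd_system"))
  diags <- list()
  lip <- species_subset_idx(sys, lipid_species)
  if (length(lip) == 0) {
    return(structure(list(label = "unclassified", ambiguous = FALSE,
                          diagnostics = tibble(metric = "n_lipid_beads", value = 0)),
                     class = "dpd_phase"))
  }
  cl <- cluster_beads(sys, species = lipid_species, cutoff = cutoff)
  main <- cl$clusters[1, ]
  ambiguous <- nrow(cl$clusters) > 1 && cl$clusters$size[2] > 0.5 * main$size
  main_idx <- cl$indices[cl$labels == main$cluster]
  nspan <- main$n_span
  diags$n_clusters <- nrow(cl$clusters)
  diags$main_size <- main$size
  diags$n_span <- nspan
  L <- sys$box

  label <- if (nspan >= 2) {
    # membrane: find normal, look for pores in the projected occupancy
    normal <- if (nspan == 2) {
      which(!c(main$spans_x, main$spans_y, main$spans_z))[1]
    } else {
      which.min(vapply(1:3, function(a)
        circular_spread(sys$pos[main_idx, a], L), numeric(1)))
    }
    plane <- c("yz", "xz", "xy")[normal]
    nb <- max(4L, floor(L))
    m2 <- density_map_2d(sys, plane = plane, n_bins = nb,
                         species = lipid_species, subset = main_idx)
    pore <- largest_empty_patch(m2$count, nb)
    diags$pore_cells <- pore
    if (pore >= min_pore_cells) "PDL" else "DL"
  } else if (nspan == 1) {
    axisn <- which(c(main$spans_x, main$spans_y, main$spans_z))[1]
    labs <- .species_levels[sys$species[main_idx]]
    nb <- max(6L, floor(L))
    bw <- L / nb
    bins <- pmin(floor(sys$pos[main_idx, axisn] / bw) + 1L, nb)
    hprof <- tabulate(bins[labs %in% head_species], nb)
    tprof <- tabulate(bins[labs %in% tail_species], nb)
    sm <- function(v) (v + c(tail(v, 1), head(v, -1)) + c(tail(v, -1), head(v, 1))) / 3
    hs <- sm(hprof)
    ts <- sm(tprof)
    prv <- c(tail(hs, 1), head(hs, -1))
    nxt <- c(tail(hs, -1), head(hs, 1))
    peaks <- sum(hs > prv & hs >= nxt & hs > 1.2 * mean(hs))
    anti <- if (sd(hs) > 0 && sd(ts) > 0) suppressWarnings(stats::cor(hs, ts)) else 0
    diags$head_peaks <- peaks
    diags$head_tail_cor <- anti
    if (peaks >= min_head_peaks && anti < 0) "HD" else "micelle"
  } else {
    wat <- cluster_beads(sys, species = "W", cutoff = cutoff)
    enclosed <- 0L
    if (nrow(wat$clusters) > 1) {
      pockets <- wat$clusters[-1, ]
      pockets <- pockets[pockets$size >= min_enclosed_water, , drop = FALSE]
      if (nrow(pockets) > 0) {
        # count pockets near the aggregate centroid as enclosed
        ctr <- c(main$cx, main$cy, main$cz)
        d <- sweep(as.matrix(pockets[, c("cx", "cy", "cz")]), 2, ctr)
        d <- d - L * round(d / L)
        enclosed <- sum(sqrt(rowSums(d^2)) < L / 2)
      }
    }
    diags$enclosed_water_pockets <- enclosed
    if (enclosed > 0) "vesicle" else "micelle"
  }
  diagnostics <- tibble(metric = names(diags), value = as.numeric(unlist(diags)))
  structure(list(label = label, ambiguous = ambiguous,
                 diagnostics = diagnostics, clusters = cl$clusters),
            class = "dpd_phase")
}

#' @export
print.dpd_phase <- function(x, ...) {
  cat(sprintf("<dpd_phase> %s%s\n", x$label,
              if (x$ambiguous) " (ambiguous: comparable second aggregate)" else ""))
  print(x$diagnostics)
  invisible(x)
}

# least-squares SSE of y ~ x over index range [i, j], from cumulative sums
make_seg_sse <- function(x, y) {
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  cxy <- cumsum(x * y)
  function(i, j) {
    n <- j - i + 1
    s <- function(cs) cs[j] - if (i > 1) cs[i - 1] else 0
    sx <- s(cx); sy <- s(cy)
    sxx <- s(cx2) - sx^2 / n
    syy <- s(cy2) - sy^2 / n
    sxy <- s(cxy) - sx * sy / n
    if (sxx <= 0) return(max(syy, 0))
    max(syy - sxy^2 / sxx, 0)
  }
}

#' Segment an energy relaxation series into dynamic stages
#'
#' Fits piecewise-linear models with 1, 2 or 3 segments (changepoints on a
#' grid of sample indices, minimum segment length a tenth of the series)
#' to the smoothed energy-versus-time curve and selects the segment count
#' by BIC. Self-assembly runs typically resolve into a fast initial decay,
#' a slow adjustment, and a stable plateau; dense systems often merge the
#' last two.
#'
#' @param energy Tibble with columns `time` and the energy to segment.
#' @param value Column name of the energy (default `"total"`).
#' @param max_stages Maximum number of stages to consider (2 or 3).
#' @param ratio Model-selection threshold: an extra changepoint is accepted
#'   only while it reduces the residual sum of squares below `ratio` times
#'   the simpler model's (default 0.5).
#' @return Tibble of class `dpd_stages` with `stage`, `label`, `t_start`,
#'   `t_end`.
#' @export
segment_stages <- function(energy, value = "total", max_stages = 3,
                           ratio = 0.5) {
  stopifnot(nrow(energy) >= 100)
  tt <- energy$time
  yy <- energy[[value]]
  k <- max(3L, round(length(yy) / 50))
  if (k %% 2 == 0) k <- k + 1L
  ys <- stats::filter(yy, rep(1 / k, k), sides = 2)
  keep <- !is.na(ys)
  tt <- tt[keep]
  ys <- as.numeric(ys[keep])
  n <- length(ys)
  sse <- make_seg_sse(tt, ys)
  minlen <- max(5L, floor(n / 10))
  s1tot <- sse(1, n)
  cand <- seq(minlen, n - minlen)
  best <- list(nseg = 1, cuts = integer(0))
  if (length(cand) > 0) {
    sse_left <- vapply(cand, function(c1) sse(1, c1), numeric(1))
    sse_right <- vapply(cand, function(c1) sse(c1 + 1, n), numeric(1))
    tot2 <- sse_left + sse_right
    i2 <- which.min(tot2)
    if (tot2[i2] < ratio * s1tot) {
      best <- list(nseg = 2, cuts = cand[i2])
      if (max_stages >= 3 && n >= 3 * minlen) {
        s3best <- Inf
        cuts3 <- NULL
        for (ci in seq_along(cand)) {
          c1 <- cand[ci]
          cand2 <- cand[cand >= c1 + minlen]
          if (length(cand2) == 0) next
          tot3 <- sse_left[ci] +
            vapply(cand2, function(c2) sse(c1 + 1, c2) + sse(c2 + 1, n),
                   numeric(1))
          i3 <- which.min(tot3)
          if (tot3[i3] < s3best) {
            s3best <- tot3[i3]
            cuts3 <- c(c1, cand2[i3])
          }
        }
        if (s3best < ratio * tot2[i2]) best <- list(nseg = 3, cuts = cuts3)
      }
    }
  }
  bounds <- c(tt[1], tt[best$cuts], tt[n])
  labels <- switch(best$nseg,
                   "stable",
                   c("initial", "stable"),
                   c("initial", "adjustment", "stable"))
  if (best$nseg == 1 && diff(range(ys)) > 0.1 * abs(mean(ys))) {
    warn("no clear plateau detected: returning a single stage")
  }
  out <- tibble(stage = seq_len(best$nseg), label = labels,
                t_start = bounds[-length(bounds)], t_end = bounds[-1])
  class(out) <- c("dpd_stages", class(out))
  out
}
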