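#' Write trajectory frames
#'
#' Writes one or more configurations as extended-XYZ (default) or a
#' LAMMPS-dump-style text dialect. Extended-XYZ frames carry the cubic box
#' and time on the comment line
#' (`Lattice="L 0 0 0 L 0 0 0 L" Properties=species:S:1:pos:R:3:velo:R:3 Time=t`);
#' the dump dialect uses the
#' `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS pp pp pp / ATOMS id type x y z vx vy vz`
#' layout with species coded 1-5 in the order H1, T1, H2, T2, W.
#'
#' @param frames A `dpd_system` or list of them.
#' @param path Output file.
#' @param format `"xyz"` or `"dump"`.
#' @param dt Time step used to derive the dump TIMESTEP from frame time.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, format = c("xyz", "dump"), dt = 0.01) {
  format <- match.arg(format)
  if (inherits(frames, "dpd_system")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$pos)
    body <- cbind(format(f$pos, trim = TRUE, digits = 10),
                  format(f$vel, trim = TRUE, digits = 10))
    if (format == "xyz") {
      writeLines(as.character(n), con)
      writeLines(sprintf(
        'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:velo:R:3 Time=%g',
        f$box, f$box, f$box, f$time), con)
      writeLines(paste(.species_levels[f$species],
                       apply(body, 1, paste, collapse = " ")), con)
    } else {
      writeLines(c("ITEM: TIMESTEP",
                   as.character(round(f$time / dt)),
                   "ITEM: NUMBER OF ATOMS",
                   as.character(n),
                   "ITEM: BOX BOUNDS pp pp pp",
                   rep(sprintf("0 %g", f$box), 3),
                   "ITEM: ATOMS id type x y z vx vy vz"), con)
      writeLines(paste(seq_len(n), f$species,
                       apply(body, 1, paste, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read trajectory frames
#'
#' Reads extended-XYZ or LAMMPS-dump-style files written by
#' [write_trajectory()] (auto-detected from the first line).
#'
#' @param path Input file.
#' @param dt Time step used to convert dump TIMESTEP back to tau.
#' @param partial If TRUE, a truncated trailing frame is dropped with a
#'   warning and the complete frames are returned; if FALSE (default) a
#'   truncated file is an error naming the frame.
#' @return List of `dpd_system` frames.
#' @export
read_trajectory <- function(path, dt = 0.01, partial = FALSE) {
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("empty trajectory file: %s", path))
  dump <- startsWith(lines[1], "ITEM:")
  frames <- list()
  i <- 1L
  k <- 0L
  bad <- function(k, why) {
    msg <- sprintf("truncated or malformed frame %d in %s (%s)", k, path, why)
    if (partial) {
      warn(paste0(msg, "; returning prior frames"))
      return(TRUE)
    }
    abort(msg)
  }
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    if (dump) {
      if (i + 8 > length(lines)) { bad(k, "incomplete header"); break }
      step <- as.numeric(lines[i + 1])
      n <- as.integer(lines[i + 3])
      box <- as.numeric(strsplit(trimws(lines[i + 5]), "\\s+")[[1]])[2]
      first <- i + 9L
      last <- first + n - 1L
      if (last > length(lines)) { bad(k, "incomplete atom block"); break }
      m <- matrix(scan(text = lines[first:last], quiet = TRUE), nrow = n, byrow = TRUE)
      if (ncol(m) < 8) { bad(k, "missing columns"); break }
      ord <- order(m[, 1])
      m <- m[ord, , drop = FALSE]
      frames[[k]] <- new_dpd_system(m[, 3:5, drop = FALSE], m[, 6:8, drop = FALSE],
                                    as.integer(m[, 2]), box, step * dt)
      i <- last + 1L
    } else {
      n <- suppressWarnings(as.integer(lines[i]))
      if (is.na(n)) { bad(k, "bad atom count"); break }
      if (i + 1 + n > length(lines)) { bad(k, "incomplete atom block"); break }
      hdr <- lines[i + 1]
      box <- as.numeric(sub('.*Lattice="([0-9.eE+-]+) .*', "\\1", hdr))
      tm <- if (grepl("Time=", hdr)) {
        as.numeric(sub(".*Time=([0-9.eE+-]+).*", "\\1", hdr))
      } else 0
      rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
      if (any(lengths(rows) < 7)) { bad(k, "missing columns"); break }
      sp <- species_index(vapply(rows, `[[`, "", 1))
      num <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:7))), nrow = n, byrow = TRUE)
      frames[[k]] <- new_dpd_system(num[, 1:3, drop = FALSE], num[, 4:6, drop = FALSE],
                                    sp, box, tm)
      i <- i + 2L + n
    }
  }
  frames[!vapply(frames, is.null, logical(1))]
}

#' Write a topology sidecar
#'
#' Plain-text bond/angle list: lines `bond i j` and `angle i j k` with
#' 0-based bead indices, preceded by `chain first length type nh nt` lines
#' describing each chain.
#'
#' @param topo A `dpd_topology`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("nbeads %d", topo$n_beads), con)
  if (nrow(topo$chains) > 0) {
    writeLines(sprintf("chain %d %d %d %d %d",
                       topo$chains$first - 1L, topo$chains$length,
                       topo$chains$type, topo$chains$nh, topo$chains$nt), con)
  }
  if (nrow(topo$bonds) > 0) {
    writeLines(sprintf("bond %d %d", topo$bonds[, 1] - 1L, topo$bonds[, 2] - 1L), con)
  }
  if (nrow(topo$angles) > 0) {
    writeLines(sprintf("angle %d %d %d", topo$angles[, 1] - 1L,
                       topo$angles[, 2] - 1L, topo$angles[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a topology sidecar
#'
#' @param path File written by [write_topology()].
#' @return A `dpd_topology`.
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  tok <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
  kw <- vapply(tok, `[[`, "", 1)
  nums <- lapply(tok, function(t) as.integer(t[-1]))
  nbeads <- nums[[which(kw == "nbeads")[1]]][1]
  ch <- nums[kw == "chain"]
  chains <- if (length(ch)) {
    m <- do.call(rbind, ch)
    tibble(chain = seq_len(nrow(m)), type = m[, 3], first = m[, 1] + 1L,
           nh = m[, 4], nt = m[, 5], length = m[, 2])
  } else tibble()
  bonds <- if (any(kw == "bond")) do.call(rbind, nums[kw == "bond"]) + 1L else
    matrix(integer(0), 0, 2)
  angles <- if (any(kw == "angle")) do.call(rbind, nums[kw == "angle"]) + 1L else
    matrix(integer(0), 0, 3)
  new_dpd_topology(chains, bonds, angles, nbeads)
}

#' Write an energy series as tab-separated text
#'
#' Columns: step, time_tau, KE, PE_pair, PE_bond, PE_angle, total, kBT.
#'
#' @param energy Energy tibble from [run_dpd()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(energy, path) {
  df <- as.data.frame(energy)
  names(df) <- c("step", "time_tau", "KE", "PE_pair", "PE_bond", "PE_angle",
                 "total", "kBT")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an energy series written by [write_energy_table()]
#' @param path Input file.
#' @return Energy tibble with the package's column names.
#' @export
read_energy_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  names(df) <- c("step", "time", "kinetic", "pe_pair", "pe_bond", "pe_angle",
                 "total", "kBT")
  as_tibble(df)
}

#' Read a sectioned key-value run configuration
#'
#' Flat INI-style text: `[section]` headers followed by `key = value`
#' lines; `#` starts a comment. Values are parsed as numbers where
#' possible. The `[forcefield]` section may give `profile = paper_defaults`
#' to pull in the bundled default parameter set.
#'
#' @param path Config file.
#' @return Nested named list, one element per section.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (!is.na(num)) num else val
    }
  }
  out
}

#' Write a run configuration
#' @param config Nested named list as from [read_run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sec in names(config)) {
    writeLines(sprintf("[%s]", sec), con)
    for (key in names(config[[sec]])) {
      writeLines(sprintf("%s = %s", key, format(config[[sec]][[key]])), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
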