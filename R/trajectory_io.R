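# Structure / trajectory / config / results input-output.
# PDB and DCD reading delegate to bio3d; the PDB and DCD writers are small
# formatters of our own (no installed package writes DCD). All coordinates
# cross the package boundary in nm; PDB and DCD files store Angstrom.

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records into a topology plus a single-frame trajectory.
#' PDB coordinates (Angstrom) are converted to nm exactly once, here.
#' Masses are assigned from the element column (falling back to bio3d's
#' atom-name based element inference); an unknown element is an error naming
#' the offending atom. Hydrogens are retained when present.
#'
#' @param path PDB file.
#' @return list with `topology` (an [abd_topology]) and `trajectory`
#'   (an [abd_trajectory] with one frame).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("Structure file not found: %s", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) abort(sprintf("No ATOM records in %s", path))
  element <- trimws(at$elesy %||% "")
  blank <- is.na(element) | element == ""
  if (any(blank)) element[blank] <- bio3d::atom2ele(at$elety[blank], rescue = TRUE)
  atoms <- tibble(
    atom_name = trimws(at$elety),
    element = element,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    residue_number = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    residue_name = trimws(at$resid)
  )
  atoms$mass <- mass_from_element(atoms$element, atoms$atom_name)
  topology <- abd_topology(atoms)
  coords <- cbind(at$x, at$y, at$z) / 10 # Angstrom -> nm
  list(topology = topology, trajectory = abd_trajectory(coords, topology, times = 0))
}

#' Write a topology + coordinates as a PDB file
#'
#' Fixed-width PDB ATOM records; nm coordinates are written as Angstrom.
#'
#' @param topology an [abd_topology].
#' @param coords `N x 3` matrix in nm (defaults to zeros).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, coords, path) {
  stopifnot(nrow(coords) == nrow(topology), ncol(coords) == 3)
  xyz <- coords * 10 # nm -> Angstrom
  name4 <- function(nm, el) {
    # PDB alignment rule: 1-letter elements start in column 14
    ifelse(nchar(nm) >= 4L | nchar(el) == 2L,
           formatC(nm, width = -4), paste0(" ", formatC(nm, width = -3)))
  }
  lines <- sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    (topology$atom_index %% 99999L) + 1L,
    name4(topology$atom_name, topology$element), "",
    formatC(topology$residue_name, width = 3),
    substr(topology$chain_id, 1, 1),
    topology$residue_number %% 10000L,
    topology$insert,
    xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00,
    toupper(topology$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a trajectory file (DCD)
#'
#' Reads a CHARMM/NAMD-style DCD file via bio3d and attaches a topology.
#' Coordinates are converted from Angstrom to nm. XTC is not supported by
#' the R toolchain; requests for `.xtc` files raise an informative error.
#'
#' @param path DCD file.
#' @param topology the [abd_topology] the frames index; atom counts must match.
#' @param dt frame spacing in ps used to construct frame times (default 1).
#' @return an [abd_trajectory].
#' @export
read_trajectory <- function(path, topology, dt = 1) {
  if (!file.exists(path)) abort(sprintf("Trajectory file not found: %s", path))
  if (grepl("\\.xtc$", path, ignore.case = TRUE)) {
    abort("XTC reading is not supported; convert to DCD (e.g. with `mdconvert`).")
  }
  mat <- tryCatch(
    bio3d::read.dcd(path, verbose = FALSE),
    error = function(e) abort(sprintf("Failed to read DCD '%s': %s", path, conditionMessage(e)))
  )
  n_atoms_file <- ncol(mat) / 3L
  if (n_atoms_file != nrow(topology)) {
    abort(sprintf(
      "Atom-count mismatch: trajectory has %d atoms, topology has %d.",
      n_atoms_file, nrow(topology)
    ))
  }
  nf <- nrow(mat)
  coords <- array(0, c(nf, n_atoms_file, 3L))
  for (d in 1:3) coords[, , d] <- mat[, seq(d, ncol(mat), by = 3L), drop = FALSE] / 10
  abd_trajectory(coords, topology, times = (seq_len(nf) - 1) * dt)
}

#' Write a trajectory as a DCD file
#'
#' Classic CHARMM DCD layout (84-byte header record, one float32 record per
#' coordinate axis per frame, little-endian). Coordinates are written in
#' Angstrom, so a round trip through [read_trajectory] reproduces nm values
#' to float32 precision (~1e-8 nm).
#'
#' @param traj an [abd_trajectory].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  record <- function(bytes) {
    writeBin(length(bytes), con, size = 4L, endian = "little")
    writeBin(bytes, con)
    writeBin(length(bytes), con, size = 4L, endian = "little")
  }
  as_bytes <- function(writer) {
    rc <- rawConnection(raw(0), "wb")
    writer(rc)
    out <- rawConnectionValue(rc)
    close(rc)
    out
  }
  icntrl <- integer(20)
  icntrl[1] <- nf       # frames in file
  icntrl[2] <- 1L       # first step
  icntrl[3] <- 1L       # save frequency
  icntrl[4] <- nf       # total steps
  icntrl[20] <- 24L     # CHARMM version tag
  record(as_bytes(function(c2) {
    writeChar("CORD", c2, 4L, eos = NULL)
    writeBin(as.integer(icntrl), c2, size = 4L, endian = "little")
  }))
  record(as_bytes(function(c2) {
    writeBin(1L, c2, size = 4L, endian = "little")
    writeChar(formatC("Written by abdyn", width = 80, flag = "-"), c2, 80L, eos = NULL)
  }))
  record(as_bytes(function(c2) writeBin(as.integer(na), c2, size = 4L, endian = "little")))
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      vals <- as.numeric(traj$coords[f, , d]) * 10 # nm -> Angstrom
      record(as_bytes(function(c2) writeBin(vals, c2, size = 4L, endian = "little")))
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Domain / analysis configuration (YAML)

#' Default analysis parameters
#'
#' Hydrogen-bond cutoffs (hydrogen-acceptor distance < 0.25 nm, strict, and
#' donor-hydrogen-acceptor angle > 120 degrees, strict), occupancy threshold
#' (> 0.80 of analyzed frames), minimum replicates for a stable bond (2) and
#' the per-atom pulling force magnitude (0.01 kcal/mol/nm).
#'
#' @return named list of parameters.
#' @export
default_parameters <- function() {
  list(
    hbond_distance_cutoff = 0.25, # nm, strict <
    hbond_angle_cutoff = 120,     # degrees, strict >
    occupancy_threshold = 0.80,   # strict >
    min_replicates = 2L,
    pull_force = 0.01,            # kcal/mol/nm per atom
    include_hydrogens_in_com = TRUE
  )
}

.fragment_labels <- c("Fc", "Fab1", "Fab2", "hinge", "other")
.bead_labels <- c(
  "Fc_CH3", "Fc_CH2", "Fab1_CH1_CL", "Fab1_VH_VL", "Fab2_CH1_CL", "Fab2_VH_VL"
)

validate_selection <- function(sel, where) {
  if (!is.list(sel) || is.null(sel$chain)) {
    abort(sprintf("%s: each selection needs a 'chain' key.", where))
  }
  resid <- sel$resid %||% c(-Inf, Inf)
  if (length(resid) != 2 || resid[1] > resid[2]) {
    abort(sprintf("%s: 'resid' must be an increasing [start, end] pair.", where))
  }
  list(chain = as.character(sel$chain), resid = as.numeric(resid))
}

#' Read a domain/analysis configuration
#'
#' The configuration is a YAML file with keys `mode` (`"antibody"` or
#' `"generic"`), `beads` (a list of `{id, label, select}` entries, where
#' `select` is a list of `{chain, resid: [start, end]}` selections),
#' optional `fragments` (named lists of selections for atoms outside beads,
#' e.g. hinge residues or non-bead donors/acceptors) and optional
#' `parameters` overriding [default_parameters()]. Antibody mode requires
#' exactly the six beads 1..6; unknown keys anywhere are rejected;
#' selections claimed by two beads are an error.
#'
#' @param path YAML file.
#' @return validated config list with elements `mode`, `beads`, `fragments`,
#'   `parameters`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Validate a configuration list
#' @param raw list with the structure documented in [read_config()].
#' @return validated config list.
#' @export
validate_config <- function(raw) {
  allowed_top <- c("mode", "beads", "fragments", "parameters")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  mode <- raw$mode %||% "antibody"
  if (!mode %in% c("antibody", "generic")) abort("mode must be 'antibody' or 'generic'.")
  if (is.null(raw$beads) || length(raw$beads) == 0) abort("Config must define beads.")
  beads <- lapply(seq_along(raw$beads), function(i) {
    b <- raw$beads[[i]]
    unknown_b <- setdiff(names(b), c("id", "label", "select"))
    if (length(unknown_b) > 0) {
      abort(paste0("Unknown bead keys: ", paste(unknown_b, collapse = ", ")))
    }
    if (is.null(b$id)) abort(sprintf("Bead %d has no id.", i))
    if (is.null(b$select) || length(b$select) == 0) {
      abort(sprintf("Bead %s has an empty selection.", b$id))
    }
    sels <- lapply(b$select, validate_selection, where = sprintf("bead %s", b$id))
    list(id = as.integer(b$id), label = b$label %||% paste0("bead_", b$id),
         select = sels)
  })
  ids <- vapply(beads, function(b) b$id, integer(1))
  if (anyDuplicated(ids)) abort("Duplicate bead ids in config.")
  if (mode == "antibody" && !identical(sort(ids), 1:6)) {
    abort("Antibody mode requires exactly beads 1..6.")
  }
  # selection-level overlap check: same chain with intersecting residue ranges
  flat <- do.call(rbind, lapply(beads, function(b) {
    do.call(rbind, lapply(b$select, function(s) {
      data.frame(id = b$id, chain = s$chain, lo = s$resid[1], hi = s$resid[2])
    }))
  }))
  if (nrow(flat) > 1) {
    for (i in seq_len(nrow(flat) - 1)) {
      for (j in seq(i + 1, nrow(flat))) {
        if (flat$id[i] != flat$id[j] && flat$chain[i] == flat$chain[j] &&
            flat$lo[i] <= flat$hi[j] && flat$lo[j] <= flat$hi[i]) {
          abort(sprintf(
            "Beads %d and %d both claim chain %s residues [%g, %g] x [%g, %g].",
            flat$id[i], flat$id[j], flat$chain[i],
            flat$lo[i], flat$hi[i], flat$lo[j], flat$hi[j]
          ))
        }
      }
    }
  }
  fragments <- list()
  if (!is.null(raw$fragments)) {
    bad <- setdiff(names(raw$fragments), .fragment_labels)
    if (length(bad) > 0) {
      abort(paste0("Unknown fragment labels: ", paste(bad, collapse = ", ")))
    }
    fragments <- lapply(names(raw$fragments), function(fr) {
      lapply(raw$fragments[[fr]], validate_selection, where = sprintf("fragment %s", fr))
    })
    names(fragments) <- names(raw$fragments)
  }
  params <- default_parameters()
  if (!is.null(raw$parameters)) {
    unknown_p <- setdiff(names(raw$parameters), names(params))
    if (length(unknown_p) > 0) {
      abort(paste0("Unknown parameters: ", paste(unknown_p, collapse = ", ")))
    }
    params[names(raw$parameters)] <- raw$parameters
  }
  list(mode = mode, beads = beads, fragments = fragments, parameters = params)
}

#' Write a configuration list as YAML
#' @param config a validated config list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result writing

#' Write analysis results to a directory
#'
#' Data frames are written as CSV (deterministic column order as given);
#' scalar/list summaries as JSON; a `manifest.json` records the package
#' version and all parameters/seeds passed in `manifest`. Writers are
#' deterministic given identical inputs.
#'
#' @param results named list; data-frame elements become `<name>.csv`,
#'   everything else `<name>.json`.
#' @param out_dir output directory, created if needed.
#' @param manifest named list of run parameters and seeds.
#' @return tibble of written files, invisibly.
#' @export
write_results <- function(results, out_dir, manifest = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(sprintf("Output directory is not writable: %s", out_dir))
  }
  if (length(results) > 0 && is.null(names(results))) abort("results must be named.")
  written <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(x, f, row.names = FALSE)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    written <- c(written, f)
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(list(package = "abdyn", version = as.character(utils::packageVersion("abdyn"))),
      manifest),
    mf, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(tibble(file = c(written, mf)))
}
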