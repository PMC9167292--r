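# Core containers: atom table (topology) and coordinate trajectory.

# Masses (amu) by element symbol, IUPAC 2021 standard atomic weights.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38, FE = 55.845,
  MN = 54.938, CU = 63.546, CO = 58.933, NI = 58.693
)

mass_from_element <- function(element, atom_name = NULL) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    label <- if (!is.null(atom_name)) atom_name[bad] else "?"
    abort(sprintf(
      "Unknown element '%s' for atom '%s' (index %d); cannot assign a mass.",
      element[bad], label, bad - 1L
    ))
  }
  unname(m)
}

# Residue names treated as amino acids (Calpha selection, glycan exclusion).
.amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "MSE", "SEC", "PYL"
)

is_amino_acid <- function(residue_name) toupper(residue_name) %in% .amino_acids

#' Build an atom table (topology)
#'
#' A topology is a tibble with one row per atom and columns `atom_index`
#' (0-based, contiguous), `atom_name`, `element`, `mass` (amu), `chain_id`,
#' `residue_number` (author numbering as found in the input file),
#' `insert` (PDB insertion code, `""` if none) and `residue_name`.
#' The `(chain_id, residue_number, insert, atom_name)` combination must be
#' unique and all masses positive.
#'
#' @param atoms data frame with at least `atom_name`, `chain_id`,
#'   `residue_number`, `residue_name`; `element`, `mass`, `insert` are
#'   filled in if missing (`element` guessed from the first letter of
#'   `atom_name` only when absent).
#' @return a `abd_topology` tibble.
#' @export
abd_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("atom_name", "chain_id", "residue_number", "residue_name")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("Topology is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("Topology must contain at least one atom.")
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!"element" %in% names(atoms)) {
    atoms$element <- gsub("[^A-Za-z].*$", "", substr(trimws(atoms$atom_name), 1, 1))
  }
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- mass_from_element(atoms$element, atoms$atom_name)
  }
  atoms$atom_index <- seq_len(nrow(atoms)) - 1L
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms <- atoms[, c(
    "atom_index", "atom_name", "element", "mass",
    "chain_id", "residue_number", "insert", "residue_name"
  )]
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("All atom masses must be positive and finite.")
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insert, atoms$atom_name)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("Duplicate atom identity in topology: %s", dup))
  }
  structure(atoms, class = c("abd_topology", class(tibble())),
            chains = unique(atoms$chain_id))
}

#' Chain identifiers of a topology, in file order
#' @param topology an `abd_topology`.
#' @return character vector of chain ids.
#' @export
chains <- function(topology) attr(topology, "chains") %||% unique(topology$chain_id)

#' Residue key combining author numbering and insertion code
#' @param topology an `abd_topology`.
#' @return character vector, one entry per atom.
#' @export
residue_key <- function(topology) {
  paste0(topology$chain_id, ":", topology$residue_number, topology$insert)
}

#' Build a trajectory
#'
#' A trajectory couples an `F x N x 3` coordinate array (nm) with per-frame
#' times (ps) and the topology whose atoms it indexes.
#'
#' @param coords numeric array `F x N x 3` in nm, or an `N x 3` matrix for a
#'   single frame.
#' @param topology the `abd_topology` the coordinates index.
#' @param times numeric vector of frame times in ps (default `0:(F-1)`).
#' @return an `abd_trajectory` object.
#' @export
abd_trajectory <- function(coords, topology, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), ncol(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("Coordinates must be an F x N x 3 array.")
  }
  n_frames <- dim(coords)[1]
  if (n_frames < 1L) abort("A trajectory needs at least one frame.")
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf(
      "Coordinate atom count (%d) does not match topology atom count (%d).",
      dim(coords)[2], nrow(topology)
    ))
  }
  if (!all(is.finite(coords))) abort("Trajectory coordinates must be finite.")
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames) abort("times must have one entry per frame.")
  structure(
    list(coords = coords, times = as.numeric(times), topology = topology),
    class = "abd_trajectory"
  )
}

#' @export
print.abd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<abd_trajectory> %d frame(s), %d atoms, t = %g..%g ps\n",
    n_frames(x), nrow(x$topology), min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `abd_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an N x 3 matrix (nm)
#' @param traj an `abd_trajectory`.
#' @param frame 1-based frame number.
#' @return `N x 3` numeric matrix.
#' @export
frame_coords <- function(traj, frame = 1L) {
  if (frame < 1L || frame > n_frames(traj)) {
    abort(sprintf("Frame %d out of range 1..%d.", frame, n_frames(traj)))
  }
  matrix(traj$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @method tidy abd_trajectory
#' @export
tidy.abd_trajectory <- function(x, ...) {
  nf <- n_frames(x); na <- nrow(x$topology)
  tibble(
    frame = rep(seq_len(nf), each = na),
    time = rep(x$times, each = na),
    atom_index = rep(x$topology$atom_index, times = nf),
    x = as.vector(t(x$coords[, , 1, drop = TRUE])),
    y = as.vector(t(x$coords[, , 2, drop = TRUE])),
    z = as.vector(t(x$coords[, , 3, drop = TRUE]))
  )
}
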