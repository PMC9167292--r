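# Mapping atoms to the six antibody beads and the Fc/Fab1/Fab2 fragments,
# and reducing trajectories to mass-weighted bead centers.
#
# Bead numbering follows the six-bead antibody coarse-graining:
#   1 Fc CH3, 2 Fc CH2, 3 Fab1 CH1+CL, 4 Fab1 VH+VL, 5 Fab2 CH1+CL, 6 Fab2 VH+VL.
# Fragments derive from beads (Fc = 1 u 2, Fab1 = 3 u 4, Fab2 = 5 u 6); atoms
# outside all beads (hinge residues, glycans, planted donor/acceptor triads)
# get their fragment from the config's explicit `fragments` selections, else
# "other".

bead_fragment <- function(bead_id) {
  c("Fc", "Fc", "Fab1", "Fab1", "Fab2", "Fab2")[bead_id]
}

selection_matches <- function(topology, sels) {
  hit <- rep(FALSE, nrow(topology))
  for (s in sels) {
    hit <- hit | (topology$chain_id == s$chain &
                    topology$residue_number >= s$resid[1] &
                    topology$residue_number <= s$resid[2])
  }
  hit
}

#' Assign atoms to beads and fragments
#'
#' Every atom matched by a bead selection is mapped to exactly one bead (an
#' atom claimed by two beads is an error, as is a bead matching zero atoms).
#' Glycan residues (non amino-acid residue names) are never auto-assigned to
#' beads. Unselected atoms carry no bead but receive a fragment label from
#' the config's `fragments` selections, defaulting to `"other"`.
#'
#' @param topology an [abd_topology].
#' @param config validated config from [read_config()] / [validate_config()].
#' @return tibble with one row per atom: `atom_index`, `bead_id` (NA outside
#'   beads), `bead_label`, `fragment`, `mass`; bead atom counts in
#'   `attr(, "bead_counts")`.
#' @export
assign_beads <- function(topology, config) {
  n <- nrow(topology)
  bead_id <- rep(NA_integer_, n)
  bead_label <- rep(NA_character_, n)
  protein <- is_amino_acid(topology$residue_name)
  for (b in config$beads) {
    hit <- selection_matches(topology, b$select) & protein
    if (!any(hit)) {
      abort(sprintf("Bead %d (%s) selects zero atoms.", b$id, b$label))
    }
    clash <- hit & !is.na(bead_id)
    if (any(clash)) {
      i <- which(clash)[1]
      abort(sprintf(
        "Atom %d (%s %s%d) claimed by beads %d and %d.",
        topology$atom_index[i], topology$atom_name[i],
        topology$chain_id[i], topology$residue_number[i], bead_id[i], b$id
      ))
    }
    bead_id[hit] <- b$id
    bead_label[hit] <- b$label
  }
  fragment <- ifelse(is.na(bead_id), NA_character_, bead_fragment(bead_id))
  for (fr in names(config$fragments)) {
    hit <- selection_matches(topology, config$fragments[[fr]])
    conflict <- hit & !is.na(fragment) & fragment != fr
    if (any(conflict)) {
      i <- which(conflict)[1]
      abort(sprintf(
        "Atom %d has bead-derived fragment %s but is selected for fragment %s.",
        topology$atom_index[i], fragment[i], fr
      ))
    }
    fragment[hit & is.na(fragment)] <- fr
  }
  fragment[is.na(fragment)] <- "other"
  out <- tibble(
    atom_index = topology$atom_index,
    bead_id = bead_id,
    bead_label = bead_label,
    fragment = fragment,
    mass = topology$mass
  )
  counts <- table(bead_id)
  attr(out, "bead_counts") <- setNames(as.integer(counts), names(counts))
  class(out) <- c("abd_assignment", class(out))
  out
}

#' Mass-weighted center of a set of atoms
#'
#' @param coords `N x 3` matrix (nm) for one frame.
#' @param subset integer vector of 0-based atom indices (or logical mask).
#' @param masses per-atom masses (amu), full length or subset length.
#' @return 3-vector in nm.
#' @export
center_of_mass <- function(coords, subset, masses) {
  if (is.logical(subset)) subset <- which(subset) - 1L
  if (length(subset) == 0) abort("center_of_mass: empty atom subset.")
  idx <- subset + 1L
  m <- if (length(masses) == nrow(coords)) masses[idx] else masses
  if (length(m) != length(idx)) abort("masses must match the subset or all atoms.")
  if (any(m <= 0)) abort("center_of_mass: masses must be positive.")
  colSums(coords[idx, , drop = FALSE] * m) / sum(m)
}

#' Reduce a trajectory to per-frame bead centers
#'
#' @param traj an [abd_trajectory].
#' @param assignment atom-to-bead map from [assign_beads()].
#' @return tibble of class `abd_beads` with columns `frame`, `time`,
#'   `bead_id`, `bead_label`, `x`, `y`, `z` (nm); per-bead total masses in
#'   `attr(, "bead_masses")`.
#' @export
compute_bead_trajectory <- function(traj, assignment) {
  sel <- !is.na(assignment$bead_id)
  ids <- sort(unique(assignment$bead_id[sel]))
  nf <- n_frames(traj)
  rows <- vector("list", length(ids))
  masses <- numeric(length(ids))
  for (k in seq_along(ids)) {
    b <- ids[k]
    idx <- which(assignment$bead_id == b & sel) # 1-based row numbers
    m <- assignment$mass[idx]
    masses[k] <- sum(m)
    w <- m / sum(m)
    # weighted mean over atoms, vectorized across frames
    cx <- traj$coords[, idx, 1, drop = FALSE]
    cy <- traj$coords[, idx, 2, drop = FALSE]
    cz <- traj$coords[, idx, 3, drop = FALSE]
    dim(cx) <- dim(cy) <- dim(cz) <- c(nf, length(idx))
    rows[[k]] <- tibble(
      frame = seq_len(nf),
      time = traj$times,
      bead_id = b,
      bead_label = assignment$bead_label[idx[1]],
      x = as.vector(cx %*% w),
      y = as.vector(cy %*% w),
      z = as.vector(cz %*% w)
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$frame, .data$bead_id)
  attr(out, "bead_masses") <- setNames(masses, ids)
  class(out) <- c("abd_beads", class(tibble()))
  out
}

#' Bead centers of one frame as a matrix
#' @param beads an `abd_beads` tibble.
#' @param frame 1-based frame number.
#' @return matrix with one row per bead (rownames = bead ids), columns x,y,z.
#' @export
bead_matrix <- function(beads, frame = 1L) {
  fb <- beads[beads$frame == frame, ]
  if (nrow(fb) == 0) abort(sprintf("No beads for frame %d.", frame))
  m <- as.matrix(fb[, c("x", "y", "z")])
  rownames(m) <- fb$bead_id
  m
}

#' Per-frame center of mass of a whole fragment
#' @param traj an [abd_trajectory].
#' @param assignment from [assign_beads()].
#' @param fragment fragment label, e.g. `"Fc"`.
#' @return tibble `frame`, `time`, `x`, `y`, `z`.
#' @export
fragment_com <- function(traj, assignment, fragment) {
  idx <- which(assignment$fragment == fragment)
  if (length(idx) == 0) abort(sprintf("Fragment '%s' has no atoms.", fragment))
  m <- assignment$mass[idx]
  w <- m / sum(m)
  nf <- n_frames(traj)
  comp <- function(d) {
    md <- traj$coords[, idx, d, drop = FALSE]
    dim(md) <- c(nf, length(idx))
    as.vector(md %*% w)
  }
  tibble(frame = seq_len(nf), time = traj$times,
         x = comp(1), y = comp(2), z = comp(3))
}
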