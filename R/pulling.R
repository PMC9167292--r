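# Constant-force pulling assay: force specification on the Fc and Fab2
# atom groups, endpoint external work, rupture detection, and the
# Fc-Fab2 center-of-mass separation series.
#
# The external work between two structures is
#   W = sum_i f_Fab2 (R_i . r_hat) - sum_j f_Fc (R_j . r_hat),
# with R_i the raw displacement of atom i between the end and start frames
# and r_hat the unit vector from COM(Fc) to COM(Fab2) in the start frame.
# No superposition is applied before taking displacements, which makes W
# frame-of-reference sensitive; the choice is recorded in the run manifest.

#' Build a constant-force pulling specification
#'
#' Per-atom force vectors are `+f * r_hat` on every Fab2 atom and
#' `-f * r_hat` on every Fc atom, with `r_hat` the unit vector between the
#' mass-weighted fragment centers in the initial frame. Per-atom magnitudes
#' are constant, so net group forces are unbalanced when the atom counts
#' differ; no correction is applied.
#'
#' @param topology an [abd_topology].
#' @param assignment from [assign_beads()].
#' @param initial_frame `N x 3` coordinates (nm) of the start structure.
#' @param f per-atom force magnitude in kcal/mol/nm (default 0.01); applied
#'   to both groups (`f_fc = f_fab2 = f`) unless overridden.
#' @param f_fc,f_fab2 optional distinct per-atom magnitudes.
#' @return an `abd_pulling_spec`: atom index vectors `group_fc`,
#'   `group_fab2` (0-based), magnitudes, and `r_hat`.
#' @export
build_pulling_spec <- function(topology, assignment, initial_frame,
                               f = 0.01, f_fc = f, f_fab2 = f) {
  if (f_fc < 0 || f_fab2 < 0) abort("Force magnitudes must be >= 0.")
  fc <- which(assignment$fragment == "Fc")
  fab2 <- which(assignment$fragment == "Fab2")
  if (length(fc) == 0 || length(fab2) == 0) {
    abort("Both Fc and Fab2 fragments must be non-empty.")
  }
  com_fc <- center_of_mass(initial_frame, fc - 1L, topology$mass)
  com_fab2 <- center_of_mass(initial_frame, fab2 - 1L, topology$mass)
  r <- com_fab2 - com_fc
  nr <- sqrt(sum(r * r))
  if (nr == 0) abort("Fc and Fab2 centers of mass coincide; pulling direction undefined.")
  structure(
    list(
      group_fc = fc - 1L,
      group_fab2 = fab2 - 1L,
      f_fc = f_fc,
      f_fab2 = f_fab2,
      r_hat = r / nr,
      com_fc = com_fc,
      com_fab2 = com_fab2
    ),
    class = "abd_pulling_spec"
  )
}

#' @export
print.abd_pulling_spec <- function(x, ...) {
  cat(sprintf(
    "<abd_pulling_spec> f_Fc = %g, f_Fab2 = %g kcal/mol/nm on %d Fc / %d Fab2 atoms; r_hat = (%.3f, %.3f, %.3f)\n",
    x$f_fc, x$f_fab2, length(x$group_fc), length(x$group_fab2),
    x$r_hat[1], x$r_hat[2], x$r_hat[3]
  ))
  invisible(x)
}

#' Per-atom force table of a pulling spec
#'
#' One row per pulled atom with its constant force vector in kcal/mol/nm;
#' atoms outside both groups are absent. Optionally written as CSV for an
#' external MD engine.
#'
#' @param spec an `abd_pulling_spec`.
#' @param path optional CSV output path.
#' @return tibble `atom_index`, `fx`, `fy`, `fz`.
#' @export
export_force_table <- function(spec, path = NULL) {
  tbl <- dplyr::bind_rows(
    tibble(
      atom_index = spec$group_fc,
      fx = -spec$f_fc * spec$r_hat[1],
      fy = -spec$f_fc * spec$r_hat[2],
      fz = -spec$f_fc * spec$r_hat[3]
    ),
    tibble(
      atom_index = spec$group_fab2,
      fx = spec$f_fab2 * spec$r_hat[1],
      fy = spec$f_fab2 * spec$r_hat[2],
      fz = spec$f_fab2 * spec$r_hat[3]
    )
  ) |> dplyr::arrange(.data$atom_index)
  if (!is.null(path)) write.csv(tbl, path, row.names = FALSE)
  tbl
}

#' Read a per-atom force table written by [export_force_table()]
#' @param path CSV file.
#' @return tibble `atom_index`, `fx`, `fy`, `fz`.
#' @export
read_force_table <- function(path) {
  as_tibble(read.csv(path))
}

#' External work between two structures
#'
#' Endpoint form of the constant-force work: displacements of the pulled
#' atoms between `frame_end` and `frame_start` are projected on `r_hat` and
#' summed with their force magnitudes. `W = fab2_term - fc_term` exactly.
#'
#' @param spec an `abd_pulling_spec`.
#' @param frame_start,frame_end `N x 3` coordinate matrices (nm) sharing the
#'   spec's topology.
#' @return an `abd_work` list: `W`, `fab2_term`, `fc_term` (kcal/mol).
#' @export
compute_work <- function(spec, frame_start, frame_end) {
  if (!all(dim(frame_start) == dim(frame_end))) {
    abort("Start and end frames have mismatched dimensions.")
  }
  n_needed <- max(c(spec$group_fc, spec$group_fab2)) + 1L
  if (nrow(frame_start) < n_needed) {
    abort("Frames have fewer atoms than the pulling spec references.")
  }
  disp <- frame_end - frame_start
  proj <- as.numeric(disp %*% spec$r_hat)
  fab2_term <- spec$f_fab2 * sum(proj[spec$group_fab2 + 1L])
  fc_term <- spec$f_fc * sum(proj[spec$group_fc + 1L])
  structure(
    list(W = fab2_term - fc_term, fab2_term = fab2_term, fc_term = fc_term),
    class = "abd_work"
  )
}

#' @export
print.abd_work <- function(x, ...) {
  cat(sprintf("<abd_work> W = %.6g kcal/mol (Fab2 term %.6g, Fc term %.6g)\n",
              x$W, x$fab2_term, x$fc_term))
  invisible(x)
}

#' @method tidy abd_work
#' @export
tidy.abd_work <- function(x, ...) {
  tibble(term = c("W", "fab2_term", "fc_term"),
         value = c(x$W, x$fab2_term, x$fc_term))
}

#' Detect rupture in a bond-count series
#'
#' Rupture is the first frame at which the count is zero and stays zero for
#' at least `sustain_frames` consecutive frames; transient rebinding before
#' a sustained zero run is ignored.
#'
#' @param counts tibble from [bond_count_series()] (or an integer vector).
#' @param sustain_frames minimum zero-run length (>= 1).
#' @return 1-based rupture frame index, or `NA_integer_` if none.
#' @export
detect_rupture <- function(counts, sustain_frames = 1L) {
  if (sustain_frames < 1) abort("sustain_frames must be >= 1.")
  v <- if (is.data.frame(counts)) counts$count else counts
  if (length(v) == 0) return(NA_integer_)
  r <- rle(v == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain_frames)
  if (length(hit) == 0) NA_integer_ else as.integer(starts[hit[1]])
}

#' Fc-Fab2 (or any two-fragment) center-of-mass separation series
#'
#' Distance between the mass-weighted centers of two whole fragments
#' (all fragment atoms, not bead centers), per frame.
#'
#' @param traj an [abd_trajectory].
#' @param assignment from [assign_beads()].
#' @param fragments two fragment labels (default `c("Fc", "Fab2")`).
#' @return tibble `frame`, `time`, `separation` (nm).
#' @export
com_separation_series <- function(traj, assignment, fragments = c("Fc", "Fab2")) {
  if (length(fragments) != 2) abort("Exactly two fragment labels are required.")
  a <- fragment_com(traj, assignment, fragments[1])
  b <- fragment_com(traj, assignment, fragments[2])
  tibble(
    frame = a$frame, time = a$time,
    separation = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  )
}
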