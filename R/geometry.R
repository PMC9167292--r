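# Inter-bead geometric observables: distances R_ij (nm), angles theta_ijk
# (degrees, vertex at the middle bead) and signed dihedrals Theta_ijkl
# (degrees in (-180, 180], IUPAC right-hand rule about the j->k axis).
# Vectorized kernels take n x 3 matrices; scalar wrappers take 3-vectors
# and raise on degenerate geometry.

.rad2deg <- 180 / pi

as_rowmat <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else p
}

row_norm <- function(m) sqrt(rowSums(m * m))

cross_rows <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

geom_distance <- function(p, q) {
  p <- as_rowmat(p); q <- as_rowmat(q)
  row_norm(q - p)
}

# Angle at vertex j between arms j->i and j->k; NA where an arm has zero length.
geom_angle <- function(pi_, pj, pk) {
  pi_ <- as_rowmat(pi_); pj <- as_rowmat(pj); pk <- as_rowmat(pk)
  u <- pi_ - pj
  v <- pk - pj
  nu <- row_norm(u); nv <- row_norm(v)
  bad <- nu == 0 | nv == 0
  cosang <- rowSums(u * v) / (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  out <- acos(cosang) * .rad2deg
  out[bad] <- NA_real_
  out
}

# Signed torsion i-j-k-l, right-hand rule about j->k; NA where i,j,k or j,k,l
# are collinear (undefined plane) or the j-k axis vanishes.
geom_dihedral <- function(pi_, pj, pk, pl) {
  pi_ <- as_rowmat(pi_); pj <- as_rowmat(pj); pk <- as_rowmat(pk); pl <- as_rowmat(pl)
  b1 <- pj - pi_
  b2 <- pk - pj
  b3 <- pl - pk
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  nb2 <- row_norm(b2)
  bad <- nb2 == 0 | row_norm(n1) == 0 | row_norm(n2) == 0
  b2_hat <- b2 / pmax(nb2, .Machine$double.xmin)
  x <- rowSums(n1 * n2)
  y <- rowSums(cross_rows(n1, n2) * b2_hat)
  out <- atan2(y, x) * .rad2deg
  out[bad] <- NA_real_
  # fold -180 to +180 so the range is (-180, 180]
  out[!is.na(out) & out <= -180] <- 180
  out
}

#' Euclidean distance between two points
#' @param p,q 3-vectors in nm.
#' @return distance in nm.
#' @export
bead_distance <- function(p, q) {
  as.numeric(geom_distance(p, q))
}

#' Angle subtended at the middle point
#'
#' The vertex is `p_j` (for theta_ijk listed as i, j, k the pivot bead is j).
#' Computed as the arccos of the normalized dot product of the two arms,
#' clamped to `[-1, 1]`.
#'
#' @param p_i,p_j,p_k 3-vectors in nm; `p_j` is the vertex.
#' @return angle in degrees in `[0, 180]`.
#' @export
bead_angle <- function(p_i, p_j, p_k) {
  out <- as.numeric(geom_angle(p_i, p_j, p_k))
  if (anyNA(out)) abort("Degenerate geometry: angle arm of zero length.")
  out
}

#' Signed dihedral angle of four points
#'
#' Torsion of the planes (i,j,k) and (j,k,l), signed by the right-hand rule
#' about the j->k axis, in `(-180, 180]`. Collinear i,j,k or j,k,l leave the
#' plane undefined and raise an error.
#'
#' @param p_i,p_j,p_k,p_l 3-vectors in nm.
#' @return dihedral in degrees.
#' @export
bead_dihedral <- function(p_i, p_j, p_k, p_l) {
  out <- as.numeric(geom_dihedral(p_i, p_j, p_k, p_l))
  if (anyNA(out)) abort("Degenerate geometry: collinear points leave the dihedral undefined.")
  out
}

#' Declare a geometric measure over beads
#'
#' @param kind `"distance"`, `"angle"` or `"dihedral"`.
#' @param bead_indices 2, 3 or 4 distinct bead ids (for angles the middle
#'   listed bead is the vertex).
#' @param label optional label; defaults to `R_ij` / `theta_ijk` /
#'   `Theta_ijkl` built from the indices.
#' @return a `measure_spec` list.
#' @export
measure_spec <- function(kind, bead_indices, label = NULL) {
  kind <- match.arg(kind, c("distance", "angle", "dihedral"))
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  if (length(bead_indices) != need) {
    abort(sprintf("A %s needs %d bead indices, got %d.", kind, need, length(bead_indices)))
  }
  if (anyDuplicated(bead_indices)) abort("Bead indices of a measure must be distinct.")
  if (is.null(label)) {
    prefix <- c(distance = "R", angle = "theta", dihedral = "Theta")[[kind]]
    label <- paste0(prefix, "_", paste(bead_indices, collapse = ""))
  }
  structure(list(kind = kind, bead_indices = as.integer(bead_indices), label = label),
            class = "measure_spec")
}

#' The default six-bead antibody measure set
#'
#' The nine observables of the six-bead analysis: Fab-Fc displacements R_23
#' and R_25, Fab-Fc orientations theta_123 and theta_125, Fc-Fab dihedrals
#' Theta_1234 and Theta_1256, intra-Fab displacements R_34 and R_56, and the
#' intra-Fc displacement R_12.
#'
#' @return list of [measure_spec()] objects.
#' @export
default_antibody_measures <- function() {
  list(
    measure_spec("distance", c(2, 3)),
    measure_spec("distance", c(2, 5)),
    measure_spec("angle", c(1, 2, 3)),
    measure_spec("angle", c(1, 2, 5)),
    measure_spec("dihedral", c(1, 2, 3, 4)),
    measure_spec("dihedral", c(1, 2, 5, 6)),
    measure_spec("distance", c(3, 4)),
    measure_spec("distance", c(5, 6)),
    measure_spec("distance", c(1, 2))
  )
}

#' Evaluate geometric measures over a bead trajectory
#'
#' Returns one frame-aligned series per measure. Frames with degenerate
#' geometry (zero-length angle arm, collinear dihedral points) are reported
#' via a warning naming the frames, carry `NA` values, and are excluded from
#' downstream density estimation.
#'
#' @param beads `abd_beads` tibble from [compute_bead_trajectory()].
#' @param specs list of [measure_spec()]; default [default_antibody_measures()].
#' @return tibble of class `abd_series`: `frame`, `time`, `label`, `kind`,
#'   `value` (nm or degrees).
#' @export
evaluate_measures <- function(beads, specs = default_antibody_measures()) {
  if (inherits(specs, "measure_spec")) specs <- list(specs)
  ids <- sort(unique(beads$bead_id))
  # one n_frames x 3 matrix per bead
  pos <- lapply(ids, function(b) {
    fb <- beads[beads$bead_id == b, ]
    as.matrix(fb[order(fb$frame), c("x", "y", "z")])
  })
  names(pos) <- ids
  frames <- sort(unique(beads$frame))
  times <- beads$time[match(frames, beads$frame)]
  out <- lapply(specs, function(sp) {
    miss <- setdiff(sp$bead_indices, ids)
    if (length(miss) > 0) {
      abort(sprintf("Measure %s references missing bead(s) %s.",
                    sp$label, paste(miss, collapse = ", ")))
    }
    p <- lapply(as.character(sp$bead_indices), function(b) pos[[b]])
    value <- switch(sp$kind,
      distance = geom_distance(p[[1]], p[[2]]),
      angle = geom_angle(p[[1]], p[[2]], p[[3]]),
      dihedral = geom_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    )
    if (anyNA(value)) {
      warn(sprintf(
        "Measure %s is degenerate at frame(s) %s; values set to NA.",
        sp$label, paste(frames[is.na(value)], collapse = ", ")
      ))
    }
    tibble(frame = frames, time = times, label = sp$label, kind = sp$kind,
           value = value)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("abd_series", class(tibble()))
  out
}
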