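# Fc-aligned essential dynamics: Kabsch superposition of every frame onto
# the Fc Calpha atoms of a reference frame, PCA of the aligned Calpha
# coordinate covariance (population 1/F normalization), per-frame component
# projections with per-fragment partial sums, and per-atom contribution
# vectors for porcupine-style rendering.

#' Select Calpha atoms
#'
#' All atoms named `CA` in amino-acid residues, in file order. Calcium ions
#' and glycan atoms are never selected (residue-name filter).
#'
#' @param topology an [abd_topology].
#' @return integer vector of 0-based atom indices.
#' @export
select_calpha <- function(topology) {
  idx <- which(toupper(topology$atom_name) == "CA" &
                 is_amino_acid(topology$residue_name))
  if (length(idx) == 0) abort("Topology contains no Calpha atoms.")
  topology$atom_index[idx]
}

# Kabsch: proper rotation R and translation minimizing RMSD of P onto Q
# (both n x 3, rows paired). Returns list(R, t) with y = x %*% R + t.
kabsch_transform <- function(P, Q) {
  if (nrow(P) < 3) abort("Alignment needs at least 3 atoms.")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (qr(P0)$rank < 2) abort("Alignment subset is collinear or degenerate.")
  H <- crossprod(P0, Q0) # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u) # so that P0 %*% t(R) ~ Q0
  R <- t(R)                                 # y = x %*% R
  list(R = R, t = as.numeric(cq - cp %*% R))
}

#' Rigidly align every frame to a reference
#'
#' Least-squares (Kabsch) superposition of the `alignment_subset` atoms of
#' each frame onto those of `reference_frame`; the proper rotation
#' (determinant +1) and translation are then applied to all atoms of the
#' frame. Mirror solutions are never returned.
#'
#' @param traj an [abd_trajectory].
#' @param alignment_subset 0-based atom indices used for the fit (e.g. the
#'   Fc Calpha atoms); at least 3 non-collinear atoms.
#' @param reference_frame 1-based frame number of the reference (default 1).
#' @return an [abd_trajectory] of aligned coordinates.
#' @export
align_frames <- function(traj, alignment_subset, reference_frame = 1L) {
  idx <- alignment_subset + 1L
  if (length(idx) < 3) abort("Alignment needs at least 3 atoms.")
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  nf <- n_frames(traj)
  out <- traj$coords
  for (f in seq_len(nf)) {
    fr <- matrix(traj$coords[f, , ], ncol = 3)
    tr <- kabsch_transform(fr[idx, , drop = FALSE], ref)
    out[f, , ] <- sweep(fr %*% tr$R, 2, tr$t, `+`)
  }
  abd_trajectory(out, traj$topology, traj$times)
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b `n x 3` matrices (nm), rows paired.
#' @return RMSD in nm.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Essential-dynamics PCA of Calpha coordinates
#'
#' Builds the `3M`-dimensional coordinate vector of the selected atoms per
#' frame, removes the mean structure, and eigen-decomposes the population
#' covariance (`1/F`). Eigenvalues (nm^2) are sorted descending; each
#' eigenvector's sign is fixed so its largest-magnitude entry is positive,
#' making outputs deterministic. Atom order within eigenvectors is
#' `(x1, y1, z1, x2, ...)` over `atom_subset`.
#'
#' @param traj an aligned [abd_trajectory] (see [align_frames()]).
#' @param atom_subset 0-based atom indices (e.g. from [select_calpha()]).
#' @param n_components number of components to retain (default all).
#' @return an `abd_ed` object with `mean_coordinates` (M x 3),
#'   `eigenvalues`, `eigenvectors` (3M x K), `projections` (F x K),
#'   `atom_indices`, `total_variance`, `times`.
#' @export
fit_essential_dynamics <- function(traj, atom_subset, n_components = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) abort("PCA needs at least two frames.")
  idx <- atom_subset + 1L
  M <- length(idx)
  X <- matrix(0, nf, 3L * M)
  for (d in 1:3) {
    m <- traj$coords[, idx, d, drop = FALSE]
    dim(m) <- c(nf, M)
    X[, seq(d, 3L * M, by = 3L)] <- m
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf
  eg <- eigen(C, symmetric = TRUE)
  k <- n_components %||% ncol(eg$vectors)
  k <- min(k, ncol(eg$vectors))
  values <- pmax(eg$values, 0)[seq_len(k)]
  vectors <- eg$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vectors[, j]))
    if (vectors[i_max, j] < 0) vectors[, j] <- -vectors[, j]
  }
  structure(
    list(
      mean_coordinates = matrix(mu, M, 3, byrow = TRUE,
                                dimnames = list(NULL, c("x", "y", "z"))),
      eigenvalues = values,
      eigenvectors = vectors,
      projections = Xc %*% vectors,
      displacements = Xc,
      atom_indices = atom_subset,
      total_variance = sum(pmax(eg$values, 0)),
      trace_covariance = sum(diag(C)),
      n_frames = nf,
      times = traj$times
    ),
    class = "abd_ed"
  )
}

#' @export
print.abd_ed <- function(x, ...) {
  frac <- if (x$total_variance > 0) x$eigenvalues / x$total_variance else x$eigenvalues
  cat(sprintf(
    "<abd_ed> %d atoms, %d frames; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    length(x$atom_indices), x$n_frames,
    100 * frac[1], 100 * (if (length(frac) > 1) frac[2] else 0)
  ))
  invisible(x)
}

#' @method tidy abd_ed
#' @export
tidy.abd_ed <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = if (x$total_variance > 0) x$eigenvalues / x$total_variance else NA_real_
  )
}

#' @method glance abd_ed
#' @export
glance.abd_ed <- function(x, ...) {
  tibble(
    n_atoms = length(x$atom_indices),
    n_frames = x$n_frames,
    n_components = length(x$eigenvalues),
    total_variance = x$total_variance,
    pc1_fraction = x$eigenvalues[1] / max(x$total_variance, .Machine$double.xmin)
  )
}

#' Project frames onto a principal component
#'
#' The partial projection of an atom subset is the sum over those atoms of
#' the dot product between the atom's mean-centered displacement and its
#' 3-entry block of the eigenvector. With `atom_subset = NULL` (all atoms)
#' this is the standard PC score; disjoint subsets covering all atoms sum
#' to the full score frame by frame.
#'
#' @param ed an `abd_ed` fit.
#' @param component 1-based component number.
#' @param atom_subset 0-based atom indices (subset of the fitted atoms), or
#'   `NULL` for all.
#' @return tibble `frame`, `time`, `score`.
#' @export
project_component <- function(ed, component, atom_subset = NULL) {
  if (component < 1 || component > length(ed$eigenvalues)) {
    abort(sprintf("Component %d not in fit (1..%d).", component, length(ed$eigenvalues)))
  }
  v <- ed$eigenvectors[, component]
  if (is.null(atom_subset)) {
    score <- as.numeric(ed$displacements %*% v)
  } else {
    pos <- match(atom_subset, ed$atom_indices)
    if (anyNA(pos)) abort("atom_subset contains atoms outside the fitted set.")
    if (length(pos) == 0) abort("Empty atom subset.")
    cols <- as.vector(t(outer(pos - 1L, 1:3, function(p, d) 3L * p + d)))
    score <- as.numeric(ed$displacements[, cols, drop = FALSE] %*% v[cols])
  }
  tibble(frame = seq_len(ed$n_frames), time = ed$times, score = score)
}

#' Per-atom contribution vectors of a component
#'
#' Each fitted atom's 3-entry block of the eigenvector, plus its norm (the
#' atom's contribution magnitude; squared norms sum to 1 over atoms). A
#' component with zero eigenvalue is flagged as null-space.
#'
#' @param ed an `abd_ed` fit.
#' @param component 1-based component number.
#' @return tibble `atom_index`, `dx`, `dy`, `dz`, `magnitude`, `null_space`.
#' @export
atom_contributions <- function(ed, component) {
  if (component < 1 || component > length(ed$eigenvalues)) {
    abort(sprintf("Component %d not in fit (1..%d).", component, length(ed$eigenvalues)))
  }
  v <- matrix(ed$eigenvectors[, component], ncol = 3, byrow = TRUE)
  tibble(
    atom_index = ed$atom_indices,
    dx = v[, 1], dy = v[, 2], dz = v[, 3],
    magnitude = sqrt(rowSums(v * v)),
    null_space = ed$eigenvalues[component] <= .Machine$double.eps * ed$total_variance
  )
}
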