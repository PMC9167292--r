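# Hydrogen-bond detection and persistence analysis.
#
# Candidate bonds are donor-hydrogen-acceptor (D-H-A) triples in the
# Baker-Hubbard style: every N-H or O-H donor paired with every N or O
# acceptor outside the donor's own residue. A bond is *bound* in a frame iff
# the hydrogen-acceptor distance is strictly below the distance cutoff
# (default 0.25 nm) AND the D-H-A angle is strictly above the angle cutoff
# (default 120 degrees). Bond identity is the full D-H-A triple, so a donor
# with two hydrogens contributes two distinct bonds.

bond_key_of <- function(topology, donor, hydrogen, acceptor) {
  atom_tag <- function(i) {
    paste0(
      topology$chain_id[i + 1L], ":", topology$residue_name[i + 1L],
      topology$residue_number[i + 1L], topology$insert[i + 1L], ":",
      topology$atom_name[i + 1L]
    )
  }
  paste0(atom_tag(donor), "--", atom_tag(hydrogen), "...", atom_tag(acceptor))
}

#' Enumerate candidate hydrogen bonds
#'
#' Donors are hydrogens covalently bound to an N or O heavy atom (covalency
#' inferred from a H-heavy distance < `covalent_cutoff` in the reference
#' frame); acceptors are all N and O atoms. Pairs within one residue are
#' excluded, as is the donor heavy atom itself. Each candidate carries the
#' donor and acceptor fragment labels from `assignment`.
#'
#' @param topology an [abd_topology] (must contain hydrogens).
#' @param frame0 `N x 3` reference coordinates in nm (for covalency and the
#'   optional distance prefilter).
#' @param assignment from [assign_beads()].
#' @param covalent_cutoff H-to-heavy covalent bond cutoff in nm (0.12).
#' @param max_ha_distance optional neighbour prefilter: drop candidates whose
#'   H...A distance in `frame0` exceeds this (nm). `NULL` keeps all pairs.
#' @return tibble with `donor_index`, `hydrogen_index`, `acceptor_index`
#'   (0-based), `donor_fragment`, `acceptor_fragment`, `bond_key`.
#' @export
find_candidate_bonds <- function(topology, frame0, assignment,
                                 covalent_cutoff = 0.12,
                                 max_ha_distance = NULL) {
  is_h <- toupper(topology$element) == "H"
  if (!any(is_h)) {
    abort(paste(
      "Topology contains no hydrogens: the geometric hydrogen-bond criterion",
      "needs explicit hydrogen positions."
    ))
  }
  heavy_no <- which(toupper(topology$element) %in% c("N", "O"))
  h_idx <- which(is_h)
  if (length(heavy_no) == 0) abort("No N or O atoms to act as donors/acceptors.")
  rkey <- residue_key(topology)
  # attach each hydrogen to its nearest N/O within the covalent cutoff
  donors <- list()
  for (h in h_idx) {
    d2 <- rowSums((frame0[heavy_no, , drop = FALSE] -
                     matrix(frame0[h, ], length(heavy_no), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) < covalent_cutoff) {
      donors[[length(donors) + 1L]] <- c(heavy = heavy_no[j], hydrogen = h)
    }
  }
  if (length(donors) == 0) {
    return(tibble(
      donor_index = integer(0), hydrogen_index = integer(0),
      acceptor_index = integer(0), donor_fragment = character(0),
      acceptor_fragment = character(0), bond_key = character(0)
    ))
  }
  dm <- do.call(rbind, donors)
  # all donor x acceptor pairs
  nd <- nrow(dm); na_ <- length(heavy_no)
  donor_heavy <- rep(dm[, "heavy"], times = na_)
  hydrogen <- rep(dm[, "hydrogen"], times = na_)
  acceptor <- rep(heavy_no, each = nd)
  keep <- acceptor != donor_heavy & rkey[acceptor] != rkey[donor_heavy]
  donor_heavy <- donor_heavy[keep]; hydrogen <- hydrogen[keep]; acceptor <- acceptor[keep]
  if (!is.null(max_ha_distance)) {
    dha <- sqrt(rowSums((frame0[hydrogen, , drop = FALSE] -
                           frame0[acceptor, , drop = FALSE])^2))
    keep2 <- dha <= max_ha_distance
    donor_heavy <- donor_heavy[keep2]; hydrogen <- hydrogen[keep2]
    acceptor <- acceptor[keep2]
  }
  d0 <- donor_heavy - 1L; h0 <- hydrogen - 1L; a0 <- acceptor - 1L
  tibble(
    donor_index = d0,
    hydrogen_index = h0,
    acceptor_index = a0,
    donor_fragment = assignment$fragment[donor_heavy],
    acceptor_fragment = assignment$fragment[acceptor],
    bond_key = bond_key_of(topology, d0, h0, a0)
  )
}

#' Evaluate per-frame bound states of candidate bonds
#'
#' `bound[f]` is true iff the H...A distance is strictly `<` `dist_cutoff`
#' and the D-H-A angle strictly `>` `angle_cutoff`; frames exactly at a
#' cutoff are unbound. Occupancy is the exact bound-frame fraction.
#'
#' @param traj an [abd_trajectory].
#' @param bonds tibble from [find_candidate_bonds()].
#' @param dist_cutoff nm (default 0.25).
#' @param angle_cutoff degrees (default 120).
#' @return tibble of class `abd_hbond_states`, one row per bond: `bond_key`,
#'   `donor_fragment`, `acceptor_fragment`, `occupancy`, `n_frames`, and a
#'   `bound` list-column of per-frame logicals.
#' @export
evaluate_bound_states <- function(traj, bonds, dist_cutoff = 0.25,
                                  angle_cutoff = 120) {
  if (dist_cutoff <= 0 || angle_cutoff <= 0) abort("Cutoffs must be positive.")
  nf <- n_frames(traj)
  nb <- nrow(bonds)
  if (nb == 0) {
    out <- tibble(bond_key = character(0), donor_fragment = character(0),
                  acceptor_fragment = character(0), occupancy = numeric(0),
                  n_frames = integer(0), bound = list())
    class(out) <- c("abd_hbond_states", class(tibble()))
    return(out)
  }
  hi <- bonds$hydrogen_index + 1L
  ai <- bonds$acceptor_index + 1L
  di <- bonds$donor_index + 1L
  take <- function(idx, d) {
    m <- traj$coords[, idx, d, drop = FALSE]
    dim(m) <- c(nf, length(idx))
    m
  }
  # H...A distance, frames x bonds
  dx <- take(hi, 1) - take(ai, 1)
  dy <- take(hi, 2) - take(ai, 2)
  dz <- take(hi, 3) - take(ai, 3)
  dist_ha <- sqrt(dx * dx + dy * dy + dz * dz)
  # D-H-A angle at vertex H
  ux <- take(di, 1) - take(hi, 1); vx <- -dx
  uy <- take(di, 2) - take(hi, 2); vy <- -dy
  uz <- take(di, 3) - take(hi, 3); vz <- -dz
  nu <- sqrt(ux * ux + uy * uy + uz * uz)
  nv <- dist_ha
  cosang <- (ux * vx + uy * vy + uz * vz) / (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * .rad2deg
  bound <- (dist_ha < dist_cutoff) & (ang > angle_cutoff)
  out <- bonds[, c("bond_key", "donor_fragment", "acceptor_fragment")]
  out$occupancy <- colSums(bound) / nf
  out$n_frames <- nf
  out$bound <- lapply(seq_len(nb), function(b) unname(bound[, b]))
  out <- as_tibble(out)
  class(out) <- c("abd_hbond_states", class(tibble()))
  out
}

#' Keep bonds joining two fragments
#'
#' Retains bonds whose donor and acceptor fragments are exactly the given
#' pair, in either orientation. Uniqueness of the kept set is keyed by the
#' full D-H-A triple; the donor-acceptor *pair* count (collapsing multiple
#' hydrogens) is attached as `attr(, "n_pairs")`.
#'
#' @param states `abd_hbond_states` (or candidate) tibble with fragment columns.
#' @param fragment_a,fragment_b fragment labels (default `"Fab2"`, `"Fc"`).
#' @return filtered tibble of the same class.
#' @export
filter_interfragment <- function(states, fragment_a = "Fab2", fragment_b = "Fc") {
  for (fr in c(fragment_a, fragment_b)) {
    if (!fr %in% .fragment_labels) abort(sprintf("Unknown fragment label '%s'.", fr))
  }
  keep <- (states$donor_fragment == fragment_a & states$acceptor_fragment == fragment_b) |
    (states$donor_fragment == fragment_b & states$acceptor_fragment == fragment_a)
  out <- states[keep, ]
  pair_key <- sub("--[^.]*\\.\\.\\.", "...", out$bond_key)
  attr(out, "n_pairs") <- length(unique(pair_key))
  out
}

#' Occupancy / persistence filter across replicates
#'
#' A bond is *persistent* in a replicate when its occupancy is strictly
#' above `occupancy_threshold` there ("present in over 80% of a trajectory");
#' it is *stable* when persistent in at least `min_replicates` replicates.
#' Replicates with differing bond sets are aligned by the union of keys;
#' a bond missing from a replicate counts as occupancy 0 there.
#'
#' @param replicates list of `abd_hbond_states` tibbles (or any data frames
#'   with `bond_key` and `occupancy`), one per replicate.
#' @param occupancy_threshold strict lower bound (default 0.80).
#' @param min_replicates minimum replicate count for stability (default 2).
#' @return `abd_persistence` list: `occupancy` (wide tibble bond_key x
#'   replicate), `persistent` (tibble `replicate`, `bond_key`), `stable`
#'   (character vector of bond keys), thresholds.
#' @export
persistence_filter <- function(replicates, occupancy_threshold = 0.80,
                               min_replicates = 2L) {
  if (length(replicates) < 1) abort("persistence_filter needs at least one replicate.")
  if (is.data.frame(replicates)) replicates <- list(replicates)
  keys <- sort(unique(unlist(lapply(replicates, function(r) r$bond_key))))
  occ <- sapply(replicates, function(r) {
    v <- setNames(rep(0, length(keys)), keys)
    v[r$bond_key] <- r$occupancy
    v
  })
  occ <- matrix(occ, nrow = length(keys),
                dimnames = list(keys, paste0("replicate_", seq_along(replicates))))
  persistent_mask <- occ > occupancy_threshold
  persistent <- dplyr::bind_rows(lapply(seq_along(replicates), function(i) {
    tibble(replicate = i, bond_key = keys[persistent_mask[, i]])
  }))
  stable <- keys[rowSums(persistent_mask) >= min_replicates]
  structure(
    list(
      occupancy = dplyr::bind_cols(tibble(bond_key = keys), as_tibble(occ)),
      persistent = persistent,
      stable = stable,
      occupancy_threshold = occupancy_threshold,
      min_replicates = as.integer(min_replicates)
    ),
    class = "abd_persistence"
  )
}

#' @export
print.abd_persistence <- function(x, ...) {
  cat(sprintf(
    "<abd_persistence> %d bonds, %d replicates; %d persistent occurrences (occupancy > %.2f), %d stable in >= %d replicates\n",
    nrow(x$occupancy), ncol(x$occupancy) - 1L, nrow(x$persistent),
    x$occupancy_threshold, length(x$stable), x$min_replicates
  ))
  invisible(x)
}

#' @method tidy abd_persistence
#' @export
tidy.abd_persistence <- function(x, ...) {
  tidyr::pivot_longer(x$occupancy, -"bond_key",
                      names_to = "replicate", values_to = "occupancy") |>
    dplyr::mutate(
      replicate = as.integer(sub("replicate_", "", .data$replicate)),
      persistent = .data$occupancy > x$occupancy_threshold,
      stable = .data$bond_key %in% x$stable
    )
}

#' @method glance abd_persistence
#' @export
glance.abd_persistence <- function(x, ...) {
  tibble(
    n_bonds = nrow(x$occupancy),
    n_replicates = ncol(x$occupancy) - 1L,
    n_persistent_any = length(unique(x$persistent$bond_key)),
    n_stable = length(x$stable),
    occupancy_threshold = x$occupancy_threshold,
    min_replicates = x$min_replicates
  )
}

#' Per-frame count of bound bonds
#'
#' @param states `abd_hbond_states` tibble (frame-aligned `bound` columns).
#' @param times optional per-frame times (ps).
#' @return tibble `frame`, `time`, `count`.
#' @export
bond_count_series <- function(states, times = NULL) {
  if (nrow(states) == 0) {
    return(tibble(frame = integer(0), time = numeric(0), count = integer(0)))
  }
  nf <- unique(states$n_frames)
  if (length(nf) != 1) abort("Bond state series are not frame-aligned.")
  counts <- Reduce(`+`, lapply(states$bound, as.integer))
  tibble(
    frame = seq_len(nf),
    time = times %||% as.numeric(seq_len(nf) - 1L),
    count = as.integer(counts)
  )
}
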