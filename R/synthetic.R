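# Ground-truth synthetic antibody-like systems.
#
# The generator builds a six-domain Y-shaped topology (one chain per domain,
# one Calpha pseudo-atom per residue), places the six domain beads from a
# Z-matrix over the nine antibody observables, and rebuilds every frame so
# that per-frame sampled values of all nine measures are realized *exactly*
# (domains translate rigidly with their bead; planted values are
# construction-exact, not approximate targets). Optional donor-H-acceptor
# triads follow programmed bound/unbound schedules for the hydrogen-bond
# pipeline.

#' Default fluctuation model for the synthetic antibody
#'
#' Target mean and standard deviation per observable. The defaults emulate
#' the asymmetric Fab statistics of an IgG1 with a tethered Fab2 arm: a
#' broad Fab1 (R_23 ~ 5.8 +/- 0.4 nm, theta_123 ~ 120 +/- 10 deg,
#' Theta_1234 +/- 15 deg) against a tightly constrained Fab2
#' (R_25 ~ 3.5 +/- 0.05 nm, theta_125 ~ 60 +/- 3 deg, Theta_1256 +/- 4 deg),
#' with stiff intra-fragment distances.
#'
#' @return tibble `label`, `kind`, `mean`, `sd`.
#' @export
default_fluctuations <- function() {
  tibble(
    label = c("R_12", "R_23", "R_25", "theta_123", "theta_125",
              "Theta_1234", "Theta_1256", "R_34", "R_56"),
    kind = c("distance", "distance", "distance", "angle", "angle",
             "dihedral", "dihedral", "distance", "distance"),
    mean = c(4.0, 5.8, 3.5, 120, 60, 100, -100, 3.0, 3.0),
    sd = c(0.05, 0.4, 0.05, 10, 3, 15, 4, 0.05, 0.05)
  )
}

#' Specification of a synthetic antibody system
#'
#' @param atoms_per_domain pseudo-atoms per domain (>= 3).
#' @param n_frames frames to generate.
#' @param seed RNG seed (mandatory: every generator is bit-reproducible
#'   given the spec and seed).
#' @param fluctuations tibble as [default_fluctuations()]; `sd = 0`
#'   freezes a measure.
#' @param n_triads number of donor-H-acceptor triads to add.
#' @param hinge_atoms pseudo-atoms in the hinge chain.
#' @return a `synthetic_antibody_spec` list.
#' @export
synthetic_antibody_spec <- function(atoms_per_domain = 10L, n_frames = 100L,
                                    seed, fluctuations = default_fluctuations(),
                                    n_triads = 0L, hinge_atoms = 3L) {
  if (missing(seed)) abort("synthetic_antibody_spec requires a seed.")
  if (atoms_per_domain < 3) abort("atoms_per_domain must be >= 3.")
  if (any(fluctuations$sd < 0)) abort("Fluctuation sds must be >= 0.")
  required <- default_fluctuations()$label
  if (!setequal(fluctuations$label, required)) {
    abort(paste("fluctuations must define exactly the nine measures:",
                paste(required, collapse = ", ")))
  }
  structure(
    list(
      atoms_per_domain = as.integer(atoms_per_domain),
      n_frames = as.integer(n_frames),
      seed = as.integer(seed),
      fluctuations = fluctuations,
      n_triads = as.integer(n_triads),
      hinge_atoms = as.integer(hinge_atoms),
      # template internal constants of the Z-matrix (not observables)
      theta_234 = 150, theta_256 = 150,
      azimuth_fab1 = 0, azimuth_fab2 = 180
    ),
    class = "synthetic_antibody_spec"
  )
}

unit3 <- function(v) v / sqrt(sum(v * v))

# Natural-extension placement: D given A, B, C with |CD| = r, angle BCD =
# theta (deg), dihedral ABCD = phi (deg, package sign convention).
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- unit3(C - B)
  ab <- unit3(B - A)
  n <- unit3(c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  ))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  C + r * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

# Bead centers (6 x 3) realizing the given named measure values exactly.
place_beads <- function(values, spec) {
  v <- as.list(values)
  for (ang in c("theta_123", "theta_125")) {
    if (v[[ang]] <= 0 || v[[ang]] >= 180) {
      abort(sprintf("Unsatisfiable geometry: %s = %g out of (0, 180).", ang, v[[ang]]))
    }
  }
  for (d in c("R_12", "R_23", "R_25", "R_34", "R_56")) {
    if (v[[d]] <= 0) abort(sprintf("Unsatisfiable geometry: %s = %g <= 0.", d, v[[d]]))
  }
  dir_from_b2 <- function(theta, azimuth) {
    th <- theta * pi / 180; az <- azimuth * pi / 180
    c(sin(th) * cos(az), sin(th) * sin(az), -cos(th))
  }
  b1 <- c(0, 0, 0)
  b2 <- c(0, 0, v$R_12)
  b3 <- b2 + v$R_23 * dir_from_b2(v$theta_123, spec$azimuth_fab1)
  b5 <- b2 + v$R_25 * dir_from_b2(v$theta_125, spec$azimuth_fab2)
  b4 <- nerf_place(b1, b2, b3, v$R_34, spec$theta_234, v$Theta_1234)
  b6 <- nerf_place(b1, b2, b5, v$R_56, spec$theta_256, v$Theta_1256)
  rbind(b1, b2, b3, b4, b5, b6)
}

triad_geometry <- function(base, ha_distance) {
  # donor N at base; H 0.10 nm along +x; acceptor placed so the D-H-A angle
  # is exactly 160 degrees whatever the planted H...A distance.
  u <- c(1, 0, 0)
  w <- c(cos(20 * pi / 180), 0, sin(20 * pi / 180))
  D <- base
  H <- D + 0.10 * u
  A <- H + ha_distance * w
  rbind(D, H, A)
}

#' Build a synthetic antibody topology and reference frame
#'
#' Six chains A..F hold the six domains (one ALA Calpha pseudo-atom per
#' residue, carbon masses); chain G is the hinge; donor/H/acceptor triads
#' live in extra high-numbered residues of chains E (donor, Fab2 side) and
#' B (acceptor, Fc side), outside all bead selections so planting their
#' positions never perturbs bead centers. Domain atoms are placed with their
#' mass-weighted center exactly at the template bead position.
#'
#' @param spec a [synthetic_antibody_spec()].
#' @return list `topology`, `frame0` (N x 3 nm), `config` (validated bead /
#'   fragment config), `triads` (tibble of 0-based triad atom indices),
#'   `local_offsets`, `template_beads`.
#' @export
build_synthetic_topology <- function(spec) {
  apd <- spec$atoms_per_domain
  template <- place_beads(setNames(as.list(spec$fluctuations$mean),
                                   spec$fluctuations$label), spec)
  chains6 <- c("A", "B", "C", "D", "E", "F")
  # deterministic rigid internal arrangements, mass-centered on the bead
  local_offsets <- withr::with_seed(spec$seed, {
    lapply(1:6, function(d) {
      off <- matrix(rnorm(apd * 3, sd = 0.3), apd, 3)
      sweep(off, 2, colMeans(off)) # equal masses: COM at exactly zero
    })
  })
  atoms <- list()
  coords <- list()
  for (d in 1:6) {
    atoms[[d]] <- tibble(
      atom_name = "CA", element = "C",
      chain_id = chains6[d], residue_number = seq_len(apd),
      residue_name = "ALA"
    )
    coords[[d]] <- sweep(local_offsets[[d]], 2, template[d, ], `+`)
  }
  # hinge atoms near bead 2 (they translate with the Fc stem)
  hinge_off <- matrix(0, spec$hinge_atoms, 3)
  if (spec$hinge_atoms > 0) {
    hinge_off <- cbind(seq_len(spec$hinge_atoms) * 0.2, 0, 0.5)
    atoms[["hinge"]] <- tibble(
      atom_name = "CA", element = "C",
      chain_id = "G", residue_number = seq_len(spec$hinge_atoms),
      residue_name = "GLY"
    )
    coords[["hinge"]] <- sweep(hinge_off, 2, template[2, ], `+`)
  }
  triads <- tibble(donor_index = integer(0), hydrogen_index = integer(0),
                   acceptor_index = integer(0))
  if (spec$n_triads > 0) {
    # widely spaced static bases so candidate enumeration with a neighbour
    # prefilter sees exactly the planted triads
    t_id <- seq_len(spec$n_triads)
    gx <- 30 + 3 * ((t_id - 1) %% 40)
    gy <- 3 * (((t_id - 1) %/% 40) %% 40)
    gz <- 3 * ((t_id - 1) %/% 1600)
    n_before <- sum(vapply(atoms, nrow, integer(1)))
    donor_atoms <- list(); triad_coords <- list()
    for (t in t_id) {
      g <- triad_geometry(c(gx[t], gy[t], gz[t]), ha_distance = 0.40)
      donor_atoms[[t]] <- tibble(
        atom_name = c("N", "HN", "O"), element = c("N", "H", "O"),
        chain_id = c("E", "E", "B"),
        residue_number = rep(500L + t, 3),
        residue_name = c("ALA", "ALA", "ALA")
      )
      triad_coords[[t]] <- g
    }
    atoms[["triads"]] <- dplyr::bind_rows(donor_atoms)
    coords[["triads"]] <- do.call(rbind, triad_coords)
    base0 <- n_before # 0-based index of first triad atom
    triads <- tibble(
      donor_index = base0 + 3L * (t_id - 1L),
      hydrogen_index = base0 + 3L * (t_id - 1L) + 1L,
      acceptor_index = base0 + 3L * (t_id - 1L) + 2L,
      base_x = gx, base_y = gy, base_z = gz
    )
  }
  topology <- abd_topology(dplyr::bind_rows(atoms))
  frame0 <- do.call(rbind, coords)
  bead_labels <- .bead_labels
  config <- validate_config(list(
    mode = "antibody",
    beads = lapply(1:6, function(d) {
      list(id = d, label = bead_labels[d],
           select = list(list(chain = chains6[d], resid = c(1, apd))))
    }),
    fragments = list(
      Fc = list(list(chain = "A", resid = c(1, 10000)),
                list(chain = "B", resid = c(1, 10000))),
      Fab1 = list(list(chain = "C", resid = c(1, 10000)),
                  list(chain = "D", resid = c(1, 10000))),
      Fab2 = list(list(chain = "E", resid = c(1, 10000)),
                  list(chain = "F", resid = c(1, 10000))),
      hinge = list(list(chain = "G", resid = c(1, 10000)))
    )
  ))
  list(
    topology = topology, frame0 = frame0, config = config, triads = triads,
    local_offsets = local_offsets, hinge_offsets = hinge_off,
    template_beads = template, spec = spec
  )
}

#' Generate a rigid-domain-motion trajectory with exact planted observables
#'
#' Per frame, the nine observable values are drawn from their configured
#' normal distributions (seeded) and the six bead centers are rebuilt from
#' them by the Z-matrix construction, so the planted values are realized
#' exactly. Domains translate rigidly with their bead; hinge atoms follow
#' bead 2; triad atoms stay at their static bases (until
#' [plant_hbond_schedule()] programs them). Draws outside a satisfiable
#' geometry (angles outside (0, 180), non-positive distances) are an error.
#'
#' @param system list from [build_synthetic_topology()].
#' @param n_frames number of frames (default from the spec).
#' @param seed RNG seed (default from the spec).
#' @return list `trajectory` (an [abd_trajectory]) and `ground_truth`
#'   (tibble `frame`, `label`, `value`).
#' @export
generate_rigid_motion_trajectory <- function(system, n_frames = NULL, seed = NULL) {
  spec <- system$spec
  nf <- n_frames %||% spec$n_frames
  seed <- seed %||% spec$seed
  fl <- spec$fluctuations
  draws <- withr::with_seed(seed, {
    m <- sapply(seq_len(nrow(fl)), function(i) rnorm(nf, fl$mean[i], fl$sd[i]))
    matrix(m, nrow = nf, dimnames = list(NULL, fl$label))
  })
  # dihedral draws fold into (-180, 180]
  for (lb in fl$label[fl$kind == "dihedral"]) {
    x <- draws[, lb]
    x <- ((x + 180) %% 360) - 180
    x[x == -180] <- 180
    draws[, lb] <- x
  }
  apd <- spec$atoms_per_domain
  n_atoms <- nrow(system$topology)
  coords <- array(0, c(nf, n_atoms, 3))
  domain_idx <- lapply(1:6, function(d) ((d - 1L) * apd + 1L):(d * apd))
  hinge_idx <- if (spec$hinge_atoms > 0) (6L * apd + 1L):(6L * apd + spec$hinge_atoms) else integer(0)
  for (f in seq_len(nf)) {
    beads <- place_beads(as.list(draws[f, ]), spec)
    for (d in 1:6) {
      coords[f, domain_idx[[d]], ] <- sweep(system$local_offsets[[d]], 2, beads[d, ], `+`)
    }
    if (length(hinge_idx) > 0) {
      coords[f, hinge_idx, ] <- sweep(system$hinge_offsets, 2, beads[2, ], `+`)
    }
  }
  if (nrow(system$triads) > 0) {
    for (t in seq_len(nrow(system$triads))) {
      g <- triad_geometry(
        c(system$triads$base_x[t], system$triads$base_y[t], system$triads$base_z[t]),
        ha_distance = 0.40
      )
      idx <- c(system$triads$donor_index[t], system$triads$hydrogen_index[t],
               system$triads$acceptor_index[t]) + 1L
      for (k in 1:3) coords[, idx[k], ] <- matrix(g[k, ], nf, 3, byrow = TRUE)
    }
  }
  gt <- tibble(
    frame = rep(seq_len(nf), times = ncol(draws)),
    label = rep(colnames(draws), each = nf),
    value = as.vector(draws)
  )
  list(
    trajectory = abd_trajectory(coords, system$topology, times = as.numeric(seq_len(nf) - 1L)),
    ground_truth = gt
  )
}

#' Program a hydrogen-bond triad's bound/unbound schedule into a trajectory
#'
#' Bound frames get an H...A distance of exactly 0.20 nm and a D-H-A angle
#' of exactly 160 degrees; unbound frames get H...A = 0.40 nm at the same
#' angle. Only the triad's hydrogen and acceptor atoms move; all other
#' atoms are untouched.
#'
#' @param traj an [abd_trajectory].
#' @param system list from [build_synthetic_topology()].
#' @param triad 1-based row number into `system$triads`.
#' @param schedule logical vector of length `n_frames(traj)` (TRUE = bound).
#' @return the modified [abd_trajectory].
#' @export
plant_hbond_schedule <- function(traj, system, triad, schedule) {
  if (triad < 1 || triad > nrow(system$triads)) {
    abort(sprintf("Triad %d not present (system has %d).", triad, nrow(system$triads)))
  }
  nf <- n_frames(traj)
  if (length(schedule) != nf) {
    abort(sprintf("Schedule length %d != %d frames.", length(schedule), nf))
  }
  tr <- system$triads[triad, ]
  base <- c(tr$base_x, tr$base_y, tr$base_z)
  g_bound <- triad_geometry(base, ha_distance = 0.20)
  g_unbound <- triad_geometry(base, ha_distance = 0.40)
  hi <- tr$hydrogen_index + 1L
  ai <- tr$acceptor_index + 1L
  bound <- as.logical(schedule)
  for (k in 1:3) {
    traj$coords[, hi, k] <- ifelse(bound, g_bound[2, k], g_unbound[2, k])
    traj$coords[, ai, k] <- ifelse(bound, g_bound[3, k], g_unbound[3, k])
  }
  traj
}
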