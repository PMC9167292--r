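# Overdamped Langevin toy bead system with a breakable inter-domain well.
#
# Dynamics: Euler-Maruyama on  dx = F/zeta dt + sqrt(2 kT dt / zeta) eta,
# with zeta a friction coefficient in kcal mol^-1 ps nm^-2 (force per
# velocity; overdamped motion depends only on this product, so mass never
# enters). The potential is a sum of harmonic pair springs, harmonic
# tethers to fixed points, and one breakable attraction between two beads:
# a truncated shifted harmonic well
#     U_well(r) = 0.5 k (r - r0)^2 - epsilon   for r < r_c,   0 otherwise,
# with r_c = r0 + sqrt(2 epsilon / k) so the well is continuous at the
# cutoff and has closed-form maximum restoring force k (r_c - r0).
#
# Two pulling modes:
#  * constant per-bead forces (the rupture assay): the work ledger
#    accumulates sum F_ext . dx per step;
#  * a constant-velocity harmonic trap on the well pair's separation (the
#    steered assay used for the free-energy bound): the ledger accumulates
#    the exact discrete protocol work U_trap(r, c_{t+dt}) - U_trap(r, c_t),
#    whose mean over repeats obeys the Jarzynski bound mean(W) >= delta F.

well_cutoff <- function(well) well$r0 + sqrt(2 * well$epsilon / well$k)

well_energy <- function(well, r) {
  rc <- well_cutoff(well)
  ifelse(r < rc, 0.5 * well$k * (r - well$r0)^2 - well$epsilon, 0)
}

# dU/dr
well_force_mag <- function(well, r) {
  rc <- well_cutoff(well)
  ifelse(r < rc, well$k * (r - well$r0), 0)
}

#' Specification of the toy Langevin bead system
#'
#' @param positions0 `B x 3` start coordinates (nm).
#' @param zeta per-bead friction coefficient (kcal mol^-1 ps nm^-2).
#' @param kT thermal energy (kcal/mol); 0.593 is 300 K.
#' @param springs tibble/data frame `i`, `j`, `k`, `r0` of harmonic pair
#'   springs (k in kcal/mol/nm^2, r0 in nm); may be empty.
#' @param tethers tibble `i`, `k`, `x`, `y`, `z` of harmonic tethers to
#'   fixed points; may be empty.
#' @param well breakable attraction `list(i, j, epsilon, k, r0)` between two
#'   beads, or `NULL`.
#' @param forces `B x 3` constant external force matrix (kcal/mol/nm), or
#'   `NULL`.
#' @param trap moving harmonic trap on the well pair separation:
#'   `list(k, c0, v)` (stiffness, start center nm, speed nm/ps), or `NULL`.
#'   Requires `well` (the trap acts on the same pair).
#' @param dt timestep (ps); must resolve the stiffest mode
#'   (`dt * k_total / zeta` well below 1).
#' @param n_steps number of integration steps.
#' @return a `toy_langevin_spec` list.
#' @export
toy_langevin_spec <- function(positions0, zeta = 1, kT = 0.593,
                              springs = NULL, tethers = NULL, well = NULL,
                              forces = NULL, trap = NULL,
                              dt = 5e-4, n_steps = 1000L) {
  positions0 <- as.matrix(positions0)
  if (ncol(positions0) != 3) abort("positions0 must be B x 3.")
  if (dt <= 0 || zeta <= 0) abort("timestep and friction must be positive.")
  if (kT < 0) abort("kT must be >= 0.")
  if (!is.null(well)) {
    stopifnot(all(c("i", "j", "epsilon", "k", "r0") %in% names(well)))
    if (well$epsilon < 0 || well$k <= 0) abort("Well depth >= 0 and stiffness > 0 required.")
  }
  if (!is.null(trap)) {
    if (is.null(well)) abort("A trap requires a well pair to act on.")
    stopifnot(all(c("k", "c0", "v") %in% names(trap)))
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    stopifnot(all(dim(forces) == dim(positions0)))
  }
  structure(
    list(
      positions0 = positions0, zeta = zeta, kT = kT,
      springs = if (is.null(springs)) NULL else as.data.frame(springs),
      tethers = if (is.null(tethers)) NULL else as.data.frame(tethers),
      well = well, forces = forces, trap = trap,
      dt = dt, n_steps = as.integer(n_steps)
    ),
    class = "toy_langevin_spec"
  )
}

#' Potential energy of a toy-system configuration
#' @param spec a [toy_langevin_spec()].
#' @param X `B x 3` coordinates; defaults to the spec's start positions.
#' @param trap_center trap center to use (NULL = exclude the trap term).
#' @return energy in kcal/mol.
#' @export
toy_potential_energy <- function(spec, X = spec$positions0, trap_center = NULL) {
  U <- 0
  if (!is.null(spec$springs)) {
    for (s in seq_len(nrow(spec$springs))) {
      r <- sqrt(sum((X[spec$springs$i[s], ] - X[spec$springs$j[s], ])^2))
      U <- U + 0.5 * spec$springs$k[s] * (r - spec$springs$r0[s])^2
    }
  }
  if (!is.null(spec$tethers)) {
    for (s in seq_len(nrow(spec$tethers))) {
      d <- X[spec$tethers$i[s], ] - c(spec$tethers$x[s], spec$tethers$y[s], spec$tethers$z[s])
      U <- U + 0.5 * spec$tethers$k[s] * sum(d * d)
    }
  }
  if (!is.null(spec$well)) {
    r <- sqrt(sum((X[spec$well$i, ] - X[spec$well$j, ])^2))
    U <- U + well_energy(spec$well, r)
  }
  if (!is.null(spec$trap) && !is.null(trap_center)) {
    r <- sqrt(sum((X[spec$well$i, ] - X[spec$well$j, ])^2))
    U <- U + 0.5 * spec$trap$k * (r - trap_center)^2
  }
  U
}

# Forces on all beads for a batch of replicas.
# X is a list of n x 3 matrices, one per bead. Returns list of n x 3.
toy_forces_batch <- function(spec, X, trap_center = NULL) {
  B <- length(X)
  n <- nrow(X[[1]])
  Fo <- lapply(seq_len(B), function(b) matrix(0, n, 3))
  pair_force <- function(i, j, fmag_fun) {
    d <- X[[i]] - X[[j]]
    r <- sqrt(rowSums(d * d))
    r <- pmax(r, 1e-12)
    fm <- fmag_fun(r) # dU/dr
    fv <- d * (-fm / r)
    Fo[[i]] <<- Fo[[i]] + fv
    Fo[[j]] <<- Fo[[j]] - fv
  }
  if (!is.null(spec$springs)) {
    for (s in seq_len(nrow(spec$springs))) {
      k <- spec$springs$k[s]; r0 <- spec$springs$r0[s]
      pair_force(spec$springs$i[s], spec$springs$j[s], function(r) k * (r - r0))
    }
  }
  if (!is.null(spec$tethers)) {
    for (s in seq_len(nrow(spec$tethers))) {
      i <- spec$tethers$i[s]
      x0 <- c(spec$tethers$x[s], spec$tethers$y[s], spec$tethers$z[s])
      Fo[[i]] <- Fo[[i]] - spec$tethers$k[s] *
        sweep(X[[i]], 2, x0)
    }
  }
  if (!is.null(spec$well)) {
    w <- spec$well
    pair_force(w$i, w$j, function(r) well_force_mag(w, r))
    if (!is.null(spec$trap) && !is.null(trap_center)) {
      k <- spec$trap$k
      pair_force(w$i, w$j, function(r) k * (r - trap_center))
    }
  }
  if (!is.null(spec$forces)) {
    for (b in seq_len(B)) {
      Fo[[b]] <- sweep(Fo[[b]], 2, spec$forces[b, ], `+`)
    }
  }
  Fo
}

#' Run the overdamped Langevin toy simulation
#'
#' Seeded Euler-Maruyama integration; any coordinate exceeding `bound`
#' aborts with the step index (divergence guard). The work ledger
#' accumulates constant-force work `sum F_ext . dx` per step and, when a
#' trap is present, the discrete protocol work of the moving trap.
#'
#' @param spec a [toy_langevin_spec()].
#' @param seed RNG seed (mandatory).
#' @param record_stride store every `record_stride`-th frame (default 10).
#' @param bound divergence guard in nm (default 1e3).
#' @return an `abd_langevin`: `centers` (recorded F x B x 3), `times`,
#'   `work_external`, `work_protocol`, `final`, `trap_center_final`, `spec`.
#' @export
run_langevin <- function(spec, seed, record_stride = 10L, bound = 1e3) {
  if (missing(seed)) abort("run_langevin requires a seed.")
  res <- withr::with_seed(seed, {
    langevin_batch(spec, n_replicas = 1L, record_stride = record_stride, bound = bound)
  })
  centers <- res$frames # list over records of list over beads of 1 x 3
  nrec <- length(res$record_steps)
  B <- nrow(spec$positions0)
  arr <- array(0, c(nrec, B, 3))
  for (r in seq_len(nrec)) {
    for (b in seq_len(B)) arr[r, b, ] <- res$frames[[r]][[b]][1, ]
  }
  structure(
    list(
      centers = arr,
      times = res$record_steps * spec$dt,
      work_external = res$work_external[1],
      work_protocol = res$work_protocol[1],
      final = t(vapply(res$X, function(m) m[1, ], numeric(3))),
      trap_center_final = res$trap_center,
      spec = spec
    ),
    class = "abd_langevin"
  )
}

#' @export
print.abd_langevin <- function(x, ...) {
  cat(sprintf(
    "<abd_langevin> %d beads, %d recorded frames, t = %g ps; W_ext = %.4g, W_protocol = %.4g kcal/mol\n",
    dim(x$centers)[2], dim(x$centers)[1], max(x$times),
    x$work_external, x$work_protocol
  ))
  invisible(x)
}

#' @method tidy abd_langevin
#' @export
tidy.abd_langevin <- function(x, ...) {
  nrec <- dim(x$centers)[1]; B <- dim(x$centers)[2]
  tibble(
    frame = rep(seq_len(nrec), times = B),
    time = rep(x$times, times = B),
    bead = rep(seq_len(B), each = nrec),
    x = as.vector(x$centers[, , 1]),
    y = as.vector(x$centers[, , 2]),
    z = as.vector(x$centers[, , 3])
  )
}

#' Per-frame distance between two beads of a Langevin run
#' @param run an `abd_langevin`.
#' @param i,j bead indices.
#' @return tibble `frame`, `time`, `distance`.
#' @export
langevin_pair_distance <- function(run, i, j) {
  d <- matrix(run$centers[, i, , drop = FALSE] -
                run$centers[, j, , drop = FALSE], ncol = 3)
  tibble(
    frame = seq_len(dim(run$centers)[1]),
    time = run$times,
    distance = sqrt(rowSums(d * d))
  )
}

# Core integrator, vectorized over independent replicas (shared spec,
# independent noise). Used by run_langevin (n=1) and pull_work_samples.
langevin_batch <- function(spec, n_replicas, record_stride = 0L, bound = 1e3) {
  B <- nrow(spec$positions0)
  n <- n_replicas
  X <- lapply(seq_len(B), function(b) {
    matrix(spec$positions0[b, ], n, 3, byrow = TRUE)
  })
  dt <- spec$dt
  mob <- dt / spec$zeta
  noise_sd <- sqrt(2 * spec$kT * dt / spec$zeta)
  w_ext <- numeric(n)
  w_prot <- numeric(n)
  trap_center <- if (!is.null(spec$trap)) spec$trap$c0 else NULL
  frames <- list()
  record_steps <- integer(0)
  store <- function(step) {
    frames[[length(frames) + 1L]] <<- lapply(X, function(m) m)
    record_steps[length(record_steps) + 1L] <<- step
  }
  if (record_stride > 0) store(0L)
  for (step in seq_len(spec$n_steps)) {
    new_center <- trap_center
    if (!is.null(spec$trap)) {
      new_center <- spec$trap$c0 + spec$trap$v * step * dt
      # protocol work at fixed configuration
      d <- X[[spec$well$i]] - X[[spec$well$j]]
      r <- sqrt(rowSums(d * d))
      w_prot <- w_prot + 0.5 * spec$trap$k *
        ((r - new_center)^2 - (r - trap_center)^2)
      trap_center <- new_center
    }
    Fo <- toy_forces_batch(spec, X, trap_center)
    for (b in seq_len(B)) {
      dx <- Fo[[b]] * mob
      if (spec$kT > 0) {
        dx <- dx + matrix(rnorm(n * 3, sd = noise_sd), n, 3)
      }
      if (!is.null(spec$forces)) {
        w_ext <- w_ext + as.vector(dx %*% spec$forces[b, ])
      }
      X[[b]] <- X[[b]] + dx
    }
    if (any(vapply(X, function(m) any(abs(m) > bound), logical(1)))) {
      abort(sprintf("Langevin trajectory diverged at step %d (|coordinate| > %g nm).",
                    step, bound))
    }
    if (record_stride > 0 && step %% record_stride == 0L) store(step)
  }
  list(X = X, frames = frames, record_steps = record_steps,
       work_external = w_ext, work_protocol = w_prot,
       trap_center = trap_center)
}

#' Sample pulling work over many seeded repeats
#'
#' Runs `n_pulls` independent replicas of the trap protocol (shared spec,
#' independent thermal noise) and returns the protocol work of each pull.
#'
#' @param spec a [toy_langevin_spec()] with a `trap`.
#' @param n_pulls number of repeats.
#' @param seed RNG seed.
#' @return tibble `pull`, `work` (kcal/mol).
#' @export
pull_work_samples <- function(spec, n_pulls, seed) {
  if (is.null(spec$trap)) abort("pull_work_samples needs a spec with a trap.")
  if (missing(seed)) abort("pull_work_samples requires a seed.")
  res <- withr::with_seed(seed, {
    langevin_batch(spec, n_replicas = n_pulls, record_stride = 0L)
  })
  tibble(pull = seq_len(n_pulls), work = res$work_protocol)
}

#' Analytic free-energy difference of the toy potential
#'
#' One-dimensional quadrature over the radial separation of the well pair
#' (with the `r^2` Jacobian of the two-bead relative coordinate).
#'
#' Modes:
#' * `"trap"`: `delta F = F(c_end) - F(c_start)` of the trapped system,
#'   `F(c) = -kT ln integral r^2 exp(-(U_well + U_trap(r; c)) / kT) dr` —
#'   the reference value for the Jarzynski bound on [pull_work_samples()].
#' * `"interval"`: bound-vs-released split of the bare well,
#'   `delta F = -kT ln(Z_released / Z_bound)` with `Z_bound` over
#'   `[0, r_c]` and `Z_released` over `[r_c, r_max]`; tends to the well
#'   depth epsilon as `kT -> 0`.
#'
#' @param spec a [toy_langevin_spec()] with a `well` (and a `trap` for
#'   `mode = "trap"`).
#' @param mode `"trap"` or `"interval"`.
#' @param kT thermal energy; defaults to the spec's.
#' @param r_max outer integration limit for `"interval"` (default
#'   `r_c + 2` nm).
#' @return an `abd_free_energy` list: `delta_f` (kcal/mol), `mode`, parts.
#' @export
analytic_delta_f <- function(spec, mode = c("trap", "interval"), kT = spec$kT,
                             r_max = NULL) {
  mode <- match.arg(mode)
  if (is.null(spec$well)) abort("analytic_delta_f needs a spec with a well.")
  if (kT <= 0) abort("Quadrature needs kT > 0.")
  w <- spec$well
  rc <- well_cutoff(w)
  if (mode == "trap") {
    if (is.null(spec$trap)) abort("mode = 'trap' needs a trap in the spec.")
    k_s <- spec$trap$k
    c_start <- spec$trap$c0
    c_end <- spec$trap$c0 + spec$trap$v * spec$n_steps * spec$dt
    sigma <- sqrt(kT / k_s)
    upper <- max(c_start, c_end, rc) + 12 * sigma + 1
    # integrand shifted by the well depth so exp() stays in range for deep
    # wells; the -epsilon constant cancels in the difference F(c1) - F(c0)
    fe <- function(cc) {
      z <- integrate(
        function(r) r^2 * exp(-(well_energy(w, r) + w$epsilon +
                                  0.5 * k_s * (r - cc)^2) / kT),
        lower = 0, upper = upper, rel.tol = 1e-10, subdivisions = 2000L
      )
      if (z$message != "OK") abort(sprintf("Quadrature failed: %s", z$message))
      -w$epsilon - kT * log(z$value)
    }
    f0 <- fe(c_start); f1 <- fe(c_end)
    structure(list(delta_f = f1 - f0, f_start = f0, f_end = f1,
                   c_start = c_start, c_end = c_end, kT = kT, mode = mode),
              class = "abd_free_energy")
  } else {
    r_max <- r_max %||% (rc + 2)
    # ln Z_bound = epsilon/kT + ln integral r^2 exp(-(U + epsilon)/kT)
    # (shift keeps the exponentials in range for deep wells)
    zin <- integrate(function(r) r^2 * exp(-(well_energy(w, r) + w$epsilon) / kT),
                     lower = 0, upper = rc, rel.tol = 1e-10, subdivisions = 2000L)
    zout <- integrate(function(r) r^2 * exp(-well_energy(w, r) / kT),
                      lower = rc, upper = r_max, rel.tol = 1e-10, subdivisions = 2000L)
    if (zin$message != "OK" || zout$message != "OK") abort("Quadrature failed.")
    delta_f <- -kT * log(zout$value) + w$epsilon + kT * log(zin$value)
    structure(list(delta_f = delta_f,
                   log_z_bound = w$epsilon / kT + log(zin$value),
                   log_z_released = log(zout$value),
                   r_c = rc, r_max = r_max, kT = kT, mode = mode),
              class = "abd_free_energy")
  }
}

#' @export
print.abd_free_energy <- function(x, ...) {
  cat(sprintf("<abd_free_energy> delta F = %.6g kcal/mol (%s mode, kT = %g)\n",
              x$delta_f, x$mode, x$kT))
  invisible(x)
}

#' A ready-made two-bead pulling system
#'
#' Two beads bound by the breakable well (depth 5 kcal/mol, stiffness
#' 40 kcal/mol/nm^2, rest separation 0.5 nm, cutoff 1 nm) with a harmonic
#' trap (15 kcal/mol/nm^2) on their separation dragged from 0.5 nm at speed
#' `v`. At 300 K (kT = 0.593) and the default speeds the assay is in the
#' near-quasi-static regime analyzed by [analytic_delta_f()].
#'
#' @param v trap speed in nm/ps (default 0.05).
#' @param pull_distance total trap displacement in nm (default 1.0).
#' @param kT thermal energy (default 0.593).
#' @param dt timestep (default 5e-4 ps).
#' @return a [toy_langevin_spec()].
#' @export
two_bead_pull_spec <- function(v = 0.05, pull_distance = 1.0, kT = 0.593,
                               dt = 5e-4) {
  n_steps <- ceiling(pull_distance / (v * dt))
  toy_langevin_spec(
    positions0 = rbind(c(0, 0, 0), c(0.5, 0, 0)),
    zeta = 1, kT = kT,
    tethers = data.frame(i = 1, k = 10, x = 0, y = 0, z = 0),
    well = list(i = 1, j = 2, epsilon = 5, k = 40, r0 = 0.5),
    trap = list(k = 15, c0 = 0.5, v = v),
    dt = dt, n_steps = n_steps
  )
}

#' A ready-made six-bead antibody-like toy system for rupture assays
#'
#' Six beads at the Y-shaped template positions, harmonic springs along the
#' Fc stem and within each arm, the breakable well between beads 2 (Fc CH2)
#' and 5 (Fab2 CH1+CL), and constant pulling forces `+f` on each Fab2 bead
#' and `-f` on each Fc bead along the initial bead2 -> bead5 direction.
#'
#' @param f per-bead constant force (kcal/mol/nm).
#' @param kT thermal energy (default 0: deterministic descent).
#' @param epsilon,k_well well depth and stiffness.
#' @param dt,n_steps integration parameters.
#' @return a [toy_langevin_spec()].
#' @export
toy_antibody_langevin_spec <- function(f = 15, kT = 0,
                                       epsilon = 5, k_well = 40,
                                       dt = 5e-4, n_steps = 4000L) {
  spec_ab <- synthetic_antibody_spec(atoms_per_domain = 3, n_frames = 1, seed = 1)
  template <- place_beads(setNames(as.list(spec_ab$fluctuations$mean),
                                   spec_ab$fluctuations$label), spec_ab)
  dist_t <- function(i, j) sqrt(sum((template[i, ] - template[j, ])^2))
  r25 <- dist_t(2, 5)
  r_hat <- unit3(template[5, ] - template[2, ])
  forces <- matrix(0, 6, 3)
  for (b in c(1, 2)) forces[b, ] <- -f * r_hat
  for (b in c(5, 6)) forces[b, ] <- f * r_hat
  toy_langevin_spec(
    positions0 = template,
    zeta = 1, kT = kT,
    springs = data.frame(
      i = c(1, 2, 3, 5),
      j = c(2, 3, 4, 6),
      k = c(50, 50, 50, 50),
      r0 = c(dist_t(1, 2), dist_t(2, 3), dist_t(3, 4), dist_t(5, 6))
    ),
    tethers = data.frame(i = 1, k = 20, x = template[1, 1], y = template[1, 2],
                         z = template[1, 3]),
    well = list(i = 2, j = 5, epsilon = epsilon, k = k_well, r0 = r25),
    forces = forces,
    dt = dt, n_steps = n_steps
  )
}
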