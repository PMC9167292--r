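# Shared fixtures and independent brute-force oracles.

# Independent geometry oracles, formulated differently from the package
# (component-wise loops, cross-product angle, explicit normal construction).
oracle_distance <- function(p, q) {
  s <- 0
  for (d in 1:3) s <- s + (q[d] - p[d])^2
  sqrt(s)
}

oracle_angle <- function(pi_, pj, pk) {
  u <- pi_ - pj
  v <- pk - pj
  cr <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  y <- sum(cr(n1, n2) * b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  atan2(y, x) * 180 / pi
}

tiny_topology <- function(n = 10, chain = "A", atom_name = "CA",
                          residue_name = "ALA", element = "C") {
  abd_topology(tibble::tibble(
    atom_name = atom_name, element = element, chain_id = chain,
    residue_number = seq_len(n), residue_name = residue_name
  ))
}

# A small antibody system shared across tests (built once per test run).
shared_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_antibody_spec(atoms_per_domain = 10, n_frames = 60,
                                      seed = 101, n_triads = 3)
      sys <- build_synthetic_topology(spec)
      cache <<- list(
        spec = spec, sys = sys,
        assignment = assign_beads(sys$topology, sys$config),
        gen = generate_rigid_motion_trajectory(sys)
      )
    }
    cache
  }
})

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    rbind(
      c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
      c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
      c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2)
    )
  })
}
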