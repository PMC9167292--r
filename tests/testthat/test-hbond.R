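# Hydrogen-bond detection, bound-state criterion and persistence filters.

# A hand-built system: donors/acceptors at controllable geometry.
make_triad_frame <- function(ha = 0.20, angle = 160) {
  # donor N at origin, H at 0.1 nm along +x, acceptor placed at the given
  # H...A distance with the given D-H-A angle
  topo <- abd_topology(tibble::tibble(
    atom_name = c("N", "HN", "O"),
    element = c("N", "H", "O"),
    chain_id = c("A", "A", "B"),
    residue_number = c(1, 1, 2),
    residue_name = "ALA"
  ))
  u <- c(1, 0, 0)
  th <- (180 - angle) * pi / 180
  w <- c(cos(th), sin(th), 0)
  co <- rbind(c(0, 0, 0), 0.1 * u, 0.1 * u + ha * w)
  list(topology = topo, coords = co)
}

generic_assignment <- function(topology, frag_by_chain) {
  tibble::tibble(
    atom_index = topology$atom_index,
    bead_id = NA_integer_, bead_label = NA_character_,
    fragment = unname(frag_by_chain[topology$chain_id]),
    mass = topology$mass
  )
}

test_that("candidate enumeration pairs every N-H/O-H donor with every N/O acceptor", {
  x <- make_triad_frame()
  asg <- generic_assignment(x$topology, c(A = "Fab2", B = "Fc"))
  cands <- find_candidate_bonds(x$topology, x$coords, asg)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$donor_fragment, "Fab2")
  expect_equal(cands$acceptor_fragment, "Fc")
  # 3 donors x 2 acceptors across fragments -> 6 candidates
  topo <- abd_topology(tibble::tibble(
    atom_name = c("N", "HN", "N", "HN", "O", "HO", "O", "N"),
    element   = c("N", "H", "N", "H", "O", "H", "O", "N"),
    chain_id  = c("A", "A", "A", "A", "A", "A", "B", "B"),
    residue_number = c(1, 1, 2, 2, 3, 3, 10, 11),
    residue_name = "ALA"
  ))
  co <- rbind(c(0, 0, 0), c(0.1, 0, 0),
              c(1, 0, 0), c(1.1, 0, 0),
              c(2, 0, 0), c(2.1, 0, 0),
              c(5, 0, 0), c(6, 0, 0))
  asg2 <- generic_assignment(topo, c(A = "Fab2", B = "Fc"))
  cands2 <- find_candidate_bonds(topo, co, asg2)
  expect_equal(nrow(cands2), 3 * 2 + 3 * 2)
  # donors can also hit the other chain-A acceptors; restrict to interfragment:
  expect_equal(nrow(filter_interfragment(cands2, "Fab2", "Fc")), 6)
})

test_that("same-residue pairs are excluded and missing hydrogens are an error", {
  topo <- abd_topology(tibble::tibble(
    atom_name = c("N", "HN", "O"),
    element = c("N", "H", "O"),
    chain_id = "A", residue_number = c(1, 1, 1), residue_name = "ALA"
  ))
  co <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0))
  asg <- generic_assignment(topo, c(A = "Fc"))
  expect_equal(nrow(find_candidate_bonds(topo, co, asg)), 0)
  noh <- abd_topology(tibble::tibble(
    atom_name = c("N", "O"), element = c("N", "O"),
    chain_id = "A", residue_number = c(1, 2), residue_name = "ALA"
  ))
  expect_error(find_candidate_bonds(noh, co[c(1, 3), ], asg[c(1, 3), ]),
               "hydrogen")
})

test_that("the bound-state criterion uses strict cutoffs on distance and angle", {
  eval_one <- function(ha, angle, ...) {
    x <- make_triad_frame(ha, angle)
    asg <- generic_assignment(x$topology, c(A = "Fab2", B = "Fc"))
    cands <- find_candidate_bonds(x$topology, x$coords, asg)
    st <- evaluate_bound_states(abd_trajectory(x$coords, x$topology), cands, ...)
    st$bound[[1]]
  }
  expect_true(eval_one(0.20, 160))   # satisfies both published cutoffs
  expect_true(eval_one(0.249, 121))
  expect_false(eval_one(0.40, 160))  # distance fails
  expect_false(eval_one(0.20, 110))  # angle fails
  # strictness at the boundary: a frame sitting exactly at a cutoff is unbound
  x <- make_triad_frame(0.20, 160)
  d0 <- bead_distance(x$coords[2, ], x$coords[3, ])
  a0 <- bead_angle(x$coords[1, ], x$coords[2, ], x$coords[3, ])
  expect_false(eval_one(0.20, 160, dist_cutoff = d0))          # d == cutoff
  expect_true(eval_one(0.20, 160, dist_cutoff = d0 * (1 + 1e-9)))
  expect_false(eval_one(0.20, 160, angle_cutoff = a0))          # angle == cutoff
  expect_true(eval_one(0.20, 160, angle_cutoff = a0 * (1 - 1e-9)))
})

test_that("occupancy counts bound frames exactly", {
  x <- shared_system()
  traj <- x$gen$trajectory
  sched <- c(rep(TRUE, 8), rep(FALSE, n_frames(traj) - 8))
  traj <- plant_hbond_schedule(traj, x$sys, 1, sched)
  cands <- find_candidate_bonds(x$sys$topology, frame_coords(traj, 1),
                                x$assignment, max_ha_distance = 1.0)
  st <- evaluate_bound_states(traj, cands)
  row <- st[match(x$sys$triads$hydrogen_index[1],
                  cands$hydrogen_index), ]
  expect_equal(row$occupancy, 8 / n_frames(traj))
  expect_identical(row$bound[[1]], sched)
})

test_that("occupancy is invariant to frame order and monotone in the cutoffs", {
  x <- shared_system()
  traj <- x$gen$trajectory
  withr::with_seed(41, {
    scheds <- lapply(1:3, function(i) runif(n_frames(traj)) < 0.6)
  })
  for (t in 1:3) traj <- plant_hbond_schedule(traj, x$sys, t, scheds[[t]])
  cands <- find_candidate_bonds(x$sys$topology, frame_coords(traj, 1),
                                x$assignment, max_ha_distance = 1.0)
  st <- evaluate_bound_states(traj, cands)
  perm <- withr::with_seed(42, sample(n_frames(traj)))
  permuted <- traj
  permuted$coords <- traj$coords[perm, , , drop = FALSE]
  st_p <- evaluate_bound_states(permuted, cands)
  expect_equal(st_p$occupancy, st$occupancy)
  # tightening either cutoff never increases any occupancy
  tight_d <- evaluate_bound_states(traj, cands, dist_cutoff = 0.15)
  tight_a <- evaluate_bound_states(traj, cands, angle_cutoff = 170)
  expect_true(all(tight_d$occupancy <= st$occupancy))
  expect_true(all(tight_a$occupancy <= st$occupancy))
})

test_that("interfragment filtering is orientation-agnostic and keyed by triple", {
  tbl <- tibble::tibble(
    bond_key = c("k1--h1...a1", "k2--h2...a2", "k3--h3...a3", "k4--h4...a4"),
    donor_fragment = c("Fab2", "Fc", "Fc", "Fab1"),
    acceptor_fragment = c("Fc", "Fab2", "Fc", "Fc"),
    occupancy = c(0.9, 0.5, 0.8, 0.7)
  )
  kept <- filter_interfragment(tbl, "Fab2", "Fc")
  expect_equal(kept$bond_key, c("k1--h1...a1", "k2--h2...a2"))
  expect_error(filter_interfragment(tbl, "Fab3", "Fc"), "Unknown fragment")
})

test_that("persistence filter applies the strict threshold and replicate rule", {
  mk <- function(keys, occ) tibble::tibble(bond_key = keys, occupancy = occ)
  reps <- list(
    mk(c("a", "b", "c"), c(0.9, 0.80, 0.10)),
    mk(c("a", "c"), c(0.85, 0.95)),
    mk(c("a", "b"), c(0.10, 0.82))
  )
  rep_out <- persistence_filter(reps)
  # a: persistent in replicates 1 and 2 -> stable
  expect_equal(rep_out$stable, "a")
  # occupancy exactly 0.80 is not persistent (strict >)
  expect_false(any(rep_out$persistent$bond_key == "b" & rep_out$persistent$replicate == 1))
  # b persistent only in replicate 3; c only in replicate 2
  expect_equal(sort(unique(rep_out$persistent$bond_key)), c("a", "b", "c"))
  # missing bonds count as occupancy 0
  occ_b <- rep_out$occupancy[rep_out$occupancy$bond_key == "b", ]
  expect_equal(occ_b$replicate_2, 0)
  g <- glance(rep_out)
  expect_equal(g$n_stable, 1)
  expect_equal(g$n_persistent_any, 3)
})

test_that("bond counts per frame equal the schedule sums", {
  x <- shared_system()
  traj <- x$gen$trajectory
  withr::with_seed(43, {
    scheds <- lapply(1:3, function(i) runif(n_frames(traj)) < 0.5)
  })
  for (t in 1:3) traj <- plant_hbond_schedule(traj, x$sys, t, scheds[[t]])
  cands <- find_candidate_bonds(x$sys$topology, frame_coords(traj, 1),
                                x$assignment, max_ha_distance = 1.0)
  st <- evaluate_bound_states(traj, cands)
  counts <- bond_count_series(st)
  expected <- Reduce(`+`, lapply(scheds, as.integer))
  expect_equal(counts$count, expected)
  empty <- st[0, ]
  expect_equal(nrow(bond_count_series(empty)), 0)
})
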