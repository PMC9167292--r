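# Calpha selection, Kabsch alignment and the essential-dynamics PCA.

test_that("Calpha selection takes CA atoms of amino acids only, in file order", {
  topo <- abd_topology(tibble::tibble(
    atom_name = c("N", "CA", "C", "CA", "C1", "CA"),
    element = c("N", "C", "C", "C", "C", "CA"),
    chain_id = "A",
    residue_number = c(1, 1, 1, 2, 3, 4),
    residue_name = c("ALA", "ALA", "ALA", "GLY", "NAG", "NAG")
  ))
  # residue 3 is a glycan (NAG): its atoms, even one *named* CA, are excluded
  expect_equal(select_calpha(topo), c(1L, 3L))
  x <- shared_system()
  ca <- select_calpha(x$sys$topology)
  expect_equal(length(ca), 6 * 10 + 3) # domain + hinge pseudo-Calphas
  glyc <- abd_topology(tibble::tibble(
    atom_name = "C1", element = "C", chain_id = "A",
    residue_number = 1, residue_name = "NAG"
  ))
  expect_error(select_calpha(glyc), "no Calpha")
})

test_that("Kabsch alignment recovers known rigid transforms with proper rotations", {
  withr::with_seed(51, {
    P <- matrix(rnorm(60, sd = 2), 20, 3)
    for (i in 1:10) {
      R <- random_rotation(100 + i)
      t_vec <- rnorm(3, sd = 5)
      Q <- sweep(P %*% t(R), 2, t_vec, `+`)
      co <- array(0, c(2, 20, 3))
      co[1, , ] <- P
      co[2, , ] <- Q
      traj <- abd_trajectory(co, tiny_topology(20))
      al <- align_frames(traj, 0:19, reference_frame = 1)
      expect_lt(coord_rmsd(frame_coords(al, 2), P), 1e-10)
    }
  })
})

test_that("alignment of the identical frame is the identity and degenerate subsets error", {
  withr::with_seed(52, {
    P <- matrix(rnorm(30), 10, 3)
  })
  co <- array(0, c(2, 10, 3)); co[1, , ] <- P; co[2, , ] <- P
  traj <- abd_trajectory(co, tiny_topology(10))
  al <- align_frames(traj, 0:9)
  expect_lt(max(abs(al$coords - traj$coords)), 1e-12)
  # collinear subset
  line <- cbind(1:10, 0, 0)
  co2 <- array(0, c(2, 10, 3)); co2[1, , ] <- line; co2[2, , ] <- line
  expect_error(align_frames(abd_trajectory(co2, tiny_topology(10)), 0:9),
               "collinear|degenerate")
  expect_error(align_frames(traj, 0:1), "at least 3")
})

test_that("a mirror-image frame gets the best proper rotation, never a reflection", {
  withr::with_seed(53, {
    P <- matrix(rnorm(45, sd = 2), 15, 3)
  })
  M <- P %*% diag(c(1, 1, -1)) # reflection
  tr <- abdyn:::kabsch_transform(M, P)
  expect_equal(det(tr$R), 1, tolerance = 1e-12)
  # a reflection cannot be undone by a proper rotation: RMSD stays > 0
  aligned <- sweep(M %*% tr$R, 2, tr$t, `+`)
  expect_gt(coord_rmsd(aligned, P), 0.1)
})

test_that("a two-frame trajectory gives a rank-1 covariance along the displacement", {
  withr::with_seed(54, {
    A <- matrix(rnorm(30), 10, 3)
    B <- A + matrix(rnorm(30, sd = 0.1), 10, 3)
  })
  co <- array(0, c(2, 10, 3)); co[1, , ] <- A; co[2, , ] <- B
  traj <- abd_trajectory(co, tiny_topology(10))
  ed <- fit_essential_dynamics(traj, 0:9)
  expect_gt(ed$eigenvalues[1], 0)
  expect_lt(max(ed$eigenvalues[-1]), 1e-12 * ed$eigenvalues[1])
  # PC1 parallel to the inter-frame displacement
  disp <- as.vector(t(B - A))
  cosang <- abs(sum(disp * ed$eigenvectors[, 1])) / sqrt(sum(disp^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
  expect_error(fit_essential_dynamics(abd_trajectory(A, tiny_topology(10)), 0:9),
               "two frames")
})

test_that("eigenvalues conserve total variance and eigenvectors are orthonormal", {
  x <- shared_system()
  ca <- select_calpha(x$sys$topology)
  fc_ca <- intersect(ca, x$assignment$atom_index[x$assignment$fragment == "Fc"])
  al <- align_frames(x$gen$trajectory, fc_ca)
  ed <- fit_essential_dynamics(al, ca)
  expect_equal(ed$total_variance, ed$trace_covariance,
               tolerance = 1e-9)
  V <- ed$eigenvectors[, 1:10]
  G <- crossprod(V)
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(ed$eigenvalues) <= 1e-12))
  expect_true(all(ed$eigenvalues >= 0))
})

test_that("a planted collective mode is recovered with its variance", {
  withr::with_seed(55, {
    M <- 20
    nf <- 2000
    base <- matrix(rnorm(M * 3, sd = 2), M, 3)
    mode <- matrix(rnorm(M * 3), M, 3)
    mode <- mode / sqrt(sum(mode^2))
    amp <- rnorm(nf, sd = sqrt(0.5)) # planted variance 0.5 nm^2
    eps <- 0.02                      # isotropic noise variance per coordinate
    co <- array(0, c(nf, M, 3))
    for (f in 1:nf) {
      co[f, , ] <- base + amp[f] * mode + matrix(rnorm(M * 3, sd = sqrt(eps)), M, 3)
    }
    ed <- fit_essential_dynamics(abd_trajectory(co, tiny_topology(M)), 0:(M - 1))
    v_expected <- 0.5 + eps
    expect_lt(abs(ed$eigenvalues[1] - v_expected) / v_expected, 0.10)
  })
})

test_that("partial projections decompose the full PC score over disjoint subsets", {
  x <- shared_system()
  ca <- select_calpha(x$sys$topology)
  fc_ca <- intersect(ca, x$assignment$atom_index[x$assignment$fragment == "Fc"])
  al <- align_frames(x$gen$trajectory, fc_ca)
  ed <- fit_essential_dynamics(al, ca)
  frg <- lapply(c("Fc", "Fab1", "Fab2", "hinge"), function(fr) {
    intersect(ca, x$assignment$atom_index[x$assignment$fragment == fr])
  })
  full <- project_component(ed, 1)$score
  full2 <- project_component(ed, 1, ca)$score
  expect_equal(full2, full, tolerance = 1e-12)
  parts <- lapply(frg, function(s) project_component(ed, 1, s)$score)
  expect_equal(Reduce(`+`, parts), full, tolerance = 1e-9)
  expect_error(project_component(ed, 1, c(99999L)), "outside")
  expect_error(project_component(ed, 999), "not in fit")
})

test_that("atom contributions are eigenvector blocks with unit total square norm", {
  x <- shared_system()
  ca <- select_calpha(x$sys$topology)
  al <- align_frames(x$gen$trajectory, ca[1:20])
  ed <- fit_essential_dynamics(al, ca)
  ac <- atom_contributions(ed, 1)
  expect_equal(sum(ac$magnitude^2), 1, tolerance = 1e-10)
  # null-space components are flagged
  k_null <- length(ed$eigenvalues)
  ac_null <- atom_contributions(ed, k_null)
  expect_true(all(ac_null$null_space))
})

test_that("PCA is invariant to a rigid transform applied before alignment", {
  x <- shared_system()
  ca <- select_calpha(x$sys$topology)
  fc_ca <- intersect(ca, x$assignment$atom_index[x$assignment$fragment == "Fc"])
  traj <- x$gen$trajectory
  R <- random_rotation(56)
  t_vec <- c(5, -3, 1)
  moved <- traj
  flat <- matrix(aperm(traj$coords, c(2, 1, 3)), ncol = 3)
  mflat <- sweep(flat %*% t(R), 2, t_vec, `+`)
  moved$coords <- aperm(array(mflat, c(dim(traj$coords)[2], dim(traj$coords)[1], 3)),
                        c(2, 1, 3))
  ed1 <- fit_essential_dynamics(align_frames(traj, fc_ca), ca)
  ed2 <- fit_essential_dynamics(align_frames(moved, fc_ca), ca)
  expect_equal(ed2$eigenvalues[1:5], ed1$eigenvalues[1:5], tolerance = 1e-8)
})
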