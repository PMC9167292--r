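# Structure / trajectory / config / results IO.

test_that("PDB coordinates are converted from Angstrom to nm exactly once", {
  pdb <- c(
    "ATOM      1  N   ALA H   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA H   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  O   GLY L   5       0.300   0.400   0.000  1.00  0.00           O",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  st <- read_structure(f)
  expect_equal(nrow(st$topology), 3)
  expect_equal(frame_coords(st$trajectory, 1)[1, ], c(x = 1, y = 0, z = 0))
  expect_equal(frame_coords(st$trajectory, 1)[2, ], c(x = 0.1, y = 0.2, z = 0.3))
  expect_equal(chains(st$topology), c("H", "L"))
  expect_equal(st$topology$mass[1], 14.007)
})

test_that("structure read errors are informative", {
  expect_error(read_structure("no/such/file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here"), f)
  expect_error(read_structure(f))
})

test_that("a synthetic topology survives a PDB write/read round trip", {
  x <- shared_system()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(x$sys$topology, x$sys$frame0, f)
  st <- read_structure(f)
  expect_equal(st$topology$atom_name, x$sys$topology$atom_name)
  expect_equal(st$topology$chain_id, x$sys$topology$chain_id)
  expect_equal(st$topology$residue_number, x$sys$topology$residue_number)
  expect_equal(st$topology$residue_name, x$sys$topology$residue_name)
  expect_equal(st$topology$element, x$sys$topology$element)
  # PDB stores 3 decimals in Angstrom -> 5e-5 nm worst case
  expect_lt(max(abs(frame_coords(st$trajectory, 1) - x$sys$frame0)), 1e-4)
})

test_that("DCD write/read round trip preserves coordinates to format precision", {
  x <- shared_system()
  traj <- x$gen$trajectory
  f <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(traj, f)
  back <- read_trajectory(f, x$sys$topology)
  expect_equal(n_frames(back), n_frames(traj))
  # float32 Angstrom storage: ~1e-6 nm at these magnitudes
  expect_lt(max(abs(back$coords - traj$coords)), 1e-5)
})

test_that("trajectory reading validates atom counts and formats", {
  x <- shared_system()
  f <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(x$gen$trajectory, f)
  expect_error(read_trajectory(f, tiny_topology(5)), "mismatch")
  expect_error(read_trajectory("traj.xtc", x$sys$topology), "not found")
  f2 <- withr::local_tempfile(fileext = ".xtc")
  writeLines("x", f2)
  expect_error(read_trajectory(f2, x$sys$topology), "XTC")
  # single-frame file
  one <- abd_trajectory(x$sys$frame0, x$sys$topology)
  f3 <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(one, f3)
  expect_equal(n_frames(read_trajectory(f3, x$sys$topology)), 1)
})

test_that("config defaults equal the published hydrogen-bond and pulling parameters", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "mode: antibody",
    "beads:",
    paste0(vapply(1:6, function(i) paste0(
      "  - {id: ", i, ", label: b", i,
      ", select: [{chain: A, resid: [", (i - 1) * 10 + 1, ", ", i * 10, "]}]}"
    ), character(1)))
  ), f)
  cfg <- read_config(f)
  expect_equal(cfg$parameters$hbond_distance_cutoff, 0.25)
  expect_equal(cfg$parameters$hbond_angle_cutoff, 120)
  expect_equal(cfg$parameters$occupancy_threshold, 0.80)
  expect_equal(cfg$parameters$min_replicates, 2L)
  expect_equal(cfg$parameters$pull_force, 0.01)
})

test_that("config validation rejects overlaps, empty selections and unknown keys", {
  base <- function(extra_bead2) list(
    mode = "antibody",
    beads = c(list(list(id = 1, label = "b1",
                        select = list(list(chain = "H", resid = c(1, 100))))),
              extra_bead2)
  )
  overlapping <- base(lapply(2:6, function(i) {
    sel <- if (i == 2) list(list(chain = "H", resid = c(50, 150)))
           else list(list(chain = "X", resid = c(i * 100, i * 100 + 10)))
    list(id = i, label = paste0("b", i), select = sel)
  }))
  expect_error(validate_config(overlapping), "claim")
  empty_sel <- base(lapply(2:6, function(i) {
    list(id = i, label = paste0("b", i),
         select = if (i == 3) list() else list(list(chain = "X", resid = c(i, i))))
  }))
  expect_error(validate_config(empty_sel), "empty selection")
  five <- list(mode = "antibody", beads = lapply(1:5, function(i) {
    list(id = i, select = list(list(chain = "A", resid = c(i * 10, i * 10 + 5))))
  }))
  expect_error(validate_config(five), "1..6")
  unk <- list(mode = "antibody", frobnicate = 1, beads = list())
  expect_error(validate_config(unk), "Unknown config keys")
  unk_param <- list(
    mode = "generic",
    beads = list(list(id = 1, select = list(list(chain = "A", resid = c(1, 5))))),
    parameters = list(hbond_distance_cutof = 0.3)
  )
  expect_error(validate_config(unk_param), "Unknown parameters")
})

test_that("result writing is deterministic and round-trips tables", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  occ <- data.frame(bond_key = c("a", "b"), occupancy = c(0.91, 0.15))
  res <- list(
    occupancy = occ,
    empty_series = data.frame(frame = integer(0), label = character(0),
                              value = numeric(0)),
    work = list(W = 1.5, fab2_term = 2.0, fc_term = 0.5)
  )
  write_results(res, out1, manifest = list(seed = 7))
  write_results(res, out2, manifest = list(seed = 7))
  expect_identical(readLines(file.path(out1, "occupancy.csv")),
                   readLines(file.path(out2, "occupancy.csv")))
  back <- read.csv(file.path(out1, "occupancy.csv"))
  expect_equal(back$occupancy, occ$occupancy)
  # header-only CSV is still a valid file
  empty <- readLines(file.path(out1, "empty_series.csv"))
  expect_equal(length(empty), 1)
  wk <- jsonlite::read_json(file.path(out1, "work.json"))
  expect_named(wk, c("W", "fab2_term", "fc_term"))
  mf <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(mf$seed, 7)
})
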