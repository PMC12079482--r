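test_that("multi-model PDB round-trips frames, coordinates and bytes", {
  sc <- make_contact_scaffold(8, NULL, seed = 2)
  ens <- make_fluctuation_ensemble(sc, 0.4, 2, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, tmp)
  back <- read_pdb(tmp)
  expect_equal(n_frames(back), 2L)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  # PDB fixed-width precision is 3 decimals
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3)
  # read-write-read is a fixed point
  write_pdb(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("malformed models and insertion codes are rejected", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.100   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), bad)
  expect_error(read_pdb(bad), "topology")

  ins <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C",
    ins)
  expect_error(read_pdb(ins), "insertion")
})

test_that("alternate locations resolve to the highest occupancy", {
  alt <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   5       3.800   0.000   0.000  1.00  0.00           C"),
    alt)
  ens <- read_pdb(alt)
  expect_equal(nrow(ens$atoms), 2L)
  expect_equal(unname(frame_coords(ens)[1, "x"]), 1.0)  # 0.60-occupancy copy
})

test_that("frame CSV interchange preserves the ensemble", {
  sc <- make_contact_scaffold(6, NULL, seed = 4)
  ens <- make_fluctuation_ensemble(sc, 0.2, 3, seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(ens, csv)
  back <- read_frame_csv(csv)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$xyz, ens$xyz, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pose sets index poses and count skipped files", {
  d <- withr::local_tempdir()
  for (k in 1:5) {
    write_pdb(make_dimer_pose(8, 8, contacts = data.frame(res_a = 3, res_b = 3)),
              file.path(d, sprintf("pose_%d.pdb", k)))
  }
  # a 1-chain intruder is skipped with a warning
  write_pdb(make_ideal_helix(5), file.path(d, "single_chain.pdb"))
  expect_warning(ps <- read_pose_set(d), "skipping")
  expect_length(ps, 5L)
  expect_equal(ps$n_skipped, 1L)

  empty <- withr::local_tempdir()
  expect_warning(e <- read_pose_set(empty), "empty")
  expect_length(e, 0L)
})

test_that("ensemble invariants are enforced", {
  atoms <- data.frame(chain = "A", resno = c(1, 1, 2), resname = "GLY",
                      elety = c("CA", "CB", "CA"), element = "C")
  expect_error(ensemble(atoms, rep(0, 6)), "expected")
  expect_error(ensemble(atoms, c(rep(0, 8), Inf)), "finite")
  expect_error(ensemble(atoms, rep(0, 9), time_ns = c(2, 1)),
               "one time stamp")
  bad <- atoms; bad$resno <- c(2, 2, 1)
  expect_error(ensemble(bad, rep(0, 9)), "sorted")
  # CG detection
  ca <- data.frame(chain = "A", resno = 1:3, resname = "GLY",
                   elety = "CA", element = "C")
  expect_true(ensemble(ca, rep(0:2, each = 3))$cg)
})
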