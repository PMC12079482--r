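test_that("ideal helix geometry is canonical", {
  h <- make_ideal_helix(12)
  ca <- frame_coords(h)[h$atoms$elety == "CA", ]
  steps <- sqrt(rowSums((ca[-1, ] - ca[-12, ])^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  d3 <- vapply(1:9, function(i) sqrt(sum((ca[i, ] - ca[i + 3, ])^2)),
               numeric(1))
  expect_true(all(d3 >= 4.8 & d3 <= 5.6))
  d4 <- vapply(1:8, function(i) sqrt(sum((ca[i, ] - ca[i + 4, ])^2)),
               numeric(1))
  expect_true(all(d4 >= 5.9 & d4 <= 6.9))
  expect_error(make_ideal_helix(3), "at least 4")
})

test_that("generators are deterministic given spec and seed", {
  a <- make_contact_scaffold(30, data.frame(i = 5, j = 20), seed = 42)
  b <- make_contact_scaffold(30, data.frame(i = 5, j = 20), seed = 42)
  expect_identical(a$xyz, b$xyz)
  c <- make_contact_scaffold(30, data.frame(i = 5, j = 20), seed = 43)
  expect_false(identical(c$xyz, a$xyz))
  e1 <- make_fluctuation_ensemble(a, 0.4, 5, seed = 7)
  e2 <- make_fluctuation_ensemble(b, 0.4, 5, seed = 7)
  expect_identical(e1$xyz, e2$xyz)
  # byte-identical PDB output
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(e1, f1); write_pdb(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(make_contact_scaffold(20, NULL, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("scaffolds self-verify their planted contact topology", {
  # a planted nested ladder has an all-parallel census
  lad <- data.frame(i = c(2, 4, 6, 8), j = c(40, 38, 36, 34))
  sc <- make_contact_scaffold(42, lad, seed = 12)
  cen <- topology_census(residue_contacts(sc))
  expect_equal(c(cen$n_P, cen$n_S, cen$n_X), c(6L, 0L, 0L))
  # contact-free chains stay contact-free
  empty <- make_contact_scaffold(50, NULL, seed = 13)
  expect_equal(nrow(residue_contacts(empty)), 0L)
  # infeasible plant is rejected up front
  expect_error(make_contact_scaffold(20, data.frame(i = 5, j = 7)),
               "neighbour exclusion")
})

test_that("fluctuation ensembles honour sigma and schedules", {
  base <- make_contact_scaffold(30, NULL, seed = 14)
  rigid <- make_fluctuation_ensemble(base, 0, 4, seed = 1)
  expect_true(all(rigid$xyz[1, ] == rigid$xyz[4, ]))
  ens <- make_fluctuation_ensemble(
    base, 0.2, 10, schedule = list(list(i = 4L, j = 22L, on = c(2L, 5L, 9L))),
    seed = 2)
  cf <- contact_frequency(ens)
  expect_equal(cf$frequency[cf$i == 4 & cf$j == 22], 0.3)
  per_frame <- vapply(1:10, function(f) {
    cm <- residue_contacts(ens, f)
    any(cm$i == 4 & cm$j == 22)
  }, logical(1))
  expect_equal(which(per_frame), c(2L, 5L, 9L))
  expect_equal(ens$time_ns, seq(0, by = 25, length.out = 10))
})

test_that("dimer designs reject conflicting specifications", {
  expect_error(make_dimer_pose(10, 10,
                               contacts = data.frame(res_a = c(3, 3),
                                                     res_b = c(5, 8))),
               "only one pair")
  expect_error(make_dimer_pose(10, 10,
                               contacts = data.frame(res_a = 12, res_b = 5)),
               "outside")
  expect_error(make_dimer_pose(
    20, 20,
    interactions = list(list(type = "salt_bridge", res_a = 5, res_b = 5),
                        list(type = "pi_stacking", res_a = 7, res_b = 7))),
    ">= 4 residues")
})
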