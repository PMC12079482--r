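random_cloud <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), ncol = 3)
}

rotation_matrix <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

test_that("superposition removes rigid motion and preserves chirality", {
  x <- random_cloud(20, seed = 3)
  moved <- x %*% t(rotation_matrix(0.4, -1.1, 2.2)) +
    matrix(rep(c(5, -3, 8), each = 20), ncol = 3)
  fit <- kabsch_superpose(moved, x)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # mirror images cannot be superposed by proper rotations
  mirror <- x %*% diag(c(1, 1, -1))
  expect_gt(kabsch_superpose(mirror, x)$rmsd, 0.5)
  # collinear selections are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("superposition attains the numerically optimal RMSD", {
  x <- random_cloud(12, seed = 8)
  y <- x
  y[1, ] <- y[1, ] + c(2.5, 0, 0)  # one displaced atom
  got <- kabsch_superpose(y, x)$rmsd
  # independent numeric optimization over rotations + translation
  objective <- function(par) {
    r <- rotation_matrix(par[1], par[2], par[3])
    moved <- sweep(y %*% t(r), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - x)^2)))
  }
  direct <- optim(rep(0, 6), objective, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))$value
  expect_equal(got, direct, tolerance = 1e-5)
  # and the bio3d fitter agrees
  ref_fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(x)), as.vector(t(y))))
  bio3d_rmsd <- sqrt(mean(rowSums(
    (matrix(ref_fit, ncol = 3, byrow = TRUE) - x)^2)))
  expect_equal(got, bio3d_rmsd, tolerance = 1e-6)
})

test_that("RMSF recovers planted fluctuation amplitudes", {
  base <- make_contact_scaffold(40, NULL, seed = 5)
  # rigid ensemble: zero everywhere
  rigid <- make_fluctuation_ensemble(base, 0, 3, seed = 1)
  expect_true(all(rmsf_profile(rigid)$rmsf < 1e-9))
  # isotropic Gaussian displacements of SD sigma -> RMSF = sigma * sqrt(3)
  ens <- make_fluctuation_ensemble(base, 0.5, 800, seed = 2)
  prof <- rmsf_profile(ens, units = "angstrom")
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.05)
  # global rigid motion per frame is removed by superposition
  rot <- rotation_matrix(0.3, 0.2, -0.5)
  xyz2 <- t(apply(ens$xyz[1:50, ], 1, function(v) {
    as.vector(t(matrix(v, ncol = 3, byrow = TRUE) %*% t(rot) + 7))
  }))
  both <- ensemble(ens$atoms, rbind(ens$xyz[1:50, ], xyz2))
  p50 <- rmsf_profile(subset_frames(ens, 1:50))
  expect_lt(max(abs(rmsf_profile(both)$rmsf - p50$rmsf)), 0.02)
  # two frames, one residue displaced by d, no superposition: RMSF = d/2
  co <- frame_coords(make_ideal_helix(10))
  shifted <- co; shifted[2, ] <- shifted[2, ] + c(3, 0, 0)
  two <- ensemble(make_ideal_helix(10)$atoms,
                  rbind(as.vector(t(co)), as.vector(t(shifted))))
  p2 <- rmsf_profile(two, selection = "CA", superpose = FALSE,
                     units = "angstrom")
  expect_equal(p2$rmsf[1], 3 / 2)  # atom 2 is CA of residue 1
  expect_true(all(p2$rmsf[-1] == 0))
})

test_that("helix assignment matches planted secondary structure", {
  expect_true(all(assign_secondary_structure(make_ideal_helix(12))))
  expect_false(any(assign_secondary_structure(make_extended_chain(12))))
  seg <- c(rep(TRUE, 8), rep(FALSE, 10), rep(TRUE, 8))
  got <- assign_secondary_structure(make_segmented_chain(seg))
  expect_equal(got, seg)
  # CA-only path agrees on the ideal helix
  h <- make_ideal_helix(12)
  ca_only <- ensemble(h$atoms[h$atoms$elety == "CA", ],
                      as.vector(t(frame_coords(h)[h$atoms$elety == "CA", ])))
  expect_true(all(assign_secondary_structure(ca_only)))
})

test_that("helicity content counts residue-frames and uses population SD", {
  hel <- make_ideal_helix(40)
  ext <- make_extended_chain(40)
  seg10 <- make_segmented_chain(c(rep(FALSE, 15), rep(TRUE, 10),
                                  rep(FALSE, 15)))
  # all-helix ensemble: 100% and every residue stable
  all_h <- ensemble(hel$atoms, rbind(hel$xyz, hel$xyz))
  hp <- helicity_profile(all_h)
  expect_equal(hp$content_mean, 100)
  expect_true(all(hp$probability$stable))
  # helix in 1 of 4 frames on a 10-residue segment: 10/(40*4) = 6.25%
  mix <- ensemble(ext$atoms, rbind(seg10$xyz, ext$xyz, ext$xyz, ext$xyz))
  hp2 <- helicity_profile(mix)
  expect_equal(hp2$content_percent, 6.25)
  expect_false(any(hp2$probability$stable))  # max probability 0.25 < 0.30
  # replicate contents {0, 6.25, 25/40*100/4}: mean and population SD
  rep3 <- list(ensemble(ext$atoms, ext$xyz), mix, all_h)
  hp3 <- helicity_profile(rep3)
  expect_equal(hp3$content_percent, c(0, 6.25, 100))
  expect_equal(hp3$content_mean, mean(c(0, 6.25, 100)))
  expect_equal(hp3$content_sd, sqrt(mean((c(0, 6.25, 100) -
                                            mean(c(0, 6.25, 100)))^2)))
})

test_that("GROMOS clustering recovers planted basins deterministically", {
  tb <- make_two_basin_ensemble(40, 15, seed = 9)
  cl <- gromos_cluster(tb)
  expect_equal(length(cl$sizes), 2L)
  expect_equal(cl$sizes, c(15L, 15L))
  # planted memberships recovered exactly (up to label order)
  tab <- table(attr(tb, "basin"), cl$membership)
  expect_true(all(tab %in% c(0L, 15L)))
  # identical frames collapse to one cluster; infinite cutoff likewise
  rigid <- ensemble(tb$atoms, tb$xyz[rep(1, 6), ])
  expect_equal(length(gromos_cluster(rigid)$sizes), 1L)
  expect_equal(length(gromos_cluster(tb, cutoff_nm = Inf)$sizes), 1L)
  # deterministic rerun
  cl2 <- gromos_cluster(tb)
  expect_identical(cl$membership, cl2$membership)
  # every member lies within the cutoff of its center
  rmsd <- pairwise_rmsd(tb)
  for (k in seq_along(cl$centers)) {
    members <- which(cl$membership == k)
    expect_true(all(rmsd[cl$centers[k], members] <= cl$cutoff_nm * 10))
  }
})

test_that("representative selection honours the coverage rule", {
  expect_length(select_representatives(c(60, 30, 10), 0.5), 1L)
  expect_length(select_representatives(c(30, 25, 25, 20), 0.5), 2L)
  expect_length(select_representatives(c(60, 30, 10), 1.0), 3L)
  expect_error(select_representatives(c(10, 5), 0), "coverage")
  expect_error(select_representatives(c(10, 5), 1.5), "coverage")
})
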