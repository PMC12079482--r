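# two-residue fixture with a controllable number of close atom pairs:
# k atom pairs at `close` Angstrom, the rest far apart
two_residue_fixture <- function(k_close, n_atoms = 5L, close = 4.0) {
  ys <- (seq_len(n_atoms) - 1) * 100
  yb <- ys
  if (k_close < n_atoms) {
    yb[(k_close + 1):n_atoms] <- yb[(k_close + 1):n_atoms] + 50
  }
  atoms <- data.frame(
    chain = "A",
    resno = rep(c(1L, 6L), each = n_atoms),
    resname = "GLY",
    elety = rep(c("CA", paste0("D", seq_len(n_atoms - 1L))), 2),
    element = "C")
  co <- rbind(cbind(0, ys, 0), cbind(close, yb, 0))
  ensemble(atoms, as.vector(t(co)))
}

test_that("the atom-pair count threshold decides contacts", {
  crit <- contact_criteria(cutoff = 4.5, min_pairs = 5, exclude = 3)
  # exactly 5 atom pairs at 4.0 A: contact
  cm5 <- residue_contacts(two_residue_fixture(5), criteria = crit)
  expect_equal(nrow(cm5), 1L)
  expect_equal(c(cm5$i, cm5$j, cm5$n_atom_pairs), c(1L, 6L, 5L))
  # 4 pairs: no contact
  expect_equal(nrow(residue_contacts(two_residue_fixture(4), criteria = crit)),
               0L)
})

test_that("planted scaffolds match the brute-force all-pairs oracle", {
  for (seed in 1:4) {
    n <- c(20L, 30L, 40L, 25L)[seed]
    planted <- list(
      data.frame(i = c(2, 10), j = c(16, 20)),
      data.frame(i = c(5, 9, 3), j = c(25, 20, 14)),
      data.frame(i = c(2, 30), j = c(30, 38)),
      data.frame(i = integer(0), j = integer(0)))[[seed]]
    sc <- make_contact_scaffold(n, planted, seed = seed)
    got <- residue_contacts(sc)
    oracle <- brute_contacts(sc)
    expect_equal(got$i, oracle$i)
    expect_equal(got$j, oracle$j)
    want <- attr(sc, "contacts")
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
  }
})

test_that("contacts respect exclusion, symmetry and monotonicity", {
  sc <- make_contact_scaffold(30, data.frame(i = c(4, 10), j = c(20, 26)),
                              seed = 6)
  crit <- contact_criteria()
  cm <- residue_contacts(sc, criteria = crit)
  expect_true(all(cm$j - cm$i > crit$exclude))
  # atom order within residues is irrelevant
  perm <- order(sc$atoms$resno, rev(seq_len(nrow(sc$atoms))))
  shuffled <- ensemble(sc$atoms[perm, ],
                       as.vector(t(frame_coords(sc)[perm, ])))
  cm2 <- residue_contacts(shuffled, criteria = crit)
  expect_equal(cm2$i, cm$i)
  expect_equal(cm2$j, cm$j)
  # enlarging the cutoff or lowering min_pairs never removes a contact
  wider <- residue_contacts(sc, criteria = contact_criteria(cutoff = 6))
  expect_true(all(paste(cm$i, cm$j) %in% paste(wider$i, wider$j)))
  looser <- residue_contacts(sc, criteria = contact_criteria(min_pairs = 1))
  expect_true(all(paste(cm$i, cm$j) %in% paste(looser$i, looser$j)))
})

test_that("CG bead input demands compatible criteria", {
  ca <- data.frame(chain = "A", resno = 1:10, resname = "GLY",
                   elety = "CA", element = "C")
  ens <- ensemble(ca, as.vector(t(cbind(seq(0, by = 3.8, length.out = 10), 0, 0))))
  expect_error(residue_contacts(ens), "min_pairs")
  expect_silent(residue_contacts(ens, criteria = contact_criteria(min_pairs = 1)))
})

test_that("contact frequency counts scheduled frames exactly", {
  base <- make_contact_scaffold(45, NULL, seed = 8)
  sch <- list(list(i = 5L, j = 40L, on = 1:17))
  ens <- make_fluctuation_ensemble(base, 0.2, 34, schedule = sch, seed = 9)
  cf <- contact_frequency(ens)
  hit <- cf[cf$i == 5 & cf$j == 40, ]
  expect_equal(hit$frequency, 0.5)
  # rigid ensembles only show frequencies 0 or 1
  rigid <- make_fluctuation_ensemble(base, 0, 4, seed = 10)
  cf0 <- contact_frequency(rigid)
  expect_true(all(cf0$frequency %in% c(0, 1)))
  expect_error(contact_frequency(ens, frames = integer(0)), "no frames")
})

test_that("group contact fractions aggregate replicates with population SD", {
  base <- make_contact_scaffold(40, NULL, seed = 11)
  fracs <- c(0.2, 0.5, 0.8)
  reps <- lapply(1:3, function(r) {
    make_fluctuation_ensemble(
      base, 0.2, 10,
      schedule = list(list(i = 10L, j = 30L, on = seq_len(10 * fracs[r]))),
      seed = 20 + r, replicate = r)
  })
  out <- group_contact_fraction(reps, 1:20, 21:40)
  expect_equal(out$per_replicate, fracs)
  expect_equal(out$mean, 0.5)
  expect_equal(out$sd, sqrt(mean((fracs - 0.5)^2)))
  expect_error(group_contact_fraction(reps, 1:20, 15:40), "disjoint")
})
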