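test_that("pairwise relations follow the closed-interval rules", {
  expect_equal(classify_relation(c(1, 10), c(12, 20)), "S")
  expect_equal(classify_relation(c(1, 10), c(3, 7)), "P")
  expect_equal(classify_relation(c(3, 7), c(1, 10)), "Pinv")
  expect_equal(classify_relation(c(1, 10), c(5, 15)), "X")
  # deterministic ties at shared endpoints
  expect_equal(classify_relation(c(1, 10), c(10, 15)), "S")   # touching
  expect_equal(classify_relation(c(1, 10), c(1, 5)), "P")     # shared start
  expect_equal(classify_relation(c(2, 10), c(5, 10)), "P")    # shared end
  expect_error(classify_relation(c(1, 5), c(1, 5)), "identical")
})

test_that("census matches the interval-overlap oracle on random maps", {
  set.seed(101)
  for (rep in 1:200) {
    cm <- random_contact_map(sample(2:60, 1), len = 150L)
    cen <- topology_census(cm)
    ora <- oracle_census(cm)
    expect_equal(c(cen$n_S, cen$n_P, cen$n_X), unname(ora))
    # completeness: the three relations partition all contact pairs
    expect_equal(cen$n_S + cen$n_P + cen$n_X, choose(nrow(cm), 2))
  }
  # nested ladder: all 6 pairs parallel
  lad <- topology_census(data.frame(i = 1:4, j = 20:17))
  expect_equal(c(lad$n_S, lad$n_P, lad$n_X), c(0L, 6L, 0L))
  empty <- topology_census(data.frame(i = integer(0), j = integer(0)))
  expect_equal(c(empty$n_S, empty$n_P, empty$n_X), c(0L, 0L, 0L))
})

test_that("census is invariant under chain reversal", {
  set.seed(202)
  len <- 120L
  for (rep in 1:50) {
    cm <- random_contact_map(sample(2:40, 1), len = len)
    rev_cm <- data.frame(i = len + 1L - cm$j, j = len + 1L - cm$i)
    a <- topology_census(cm); b <- topology_census(rev_cm)
    expect_equal(c(a$n_S, a$n_P, a$n_X), c(b$n_S, b$n_P, b$n_X))
  }
  # directed parallel flips with argument order under reversal
  expect_equal(classify_relation(c(111, 120), c(114, 118)), "P")
  expect_equal(classify_relation(c(1, 10), c(3, 7)), "P")
})

test_that("inverse-parallel profile counts enclosing contacts per residue", {
  # single frame, contacts (5,30) and (10,20): (10,20) is nested once
  sc <- make_contact_scaffold(35, data.frame(i = c(5, 10), j = c(30, 20)),
                              seed = 2)
  ens <- make_fluctuation_ensemble(sc, 0, 1, seed = 1)
  prof <- local_inverse_parallel_profile(ens)
  expect_equal(prof$mean[10], 1)
  expect_equal(prof$mean[20], 1)
  expect_equal(prof$mean[5], 0)
  expect_equal(prof$mean[30], 0)
  expect_equal(prof$mean[15], 0)  # not an endpoint of any contact
  # rigid ensemble: SEM identically zero
  rigid <- make_fluctuation_ensemble(sc, 0, 4, seed = 3)
  prof4 <- local_inverse_parallel_profile(rigid)
  expect_true(all(prof4$sem == 0))
})

test_that("profile means are duplication-invariant and SEM scales by 1/sqrt(2)", {
  base <- make_contact_scaffold(
    40, data.frame(i = c(4, 8), j = c(36, 30)), seed = 5)
  ens <- make_fluctuation_ensemble(base, 0.6, 6, seed = 7)
  p1 <- local_inverse_parallel_profile(ens)
  dup <- ensemble(ens$atoms, rbind(ens$xyz, ens$xyz))
  p2 <- local_inverse_parallel_profile(dup, sample_interval_ns = 1)
  expect_equal(p2$mean, p1$mean)
  expect_equal(p2$sem, p1$sem / sqrt(2))
})

test_that("topology density is a normalized histogram over censuses", {
  sc1 <- make_contact_scaffold(
    30, data.frame(i = c(2, 3, 10), j = c(28, 27, 20)), seed = 3)
  sc2 <- make_contact_scaffold(
    30, data.frame(i = c(2, 12), j = c(8, 20)), seed = 4)
  e1 <- make_fluctuation_ensemble(sc1, 0, 3, seed = 1)
  e2 <- make_fluctuation_ensemble(sc2, 0, 3, seed = 1)
  td <- topology_density(list(e1, e2))
  expect_equal(sum(td$density), 1)
  # two rigid ensembles in equal frame numbers: two bins with mass 0.5
  expect_equal(sort(td$density[td$density > 0]), c(0.5, 0.5))
  expect_equal(nrow(td$points), 6L)
  # identical frames: all mass in one bin
  td1 <- topology_density(e1)
  expect_equal(max(td1$density), 1)
})
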