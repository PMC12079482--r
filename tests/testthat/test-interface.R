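test_that("designed interfaces yield exactly the planted residue sets", {
  pose <- make_dimer_pose(
    20, 18, contacts = data.frame(res_a = c(3, 4, 5, 6, 7, 8),
                                  res_b = c(5, 6, 7, 8, 9, 10)))
  ir <- interface_residues(pose)
  expect_equal(ir$A, 3:8)
  expect_equal(ir$B, 5:10)
  # separated chains: empty interface
  apart <- make_dimer_pose(10, 10)
  ir0 <- interface_residues(apart)
  expect_length(ir0$A, 0L)
  expect_length(ir0$B, 0L)
  # swapping chain roles swaps the orientation of the pair table but the
  # per-chain sets are unchanged
  swapped <- interface_residues(pose, chains = c("B", "A"))
  expect_equal(names(swapped)[1:2], c("B", "A"))
  expect_equal(swapped$A, ir$A)
  expect_equal(swapped$B, ir$B)
  expect_setequal(paste(swapped$pairs$res_b, swapped$pairs$res_a),
                  paste(ir$pairs$res_a, ir$pairs$res_b))
  expect_error(interface_residues(make_ideal_helix(6)), "2 chains")
})

test_that("interaction typing finds the designed exemplars and only them", {
  pose <- make_dimer_pose(
    30, 30,
    interactions = list(
      list(type = "salt_bridge", res_a = 5, res_b = 5),
      list(type = "hydrogen_bond", res_a = 11, res_b = 11),
      list(type = "pi_stacking", res_a = 17, res_b = 17),
      list(type = "pi_cation", res_a = 23, res_b = 23)))
  ti <- type_interactions(pose)
  expect_setequal(ti$type, c("salt_bridge", "hydrogen_bond",
                             "pi_stacking", "pi_cation"))
  expect_equal(nrow(ti), 4L)
  expect_equal(ti$res_a[ti$type == "salt_bridge"], 5)
  # all measurements inside their windows
  p <- interaction_params()
  expect_lte(ti$distance[ti$type == "hydrogen_bond"], p$hbond_dist)
  expect_lte(ti$distance[ti$type == "salt_bridge"], p$salt_dist)
  expect_lte(ti$distance[ti$type == "pi_stacking"], p$pistack_dist)
  expect_lte(ti$angle[ti$type == "pi_cation"], p$pication_angle)
  # typing is invariant under a global rigid motion of the whole pose
  rot <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- ensemble(pose$atoms,
                    as.vector(t(frame_coords(pose) %*% t(rot) + 13)))
  ti2 <- type_interactions(moved)
  expect_equal(ti2$type, ti$type)
  expect_equal(ti2$distance, ti$distance, tolerance = 1e-9)
})

test_that("distant ring pairs produce no interaction records", {
  # two Phe rings 9 A apart across chains: outside every window
  ring <- function(chain, y) {
    ang <- (0:5) * pi / 3
    co <- cbind(1.39 * cos(ang), y, 1.39 * sin(ang))
    atoms <- data.frame(chain = chain, resno = 1L, resname = "PHE",
                        elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                        element = "C")
    list(atoms = atoms, co = co)
  }
  a <- ring("A", 0); b <- ring("B", 9)
  pose <- ensemble(rbind(a$atoms, b$atoms),
                   as.vector(t(rbind(a$co, b$co))))
  expect_equal(nrow(type_interactions(pose)), 0L)
})

test_that("region binding fractions follow the dominance rule", {
  map <- region_map(data.frame(name = c("NR", "CR"),
                               start = c(1, 11), end = c(10, 20),
                               frame = "chain-local"),
                    chain_length = 20, frame = "chain-local")
  mk <- function(res_a, res_b) {
    make_dimer_pose(20, 15, contacts = data.frame(res_a = res_a,
                                                  res_b = res_b))
  }
  poses <- c(
    lapply(1:3, function(k) mk(c(2, 3, 4), c(4, 5, 6))),          # NR only
    lapply(1:2, function(k) mk(c(14, 15, 16), c(4, 5, 6))),       # CR only
    lapply(1:5, function(k) mk(c(8, 9, 12, 13), c(3, 4, 5, 6))))  # 50/50
  out <- region_binding_fractions(poses, map, dominance = 0.8)
  expect_equal(unname(out$fractions), c(0.3, 0.5, 0.2))
  expect_equal(sum(out$fractions), 1)
  # dominance 1.0 turns every mixed interface into dual
  strict <- region_binding_fractions(poses, map, dominance = 1.0)
  expect_equal(unname(strict$fractions["dual"]), 0.5)
})

test_that("motif blockade statuses follow the interface-overlap rule", {
  # motif 8-12 fully designed into the interface in 4 of 8 poses
  blocked <- lapply(1:4, function(k) {
    make_dimer_pose(20, 15,
                    contacts = data.frame(res_a = 8:12, res_b = 5:9))
  })
  exposed <- lapply(1:4, function(k) {
    make_dimer_pose(20, 15,
                    contacts = data.frame(res_a = 2:3, res_b = 5:6))
  })
  ms <- motif_status(c(blocked, exposed), motif = c(8, 12))
  expect_equal(ms$blockade_fraction, 0.5)
  expect_equal(ms$per_pose$status[1:4], rep("blocked", 4))
  expect_equal(ms$per_pose$status[5:8], rep("exposed", 4))
  # a single touching residue is partial involvement
  partial <- make_dimer_pose(20, 15,
                             contacts = data.frame(res_a = 12, res_b = 7))
  ms2 <- motif_status(list(partial), motif = c(8, 12))
  expect_equal(ms2$per_pose$status, "partially_involved")
  # the blockade fraction is monotone non-increasing in blocked_fraction
  ms_loose <- motif_status(c(blocked, exposed), motif = c(8, 12),
                           blocked_fraction = 0.2)
  expect_gte(ms_loose$blockade_fraction, ms$blockade_fraction)
  expect_error(motif_status(list(partial), motif = c(18, 25)), "outside")
})

test_that("complexation never increases solvent accessibility", {
  pose <- make_dimer_pose(
    12, 12, contacts = data.frame(res_a = c(4, 8), res_b = c(4, 8)))
  sa_complex <- shrake_rupley_sasa(pose, fallback_radius = 1.7)
  for (ch in c("A", "B")) {
    sel <- pose$atoms$chain == ch
    iso <- ensemble(pose$atoms[sel, ],
                    as.vector(t(frame_coords(pose)[sel, ])))
    sa_iso <- shrake_rupley_sasa(iso, fallback_radius = 1.7)
    expect_true(all(sa_complex$sasa[sa_complex$chain == ch] <=
                      sa_iso$sasa + 1e-6))
  }
})

test_that("sphere-point SASA approaches the closed form and detects burial", {
  one <- ensemble(data.frame(chain = "A", resno = 1, resname = "GLY",
                             elety = "CA", element = "C"),
                  c(0, 0, 0))
  s <- shrake_rupley_sasa(one, n_points = 4000)
  expect_equal(s$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)
  # an atom at the core of a dense cluster is almost fully occluded
  shell <- golden_shell <- rbind(c(0, 0, 0), 3.0 * cirtop:::golden_spiral_points(40))
  atoms <- data.frame(chain = "A", resno = c(1, rep(5, 40)),
                      resname = "GLY",
                      elety = c("CA", paste0("D", 1:40)), element = "C")
  buried <- ensemble(atoms[order(atoms$resno), ],
                     as.vector(t(shell[order(atoms$resno), ])))
  sb <- shrake_rupley_sasa(buried)
  expect_lt(sb$sasa[1] / (4 * pi * 3.1^2), 0.05)
  expect_error(shrake_rupley_sasa(
    ensemble(data.frame(chain = "A", resno = 1, resname = "UNK",
                        elety = "XX", element = "ZZ"), c(0, 0, 0))),
    "radius")
})
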