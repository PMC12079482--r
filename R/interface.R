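#' Interface residues of a two-chain pose
#'
#' Cross-chain residue contacts under the same atom-pair criteria engine as
#' intra-chain contact analysis; the sequence-neighbour exclusion does not
#' apply across chains.
#'
#' @param pose a 1-frame two-chain [ensemble].
#' @param criteria a [contact_criteria].
#' @param chains optional length-2 character vector naming the two chains
#'   (default: the pose's chains in order of appearance).
#' @return list with per-chain integer vectors of interface residue indices
#'   (named by chain id) and `pairs`, a data.frame of contacting
#'   cross-chain residue pairs with atom-pair counts.
#' @export
interface_residues <- function(pose, criteria = contact_criteria(),
                               chains = NULL) {
  stopifnot(inherits(pose, "ensemble"))
  ch <- unique(pose$atoms$chain)
  if (length(ch) != 2L) stop("pose must have exactly 2 chains")
  if (!is.null(chains)) ch <- chains
  co <- frame_coords(pose, 1L)
  rt <- residue_table(pose)
  ra <- which(rt$chain == ch[1]); rb <- which(rt$chain == ch[2])
  blocks <- lapply(seq_len(nrow(rt)),
                   function(k) co[rt$first[k]:rt$last[k], , drop = FALSE])
  cent <- t(vapply(blocks, colMeans, numeric(3)))
  rad <- vapply(seq_len(nrow(rt)), function(k) {
    sqrt(max(rowSums((blocks[[k]] -
                        rep(cent[k, ], each = nrow(blocks[[k]])))^2)))
  }, numeric(1))
  pairs <- list()
  for (a in ra) {
    d2 <- rowSums(sweep(cent[rb, , drop = FALSE], 2, cent[a, ])^2)
    reach <- (rad[a] + rad[rb] + criteria$cutoff)^2
    for (b in rb[d2 <= reach]) {
      cnt <- count_close_pairs(blocks[[a]], blocks[[b]], criteria$cutoff)
      ok <- cnt[1] >= criteria$min_pairs
      if (ok && criteria$per_side) {
        ok <- cnt[2] >= criteria$min_pairs && cnt[3] >= criteria$min_pairs
      }
      if (ok) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(res_a = rt$resno[a], res_b = rt$resno[b],
                     n_atom_pairs = cnt[1])
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(res_a = integer(0), res_b = integer(0),
               n_atom_pairs = integer(0))
  }
  out <- list(sort(unique(pairs$res_a)), sort(unique(pairs$res_b)))
  names(out) <- ch
  out$pairs <- pairs
  out
}

# chemistry tables for interaction typing -----------------------------------

cationic_atoms <- function() {
  list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
}

anionic_atoms <- function() {
  list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
}

donor_atoms <- function() {
  list(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
       GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
       TRP = "NE1", HIS = c("ND1", "NE2"))
}

acceptor_atoms <- function() {
  list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
       GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
       HIS = c("ND1", "NE2"), MET = "SD")
}

ring_atoms <- function() {
  list(PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
       TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
       HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
       TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                  c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))
}

match_atoms <- function(atoms, table, backbone = NULL) {
  hit <- rep(FALSE, nrow(atoms))
  for (res in names(table)) {
    hit <- hit | (atoms$resname == res & atoms$elety %in% table[[res]])
  }
  if (!is.null(backbone)) hit <- hit | atoms$elety %in% backbone
  which(hit)
}

# centroid and unit normal of a ring's atoms
ring_geometry <- function(co) {
  centroid <- colMeans(co)
  s <- svd(sweep(co, 2, centroid))
  list(centroid = centroid, normal = s$v[, 3])
}

vec_angle <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Geometric windows for cross-chain interaction typing
#'
#' Defaults follow common interaction-fingerprinting practice: hydrogen
#' bond, donor-acceptor heavy-atom distance <= 3.5 A (plus D-H...A angle
#' >= 120 degrees when hydrogens are present); salt bridge, cationic N to
#' anionic O <= 4.0 A; pi-cation, ring centroid to cationic N <= 6.0 A with
#' the centroid-cation vector within 45 degrees of the ring normal;
#' pi-stacking, centroid-centroid <= 5.5 A with inter-plane angle <= 30
#' degrees (parallel) or >= 60 degrees (T-shaped).
#'
#' @param hbond_dist,salt_dist,pication_dist,pistack_dist distance windows (A).
#' @param hbond_angle minimum D-H...A angle (degrees).
#' @param pication_angle maximum normal-offset angle (degrees).
#' @param pistack_parallel,pistack_tshape plane-angle windows (degrees).
#' @return list of class `interaction_params`.
#' @export
interaction_params <- function(hbond_dist = 3.5, hbond_angle = 120,
                               salt_dist = 4.0,
                               pication_dist = 6.0, pication_angle = 45,
                               pistack_dist = 5.5, pistack_parallel = 30,
                               pistack_tshape = 60) {
  structure(as.list(environment()), class = "interaction_params")
}

#' Typed cross-chain interactions of a pose
#'
#' Detects hydrogen bonds, salt bridges, pi-cation and pi-stacking contacts
#' between the two chains of a pose, by named side-chain/backbone atom
#' chemistry and the geometric windows of [interaction_params()]. Each
#' qualifying pair yields one record per satisfied type (a close Lys-Glu
#' pair can be both a salt bridge and a hydrogen bond).
#'
#' @param pose a 1-frame two-chain [ensemble].
#' @param params an [interaction_params].
#' @return data.frame with columns `type`, `chain_a`, `res_a`, `chain_b`,
#'   `res_b`, `atom_a`, `atom_b`, `distance`, `angle` (NA where the type has
#'   no angle term).
#' @export
type_interactions <- function(pose, params = interaction_params()) {
  stopifnot(inherits(pose, "ensemble"))
  ch <- unique(pose$atoms$chain)
  if (length(ch) != 2L) stop("pose must have exactly 2 chains")
  co <- frame_coords(pose, 1L)
  a <- pose$atoms
  rec <- list()
  emit <- function(type, ia, ib, dist, ang = NA_real_,
                   atom_a = NULL, atom_b = NULL) {
    rec[[length(rec) + 1L]] <<- data.frame(
      type = type,
      chain_a = a$chain[ia], res_a = a$resno[ia],
      chain_b = a$chain[ib], res_b = a$resno[ib],
      atom_a = if (is.null(atom_a)) a$elety[ia] else atom_a,
      atom_b = if (is.null(atom_b)) a$elety[ib] else atom_b,
      distance = dist, angle = ang,
      stringsAsFactors = FALSE)
  }
  cross <- function(ia, ib) a$chain[ia] != a$chain[ib]
  pair_scan <- function(set1, set2, max_dist) {
    if (!length(set1) || !length(set2)) {
      return(matrix(integer(0), ncol = 2))
    }
    d2 <- outer(rowSums(co[set1, , drop = FALSE]^2),
                rowSums(co[set2, , drop = FALSE]^2), "+") -
      2 * tcrossprod(co[set1, , drop = FALSE], co[set2, , drop = FALSE])
    hit <- which(d2 <= max_dist^2, arr.ind = TRUE)
    cbind(set1[hit[, 1]], set2[hit[, 2]])
  }

  # hydrogen bonds: donors (side-chain table + backbone N) to acceptors
  # (side-chain table + backbone O/OXT)
  don <- match_atoms(a, donor_atoms(), backbone = "N")
  acc <- match_atoms(a, acceptor_atoms(), backbone = c("O", "OXT"))
  hyd <- which(a$element == "H")
  for (p in seq_len(nrow(hb <- pair_scan(don, acc, params$hbond_dist)))) {
    ia <- hb[p, 1]; ib <- hb[p, 2]
    if (!cross(ia, ib)) next
    dist <- sqrt(sum((co[ia, ] - co[ib, ])^2))
    ang <- NA_real_
    if (length(hyd)) {
      # hydrogens covalently bound to the donor (within 1.2 A, same residue)
      hh <- hyd[a$chain[hyd] == a$chain[ia] & a$resno[hyd] == a$resno[ia]]
      hh <- hh[sqrt(rowSums(sweep(co[hh, , drop = FALSE], 2, co[ia, ])^2)) < 1.25]
      if (length(hh)) {
        angs <- vapply(hh, function(ih) {
          u <- co[ia, ] - co[ih, ]; v <- co[ib, ] - co[ih, ]
          acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) *
            180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < params$hbond_angle) next
      }
    }
    emit("hydrogen_bond", ia, ib, dist, ang)
  }

  # salt bridges: cationic N to anionic O (including any chain-terminal OXT)
  cat_i <- match_atoms(a, cationic_atoms())
  ani_i <- match_atoms(a, anionic_atoms(), backbone = "OXT")
  for (p in seq_len(nrow(sb <- pair_scan(cat_i, ani_i, params$salt_dist)))) {
    ia <- sb[p, 1]; ib <- sb[p, 2]
    if (!cross(ia, ib)) next
    emit("salt_bridge", ia, ib, sqrt(sum((co[ia, ] - co[ib, ])^2)))
  }

  # aromatic rings per residue
  rings <- list()
  rt <- residue_table(pose)
  rtab <- ring_atoms()
  for (k in seq_len(nrow(rt))) {
    defs <- rtab[[rt$resname[k]]]
    if (is.null(defs)) next
    rows <- rt$first[k]:rt$last[k]
    for (def in defs) {
      hit <- rows[match(def, a$elety[rows])]
      if (anyNA(hit)) next
      g <- ring_geometry(co[hit, , drop = FALSE])
      rings[[length(rings) + 1L]] <- list(k = k, chain = rt$chain[k],
                                          resno = rt$resno[k],
                                          atom_row = hit[1], geom = g)
    }
  }

  # pi-cation
  for (r in rings) {
    for (ic in cat_i) {
      if (a$chain[ic] == r$chain) next
      v <- co[ic, ] - r$geom$centroid
      dist <- sqrt(sum(v^2))
      if (dist > params$pication_dist) next
      ang <- vec_angle(v, r$geom$normal)
      if (ang <= params$pication_angle) {
        emit("pi_cation", r$atom_row, ic, dist, ang, atom_a = "ring")
      }
    }
  }

  # pi-stacking
  if (length(rings) >= 2L) {
    for (p in seq_len(length(rings) - 1L)) {
      for (q in (p + 1L):length(rings)) {
        r1 <- rings[[p]]; r2 <- rings[[q]]
        if (r1$chain == r2$chain) next
        dist <- sqrt(sum((r1$geom$centroid - r2$geom$centroid)^2))
        if (dist > params$pistack_dist) next
        ang <- vec_angle(r1$geom$normal, r2$geom$normal)
        if (ang <= params$pistack_parallel || ang >= params$pistack_tshape) {
          emit("pi_stacking", r1$atom_row, r2$atom_row, dist, ang,
               atom_a = "ring", atom_b = "ring")
        }
      }
    }
  }

  if (!length(rec)) {
    return(data.frame(type = character(0), chain_a = character(0),
                      res_a = integer(0), chain_b = character(0),
                      res_b = integer(0), atom_a = character(0),
                      atom_b = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Region binding fractions of a pose set
#'
#' Classifies each pose by where its interface residues on the disordered
#' chain fall: `NR` if at least the dominance fraction lie in the NR
#' interval, `CR` likewise, else `dual`. Fractions are over poses with a
#' non-empty interface.
#'
#' @param pose_set a `pose_set` (see [read_pose_set()]) or list of poses.
#' @param map a [region_map] covering the disordered chain.
#' @param ntd_chain chain id of the disordered chain in each pose.
#' @param dominance dominance threshold in (0.5, 1].
#' @param criteria a [contact_criteria].
#' @return list of class `pose_region_summary`: `per_pose` (data.frame
#'   `pose`, `class`, `n_interface`, `n_nr`, `n_cr`), `fractions` (named
#'   NR/dual/CR, summing to 1 over classified poses), `n_classified`,
#'   `n_empty`.
#' @export
region_binding_fractions <- function(pose_set, map, ntd_chain = "A",
                                     dominance = 0.8,
                                     criteria = contact_criteria()) {
  poses <- if (inherits(pose_set, "pose_set")) pose_set$poses else pose_set
  if (!length(poses)) stop("empty pose set")
  nr <- map$regions[map$regions$name == "NR" &
                      map$regions$frame == map$frame, ]
  cr <- map$regions[map$regions$name == "CR" &
                      map$regions$frame == map$frame, ]
  stopifnot(nrow(nr) == 1L, nrow(cr) == 1L)
  rows <- lapply(seq_along(poses), function(pidx) {
    ir <- interface_residues(poses[[pidx]], criteria)
    res <- ir[[ntd_chain]]
    n_nr <- sum(res >= nr$start & res <= nr$end)
    n_cr <- sum(res >= cr$start & res <= cr$end)
    n <- length(res)
    cls <- if (n == 0L) NA_character_
    else if (n_nr / n >= dominance) "NR"
    else if (n_cr / n >= dominance) "CR"
    else "dual"
    data.frame(pose = pidx, class = cls, n_interface = n,
               n_nr = n_nr, n_cr = n_cr, stringsAsFactors = FALSE)
  })
  per_pose <- do.call(rbind, rows)
  classified <- per_pose$class[!is.na(per_pose$class)]
  fr <- c(NR = mean(classified == "NR"),
          dual = mean(classified == "dual"),
          CR = mean(classified == "CR"))
  structure(list(per_pose = per_pose, fractions = fr,
                 n_classified = length(classified),
                 n_empty = sum(is.na(per_pose$class)),
                 dominance = dominance),
            class = "pose_region_summary")
}

#' @export
print.pose_region_summary <- function(x, ...) {
  cat("pose_region_summary: ", x$n_classified, " classified pose(s) (",
      x$n_empty, " with empty interface); NR ",
      round(x$fractions["NR"], 3), ", dual ", round(x$fractions["dual"], 3),
      ", CR ", round(x$fractions["CR"], 3), " at dominance ",
      x$dominance, "\n", sep = "")
  invisible(x)
}

#' Motif blockade / exposure across a pose set
#'
#' Per pose, a motif is `blocked` when at least `blocked_fraction` of its
#' residues are interface residues; `partially_involved` when at least one
#' but fewer; `exposed` when none are and the motif's mean relative SASA in
#' the complex reaches the exposure threshold; the residual case (no
#' interface involvement but low accessibility) is reported as `buried`.
#' The blockade fraction is blocked poses over all poses.
#'
#' @param pose_set a `pose_set` or list of poses.
#' @param motif inclusive residue interval `c(start, end)` on `chain`.
#' @param chain chain carrying the motif.
#' @param blocked_fraction fraction of motif residues at the interface that
#'   counts as blockade (0.5 default; use `any_contact = TRUE` for the >= 1
#'   residue rule, appropriate for very short motifs).
#' @param any_contact if TRUE a single interface residue already counts as
#'   blocked.
#' @param exposure_threshold mean relative-SASA threshold for `exposed`.
#' @param criteria a [contact_criteria].
#' @param compute_sasa set FALSE to skip SASA (statuses `exposed`/`buried`
#'   then collapse to `exposed`).
#' @return list of class `motif_status`: `per_pose` (data.frame `pose`,
#'   `n_interface_motif`, `mean_rel_sasa`, `status`), `blockade_fraction`,
#'   `motif`, `chain`.
#' @export
motif_status <- function(pose_set, motif, chain = "A",
                         blocked_fraction = 0.5, any_contact = FALSE,
                         exposure_threshold = 0.25,
                         criteria = contact_criteria(),
                         compute_sasa = TRUE) {
  poses <- if (inherits(pose_set, "pose_set")) pose_set$poses else pose_set
  if (!length(poses)) stop("empty pose set")
  motif <- as.integer(motif)
  stopifnot(length(motif) == 2L, motif[1] <= motif[2])
  motif_res <- motif[1]:motif[2]
  rows <- lapply(seq_along(poses), function(pidx) {
    pose <- poses[[pidx]]
    chain_res <- unique(pose$atoms$resno[pose$atoms$chain == chain])
    if (!all(motif_res %in% chain_res)) {
      stop("motif [", motif[1], ", ", motif[2], "] outside chain ", chain)
    }
    ir <- interface_residues(pose, criteria)
    n_in <- sum(motif_res %in% ir[[chain]])
    need <- if (any_contact) 1L else ceiling(blocked_fraction * length(motif_res))
    msasa <- NA_real_
    status <- if (n_in >= need) "blocked"
    else if (n_in >= 1L) "partially_involved"
    else {
      if (compute_sasa) {
        sa <- shrake_rupley_sasa(pose, fallback_radius = 1.7)
        sel <- sa$chain == chain & sa$resno %in% motif_res
        msasa <- mean(sa$rel_sasa[sel], na.rm = TRUE)
        if (is.nan(msasa) || msasa >= exposure_threshold) "exposed" else "buried"
      } else "exposed"
    }
    data.frame(pose = pidx, n_interface_motif = n_in,
               mean_rel_sasa = msasa, status = status,
               stringsAsFactors = FALSE)
  })
  per_pose <- do.call(rbind, rows)
  structure(list(per_pose = per_pose,
                 blockade_fraction = mean(per_pose$status == "blocked"),
                 motif = motif, chain = chain),
            class = "motif_status")
}

#' @export
print.motif_status <- function(x, ...) {
  cat("motif_status [", x$motif[1], "-", x$motif[2], " chain ", x$chain,
      "]: blockade fraction ", round(x$blockade_fraction, 3), " over ",
      nrow(x$per_pose), " pose(s)\n", sep = "")
  invisible(x)
}
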