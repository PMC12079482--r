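#' Synthetic conformer generators with planted ground truth
#'
#' Every generator is seeded and self-verifying: before returning, it
#' re-checks the planted property with the very analysis functions that the
#' fixtures will be used to test (and regenerates with a perturbed seed,
#' boundedly, if a random embedding fails). Fixtures are geometric, not
#' thermodynamic: they emulate the *measurable structure* of trajectory data
#' (contacts of known topology, prescribed fluctuation amplitudes and
#' contact schedules, ideal helical segments, designed interfaces), not its
#' physics.
#'
#' @name synthetic_data
NULL

# internal: run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# NeRF atom placement: position D given A-B-C, bond |CD|, angle B-C-D (deg),
# torsion A-B-C-D (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign matches the measured IUPAC dihedral
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, pracma_cross(n, bc), n)
  as.vector(m %*% d2) + c
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# build an N-CA-C(-O) backbone from per-residue (phi, psi) vectors
build_backbone <- function(phi, psi, resnames = NULL, chain = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  # ideal geometry: bonds N-CA 1.458, CA-C 1.525, C-N 1.329; angles
  # N-CA-C 111.0, CA-C-N 117.2, C-N-CA 121.7; omega fixed at 180
  co <- matrix(NA_real_, 4L * n, 3L)
  nm <- character(4L * n)
  resno <- rep(seq_len(n), each = 4L)
  row <- function(r, what) (r - 1L) * 4L + match(what, c("N", "CA", "C", "O"))
  co[row(1, "N"), ] <- c(0, 0, 0)
  co[row(1, "CA"), ] <- c(1.458, 0, 0)
  co[row(1, "C"), ] <- place_atom(c(0, 1, 0), co[row(1, "N"), ],
                                  co[row(1, "CA"), ], 1.525, 111.0,
                                  phi[1])
  nm[] <- rep(c("N", "CA", "C", "O"), n)
  for (r in 2:n) {
    co[row(r, "N"), ] <- place_atom(co[row(r - 1, "N"), ],
                                    co[row(r - 1, "CA"), ],
                                    co[row(r - 1, "C"), ],
                                    1.329, 117.2, psi[r - 1])
    co[row(r, "CA"), ] <- place_atom(co[row(r - 1, "CA"), ],
                                     co[row(r - 1, "C"), ],
                                     co[row(r, "N"), ],
                                     1.458, 121.7, 180)
    co[row(r, "C"), ] <- place_atom(co[row(r - 1, "C"), ],
                                    co[row(r, "N"), ],
                                    co[row(r, "CA"), ],
                                    1.525, 111.0, phi[r])
  }
  # carbonyl O in the peptide plane, opposite the next N
  for (r in seq_len(n)) {
    ref_tor <- if (r < n) psi[r] + 180 else psi[r] + 180
    co[row(r, "O"), ] <- place_atom(co[row(r, "N"), ], co[row(r, "CA"), ],
                                    co[row(r, "C"), ], 1.231, 120.5,
                                    ref_tor)
  }
  atoms <- data.frame(chain = chain, resno = resno,
                      resname = rep(resnames, each = 4L),
                      elety = nm, element = substr(nm, 1, 1),
                      stringsAsFactors = FALSE)
  ensemble(atoms, as.vector(t(co)))
}

#' Ideal alpha-helix conformer
#'
#' Backbone (N, CA, C, O) built at canonical helical geometry
#' (phi = -57, psi = -47 degrees), giving a rise of ~1.5 A per residue and
#' consecutive CA-CA distances of ~3.8 A.
#'
#' @param n_residues chain length (>= 4).
#' @param phi,psi backbone dihedrals in degrees.
#' @return A 1-frame [ensemble].
#' @export
make_ideal_helix <- function(n_residues, phi = -57, psi = -47) {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 4L) {
    stop("an ideal helix needs at least 4 residues")
  }
  build_backbone(rep(phi, n_residues), rep(psi, n_residues))
}

#' Extended (strand-like) conformer
#' @param n_residues chain length.
#' @return A 1-frame [ensemble] at phi = -120, psi = +120 degrees.
#' @export
make_extended_chain <- function(n_residues) {
  build_backbone(rep(-120, n_residues), rep(120, n_residues))
}

#' Helix-coil-helix chain with known helical segments
#'
#' @param segments logical vector, one element per residue (TRUE = helical
#'   dihedrals, FALSE = extended dihedrals).
#' @return A 1-frame [ensemble]; the planted labels are attached as
#'   attribute `helix`.
#' @export
make_segmented_chain <- function(segments) {
  phi <- ifelse(segments, -57, -120)
  psi <- ifelse(segments, -47, 120)
  ens <- build_backbone(phi, psi)
  attr(ens, "helix") <- segments
  ens
}

# decorate a bead chain with `n_dummy` pseudo-atoms on a fixed local sphere
# so that atom-pair contact criteria behave realistically
decorate_beads <- function(centers, resnames = NULL, chain = "A",
                           n_dummy = 5L, radius = 1.2) {
  n <- nrow(centers)
  if (is.null(resnames)) resnames <- rep("GLY", n)
  dirs <- golden_spiral_points(n_dummy)
  per_res <- n_dummy + 1L
  co <- matrix(NA_real_, n * per_res, 3L)
  nm <- character(n * per_res)
  for (r in seq_len(n)) {
    base <- (r - 1L) * per_res
    co[base + 1L, ] <- centers[r, ]
    nm[base + 1L] <- "CA"
    for (d in seq_len(n_dummy)) {
      co[base + 1L + d, ] <- centers[r, ] + radius * dirs[d, ]
      nm[base + 1L + d] <- paste0("D", d)
    }
  }
  atoms <- data.frame(chain = chain,
                      resno = rep(seq_len(n), each = per_res),
                      resname = rep(resnames, each = per_res),
                      elety = nm, element = "C",
                      stringsAsFactors = FALSE)
  ensemble(atoms, as.vector(t(co)))
}

# spring relaxation of bead centers: bonds at 3.8 A, planted pairs pulled to
# `contact_dist`, all other |i-j| > exclude pairs pushed beyond `repel_dist`
relax_chain <- function(centers, contacts, max_steps = 6000L,
                        contact_dist = 4.0, repel_dist = 7.4,
                        bond_dist = 3.8, exclude = 3L) {
  cpp_relax_chain(centers, as.integer(contacts$i), as.integer(contacts$j),
                  as.integer(max_steps), contact_dist, repel_dist,
                  bond_dist, as.integer(exclude), 0.25, 1.0)
}

#' Bead-per-residue chain with exactly the planted residue contacts
#'
#' Lays out a random open chain, relaxes it with springs so that precisely
#' the planted pairs meet the atom-pair contact criteria (centers ~4 A
#' apart, everything else pushed outside geometric reach), decorates each
#' bead with 5 pseudo-atoms so the >= 5 atom-pair rule is genuinely
#' exercised, and verifies the planted set with [residue_contacts()] before
#' returning. Infeasible embeddings are retried with perturbed seeds.
#'
#' @param n_residues chain length.
#' @param contacts data.frame with integer columns `i`, `j` (`|i-j| > 3`),
#'   or NULL for a contact-free chain.
#' @param seed RNG seed (fully determines the output).
#' @param criteria the [contact_criteria] the scaffold must reproduce.
#' @param max_retries bounded regeneration attempts.
#' @return A 1-frame [ensemble] with the planted `contacts` attached as an
#'   attribute.
#' @export
make_contact_scaffold <- function(n_residues, contacts = NULL, seed = 1L,
                                  criteria = contact_criteria(),
                                  max_retries = 20L) {
  n <- as.integer(n_residues)
  if (is.null(contacts) || !nrow(contacts)) {
    contacts <- data.frame(i = integer(0), j = integer(0))
  }
  contacts <- data.frame(i = pmin(contacts$i, contacts$j),
                         j = pmax(contacts$i, contacts$j))
  contacts <- unique(contacts[order(contacts$i, contacts$j), , drop = FALSE])
  if (nrow(contacts) &&
      any(contacts$j - contacts$i <= criteria$exclude)) {
    stop("planted contacts must respect the neighbour exclusion")
  }
  if (nrow(contacts) && (min(contacts$i) < 1L || max(contacts$j) > n)) {
    stop("planted contacts outside the chain")
  }
  for (try in 0:max_retries) {
    ens <- with_seed(seed + 1000L * try, {
      # self-avoiding-ish random walk start, then spring relaxation
      steps <- matrix(stats::rnorm(3L * (n - 1L)), ncol = 3L)
      steps <- steps / sqrt(rowSums(steps^2)) * 3.8
      # bias along a drifting direction so the start is mostly open
      drift <- matrix(stats::rnorm(3L), ncol = 3L)
      drift <- drift / sqrt(sum(drift^2))
      steps <- steps * 0.35 + matrix(rep(drift * 3.5, n - 1L),
                                     ncol = 3L, byrow = TRUE)
      centers <- apply(rbind(c(0, 0, 0), steps), 2, cumsum)
      centers <- relax_chain(centers, contacts,
                             exclude = criteria$exclude)
      decorate_beads(centers)
    })
    got <- residue_contacts(ens, 1L, criteria)
    if (nrow(got) == nrow(contacts) &&
        all(got$i == contacts$i) && all(got$j == contacts$j)) {
      attr(ens, "contacts") <- contacts
      return(ens)
    }
  }
  stop("could not realise the planted contact set after ",
       max_retries + 1L, " attempts")
}

#' Gaussian-fluctuation ensemble with optional contact schedules
#'
#' Frames are the base conformer plus independent isotropic Gaussian
#' displacements of per-residue scale `sigma` (each residue moves rigidly,
#' so its atom-pair geometry is preserved). With per-axis SD sigma the
#' expected CA fluctuation is `sigma * sqrt(3)`. A contact schedule lists
#' residue pairs and the frames in which each pair must be in contact: in
#' "on" frames the second residue is translated next to the first (center
#' distance 4 A), in "off" frames it stays at its (distant) base position.
#'
#' @param base a 1-frame [ensemble] (e.g. from [make_contact_scaffold()]).
#' @param sigma per-residue displacement SD (A); scalar or per-residue
#'   vector.
#' @param n_frames number of frames.
#' @param schedule NULL, or a list of `list(i =, j =, on = <frame idx>)`
#'   entries.
#' @param seed RNG seed.
#' @param dt_ns frame spacing used for the time stamps (ns).
#' @param replicate replicate id.
#' @return An [ensemble] of `n_frames` frames with time stamps
#'   `0, dt_ns, ...`.
#' @export
make_fluctuation_ensemble <- function(base, sigma, n_frames,
                                      schedule = NULL, seed = 1L,
                                      dt_ns = 25, replicate = NA) {
  stopifnot(inherits(base, "ensemble"), n_frames(base) == 1L)
  rt <- residue_table(base)
  nres <- nrow(rt)
  if (length(sigma) == 1L) sigma <- rep(sigma, nres)
  stopifnot(length(sigma) == nres, all(sigma >= 0))
  base_co <- frame_coords(base, 1L)
  xyz <- with_seed(seed, {
    out <- matrix(NA_real_, n_frames, 3L * nrow(base_co))
    for (f in seq_len(n_frames)) {
      disp <- matrix(stats::rnorm(3L * nres), ncol = 3L) * sigma
      co <- base_co
      for (r in seq_len(nres)) {
        rows <- rt$first[r]:rt$last[r]
        co[rows, ] <- co[rows, ] + rep(disp[r, ], each = length(rows))
      }
      if (!is.null(schedule)) {
        for (sc in schedule) {
          if (f %in% sc$on) {
            ri <- rt$first[sc$i]:rt$last[sc$i]
            rj <- rt$first[sc$j]:rt$last[sc$j]
            ci <- colMeans(co[ri, , drop = FALSE])
            cj <- colMeans(co[rj, , drop = FALSE])
            u <- cj - ci
            u <- if (sum(u^2) < 1e-9) c(1, 0, 0) else u / sqrt(sum(u^2))
            shift <- (ci + 4.0 * u) - cj
            co[rj, ] <- co[rj, ] + rep(shift, each = length(rj))
          }
        }
      }
      out[f, ] <- as.vector(t(co))
    }
    out
  })
  ensemble(base$atoms, xyz,
           time_ns = seq(0, by = dt_ns, length.out = n_frames),
           replicate = replicate)
}

#' Two-basin ensemble with planted cluster memberships
#'
#' Alternates frames drawn from two rigid conformers (an ideal helix and an
#' extended chain of the same length, whose mutual RMSD is far above the
#' clustering cutoff) with small Gaussian jitter, giving a trajectory whose
#' correct clustering is known by construction.
#'
#' @param n_residues chain length.
#' @param frames_per_basin frames in each basin.
#' @param jitter per-atom Gaussian SD (A), small against the cutoff.
#' @param seed RNG seed.
#' @return An [ensemble]; planted basin labels in attribute `basin`.
#' @export
make_two_basin_ensemble <- function(n_residues = 40L, frames_per_basin = 15L,
                                    jitter = 0.3, seed = 1L) {
  basins <- list(frame_coords(make_ideal_helix(n_residues), 1L),
                 frame_coords(make_extended_chain(n_residues), 1L))
  atoms <- make_ideal_helix(n_residues)$atoms
  labels <- rep(c(1L, 2L), frames_per_basin)
  xyz <- with_seed(seed, {
    t(vapply(labels, function(b) {
      co <- basins[[b]] + matrix(stats::rnorm(length(basins[[b]]), sd = jitter),
                                 ncol = 3L)
      as.vector(t(co))
    }, numeric(3L * nrow(atoms))))
  })
  ens <- ensemble(atoms, xyz)
  attr(ens, "basin") <- labels
  ens
}

# ---- dimer poses -----------------------------------------------------------

# side-chain exemplar atoms for designed interactions; y0 is the residue
# blob center height, ynz the typed-atom height toward the partner
exemplar_atoms <- function(type, side) {
  # returns resname plus typed atom name(s) with local offsets (A) from the
  # blob center toward the partner chain (+y for receptor, -y for ligand)
  flip <- if (side == "a") 1 else -1
  switch(type,
    salt_bridge = if (side == "a") {
      list(resname = "LYS", atoms = list(NZ = c(0, 1.4 * flip, 0)))
    } else {
      list(resname = "GLU", atoms = list(OE1 = c(0, 1.4 * flip, 0)))
    },
    hydrogen_bond = if (side == "a") {
      list(resname = "ASN", atoms = list(ND2 = c(0, 1.4 * flip, 0)))
    } else {
      list(resname = "GLN", atoms = list(OE1 = c(0, 1.4 * flip, 0)))
    },
    pi_cation = if (side == "a") {
      list(resname = "PHE", atoms = "ring")
    } else {
      list(resname = "LYS", atoms = list(NZ = c(0, 1.4 * flip, 0)))
    },
    pi_stacking = list(resname = "PHE", atoms = "ring"),
    contact = list(resname = "GLY", atoms = list())
  )
}

# hexagonal ring atom offsets in the xz-plane (normal along y)
ring_offsets <- function(radius = 1.39) {
  ang <- (0:5) * pi / 3
  off <- cbind(radius * cos(ang), 0, radius * sin(ang))
  rownames(off) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  off
}

#' Two-chain pose with a designed interface
#'
#' Builds a receptor chain (A) and ligand chain (B) as decorated bead
#' chains on parallel lines 20 A apart, then realises a designed interface:
#' contact pairs protrude toward the mid-plane so that exactly they meet
#' the atom-pair contact criteria, and interaction exemplars additionally
#' place real side-chain atom names at geometries inside the typing windows
#' (Lys NZ - Glu OE1 salt bridge at 3.8 A; Asn ND2 - Gln OE1 hydrogen bond
#' at 3.0 A; parallel Phe rings at 4.0 A for stacking; Phe ring - Lys NZ at
#' 4.5 A on the ring normal for pi-cation). All non-designed inter-chain
#' atom distances stay above 8 A. The construction is verified with
#' [interface_residues()] and [type_interactions()] before returning.
#'
#' @param n_receptor,n_ligand chain lengths.
#' @param contacts data.frame `res_a`, `res_b`: plain interface contact
#'   pairs (no typed interaction). Designed pairs must be >= 4 residues
#'   apart along each chain so their protrusions stay separated.
#' @param interactions list of `list(type =, res_a =, res_b =)` with type in
#'   hydrogen_bond / salt_bridge / pi_cation / pi_stacking; typed pairs are
#'   also interface contacts.
#' @param seed RNG seed (poses are deterministic; the seed only perturbs
#'   nothing here but is kept for interface uniformity).
#' @param criteria the [contact_criteria] the interface must reproduce.
#' @param verify re-check planted properties before returning.
#' @return A 1-frame two-chain [ensemble]; planted design attached as
#'   attribute `design`.
#' @export
make_dimer_pose <- function(n_receptor = 30L, n_ligand = 30L,
                            contacts = NULL, interactions = list(),
                            seed = 1L, criteria = contact_criteria(),
                            verify = TRUE) {
  contacts <- if (is.null(contacts)) {
    data.frame(res_a = integer(0), res_b = integer(0))
  } else as.data.frame(contacts)
  design <- contacts
  design$type <- rep("contact", nrow(design))
  for (it in interactions) {
    design <- rbind(design, data.frame(res_a = it$res_a, res_b = it$res_b,
                                       type = it$type))
  }
  if (anyDuplicated(design$res_a) || anyDuplicated(design$res_b)) {
    stop("each designed residue may appear in only one pair")
  }
  design$res_a <- as.integer(design$res_a)
  design$res_b <- as.integer(design$res_b)
  if (nrow(design)) {
    if (max(design$res_a) > n_receptor || max(design$res_b) > n_ligand ||
        min(design$res_a) < 1L || min(design$res_b) < 1L) {
      stop("designed residues outside the chains")
    }
    # typed exemplars need clean geometry: keep them >= 4 residues from any
    # other designed residue on both chains (plain contacts may be
    # contiguous, e.g. to bury a whole motif)
    typed <- design$type != "contact"
    for (k in which(typed)) {
      if (any(abs(design$res_a[-k] - design$res_a[k]) < 4L) ||
          any(abs(design$res_b[-k] - design$res_b[k]) < 4L)) {
        stop("typed interaction pairs must be >= 4 residues from other ",
             "designed pairs along each chain")
      }
    }
  }
  spacing <- 3.8
  centers_a <- cbind(spacing * seq_len(n_receptor), 0, 0)
  centers_b <- cbind(spacing * seq_len(n_ligand), 20, 0)
  resnames_a <- rep("GLY", n_receptor)
  resnames_b <- rep("GLY", n_ligand)
  extra <- list()  # typed atoms appended after decoration
  for (k in seq_len(nrow(design))) {
    ra <- design$res_a[k]; rb <- design$res_b[k]
    # protrude both residues toward the mid-plane; pair them in x
    x <- spacing * ra
    centers_a[ra, ] <- c(x, 8, 0)
    centers_b[rb, ] <- c(x, 12, 0)
    ty <- design$type[k]
    if (ty == "contact") next
    ea <- exemplar_atoms(ty, "a"); eb <- exemplar_atoms(ty, "b")
    resnames_a[ra] <- ea$resname
    resnames_b[rb] <- eb$resname
    place <- function(side, res, spec, center) {
      if (identical(spec$atoms, "ring")) {
        off <- ring_offsets()
        for (nm in rownames(off)) {
          extra[[length(extra) + 1L]] <<- list(
            chain = if (side == "a") "A" else "B", resno = res,
            resname = spec$resname, elety = nm, element = "C",
            xyz = center + off[nm, ])
        }
      } else {
        for (nm in names(spec$atoms)) {
          extra[[length(extra) + 1L]] <<- list(
            chain = if (side == "a") "A" else "B", resno = res,
            resname = spec$resname, elety = nm,
            element = substr(nm, 1, 1),
            xyz = center + spec$atoms[[nm]])
        }
      }
    }
    # typed-atom geometry per interaction type (gap between typed atoms)
    gap <- switch(ty, salt_bridge = 3.8, hydrogen_bond = 3.0,
                  pi_cation = 4.5, pi_stacking = 4.0)
    # centers sit at y = 8 and 12; typed atoms meet around y = 10
    ya <- 10 - gap / 2; yb <- 10 + gap / 2
    if (ty == "pi_stacking") {
      # rings parallel (normals along y), centroids gap apart
      place("a", ra, ea, c(x, ya, 0))
      place("b", rb, eb, c(x, yb, 0))
    } else if (ty == "pi_cation") {
      # ring centroid at ya with normal along y; cation on the normal
      place("a", ra, list(resname = ea$resname, atoms = "ring"), c(x, ya, 0))
      extra[[length(extra) + 1L]] <- list(chain = "B", resno = rb,
                                          resname = eb$resname,
                                          elety = "NZ", element = "N",
                                          xyz = c(x, ya + gap, 0))
    } else {
      # distance-only pairs: put the typed atoms on the inter-center axis
      ata <- names(ea$atoms)[1]; atb <- names(eb$atoms)[1]
      extra[[length(extra) + 1L]] <- list(chain = "A", resno = ra,
                                          resname = ea$resname, elety = ata,
                                          element = substr(ata, 1, 1),
                                          xyz = c(x, ya, 0))
      extra[[length(extra) + 1L]] <- list(chain = "B", resno = rb,
                                          resname = eb$resname, elety = atb,
                                          element = substr(atb, 1, 1),
                                          xyz = c(x, yb, 0))
    }
  }
  ens_a <- decorate_beads(centers_a, resnames_a, chain = "A")
  ens_b <- decorate_beads(centers_b, resnames_b, chain = "B")
  atoms <- rbind(ens_a$atoms, ens_b$atoms)
  co <- rbind(frame_coords(ens_a, 1L), frame_coords(ens_b, 1L))
  if (length(extra)) {
    ex_atoms <- do.call(rbind, lapply(extra, function(e) {
      data.frame(chain = e$chain, resno = e$resno, resname = e$resname,
                 elety = e$elety, element = e$element,
                 stringsAsFactors = FALSE)
    }))
    ex_co <- do.call(rbind, lapply(extra, function(e) rbind(e$xyz)))
    atoms <- rbind(atoms, ex_atoms)
    co <- rbind(co, ex_co)
  }
  # restore (chain, resno) atom grouping
  ord <- order(atoms$chain, atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  co <- co[ord, , drop = FALSE]
  pose <- ensemble(atoms, as.vector(t(co)))
  if (verify) {
    ir <- interface_residues(pose, criteria)
    want_a <- sort(unique(design$res_a)); want_b <- sort(unique(design$res_b))
    if (!identical(ir$A, want_a) || !identical(ir$B, want_b)) {
      stop("designed interface failed verification: got A {",
           paste(ir$A, collapse = ","), "} B {",
           paste(ir$B, collapse = ","), "}")
    }
    if (length(interactions)) {
      ti <- type_interactions(pose)
      for (it in interactions) {
        hit <- ti$type == it$type &
          ((ti$res_a == it$res_a & ti$res_b == it$res_b) |
             (ti$res_a == it$res_b & ti$res_b == it$res_a))
        if (!any(hit)) {
          stop("designed ", it$type, " (", it$res_a, ", ", it$res_b,
               ") failed verification")
        }
      }
    }
  }
  attr(pose, "design") <- design
  pose
}

#' Write a directory of synthetic dimer poses
#'
#' @param designs list of argument lists for [make_dimer_pose()].
#' @param dir output directory (created).
#' @param seed base seed; pose k uses `seed + k`.
#' @return The directory path, invisibly.
#' @export
write_pose_directory <- function(designs, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(designs)) {
    args <- designs[[k]]
    args$seed <- seed + k
    pose <- do.call(make_dimer_pose, args)
    write_pdb(pose, file.path(dir, sprintf("pose_%03d.pdb", k)))
  }
  invisible(dir)
}
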