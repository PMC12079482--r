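#' Kabsch superposition of two coordinate sets
#'
#' Least-squares optimal rigid-body fit (proper rotations only, so chirality
#' is preserved) of `mobile` onto `reference`, computed via SVD of the
#' covariance matrix with the determinant sign correction.
#'
#' @param mobile,reference n x 3 coordinate matrices (same n >= 3).
#' @param apply_to optional m x 3 matrix to which the fitted transform is
#'   applied (defaults to `mobile` itself), e.g. all atoms when the fit used
#'   a CA selection.
#' @return list with `coords` (transformed `apply_to`), `rmsd` (Angstrom,
#'   over the fitted selection), `rotation`, `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, apply_to = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  s <- svd(crossprod(a, b))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2L) {
    stop("degenerate (collinear) selection: rotation under-determined")
  }
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  if (is.null(apply_to)) {
    coords <- sweep(fitted, 2, cr, "+")
  } else {
    coords <- sweep(sweep(as.matrix(apply_to), 2, cm) %*% t(rot), 2, cr, "+")
  }
  list(coords = coords, rmsd = rmsd, rotation = rot,
       translation = cr - as.vector(cm %*% t(rot)))
}

# row indices of the selected atoms (default CA; falls back to every atom
# for bead models where all atoms are CA anyway)
atom_selection <- function(ens, selection = "CA") {
  if (identical(selection, "all")) return(seq_len(nrow(ens$atoms)))
  idx <- which(ens$atoms$elety %in% selection)
  if (!length(idx)) stop("selection matched no atoms")
  idx
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto an iteratively refined mean structure
#' (standard RMSF practice), then
#' `RMSF_r = sqrt(mean_f |x_rf - xbar_r|^2)` over the selected atom of each
#' residue. For residues fluctuating isotropically with per-axis SD sigma,
#' the expected RMSF is `sigma * sqrt(3)`.
#'
#' @param ens an [ensemble] with >= 2 frames.
#' @param selection atom name(s) used, default `"CA"`.
#' @param superpose remove global rigid-body motion first (default TRUE).
#' @param units `"nm"` (default, the conventional reporting unit) or
#'   `"angstrom"`.
#' @param max_iter,tol mean-structure refinement controls.
#' @return data.frame with columns `residue`, `rmsf`.
#' @export
rmsf_profile <- function(ens, selection = "CA", superpose = TRUE,
                         units = c("nm", "angstrom"),
                         max_iter = 10L, tol = 1e-6) {
  units <- match.arg(units)
  if (n_frames(ens) < 2L) stop("RMSF needs at least 2 frames")
  idx <- atom_selection(ens, selection)
  frames <- lapply(seq_len(n_frames(ens)),
                   function(f) frame_coords(ens, f)[idx, , drop = FALSE])
  if (superpose) {
    ref <- frames[[1]]
    for (it in seq_len(max_iter)) {
      fitted <- lapply(frames, function(x) kabsch_superpose(x, ref)$coords)
      newmean <- Reduce(`+`, fitted) / length(fitted)
      shift <- sqrt(mean(rowSums((newmean - ref)^2)))
      ref <- newmean
      if (shift < tol) break
    }
    frames <- lapply(frames, function(x) kabsch_superpose(x, ref)$coords)
  }
  mean_xyz <- Reduce(`+`, frames) / length(frames)
  msd <- Reduce(`+`, lapply(frames, function(x) rowSums((x - mean_xyz)^2))) /
    length(frames)
  rmsf <- sqrt(msd)
  if (units == "nm") rmsf <- rmsf / 10
  data.frame(residue = ens$atoms$resno[idx], rmsf = rmsf)
}

# dihedral angle (degrees) of four points
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- n1 / sqrt(sum(n1^2))
  m2 <- n2 / sqrt(sum(n2^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * m2)
  y <- sum(c(m1[2] * b2u[3] - m1[3] * b2u[2],
             m1[3] * b2u[1] - m1[1] * b2u[3],
             m1[1] * b2u[2] - m1[2] * b2u[1]) * m2)
  atan2(y, x) * 180 / pi
}

# backbone phi/psi table for one frame (single chain); NA at chain termini
backbone_dihedrals <- function(ens, frame = 1L) {
  co <- frame_coords(ens, frame)
  a <- ens$atoms
  rt <- residue_table(ens)
  get_atom <- function(k, name) {
    rows <- rt$first[k]:rt$last[k]
    hit <- rows[a$elety[rows] == name]
    if (length(hit) != 1L) return(NULL)
    co[hit, ]
  }
  n <- nrow(rt)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  N <- lapply(seq_len(n), get_atom, name = "N")
  CA <- lapply(seq_len(n), get_atom, name = "CA")
  C <- lapply(seq_len(n), get_atom, name = "C")
  if (any(vapply(c(N, CA, C), is.null, logical(1)))) {
    stop("missing backbone atoms (N, CA, C)")
  }
  for (k in seq_len(n)) {
    if (k > 1L) phi[k] <- dihedral(C[[k - 1L]], N[[k]], CA[[k]], C[[k]])
    if (k < n) psi[k] <- dihedral(N[[k]], CA[[k]], C[[k]], N[[k + 1L]])
  }
  data.frame(residue = rt$resno, phi = phi, psi = psi)
}

#' Per-residue alpha-helix assignment for one frame
#'
#' All-atom path: a residue is helical when it sits in a run of at least 4
#' consecutive residues whose backbone dihedrals fall in the alpha basin
#' (phi in \[-100, -30\] and psi in \[-80, -5\] degrees; undefined terminal
#' dihedrals are not held against a residue). CA-only (coarse-grained) path:
#' P-SEA-style distance criteria, `d(i, i+3)` in \[4.8, 5.6\] A and
#' `d(i, i+4)` in \[5.9, 6.9\] A, each qualifying i labelling the helical
#' turn i..i+4. Missing backbone atoms trigger a warning and the CA path.
#'
#' @param ens an [ensemble].
#' @param frame frame index.
#' @param phi_range,psi_range alpha-basin dihedral windows (degrees).
#' @param min_run minimum helical run length (all-atom path).
#' @param path `"auto"` (dihedrals when backbone is complete, warning +
#'   CA fallback otherwise), `"dihedral"`, or `"ca"`.
#' @return Logical vector, one element per residue (TRUE = helix).
#' @export
assign_secondary_structure <- function(ens, frame = 1L,
                                       phi_range = c(-100, -30),
                                       psi_range = c(-80, -5),
                                       min_run = 4L,
                                       path = c("auto", "dihedral", "ca")) {
  path <- match.arg(path)
  rt <- residue_table(ens)
  n <- nrow(rt)
  if (path == "ca" || ens$cg) return(helix_from_ca(ens, frame))
  tors <- tryCatch(backbone_dihedrals(ens, frame), error = function(e) NULL)
  if (is.null(tors)) {
    if (path == "dihedral") stop("missing backbone atoms (N, CA, C)")
    warning("missing backbone atoms; falling back to CA-distance criteria",
            call. = FALSE)
    return(helix_from_ca(ens, frame))
  }
  ok_phi <- is.na(tors$phi) |
    (tors$phi >= phi_range[1] & tors$phi <= phi_range[2])
  ok_psi <- is.na(tors$psi) |
    (tors$psi >= psi_range[1] & tors$psi <= psi_range[2])
  q <- ok_phi & ok_psi & !(is.na(tors$phi) & is.na(tors$psi))
  runs_at_least(q, min_run)
}

helix_from_ca <- function(ens, frame) {
  idx <- atom_selection(ens, "CA")
  co <- frame_coords(ens, frame)[idx, , drop = FALSE]
  n <- nrow(co)
  h <- logical(n)
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      d3 <- sqrt(sum((co[i, ] - co[i + 3L, ])^2))
      d4 <- sqrt(sum((co[i, ] - co[i + 4L, ])^2))
      if (d3 >= 4.8 && d3 <= 5.6 && d4 >= 5.9 && d4 <= 6.9) {
        h[i:(i + 4L)] <- TRUE
      }
    }
  }
  h
}

# keep only TRUE positions inside runs of >= min_run
runs_at_least <- function(q, min_run) {
  r <- rle(q)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Helicity profile and overall helical content of replicate ensembles
#'
#' Per-residue helix probability over all frames (pooled across replicates),
#' the overall helical content (percent of residue-frames that are helical)
#' per replicate with its mean and population SD, and the stable-helix
#' residue set (probability above the threshold, default 0.30).
#'
#' @param ensembles an [ensemble] or list of replicate ensembles.
#' @param threshold stable-helix probability threshold.
#' @param ... passed to [assign_secondary_structure()].
#' @return list of class `helicity_profile`: `probability` (data.frame
#'   `residue`, `p_helix`, `stable`), `content_percent` (per replicate),
#'   `content_mean`, `content_sd`, `threshold`.
#' @export
helicity_profile <- function(ensembles, threshold = 0.30, ...) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  dots <- list(...)
  if (is.null(dots$path)) {
    # decide the assignment path once for the whole set, not per frame
    has_bb <- all(c("N", "CA", "C") %in% ensembles[[1]]$atoms$elety)
    dots$path <- if (has_bb) "dihedral" else "ca"
  }
  resno <- residue_table(ensembles[[1]])$resno
  n <- length(resno)
  tot <- numeric(n); nfr <- 0L
  content <- numeric(length(ensembles))
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    hsum <- numeric(n); nf <- n_frames(ens)
    for (f in seq_len(nf)) {
      h <- do.call(assign_secondary_structure, c(list(ens, f), dots))
      hsum <- hsum + h
    }
    tot <- tot + hsum; nfr <- nfr + nf
    content[e] <- 100 * sum(hsum) / (n * nf)
  }
  p <- tot / nfr
  structure(list(
    probability = data.frame(residue = resno, p_helix = p,
                             stable = p > threshold),
    content_percent = content,
    content_mean = mean(content),
    content_sd = pop_sd(content),
    threshold = threshold
  ), class = "helicity_profile")
}

#' @export
print.helicity_profile <- function(x, ...) {
  cat("helicity_profile: content ", round(x$content_mean, 1), "% (SD ",
      round(x$content_sd, 2), " over ", length(x$content_percent),
      " replicate(s)); ", sum(x$probability$stable),
      " stable-helix residue(s) at threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Pairwise RMSD matrix over frames
#'
#' @param ens an [ensemble].
#' @param selection atom name(s) used for the fit (default CA).
#' @return Symmetric matrix of RMSD values in Angstrom.
#' @export
pairwise_rmsd <- function(ens, selection = "CA") {
  idx <- atom_selection(ens, selection)
  nf <- n_frames(ens)
  frames <- lapply(seq_len(nf),
                   function(f) frame_coords(ens, f)[idx, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (a in seq_len(nf - 1L)) {
    for (b in (a + 1L):nf) {
      m[a, b] <- m[b, a] <- kabsch_superpose(frames[[a]], frames[[b]])$rmsd
    }
  }
  m
}

#' GROMOS conformational clustering
#'
#' Iterative neighbour-count clustering under a pairwise RMSD cutoff: the
#' frame with the most neighbours within the cutoff becomes a cluster
#' center; it and its neighbours are removed; repeat until all frames are
#' assigned. Ties in neighbour count break toward the lowest frame index,
#' making the result deterministic. The conventional cutoff is 0.9 nm.
#'
#' @param ens an [ensemble].
#' @param cutoff_nm RMSD cutoff in nm.
#' @param selection atom name(s) used for the pairwise fits.
#' @param rmsd optional precomputed pairwise RMSD matrix (Angstrom).
#' @return list of class `cluster_solution`: `membership` (cluster id per
#'   frame, 1 = largest), `centers` (frame index per cluster), `sizes`,
#'   `cutoff_nm`.
#' @export
gromos_cluster <- function(ens, cutoff_nm = 0.9, selection = "CA",
                           rmsd = NULL) {
  if (is.null(rmsd)) rmsd <- pairwise_rmsd(ens, selection)
  cutoff <- cutoff_nm * 10  # matrix is in Angstrom
  nf <- nrow(rmsd)
  adj <- rmsd <= cutoff
  remaining <- rep(TRUE, nf)
  membership <- integer(nf)
  centers <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    counts <- colSums(adj[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts)  # which.max takes the first (lowest index) tie
    members <- which(remaining & adj[center, ])
    cl <- cl + 1L
    membership[members] <- cl
    centers[cl] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(membership, cl)
  ord <- order(-sizes, centers)
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  structure(list(membership = relabel[membership],
                 centers = centers[ord], sizes = sizes[ord],
                 cutoff_nm = cutoff_nm),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: ", length(x$sizes), " cluster(s) at ",
      x$cutoff_nm, " nm; sizes ", paste(x$sizes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Coverage-based cluster representative selection
#'
#' Returns the centers of the smallest prefix of size-ordered clusters whose
#' cumulative membership reaches the requested coverage of all frames
#' (default: at least 50% of frames/poses).
#'
#' @param solution a `cluster_solution`, or a numeric vector of cluster
#'   sizes (in which case cluster indices are returned).
#' @param coverage required fraction in (0, 1].
#' @return Integer vector of representative center frames (or cluster
#'   indices when `solution` is a size vector).
#' @export
select_representatives <- function(solution, coverage = 0.5) {
  if (!(coverage > 0 && coverage <= 1)) {
    stop("coverage must be in (0, 1]")
  }
  if (is.numeric(solution) && is.null(attr(solution, "class"))) {
    sizes <- sort(as.numeric(solution), decreasing = TRUE)
    centers <- order(as.numeric(solution), decreasing = TRUE)
  } else {
    stopifnot(inherits(solution, "cluster_solution"))
    sizes <- solution$sizes
    centers <- solution$centers
  }
  need <- coverage * sum(sizes)
  k <- which(cumsum(sizes) >= need - 1e-9)[1]
  centers[seq_len(k)]
}
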