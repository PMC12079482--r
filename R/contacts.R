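#' Residue-contact criteria
#'
#' A residue pair is in contact when at least `min_pairs` atom pairs (one
#' atom from each residue) lie within `cutoff` Angstrom, and the residues
#' are more than `exclude` apart in sequence (the three nearest neighbours
#' on each side are excluded by default, i.e. pairs with |i - j| <= 3 are
#' never contacts). These are the criteria used throughout: 4.5 A, >= 5
#' atom-atom contacts, 3-neighbour exclusion.
#'
#' @param cutoff atom-atom distance cutoff in Angstrom.
#' @param min_pairs minimum number of qualifying atom pairs.
#' @param exclude sequence-neighbour exclusion k: pairs with |i - j| <= k
#'   are excluded.
#' @param per_side stricter alternative reading: additionally require at
#'   least `min_pairs` distinct atoms on each residue side to participate.
#'   Off by default.
#' @return An object of class `contact_criteria`.
#' @export
contact_criteria <- function(cutoff = 4.5, min_pairs = 5L, exclude = 3L,
                             per_side = FALSE) {
  stopifnot(cutoff > 0, min_pairs >= 1L, exclude >= 0L)
  structure(list(cutoff = cutoff, min_pairs = as.integer(min_pairs),
                 exclude = as.integer(exclude), per_side = per_side),
            class = "contact_criteria")
}

#' @export
print.contact_criteria <- function(x, ...) {
  cat("contact_criteria: cutoff ", x$cutoff, " A, >= ", x$min_pairs,
      " atom pair(s), |i-j| > ", x$exclude,
      if (x$per_side) ", per-side atom rule" else "", "\n", sep = "")
  invisible(x)
}

# atom-pair count between two coordinate blocks; returns c(n_pairs,
# n_atoms_a, n_atoms_b) where the atom counts are distinct participants
count_close_pairs <- function(xa, xb, cutoff) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hit <- d2 <= cutoff^2 + 1e-12
  c(sum(hit), sum(rowSums(hit) > 0), sum(colSums(hit) > 0))
}

#' Residue-residue contacts in one frame
#'
#' Applies the atom-pair criteria to every intra-chain residue pair of a
#' frame. A residue-centroid prefilter skips pairs that cannot possibly
#' contain a qualifying atom pair, so the full atom-pair count is only
#' evaluated for candidates.
#'
#' @param ens an [ensemble] (single chain).
#' @param frame frame index.
#' @param criteria a [contact_criteria].
#' @return data.frame of class `contact_map` with columns `i`, `j`
#'   (chain-local residue indices, `i < j`) and `n_atom_pairs`; attributes
#'   `frame` and `criteria`.
#' @export
residue_contacts <- function(ens, frame = 1L, criteria = contact_criteria()) {
  stopifnot(inherits(ens, "ensemble"), inherits(criteria, "contact_criteria"))
  rt <- residue_table(ens)
  if (length(unique(rt$chain)) != 1L) {
    stop("residue_contacts expects a single chain; use interface_residues ",
         "for two-chain poses")
  }
  if (nrow(rt) < 2L) stop("frame has fewer than 2 residues")
  if (ens$cg && criteria$min_pairs > 1L) {
    stop("coarse-grained (CA-only) input cannot satisfy min_pairs = ",
         criteria$min_pairs, "; lower min_pairs for CG analysis")
  }
  co <- frame_coords(ens, frame)
  contact_scan(co, rt, criteria, frame = frame)
}

# shared scan over residue pairs of one residue table (optionally across two
# tables for inter-chain work)
contact_scan <- function(co, rt, criteria, frame = NA) {
  n <- nrow(rt)
  blocks <- lapply(seq_len(n), function(k) co[rt$first[k]:rt$last[k], , drop = FALSE])
  cent <- t(vapply(blocks, colMeans, numeric(3)))
  rad <- vapply(seq_len(n), function(k) {
    sqrt(max(rowSums((blocks[[k]] - rep(cent[k, ], each = nrow(blocks[[k]])))^2)))
  }, numeric(1))
  d2c <- outer(rowSums(cent^2), rowSums(cent^2), "+") - 2 * tcrossprod(cent)
  reach <- outer(rad, rad, "+") + criteria$cutoff
  cand <- which(upper.tri(d2c) & d2c <= reach^2 &
                  abs(outer(rt$resno, rt$resno, "-")) > criteria$exclude,
                arr.ind = TRUE)
  out <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    cnt <- count_close_pairs(blocks[[a]], blocks[[b]], criteria$cutoff)
    ok <- cnt[1] >= criteria$min_pairs
    if (ok && criteria$per_side) {
      ok <- cnt[2] >= criteria$min_pairs && cnt[3] >= criteria$min_pairs
    }
    if (ok) out[[length(out) + 1L]] <- c(rt$resno[a], rt$resno[b], cnt[1])
  }
  cm <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]),
               n_atom_pairs = m[, 3])
  } else {
    data.frame(i = integer(0), j = integer(0), n_atom_pairs = integer(0))
  }
  cm <- cm[order(cm$i, cm$j), , drop = FALSE]
  rownames(cm) <- NULL
  structure(cm, class = c("contact_map", "data.frame"),
            frame = frame, criteria = criteria)
}

#' Per-pair contact frequency over an ensemble
#'
#' @param ens an [ensemble] with at least one frame.
#' @param criteria a [contact_criteria].
#' @param frames optional frame subset (default all frames).
#' @return data.frame with columns `i`, `j`, `n_frames`, `frequency`
#'   (fraction of analysed frames in contact).
#' @export
contact_frequency <- function(ens, criteria = contact_criteria(),
                              frames = NULL) {
  if (n_frames(ens) < 1L) stop("empty ensemble")
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  if (length(frames) < 1L) stop("no frames selected")
  tal <- new.env(parent = emptyenv())
  for (f in frames) {
    cm <- residue_contacts(ens, f, criteria)
    if (nrow(cm)) {
      keys <- paste(cm$i, cm$j, sep = "_")
      for (k in keys) {
        assign(k, (if (exists(k, envir = tal)) get(k, envir = tal) else 0L) + 1L,
               envir = tal)
      }
    }
  }
  keys <- ls(tal)
  if (!length(keys)) {
    return(data.frame(i = integer(0), j = integer(0),
                      n_frames = integer(0), frequency = numeric(0)))
  }
  ij <- do.call(rbind, strsplit(keys, "_"))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    n_frames = vapply(keys, get, integer(1), envir = tal))
  out$frequency <- out$n_frames / length(frames)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population standard deviation
#' @param x numeric vector.
#' @return sqrt of the mean squared deviation from the mean (divisor n).
#' @export
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Fraction of time two residue groups are in contact
#'
#' For each replicate ensemble, the fraction of frames in which at least one
#' residue pair (one from each group) is in contact; reported as the mean
#' and population standard deviation across replicates. This is the
#' inter-region (NR vs CR) contact-time statistic.
#'
#' @param ensembles an [ensemble] or list of replicate ensembles.
#' @param group_a,group_b disjoint integer sets of residue indices.
#' @param criteria a [contact_criteria].
#' @param frames optional frame subset applied to every replicate.
#' @return list with `per_replicate` (numeric vector of fractions), `mean`,
#'   and `sd` (population SD across replicates).
#' @export
group_contact_fraction <- function(ensembles, group_a, group_b,
                                   criteria = contact_criteria(),
                                   frames = NULL) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  if (length(intersect(group_a, group_b))) {
    stop("residue groups must be disjoint")
  }
  fr <- vapply(ensembles, function(ens) {
    ff <- if (is.null(frames)) seq_len(n_frames(ens)) else frames
    hits <- vapply(ff, function(f) {
      cm <- residue_contacts(ens, f, criteria)
      any((cm$i %in% group_a & cm$j %in% group_b) |
            (cm$i %in% group_b & cm$j %in% group_a))
    }, logical(1))
    mean(hits)
  }, numeric(1))
  list(per_replicate = fr, mean = mean(fr), sd = pop_sd(fr))
}
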