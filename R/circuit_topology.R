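#' Circuit topology of intra-chain contact pairs
#'
#' Circuit topology classifies every pair of intra-chain contacts by the
#' arrangement of their sequence intervals: series (S, disjoint), parallel
#' (P, nested; the enclosed member is in the inverse-parallel relation), or
#' cross (X, interleaved). Contacts are closed intervals `[i, j]` with
#' `i < j`; ties at shared endpoints are broken deterministically: intervals
#' touching only at an endpoint are series, and containment with a shared
#' boundary counts as parallel. These tie rules make S/P/X a partition, so
#' every census satisfies `n_S + n_P + n_X = choose(m, 2)`.
#'
#' @name circuit_topology
NULL

# vectorised relation kernel over interval pairs; returns "S", "P" (second
# nested in first), "Pinv" (first nested in second) or "X"
relation_code <- function(i1, j1, i2, j2) {
  out <- character(length(i1))
  nest21 <- i1 <= i2 & j2 <= j1   # c2 inside c1
  nest12 <- i2 <= i1 & j1 <= j2   # c1 inside c2
  sep <- pmin(j1, j2) <= pmax(i1, i2)  # overlap at most one shared endpoint
  out[sep] <- "S"
  out[!sep & nest21] <- "P"
  out[!sep & !nest21 & nest12] <- "Pinv"
  out[out == ""] <- "X"
  out
}

#' Classify the topological relation of two contacts
#'
#' @param c1,c2 contacts as length-2 integer vectors `(i, j)` with `i < j`.
#' @return `"S"`, `"X"`, `"P"` (c2 nested inside c1) or `"Pinv"` (c1 nested
#'   inside c2).
#' @examples
#' classify_relation(c(1, 10), c(12, 20))  # "S"
#' classify_relation(c(1, 10), c(3, 7))    # "P"
#' classify_relation(c(1, 10), c(5, 15))   # "X"
#' @export
classify_relation <- function(c1, c2) {
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  stopifnot(length(c1) == 2L, length(c2) == 2L, c1[1] < c1[2], c2[1] < c2[2])
  if (all(c1 == c2)) stop("identical contacts have no pairwise relation")
  relation_code(c1[1], c1[2], c2[1], c2[2])
}

#' Series/parallel/cross census of a contact set
#'
#' Counts the relation of every unordered pair of contacts in a contact map
#' (parallel counted once per pair, regardless of which member is nested).
#'
#' @param contact_map a `contact_map` (from [residue_contacts()]) or any
#'   data.frame with integer columns `i`, `j`.
#' @return list of class `relation_census`: `n_S`, `n_P`, `n_X`, `n_PX`,
#'   `m` (number of contacts), `n_pairs` (= choose(m, 2)).
#' @examples
#' ladder <- data.frame(i = 1:4, j = 20:17)
#' topology_census(ladder)$n_P  # 6
#' @export
topology_census <- function(contact_map) {
  i <- as.integer(contact_map$i); j <- as.integer(contact_map$j)
  m <- length(i)
  if (m < 2L) {
    return(structure(list(n_S = 0L, n_P = 0L, n_X = 0L, n_PX = 0L,
                          m = m, n_pairs = 0L),
                     class = "relation_census"))
  }
  pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  rel <- relation_code(i[pr[, 1]], j[pr[, 1]], i[pr[, 2]], j[pr[, 2]])
  n_S <- sum(rel == "S")
  n_P <- sum(rel == "P" | rel == "Pinv")
  n_X <- sum(rel == "X")
  structure(list(n_S = n_S, n_P = n_P, n_X = n_X, n_PX = n_P + n_X,
                 m = m, n_pairs = choose(m, 2)),
            class = "relation_census")
}

#' @export
print.relation_census <- function(x, ...) {
  cat("relation_census: m = ", x$m, " contacts; S = ", x$n_S,
      ", P = ", x$n_P, ", X = ", x$n_X, "\n", sep = "")
  invisible(x)
}

# per contact, how many other contacts enclose it (parallel with this
# contact as the nested member)
enclosing_counts <- function(i, j) {
  m <- length(i)
  if (m == 0L) return(integer(0))
  vapply(seq_len(m), function(k) {
    sum(i <= i[k] & j[k] <= j & !(i == i[k] & j == j[k]))
  }, integer(1))
}

#' Per-residue inverse-parallel (local circuit topology) profile
#'
#' For each sampled frame and residue r, sums over the contacts incident to
#' r the number of other contacts whose interval encloses them: a measure of
#' how deeply sequestered r is inside the chain's contact circuitry. The
#' profile is the per-residue mean with its standard error over all sampled
#' frames, pooled across replicates. SEM uses the population SD.
#'
#' @param ensembles an [ensemble] or list of replicate ensembles.
#' @param criteria a [contact_criteria].
#' @param sample_interval_ns frame-sampling stride in ns (25 by default,
#'   matching coarse trajectory analysis practice).
#' @param n_residues number of residues (default: taken from the first
#'   ensemble).
#' @param aggregate `"sum"` (default) or `"mean"`: how a residue's incident
#'   contacts are combined within one frame.
#' @return data.frame with columns `residue`, `mean`, `sem`; attribute
#'   `n_frames`.
#' @export
local_inverse_parallel_profile <- function(ensembles,
                                           criteria = contact_criteria(),
                                           sample_interval_ns = 25,
                                           n_residues = NULL,
                                           aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  if (is.null(n_residues)) n_residues <- nrow(residue_table(ensembles[[1]]))
  per_frame <- list()
  for (ens in ensembles) {
    for (f in sample_frames(ens, sample_interval_ns)) {
      cm <- residue_contacts(ens, f, criteria)
      v <- numeric(n_residues)
      if (nrow(cm)) {
        enc <- enclosing_counts(cm$i, cm$j)
        for (k in seq_len(nrow(cm))) {
          v[cm$i[k]] <- v[cm$i[k]] + enc[k]
          v[cm$j[k]] <- v[cm$j[k]] + enc[k]
        }
        if (aggregate == "mean") {
          deg <- numeric(n_residues)
          for (k in seq_len(nrow(cm))) {
            deg[cm$i[k]] <- deg[cm$i[k]] + 1
            deg[cm$j[k]] <- deg[cm$j[k]] + 1
          }
          v <- ifelse(deg > 0, v / pmax(deg, 1), 0)
        }
      }
      per_frame[[length(per_frame) + 1L]] <- v
    }
  }
  mat <- do.call(rbind, per_frame)
  nf <- nrow(mat)
  mu <- colMeans(mat)
  sem <- apply(mat, 2, pop_sd) / sqrt(nf)
  structure(data.frame(residue = seq_len(n_residues), mean = mu, sem = sem),
            n_frames = nf)
}

#' Topology configuration-space density
#'
#' Reduces each sampled frame to the point (n_S, n_P + n_X) of its contact
#' census and aggregates frames (pooled over replicates) into a normalized
#' 2D histogram: the density of visited topological configurations.
#'
#' @param ensembles an [ensemble] or list of replicate ensembles.
#' @param criteria a [contact_criteria].
#' @param sample_interval_ns frame-sampling stride in ns.
#' @param s_breaks,px_breaks histogram bin edges; default: unit-width
#'   integer bins spanning the observed values.
#' @return list of class `topology_density`: `points` (data.frame `n_S`,
#'   `n_PX`, one row per sampled frame), `density` (matrix, rows = S bins),
#'   `s_breaks`, `px_breaks`.
#' @export
topology_density <- function(ensembles, criteria = contact_criteria(),
                             sample_interval_ns = 25,
                             s_breaks = NULL, px_breaks = NULL) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  pts <- list()
  for (ens in ensembles) {
    for (f in sample_frames(ens, sample_interval_ns)) {
      cen <- topology_census(residue_contacts(ens, f, criteria))
      pts[[length(pts) + 1L]] <- c(cen$n_S, cen$n_PX)
    }
  }
  pts <- do.call(rbind, pts)
  points <- data.frame(n_S = pts[, 1], n_PX = pts[, 2])
  if (is.null(s_breaks)) {
    s_breaks <- seq(min(points$n_S) - 0.5, max(points$n_S) + 0.5, by = 1)
  }
  if (is.null(px_breaks)) {
    px_breaks <- seq(min(points$n_PX) - 0.5, max(points$n_PX) + 0.5, by = 1)
  }
  si <- cut(points$n_S, s_breaks, include.lowest = TRUE)
  pi_ <- cut(points$n_PX, px_breaks, include.lowest = TRUE)
  dens <- table(si, pi_) / nrow(points)
  structure(list(points = points, density = unclass(dens),
                 s_breaks = s_breaks, px_breaks = px_breaks),
            class = "topology_density")
}

#' @export
print.topology_density <- function(x, ...) {
  cat("topology_density: ", nrow(x$points), " sampled frames, ",
      "S range [", min(x$points$n_S), ", ", max(x$points$n_S), "], ",
      "P+X range [", min(x$points$n_PX), ", ", max(x$points$n_PX), "]\n",
      sep = "")
  invisible(x)
}

#' Contour plot of a topology configuration-space density
#'
#' @param x a `topology_density`.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.topology_density <- function(x, ...) {
  s_mid <- (head(x$s_breaks, -1) + tail(x$s_breaks, -1)) / 2
  p_mid <- (head(x$px_breaks, -1) + tail(x$px_breaks, -1)) / 2
  graphics::filled.contour(s_mid, p_mid, x$density,
                           xlab = "S relations", ylab = "P + X relations",
                           ...)
}
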