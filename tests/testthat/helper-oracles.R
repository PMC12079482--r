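# Independent oracles, deliberately formulated differently from the package
# implementations they check.

# Relation census via integer interval-overlap arithmetic: for closed
# intervals the overlap length decides everything (<= 1 shared residue:
# series; overlap equal to the shorter interval: nested/parallel; else
# cross). The package classifies by sorted endpoint comparisons instead.
oracle_census <- function(cm) {
  m <- nrow(cm)
  if (m < 2L) return(c(S = 0L, P = 0L, X = 0L))
  pr <- t(utils::combn(m, 2L))
  i1 <- cm$i[pr[, 1]]; j1 <- cm$j[pr[, 1]]
  i2 <- cm$i[pr[, 2]]; j2 <- cm$j[pr[, 2]]
  overlap <- pmin(j1, j2) - pmax(i1, i2) + 1L
  shorter <- pmin(j1 - i1, j2 - i2) + 1L
  S <- sum(overlap <= 1L)
  P <- sum(overlap > 1L & overlap == shorter)
  c(S = S, P = P, X = as.integer(m * (m - 1L) / 2L) - S - P)
}

# random distinct contact pairs on a chain of length len
random_contact_map <- function(m, len = 200L, min_sep = 1L) {
  seen <- character(0)
  i <- integer(0); j <- integer(0)
  while (length(i) < m) {
    a <- sample.int(len - min_sep, 1L)
    b <- a + min_sep - 1L + sample.int(len - a - min_sep + 1L, 1L)
    key <- paste(a, b)
    if (!key %in% seen) {
      seen <- c(seen, key); i <- c(i, a); j <- c(j, b)
    }
  }
  data.frame(i = i, j = j)
}

# Brute-force contact oracle: full atom-atom distance matrix aggregated to
# residue-pair counts (no centroid prefilter, no early exit).
brute_contacts <- function(ens, frame = 1L, criteria = contact_criteria()) {
  co <- frame_coords(ens, frame)
  r <- ens$atoms$resno
  close <- (as.matrix(stats::dist(co)) <= criteria$cutoff + 1e-12) + 0
  counts <- rowsum(t(rowsum(close, r)), r)  # residue x residue pair counts
  res <- as.integer(rownames(counts))
  hits <- which(upper.tri(counts) & counts >= criteria$min_pairs,
                arr.ind = TRUE)
  out <- data.frame(i = res[hits[, 1]], j = res[hits[, 2]])
  out <- out[out$j - out$i > criteria$exclude, , drop = FALSE]
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quick 3-replicate fluctuation fixture around a planted-contact scaffold
make_replicate_fixture <- function(n_res = 40L, n_frames = 6L, seed = 1L,
                                   sigma = 0.3) {
  base <- make_contact_scaffold(
    n_res, data.frame(i = c(5L, 12L), j = c(25L, 30L)), seed = seed)
  lapply(1:3, function(r) {
    make_fluctuation_ensemble(base, sigma, n_frames, seed = seed + 10L * r,
                              replicate = r)
  })
}
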