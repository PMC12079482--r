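#' Conformer ensembles
#'
#' An `ensemble` holds an ordered set of conformer frames with identical
#' topology: a fixed atom table (chain, residue index, residue name, atom
#' name, element) and one row of flattened coordinates per frame, in
#' Angstrom, following the `(x1, y1, z1, x2, ...)` layout used by bio3d.
#' Optional time stamps (ns), a replicate id and a sampling interval carry
#' trajectory provenance. A single conformer is a 1-frame ensemble.
#'
#' Coarse-grained (bead-per-residue) input is detected as "only CA atoms
#' present" and flagged; geometric operations declare whether they accept it.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `elety` (atom name), `element`.
#' @param xyz numeric matrix, frames x (3 * n_atoms).
#' @param time_ns optional numeric vector of frame time stamps (ns),
#'   strictly increasing.
#' @param replicate optional replicate identifier.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, xyz, time_ns = NULL, replicate = NA) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resname", "elety", "element") %in%
                  names(atoms)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms),
         " for ", nrow(atoms), " atoms")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms$resno <- as.integer(atoms$resno)
  if (any(atoms$resno < 1L)) stop("residue indices must be >= 1")
  # residues within a chain must appear in non-decreasing index order
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices not sorted within chain ", ch)
  }
  if (!is.null(time_ns)) {
    time_ns <- as.numeric(time_ns)
    if (length(time_ns) != nrow(xyz)) stop("one time stamp per frame required")
    if (any(diff(time_ns) <= 0)) stop("time stamps must be strictly increasing")
  }
  cg <- all(atoms$elety == "CA")
  structure(list(atoms = atoms, xyz = xyz, time_ns = time_ns,
                 replicate = replicate, cg = cg),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble: ", n_frames(x), " frame(s), ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues, ",
      length(unique(x$atoms$chain)), " chain(s)",
      if (x$cg) " [coarse-grained]" else "", "\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Extract one frame's coordinates as an n_atoms x 3 matrix
#' @param ens an `ensemble`.
#' @param frame frame index.
#' @return Numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(ens, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(ens))
  matrix(ens$xyz[frame, ], ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset an ensemble's frames
#' @param ens an `ensemble`.
#' @param frames integer vector of frame indices.
#' @return An `ensemble` with the selected frames.
#' @export
subset_frames <- function(ens, frames) {
  ensemble(ens$atoms, ens$xyz[frames, , drop = FALSE],
           time_ns = if (!is.null(ens$time_ns)) ens$time_ns[frames],
           replicate = ens$replicate)
}

#' Residue table of an ensemble
#' @param ens an `ensemble`.
#' @return data.frame with one row per (chain, residue): `chain`, `resno`,
#'   `resname`, plus `first`/`last` atom-row bounds.
#' @export
residue_table <- function(ens) {
  key <- paste(ens$atoms$chain, ens$atoms$resno, sep = "\r")
  first <- which(!duplicated(key))
  last <- c(first[-1] - 1L, nrow(ens$atoms))
  data.frame(chain = ens$atoms$chain[first],
             resno = ens$atoms$resno[first],
             resname = ens$atoms$resname[first],
             first = first, last = last,
             stringsAsFactors = FALSE)
}

#' Indices of frames sampled at a fixed time interval
#'
#' Mirrors the trajectory practice of analysing at a coarse stride (e.g.
#' every 25 ns): returns the frames whose time stamps fall on multiples of
#' `interval_ns` from the first stamp. Without time stamps the interval is
#' interpreted in frame units.
#'
#' @param ens an `ensemble`.
#' @param interval_ns sampling interval (ns).
#' @return Integer frame indices.
#' @export
sample_frames <- function(ens, interval_ns) {
  if (is.null(ens$time_ns)) {
    step <- max(1L, as.integer(round(interval_ns)))
    return(seq(1L, n_frames(ens), by = step))
  }
  if (n_frames(ens) == 1L) return(1L)
  spacing <- min(diff(ens$time_ns))
  if (interval_ns < spacing - 1e-9) {
    stop("sampling interval ", interval_ns,
         " ns finer than frame spacing ", spacing, " ns")
  }
  t0 <- ens$time_ns[1]
  phase <- (ens$time_ns - t0) / interval_ns
  which(abs(phase - round(phase)) < 1e-6)
}
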