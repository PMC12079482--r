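#' Sequence constructs with an annotated polyglutamine tract
#'
#' A `seq_construct` represents a protein chain (one-letter codes, 1-based)
#' together with the inclusive span of its polyglutamine (pQ) tract and a
#' variant label. The two constructs of interest are the wild-type
#' transactivation domain (23 consecutive glutamines) and its
#' disease-associated expansion (45 glutamines); arbitrary tract lengths are
#' supported for synthetic work.
#'
#' The tract span defaults are config-supplied, not hard-coded biology: the
#' default UniProt-frame span is residues 58-80 (the P10275 poly-Gln
#' annotation), and every construct carries its numbering-frame label so that
#' downstream results can always be traced to a frame.
#'
#' @param residues character vector of one-letter codes, or a single string.
#' @param pq_span integer length-2 vector, inclusive 1-based span of the
#'   glutamine tract.
#' @param variant one of `"wt"`, `"pQe"`, `"custom"`.
#' @param frame numbering-frame label (e.g. `"wt"`, `"pQe"`, `"uniprot"`).
#' @return An object of class `seq_construct`.
#' @examples
#' x <- seq_construct("AAQQQAAAAA", pq_span = c(3, 5))
#' pq_length(x)
#' @export
seq_construct <- function(residues, pq_span,
                          variant = c("custom", "wt", "pQe"),
                          frame = "chain-local") {
  variant <- match.arg(variant)
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  n <- length(residues)
  pq_span <- as.integer(pq_span)
  if (length(pq_span) != 2L || anyNA(pq_span)) {
    stop("pq_span must be two integers (start, end)")
  }
  if (pq_span[1] < 1L || pq_span[2] > n || pq_span[1] > pq_span[2]) {
    stop("pq_span [", pq_span[1], ", ", pq_span[2],
         "] out of range for chain of length ", n)
  }
  tract <- residues[pq_span[1]:pq_span[2]]
  if (!all(tract == "Q")) {
    stop("all residues inside pq_span must be glutamine (Q)")
  }
  structure(
    list(residues = residues, pq_span = pq_span,
         variant = variant, frame = frame),
    class = "seq_construct"
  )
}

#' @export
print.seq_construct <- function(x, ...) {
  cat("seq_construct [", x$variant, "]: ", length(x$residues),
      " residues, pQ tract ", x$pq_span[1], "-", x$pq_span[2],
      " (", pq_length(x), " Q), frame ", x$frame, "\n", sep = "")
  invisible(x)
}

#' @export
length.seq_construct <- function(x) length(x$residues)

#' Length of a construct's glutamine tract
#' @param x a `seq_construct`.
#' @return Integer tract length.
#' @export
pq_length <- function(x) {
  stopifnot(inherits(x, "seq_construct"))
  x$pq_span[2] - x$pq_span[1] + 1L
}

#' Expand or contract the polyglutamine tract of a construct
#'
#' Returns a construct whose tract has exactly `target_pq_length` glutamines;
#' the flanking sequence is unchanged and the chain length changes by the
#' difference in tract length. Glutamines are inserted at (or removed from)
#' the tract C-terminus by default; since the tract is homopolymeric every
#' insertion point gives the same residue sequence, so the switch only
#' matters for bookkeeping of frames.
#'
#' @param base a `seq_construct` with a valid tract.
#' @param target_pq_length positive integer, desired tract length.
#' @param variant variant label for the result (default `"custom"`, or kept
#'   when the length is unchanged).
#' @param insertion `"c-terminal"` or `"mid-tract"`; where extra glutamines
#'   are conceptually inserted.
#' @return A `seq_construct`.
#' @examples
#' wt <- synthetic_ntd_construct(pq_len = 23)
#' pqe <- build_construct(wt, 45, variant = "pQe")
#' length(pqe) - length(wt)  # 22
#' @export
build_construct <- function(base, target_pq_length,
                            variant = NULL,
                            insertion = c("c-terminal", "mid-tract")) {
  stopifnot(inherits(base, "seq_construct"))
  insertion <- match.arg(insertion)
  target_pq_length <- as.integer(target_pq_length)
  if (is.na(target_pq_length) || target_pq_length < 1L) {
    stop("target_pq_length must be a positive integer")
  }
  old_len <- pq_length(base)
  if (target_pq_length == old_len) {
    out <- base
    if (!is.null(variant)) out$variant <- variant
    return(out)
  }
  pre <- base$residues[seq_len(base$pq_span[1] - 1L)]
  post <- if (base$pq_span[2] < length(base$residues)) {
    base$residues[(base$pq_span[2] + 1L):length(base$residues)]
  } else character(0)
  residues <- c(pre, rep("Q", target_pq_length), post)
  seq_construct(
    residues,
    pq_span = c(base$pq_span[1], base$pq_span[1] + target_pq_length - 1L),
    variant = if (is.null(variant)) "custom" else variant,
    frame = if (is.null(variant)) base$frame else variant
  )
}

#' Synthetic stand-in for the disordered transactivation-domain construct
#'
#' Builds a 538-residue synthetic chain with a glutamine tract at the
#' annotated span (residues 58-80 in the wild-type/UniProt frame by default)
#' and alanine elsewhere. This is a numbering-faithful stand-in, not the real
#' receptor sequence: tract coordinates, chain length and all numbering lifts
#' match the domain, while non-tract residues are placeholders. Use it where
#' only numbering and tract structure matter (lifts, region classification,
#' fixture generation).
#'
#' @param pq_len tract length (23 for wild type, 45 for the expansion).
#' @param pq_start first tract residue in the wild-type frame.
#' @param chain_len_wt chain length in the wild-type frame.
#' @return A `seq_construct` labelled `wt` (23 Q) or `pQe` (45 Q) or
#'   `custom` otherwise.
#' @export
synthetic_ntd_construct <- function(pq_len = 23L, pq_start = 58L,
                                    chain_len_wt = 538L) {
  pq_len <- as.integer(pq_len)
  residues <- rep("A", chain_len_wt)
  residues[pq_start:(pq_start + 22L)] <- "Q"
  wt <- seq_construct(residues, pq_span = c(pq_start, pq_start + 22L),
                      variant = "wt", frame = "wt")
  if (pq_len == 23L) return(wt)
  build_construct(wt, pq_len,
                  variant = if (pq_len == 45L) "pQe" else "custom")
}

#' Write constructs to FASTA
#'
#' @param constructs a `seq_construct` or list of them.
#' @param path output file.
#' @param names optional sequence names (default: variant labels).
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(constructs, path, names = NULL) {
  if (inherits(constructs, "seq_construct")) constructs <- list(constructs)
  seqs <- lapply(constructs, function(x) x$residues)
  if (is.null(names)) {
    names <- vapply(constructs, function(x) {
      paste0(x$variant, "_", length(x$residues), "aa_synthetic")
    }, character(1))
  }
  seqinr::write.fasta(seqs, names = names, file.out = path)
  invisible(path)
}
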