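#' Read a (multi-model) PDB file as an ensemble
#'
#' MODEL/ENDMDL blocks become frames; a single-model file yields a 1-frame
#' ensemble. Parsing is delegated to [bio3d::read.pdb()]; on top of it this
#' reader resolves alternate locations to the highest-occupancy copy,
#' rejects insertion codes, and enforces identical topology across models.
#'
#' @param path PDB file.
#' @param time_ns optional frame time stamps (ns), or a single sampling
#'   interval from which stamps `0, dt, 2*dt, ...` are built.
#' @param replicate optional replicate id attached to the ensemble.
#' @return An [ensemble].
#' @export
read_pdb <- function(path, time_ns = NULL, replicate = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch({
    utils::capture.output(
      p <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            rm.alt = FALSE,
                                            verbose = FALSE)))
    p
  }, error = function(e) stop("PDB parse error in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  keep <- atom$type %in% c("ATOM", "HETATM")
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no atom records in ", path)
  if (any(!is.na(atom$insert) & atom$insert != "")) {
    stop("insertion codes are not supported (file ", path, ")")
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * length(keep)) {
    stop("inconsistent atom count across models in ", path,
         ": topology must be identical in every MODEL")
  }
  xyz <- xyz[, rep((which(keep) - 1L) * 3L, each = 3L) + 1:3, drop = FALSE]

  # resolve altlocs: keep highest occupancy per (chain, resno, atom name)
  alt <- !is.na(atom$alt) & atom$alt != ""
  if (any(alt)) {
    key <- paste(atom$chain, atom$resno, atom$elety, sep = "\r")
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    ord <- order(key, -occ)
    keep2 <- ord[!duplicated(key[ord])]
    keep2 <- sort(keep2)
    atom <- atom[keep2, , drop = FALSE]
    xyz <- xyz[, rep((keep2 - 1L) * 3L, each = 3L) + 1:3, drop = FALSE]
  }
  n_models <- nrow(xyz)
  if (anyNA(xyz)) {
    stop("inconsistent atom count across models in ", path,
         ": topology must be identical in every MODEL")
  }
  atoms <- data.frame(chain = ifelse(is.na(atom$chain), "A", atom$chain),
                      resno = atom$resno,
                      resname = atom$resid,
                      elety = atom$elety,
                      element = guess_element(atom$elety, atom$elesy),
                      stringsAsFactors = FALSE)
  if (length(time_ns) == 1L && n_models > 1L) {
    time_ns <- seq(0, by = time_ns, length.out = n_models)
  }
  ensemble(atoms, xyz, time_ns = time_ns, replicate = replicate)
}

guess_element <- function(elety, elesy = NULL) {
  out <- if (!is.null(elesy)) toupper(trimws(elesy)) else rep("", length(elety))
  miss <- is.na(out) | out == ""
  if (any(miss)) {
    # first alphabetic character of the atom name, PDB convention
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", elety[miss]))
    out[miss] <- toupper(substr(nm, 1, 1))
  }
  out
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' Inverse of [read_pdb()] up to the fixed-width PDB coordinate precision
#' (3 decimals). Frames become MODEL blocks. Writing then re-reading then
#' writing again is byte-identical.
#'
#' @param ens an [ensemble].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  if (any(nchar(ens$atoms$chain) != 1L)) {
    stop("PDB chain ids must be a single character")
  }
  bio3d::write.pdb(file = path,
                   xyz = ens$xyz,
                   resno = ens$atoms$resno,
                   resid = ens$atoms$resname,
                   eleno = seq_len(nrow(ens$atoms)),
                   elety = ens$atoms$elety,
                   chain = ens$atoms$chain,
                   elesy = ens$atoms$element)
  invisible(path)
}

#' Write/read an ensemble as a per-frame coordinate CSV
#'
#' Plain-text interchange table with columns
#' `frame, chain, resno, resname, atom, x, y, z`.
#'
#' @param ens an [ensemble].
#' @param path CSV file.
#' @return `path` (write) or an [ensemble] (read).
#' @export
write_frame_csv <- function(ens, path) {
  nf <- n_frames(ens)
  na <- nrow(ens$atoms)
  co <- do.call(rbind, lapply(seq_len(nf), frame_coords, ens = ens))
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   chain = rep(ens$atoms$chain, nf),
                   resno = rep(ens$atoms$resno, nf),
                   resname = rep(ens$atoms$resname, nf),
                   atom = rep(ens$atoms$elety, nf),
                   x = co[, 1], y = co[, 2], z = co[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  f1 <- df[df$frame == df$frame[1], , drop = FALSE]
  atoms <- data.frame(chain = as.character(f1$chain), resno = f1$resno,
                      resname = f1$resname, elety = f1$atom,
                      element = guess_element(f1$atom),
                      stringsAsFactors = FALSE)
  frames <- sort(unique(df$frame))
  xyz <- t(vapply(frames, function(f) {
    d <- df[df$frame == f, , drop = FALSE]
    as.numeric(t(as.matrix(d[, c("x", "y", "z")])))
  }, numeric(3L * nrow(atoms))))
  ensemble(atoms, xyz)
}

#' Read a directory of two-chain docking poses
#'
#' Each PDB file in the directory (lexicographic order) becomes one pose.
#' Files that do not contain exactly two chains are skipped with a warning
#' and counted.
#'
#' @param dir directory of pose PDB files.
#' @param receptor_chain,ligand_chain chain ids taken as receptor/ligand.
#' @param pattern filename pattern (default `"\\.pdb$"`).
#' @return An object of class `pose_set`: list with `poses` (list of
#'   1-frame [ensemble]s), `files`, `n_skipped`, and the chain roles.
#' @export
read_pose_set <- function(dir, receptor_chain = "A", ligand_chain = "B",
                          pattern = "\\.pdb$") {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  poses <- list()
  kept <- character(0)
  skipped <- 0L
  for (f in files) {
    ens <- read_pdb(f)
    chains <- unique(ens$atoms$chain)
    if (length(chains) != 2L) {
      warning("skipping ", basename(f), ": ", length(chains),
              " chain(s), expected 2", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    poses[[length(poses) + 1L]] <- ens
    kept <- c(kept, basename(f))
  }
  if (length(poses) == 0L) {
    warning("pose set from ", dir, " is empty", call. = FALSE)
  }
  structure(list(poses = poses, files = kept, n_skipped = skipped,
                 receptor_chain = receptor_chain,
                 ligand_chain = ligand_chain),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("pose_set: ", length(x$poses), " pose(s), ", x$n_skipped,
      " skipped; receptor chain ", x$receptor_chain,
      ", ligand chain ", x$ligand_chain, "\n", sep = "")
  invisible(x)
}

#' @export
length.pose_set <- function(x) length(x$poses)
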