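#' Region and motif maps over a numbering frame
#'
#' A `region_map` is a set of named inclusive residue intervals, each tagged
#' with the numbering frame it is expressed in. The default map carries the
#' two dynamic sub-regions of the transactivation domain - the N-terminal
#' region NR (residues 1-224) and C-terminal region CR (225-538) - plus the
#' functionally important motifs: the pQ tract, FQNLF, the androgen
#' N-terminal signature (ANTS, residues 233-246 in the wild-type/UniProt
#' frame), Tau-5, and the partner-chain P-box.
#'
#' NR and CR must be disjoint; together they classify every residue of the
#' domain. Motifs may overlap regions freely.
#'
#' @param regions data.frame with columns `name`, `start`, `end`, `frame`.
#' @param chain_length declared chain length in the map's primary frame
#'   (intervals in that frame must fit inside it).
#' @param frame the primary numbering frame of the map.
#' @return An object of class `region_map`.
#' @examples
#' rm <- default_region_map()
#' classify_region(rm, 100)
#' @export
region_map <- function(regions, chain_length, frame = "wt") {
  stopifnot(is.data.frame(regions),
            all(c("name", "start", "end", "frame") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start < 1L) || any(regions$start > regions$end)) {
    stop("malformed interval in region map")
  }
  local <- regions[regions$frame == frame, , drop = FALSE]
  if (any(local$end > chain_length)) {
    stop("region map interval exceeds declared chain length ", chain_length)
  }
  nr <- regions[regions$name == "NR", , drop = FALSE]
  cr <- regions[regions$name == "CR", , drop = FALSE]
  if (nrow(nr) == 1L && nrow(cr) == 1L && nr$frame == cr$frame) {
    if (nr$end >= cr$start && cr$end >= nr$start) {
      stop("NR and CR intervals must be disjoint")
    }
  }
  structure(list(regions = regions, chain_length = as.integer(chain_length),
                 frame = frame),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map (frame ", x$frame, ", chain length ",
      x$chain_length, "):\n", sep = "")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Default region/motif annotations for the transactivation domain
#'
#' Intervals are in the wild-type (UniProt) frame except where noted.
#' NR/CR are the printed sub-regions 1-224 / 225-538; ANTS is the printed
#' 233-246. The pQ tract (58-80), FQNLF (23-27) and Tau-5 (361-537) default
#' to UniProt-derived annotations; the P-box (577-581) lies on the partner
#' DNA-binding domain and is tagged with a partner-chain frame.
#'
#' @param frame `"wt"` (default) or `"pQe"`; for `"pQe"` all intervals on
#'   the expanded chain are lifted through the +22 numbering offset.
#' @param pq_span tract span in the wt frame.
#' @param pqe_tract_length tract length in the pQe frame (used for lifting).
#' @return A `region_map`.
#' @export
default_region_map <- function(frame = c("wt", "pQe"),
                               pq_span = c(58L, 80L),
                               pqe_tract_length = 45L) {
  frame <- match.arg(frame)
  regions <- data.frame(
    name  = c("NR", "CR", "pQ", "FQNLF", "ANTS", "Tau-5", "P-box"),
    start = c(1L, 225L, pq_span[1], 23L, 233L, 361L, 577L),
    end   = c(224L, 538L, pq_span[2], 27L, 246L, 537L, 581L),
    frame = c(rep("wt", 6), "partner"),
    stringsAsFactors = FALSE
  )
  if (frame == "wt") {
    return(region_map(regions, chain_length = 538L, frame = "wt"))
  }
  offset <- as.integer(pqe_tract_length) - (pq_span[2] - pq_span[1] + 1L)
  lift <- numbering_lift(tract_end = pq_span[2], offset = offset,
                         source = "wt", target = "pQe")
  shift <- regions$frame == "wt"
  for (i in which(shift)) {
    if (regions$name[i] == "pQ") {
      regions$start[i] <- pq_span[1]
      regions$end[i] <- pq_span[1] + pqe_tract_length - 1L
    } else {
      # spans entirely on one side of the tract lift cleanly; NR/CR straddle
      # checked: tract 58-80 sits inside NR, so only starts <= 57 stay put
      regions$start[i] <- lift_index(lift, regions$start[i],
                                     tract_rule = "start")
      regions$end[i] <- lift_index(lift, regions$end[i],
                                   tract_rule = "end")
    }
  }
  regions$frame[shift] <- "pQe"
  region_map(regions, chain_length = 538L + offset, frame = "pQe")
}

#' Classify a residue into NR/CR and overlapping motifs
#'
#' @param map a `region_map`.
#' @param residue_index 1-based residue index in the map's primary frame.
#' @return list with `region` (`"NR"` or `"CR"`) and `motifs` (character
#'   vector of motif names containing the index, possibly empty).
#' @examples
#' classify_region(default_region_map(), 224)$region  # "NR"
#' classify_region(default_region_map(), 225)$region  # "CR"
#' @export
classify_region <- function(map, residue_index) {
  stopifnot(inherits(map, "region_map"))
  residue_index <- as.integer(residue_index)
  if (length(residue_index) != 1L || is.na(residue_index) ||
      residue_index < 1L || residue_index > map$chain_length) {
    stop("residue index ", residue_index, " outside chain 1..",
         map$chain_length)
  }
  local <- map$regions[map$regions$frame == map$frame, , drop = FALSE]
  hit <- local[local$start <= residue_index & residue_index <= local$end, ]
  region <- hit$name[hit$name %in% c("NR", "CR")]
  if (length(region) != 1L) {
    stop("residue ", residue_index,
         " not classified by exactly one of NR/CR")
  }
  list(region = region, motifs = setdiff(hit$name, c("NR", "CR")))
}

#' Numbering lifts across polyglutamine expansion
#'
#' A `numbering_lift` maps residue indices between two numbering frames that
#' differ only by a tract-length change: the identity N-terminal of the
#' tract, plus a constant offset C-terminal of it. The printed example is
#' the ANTS motif: wild-type/UniProt residues 233-246 become 255-268 on the
#' expanded chain (offset +22 for a 23Q -> 45Q expansion).
#'
#' Indices strictly inside the expanded part of the tract have no
#' well-defined image and raise an error.
#'
#' @param tract_end last tract residue in the source frame.
#' @param offset target tract length minus source tract length.
#' @param source,target frame labels.
#' @param tract_start first tract residue in the source frame (defaults to
#'   `tract_end - 22` for the 23Q wild-type tract; only used for validity
#'   checks when lifting tract-interior indices).
#' @return An object of class `numbering_lift`.
#' @examples
#' lift <- numbering_lift(tract_end = 80, offset = 22)
#' lift_index(lift, 233)  # 255
#' @export
numbering_lift <- function(tract_end, offset, source = "wt",
                           target = "pQe", tract_start = tract_end - 22L) {
  structure(list(tract_start = as.integer(tract_start),
                 tract_end = as.integer(tract_end),
                 offset = as.integer(offset),
                 source = source, target = target),
            class = "numbering_lift")
}

#' Invert a numbering lift
#' @param lift a `numbering_lift`.
#' @return The inverse `numbering_lift` (target frame back to source frame).
#' @export
invert_lift <- function(lift) {
  stopifnot(inherits(lift, "numbering_lift"))
  numbering_lift(tract_end = lift$tract_end + lift$offset,
                 offset = -lift$offset,
                 source = lift$target, target = lift$source,
                 tract_start = lift$tract_start)
}

#' Lift a residue index between numbering frames
#'
#' @param lift a `numbering_lift`.
#' @param residue_index index in the source frame (vectorised).
#' @param tract_rule how to treat indices inside the tract when the tract
#'   shrinks/grows: `"error"` (default) rejects interior indices whose image
#'   is ambiguous; `"start"`/`"end"` anchor interval endpoints when lifting
#'   whole intervals.
#' @return Integer vector of target-frame indices.
#' @export
lift_index <- function(lift, residue_index, tract_rule = c("error", "start", "end")) {
  stopifnot(inherits(lift, "numbering_lift"))
  tract_rule <- match.arg(tract_rule)
  r <- as.integer(residue_index)
  if (anyNA(r) || any(r < 1L)) stop("invalid residue index")
  out <- integer(length(r))
  before <- r <= lift$tract_end
  if (lift$offset >= 0L) {
    # expansion: everything up to and including the source tract end keeps
    # its index; everything after shifts by +offset
    out[before] <- r[before]
    out[!before] <- r[!before] + lift$offset
  } else {
    interior <- r > lift$tract_end + lift$offset & r <= lift$tract_end
    if (any(interior) && tract_rule == "error") {
      stop("index ", paste(r[interior], collapse = ","),
           " lies inside the expanded tract interior: ambiguous mapping")
    }
    out[interior] <- if (tract_rule == "start") lift$tract_end + lift$offset
                     else lift$tract_end + lift$offset
    out[before & !interior] <- r[before & !interior]
    out[!before] <- r[!before] + lift$offset
  }
  out
}
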