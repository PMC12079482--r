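#' Analysis configuration
#'
#' Configurations are plain nested lists, readable from YAML. Every
#' threshold used by a stage is echoed into the report's provenance block so
#' that each number in a report is traceable to its parameters.
#'
#' @param path YAML file.
#' @return Nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  yaml::read_yaml(path)
}

#' Read a region/motif map from a YAML config
#'
#' Expects a top-level `regions:` list of entries with `name`, `start`,
#' `end`, `frame`, plus `chain_length` and `frame` keys.
#'
#' @param path YAML file.
#' @return A [region_map].
#' @export
read_region_map <- function(path) {
  cfg <- read_config(path)
  regions <- do.call(rbind, lapply(cfg$regions, function(r) {
    data.frame(name = r$name, start = r$start, end = r$end,
               frame = if (is.null(r$frame)) cfg$frame else r$frame,
               stringsAsFactors = FALSE)
  }))
  region_map(regions, chain_length = cfg$chain_length, frame = cfg$frame)
}

criteria_from_config <- function(cfg) {
  defaults <- contact_criteria()
  if (is.null(cfg)) return(defaults)
  contact_criteria(
    cutoff = if (is.null(cfg$cutoff)) defaults$cutoff else cfg$cutoff,
    min_pairs = if (is.null(cfg$min_pairs)) defaults$min_pairs else cfg$min_pairs,
    exclude = if (is.null(cfg$exclude)) defaults$exclude else cfg$exclude,
    per_side = isTRUE(cfg$per_side))
}

#' Conformational-ensemble report
#'
#' Runs the full single-chain workflow over replicate ensembles: RMSF,
#' helicity (per-replicate contents with mean and SD), inter-region
#' contact-time fraction, circuit-topology census/density/per-residue
#' inverse-parallel profile, and GROMOS clustering with coverage-based
#' representative selection. Deterministic given the config.
#'
#' @param ensembles list of replicate [ensemble]s (or one ensemble).
#' @param config nested list (or YAML path) with optional sections
#'   `contacts` (cutoff, min_pairs, exclude), `ct` (sample_interval_ns),
#'   `regions` (group_a/group_b residue bounds; default NR/CR split at 224),
#'   `cluster` (cutoff_nm, coverage), `helicity` (threshold).
#' @return list of class `conformation_report` with sections `rmsf`,
#'   `helicity`, `region_contact`, `ct`, `clusters`, `provenance`.
#' @export
run_conformation_report <- function(ensembles, config = list()) {
  if (is.character(config)) config <- read_config(config)
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  criteria <- criteria_from_config(config$contacts)
  interval <- config$ct$sample_interval_ns
  if (is.null(interval)) interval <- 25
  cutoff_nm <- config$cluster$cutoff_nm
  if (is.null(cutoff_nm)) cutoff_nm <- 0.9
  coverage <- config$cluster$coverage
  if (is.null(coverage)) coverage <- 0.5
  threshold <- config$helicity$threshold
  if (is.null(threshold)) threshold <- 0.30
  nres <- nrow(residue_table(ensembles[[1]]))
  nr_end <- config$regions$nr_end
  if (is.null(nr_end)) nr_end <- min(224L, nres - 1L)
  group_a <- seq_len(nr_end)
  group_b <- (nr_end + 1L):nres

  rmsf <- lapply(ensembles, rmsf_profile)
  hel <- helicity_profile(ensembles, threshold = threshold)
  region <- group_contact_fraction(ensembles, group_a, group_b, criteria)
  profile <- local_inverse_parallel_profile(ensembles, criteria, interval)
  density <- topology_density(ensembles, criteria, interval)
  census <- lapply(ensembles, function(ens) {
    do.call(rbind, lapply(sample_frames(ens, interval), function(f) {
      cen <- topology_census(residue_contacts(ens, f, criteria))
      data.frame(frame = f, n_S = cen$n_S, n_P = cen$n_P, n_X = cen$n_X)
    }))
  })
  pooled <- do.call(rbind, lapply(seq_along(ensembles), function(e) {
    nf <- n_frames(ensembles[[e]])
    cbind(replicate = e, frame = seq_len(nf), ensembles[[e]]$xyz)
  }))
  pooled_ens <- ensemble(ensembles[[1]]$atoms,
                         pooled[, -(1:2), drop = FALSE])
  clusters <- gromos_cluster(pooled_ens, cutoff_nm = cutoff_nm)
  reps <- select_representatives(clusters, coverage)

  structure(list(
    rmsf = rmsf,
    helicity = hel,
    region_contact = region,
    ct = list(census = census, profile = profile, density = density),
    clusters = list(solution = clusters, representatives = reps,
                    representative_frames = data.frame(
                      replicate = pooled[reps, 1], frame = pooled[reps, 2])),
    provenance = list(
      contacts = unclass(criteria), ct_sample_interval_ns = interval,
      cluster_cutoff_nm = cutoff_nm, cluster_coverage = coverage,
      helix_threshold = threshold, nr_end = nr_end,
      n_replicates = length(ensembles),
      n_frames = vapply(ensembles, n_frames, integer(1)))
  ), class = "conformation_report")
}

#' Docking-pose ensemble report
#'
#' Runs the two-chain workflow over a pose set: region binding fractions,
#' per-motif blockade/exposure, interaction-type tallies and the per-pose
#' table.
#'
#' @param pose_set a `pose_set` from [read_pose_set()].
#' @param map a [region_map] for the disordered chain.
#' @param motifs named list of `c(start, end)` intervals (on the disordered
#'   chain unless the name is `P-box`-like and `partner_chain` is given).
#' @param config nested list (or YAML path) with optional sections
#'   `contacts`, `poses` (dominance, blocked_fraction, any_contact,
#'   exposure_threshold).
#' @param ntd_chain chain id of the disordered chain.
#' @param partner_chain chain carrying partner-frame motifs.
#' @return list of class `pose_report` with sections `region_fractions`,
#'   `motifs`, `interaction_counts`, `per_pose_interactions`, `provenance`.
#' @export
run_pose_report <- function(pose_set, map, motifs = list(),
                            config = list(), ntd_chain = "A",
                            partner_chain = "B") {
  if (is.character(config)) config <- read_config(config)
  criteria <- criteria_from_config(config$contacts)
  dominance <- config$poses$dominance
  if (is.null(dominance)) dominance <- 0.8
  blocked_fraction <- config$poses$blocked_fraction
  if (is.null(blocked_fraction)) blocked_fraction <- 0.5
  any_contact <- isTRUE(config$poses$any_contact)
  exposure <- config$poses$exposure_threshold
  if (is.null(exposure)) exposure <- 0.25

  region <- region_binding_fractions(pose_set, map, ntd_chain = ntd_chain,
                                     dominance = dominance,
                                     criteria = criteria)
  motif_out <- lapply(names(motifs), function(nm) {
    chain <- if (grepl("P-box", nm, fixed = TRUE)) partner_chain else ntd_chain
    motif_status(pose_set, motifs[[nm]], chain = chain,
                 blocked_fraction = blocked_fraction,
                 any_contact = any_contact,
                 exposure_threshold = exposure, criteria = criteria)
  })
  names(motif_out) <- names(motifs)
  inter <- lapply(pose_set$poses, type_interactions)
  counts <- table(factor(unlist(lapply(inter, function(x) x$type)),
                         levels = c("hydrogen_bond", "salt_bridge",
                                    "pi_cation", "pi_stacking")))
  structure(list(
    region_fractions = region,
    motifs = motif_out,
    interaction_counts = as.list(counts),
    per_pose_interactions = inter,
    provenance = list(contacts = unclass(criteria), dominance = dominance,
                      blocked_fraction = blocked_fraction,
                      any_contact = any_contact,
                      exposure_threshold = exposure,
                      n_poses = length(pose_set$poses),
                      n_skipped = pose_set$n_skipped)
  ), class = "pose_report")
}

#' Serialise a report to JSON
#'
#' Writes a stable, human-diffable JSON rendering of a report (numbers at
#' full precision, keys in fixed order), so reruns with identical inputs
#' are byte-identical.
#'
#' @param report a `conformation_report` or `pose_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.table(x)) return(as.list(x))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
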