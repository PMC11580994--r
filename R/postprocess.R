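#' Construct an assigned profile
#'
#' The container for one profiler's output at (or below) one rank: a named
#' abundance vector, keyed either by raw method-reported names or by numeric
#' taxonomy ids, plus any mass the method itself declared unknown.
#'
#' @param entries named nonnegative numeric vector.
#' @param rank canonical rank of the entries (entries may sit above it after
#'   rank truncation by a profiler).
#' @param unknown_mass abundance the method declared unknown (>= 0).
#' @return an object of class `assigned_profile`.
#' @export
assigned_profile <- function(entries, rank = "species", unknown_mass = 0) {
  if (any(entries < 0) || unknown_mass < 0)
    stop_mdm("negative abundance", class = "mdmbench_validation_error")
  structure(list(entries = entries, rank = match.arg(rank, CANONICAL_RANKS),
                 unknown_mass = unknown_mass),
            class = "assigned_profile")
}

#' @export
print.assigned_profile <- function(x, ...) {
  cat("assigned_profile [", x$rank, "]: ", length(x$entries),
      " taxa, declared unknown mass ", signif(x$unknown_mass, 4), "\n", sep = "")
  invisible(x)
}

rank_profile <- function(entries, rank, provenance = "assigned") {
  structure(list(entries = entries, rank = rank, provenance = provenance),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat("rank_profile [", x$rank, ", ", x$provenance, "]: ",
      length(x$entries), " taxa, total ", signif(sum(x$entries), 6),
      "\n", sep = "")
  invisible(x)
}

#' Remove low-abundance taxa and renormalize
#'
#' Drops entries with relative abundance below `theta` (default 0.05%, the
#' false-positive filter applied to all assigned profiles) and renormalizes
#' the survivors to sum to 1. The comparison is against the profile total at
#' call time, so `theta` is always a fraction of current mass. Declared
#' unknown mass is rescaled by the same factor as the surviving entries.
#'
#' @param profile an `assigned_profile` (entries need not sum to 1).
#' @param theta abundance threshold (default 0.0005).
#' @return a thresholded, renormalized `assigned_profile`.
#' @export
apply_threshold <- function(profile, theta = 0.0005) {
  stopifnot(inherits(profile, "assigned_profile"))
  total <- sum(profile$entries) + profile$unknown_mass
  if (total <= 0)
    stop_mdm("empty profile", class = "mdmbench_degenerate_profile")
  rel <- profile$entries / total
  keep <- rel >= theta
  if (!any(keep) && profile$unknown_mass == 0)
    stop_mdm("all entries below threshold", class = "mdmbench_degenerate_profile")
  kept <- profile$entries[keep]
  new_total <- sum(kept) + profile$unknown_mass
  assigned_profile(kept / new_total, rank = profile$rank,
                   unknown_mass = profile$unknown_mass / new_total)
}

#' Remove unknown and unmappable mass, renormalize
#'
#' Drops the declared unknown mass, entries whose labels match
#' [is_unknown_label()], and entries flagged unmappable (non-numeric keys
#' once a name map has been applied, or keys listed in `unmappable`), then
#' renormalizes the survivors to 1. This is the step that makes profiles
#' comparable across methods: only mass on resolvable taxonomy ids remains.
#'
#' @param profile an `assigned_profile`.
#' @param unmappable optional character vector of keys to treat as
#'   unmappable in addition to non-numeric keys.
#' @return a `rank_profile` keyed by taxon id.
#' @export
strip_unknown_and_unmappable <- function(profile, unmappable = character(0)) {
  stopifnot(inherits(profile, "assigned_profile"))
  keys <- names(profile$entries)
  drop <- is_unknown_label(keys) | keys %in% unmappable |
    is.na(suppressWarnings(as.numeric(keys)))
  kept <- profile$entries[!drop]
  if (!length(kept) || sum(kept) <= 0)
    stop_mdm("no mappable mass survives", class = "mdmbench_degenerate_profile")
  rank_profile(kept / sum(kept), profile$rank, "assigned")
}

#' Aggregate a profile to a higher rank
#'
#' Sums abundances into ancestor taxa via [lineage_query()]. Mass whose key
#' has no ancestor at the target rank (including entries a profiler
#' truncated to a rank above the target) becomes unknown mass; callers
#' strip and renormalize as needed.
#'
#' @param profile a `rank_profile` keyed by taxon id.
#' @param target_rank rank at or above the profile's entries.
#' @param taxonomy a `taxonomy_table`.
#' @return list with `profile` (a `rank_profile` at `target_rank`, summing
#'   to the input's aggregable mass) and `unknown_mass`.
#' @export
aggregate_to_rank <- function(profile, target_rank, taxonomy) {
  target_rank <- match.arg(target_rank, CANONICAL_RANKS)
  ids <- as.integer(names(profile$entries))
  anc <- vapply(ids, lineage_query, integer(1), rank = target_rank,
                taxonomy = taxonomy)
  known <- !is.na(anc)
  unknown_mass <- sum(profile$entries[!known])
  entries <- if (any(known)) {
    v <- tapply(profile$entries[known], anc[known], sum)
    setNames(as.numeric(v), names(v))
  } else setNames(numeric(0), character(0))
  list(profile = rank_profile(entries, target_rank, profile$provenance),
       unknown_mass = unknown_mass)
}

#' Restrict the true profile to NCBI-available taxa at a rank
#'
#' A genome contributes at rank `r` iff it is NCBI-available at `r`, i.e.
#' `r` is at or above the genome's `available_rank` and its lineage carries
#' a taxon id there. Contributions are aggregated to taxon ids and
#' renormalized to 1. This implements the evaluation principle that a
#' genome unknown below (say) family can legitimately be called unknown at
#' species and genus, but must be assigned its correct taxon at family and
#' above.
#'
#' @param true_profile a `true_profile` keyed by genome_id.
#' @param rank evaluation rank.
#' @param catalog a `genome_catalog` describing the profile's genomes.
#' @return a `rank_profile` with provenance `"truth"`.
#' @export
restrict_truth_to_available <- function(true_profile, rank, catalog) {
  rank <- match.arg(rank, CANONICAL_RANKS)
  rec <- catalog$records
  ids <- names(true_profile$abundances)
  m <- match(ids, rec$genome_id)
  if (anyNA(m))
    stop_mdm("profile genomes missing from catalog: ",
             paste(ids[is.na(m)], collapse = ", "),
             class = "mdmbench_validation_error")
  avail_depth <- rank_depth(rec$available_rank[m])
  taxid <- rec[[paste0("taxid_", rank)]][m]
  ok <- rank_depth(rank) <= avail_depth & !is.na(taxid)
  if (!any(ok))
    stop_mdm("no genome NCBI-available at rank ", rank,
             class = "mdmbench_degenerate_profile")
  v <- tapply(true_profile$abundances[ok], taxid[ok], sum)
  entries <- setNames(as.numeric(v), names(v))
  rank_profile(entries / sum(entries), rank, "truth")
}

#' Unknown fraction of an assembly-based profile
#'
#' For assembly pipelines the unknown abundance is the sum of the
#' proportion of reads aligning to no MAG, the abundance of low-quality
#' MAGs, and the abundance of MAGs unplaced at the rank of interest.
#'
#' @param unaligned_read_prop,low_quality_mag_mass,unplaced_mag_mass
#'   fractions in `[0, 1]` summing to at most 1.
#' @return the three-term sum.
#' @export
assembly_unknown_fraction <- function(unaligned_read_prop,
                                      low_quality_mag_mass,
                                      unplaced_mag_mass) {
  v <- c(unaligned_read_prop, low_quality_mag_mass, unplaced_mag_mass)
  if (any(v < 0 | v > 1))
    stop_mdm("inputs must lie in [0, 1]", class = "mdmbench_validation_error")
  s <- sum(v)
  if (s > 1 + 1e-12)
    stop_mdm("unknown components sum to more than 1",
             class = "mdmbench_validation_error")
  s
}

#' Post-process an assigned profile for evaluation at one rank
#'
#' The full pipeline applied to every assigned profile before comparison:
#' threshold (0.05% by default) on the normalized profile, removal of
#' unknown-labeled and unmappable mass, aggregation to the evaluation rank,
#' then a final strip/renormalization of mass lacking an ancestor at that
#' rank. Applying the pipeline twice equals applying it once.
#'
#' @param profile an `assigned_profile` keyed by taxon id (harmonize first
#'   if keyed by name).
#' @param rank evaluation rank.
#' @param taxonomy a `taxonomy_table`.
#' @param theta abundance threshold.
#' @return a `rank_profile` at `rank`, summing to 1.
#' @export
postprocess_assigned <- function(profile, rank, taxonomy, theta = 0.0005) {
  p <- apply_threshold(profile, theta)
  p <- strip_unknown_and_unmappable(p)
  agg <- aggregate_to_rank(p, rank, taxonomy)
  if (!length(agg$profile$entries))
    stop_mdm("no mass aggregable to rank ", rank,
             class = "mdmbench_degenerate_profile")
  ent <- agg$profile$entries / sum(agg$profile$entries)
  rank_profile(ent, rank, "assigned")
}
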