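#' MinHash sketch of a genome
#'
#' Bottom-`sketch_size` sketch of the canonical k-mer hashes of a sequence
#' (canonical = lexicographic minimum of the k-mer and its reverse
#' complement, so a sequence and its reverse complement sketch identically).
#' The hash is a fixed 64-bit FNV-1a truncated to 53 bits, so sketching is
#' fully deterministic. Defaults `k = 21`, `s = 1000` follow the published
#' Mash convention.
#'
#' @param sequence nucleotide string, length >= `kmer_size`.
#' @param kmer_size k-mer length (default 21).
#' @param sketch_size maximum sketch size (default 1000).
#' @return an object of class `minhash_sketch`.
#' @export
sketch_genome <- function(sequence, kmer_size = 21, sketch_size = 1000) {
  if (nchar(sequence) < kmer_size)
    stop_mdm("sequence shorter than kmer_size", class = "mdmbench_validation_error")
  structure(list(hashes = sketch_hashes_cpp(sequence, as.integer(kmer_size),
                                            as.integer(sketch_size)),
                 kmer_size = as.integer(kmer_size),
                 sketch_size = as.integer(sketch_size)),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat("minhash_sketch: k =", x$kmer_size, ", ", length(x$hashes), "/",
      x$sketch_size, "hashes\n")
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Jaccard similarity `j` is estimated from the merged bottom sketch (the
#' smallest `min(s, |union|)` hashes of the union; shared hashes within that
#' set are counted), then converted with the Mash estimator
#' `d = -(1/k) * ln(2j / (1 + j))`, with `d = 1` when `j = 0` and `d = 0`
#' when `j = 1`. About 0.05 corresponds to the intra-species average
#' nucleotide identity boundary.
#'
#' @param a,b `minhash_sketch` objects with equal `kmer_size`.
#' @return distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$kmer_size != b$kmer_size)
    stop_mdm("sketches have different kmer_size", class = "mdmbench_validation_error")
  s <- min(max(a$sketch_size, b$sketch_size),
           length(union(a$hashes, b$hashes)))
  merged <- sort(union(a$hashes, b$hashes))[seq_len(s)]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- shared / s
  if (j <= 0) return(1)
  if (j >= 1) return(0)
  min(1, -log(2 * j / (1 + j)) / a$kmer_size)
}

#' MAG quality gate
#'
#' A metagenome-assembled genome counts as medium/high quality when it is at
#' least 50% complete and less than 10% contaminated.
#'
#' @param completeness,contamination numeric vectors in percent.
#' @return logical vector.
#' @export
is_quality_mag <- function(completeness, contamination) {
  completeness >= 50 & contamination < 10
}

#' Is a MAG's NCBI-mappable taxonomy contained in a genome's?
#'
#' TRUE iff at every rank where the MAG lineage carries a taxon id the
#' genome lineage carries the same id. A MAG placed only to (say) family
#' still qualifies when the genome is known to genus — stopping higher than
#' the genome's lowest known rank is allowed, contradicting it is not. An
#' empty MAG lineage is vacuously contained.
#'
#' @param mag_lineage,genome_lineage named integer vectors over the
#'   canonical ranks (`NA` = unassigned at that rank).
#' @return logical scalar.
#' @export
taxonomy_contained <- function(mag_lineage, genome_lineage) {
  r <- intersect(names(mag_lineage)[!is.na(mag_lineage)], CANONICAL_RANKS)
  if (!length(r)) return(TRUE)
  all(!is.na(genome_lineage[r]) & genome_lineage[r] == mag_lineage[r])
}

lineage_from_row <- function(row) {
  setNames(as.integer(row[paste0("taxid_", CANONICAL_RANKS)]), CANONICAL_RANKS)
}

#' Assess which uncharacterized genomes an assembly run recovered
#'
#' An uncharacterized genome (catalog status `new_ncbi` or `new_sgb`)
#' counts as successfully reconstructed iff some MAG (1) passes the
#' [is_quality_mag()] gate, (2) has strictly smaller distance to that genome
#' than to every other input genome — known or unknown; ties are
#' conservatively not recovered — and (3) has its NCBI-mappable assigned
#' taxonomy contained within the genome's taxonomy
#' ([taxonomy_contained()]). The recovered abundance is the sum of the
#' recovered genomes' abundances in the *true* profile, in percent.
#'
#' @param mags data.frame with columns `mag_id`, `completeness`,
#'   `contamination` and per-rank lineage columns `taxid_superkingdom` ...
#'   `taxid_species`.
#' @param catalog a `genome_catalog` of all input genomes.
#' @param true_profile a `true_profile` over the catalog's genomes.
#' @param distances matrix of MAG-to-genome distances (rownames = mag_id,
#'   colnames = genome_id covering all catalog genomes); or `NULL` to
#'   compute from sketches.
#' @param mag_sketches,genome_sketches named lists of `minhash_sketch`
#'   objects, used when `distances` is `NULL`.
#' @return an object of class `recovery_result`: list with `per_genome`
#'   (data.frame: `genome_id`, `recovered`, `failed`, `nearest_mag`,
#'   `distance`) and `recovered_abundance_percent`.
#' @export
assess_recovery <- function(mags, catalog, true_profile, distances = NULL,
                            mag_sketches = NULL, genome_sketches = NULL) {
  rec <- catalog$records
  if (!nrow(rec))
    stop_mdm("empty input genome set", class = "mdmbench_validation_error")
  if (is.null(distances)) {
    if (nrow(mags) && (is.null(mag_sketches) || is.null(genome_sketches)))
      stop_mdm("need either distances or sketches", class = "mdmbench_validation_error")
    ks <- unique(c(vapply(mag_sketches, `[[`, 1L, "kmer_size"),
                   vapply(genome_sketches, `[[`, 1L, "kmer_size")))
    if (length(ks) > 1)
      stop_mdm("all sketches must share kmer_size", class = "mdmbench_validation_error")
    distances <- matrix(NA_real_, nrow(mags), nrow(rec),
                        dimnames = list(mags$mag_id, rec$genome_id))
    for (m in mags$mag_id) for (g in rec$genome_id)
      distances[m, g] <- mash_distance(mag_sketches[[m]], genome_sketches[[g]])
  }
  unchar <- rec[rec$status != "ncbi_available", , drop = FALSE]
  quality <- if (nrow(mags)) is_quality_mag(mags$completeness, mags$contamination)
             else logical(0)

  res <- data.frame(genome_id = unchar$genome_id,
                    recovered = FALSE, failed = NA_character_,
                    nearest_mag = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(unchar))) {
    g <- unchar$genome_id[i]
    glin <- lineage_from_row(unchar[i, ])
    # MAGs whose strictly nearest input genome is g
    matches <- which(vapply(seq_len(nrow(mags)), function(m) {
      d <- distances[mags$mag_id[m], ]
      all(d[g] < d[setdiff(names(d), g)])
    }, logical(1)))
    if (!length(matches)) { res$failed[i] <- "no_matching_mag"; next }
    best <- matches[order(distances[mags$mag_id[matches], g])]
    res$nearest_mag[i] <- mags$mag_id[best[1]]
    res$distance[i] <- distances[mags$mag_id[best[1]], g]
    qual <- best[quality[best]]
    if (!length(qual)) { res$failed[i] <- "quality"; next }
    ok <- qual[vapply(qual, function(m)
      taxonomy_contained(lineage_from_row(mags[m, ]), glin), logical(1))]
    if (!length(ok)) { res$failed[i] <- "taxonomy"; next }
    res$recovered[i] <- TRUE
    res$nearest_mag[i] <- mags$mag_id[ok[1]]
    res$distance[i] <- distances[mags$mag_id[ok[1]], g]
  }
  recovered_mass <- sum(true_profile$abundances[
    res$genome_id[res$recovered]], na.rm = TRUE)
  structure(list(per_genome = res,
                 recovered_abundance_percent = 100 * recovered_mass),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("recovery_result:", sum(x$per_genome$recovered), "of",
      nrow(x$per_genome), "uncharacterized genomes recovered;",
      signif(x$recovered_abundance_percent, 4), "% abundance\n")
  invisible(x)
}

#' Optimal coverage threshold separating recovered from non-recovered
#'
#' Finds the threshold `t` minimizing misclassifications of the rule
#' "coverage >= t implies recovered"; among minimizers, returns the midpoint
#' of the widest separating gap between adjacent observed coverages.
#'
#' @param coverages numeric fold-coverage vector.
#' @param recovered logical vector of the same length, both classes present.
#' @return the threshold.
#' @export
optimal_coverage_threshold <- function(coverages, recovered) {
  stopifnot(length(coverages) == length(recovered))
  if (all(recovered) || !any(recovered))
    stop_mdm("need both recovered and non-recovered genomes",
             class = "mdmbench_validation_error")
  u <- sort(unique(coverages))
  # candidate regions: below all values, between adjacent values, above all
  cand_t <- c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
              u[length(u)] + 1)
  width <- c(0, if (length(u) > 1) diff(u), 0)
  err <- vapply(cand_t, function(t)
    sum((coverages >= t) != recovered), integer(1))
  best <- which(err == min(err))
  best <- best[order(-width[best], cand_t[best])]
  cand_t[best[1]]
}
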