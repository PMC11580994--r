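#' Construct a genome catalog
#'
#' A catalog holds the genomes a synthetic community can draw on, in three
#' characterization classes: `ncbi_available` (species present in the
#' reference taxonomy before the profiler-database cutoff), `new_ncbi`
#' (species added after the cutoff — characterized now, invisible to the
#' profilers), and `new_sgb` (species-level genome bins with no species-level
#' placement at all). The `available_rank` column records the lowest
#' canonical rank at which each genome counts as NCBI-available.
#'
#' @param records data.frame with columns `genome_id`, `length_bp`, `status`,
#'   `completeness`, `contamination`, `rank_order` (integer or `NA`),
#'   `available_rank`, and per-rank lineage columns `taxid_superkingdom` ...
#'   `taxid_species` (integer taxon ids, `NA` = unknown at that rank).
#' @param environment free-form environment label (e.g. `"soil"`).
#' @param sequences optional named character vector of genome sequences
#'   (names = genome_id).
#' @return an object of class `genome_catalog`.
#' @export
genome_catalog <- function(records, environment = "generic", sequences = NULL) {
  req <- c("genome_id", "length_bp", "status", "completeness",
           "contamination", "rank_order", "available_rank",
           paste0("taxid_", CANONICAL_RANKS))
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop_mdm("catalog missing column(s): ", paste(missing_cols, collapse = ", "),
             class = "mdmbench_validation_error")
  if (anyDuplicated(records$genome_id))
    stop_mdm("duplicate genome_id in catalog", class = "mdmbench_validation_error")
  bad <- !(records$status %in% c("ncbi_available", "new_ncbi", "new_sgb"))
  if (any(bad))
    stop_mdm("unknown status: ", paste(unique(records$status[bad]), collapse = ", "),
             class = "mdmbench_validation_error")
  if (any(records$length_bp <= 0))
    stop_mdm("length_bp must be positive", class = "mdmbench_validation_error")
  sp_missing <- records$status == "ncbi_available" & is.na(records$taxid_species)
  if (any(sp_missing))
    stop_mdm("ncbi_available genomes must have species-level lineage: ",
             paste(records$genome_id[sp_missing], collapse = ", "),
             class = "mdmbench_validation_error")
  rownames(records) <- NULL
  if (!is.null(sequences)) {
    stopifnot(all(records$genome_id %in% names(sequences)))
    sequences <- sequences[records$genome_id]
  }
  structure(list(records = records, environment = environment,
                 sequences = sequences),
            class = "genome_catalog")
}

#' @export
print.genome_catalog <- function(x, ...) {
  st <- table(x$records$status)
  cat("genome_catalog (", x$environment, "): ", nrow(x$records), " genomes [",
      paste(names(st), st, sep = "=", collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Genome quality score
#'
#' The curation score used to rank genome bins: completeness minus five times
#' contamination, both in percent.
#'
#' @param completeness,contamination numeric vectors in `[0, 100]`.
#' @return numeric vector of scores.
#' @examples
#' quality_score(90, 5)  # 65
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE) ||
      any(contamination < 0 | contamination > 100, na.rm = TRUE))
    stop_mdm("completeness/contamination must lie in [0, 100]",
             class = "mdmbench_validation_error")
  completeness - 5 * contamination
}

#' Cap the number of new SGBs per genus
#'
#' Within each genus, keeps at most `max_per_genus` `new_sgb` genomes, the
#' best by [quality_score()]; records with unknown genus form their own
#' group. Ties are broken by ascending genome_id.
#'
#' @param catalog a `genome_catalog`.
#' @param max_per_genus maximum SGBs retained per genus (default 10).
#' @return character vector of selected genome_ids.
#' @export
select_sgbs_per_genus <- function(catalog, max_per_genus = 10) {
  rec <- catalog$records
  sgb <- rec[rec$status == "new_sgb", , drop = FALSE]
  if (!nrow(sgb)) return(character(0))
  q <- quality_score(sgb$completeness, sgb$contamination)
  genus <- ifelse(is.na(sgb$taxid_genus), "genus_unknown",
                  as.character(sgb$taxid_genus))
  keep <- unlist(lapply(split(seq_len(nrow(sgb)), genus), function(ix) {
    ix[order(-q[ix], sgb$genome_id[ix])][seq_len(min(max_per_genus, length(ix)))]
  }), use.names = FALSE)
  sort(sgb$genome_id[keep])
}

#' Swap reference genomes for high-quality conspecific SGBs
#'
#' If a `new_sgb` genome (1) carries an NCBI-recognized species assignment,
#' (2) that species is already present among the `ncbi_available` records,
#' and (3) the SGB is more than 90% complete with less than 5% contamination,
#' the reference genome's sequence and length are replaced by the SGB's —
#' the SGB is assumed to better exemplify an environmental strain — while
#' the record keeps its `ncbi_available` status and species identity. The
#' swapped-in SGB leaves the uncharacterized pool. When several SGBs qualify
#' for one species the best [quality_score()] wins (ties by genome_id).
#'
#' @param catalog a `genome_catalog`.
#' @return a `genome_catalog` with swaps applied; swapped reference records
#'   gain a `swapped_from` attribute column.
#' @export
swap_reference_with_sgb <- function(catalog) {
  rec <- catalog$records
  seqs <- catalog$sequences
  if (!"swapped_from" %in% names(rec)) rec$swapped_from <- NA_character_
  sgb <- which(rec$status == "new_sgb" & !is.na(rec$taxid_species) &
                 rec$completeness > 90 & rec$contamination < 5)
  ref_species <- rec$taxid_species[rec$status == "ncbi_available"]
  sgb <- sgb[rec$taxid_species[sgb] %in% ref_species]
  if (length(sgb)) {
    q <- quality_score(rec$completeness[sgb], rec$contamination[sgb])
    sgb <- sgb[order(-q, rec$genome_id[sgb])]
    sgb <- sgb[!duplicated(rec$taxid_species[sgb])]  # best per species
    drop <- integer(0)
    for (i in sgb) {
      j <- which(rec$status == "ncbi_available" &
                   rec$taxid_species == rec$taxid_species[i])[1]
      rec$length_bp[j] <- rec$length_bp[i]
      rec$swapped_from[j] <- rec$genome_id[i]
      if (!is.null(seqs)) seqs[rec$genome_id[j]] <- seqs[rec$genome_id[i]]
      drop <- c(drop, i)
    }
    rec <- rec[-drop, , drop = FALSE]
    rownames(rec) <- NULL
    if (!is.null(seqs)) seqs <- seqs[rec$genome_id]
  }
  structure(list(records = rec, environment = catalog$environment,
                 sequences = seqs),
            class = "genome_catalog")
}

#' Rank known species by mean abundance
#'
#' Orders species by descending mean abundance across profiling methods
#' (ties by ascending species id) and assigns `rank_order` 1..n, 1 = most
#' abundant. This ordering drives which well-characterized species dominate
#' a simulated community.
#'
#' @param mean_abundances named nonnegative numeric vector: species id ->
#'   mean abundance across methods.
#' @return data.frame with columns `species`, `mean_abundance`, `rank_order`.
#' @export
rank_known_species <- function(mean_abundances) {
  if (any(mean_abundances < 0))
    stop_mdm("abundances must be nonnegative", class = "mdmbench_validation_error")
  o <- order(-mean_abundances, names(mean_abundances))
  data.frame(species = names(mean_abundances)[o],
             mean_abundance = as.numeric(mean_abundances[o]),
             rank_order = seq_along(o),
             stringsAsFactors = FALSE)
}

#' Read/write a genome catalog as TSV
#'
#' @param catalog a `genome_catalog`.
#' @param path file path.
#' @param environment environment label applied on read.
#' @return `read_catalog` returns a `genome_catalog` (without sequences).
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path, environment = "generic") {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  for (col in c("rank_order", paste0("taxid_", CANONICAL_RANKS)))
    df[[col]] <- as.integer(df[[col]])
  genome_catalog(df, environment = environment)
}

#' Write genome sequences as FASTA
#'
#' One record per genome, header = genome_id, sequence wrapped at 80 columns.
#'
#' @param sequences named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1, nchar(s), by = 80)
    writeLines(substring(s, starts, pmin(starts + 79, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_mdm("no FASTA headers in ", path,
                          class = "mdmbench_parse_error")
  id <- sub("^>", "", lines[hdr])
  id <- sub("[[:space:]].*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  setNames(as.character(seqs), id)
}
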