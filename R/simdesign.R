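#' Sequencing-depth identities
#'
#' `reads_for_depth` converts a sequencing depth in giga-base pairs into the
#' read count it represents at a given read length (7.5 Gbp at 150 bp is 50
#' million reads). `min_abundance_for_coverage` gives the minimum relative
#' abundance a genome needs to reach a target fold coverage in a library of
#' `n_reads` reads — e.g. about 3% for 10x coverage of a 4 Mbp genome in a
#' 10-million-read, 150-base library, the practical floor for assembling a
#' genome from a single sample.
#'
#' @param depth_gbp sequencing depth in giga-base pairs.
#' @param read_length read length in bases (default 150).
#' @return `reads_for_depth`: number of reads.
#' @export
reads_for_depth <- function(depth_gbp, read_length = 150) {
  depth_gbp * 1e9 / read_length
}

#' @rdname reads_for_depth
#' @param coverage target fold coverage.
#' @param genome_bp genome length in base pairs.
#' @param n_reads library size in reads.
#' @return `min_abundance_for_coverage`: minimum relative abundance (fraction).
#' @export
min_abundance_for_coverage <- function(coverage, genome_bp, n_reads,
                                       read_length = 150) {
  coverage * genome_bp / (n_reads * read_length)
}

#' Define one synthetic sample's parameters
#'
#' Captures everything needed to reproduce one simulated community: species
#' count, sequencing depth in giga-base pairs, the proportion of the sample
#' (by species number and by abundance) from uncharacterized genomes, the
#' per-base substitution rate applied to all input genomes, the genome-size
#' skew constant `k` (sizes follow a geometric sequence with ratio
#' `(k-1)/k`; smaller `k` = wider spread), and the log-normal abundance
#' parameters `mu`/`sigma` on the natural-log scale.
#'
#' Defaults are the core study conditions: 300 species, 7.5 Gbp (50 million
#' 150-bp paired reads), mutation rate 0, `k = 100`, `mu = -3`, `sigma = 1`,
#' with the unknown proportion 0.75 for soil and ocean communities and 0.5
#' for animal-gut communities.
#'
#' @param environment community label; `"soil"`, `"ocean"`, `"animal_gut"`
#'   or free-form.
#' @param n_species number of species in the sample.
#' @param depth_gbp sequencing depth in giga-base pairs.
#' @param unknown_prop proportion of uncharacterized species in `[0, 1]`;
#'   default depends on `environment`.
#' @param mutation_rate per-base substitution probability in `[0, 1]`.
#' @param size_skew_k genome-size skew constant, integer > 1.
#' @param sigma,mu log-normal abundance parameters (natural log scale).
#' @param read_length read length in bp.
#' @param paired paired-end reads?
#' @param seed integer root seed for all of the sample's randomness.
#' @return an object of class `sample_design`.
#' @export
sample_design <- function(environment = "soil",
                          n_species = 300L,
                          depth_gbp = 7.5,
                          unknown_prop = NULL,
                          mutation_rate = 0,
                          size_skew_k = 100L,
                          sigma = 1,
                          mu = -3,
                          read_length = 150L,
                          paired = TRUE,
                          seed = 1L) {
  if (is.null(unknown_prop))
    unknown_prop <- if (environment == "animal_gut") 0.5 else 0.75
  stopifnot(n_species >= 1, depth_gbp > 0,
            unknown_prop >= 0, unknown_prop <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            size_skew_k > 1, sigma > 0, read_length > 0)
  structure(list(environment = environment,
                 n_species = as.integer(n_species),
                 depth_gbp = depth_gbp,
                 unknown_prop = unknown_prop,
                 mutation_rate = mutation_rate,
                 size_skew_k = as.integer(size_skew_k),
                 sigma = sigma, mu = mu,
                 read_length = as.integer(read_length),
                 paired = paired,
                 seed = as.integer(seed)),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design [", x$environment, "]: ",
      x$n_species, " species, ", x$depth_gbp, " Gbp, unknown ",
      x$unknown_prop, ", mutation ", x$mutation_rate,
      ", k=", x$size_skew_k, ", lognormal(", x$mu, ", ", x$sigma,
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' The study's parameter grid
#'
#' The values over which each sample parameter is varied, one at a time,
#' around the core design: species count 75/150/300/600; depth 0.05/0.5/
#' 1.5/7.5/30 Gbp; unknown proportion 0/0.25/0.5/0.75/1; mutation rate
#' 0/0.01/0.02/0.05; size skew k 40/100/250; abundance sigma 0.5/1/2/4.
#'
#' @return named list of parameter value vectors.
#' @export
default_parameter_grid <- function() {
  list(n_species     = c(75L, 150L, 300L, 600L),
       depth_gbp     = c(0.05, 0.5, 1.5, 7.5, 30),
       unknown_prop  = c(0, 0.25, 0.5, 0.75, 1),
       mutation_rate = c(0, 0.01, 0.02, 0.05),
       size_skew_k   = c(40L, 100L, 250L),
       sigma         = c(0.5, 1, 2, 4))
}

#' Expand a one-parameter-at-a-time design grid
#'
#' Produces `length(values) * replicates` designs, each identical to `core`
#' except for the varied parameter. Every design gets a seed derived
#' deterministically from `(core$seed, parameter, value, replicate)`, so two
#' expansions of the same core agree byte for byte.
#'
#' @param core a `sample_design`.
#' @param parameter name of the varied `sample_design` field.
#' @param values vector of values for that parameter.
#' @param replicates designs per value (default 5).
#' @return list of `sample_design` objects.
#' @export
expand_grid <- function(core, parameter, values, replicates = 5L) {
  stopifnot(inherits(core, "sample_design"))
  if (!parameter %in% setdiff(names(core), c("seed", "environment")))
    stop_mdm("unknown design parameter: ", parameter,
             class = "mdmbench_config_error")
  out <- vector("list", length(values) * replicates)
  i <- 0L
  for (v in values) for (r in seq_len(replicates)) {
    d <- core
    d[[parameter]] <- if (is.integer(core[[parameter]])) as.integer(v) else v
    d$seed <- derive_seed(core$seed, parameter, v, r)
    i <- i + 1L
    out[[i]] <- d
  }
  out
}

#' Assign abundances to the known (characterized) block
#'
#' Takes the species ranked by real-data abundance, truncates to the first
#' `n_known`, randomly splits the list into two equal groups (first group
#' gets the extra member when `n_known` is odd; both preserve internal rank
#' order), interleaves them, and assigns a descending-sorted vector of
#' log-normal draws positionally. Top-ranked species therefore tend to
#' dominate the simulated profile while their exact order and abundances
#' vary between samples.
#'
#' @param ranked_species character vector of species/genome ids, most
#'   abundant first.
#' @param n_known number of species to keep.
#' @param mu,sigma log-normal parameters (natural log scale).
#' @param seed integer seed.
#' @return named numeric vector of unnormalized weights (names follow
#'   `ranked_species` order after truncation).
#' @export
build_known_block <- function(ranked_species, n_known, mu, sigma, seed) {
  if (n_known > length(ranked_species))
    stop_mdm("n_known exceeds ranked species list",
             class = "mdmbench_validation_error")
  if (n_known == 0) return(setNames(numeric(0), character(0)))
  ids <- ranked_species[seq_len(n_known)]
  with_seed(seed, {
    n1 <- ceiling(n_known / 2)
    g1 <- sort(sample(n_known, n1))          # indices, rank order preserved
    g2 <- setdiff(seq_len(n_known), g1)
    inter <- integer(n_known)
    inter[seq(1, 2 * n1 - 1, by = 2)] <- g1
    if (length(g2)) inter[seq(2, 2 * length(g2), by = 2)] <- g2
    draws <- sort(exp(rnorm(n_known, mu, sigma)), decreasing = TRUE)
    w <- numeric(n_known)
    w[inter] <- draws                         # position j of interleaving gets draw j
    setNames(w, ids)
  })
}

#' Geometric target genome-size sequence
#'
#' Size targets `s_j = median_size * r^(j - (n-1)/2)` with `r = (k-1)/k`,
#' `j = 0..n-1`: strictly decreasing and log-symmetric around the median
#' genome size, so its geometric center equals `median_size`. Smaller `k`
#' gives a wider size spread.
#'
#' @param n number of targets (>= 1).
#' @param k skew constant (>= 2).
#' @param median_size median genome size in bp.
#' @return numeric vector of n sizes, decreasing.
#' @export
target_size_sequence <- function(n, k, median_size) {
  stopifnot(n >= 1, k >= 2, median_size > 0)
  r <- (k - 1) / k
  j <- seq_len(n) - 1
  median_size * r^(j - (n - 1) / 2)
}

#' Greedily match genomes to the size sequence
#'
#' The already-chosen known genomes are slotted first: processed in
#' descending length order, each takes the unfilled target minimizing the
#' absolute size difference. The remaining slots are then filled in sequence
#' order, each taking the unused pool (uncharacterized) genome minimizing
#' the absolute size difference. Ties break on earliest slot / ascending
#' genome_id.
#'
#' @param known_lengths named numeric vector: known genome_id -> length_bp.
#' @param pool_lengths named numeric vector: candidate uncharacterized
#'   genome_id -> length_bp.
#' @param targets numeric target sizes, `length(known_lengths) + n_unknown`
#'   long.
#' @param n_unknown number of pool genomes to select.
#' @return character vector of selected pool genome_ids, in slot order.
#' @export
greedy_size_match <- function(known_lengths, pool_lengths, targets, n_unknown) {
  if (length(pool_lengths) < n_unknown)
    stop_mdm("uncharacterized pool smaller than requested selection",
             class = "mdmbench_validation_error")
  if (length(targets) != length(known_lengths) + n_unknown)
    stop_mdm("targets length must equal n_known + n_unknown",
             class = "mdmbench_validation_error")
  filled <- logical(length(targets))
  # knowns first, largest genome first (ties: ascending id)
  ko <- order(-known_lengths, names(known_lengths))
  for (i in ko) {
    free <- which(!filled)
    slot <- free[which.min(abs(known_lengths[i] - targets[free]))]
    filled[slot] <- TRUE
  }
  if (n_unknown == 0) return(character(0))
  pool <- pool_lengths[order(names(pool_lengths))]
  used <- logical(length(pool))
  sel <- character(n_unknown)
  s <- 0L
  for (slot in which(!filled)) {
    avail <- which(!used)
    pick <- avail[which.min(abs(pool[avail] - targets[slot]))]
    used[pick] <- TRUE
    s <- s + 1L
    sel[s] <- names(pool)[pick]
  }
  sel
}

#' Assign abundances to the uncharacterized block
#'
#' One log-normal draw per selected genome with the same `mu`/`sigma` as the
#' known block, assigned in selection order (unsorted — the rank structure
#' of real data applies only to characterized species).
#'
#' @param selected character vector of genome_ids.
#' @param mu,sigma log-normal parameters.
#' @param seed integer seed.
#' @return named numeric vector of unnormalized weights.
#' @export
build_unknown_block <- function(selected, mu, sigma, seed) {
  if (!length(selected)) return(setNames(numeric(0), character(0)))
  with_seed(seed, setNames(exp(rnorm(length(selected), mu, sigma)), selected))
}

#' Combine known and unknown blocks into a true profile
#'
#' The known block is scaled to sum to `1 - unknown_prop` and the unknown
#' block to `unknown_prop`, so both the number and the relative abundance of
#' uncharacterized species match the nominal design value.
#'
#' @param known_block,unknown_block named numeric weight vectors with
#'   disjoint names.
#' @param unknown_prop proportion of abundance from uncharacterized genomes.
#' @return an object of class `true_profile`: list with `abundances` (named,
#'   sums to 1), `status` (`"known"`/`"unknown"` per genome), `known_mass`,
#'   `unknown_mass`.
#' @export
assemble_profile <- function(known_block, unknown_block, unknown_prop) {
  if (length(intersect(names(known_block), names(unknown_block))))
    stop_mdm("known and unknown blocks overlap", class = "mdmbench_validation_error")
  if (!length(known_block) && !length(unknown_block))
    stop_mdm("both blocks empty", class = "mdmbench_validation_error")
  if (unknown_prop > 0 && !length(unknown_block))
    stop_mdm("unknown_prop > 0 with empty unknown block",
             class = "mdmbench_validation_error")
  if (unknown_prop < 1 && !length(known_block))
    stop_mdm("unknown_prop < 1 with empty known block",
             class = "mdmbench_validation_error")
  known <- if (length(known_block) && unknown_prop < 1)
    known_block / sum(known_block) * (1 - unknown_prop) else
      setNames(numeric(0), character(0))
  unknown <- if (length(unknown_block) && unknown_prop > 0)
    unknown_block / sum(unknown_block) * unknown_prop else
      setNames(numeric(0), character(0))
  ab <- c(known, unknown)
  structure(list(abundances = ab,
                 status = setNames(rep(c("known", "unknown"),
                                       c(length(known), length(unknown))),
                                   names(ab)),
                 known_mass = sum(known),
                 unknown_mass = sum(unknown)),
            class = "true_profile")
}

#' @export
print.true_profile <- function(x, ...) {
  cat("true_profile:", length(x$abundances), "genomes; known mass",
      signif(x$known_mass, 4), "| unknown mass", signif(x$unknown_mass, 4), "\n")
  invisible(x)
}

#' Apply random substitution point mutations to a genome
#'
#' Each A/C/G/T position is independently substituted with probability
#' `rate`, uniformly to one of the other three bases; ambiguous IUPAC bases
#' are left untouched and length is preserved. Conserved regions are *not*
#' modeled — the mutations emulate divergence between a database genome and
#' an environmental strain, not realistic mutation patterns.
#'
#' @param sequence nucleotide string (IUPAC alphabet).
#' @param rate per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return mutated nucleotide string.
#' @export
mutate_genome <- function(sequence, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                        "B", "D", "H", "V", "N")))
    stop_mdm("sequence contains non-IUPAC characters",
             class = "mdmbench_validation_error")
  if (rate == 0) return(paste(chars, collapse = ""))
  acgt <- c("A", "C", "G", "T")
  with_seed(seed, {
    eligible <- chars %in% acgt
    hit <- eligible & (runif(length(chars)) < rate)
    if (any(hit)) {
      # uniform over the three other bases
      cur <- match(chars[hit], acgt)
      offset <- sample.int(3, sum(hit), replace = TRUE)
      chars[hit] <- acgt[((cur - 1 + offset) %% 4) + 1]
    }
    paste(chars, collapse = "")
  })
}

#' Expected per-genome fold coverage
#'
#' Under cell-abundance semantics (the read simulator's input contract) a
#' genome's read share is proportional to abundance times genome length, so
#' `coverage_i = a_i * depth_bp / sum_j(a_j * g_j)`. Under
#' sequence-abundance semantics the abundance is already a base-pair share:
#' `coverage_i = a_i * depth_bp / g_i`.
#'
#' @param profile a `true_profile`.
#' @param design a `sample_design` (supplies `depth_gbp`).
#' @param catalog a `genome_catalog` covering all profile genomes.
#' @param semantics `"cell"` (default) or `"sequence"`.
#' @return named numeric vector of fold coverages.
#' @export
expected_coverage <- function(profile, design, catalog,
                              semantics = c("cell", "sequence")) {
  semantics <- match.arg(semantics)
  ids <- names(profile$abundances)
  len <- catalog$records$length_bp[match(ids, catalog$records$genome_id)]
  if (anyNA(len))
    stop_mdm("profile genomes missing from catalog",
             class = "mdmbench_validation_error")
  if (any(len <= 0))
    stop_mdm("zero-length genome", class = "mdmbench_validation_error")
  depth_bp <- design$depth_gbp * 1e9
  a <- profile$abundances
  if (semantics == "cell") setNames(a * depth_bp / sum(a * len), ids)
  else setNames(a * depth_bp / len, ids)
}

#' Emit a CAMISIM configuration for one designed sample
#'
#' Writes the INI config (art_illumina error profile, 150-bp paired-end
#' reads, size field = sequencing depth in Gbp), `genome_to_id.tsv`,
#' `metadata.tsv`, and the per-sample abundance TSV whose column sums to 1.
#' Emission is deterministic: identical inputs give byte-identical files.
#' CAMISIM itself is not invoked; [camisim_command()] prints the call.
#'
#' @param profile a `true_profile`.
#' @param design a `sample_design`.
#' @param genome_paths named character vector: genome_id -> FASTA path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, named list of written file paths.
#' @export
emit_camisim_config <- function(profile, design, genome_paths, out_dir) {
  ids <- names(profile$abundances)
  missing_fa <- setdiff(ids, names(genome_paths))
  if (length(missing_fa))
    stop_mdm("missing FASTA path for: ", paste(missing_fa, collapse = ", "),
             class = "mdmbench_validation_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.10g", x)

  ab_path <- file.path(out_dir, "abundance.tsv")
  ab <- profile$abundances / sum(profile$abundances)
  writeLines(paste0(ids, "\t", fmt(ab)), ab_path)

  g2i_path <- file.path(out_dir, "genome_to_id.tsv")
  writeLines(paste0(ids, "\t", genome_paths[ids]), g2i_path)

  meta_path <- file.path(out_dir, "metadata.tsv")
  writeLines(c("genome_ID\tOTU\tNCBI_ID\tnovelty_category",
               paste0(ids, "\t", seq_along(ids), "\t1\t",
                      ifelse(profile$status[ids] == "known",
                             "known_strain", "new_species"))),
             meta_path)

  cfg_path <- file.path(out_dir, "config.ini")
  writeLines(c(
    "[Main]",
    "seed=" %+% design$seed,
    "phase=0",
    "max_processors=1",
    "dataset_id=" %+% design$environment,
    "output_directory=" %+% file.path(out_dir, "out"),
    "temp_directory=" %+% file.path(out_dir, "tmp"),
    "gsa=False",
    "pooled_gsa=False",
    "anonymous=False",
    "compress=1",
    "",
    "[ReadSimulator]",
    "readsim=art_illumina",
    "error_profiles=mbarc",
    "samtools=samtools",
    "profile=mbarc",
    "size=" %+% fmt(design$depth_gbp),
    "type=art",
    "fragments_size_mean=270",
    "fragment_size_standard_deviation=27",
    "",
    "[CommunityDesign]",
    "distribution_file_paths=" %+% ab_path,
    "ncbi_taxdump=taxdump",
    "number_of_samples=1",
    "",
    "[community0]",
    "metadata=" %+% meta_path,
    "id_to_genome_file=" %+% g2i_path,
    "genomes_total=" %+% length(ids),
    "genomes_real=" %+% length(ids),
    "max_strains_per_otu=1",
    "ratio=1",
    "mode=known_distribution",
    "equally_distributed_strains=False",
    "input_genomes_to_zero=False"
  ), cfg_path)

  invisible(list(config = cfg_path, abundance = ab_path,
                 genome_to_id = g2i_path, metadata = meta_path))
}

`%+%` <- function(a, b) paste0(a, b)

#' Print the CAMISIM invocation for an emitted configuration
#'
#' @param config_path path to the emitted `config.ini`.
#' @return the command string, invisibly (also printed).
#' @export
camisim_command <- function(config_path) {
  cmd <- paste("python metagenomesimulation.py", config_path)
  message(cmd)
  invisible(cmd)
}

#' Simulate one community: select genomes and build the true profile
#'
#' End-to-end constructor for one designed sample. Known (characterized)
#' species are the `ncbi_available` catalog records taken in `rank_order`
#' and truncated to `n_species * (1 - unknown_prop)`; uncharacterized
#' genomes (`new_ncbi` plus per-genus-capped `new_sgb` records) are selected
#' by greedily matching genome sizes to the geometric size sequence after
#' the knowns are slotted in. Both blocks receive log-normal abundances and
#' are scaled to the designed known/unknown mass split. All randomness
#' derives from `design$seed` via labeled substreams.
#'
#' @param design a `sample_design`.
#' @param catalog a `genome_catalog` (after any [swap_reference_with_sgb()]).
#' @param max_sgbs_per_genus per-genus SGB cap (default 10).
#' @return list with `profile` (a `true_profile`), `design`, and
#'   `selected_unknown` (character vector of uncharacterized genome_ids).
#' @export
simulate_sample <- function(design, catalog, max_sgbs_per_genus = 10) {
  rec <- catalog$records
  known_rec <- rec[rec$status == "ncbi_available" & !is.na(rec$rank_order), ,
                   drop = FALSE]
  ranked <- known_rec$genome_id[order(known_rec$rank_order)]
  n_known <- round(design$n_species * (1 - design$unknown_prop))
  n_unknown <- design$n_species - n_known
  if (n_known > length(ranked))
    stop_mdm("catalog has too few ranked ncbi_available genomes",
             class = "mdmbench_validation_error")

  known_block <- build_known_block(ranked, n_known, design$mu, design$sigma,
                                   derive_seed(design$seed, "known_block"))

  pool_ids <- c(rec$genome_id[rec$status == "new_ncbi"],
                select_sgbs_per_genus(catalog, max_sgbs_per_genus))
  targets <- target_size_sequence(design$n_species, design$size_skew_k,
                                  median(rec$length_bp))
  known_len <- setNames(
    rec$length_bp[match(names(known_block), rec$genome_id)],
    names(known_block))
  pool_len <- setNames(rec$length_bp[match(pool_ids, rec$genome_id)], pool_ids)
  selected <- greedy_size_match(known_len, pool_len, targets, n_unknown)

  unknown_block <- build_unknown_block(selected, design$mu, design$sigma,
                                       derive_seed(design$seed, "unknown_block"))
  profile <- assemble_profile(known_block, unknown_block, design$unknown_prop)
  list(profile = profile, design = design, selected_unknown = selected)
}

#' Read/write a true profile as TSV
#'
#' Columns: `genome_id`, `abundance`, `status` (`known`/`unknown`).
#' @param profile a `true_profile`.
#' @param path file path.
#' @return `read_true_profile` returns a `true_profile`.
#' @export
write_true_profile <- function(profile, path) {
  df <- data.frame(genome_id = names(profile$abundances),
                   abundance = as.numeric(profile$abundances),
                   status = as.character(profile$status),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_true_profile
#' @export
read_true_profile <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  ab <- setNames(df$abundance, df$genome_id)
  structure(list(abundances = ab,
                 status = setNames(df$status, df$genome_id),
                 known_mass = sum(ab[df$status == "known"]),
                 unknown_mass = sum(ab[df$status == "unknown"])),
            class = "true_profile")
}
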