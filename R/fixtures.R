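#' Specify a synthetic taxonomy/catalog fixture
#'
#' Controls the shape of fully synthetic test worlds: a rank-complete
#' taxonomy (root, superkingdom, kingdom, then `n_phyla` phyla each with one
#' class per family group, and so on down to species), a genome catalog
#' with a characterization-status mix, log-normal genome sizes, and a
#' method database with synonym and missing-name rates.
#'
#' @param n_phyla,families_per_phylum,genera_per_family,species_per_genus
#'   taxonomy shape counts (each >= 1). One class per phylum and one order
#'   per family are inserted to complete the rank ladder.
#' @param status_mix named numeric proportions over
#'   `c(ncbi_available, new_ncbi, new_sgb)`, summing to 1.
#' @param size_median median genome size in bp.
#' @param size_spread standard deviation of log genome size.
#' @param synonym_rate probability a taxon gets a synonym line / is reported
#'   by its synonym.
#' @param missing_rate probability a taxon is absent from a method database.
#' @param seed integer seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_phyla = 2L, families_per_phylum = 2L,
                         genera_per_family = 2L, species_per_genus = 4L,
                         status_mix = c(ncbi_available = 0.4, new_ncbi = 0.2,
                                        new_sgb = 0.4),
                         size_median = 20000, size_spread = 0.3,
                         synonym_rate = 0.2, missing_rate = 0.1,
                         seed = 1L) {
  stopifnot(n_phyla >= 1, families_per_phylum >= 1, genera_per_family >= 1,
            species_per_genus >= 1, abs(sum(status_mix) - 1) < 1e-9,
            synonym_rate >= 0, synonym_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_phyla = as.integer(n_phyla),
                 families_per_phylum = as.integer(families_per_phylum),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 status_mix = status_mix,
                 size_median = size_median, size_spread = size_spread,
                 synonym_rate = synonym_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate synthetic taxonomy dump files
#'
#' Emits `names.dmp`/`nodes.dmp` lines for a rank-complete synthetic
#' taxonomy: root (its own parent, rank `no rank`), one superkingdom, one
#' kingdom, then phyla / one class per phylum / orders (one per family) /
#' families / genera / species per the spec counts. Species receive synonym
#' lines (`syn <species name>`) at `synonym_rate`. Deterministic for a fixed
#' seed.
#'
#' @param spec a `fixture_spec`.
#' @param dir optional directory; when given, `names.dmp` and `nodes.dmp`
#'   are written there.
#' @return list with `names` and `nodes` line vectors, `paths` (when `dir`
#'   given) and `n_species`.
#' @export
make_taxonomy <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  nodes <- list()  # taxon_id, parent_id, rank, name
  add <- function(id, parent, rank, name)
    nodes[[length(nodes) + 1]] <<- list(id = id, parent = parent,
                                        rank = rank, name = name)
  next_id <- 1L
  new_id <- function() { id <- next_id; next_id <<- next_id + 1L; id }

  root <- new_id(); add(root, root, "no rank", "root")
  sk <- new_id(); add(sk, root, "superkingdom", "Bacteria")
  kg <- new_id(); add(kg, sk, "kingdom", "Bacteria_kingdom")
  species_ids <- integer(0)
  for (p in seq_len(spec$n_phyla)) {
    ph <- new_id(); add(ph, kg, "phylum", paste0("Phylum_", p))
    cl <- new_id(); add(cl, ph, "class", paste0("Class_", p))
    for (f in seq_len(spec$families_per_phylum)) {
      od <- new_id(); add(od, cl, "order", paste0("Order_", p, "_", f))
      fa <- new_id(); add(fa, od, "family", paste0("Family_", p, "_", f))
      for (g in seq_len(spec$genera_per_family)) {
        ge <- new_id(); add(ge, fa, "genus", paste0("Genus_", p, "_", f, "_", g))
        for (s in seq_len(spec$species_per_genus)) {
          sp <- new_id()
          add(sp, ge, "species", paste0("Species_", p, "_", f, "_", g, "_", s))
          species_ids <- c(species_ids, sp)
        }
      }
    }
  }
  df <- do.call(rbind, lapply(nodes, as.data.frame))
  syn <- with_seed(derive_seed(spec$seed, "synonyms"), {
    hit <- df$rank == "species" & runif(nrow(df)) < spec$synonym_rate
    df[hit, c("id", "name"), drop = FALSE]
  })
  node_lines <- paste0(df$id, "\t|\t", df$parent, "\t|\t", df$rank, "\t|")
  name_lines <- c(paste0(df$id, "\t|\t", df$name,
                         "\t|\t\t|\tscientific name\t|"),
                  if (nrow(syn)) paste0(syn$id, "\t|\tsyn ", syn$name,
                                        "\t|\t\t|\tsynonym\t|"))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(names = file.path(dir, "names.dmp"),
                  nodes = file.path(dir, "nodes.dmp"))
    writeLines(name_lines, paths$names)
    writeLines(node_lines, paths$nodes)
  }
  list(names = name_lines, nodes = node_lines, paths = paths,
       n_species = length(species_ids), species_ids = species_ids)
}

#' Generate a synthetic genome catalog with sequences
#'
#' One genome per species of a [make_taxonomy()] taxonomy. Genome sizes are
#' log-normal around the spec median; statuses are drawn from the status
#' mix; `new_sgb` genomes get an `available_rank` drawn from genus / family
#' / order with the lineage blanked below it; `new_ncbi` genomes are
#' available to genus. `rank_order` (the real-data abundance rank) is a
#' random permutation over the `ncbi_available` genomes. Sequences are
#' i.i.d. uniform bases of the recorded lengths — adequate for sketching
#' and mutation testing, not for read-simulator realism.
#'
#' @param taxonomy a `taxonomy_table` (parse of [make_taxonomy()] output).
#' @param spec the `fixture_spec`.
#' @param environment environment label for the catalog.
#' @param with_sequences generate sequences? (default TRUE)
#' @return a `genome_catalog` (with sequences attached when requested).
#' @export
make_catalog_and_sequences <- function(taxonomy, spec, environment = "soil",
                                       with_sequences = TRUE) {
  nd <- taxonomy$nodes
  sp <- nd[nd$rank == "species", , drop = FALSE]
  n <- nrow(sp)
  with_seed(derive_seed(spec$seed, "catalog"), {
    lin <- t(vapply(sp$taxon_id, full_lineage, integer(length(CANONICAL_RANKS)),
                    taxonomy = taxonomy))
    colnames(lin) <- paste0("taxid_", CANONICAL_RANKS)
    status <- sample(names(spec$status_mix), n, replace = TRUE,
                     prob = spec$status_mix)
    avail <- ifelse(status == "ncbi_available", "species",
                    ifelse(status == "new_ncbi", "genus", NA))
    avail[status == "new_sgb"] <- sample(c("genus", "family", "order"),
                                         sum(status == "new_sgb"),
                                         replace = TRUE)
    len <- pmax(1000L, as.integer(round(
      spec$size_median * exp(rnorm(n, 0, spec$size_spread)))))
    comp <- pmin(100, 50 + 50 * runif(n))
    cont <- pmin(100, 10 * runif(n))
    rec <- data.frame(genome_id = sprintf("G%04d", sp$taxon_id),
                      length_bp = len, status = status,
                      completeness = round(comp, 2),
                      contamination = round(cont, 2),
                      rank_order = NA_integer_,
                      available_rank = avail,
                      lin, stringsAsFactors = FALSE)
    # blank the lineage below available_rank for uncharacterized genomes
    for (i in which(rec$status != "ncbi_available")) {
      below <- CANONICAL_RANKS[rank_depth(CANONICAL_RANKS) >
                                 rank_depth(rec$available_rank[i])]
      rec[i, paste0("taxid_", below)] <- NA_integer_
    }
    ka <- which(rec$status == "ncbi_available")
    rec$rank_order[ka] <- sample(length(ka))
    seqs <- NULL
    if (with_sequences) {
      seqs <- setNames(vapply(rec$length_bp, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), ""), rec$genome_id)
    }
    genome_catalog(rec, environment = environment, sequences = seqs)
  })
}

#' Generate a synthetic method database taxa list
#'
#' Emulates a profiler database: each taxonomy name is included with
#' probability `1 - missing_rate`, and an included species is reported by
#' its synonym spelling (`syn <name>`) with probability `synonym_rate` —
#' real databases differ in which taxa they contain and how they spell
#' them.
#'
#' @param taxonomy a `taxonomy_table`.
#' @param spec the `fixture_spec`.
#' @return character vector of database taxon names.
#' @export
make_method_namemap <- function(taxonomy, spec) {
  nd <- taxonomy$nodes
  nm <- nd$scientific_name[nd$rank %in% CANONICAL_RANKS]
  with_seed(derive_seed(spec$seed, "namemap"), {
    keep <- runif(length(nm)) >= spec$missing_rate
    nm <- nm[keep]
    syn <- runif(length(nm)) < spec$synonym_rate
    ifelse(syn, paste0("syn ", nm), nm)
  })
}

#' Specify profiler error modes for perturbing a true profile
#'
#' @param drop_rate probability each true taxon is dropped (false
#'   negatives).
#' @param false_positive_rate expected false positives as a fraction of the
#'   truth's taxon count.
#' @param abundance_noise_cv coefficient of variation of multiplicative
#'   log-normal abundance noise.
#' @param rank_truncation_prob probability a surviving taxon is reported at
#'   its parent genus/family instead of its own rank.
#' @param extra_unknown_mass declared-unknown mass inserted before
#'   renormalization.
#' @param seed integer seed.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(drop_rate = 0, false_positive_rate = 0,
                              abundance_noise_cv = 0,
                              rank_truncation_prob = 0,
                              extra_unknown_mass = 0, seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1,
            abundance_noise_cv >= 0,
            rank_truncation_prob >= 0, rank_truncation_prob <= 1,
            extra_unknown_mass >= 0, extra_unknown_mass <= 1)
  structure(list(drop_rate = drop_rate,
                 false_positive_rate = false_positive_rate,
                 abundance_noise_cv = abundance_noise_cv,
                 rank_truncation_prob = rank_truncation_prob,
                 extra_unknown_mass = extra_unknown_mass,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Perturb a true rank profile with profiler-style errors
#'
#' Applies, in order: random taxon drops, multiplicative log-normal
#' abundance noise, false positives drawn from same-rank taxa of the
#' fixture taxonomy not already in the profile, rank truncation (a taxon
#' replaced by its parent-rank ancestor), and insertion of declared unknown
#' mass; then renormalizes. With an all-zero spec the output equals the
#' truth exactly, which is the identity path the evaluation pipeline must
#' map to F1 = 1 / BC = 0 / IOU = 1.
#'
#' @param truth a `rank_profile` keyed by taxon id, summing to 1.
#' @param spec a `perturbation_spec`.
#' @param taxonomy a `taxonomy_table` (source of false positives and
#'   truncation ancestors).
#' @return an `assigned_profile` keyed by taxon id.
#' @export
perturb_profile <- function(truth, spec, taxonomy) {
  stopifnot(inherits(truth, "rank_profile"), inherits(spec, "perturbation_spec"))
  ent <- truth$entries
  with_seed(spec$seed, {
    keep <- runif(length(ent)) >= spec$drop_rate
    dropped_mass <- sum(ent[!keep])
    ent <- ent[keep]
    if (length(ent) && spec$abundance_noise_cv > 0) {
      sdlog <- sqrt(log(1 + spec$abundance_noise_cv^2))
      ent <- ent * exp(rnorm(length(ent), -sdlog^2 / 2, sdlog))
    }
    if (spec$false_positive_rate > 0) {
      nd <- taxonomy$nodes
      pool <- setdiff(nd$taxon_id[nd$rank == truth$rank],
                      as.integer(names(truth$entries)))
      n_fp <- min(length(pool),
                  stats::rpois(1, spec$false_positive_rate *
                                 length(truth$entries)))
      if (n_fp > 0) {
        fp <- sample(pool, n_fp)
        mean_ab <- if (length(ent)) mean(ent) else 0.01
        ent <- c(ent, setNames(rep(mean_ab * 0.5, n_fp), fp))
      }
    }
    if (length(ent) && spec$rank_truncation_prob > 0 &&
          truth$rank != "superkingdom") {
      parent_rank <- CANONICAL_RANKS[rank_depth(truth$rank) - 1]
      trunc <- runif(length(ent)) < spec$rank_truncation_prob
      if (any(trunc)) {
        anc <- vapply(as.integer(names(ent)[trunc]), lineage_query,
                      integer(1), rank = parent_rank, taxonomy = taxonomy)
        names(ent)[trunc] <- as.character(anc)
        v <- tapply(ent, names(ent), sum)
        ent <- setNames(as.numeric(v), names(v))
      }
    }
    unknown <- dropped_mass + spec$extra_unknown_mass
    total <- sum(ent) + unknown
    assigned_profile(ent / total, rank = truth$rank,
                     unknown_mass = unknown / total)
  })
}
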