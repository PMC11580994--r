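# Shared fixtures and independent brute-force oracles.

# Hand-written minimal dump: root -> superkingdom -> phylum -> genus -> 2
# species, one with a synonym.
tiny_dump <- function() {
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "3\t|\t2\t|\tphylum\t|",
    "4\t|\t3\t|\tgenus\t|",
    "5\t|\t4\t|\tspecies\t|",
    "6\t|\t4\t|\tspecies\t|"
  )
  names <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
    "3\t|\tProteobacteria\t|\t\t|\tscientific name\t|",
    "4\t|\tEscherichia\t|\t\t|\tscientific name\t|",
    "5\t|\tEscherichia coli\t|\t\t|\tscientific name\t|",
    "5\t|\tBacterium coli\t|\t\t|\tsynonym\t|",
    "6\t|\tEscherichia fergusonii\t|\t\t|\tscientific name\t|"
  )
  list(names = names, nodes = nodes)
}

# Memoised fixture worlds (taxonomy + catalog), keyed by their parameters.
.world_cache <- new.env(parent = emptyenv())

fixture_world <- function(seed = 7, n_phyla = 2, families_per_phylum = 2,
                          genera_per_family = 2, species_per_genus = 4,
                          status_mix = c(ncbi_available = 0.4, new_ncbi = 0.2,
                                         new_sgb = 0.4),
                          size_median = 20000, with_sequences = TRUE) {
  key <- paste(seed, n_phyla, families_per_phylum, genera_per_family,
               species_per_genus, paste(status_mix, collapse = ","),
               size_median, with_sequences, sep = "|")
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  spec <- fixture_spec(n_phyla = n_phyla,
                       families_per_phylum = families_per_phylum,
                       genera_per_family = genera_per_family,
                       species_per_genus = species_per_genus,
                       status_mix = status_mix,
                       size_median = size_median, seed = seed)
  dumps <- make_taxonomy(spec)
  taxonomy <- parse_taxonomy_dump(dumps$names, dumps$nodes)
  catalog <- make_catalog_and_sequences(taxonomy, spec,
                                        with_sequences = with_sequences)
  w <- list(spec = spec, dumps = dumps, taxonomy = taxonomy, catalog = catalog)
  .world_cache[[key]] <- w
  w
}

# ---- independent oracles -------------------------------------------------

bc_brute <- function(x, y) {
  keys <- union(names(x), names(y))
  xv <- ifelse(is.na(x[keys]), 0, x[keys])
  yv <- ifelse(is.na(y[keys]), 0, y[keys])
  0.5 * sum(abs(xv - yv))
}

prf_brute <- function(a, t) {
  inter <- sum(a %in% t)
  p <- inter / length(a)
  r <- inter / length(t)
  c(p, r, if (p + r == 0) 0 else 2 * p * r / (p + r))
}

iou_brute <- function(a, b) length(intersect(a, b)) / length(union(a, b))

spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

mantel_r_brute <- function(d1, d2) {
  u1 <- d1[upper.tri(d1)]
  u2 <- d2[upper.tri(d2)]
  sum((u1 - mean(u1)) * (u2 - mean(u2))) /
    sqrt(sum((u1 - mean(u1))^2) * sum((u2 - mean(u2))^2))
}

# exhaustive permutation p-value for small n
mantel_p_exhaustive <- function(d1, d2) {
  n <- nrow(d1)
  perms <- gtools_permutations(n)
  r_obs <- mantel_r_brute(d1, d2)
  rs <- apply(perms, 1, function(p) mantel_r_brute(d1, d2[p, p]))
  mean(rs >= r_obs - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

greedy_brute <- function(known_lengths, pool_lengths, targets, n_unknown) {
  taken <- rep(FALSE, length(targets))
  for (i in order(-known_lengths, names(known_lengths))) {
    free <- which(!taken)
    j <- free[which.min(abs(known_lengths[i] - targets[free]))]
    taken[j] <- TRUE
  }
  pool <- pool_lengths[order(names(pool_lengths))]
  used <- rep(FALSE, length(pool))
  out <- character(0)
  for (slot in which(!taken)) {
    avail <- which(!used)
    j <- avail[which.min(abs(pool[avail] - targets[slot]))]
    used[j] <- TRUE
    out <- c(out, names(pool)[j])
  }
  out
}

oct_brute <- function(cov, rec) {
  u <- sort(unique(cov))
  t_cand <- c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
              u[length(u)] + 1)
  w_cand <- c(0, if (length(u) > 1) diff(u), 0)
  err <- vapply(t_cand, function(t) sum((cov >= t) != rec), integer(1))
  keep <- which(err == min(err))
  keep <- keep[order(-w_cand[keep], t_cand[keep])]
  t_cand[keep[1]]
}

rank_profile_for_test <- function(entries, rank, provenance = "assigned")
  structure(list(entries = entries, rank = rank, provenance = provenance),
            class = "rank_profile")

# minimal hand-built catalog records row
catalog_row <- function(genome_id, length_bp = 10000, status = "ncbi_available",
                        completeness = 100, contamination = 0,
                        rank_order = NA_integer_, available_rank = "species",
                        lineage = NULL) {
  row <- data.frame(genome_id = genome_id, length_bp = length_bp,
                    status = status, completeness = completeness,
                    contamination = contamination, rank_order = rank_order,
                    available_rank = available_rank,
                    stringsAsFactors = FALSE)
  lin <- setNames(rep(NA_integer_, 8),
                  paste0("taxid_", c("superkingdom", "kingdom", "phylum",
                                     "class", "order", "family", "genus",
                                     "species")))
  if (!is.null(lineage)) lin[paste0("taxid_", names(lineage))] <- lineage
  cbind(row, as.data.frame(as.list(lin)))
}
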