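random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("sketching is deterministic and strand-canonical", {
  s <- random_seq(5000, 1)
  expect_identical(sketch_genome(s)$hashes, sketch_genome(s)$hashes)
  expect_identical(sketch_genome(revcomp(s))$hashes, sketch_genome(s)$hashes)
  expect_error(sketch_genome("ACGT", kmer_size = 21),
               class = "mdmbench_validation_error")
})

test_that("bottom-s sketch equals the smallest hashes of the full k-mer set", {
  s <- random_seq(10000, 2)
  full <- mdmbench:::all_kmer_hashes_cpp(s, 21L)
  sk <- sketch_genome(s, 21, 1000)
  expect_equal(sk$hashes, sort(full)[seq_len(1000)])
  # sketch larger than the k-mer set degrades to the full set
  small <- random_seq(100, 3)
  expect_equal(sketch_genome(small, 21, 10000)$hashes,
               mdmbench:::all_kmer_hashes_cpp(small, 21L))
})

test_that("Mash distance: identity, disjoint, direct formula, symmetry", {
  a <- sketch_genome(random_seq(5000, 4))
  b <- sketch_genome(random_seq(5000, 5))
  expect_equal(mash_distance(a, a), 0)
  expect_equal(mash_distance(a, b), mash_distance(b, a))
  # two unrelated random sequences share essentially no 21-mers
  expect_equal(mash_distance(a, b), 1)
  # hand-built sketches with Jaccard 0.5 at k = 21
  mk <- function(h) structure(list(hashes = as.numeric(h), kmer_size = 21L,
                                   sketch_size = 10L),
                              class = "minhash_sketch")
  d <- mash_distance(mk(1:10), mk(6:15))
  expect_equal(d, -log(2 * 0.5 / 1.5) / 21, tolerance = 1e-9)
  expect_equal(d, 0.01931, tolerance = 1e-3)
  expect_error(mash_distance(a, sketch_genome(random_seq(500, 1), 15)),
               class = "mdmbench_validation_error")
})

test_that("larger sketches estimate Jaccard more accurately", {
  # two sequences sharing half their content
  base <- random_seq(20000, 6)
  other <- random_seq(10000, 7)
  s1 <- paste0(substr(base, 1, 10000), substr(base, 10001, 20000))
  s2 <- paste0(substr(base, 1, 10000), other)
  exact_j <- local({
    h1 <- mdmbench:::all_kmer_hashes_cpp(s1, 21L)
    h2 <- mdmbench:::all_kmer_hashes_cpp(s2, 21L)
    length(intersect(h1, h2)) / length(union(h1, h2))
  })
  err <- vapply(c(100, 2000), function(sz) {
    a <- sketch_genome(s1, 21, sz); b <- sketch_genome(s2, 21, sz)
    s <- min(sz, length(union(a$hashes, b$hashes)))
    merged <- sort(union(a$hashes, b$hashes))[seq_len(s)]
    j <- sum(merged %in% a$hashes & merged %in% b$hashes) / s
    abs(j - exact_j)
  }, numeric(1))
  expect_lt(err[2], err[1] + 1e-9)
})

test_that("MAG quality gate: boundary cases", {
  expect_true(is_quality_mag(50, 9.9))
  expect_false(is_quality_mag(49.9, 0))
  expect_false(is_quality_mag(100, 10))
  expect_equal(is_quality_mag(c(50, 49.9, 100), c(9.9, 0, 10)),
               c(TRUE, FALSE, FALSE))
})

test_that("taxonomy containment allows stopping higher, forbids contradiction", {
  ranks <- c("superkingdom", "kingdom", "phylum", "class", "order",
             "family", "genus", "species")
  lin <- function(...) {
    v <- setNames(rep(NA_integer_, 8), ranks)
    args <- list(...)
    v[names(args)] <- as.integer(unlist(args))
    v
  }
  genome <- lin(superkingdom = 2, phylum = 3, family = 7, genus = 4)
  expect_true(taxonomy_contained(lin(superkingdom = 2, phylum = 3,
                                     family = 7), genome))
  expect_false(taxonomy_contained(lin(superkingdom = 2, phylum = 3,
                                      family = 7, genus = 99), genome))
  # MAG deeper than the genome's known lineage: contradiction
  expect_false(taxonomy_contained(lin(species = 12), genome))
  expect_true(taxonomy_contained(lin(), genome))
})

test_that("recovery assessment matches brute-force evaluation of the criteria", {
  genomes <- rbind(
    catalog_row("gk", length_bp = 5000, rank_order = 1L,
                lineage = c(superkingdom = 2L, phylum = 3L, genus = 4L,
                            species = 5L)),
    catalog_row("gu1", length_bp = 5000, status = "new_sgb",
                available_rank = "genus", completeness = 90,
                lineage = c(superkingdom = 2L, phylum = 3L, genus = 4L)),
    catalog_row("gu2", length_bp = 5000, status = "new_sgb",
                available_rank = "family", completeness = 90,
                lineage = c(superkingdom = 2L, phylum = 3L, family = 7L)),
    catalog_row("gu3", length_bp = 5000, status = "new_ncbi",
                available_rank = "genus",
                lineage = c(superkingdom = 2L, phylum = 3L, genus = 8L)),
    catalog_row("gu4", length_bp = 5000, status = "new_sgb",
                available_rank = "order",
                lineage = c(superkingdom = 2L, phylum = 3L)))
  cat <- genome_catalog(genomes)
  truth <- structure(list(abundances = c(gk = 0.4, gu1 = 0.3, gu2 = 0.1,
                                         gu3 = 0.15, gu4 = 0.05)),
                     class = "true_profile")
  mags <- rbind(
    cbind(data.frame(mag_id = "m1", completeness = 95, contamination = 1),
          catalog_row("x1", lineage = c(superkingdom = 2L, phylum = 3L,
                                        genus = 4L))[-(1:7)]),
    cbind(data.frame(mag_id = "m2", completeness = 40, contamination = 1),
          catalog_row("x2", lineage = c(superkingdom = 2L,
                                        phylum = 3L))[-(1:7)]),
    cbind(data.frame(mag_id = "m3", completeness = 80, contamination = 2),
          catalog_row("x3", lineage = c(superkingdom = 2L, phylum = 3L,
                                        genus = 99L))[-(1:7)]))
  D <- matrix(1, 3, 5, dimnames = list(c("m1", "m2", "m3"),
                                       genomes$genome_id))
  D["m1", "gu1"] <- 0.01          # quality + nearest + contained -> recovered
  D["m2", "gu2"] <- 0.01          # fails quality
  D["m3", "gu3"] <- 0.01          # wrong genus -> fails containment
  # gu4: no MAG nearest to it
  res <- assess_recovery(mags, cat, truth, distances = D)
  pg <- res$per_genome
  expect_equal(pg$recovered[pg$genome_id == "gu1"], TRUE)
  expect_equal(pg$failed[pg$genome_id == "gu2"], "quality")
  expect_equal(pg$failed[pg$genome_id == "gu3"], "taxonomy")
  expect_equal(pg$failed[pg$genome_id == "gu4"], "no_matching_mag")
  expect_equal(res$recovered_abundance_percent, 30)
  # distance tie -> conservatively not recovered
  D2 <- D; D2["m1", "gk"] <- 0.01
  res2 <- assess_recovery(mags, cat, truth, distances = D2)
  expect_false(res2$per_genome$recovered[res2$per_genome$genome_id == "gu1"])
  # contamination gate flips recovery off
  mags3 <- mags; mags3$contamination[1] <- 15
  res3 <- assess_recovery(mags3, cat, truth, distances = D)
  expect_false(res3$per_genome$recovered[res3$per_genome$genome_id == "gu1"])
})

test_that("sketch-derived and precomputed distance routes agree", {
  set.seed(8)
  w <- fixture_world(seed = 8, n_phyla = 1, species_per_genus = 3,
                     size_median = 4000)
  cat <- w$catalog
  ids <- cat$records$genome_id
  gsk <- lapply(setNames(ids, ids), function(id)
    sketch_genome(cat$sequences[[id]], sketch_size = 200))
  unchar <- cat$records$genome_id[cat$records$status != "ncbi_available"][1]
  mag_seq <- cat$sequences[[unchar]]
  msk <- list(mag1 = sketch_genome(mag_seq, sketch_size = 200))
  mrow <- cat$records[cat$records$genome_id == unchar, ]
  mags <- cbind(data.frame(mag_id = "mag1", completeness = 99,
                           contamination = 0),
                mrow[paste0("taxid_", c("superkingdom", "kingdom", "phylum",
                                        "class", "order", "family", "genus",
                                        "species"))])
  truth <- structure(list(abundances = setNames(rep(1 / length(ids),
                                                    length(ids)), ids)),
                     class = "true_profile")
  via_sketch <- assess_recovery(mags, cat, truth, mag_sketches = msk,
                                genome_sketches = gsk)
  D <- matrix(NA_real_, 1, length(ids), dimnames = list("mag1", ids))
  for (g in ids) D["mag1", g] <- mash_distance(msk$mag1, gsk[[g]])
  via_matrix <- assess_recovery(mags, cat, truth, distances = D)
  expect_equal(via_sketch$per_genome, via_matrix$per_genome)
  expect_true(via_sketch$per_genome$recovered[
    via_sketch$per_genome$genome_id == unchar])
})

test_that("optimal coverage threshold: midpoint, single-class error, brute force", {
  expect_equal(optimal_coverage_threshold(c(10, 10, 20, 20),
                                          c(FALSE, FALSE, TRUE, TRUE)), 15)
  expect_error(optimal_coverage_threshold(c(1, 2), c(TRUE, TRUE)),
               class = "mdmbench_validation_error")
  set.seed(12)
  for (i in 1:20) {
    cov <- round(c(rlnorm(10, 2, 0.7), rlnorm(10, 3, 0.7)), 2)
    rec <- c(runif(10) < 0.25, runif(10) < 0.8)
    if (all(rec) || !any(rec)) next
    t_impl <- optimal_coverage_threshold(cov, rec)
    t_brute <- oct_brute(cov, rec)
    expect_equal(t_impl, t_brute)
    # the returned threshold achieves the global misclassification minimum
    errs <- vapply(sort(unique(c(cov, cov - 1e-6, cov + 1e-6))),
                   function(t) sum((cov >= t) != rec), integer(1))
    expect_equal(sum((cov >= t_impl) != rec), min(errs))
  }
})

test_that("recovered abundance is monotone in the quality gates", {
  # with a stricter completeness gate, fewer genomes recover
  genomes <- rbind(
    catalog_row("u1", status = "new_sgb", available_rank = "genus",
                lineage = c(genus = 4L)),
    catalog_row("u2", status = "new_sgb", available_rank = "genus",
                lineage = c(genus = 4L)))
  cat <- genome_catalog(genomes)
  truth <- structure(list(abundances = c(u1 = 0.5, u2 = 0.5)),
                     class = "true_profile")
  mags <- rbind(
    cbind(data.frame(mag_id = "m1", completeness = 55, contamination = 1),
          catalog_row("x", lineage = c(genus = 4L))[-(1:7)]),
    cbind(data.frame(mag_id = "m2", completeness = 95, contamination = 1),
          catalog_row("x", lineage = c(genus = 4L))[-(1:7)]))
  D <- matrix(c(0.01, 1, 1, 0.01), 2, 2,
              dimnames = list(c("m1", "m2"), c("u1", "u2")))
  base <- assess_recovery(mags, cat, truth, distances = D)
  expect_equal(base$recovered_abundance_percent, 100)
  stricter <- mags; stricter$completeness <- stricter$completeness - 10
  res <- assess_recovery(stricter, cat, truth, distances = D)
  expect_lte(res$recovered_abundance_percent,
             base$recovered_abundance_percent)
  expect_equal(res$recovered_abundance_percent, 50)
})
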