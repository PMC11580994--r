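test_that("grid expansion: counts, identity, seed determinism", {
  core <- sample_design(seed = 42)
  g <- expand_grid(core, "depth_gbp", c(0.05, 0.5, 1.5, 7.5, 30),
                   replicates = 5)
  expect_length(g, 25)
  expect_equal(unique(vapply(g, `[[`, 1, "depth_gbp")),
               c(0.05, 0.5, 1.5, 7.5, 30))
  # replicates = 1 at the core value reproduces the core design (bar seed)
  one <- expand_grid(core, "sigma", 1, replicates = 1)[[1]]
  expect_equal(one[setdiff(names(one), "seed")],
               core[setdiff(names(core), "seed")])
  # same core seed -> identical derived seed lists
  g2 <- expand_grid(core, "depth_gbp", c(0.05, 0.5, 1.5, 7.5, 30), 5)
  expect_identical(vapply(g, `[[`, 1L, "seed"), vapply(g2, `[[`, 1L, "seed"))
  expect_error(expand_grid(core, "not_a_param", 1),
               class = "mdmbench_config_error")
})

# reproduce the draw stream the block builder consumes after its split step
with_seed_draws <- function(n, mu, sigma, seed) {
  set.seed(seed)
  n1 <- ceiling(n / 2)
  invisible(sample(n, n1))
  exp(rnorm(n, mu, sigma))
}

test_that("known block: degenerate sizes, multiset preservation", {
  expect_length(build_known_block(letters, 0, -3, 1, 1), 0)
  one <- build_known_block(letters, 1, -3, 1, 1)
  expect_equal(names(one), "a")
  expect_true(one > 0)
  # the assignment permutes, never alters, the sorted log-normal draws
  for (s in 1:5) {
    w <- build_known_block(paste0("sp", 1:17), 17, -3, 1.5, s)
    draws <- with_seed_draws(17, -3, 1.5, s)
    expect_equal(sort(unname(w)), sort(draws), tolerance = 1e-12)
  }
  expect_error(build_known_block(letters[1:3], 5, -3, 1, 1),
               class = "mdmbench_validation_error")
})

test_that("known block favours top-ranked species across seeds", {
  n <- 20
  mean_w <- numeric(n)
  for (s in 1:200) {
    w <- build_known_block(sprintf("sp%02d", 1:n), n, -3, 1, s)
    mean_w <- mean_w + w[sprintf("sp%02d", 1:n)]
  }
  rho <- cor(seq_len(n), mean_w, method = "spearman")
  expect_lt(rho, 0)
})

test_that("target size sequence: limits, symmetry, direct values", {
  # r -> 1 limit: all entries collapse to the median
  s <- target_size_sequence(7, 1e9, 4e6)
  expect_lt(diff(range(s)) / 4e6, 1e-6)
  # odd n: middle entry is exactly the median
  s5 <- target_size_sequence(5, 40, 4e6)
  expect_equal(s5[3], 4e6)
  # direct evaluation at n = 3, k = 40
  expect_equal(target_size_sequence(3, 40, 4e6),
               c(4e6 * 40 / 39, 4e6, 3.9e6), tolerance = 1e-12)
  # strictly decreasing with the declared log-range
  s9 <- target_size_sequence(9, 40, 4e6)
  expect_true(all(diff(s9) < 0))
  expect_equal(log(s9[1]) - log(s9[9]), 8 * abs(log(39 / 40)),
               tolerance = 1e-12)
})

test_that("greedy size matching reproduces an independent greedy trace", {
  # perfect matching: pool equals targets, no knowns
  targets <- c(5000, 4000, 3000)
  pool <- setNames(c(3000, 5000, 4000), c("u3", "u1", "u2"))
  sel <- greedy_size_match(setNames(numeric(0), character(0)), pool,
                           targets, 3)
  expect_equal(sel, c("u1", "u2", "u3"))
  expect_length(greedy_size_match(setNames(c(k1 = 5000), "k1"), pool,
                                  targets[1:1], 0), 0)
  set.seed(99)
  for (i in 1:20) {
    nk <- sample(0:4, 1); nu <- sample(1:5, 1)
    kn <- setNames(round(runif(nk, 2000, 8000)), sprintf("k%02d", seq_len(nk)))
    pl <- setNames(round(runif(nu + 5, 2000, 8000)),
                   sprintf("u%02d", seq_len(nu + 5)))
    tg <- sort(runif(nk + nu, 2000, 8000), decreasing = TRUE)
    expect_equal(greedy_size_match(kn, pl, tg, nu),
                 greedy_brute(kn, pl, tg, nu))
  }
  expect_error(
    greedy_size_match(setNames(numeric(0), character(0)),
                      setNames(3000, "u1"), c(3000, 4000), 2),
    class = "mdmbench_validation_error")
})

test_that("unknown block keeps selection order and log-normal spread", {
  expect_length(build_unknown_block(character(0), -3, 1, 1), 0)
  w <- build_unknown_block(paste0("u", 1:50), -3, 1, 3)
  expect_true(all(w > 0))
  expect_equal(names(w), paste0("u", 1:50))
  big <- build_unknown_block(paste0("u", 1:10000), -3, 1, 5)
  expect_lt(abs(sd(log(big)) - 1), 0.05)
  expect_lt(abs(mean(log(big)) + 3), 0.05)
})

test_that("profile assembly hits the designed known/unknown split", {
  kb <- c(a = 2, b = 1); ub <- c(x = 5, y = 1)
  p <- assemble_profile(kb, ub, 0.25)
  expect_equal(sum(p$abundances), 1, tolerance = 1e-12)
  expect_equal(p$known_mass, 0.75, tolerance = 1e-12)
  expect_equal(p$unknown_mass, 0.25, tolerance = 1e-12)
  expect_equal(unname(p$abundances["a"] / p$abundances["b"]), 2)
  # boundary proportions
  expect_equal(assemble_profile(kb, ub, 0)$unknown_mass, 0)
  expect_equal(assemble_profile(kb, ub, 1)$known_mass, 0)
  expect_equal(sum(assemble_profile(kb, ub, 1)$abundances), 1)
  expect_error(assemble_profile(c(a = 1), c(a = 1), 0.5),
               class = "mdmbench_validation_error")
  expect_error(assemble_profile(numeric(0), numeric(0), 0.5),
               class = "mdmbench_validation_error")
  expect_error(assemble_profile(kb, numeric(0), 1),
               class = "mdmbench_validation_error")
})

test_that("mutation: identity at 0, total change at 1, length preserved", {
  seq0 <- paste(rep("ACGTN", 20), collapse = "")
  expect_identical(mutate_genome(seq0, 0, 1), seq0)
  m1 <- mutate_genome(seq0, 1, 2)
  expect_equal(nchar(m1), nchar(seq0))
  c0 <- strsplit(seq0, "")[[1]]; c1 <- strsplit(m1, "")[[1]]
  acgt <- c0 %in% c("A", "C", "G", "T")
  expect_true(all(c1[acgt] != c0[acgt]))      # every eligible base changed
  expect_true(all(c1[!acgt] == c0[!acgt]))    # ambiguity codes untouched
  expect_true(all(c1 %in% c("A", "C", "G", "T", "N")))
  expect_error(mutate_genome("ACGTX", 0.1, 1),
               class = "mdmbench_validation_error")
  # same seed, same mutation
  expect_identical(mutate_genome(seq0, 0.3, 9), mutate_genome(seq0, 0.3, 9))
})

test_that("expected coverage follows cell and sequence semantics", {
  rows <- rbind(
    catalog_row("g1", length_bp = 4e6, rank_order = 1L,
                lineage = c(species = 5L)),
    catalog_row("g2", length_bp = 2e6, rank_order = 2L,
                lineage = c(species = 6L)))
  cat <- genome_catalog(rows)
  one <- structure(list(abundances = c(g1 = 1), status = c(g1 = "known"),
                        known_mass = 1, unknown_mass = 0),
                   class = "true_profile")
  d40 <- sample_design(depth_gbp = 0.04)
  expect_equal(unname(expected_coverage(one, d40, cat, "cell")["g1"]), 10)
  expect_equal(unname(expected_coverage(one, d40, cat, "sequence")["g1"]), 10)
  p <- structure(list(abundances = c(g1 = 0.75, g2 = 0.25),
                      status = c(g1 = "known", g2 = "known"),
                      known_mass = 1, unknown_mass = 0),
                 class = "true_profile")
  cov <- expected_coverage(p, sample_design(depth_gbp = 7), cat, "cell")
  expect_equal(unname(cov), c(1500, 500), tolerance = 1e-12)
  # equal lengths, equal abundances -> equal coverage
  rows2 <- rows; rows2$length_bp <- c(3e6, 3e6)
  eq <- expected_coverage(
    structure(list(abundances = c(g1 = 0.5, g2 = 0.5)),
              class = "true_profile"),
    sample_design(depth_gbp = 7), genome_catalog(rows2), "cell")
  expect_equal(eq[["g1"]], eq[["g2"]])
})

test_that("read-simulator config emission is conservative and deterministic", {
  w <- fixture_world(seed = 5, n_phyla = 1, species_per_genus = 2)
  d <- sample_design(n_species = 4, unknown_prop = 0.5, seed = 8,
                     depth_gbp = 1.5)
  sim <- simulate_sample(d, w$catalog)
  ids <- names(sim$profile$abundances)
  paths <- setNames(file.path("fasta", paste0(ids, ".fna")), ids)
  out1 <- file.path(tempdir(), "cam1")
  f1 <- emit_camisim_config(sim$profile, d, paths, out1)
  first <- lapply(f1, readLines)
  ab <- read.table(f1$abundance, sep = "\t")
  expect_equal(sum(ab$V2), 1, tolerance = 1e-6)
  expect_true("size=1.5" %in% first$config)
  # re-emission over the same directory is byte-identical
  f2 <- emit_camisim_config(sim$profile, d, paths, out1)
  for (nm in names(f1))
    expect_identical(readLines(f2[[nm]]), first[[nm]])
  expect_error(emit_camisim_config(sim$profile, d, paths[-1], out1),
               class = "mdmbench_validation_error")
})

test_that("full pipeline is deterministic in the design seed", {
  w <- fixture_world(seed = 5, n_phyla = 1, species_per_genus = 2)
  d <- sample_design(n_species = 4, unknown_prop = 0.5, seed = 13)
  s1 <- simulate_sample(d, w$catalog)
  s2 <- simulate_sample(d, w$catalog)
  expect_identical(s1$profile, s2$profile)
  expect_identical(s1$selected_unknown, s2$selected_unknown)
  d2 <- d; d2$seed <- 14L
  expect_false(identical(simulate_sample(d2, w$catalog)$profile$abundances,
                         s1$profile$abundances))
})

test_that("true profile TSV round-trips", {
  w <- fixture_world(seed = 5, n_phyla = 1, species_per_genus = 2)
  sim <- simulate_sample(sample_design(n_species = 4, unknown_prop = 0.5,
                                       seed = 2), w$catalog)
  path <- tempfile(fileext = ".tsv")
  write_true_profile(sim$profile, path)
  back <- read_true_profile(path)
  expect_equal(back$abundances, sim$profile$abundances, tolerance = 1e-12)
  expect_equal(back$status, sim$profile$status)
})
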