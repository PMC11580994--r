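#' Precision, recall and F1 between assigned and true taxon sets
#'
#' Computed over the taxon-id sets of two post-processed profiles at the
#' same rank: precision = |A∩T|/|A|, recall = |A∩T|/|T|, and F1 their
#' harmonic mean (0 when both are 0).
#'
#' @param assigned,truth `rank_profile`s at the same rank (or plain
#'   character vectors of taxon ids).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(assigned, truth) {
  a <- profile_keys(assigned)
  t <- profile_keys(truth)
  if (!length(t))
    stop_mdm("empty truth set", class = "mdmbench_validation_error")
  if (!length(a)) return(c(precision = 0, recall = 0, f1 = 0))
  inter <- length(intersect(a, t))
  p <- inter / length(a)
  r <- inter / length(t)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

profile_keys <- function(x) {
  if (inherits(x, "rank_profile")) unique(names(x$entries))
  else unique(as.character(x))
}

profile_vector <- function(x) {
  if (inherits(x, "rank_profile")) x$entries else x
}

#' Bray-Curtis dissimilarity between two relative-abundance profiles
#'
#' `0.5 * sum(|x_i - y_i|)` over the union of taxa, absent taxa counting as
#' zero; 0 for identical profiles, 1 for disjoint support. Delegated to
#' `vegan::vegdist`.
#'
#' @param x,y `rank_profile`s or named numeric vectors, each summing to 1.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  xv <- profile_vector(x); yv <- profile_vector(y)
  if (abs(sum(xv) - 1) > 1e-6 || abs(sum(yv) - 1) > 1e-6)
    stop_mdm("profiles must each sum to 1", class = "mdmbench_validation_error")
  keys <- union(names(xv), names(yv))
  m <- rbind(ifelse(is.na(xv[keys]), 0, xv[keys]),
             ifelse(is.na(yv[keys]), 0, yv[keys]))
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' Intersection over union (Jaccard index) of two taxon sets
#'
#' @param a,b `rank_profile`s or character vectors; not both empty.
#' @return `|a∩b| / |a∪b|`.
#' @export
iou <- function(a, b) {
  a <- profile_keys(a); b <- profile_keys(b)
  u <- length(union(a, b))
  if (u == 0)
    stop_mdm("both sets empty", class = "mdmbench_validation_error")
  length(intersect(a, b)) / u
}

#' Alpha diversity of a relative-abundance profile
#'
#' Inverse Simpson (`1 / sum(p^2)`, an effective species number) or Shannon
#' (`-sum(p log p)`, natural log). Delegated to `vegan::diversity`.
#'
#' @param p a `rank_profile` or named numeric vector summing to 1.
#' @param index `"inverse_simpson"` (default) or `"shannon"`.
#' @return the diversity value.
#' @export
diversity_index <- function(p, index = c("inverse_simpson", "shannon")) {
  index <- match.arg(index)
  v <- profile_vector(p)
  if (!length(v))
    stop_mdm("empty profile", class = "mdmbench_validation_error")
  vegan::diversity(v, index = switch(index, inverse_simpson = "invsimpson",
                                     shannon = "shannon"))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), via
#' `stats::cor`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_mdm("constant vector: Spearman correlation undefined",
             class = "mdmbench_undefined_signal")
  cor(x, y, method = "spearman")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance
#' from simultaneous row/column permutation of the second matrix:
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`. Delegated to
#' `vegan::mantel`.
#'
#' @param d1,d2 square symmetric matrices (or `dist` objects) over the same
#'   samples, `n >= 4`; if both carry dimnames the sample sets must match.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with elements `r` and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop_mdm("distance matrices cover different samples",
               class = "mdmbench_validation_error")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  if (nrow(d1) < 4 || any(dim(d1) != dim(d2)))
    stop_mdm("need matching square matrices with n >= 4",
             class = "mdmbench_validation_error")
  fit <- with_seed(seed,
                   vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                                 method = "pearson", permutations = n_perm))
  list(r = unname(fit$statistic), p = unname(fit$signif))
}

#' Calibration of estimated unknown abundance against the truth
#'
#' Ordinary least-squares fit of the estimated unknown fraction on the true
#' unknown fraction across samples. A slope of 1 means perfectly calibrated
#' dark-matter estimation; profilers in practice fall well below.
#'
#' @param true_unknown,estimated_unknown numeric vectors in `[0, 1]`, equal
#'   length >= 2.
#' @return named numeric vector `c(slope, intercept)`.
#' @export
unknown_calibration_slope <- function(true_unknown, estimated_unknown) {
  stopifnot(length(true_unknown) == length(estimated_unknown),
            length(true_unknown) >= 2)
  if (any(true_unknown < 0 | true_unknown > 1 |
            estimated_unknown < 0 | estimated_unknown > 1))
    stop_mdm("unknown fractions must lie in [0, 1]",
             class = "mdmbench_validation_error")
  if (length(unique(true_unknown)) < 2)
    stop_mdm("constant true unknown vector: slope undefined",
             class = "mdmbench_undefined_signal")
  fit <- lm(estimated_unknown ~ true_unknown)
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' All-versus-all Bray-Curtis distance matrix
#'
#' @param profiles named list of `rank_profile`s or named numeric vectors,
#'   each summing to 1.
#' @return symmetric matrix with zero diagonal and sample dimnames.
#' @export
bray_curtis_matrix <- function(profiles) {
  keys <- Reduce(union, lapply(profiles, function(p) names(profile_vector(p))))
  m <- t(vapply(profiles, function(p) {
    v <- profile_vector(p)[keys]
    ifelse(is.na(v), 0, v)
  }, numeric(length(keys))))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(names(profiles), names(profiles))
  d
}

#' Write/read a square distance matrix as TSV with header row and column
#'
#' @param d square matrix with dimnames.
#' @param path file path.
#' @return `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
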