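#' Evaluate one assigned profile against the truth across ranks
#'
#' For each evaluation rank the truth is restricted to NCBI-available taxa
#' ([restrict_truth_to_available()]) and the assigned profile is
#' post-processed ([postprocess_assigned()]); precision/recall/F1,
#' Bray-Curtis dissimilarity and intersection-over-union are then computed
#' on the two normalized rank profiles. Degenerate profiles (nothing
#' survives restriction or post-processing at a rank) yield `NA` metrics
#' and `degenerate = TRUE` rather than an error.
#'
#' @param assigned an `assigned_profile` keyed by taxon id.
#' @param truth a `true_profile` keyed by genome id.
#' @param catalog a `genome_catalog`.
#' @param taxonomy a `taxonomy_table`.
#' @param ranks ranks to evaluate (default phylum/family/genus/species).
#' @param theta abundance threshold (default 0.0005).
#' @param threshold_truth also apply `theta` to the restricted truth
#'   (default `FALSE`: the truth is exact by construction; set `TRUE` to
#'   post-process both sides identically, e.g. for identity checks).
#' @return data.frame with one row per rank: `rank`, `precision`, `recall`,
#'   `f1`, `bray_curtis`, `iou`, `degenerate`.
#' @export
evaluate_sample <- function(assigned, truth, catalog, taxonomy,
                            ranks = EVAL_RANKS, theta = 0.0005,
                            threshold_truth = FALSE) {
  rows <- lapply(ranks, function(r) {
    out <- data.frame(rank = r, precision = NA_real_, recall = NA_real_,
                      f1 = NA_real_, bray_curtis = NA_real_, iou = NA_real_,
                      degenerate = FALSE, stringsAsFactors = FALSE)
    res <- tryCatch({
      tr <- restrict_truth_to_available(truth, r, catalog)
      if (threshold_truth) {
        keep <- tr$entries >= theta
        if (!any(keep))
          stop_mdm("truth degenerate under threshold",
                   class = "mdmbench_degenerate_profile")
        tr <- rank_profile(tr$entries[keep] / sum(tr$entries[keep]), r, "truth")
      }
      as_ <- postprocess_assigned(assigned, r, taxonomy, theta)
      prf <- precision_recall_f1(as_, tr)
      list(prf = prf, bc = bray_curtis(as_, tr), iou = iou(as_, tr))
    }, mdmbench_degenerate_profile = function(e) NULL)
    if (is.null(res)) out$degenerate <- TRUE
    else {
      out$precision <- res$prf[["precision"]]
      out$recall <- res$prf[["recall"]]
      out$f1 <- res$prf[["f1"]]
      out$bray_curtis <- res$bc
      out$iou <- res$iou
    }
    out
  })
  do.call(rbind, rows)
}

#' Estimated unknown abundance of an assigned profile at species level
#'
#' After thresholding, the estimated dark-matter fraction is the declared
#' unknown mass plus mass on unknown-labeled or unmappable keys plus mass
#' that cannot be aggregated to a species-level taxon.
#'
#' @inheritParams evaluate_sample
#' @return estimated unknown fraction in `[0, 1]`.
#' @export
estimated_unknown_fraction <- function(assigned, taxonomy, theta = 0.0005) {
  p <- apply_threshold(assigned, theta)
  keys <- names(p$entries)
  bad <- is_unknown_label(keys) | is.na(suppressWarnings(as.numeric(keys)))
  est <- p$unknown_mass + sum(p$entries[bad])
  ids <- as.integer(keys[!bad])
  if (length(ids)) {
    anc <- vapply(ids, lineage_query, integer(1), rank = "species",
                  taxonomy = taxonomy)
    est <- est + sum(p$entries[!bad][is.na(anc)])
  }
  min(1, est)
}

#' Evaluate a whole dataset: accuracy, community structure, calibration
#'
#' Per-sample rank-wise accuracy via [evaluate_sample()], plus
#' dataset-level community-structure agreement: a Mantel test between the
#' all-sample Bray-Curtis matrices of the true and assigned profiles (full
#' profiles, no unmappable-removal — naming is irrelevant for structure), a
#' Spearman correlation of inverse Simpson alpha diversities, and the
#' unknown-abundance calibration slope.
#'
#' @param assigned_list named list of `assigned_profile`s (one per sample).
#' @param truth_list named list of `true_profile`s (same names).
#' @param catalog a `genome_catalog`.
#' @param taxonomy a `taxonomy_table`.
#' @param theta abundance threshold.
#' @param n_perm Mantel permutations.
#' @param seed seed for the Mantel permutations.
#' @return list with `per_sample` (tidy data.frame: sample, rank, metric,
#'   value) and `dataset` (data.frame: metric, value).
#' @export
evaluate_dataset <- function(assigned_list, truth_list, catalog, taxonomy,
                             theta = 0.0005, n_perm = 999, seed = 1L) {
  stopifnot(setequal(names(assigned_list), names(truth_list)),
            length(assigned_list) >= 1)
  samples <- names(assigned_list)

  per_sample <- do.call(rbind, lapply(samples, function(s) {
    df <- evaluate_sample(assigned_list[[s]], truth_list[[s]], catalog,
                          taxonomy, theta = theta)
    long <- do.call(rbind, lapply(
      c("precision", "recall", "f1", "bray_curtis", "iou", "degenerate"),
      function(m) data.frame(sample = s, rank = df$rank, metric = m,
                             value = as.numeric(df[[m]]),
                             stringsAsFactors = FALSE)))
    long
  }))

  dataset <- data.frame(metric = character(0), value = numeric(0))
  if (length(samples) >= 4) {
    truth_vecs <- lapply(truth_list, `[[`, "abundances")
    assigned_vecs <- lapply(assigned_list, function(a) {
      p <- apply_threshold(a, theta)
      p$entries / sum(p$entries)
    })
    d_true <- bray_curtis_matrix(truth_vecs)
    d_assigned <- bray_curtis_matrix(assigned_vecs)
    mt <- mantel_test(d_true, d_assigned, n_perm = n_perm, seed = seed)
    dataset <- rbind(dataset,
                     data.frame(metric = c("mantel_r", "mantel_p"),
                                value = c(mt$r, mt$p)))
  }
  if (length(samples) >= 3) {
    a_true <- vapply(truth_list, function(tp)
      diversity_index(tp$abundances), numeric(1))
    a_assigned <- vapply(assigned_list, function(a) {
      p <- apply_threshold(a, theta)
      diversity_index(p$entries / sum(p$entries))
    }, numeric(1))
    rho <- tryCatch(spearman(a_true, a_assigned),
                    mdmbench_undefined_signal = function(e) NA_real_)
    dataset <- rbind(dataset,
                     data.frame(metric = "alpha_spearman", value = rho))
  }
  if (length(samples) >= 2) {
    tu <- vapply(truth_list, `[[`, numeric(1), "unknown_mass")
    eu <- vapply(assigned_list, estimated_unknown_fraction, numeric(1),
                 taxonomy = taxonomy, theta = theta)
    sl <- tryCatch(unknown_calibration_slope(tu, eu),
                   mdmbench_undefined_signal = function(e)
                     c(slope = NA_real_, intercept = NA_real_))
    dataset <- rbind(dataset,
                     data.frame(metric = c("unknown_slope", "unknown_intercept"),
                                value = as.numeric(sl)))
  }
  list(per_sample = per_sample, dataset = dataset)
}

#' Build a species-level assigned profile from the simulation truth
#'
#' Maps a genome-keyed `true_profile` onto taxonomy ids: each genome
#' contributes at its `available_rank` (genomes known only to family appear
#' as their family id, emulating a best-possible profiler that cannot name
#' what the taxonomy lacks), or, with `oracle = TRUE`, at its deepest
#' assigned rank regardless of availability. Feeding the `oracle = FALSE`
#' version back through evaluation is the identity path: F1 = 1, BC = 0,
#' IOU = 1 at every rank.
#'
#' @param truth a `true_profile`.
#' @param catalog a `genome_catalog`.
#' @param oracle use the full lineage rather than the available part.
#' @return an `assigned_profile` keyed by taxon id.
#' @export
truth_as_assigned <- function(truth, catalog, oracle = FALSE) {
  rec <- catalog$records
  m <- match(names(truth$abundances), rec$genome_id)
  stopifnot(!anyNA(m))
  key <- vapply(seq_along(m), function(i) {
    row <- rec[m[i], ]
    ranks <- if (oracle) CANONICAL_RANKS else
      CANONICAL_RANKS[rank_depth(CANONICAL_RANKS) <=
                        rank_depth(row$available_rank)]
    ids <- unlist(row[paste0("taxid_", ranks)])
    deepest <- which(!is.na(ids))
    if (!length(deepest)) NA_character_
    else as.character(ids[max(deepest)])
  }, "")
  ab <- truth$abundances
  ok <- !is.na(key)
  v <- tapply(ab[ok], key[ok], sum)
  assigned_profile(setNames(as.numeric(v), names(v)), rank = "species",
                   unknown_mass = sum(ab[!ok]))
}
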