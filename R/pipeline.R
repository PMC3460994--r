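#' Run the full proximity analysis on a catalog
#'
#' The composite pipeline behind the study design: build the mask, fit and
#' smooth the per-bin expected model, compute Hi-C scores, assign
#' compartments (gene-content oriented), score the catalog's proximity,
#' run the group and per-translocation permutation tests, and assemble a
#' dataset summary table (mean observed and permuted scores, permutation
#' and rank-sum p-values, individually significant and unique pair counts,
#' genome and trans-bin coverage).
#'
#' @param pairs Parsed catalog pairs ([parse_karyotype_catalog()] /
#'   [breakpoints_to_pairs()] output; only `status == "ok"` rows are used).
#' @param map A `contact_map`.
#' @param bands Cytoband tibble (for centromere masking).
#' @param genes Gene intervals (orientation anchor and gene-content
#'   features).
#' @param config A [perm_config()].
#' @param smoothing_window Expected-model smoothing window (bins).
#' @param pseudocount Hi-C score pseudocount.
#' @param out_dir Optional directory: when given, writes the mask, score
#'   triplets, compartment track, proximity TSV, test TSVs, and summary.
#' @return List with `mask`, `expected`, `scores`, `track`, `proximity`,
#'   `group`, `individual`, `coverage`, and the one-row-per-dataset
#'   `summary` tibble.
#' @export
analyze_catalog <- function(pairs, map, bands, genes, config = perm_config(),
                            smoothing_window = 3, pseudocount = 1,
                            out_dir = NULL) {
  scheme <- map$scheme
  mask <- build_mask(map, bands)
  expected <- smooth_expected(expected_trans(map, mask), smoothing_window)
  scores <- hic_score(map, expected, mask, pseudocount)
  orientation <- gene_content_track(scheme, genes)
  track <- compartment_track(scores, orientation)
  pairs_ok <- unique_pairs(ok_pairs(pairs))
  prox <- proximity_scores(pairs_ok, scores)
  group <- perm_group_test(pairs_ok, scores, config, genes = genes, track = track)
  indiv <- perm_individual_test(pairs_ok, scores, config, genes = genes, track = track)
  coverage <- dataset_coverage(pairs_ok, scheme, mask)
  ds <- if ("dataset_id" %in% names(prox)) unique(prox$dataset_id) else "catalog"
  summary <- tibble::tibble(
    dataset_id = paste(ds, collapse = ","),
    n_unique_pairs = nrow(pairs_ok),
    mean_score = group$observed_mean,
    mean_permuted = mean(group$null_means),
    permutation_p = group$p_value,
    rank_sum_p = group$rank_sum_p,
    t_test_p = group$t_test_p,
    n_individual_significant = sum(indiv$significant, na.rm = TRUE),
    pct_genome_covered = 100 * coverage$genome_fraction,
    pct_interactions_covered = 100 * coverage$trans_bin_fraction
  )
  out <- list(
    mask = mask, expected = expected, scores = scores, track = track,
    proximity = prox, group = group, individual = indiv,
    coverage = coverage, summary = summary
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf(
      "hictrans %s | method=%d n_perms=%d seed=%s statistic=%s",
      as.character(utils::packageVersion("hictrans")),
      config$method, config$n_perms,
      ifelse(is.null(config$seed), "NULL", config$seed), config$statistic
    )
    write_mask(mask, file.path(out_dir, "mask.tsv"))
    write_contact_triplets(
      structure(list(scheme = scheme, blocks = scores$blocks), class = "contact_map"),
      file.path(out_dir, "scores.tsv"), hdr
    )
    write_compartment_track(track, file.path(out_dir, "compartments.tsv"))
    write_proximity(prox, file.path(out_dir, "proximity.tsv"))
    readr::write_tsv(glance(group), file.path(out_dir, "group_test.tsv"))
    readr::write_tsv(
      indiv[, setdiff(names(indiv), "status")],
      file.path(out_dir, "individual_test.tsv")
    )
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  out
}

#' Cumulative score-distribution plot for a group test
#'
#' Compares the empirical cumulative distribution of observed per-pair
#' statistics against the pooled permuted statistics.
#'
#' @param group A `perm_group_test`.
#' @param permuted Optional numeric vector of pooled permuted statistics;
#'   defaults to the replicate means (a coarser view).
#' @return A ggplot.
#' @export
plot_score_cdf <- function(group, permuted = NULL) {
  if (is.null(permuted)) permuted <- group$null_means
  df <- dplyr::bind_rows(
    tibble::tibble(score = group$observed[!is.na(group$observed)], set = "observed"),
    tibble::tibble(score = permuted, set = "permuted")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$score, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "proximity score", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}
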