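#' Proximity scores for translocation pairs
#'
#' The proximity score of a translocation is the mean Hi-C score over the
#' full 2-D block of trans bin pairs spanned by its two partner regions
#' (every unmasked bin of region A against every unmasked bin of region B).
#' Masked bin pairs are excluded and counted; a pair whose block holds no
#' scored bin pair gets an explicit missing score.
#'
#' @param pairs Pair tibble (columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`; rows rejected by the parsers are
#'   ignored).
#' @param scores A `hic_scores` object ([hic_score()]).
#' @return The input rows with `proximity_score`, `n_bin_pairs_used`, and
#'   `n_bin_pairs_masked` appended; undefined scores are `NA`.
#' @export
proximity_scores <- function(pairs, scores) {
  pairs <- ok_pairs(pairs)
  pairs <- pairs[!is.na(pairs$chrom_a), ]
  if (nrow(pairs) == 0) stop("no scorable pairs", call. = FALSE)
  if (any(pairs$chrom_a == pairs$chrom_b)) {
    stop("proximity scores are defined for inter-chromosomal pairs only", call. = FALSE)
  }
  engine <- build_score_engine(scores)
  scheme <- scores$scheme
  ra <- region_bin_range(scheme, pairs$chrom_a, pairs$start_a, pairs$end_a)
  rb <- region_bin_range(scheme, pairs$chrom_b, pairs$start_b, pairs$end_b)
  st <- engine_block_stats(
    engine, pairs$chrom_a, ra$first_bin, ra$last_bin,
    pairs$chrom_b, rb$first_bin, rb$last_bin
  )
  out <- tibble::as_tibble(pairs)
  out$proximity_score <- ifelse(st$n > 0, st$sum / st$n, NA_real_)
  out$n_bin_pairs_used <- as.integer(st$n)
  out$n_bin_pairs_masked <- as.integer(st$total - st$n)
  out
}

#' Summarise proximity scores per dataset
#'
#' @param results Tibble from [proximity_scores()]; grouped by `dataset_id`
#'   when that column is present. Pairs with undefined scores are excluded
#'   (and counted in `n_undefined`).
#' @return Tibble with `n_pairs`, `mean_score`, and the normal-approximation
#'   95% confidence interval `ci95_low`/`ci95_high`
#'   (mean +/- 1.96 * sd / sqrt(n)).
#' @export
summarize_dataset <- function(results) {
  grp <- if ("dataset_id" %in% names(results)) "dataset_id" else character()
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$proximity_score)),
      n_undefined = sum(is.na(.data$proximity_score)),
      mean_score = mean(.data$proximity_score, na.rm = TRUE),
      sem = stats::sd(.data$proximity_score, na.rm = TRUE) / sqrt(.data$n_pairs),
      .groups = "drop"
    )
  if (any(out$n_pairs < 2)) {
    stop("need at least 2 defined proximity scores per dataset", call. = FALSE)
  }
  out$ci95_low <- out$mean_score - 1.96 * out$sem
  out$ci95_high <- out$mean_score + 1.96 * out$sem
  out$sem <- NULL
  out
}

#' Per-pair feature scores (gene content or compartment)
#'
#' Averages a per-region genomic feature over a translocation's two partner
#' regions: gene content (fraction of bases covered by transcripts) or
#' chromatin compartment score (mean PC1 of overlapping bins).
#'
#' @param pairs Pair tibble.
#' @param feature `"gene_content"` or `"compartment"`.
#' @param genes Transcript intervals (required for gene content).
#' @param track A `compartment_track` (required for compartment).
#' @return Input rows with a `feature_score` column (`NA` when either
#'   region's feature is undefined).
#' @export
feature_scores <- function(pairs, feature = c("gene_content", "compartment"),
                           genes = NULL, track = NULL) {
  feature <- match.arg(feature)
  pairs <- ok_pairs(pairs)
  pairs <- pairs[!is.na(pairs$chrom_a), ]
  reg_a <- tibble::tibble(chrom = pairs$chrom_a, start = pairs$start_a, end = pairs$end_a)
  reg_b <- tibble::tibble(chrom = pairs$chrom_b, start = pairs$start_b, end = pairs$end_b)
  if (feature == "gene_content") {
    if (is.null(genes)) stop("gene content needs gene intervals", call. = FALSE)
    fa <- gene_content(reg_a, genes)
    fb <- gene_content(reg_b, genes)
  } else {
    if (is.null(track)) stop("compartment feature needs a compartment track", call. = FALSE)
    fa <- region_compartment_score(reg_a, track)
    fb <- region_compartment_score(reg_b, track)
  }
  out <- tibble::as_tibble(pairs)
  out$feature_score <- (fa + fb) / 2
  out
}

#' Write proximity results
#'
#' @param results Tibble from [proximity_scores()].
#' @param file Output TSV path.
#' @export
write_proximity <- function(results, file) {
  cols <- intersect(
    c(
      "dataset_id", "source_label", "chrom_a", "start_a", "end_a",
      "chrom_b", "start_b", "end_b", "proximity_score",
      "n_bin_pairs_used", "n_bin_pairs_masked"
    ),
    names(results)
  )
  readr::write_tsv(results[, cols], file)
}
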