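#' First principal eigenvector of a chromosome's trans contact correlation
#'
#' Builds the matrix of the chromosome's unmasked bins against all unmasked
#' bins on the other chromosomes, computes the Pearson correlation matrix
#' between the chromosome's bin rows, and returns the eigenvector of the
#' largest eigenvalue (PC1, unit norm). The sign is fixed so that PC1
#' correlates non-negatively with an orientation reference (gene content by
#' default): positive values mark the open (A) compartment, negative the
#' closed (B) compartment.
#'
#' @param scores A `hic_scores` object.
#' @param chrom Chromosome to decompose (needs >= 3 unmasked bins).
#' @param orientation Per-bin reference values for the chromosome's bins: a
#'   tibble with `chrom`, `bin`, `value` (only this chromosome's rows are
#'   used). Bins without a reference value are treated as 0 for orientation.
#' @return Tibble `chrom`, `bin`, `start`, `end`, `pc1` over the bins that
#'   entered the decomposition. Constant (degenerate) rows are dropped with
#'   a warning; an all-constant matrix is an error.
#' @export
compartment_pc1 <- function(scores, chrom, orientation) {
  scheme <- scores$scheme
  mv <- mask_vectors(scores$mask, scheme)
  keep <- which(!mv[[chrom]])
  if (length(keep) < 3) {
    stop("need at least 3 unmasked bins on ", chrom, call. = FALSE)
  }
  others <- setdiff(scheme$chroms$chrom, chrom)
  cols <- lapply(others, function(oc) {
    blk <- map_block(scores, chrom, oc)
    blk[keep, !mv[[oc]], drop = FALSE]
  })
  M <- do.call(cbind, cols)
  # drop columns from uncomputable chromosome pairs (all NA)
  M <- M[, colSums(is.finite(M)) == nrow(M), drop = FALSE]
  if (ncol(M) < 2) stop("too few scored trans bins for ", chrom, call. = FALSE)
  sds <- apply(M, 1, stats::sd)
  degen <- sds == 0 | !is.finite(sds)
  if (any(degen)) {
    if (all(degen)) {
      stop("degenerate correlation: all bin rows constant on ", chrom, call. = FALSE)
    }
    warning(sum(degen), " constant bin row(s) dropped on ", chrom, call. = FALSE)
    keep <- keep[!degen]
    M <- M[!degen, , drop = FALSE]
  }
  # column-center: removes any residual partner-bin bias shared by all rows,
  # which would otherwise inflate every row-row correlation uniformly
  M <- sweep(M, 2, colMeans(M))
  sds2 <- apply(M, 1, stats::sd)
  if (all(sds2 == 0)) {
    stop("degenerate correlation: all bin rows constant on ", chrom, call. = FALSE)
  }
  C <- stats::cor(t(M))
  ev <- eigen(C, symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  ref <- rep(0, length(keep))
  sel <- orientation$chrom == chrom & orientation$bin %in% keep
  ref[match(orientation$bin[sel], keep)] <- orientation$value[sel]
  rho <- suppressWarnings(stats::cor(pc1, ref))
  if (is.finite(rho) && rho < 0) pc1 <- -pc1
  bs <- scheme$bin_size
  tibble::tibble(
    chrom = chrom, bin = keep,
    start = (keep - 1) * bs,
    end = pmin(keep * bs, chrom_length(scheme, chrom)),
    pc1 = pc1
  )
}

#' Genome-wide compartment track
#'
#' Runs [compartment_pc1()] on every chromosome with enough unmasked bins.
#'
#' @param scores A `hic_scores` object.
#' @param orientation Per-bin orientation reference (`chrom`, `bin`,
#'   `value`); use [gene_content_track()] for the gene-content default.
#' @return A `compartment_track` tibble: `chrom`, `bin`, `start`, `end`,
#'   `pc1`.
#' @export
compartment_track <- function(scores, orientation) {
  out <- purrr::map_dfr(
    scores$scheme$chroms$chrom,
    function(ch) compartment_pc1(scores, ch, orientation)
  )
  class(out) <- c("compartment_track", class(out))
  out
}

#' Per-bin gene content orientation reference
#'
#' @param scheme A [bin_scheme()].
#' @param genes Transcript intervals.
#' @return Tibble `chrom`, `bin`, `value` (fraction of the bin covered).
#' @export
gene_content_track <- function(scheme, genes) {
  cov <- gene_bin_coverage(scheme, genes)
  bins <- scheme_bins(scheme)
  tibble::tibble(
    chrom = cov$chrom, bin = cov$bin,
    value = cov$covered / (bins$end - bins$start)
  )
}

#' Compartment score of regions
#'
#' The compartment score of a region is the arithmetic mean of PC1 over the
#' megabase bins it overlaps; masked bins (absent from the track) are
#' excluded. A region overlapping no scored bin gets `NA`, kept distinct
#' from a true 0.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param track A `compartment_track`.
#' @return Numeric vector of scores.
#' @export
region_compartment_score <- function(regions, track) {
  validate_regions(regions)
  bs <- attr(track, "bin_size")
  # bin width is recoverable from the track itself
  if (is.null(bs)) bs <- max(track$end - track$start)
  purrr::map_dbl(seq_len(nrow(regions)), function(i) {
    sel <- track$chrom == regions$chrom[i] &
      track$start < regions$end[i] & track$end > regions$start[i]
    if (!any(sel)) {
      return(NA_real_)
    }
    mean(track$pc1[sel])
  })
}

#' Classify a compartment score
#'
#' @param score Numeric compartment score(s).
#' @return `"open"` for positive scores (ties at exactly 0 count as open),
#'   `"closed"` for negative; `NA` propagates.
#' @export
compartment_sign <- function(score) {
  ifelse(is.na(score), NA_character_, ifelse(score >= 0, "open", "closed"))
}

#' Write a compartment track as bedGraph-style TSV
#'
#' @param track A `compartment_track`.
#' @param file Output path.
#' @export
write_compartment_track <- function(track, file) {
  readr::write_tsv(track[, c("chrom", "start", "end", "pc1")], file)
}

#' Compartment profile plot
#'
#' @param track A `compartment_track`.
#' @return A ggplot of PC1 along each chromosome, filled by compartment.
#' @export
plot_compartments <- function(track) {
  df <- dplyr::mutate(track, compartment = compartment_sign(.data$pc1))
  ggplot2::ggplot(df, ggplot2::aes(.data$start / 1e6, .data$pc1, fill = .data$compartment)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "PC1 (compartment score)") +
    ggplot2::theme_minimal()
}
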