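#' Read a BED3+ gene annotation
#'
#' Only the first three columns (chrom, start, end) are used; transcripts may
#' overlap freely.
#'
#' @param file Path or character vector of lines.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_genes_bed <- function(file) {
  if (length(file) == 1 && !grepl("\t", file) && file.exists(file)) {
    lines <- readr::read_lines(file)
  } else {
    lines <- file
  }
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("BED parse error: fewer than 3 columns", call. = FALSE)
  tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.numeric(vapply(fields, `[`, character(1), 2)),
    end = as.numeric(vapply(fields, `[`, character(1), 3))
  )
}

#' Fraction of a region covered by genes
#'
#' Gene content of a region is the fraction of its bases covered by the
#' union of transcript intervals (overlapping transcripts counted once),
#' exons and introns alike.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Data frame of transcript intervals (`chrom`, `start`, `end`).
#' @return Numeric vector of fractions in `[0, 1]`, one per region.
#' @export
#' @examples
#' gene_content(
#'   data.frame(chrom = "chr1", start = 0, end = 100),
#'   data.frame(chrom = "chr1", start = c(10, 15), end = c(20, 30))
#' )
gene_content <- function(regions, genes) {
  validate_regions(regions)
  red <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(~ IRanges::reduce(IRanges::IRanges(.x$start + 1, .x$end)),
      .keep = TRUE
    )
  names(red) <- unlist(
    genes |> dplyr::group_by(.data$chrom) |> dplyr::group_keys()
  )
  purrr::map_dbl(seq_len(nrow(regions)), function(i) {
    r <- red[[regions$chrom[i]]]
    if (is.null(r)) {
      return(0)
    }
    q <- IRanges::IRanges(regions$start[i] + 1, regions$end[i])
    ov <- IRanges::intersect(r, q)
    sum(IRanges::width(ov)) / (regions$end[i] - regions$start[i])
  })
}

#' Catalog coverage of the genome and of trans bin space
#'
#' Summarises how much of the assembly, and how many distinct unmasked trans
#' bin pairs, a translocation catalog touches.
#'
#' @param pairs Pair tibble (regions `chrom_a`/`start_a`/... as produced by
#'   the catalog parsers; rejected rows ignored).
#' @param scheme A [bin_scheme()].
#' @param mask Optional mask tibble.
#' @return One-row tibble: `genome_fraction` (bases in the union of all
#'   catalog regions over total assembly length) and `trans_bin_fraction`
#'   (distinct unmasked trans bin pairs covered by any pair's region-a x
#'   region-b block, over all unmasked trans bin pairs).
#' @export
dataset_coverage <- function(pairs, scheme, mask = NULL) {
  pairs <- ok_pairs(pairs)
  pairs <- pairs[!is.na(pairs$chrom_a), ]
  if (nrow(pairs) == 0) stop("empty catalog", call. = FALSE)
  regions <- dplyr::bind_rows(
    tibble::tibble(chrom = pairs$chrom_a, start = pairs$start_a, end = pairs$end_a),
    tibble::tibble(chrom = pairs$chrom_b, start = pairs$start_b, end = pairs$end_b)
  )
  covered <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(~ sum(IRanges::width(
      IRanges::reduce(IRanges::IRanges(.x$start + 1, .x$end))
    ))) |>
    unlist() |>
    sum()
  genome_fraction <- covered / sum(scheme$chroms$length)

  mv <- mask_vectors(mask, scheme)
  flags <- lapply(canonical_pairs(scheme), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    matrix(FALSE, chrom_nbins(scheme, p[1]), chrom_nbins(scheme, p[2]))
  })
  names(flags) <- canonical_pairs(scheme)
  ra <- region_bin_range(scheme, pairs$chrom_a, pairs$start_a, pairs$end_a)
  rb <- region_bin_range(scheme, pairs$chrom_b, pairs$start_b, pairs$end_b)
  for (i in seq_len(nrow(pairs))) {
    key <- pair_key(scheme, pairs$chrom_a[i], pairs$chrom_b[i])
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (pairs$chrom_a[i] == p[1]) {
      flags[[key]][ra$first_bin[i]:ra$last_bin[i], rb$first_bin[i]:rb$last_bin[i]] <- TRUE
    } else {
      flags[[key]][rb$first_bin[i]:rb$last_bin[i], ra$first_bin[i]:ra$last_bin[i]] <- TRUE
    }
  }
  tot_unmasked <- 0
  cov_unmasked <- 0
  for (k in names(flags)) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    un <- outer(!mv[[p[1]]], !mv[[p[2]]], FUN = "&")
    tot_unmasked <- tot_unmasked + sum(un)
    cov_unmasked <- cov_unmasked + sum(flags[[k]] & un)
  }
  tibble::tibble(
    genome_fraction = genome_fraction,
    trans_bin_fraction = cov_unmasked / tot_unmasked
  )
}
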