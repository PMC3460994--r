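#' Define a genome assembly
#'
#' A genome assembly is the ordered set of chromosomes the analysis runs on,
#' with their lengths in base pairs. All coordinates in the package are
#' 0-based half-open, following the UCSC convention.
#'
#' @param chrom Character vector of unique chromosome labels, in order.
#' @param length Positive integer vector of chromosome lengths (bp).
#'
#' @return A tibble with columns `chrom` and `length`, classed
#'   `genome_assembly`.
#' @export
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(20e6, 15e6))
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (length(chrom) != length(length) || any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive and match names", call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  class(out) <- c("genome_assembly", class(out))
  out
}

#' Build a binning scheme over an assembly
#'
#' Partitions every chromosome into fixed-width bins (the last bin of each
#' chromosome may be truncated). Every base maps to exactly one bin, and bins
#' carry both a per-chromosome ordinal (1-based) and a global index.
#'
#' @param assembly A [genome_assembly()].
#' @param bin_size Bin width in bp. Default 1 Mb, the resolution at which
#'   proximity scoring operates.
#'
#' @return An object of class `bin_scheme`: a list with the per-chromosome
#'   table (`chroms`), `bin_size`, and `total_bins`.
#' @export
bin_scheme <- function(assembly, bin_size = 1e6) {
  stopifnot(inherits(assembly, "genome_assembly") || is.data.frame(assembly))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1) {
    stop("bin_size must be a positive number", call. = FALSE)
  }
  n_bins <- as.integer(ceiling(assembly$length / bin_size))
  chroms <- tibble::tibble(
    chrom = assembly$chrom,
    length = assembly$length,
    n_bins = n_bins,
    offset = cumsum(c(0L, n_bins[-length(n_bins)]))
  )
  structure(
    list(chroms = chroms, bin_size = bin_size, total_bins = sum(n_bins)),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(
    "<bin_scheme> ", nrow(x$chroms), " chromosomes, bin size ",
    format(x$bin_size, big.mark = ","), " bp, ", x$total_bins, " bins total\n",
    sep = ""
  )
  invisible(x)
}

#' Enumerate the bins of a scheme
#'
#' @param scheme A [bin_scheme()].
#' @return Tibble with one row per bin: `chrom`, `bin` (1-based ordinal on
#'   its chromosome), `start`, `end` (bp, half-open, end clipped to the
#'   chromosome), and `global_bin`.
#' @export
scheme_bins <- function(scheme) {
  ch <- scheme$chroms
  out <- tidyr::uncount(ch, weights = ch$n_bins, .id = "bin")
  out$bin <- as.integer(out$bin)
  out$start <- (out$bin - 1) * scheme$bin_size
  out$end <- pmin(out$bin * scheme$bin_size, out$length)
  out$global_bin <- out$offset + out$bin
  out[, c("chrom", "bin", "start", "end", "global_bin")]
}

chrom_index <- function(scheme, chrom) {
  idx <- match(chrom, scheme$chroms$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome: ", paste(unique(chrom[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  idx
}

chrom_length <- function(scheme, chrom) {
  scheme$chroms$length[chrom_index(scheme, chrom)]
}

chrom_nbins <- function(scheme, chrom) {
  scheme$chroms$n_bins[chrom_index(scheme, chrom)]
}

#' Map positions to bin ordinals
#'
#' @param scheme A [bin_scheme()].
#' @param chrom,pos Parallel vectors of chromosome labels and 0-based
#'   positions.
#' @return Integer vector of 1-based bin ordinals on each chromosome.
#' @export
bin_of_position <- function(scheme, chrom, pos) {
  len <- chrom_length(scheme, chrom)
  if (any(pos < 0 | pos >= len)) {
    bad <- which(pos < 0 | pos >= len)
    stop("position out of range for ", chrom[bad[1]], ": ", pos[bad[1]],
      call. = FALSE
    )
  }
  as.integer(pos %/% scheme$bin_size) + 1L
}

#' Snap a region to whole bins
#'
#' Regions are snapped outward to whole bins (floor of the start, ceiling of
#' the end) before any bin-level computation, so a region counts every bin it
#' overlaps.
#'
#' @param scheme A [bin_scheme()].
#' @param chrom,start,end Parallel region vectors (0-based half-open bp).
#' @return Tibble with `first_bin`, `last_bin` (1-based ordinals, inclusive)
#'   and `width_bins`.
#' @export
region_bin_range <- function(scheme, chrom, start, end) {
  len <- chrom_length(scheme, chrom)
  if (any(start < 0 | end > len | start >= end)) {
    stop("invalid region: need 0 <= start < end <= chromosome length", call. = FALSE)
  }
  first <- as.integer(start %/% scheme$bin_size) + 1L
  last <- as.integer(ceiling(end / scheme$bin_size))
  tibble::tibble(
    first_bin = first, last_bin = last,
    width_bins = last - first + 1L
  )
}

validate_regions <- function(regions, assembly = NULL) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(regions))) {
    stop("regions need columns chrom, start, end", call. = FALSE)
  }
  if (any(regions$start < 0) || any(regions$start >= regions$end)) {
    stop("regions must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(assembly)) {
    len <- assembly$length[match(regions$chrom, assembly$chrom)]
    if (anyNA(len)) stop("region on unknown chromosome", call. = FALSE)
    if (any(regions$end > len)) stop("region end beyond chromosome length", call. = FALSE)
  }
  invisible(regions)
}

# canonical chromosome-pair key: lower assembly index first
pair_key <- function(scheme, chrom1, chrom2) {
  i1 <- chrom_index(scheme, chrom1)
  i2 <- chrom_index(scheme, chrom2)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  paste(scheme$chroms$chrom[lo], scheme$chroms$chrom[hi], sep = "|")
}
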