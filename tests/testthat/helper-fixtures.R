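# Shared fixture builders. Everything is constructed in code; no data files.

toy_assembly <- function(n_chrom = 2, length_mb = 10) {
  genome_assembly(paste0("chr", seq_len(n_chrom)), rep(length_mb * 1e6, n_chrom))
}

# a hic_scores object built directly from score matrices, bypassing the
# expected-model pipeline (for unit tests of downstream consumers)
scores_from_blocks <- function(scheme, blocks, mask = NULL) {
  structure(
    list(scheme = scheme, blocks = blocks, pseudocount = 1, mask = mask),
    class = "hic_scores"
  )
}

# mask tibble from (chrom, bin) pairs
mask_from_bins <- function(scheme, chrom, bin, reason = "no_coverage") {
  bs <- scheme$bin_size
  tibble::tibble(
    chrom = chrom, bin = as.integer(bin),
    start = (bin - 1) * bs,
    end = pmin(bin * bs, scheme$chroms$length[match(chrom, scheme$chroms$chrom)]),
    reason = reason
  )
}

# small two-chromosome score fixture with known values
two_chrom_scores <- function(n1 = 10, n2 = 10, fill = 0, mask = NULL) {
  asm <- genome_assembly(c("chr1", "chr2"), c(n1 * 1e6, n2 * 1e6))
  scheme <- bin_scheme(asm)
  blocks <- list("chr1|chr2" = matrix(fill, n1, n2))
  list(
    scheme = scheme,
    scores = scores_from_blocks(scheme, blocks, mask)
  )
}

# simple cytoband text for a 2 x 10 Mb genome: p arm 2 bands, acen, q arm 2
toy_cytoband_lines <- function(chroms = c("chr1", "chr2")) {
  unlist(lapply(chroms, function(ch) {
    c(
      paste(ch, "0", "2000000", "p22", "gneg", sep = "\t"),
      paste(ch, "2000000", "4000000", "p21", "gpos50", sep = "\t"),
      paste(ch, "4000000", "5000000", "q11", "acen", sep = "\t"),
      paste(ch, "5000000", "8000000", "q21", "gneg", sep = "\t"),
      paste(ch, "8000000", "10000000", "q22", "gpos50", sep = "\t")
    )
  }))
}

# catalog pair row from explicit regions
make_pair <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b,
                      dataset_id = "toy", ...) {
  tibble::tibble(
    source_label = paste0(chrom_a, ":", start_a, "-", chrom_b, ":", start_b),
    status = "ok",
    chrom_a = chrom_a, start_a = start_a, end_a = end_a,
    chrom_b = chrom_b, start_b = start_b, end_b = end_b,
    dataset_id = dataset_id, ...
  )
}

# independent brute-force proximity oracle: double loop over the bin block
oracle_proximity <- function(scores, pair) {
  scheme <- scores$scheme
  ra <- region_bin_range(scheme, pair$chrom_a, pair$start_a, pair$end_a)
  rb <- region_bin_range(scheme, pair$chrom_b, pair$start_b, pair$end_b)
  vals <- c()
  for (i in ra$first_bin:ra$last_bin) {
    for (j in rb$first_bin:rb$last_bin) {
      blk <- map_block(scores, pair$chrom_a, pair$chrom_b)
      vals <- c(vals, blk[i, j])
    }
  }
  list(mean = mean(vals, na.rm = TRUE), n = sum(!is.na(vals)))
}

# textbook Benjamini-Hochberg step-up, written independently of the package
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
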