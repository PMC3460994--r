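# Internal prefix-sum engines. All block statistics used by proximity
# scoring and permutation testing reduce to sums over contiguous bin
# ranges, so each score block gets a padded 2-D cumulative table (values
# with NA as 0, plus a defined-cell counter) and each per-bin track gets a
# padded 1-D cumulative vector. A block mean then costs eight lookups
# regardless of region size, which is what makes thousands of permutation
# draws per pair affordable.

cumsum2_pad <- function(M) {
  out <- matrix(0, nrow(M) + 1, ncol(M) + 1)
  if (nrow(M) > 0 && ncol(M) > 0) {
    out[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  }
  out
}

build_score_engine <- function(scores) {
  scheme <- scores$scheme
  blocks <- lapply(scores$blocks, function(S) {
    def <- is.finite(S)
    list(
      P = cumsum2_pad(ifelse(def, S, 0)),
      N = cumsum2_pad(def * 1)
    )
  })
  mv <- mask_vectors(scores$mask, scheme)
  mp <- lapply(mv, function(v) c(0, cumsum(v)))
  list(scheme = scheme, blocks = blocks, mask_prefix = mp, mask_vectors = mv)
}

# vectorized block sum/count for bin ranges [fa,la] x [fb,lb]
engine_block_stats <- function(engine, chrom_a, fa, la, chrom_b, fb, lb) {
  scheme <- engine$scheme
  n <- length(chrom_a)
  s <- numeric(n)
  cnt <- numeric(n)
  i1 <- chrom_index(scheme, chrom_a)
  i2 <- chrom_index(scheme, chrom_b)
  swap <- i1 > i2
  key <- pair_key(scheme, chrom_a, chrom_b)
  r0 <- ifelse(swap, fb, fa)
  r1 <- ifelse(swap, lb, la)
  c0 <- ifelse(swap, fa, fb)
  c1 <- ifelse(swap, la, lb)
  for (k in unique(key)) {
    sel <- which(key == k)
    blk <- engine$blocks[[k]]
    a <- r0[sel]
    b <- r1[sel] + 1
    cc <- c0[sel]
    d <- c1[sel] + 1
    s[sel] <- blk$P[cbind(b, d)] - blk$P[cbind(a, d)] -
      blk$P[cbind(b, cc)] + blk$P[cbind(a, cc)]
    cnt[sel] <- blk$N[cbind(b, d)] - blk$N[cbind(a, d)] -
      blk$N[cbind(b, cc)] + blk$N[cbind(a, cc)]
  }
  list(sum = s, n = cnt, total = (la - fa + 1) * (lb - fb + 1))
}

# per-bin track engine: prefix sums of a value (NA -> 0), a defined
# counter, and base-pair bin lengths
build_track_engine <- function(scheme, chrom, bin, value) {
  bins <- scheme_bins(scheme)
  vals <- lapply(seq_len(nrow(scheme$chroms)), function(i) {
    rep(NA_real_, scheme$chroms$n_bins[i])
  })
  names(vals) <- scheme$chroms$chrom
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    vals[[ch]][bin[sel]] <- value[sel]
  }
  lens <- split(bins$end - bins$start, bins$chrom)[scheme$chroms$chrom]
  list(
    scheme = scheme,
    val = lapply(vals, function(v) c(0, cumsum(ifelse(is.na(v), 0, v)))),
    cnt = lapply(vals, function(v) c(0, cumsum(!is.na(v)))),
    bp = lapply(lens, function(l) c(0, cumsum(l)))
  )
}

# mean of a track over bin range [f,l]; NaN when no defined bin
track_range_mean <- function(engine, chrom, f, l) {
  s <- numeric(length(chrom))
  n <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s[sel] <- engine$val[[ch]][l[sel] + 1] - engine$val[[ch]][f[sel]]
    n[sel] <- engine$cnt[[ch]][l[sel] + 1] - engine$cnt[[ch]][f[sel]]
  }
  ifelse(n > 0, s / n, NA_real_)
}

# total of a track over bin range divided by its base-pair span
track_range_density <- function(engine, chrom, f, l) {
  s <- numeric(length(chrom))
  bp <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s[sel] <- engine$val[[ch]][l[sel] + 1] - engine$val[[ch]][f[sel]]
    bp[sel] <- engine$bp[[ch]][l[sel] + 1] - engine$bp[[ch]][f[sel]]
  }
  s / bp
}

# masked-bin count over bin range
masked_in_range <- function(engine, chrom, f, l) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- engine$mask_prefix[[ch]][l[sel] + 1] - engine$mask_prefix[[ch]][f[sel]]
  }
  out
}

# per-bin gene coverage (bases of each bin covered by the transcript union)
gene_bin_coverage <- function(scheme, genes) {
  bins <- scheme_bins(scheme)
  cov <- numeric(nrow(bins))
  if (!is.null(genes) && nrow(genes) > 0) {
    for (ch in unique(genes$chrom)) {
      sel_b <- which(bins$chrom == ch)
      if (length(sel_b) == 0) next
      g <- genes[genes$chrom == ch, ]
      red <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
      q <- IRanges::IRanges(bins$start[sel_b] + 1, bins$end[sel_b])
      ov <- IRanges::findOverlaps(q, red)
      if (length(ov) > 0) {
        qh <- S4Vectors::queryHits(ov)
        w <- IRanges::width(IRanges::pintersect(q[qh], red[S4Vectors::subjectHits(ov)]))
        agg <- rowsum(w, qh)
        cov[sel_b[as.integer(rownames(agg))]] <- agg[, 1]
      }
    }
  }
  tibble::tibble(chrom = bins$chrom, bin = bins$bin, covered = cov)
}
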