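#' Fine-mapping configuration
#'
#' Thresholds for the hierarchical breakpoint search: a 1-Mb candidate bin,
#' a 3-Mb read window around it, a 50-kb corner with a one-quadrant decay
#' signature, and optional 1-kb refinement.
#'
#' @param min_window_reads Minimum reads in the 3-Mb window to attempt a
#'   corner call (default 200).
#' @param min_refine_reads Minimum reads in the 50-kb corner bin to attempt
#'   1-kb refinement (default 20).
#' @param signature_threshold Minimum fraction of window reads in the
#'   winning quadrant (default 0.6; 0.25 is the uniform expectation).
#' @param decay_threshold Maximum Spearman correlation of the marginal read
#'   profile with distance from the corner, along both open directions
#'   (default -0.5).
#' @param z_threshold Genome scan flag threshold in SDs above the
#'   chromosome pair's mean unmasked count (default 8).
#' @param window_span Window width in bp (default 3 Mb, the candidate bin
#'   plus 1 Mb on each side).
#' @param fine_bin,refine_bin Corner and refinement bin sizes (50 kb, 1 kb).
#' @return A `finemap_config` list.
#' @export
finemap_config <- function(min_window_reads = 200, min_refine_reads = 20,
                           signature_threshold = 0.6, decay_threshold = -0.5,
                           z_threshold = 8, window_span = 3e6,
                           fine_bin = 5e4, refine_bin = 1e3) {
  structure(
    list(
      min_window_reads = min_window_reads, min_refine_reads = min_refine_reads,
      signature_threshold = signature_threshold, decay_threshold = decay_threshold,
      z_threshold = z_threshold, window_span = window_span,
      fine_bin = fine_bin, refine_bin = refine_bin
    ),
    class = "finemap_config"
  )
}

#' Strongest trans bin of a chromosome pair
#'
#' Finds the 1-Mb bin pair with the highest (optionally expected-normalized)
#' count; ties break to the lowest `(bin1, bin2)` index.
#'
#' @param map A `contact_map`.
#' @param chrom1,chrom2 Chromosome pair.
#' @param expected Optional `expected_model`; when supplied the argmax is
#'   taken over `O/E` (strong signals agree with the raw argmax).
#' @return One-row tibble: bins, bp bounds, raw `count`, and the maximized
#'   `value`.
#' @export
max_trans_bin <- function(map, chrom1, chrom2, expected = NULL) {
  O <- map_block(map, chrom1, chrom2)
  val <- O
  if (!is.null(expected)) {
    E <- map_block(expected, chrom1, chrom2)
    val <- ifelse(is.finite(E) & E > 0, O / E, NA_real_)
  }
  if (all(is.na(val)) || max(val, na.rm = TRUE) <= 0) {
    stop("no trans signal on ", chrom1, "/", chrom2, call. = FALSE)
  }
  mx <- max(val, na.rm = TRUE)
  hits <- which(val == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- unname(hits[1, 1])
  j <- unname(hits[1, 2])
  bs <- map$scheme$bin_size
  tibble::tibble(
    chrom1 = chrom1, bin1 = as.integer(i),
    start1 = (i - 1) * bs, end1 = pmin(i * bs, chrom_length(map$scheme, chrom1)),
    chrom2 = chrom2, bin2 = as.integer(j),
    start2 = (j - 1) * bs, end2 = pmin(j * bs, chrom_length(map$scheme, chrom2)),
    count = O[i, j], value = mx
  )
}

#' Reads inside the fine-mapping window
#'
#' Selects reads with both ends inside the window centered on a candidate
#' 1-Mb bin pair (the bin plus equal margins to `window_span`, clipped at
#' chromosome ends). Read records with the pair's chromosomes in either
#' order are normalized so `x` lies on `chrom1`.
#'
#' @param reads Read-pair tibble (`chrom1`, `pos1`, `chrom2`, `pos2`).
#' @param scheme A [bin_scheme()].
#' @param center One-row tibble from [max_trans_bin()] (or with the same
#'   `chrom1`/`bin1`/`chrom2`/`bin2` columns).
#' @param config A [finemap_config()].
#' @return Tibble with `x`, `y` positions, carrying the window bounds as
#'   attributes `x_range` and `y_range`.
#' @export
window_reads <- function(reads, scheme, center, config = finemap_config()) {
  bs <- scheme$bin_size
  margin <- (config$window_span - bs) / 2
  x0 <- max(0, (center$bin1 - 1) * bs - margin)
  x1 <- min(chrom_length(scheme, center$chrom1), center$bin1 * bs + margin)
  y0 <- max(0, (center$bin2 - 1) * bs - margin)
  y1 <- min(chrom_length(scheme, center$chrom2), center$bin2 * bs + margin)
  fwd <- reads$chrom1 == center$chrom1 & reads$chrom2 == center$chrom2
  rev <- reads$chrom1 == center$chrom2 & reads$chrom2 == center$chrom1 &
    center$chrom1 != center$chrom2
  x <- c(reads$pos1[fwd], reads$pos2[rev])
  y <- c(reads$pos2[fwd], reads$pos1[rev])
  keep <- x >= x0 & x < x1 & y >= y0 & y < y1
  out <- tibble::tibble(x = x[keep], y = y[keep])
  attr(out, "x_range") <- c(x0, x1)
  attr(out, "y_range") <- c(y0, y1)
  attr(out, "chroms") <- c(center$chrom1, center$chrom2)
  out
}

# marginal profile decay check: counts per fine bin moving away from the
# corner along one axis's open direction
marginal_decay <- function(pos, corner_lo, corner_hi, lim_lo, lim_hi, sign_open, bin) {
  if (sign_open > 0) {
    k <- floor((pos - corner_lo) / bin)
    K <- ceiling((lim_hi - corner_lo) / bin)
  } else {
    k <- ceiling((corner_hi - pos) / bin) - 1
    K <- ceiling((corner_hi - lim_lo) / bin)
  }
  if (K < 3) {
    return(NA_real_)
  }
  counts <- tabulate(k + 1, nbins = K)
  if (stats::sd(counts) == 0) {
    return(NA_real_)
  }
  suppressWarnings(stats::cor(counts, seq_len(K), method = "spearman"))
}

#' Detect the unbalanced-translocation corner signature
#'
#' Bins the window reads at 50 kb, takes the count-argmax bin as the
#' candidate corner, and scores each of the four quadrant orientations
#' (`++`, `+-`, `-+`, `--`; `+` opens toward increasing coordinates) by the
#' fraction of window reads in the quadrant the orientation opens from that
#' corner (corner bin inclusive). A call requires the winning signature to
#' reach `signature_threshold` and both marginal profiles to decay away
#' from the corner (Spearman correlation with distance at most
#' `decay_threshold`).
#'
#' @param window Read window from [window_reads()].
#' @param config A [finemap_config()].
#' @return One-row tibble: `status` (`"ok"`, `"no_call"`, or
#'   `"insufficient_coverage"`), `orientation`, corner bin bounds
#'   (`corner_start1` ... `corner_end2`), `signature_score`, `decay_ok`,
#'   `window_read_count`, `corner_read_count`.
#' @export
corner_detect <- function(window, config = finemap_config()) {
  xr <- attr(window, "x_range")
  yr <- attr(window, "y_range")
  fb <- config$fine_bin
  n <- nrow(window)
  empty <- tibble::tibble(
    status = "insufficient_coverage", orientation = NA_character_,
    corner_start1 = NA_real_, corner_end1 = NA_real_,
    corner_start2 = NA_real_, corner_end2 = NA_real_,
    signature_score = NA_real_, decay_ok = NA,
    window_read_count = n, corner_read_count = NA_integer_
  )
  if (n < config$min_window_reads) {
    return(empty)
  }
  gx <- floor(window$x / fb)
  gy <- floor(window$y / fb)
  gx0 <- floor(xr[1] / fb)
  gy0 <- floor(yr[1] / fb)
  nx <- floor((xr[2] - 1e-9) / fb) - gx0 + 1
  ny <- floor((yr[2] - 1e-9) / fb) - gy0 + 1
  cnt <- matrix(0L, nx, ny)
  idx <- cbind(gx - gx0 + 1, gy - gy0 + 1)
  agg <- rowsum(rep(1L, n), (idx[, 2] - 1) * nx + idx[, 1])
  cnt[as.integer(rownames(agg))] <- agg[, 1]
  mx <- max(cnt)
  hits <- which(cnt == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  cx0 <- (gx0 + unname(hits[1, 1]) - 1) * fb
  cx1 <- cx0 + fb
  cy0 <- (gy0 + unname(hits[1, 2]) - 1) * fb
  cy1 <- cy0 + fb
  orients <- c("++", "+-", "-+", "--")
  sig <- vapply(orients, function(o) {
    sx <- if (substr(o, 1, 1) == "+") 1 else -1
    sy <- if (substr(o, 2, 2) == "+") 1 else -1
    in_x <- if (sx > 0) window$x >= cx0 else window$x < cx1
    in_y <- if (sy > 0) window$y >= cy0 else window$y < cy1
    sum(in_x & in_y) / n
  }, numeric(1))
  best <- orients[which.max(sig)]
  sx <- if (substr(best, 1, 1) == "+") 1 else -1
  sy <- if (substr(best, 2, 2) == "+") 1 else -1
  in_x <- if (sx > 0) window$x >= cx0 else window$x < cx1
  in_y <- if (sy > 0) window$y >= cy0 else window$y < cy1
  quad <- window[in_x & in_y, ]
  rho_x <- marginal_decay(quad$x, cx0, cx1, xr[1], xr[2], sx, fb)
  rho_y <- marginal_decay(quad$y, cy0, cy1, yr[1], yr[2], sy, fb)
  decay_ok <- !is.na(rho_x) && !is.na(rho_y) &&
    rho_x <= config$decay_threshold && rho_y <= config$decay_threshold
  called <- sig[best] >= config$signature_threshold && decay_ok
  tibble::tibble(
    status = if (called) "ok" else "no_call", orientation = best,
    corner_start1 = cx0, corner_end1 = cx1,
    corner_start2 = cy0, corner_end2 = cy1,
    signature_score = unname(sig[best]), decay_ok = decay_ok,
    window_read_count = n,
    corner_read_count = sum(window$x >= cx0 & window$x < cx1 &
      window$y >= cy0 & window$y < cy1)
  )
}

#' Refine a corner call to 1-kb bins
#'
#' Counts reads in 1-kb bins inside the 50-kb corner bin; refinement is
#' attempted when the corner holds at least `min_refine_reads` reads
#' (boundary inclusive), otherwise the call stays at 50 kb with status
#' `"sparse"`.
#'
#' @param window Read window from [window_reads()].
#' @param corner One-row tibble from [corner_detect()].
#' @param config A [finemap_config()].
#' @return One-row tibble: `refinement_status` (`"refined"`/`"sparse"`),
#'   and for refined calls the 1-kb bin bounds `refined_start1` ...
#'   `refined_end2`.
#' @export
refine_1kb <- function(window, corner, config = finemap_config()) {
  rb <- config$refine_bin
  inc <- window$x >= corner$corner_start1 & window$x < corner$corner_end1 &
    window$y >= corner$corner_start2 & window$y < corner$corner_end2
  sub <- window[inc, ]
  if (nrow(sub) < config$min_refine_reads) {
    return(tibble::tibble(
      refinement_status = "sparse",
      refined_start1 = NA_real_, refined_end1 = NA_real_,
      refined_start2 = NA_real_, refined_end2 = NA_real_
    ))
  }
  kx <- floor((sub$x - corner$corner_start1) / rb)
  ky <- floor((sub$y - corner$corner_start2) / rb)
  nk <- ceiling((corner$corner_end1 - corner$corner_start1) / rb)
  cnt <- matrix(0L, nk, nk)
  agg <- rowsum(rep(1L, nrow(sub)), ky * nk + kx + 1)
  cnt[as.integer(rownames(agg))] <- agg[, 1]
  hits <- which(cnt == max(cnt), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  tibble::tibble(
    refinement_status = "refined",
    refined_start1 = corner$corner_start1 + (unname(hits[1, 1]) - 1) * rb,
    refined_end1 = corner$corner_start1 + unname(hits[1, 1]) * rb,
    refined_start2 = corner$corner_start2 + (unname(hits[1, 2]) - 1) * rb,
    refined_end2 = corner$corner_start2 + unname(hits[1, 2]) * rb
  )
}

#' Scan all chromosome pairs for translocation candidates
#'
#' Flags, per chromosome pair, the maximal unmasked bin when its count
#' exceeds the pair's mean by `z_threshold` standard deviations.
#'
#' @param map A `contact_map`.
#' @param mask Optional mask tibble.
#' @param config A [finemap_config()].
#' @return Tibble of flagged candidates (`chrom1`, `bin1`, `chrom2`,
#'   `bin2`, `count`, `z`), sorted by decreasing `z`; empty when nothing is
#'   flagged.
#' @export
scan_genome <- function(map, mask = NULL, config = finemap_config()) {
  mv <- mask_vectors(mask, map$scheme)
  out <- purrr::map_dfr(names(map$blocks), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    O <- map$blocks[[k]]
    keep <- outer(!mv[[p[1]]], !mv[[p[2]]], FUN = "&")
    v <- O[keep]
    if (length(v) < 2) {
      return(NULL)
    }
    mu <- mean(v)
    s <- stats::sd(v)
    if (s == 0) {
      return(NULL)
    }
    Ok <- ifelse(keep, O, -Inf)
    mx <- max(Ok)
    z <- (mx - mu) / s
    if (z <= config$z_threshold) {
      return(NULL)
    }
    hits <- which(Ok == mx, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    tibble::tibble(
      chrom1 = p[1], bin1 = as.integer(unname(hits[1, 1])),
      chrom2 = p[2], bin2 = as.integer(unname(hits[1, 2])),
      count = mx, z = z
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(
      chrom1 = character(), bin1 = integer(), chrom2 = character(),
      bin2 = integer(), count = numeric(), z = numeric()
    ))
  }
  dplyr::arrange(out, dplyr::desc(.data$z))
}

#' Hierarchical fine-mapping of unbalanced translocations
#'
#' End-to-end pipeline over read-level data: bin reads at the scheme's
#' resolution, scan chromosome pairs (or take supplied candidates), extract
#' the 3-Mb window around each maximal bin, call the 50-kb corner signature,
#' and refine to 1 kb where coverage allows.
#'
#' @param reads Read-pair tibble.
#' @param scheme A [bin_scheme()].
#' @param config A [finemap_config()].
#' @param bands Optional cytoband tibble for centromere masking during the
#'   scan.
#' @param candidates Optional tibble of chromosome pairs to fine-map
#'   (columns `chrom1`, `chrom2`); defaults to the genome scan's flags.
#' @return BEDPE-style tibble: one row per investigated candidate with the
#'   coarse bin, corner call, signature diagnostics, and refinement.
#' @export
finemap_breakpoints <- function(reads, scheme, config = finemap_config(),
                                bands = NULL, candidates = NULL) {
  map <- bin_read_pairs(reads, scheme)
  if (is.null(candidates)) {
    mask <- build_mask(map, bands)
    candidates <- scan_genome(map, mask, config)
  }
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      chrom1 = character(), start1 = numeric(), end1 = numeric(),
      chrom2 = character(), start2 = numeric(), end2 = numeric(),
      orientation = character(), signature_score = numeric(),
      window_reads = integer(), corner_reads = integer(),
      status = character(), refinement_status = character()
    ))
  }
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    center <- max_trans_bin(map, candidates$chrom1[i], candidates$chrom2[i])
    win <- window_reads(reads, scheme, center, config)
    corner <- corner_detect(win, config)
    ref <- if (identical(corner$status, "ok")) {
      refine_1kb(win, corner, config)
    } else {
      tibble::tibble(
        refinement_status = corner$status,
        refined_start1 = NA_real_, refined_end1 = NA_real_,
        refined_start2 = NA_real_, refined_end2 = NA_real_
      )
    }
    tibble::tibble(
      chrom1 = center$chrom1, start1 = corner$corner_start1, end1 = corner$corner_end1,
      chrom2 = center$chrom2, start2 = corner$corner_start2, end2 = corner$corner_end2,
      coarse_bin1 = center$bin1, coarse_bin2 = center$bin2,
      orientation = corner$orientation,
      signature_score = corner$signature_score,
      window_reads = corner$window_read_count,
      corner_reads = corner$corner_read_count,
      status = corner$status,
      refinement_status = ref$refinement_status,
      refined_start1 = ref$refined_start1, refined_end1 = ref$refined_end1,
      refined_start2 = ref$refined_start2, refined_end2 = ref$refined_end2
    )
  })
}

#' Write fine-mapping calls as BEDPE-style TSV
#'
#' @param calls Tibble from [finemap_breakpoints()].
#' @param file Output path.
#' @export
write_breakpoint_calls <- function(calls, file) {
  readr::write_tsv(calls, file)
}
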