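#' @keywords internal
# A contact map stores, for every canonical chromosome pair (lower assembly
# index first), a dense bins-x-bins matrix of trans contact counts. Dense
# blocks are the right trade-off at the megabase resolutions this package
# targets (tens to a few hundred bins per chromosome).
new_contact_map <- function(scheme, blocks) {
  structure(list(scheme = scheme, blocks = blocks), class = "contact_map")
}

canonical_pairs <- function(scheme) {
  ch <- scheme$chroms$chrom
  if (length(ch) < 2) {
    return(character())
  }
  cp <- utils::combn(ch, 2)
  paste(cp[1, ], cp[2, ], sep = "|")
}

empty_blocks <- function(scheme) {
  keys <- canonical_pairs(scheme)
  out <- lapply(keys, function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    matrix(0, chrom_nbins(scheme, p[1]), chrom_nbins(scheme, p[2]))
  })
  names(out) <- keys
  out
}

#' Retrieve one chromosome pair's count block
#'
#' @param map A `contact_map` (or object with the same block layout).
#' @param chrom1,chrom2 Chromosome labels; the returned matrix has `chrom1`
#'   bins as rows regardless of storage order.
#' @return Numeric matrix of counts (or scores).
#' @export
map_block <- function(map, chrom1, chrom2) {
  scheme <- map$scheme
  i1 <- chrom_index(scheme, chrom1)
  i2 <- chrom_index(scheme, chrom2)
  if (i1 == i2) stop("trans maps hold no cis blocks", call. = FALSE)
  key <- pair_key(scheme, chrom1, chrom2)
  blk <- map$blocks[[key]]
  if (is.null(blk)) stop("no block stored for ", key, call. = FALSE)
  if (i1 < i2) blk else t(blk)
}

#' @export
print.contact_map <- function(x, ...) {
  tot <- sum(vapply(x$blocks, sum, numeric(1)))
  cat("<contact_map> ", length(x$blocks), " chromosome pairs, ",
    format(tot, big.mark = ","), " total counts\n",
    sep = ""
  )
  invisible(x)
}

#' Read a sparse triplet contact file
#'
#' Triplet format: tab-separated `chrom1 start1 chrom2 start2 count`, starts
#' bin-aligned, `#` lines are comments. Duplicate triplets are summed.
#'
#' @param file Path or character vector of lines.
#' @param scheme A [bin_scheme()].
#' @return A `contact_map`.
#' @export
read_contact_triplets <- function(file, scheme) {
  if (length(file) == 1 && !grepl("\t", file) && file.exists(file)) {
    lines <- readr::read_lines(file)
  } else {
    lines <- file
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  blocks <- empty_blocks(scheme)
  if (length(lines) == 0) {
    return(new_contact_map(scheme, blocks))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 5)) {
    stop("triplet parse error: expected 5 columns at line ",
      which(lengths(fields) != 5)[1],
      call. = FALSE
    )
  }
  m <- matrix(unlist(fields), ncol = 5, byrow = TRUE)
  start1 <- as.numeric(m[, 2])
  start2 <- as.numeric(m[, 4])
  count <- as.numeric(m[, 5])
  if (anyNA(start1) || anyNA(start2) || anyNA(count)) {
    stop("triplet parse error: non-numeric field", call. = FALSE)
  }
  if (any(count < 0)) stop("negative contact count", call. = FALSE)
  if (any(start1 %% scheme$bin_size != 0) || any(start2 %% scheme$bin_size != 0)) {
    stop("triplet start not aligned to bin size ", scheme$bin_size, call. = FALSE)
  }
  df <- tibble::tibble(
    chrom1 = m[, 1], bin1 = bin_of_position(scheme, m[, 1], start1),
    chrom2 = m[, 3], bin2 = bin_of_position(scheme, m[, 3], start2),
    count = count
  )
  accumulate_pairs(blocks, scheme, df)
}

# add (chrom1, bin1, chrom2, bin2, count) rows into canonical blocks
accumulate_pairs <- function(blocks, scheme, df) {
  i1 <- chrom_index(scheme, df$chrom1)
  i2 <- chrom_index(scheme, df$chrom2)
  if (any(i1 == i2)) stop("cis record in trans map", call. = FALSE)
  swap <- i1 > i2
  ra <- ifelse(swap, df$bin2, df$bin1)
  rb <- ifelse(swap, df$bin1, df$bin2)
  key <- pair_key(scheme, df$chrom1, df$chrom2)
  for (k in unique(key)) {
    sel <- key == k
    blk <- blocks[[k]]
    idx <- (rb[sel] - 1) * nrow(blk) + ra[sel]
    agg <- rowsum(df$count[sel], idx)
    blk[as.integer(rownames(agg))] <- blk[as.integer(rownames(agg))] + agg[, 1]
    blocks[[k]] <- blk
  }
  new_contact_map(scheme, blocks)
}

#' Bin read pairs into a contact map
#'
#' Each read pair increments exactly one bin pair at the scheme's
#' resolution; cis pairs (same chromosome) are excluded.
#'
#' @param reads Data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (0-based positions). Extra columns (strands) are ignored.
#' @param scheme A [bin_scheme()].
#' @param chroms Optional chromosome filter: keep only pairs with both ends
#'   on these chromosomes.
#' @return A `contact_map`.
#' @export
bin_read_pairs <- function(reads, scheme, chroms = NULL) {
  req <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(req %in% names(reads))) {
    stop("read pairs need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!is.null(chroms)) {
    reads <- reads[reads$chrom1 %in% chroms & reads$chrom2 %in% chroms, ]
  }
  reads <- reads[reads$chrom1 != reads$chrom2, ]
  blocks <- empty_blocks(scheme)
  if (nrow(reads) == 0) {
    return(new_contact_map(scheme, blocks))
  }
  df <- tibble::tibble(
    chrom1 = reads$chrom1, bin1 = bin_of_position(scheme, reads$chrom1, reads$pos1),
    chrom2 = reads$chrom2, bin2 = bin_of_position(scheme, reads$chrom2, reads$pos2),
    count = 1
  )
  accumulate_pairs(blocks, scheme, df)
}

#' Tidy a contact map into triplets
#'
#' @param x A `contact_map`.
#' @param keep_zero Keep zero-count cells? Default `FALSE`.
#' @param ... Unused.
#' @return Tibble `chrom1`, `start1`, `chrom2`, `start2`, `count`.
#' @export
tidy.contact_map <- function(x, keep_zero = FALSE, ...) {
  scheme <- x$scheme
  bs <- scheme$bin_size
  purrr::map_dfr(names(x$blocks), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    blk <- x$blocks[[k]]
    keep <- if (keep_zero) which(is.finite(blk)) else which(blk != 0)
    if (length(keep) == 0) {
      return(NULL)
    }
    i <- (keep - 1) %% nrow(blk) + 1
    j <- (keep - 1) %/% nrow(blk) + 1
    tibble::tibble(
      chrom1 = p[1], start1 = (i - 1) * bs,
      chrom2 = p[2], start2 = (j - 1) * bs,
      count = blk[keep]
    )
  })
}

#' Write a contact map as triplet text
#'
#' @param map A `contact_map`.
#' @param file Output path.
#' @param header Optional comment lines (written with a leading `#`).
#' @export
write_contact_triplets <- function(map, file, header = NULL) {
  df <- tidy(map)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%g", df$chrom1, as.integer(df$start1),
    df$chrom2, as.integer(df$start2), df$count
  )
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  readr::write_lines(lines, file)
}

#' Build the analysis mask for a contact map
#'
#' Bins are masked when they overlap a centromeric (`acen`) band, or when
#' they have zero total contact count across every partner chromosome in the
#' dataset. A bin can carry both reasons.
#'
#' @param map A `contact_map`.
#' @param bands Cytoband tibble (may be empty for no centromere masking).
#' @return Tibble `chrom`, `bin`, `start`, `end`, `reason` (one row per bin
#'   and reason; reasons are `"centromere"` and `"no_coverage"`).
#' @export
build_mask <- function(map, bands = NULL) {
  scheme <- map$scheme
  bins <- scheme_bins(scheme)
  # total coverage of each bin over all stored partners
  cov <- stats::setNames(numeric(nrow(bins)), paste(bins$chrom, bins$bin))
  for (k in names(map$blocks)) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    blk <- map$blocks[[k]]
    cov[paste(p[1], seq_len(nrow(blk)))] <-
      cov[paste(p[1], seq_len(nrow(blk)))] + rowSums(blk)
    cov[paste(p[2], seq_len(ncol(blk)))] <-
      cov[paste(p[2], seq_len(ncol(blk)))] + colSums(blk)
  }
  no_cov <- bins[cov == 0, ]
  cen <- NULL
  if (!is.null(bands) && nrow(bands) > 0) {
    acen <- bands[bands$stain == "acen", ]
    if (nrow(acen) > 0) {
      hit <- purrr::map_lgl(seq_len(nrow(bins)), function(i) {
        any(acen$chrom == bins$chrom[i] &
          acen$start < bins$end[i] & acen$end > bins$start[i])
      })
      cen <- bins[hit, ]
    }
  }
  out <- dplyr::bind_rows(
    if (!is.null(cen) && nrow(cen) > 0) dplyr::mutate(cen, reason = "centromere"),
    if (nrow(no_cov) > 0) dplyr::mutate(no_cov, reason = "no_coverage")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(
      chrom = character(), bin = integer(), start = numeric(),
      end = numeric(), reason = character()
    ))
  }
  dplyr::arrange(
    out[, c("chrom", "bin", "start", "end", "reason")],
    .data$chrom, .data$bin, .data$reason
  )
}

# logical masked-vector per chromosome
mask_vectors <- function(mask, scheme) {
  out <- lapply(seq_len(nrow(scheme$chroms)), function(i) {
    rep(FALSE, scheme$chroms$n_bins[i])
  })
  names(out) <- scheme$chroms$chrom
  if (!is.null(mask) && nrow(mask) > 0) {
    for (ch in unique(mask$chrom)) {
      out[[ch]][unique(mask$bin[mask$chrom == ch])] <- TRUE
    }
  }
  out
}

#' Write a mask track
#'
#' @param mask Mask tibble from [build_mask()].
#' @param file Output path (TSV: chrom, start, end, reason).
#' @export
write_mask <- function(mask, file) {
  readr::write_tsv(mask[, c("chrom", "start", "end", "reason")], file)
}

#' Per-bin expected trans contact counts
#'
#' Fits the per-bin coverage model: within each chromosome pair, with
#' unmasked marginals \eqn{m_i = \sum_j O(i,j)} and total \eqn{T},
#' \eqn{E(i,j) = m_i m_j / T}. This absorbs multiplicative per-bin biases
#' (coverage, mappability, restriction-site density) and conserves the
#' block total exactly. An optional iterative variant alternates marginal
#' rebalancing for strictly stronger bias removal.
#'
#' @param map A `contact_map`.
#' @param mask Mask tibble ([build_mask()]); masked bins are excluded from
#'   marginals and carry no expected value.
#' @param method `"marginal"` (default) or `"iterative"`.
#' @param iterations,tol Iterative variant controls.
#' @return An `expected_model`: block layout as the map, `NA` outside the
#'   unmasked set; chromosome pairs with zero unmasked total are flagged
#'   uncomputable (all-`NA` block).
#' @export
expected_trans <- function(map, mask = NULL, method = c("marginal", "iterative"),
                           iterations = 10, tol = 1e-6) {
  method <- match.arg(method)
  scheme <- map$scheme
  mv <- mask_vectors(mask, scheme)
  uncomputable <- character()
  blocks <- lapply(names(map$blocks), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    O <- map$blocks[[k]]
    keep_r <- !mv[[p[1]]]
    keep_c <- !mv[[p[2]]]
    E <- matrix(NA_real_, nrow(O), ncol(O))
    Ouse <- O[keep_r, keep_c, drop = FALSE]
    tot <- sum(Ouse)
    if (tot == 0 || !any(keep_r) || !any(keep_c)) {
      uncomputable <<- c(uncomputable, k)
      return(E)
    }
    mi <- rowSums(Ouse)
    mj <- colSums(Ouse)
    Eu <- outer(mi, mj) / tot
    if (method == "iterative") {
      for (it in seq_len(iterations)) {
        rs <- rowSums(Eu)
        Eu <- Eu * ifelse(rs > 0, mi / rs, 0)
        cs <- colSums(Eu)
        Eu <- sweep(Eu, 2, ifelse(cs > 0, mj / cs, 0), "*")
        if (max(abs(rowSums(Eu) - mi)) < tol * max(1, max(mi))) break
      }
      Eu <- Eu * (tot / sum(Eu))
    }
    E[keep_r, keep_c] <- Eu
    E
  })
  names(blocks) <- names(map$blocks)
  structure(
    list(
      scheme = scheme, blocks = blocks, mask = mask,
      provenance = paste0(method, "-product"), uncomputable = uncomputable,
      sum_obs = vapply(names(map$blocks), function(k) {
        p <- strsplit(k, "|", fixed = TRUE)[[1]]
        sum(map$blocks[[k]][!mv[[p[1]]], !mv[[p[2]]], drop = FALSE])
      }, numeric(1))
    ),
    class = "expected_model"
  )
}

#' Linearly smooth an expected model
#'
#' Replaces each defined expected value by the mean of defined values in a
#' `window` x `window` bin neighborhood (undefined / masked cells excluded
#' from the mean), then rescales each chromosome pair so the expected total
#' again equals the observed total.
#'
#' @param model An `expected_model`.
#' @param window Odd window width in bins (default 3; 1 is the identity).
#' @return The smoothed `expected_model` (provenance `"smoothed"`).
#' @export
smooth_expected <- function(model, window = 3) {
  if (window < 1 || window %% 2 != 1) {
    stop("smoothing window must be odd and >= 1", call. = FALSE)
  }
  if (window == 1) {
    return(model)
  }
  h <- (window - 1) / 2
  blocks <- lapply(names(model$blocks), function(k) {
    E <- model$blocks[[k]]
    def <- is.finite(E)
    if (!any(def)) {
      return(E)
    }
    E0 <- ifelse(def, E, 0)
    num <- matrix(0, nrow(E), ncol(E))
    den <- matrix(0, nrow(E), ncol(E))
    for (di in -h:h) {
      ri <- seq_len(nrow(E)) + di
      okr <- ri >= 1 & ri <= nrow(E)
      for (dj in -h:h) {
        cj <- seq_len(ncol(E)) + dj
        okc <- cj >= 1 & cj <= ncol(E)
        num[okr, okc] <- num[okr, okc] + E0[ri[okr], cj[okc], drop = FALSE]
        den[okr, okc] <- den[okr, okc] + def[ri[okr], cj[okc], drop = FALSE]
      }
    }
    Es <- matrix(NA_real_, nrow(E), ncol(E))
    ok <- def & den > 0
    Es[ok] <- num[ok] / den[ok]
    tot <- model$sum_obs[[k]]
    s <- sum(Es[ok])
    if (s > 0 && tot > 0) Es[ok] <- Es[ok] * (tot / s)
    Es
  })
  names(blocks) <- names(model$blocks)
  model$blocks <- blocks
  model$provenance <- "smoothed"
  model
}

#' Compute the Hi-C score map
#'
#' The Hi-C score of a trans bin pair is the log2 enrichment of observed
#' over expected contacts, \eqn{S = \log_2((O + c)/(E + c))}, with
#' pseudocount `c` stabilising zero-count bins. Scores exist only on
#' unmasked bin pairs of computable chromosome pairs.
#'
#' @param map A `contact_map`.
#' @param model Matching `expected_model`.
#' @param mask Mask tibble; defaults to the model's.
#' @param pseudocount Pseudocount `c` (default 1). `c = 0` is allowed only
#'   when every scored bin has a positive observed count.
#' @return A `hic_scores` object (block layout of the map, `NA` where no
#'   score is defined).
#' @export
hic_score <- function(map, model, mask = model$mask, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  mv <- mask_vectors(mask, map$scheme)
  blocks <- lapply(names(map$blocks), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    O <- map$blocks[[k]]
    E <- model$blocks[[k]]
    S <- matrix(NA_real_, nrow(O), ncol(O))
    def <- is.finite(E)
    def[mv[[p[1]]], ] <- FALSE
    def[, mv[[p[2]]]] <- FALSE
    if (pseudocount == 0 && any(O[def] == 0)) {
      stop("pseudocount 0 with zero observed counts: score undefined", call. = FALSE)
    }
    S[def] <- log2((O[def] + pseudocount) / (E[def] + pseudocount))
    S
  })
  names(blocks) <- names(map$blocks)
  structure(
    list(
      scheme = map$scheme, blocks = blocks, pseudocount = pseudocount,
      mask = mask
    ),
    class = "hic_scores"
  )
}

#' @export
print.hic_scores <- function(x, ...) {
  v <- unlist(lapply(x$blocks, function(b) b[is.finite(b)]))
  cat("<hic_scores> ", length(x$blocks), " chromosome pairs, ",
    length(v), " scored bin pairs, mean ", signif(mean(v), 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a score map into triplets
#'
#' @param x A `hic_scores` object.
#' @param ... Unused.
#' @return Tibble `chrom1`, `start1`, `chrom2`, `start2`, `score` over
#'   defined bin pairs.
#' @export
tidy.hic_scores <- function(x, ...) {
  bs <- x$scheme$bin_size
  purrr::map_dfr(names(x$blocks), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    blk <- x$blocks[[k]]
    keep <- which(is.finite(blk))
    if (length(keep) == 0) {
      return(NULL)
    }
    i <- (keep - 1) %% nrow(blk) + 1
    j <- (keep - 1) %/% nrow(blk) + 1
    tibble::tibble(
      chrom1 = p[1], start1 = (i - 1) * bs,
      chrom2 = p[2], start2 = (j - 1) * bs, score = blk[keep]
    )
  })
}

#' Look up scores for bin pairs
#'
#' @param scores A `hic_scores` object.
#' @param chrom1,bin1,chrom2,bin2 Parallel vectors (1-based bin ordinals).
#' @return Numeric scores (`NA` where undefined).
#' @export
score_at <- function(scores, chrom1, bin1, chrom2, bin2) {
  purrr::map_dbl(seq_along(chrom1), function(i) {
    blk <- map_block(scores, chrom1[i], chrom2[i])
    blk[bin1[i], bin2[i]]
  })
}

#' Heatmap of one chromosome pair's scores
#'
#' @param object A `hic_scores` object.
#' @param chrom1,chrom2 Chromosome pair to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_scores <- function(object, chrom1, chrom2, ...) {
  blk <- map_block(object, chrom1, chrom2)
  df <- tidyr::expand_grid(
    bin1 = seq_len(nrow(blk)),
    bin2 = seq_len(ncol(blk))
  )
  df$score <- blk[cbind(df$bin1, df$bin2)]
  ggplot2::ggplot(df, ggplot2::aes(.data$bin2, .data$bin1, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red", na.value = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = paste(chrom2, "bin"), y = paste(chrom1, "bin"),
      fill = "Hi-C score"
    ) +
    ggplot2::theme_minimal()
}
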