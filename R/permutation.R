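#' Permutation test configuration
#'
#' The four null constructions randomize a translocation's partner regions
#' while preserving their chromosomes and bin sizes:
#' \describe{
#'   \item{Method 1}{both regions re-placed uniformly on their own
#'     chromosomes (controls chromosome-pair association);}
#'   \item{Method 2}{one region fixed, the partner re-placed on the
#'     partner's own chromosome;}
#'   \item{Method 3}{one region fixed, the partner re-placed uniformly over
#'     every placement on any other chromosome;}
#'   \item{Method 4}{one region fixed, the partner drawn from the catalog's
#'     own set of partner regions on other chromosomes, keeping the drawn
#'     region's size.}
#' }
#' A candidate region is rejected and redrawn when at least
#' `validity_threshold` of its bins are masked (centromere or no coverage).
#' With `compartment_control`, candidates must additionally have a
#' compartment score of the same sign as the region they replace.
#'
#' @param method Null construction, 1-4.
#' @param n_perms Number of permutation draws (default 1000).
#' @param compartment_control Constrain draws to the same compartment sign?
#' @param validity_threshold Maximum masked fraction of a candidate region
#'   (default 0.5, i.e. fewer than half the bins masked).
#' @param max_attempts Rejection-sampling budget per needed draw.
#' @param seed Integer seed; identical seed and config reproduce identical
#'   results bit for bit.
#' @param statistic Per-pair statistic: `"proximity"` (block-mean Hi-C
#'   score), `"gene_content"`, or `"compartment"`.
#' @return A `perm_config` list.
#' @export
perm_config <- function(method = 1, n_perms = 1000, compartment_control = FALSE,
                        validity_threshold = 0.5, max_attempts = 1000,
                        seed = NULL,
                        statistic = c("proximity", "gene_content", "compartment")) {
  statistic <- match.arg(statistic)
  if (!method %in% 1:4) stop("method must be 1, 2, 3 or 4", call. = FALSE)
  if (n_perms < 1) stop("n_perms must be >= 1", call. = FALSE)
  if (validity_threshold <= 0 || validity_threshold > 1) {
    stop("validity_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      method = as.integer(method), n_perms = as.integer(n_perms),
      compartment_control = isTRUE(compartment_control),
      validity_threshold = validity_threshold,
      max_attempts = as.integer(max_attempts), seed = seed,
      statistic = statistic
    ),
    class = "perm_config"
  )
}

# assemble engines, snapped catalog ranges, and the method-4 pool
perm_context <- function(pairs, scores, config, genes = NULL, track = NULL) {
  pairs <- ok_pairs(pairs)
  pairs <- pairs[!is.na(pairs$chrom_a), ]
  if (nrow(pairs) == 0) stop("no usable pairs", call. = FALSE)
  scheme <- scores$scheme
  engine <- build_score_engine(scores)
  ra <- region_bin_range(scheme, pairs$chrom_a, pairs$start_a, pairs$end_a)
  rb <- region_bin_range(scheme, pairs$chrom_b, pairs$start_b, pairs$end_b)
  gene_eng <- NULL
  if (config$statistic == "gene_content") {
    if (is.null(genes)) stop("gene_content statistic needs gene intervals", call. = FALSE)
    cov <- gene_bin_coverage(scheme, genes)
    gene_eng <- build_track_engine(scheme, cov$chrom, cov$bin, cov$covered)
  }
  comp_eng <- NULL
  if (config$statistic == "compartment" || config$compartment_control) {
    if (is.null(track)) {
      stop("compartment statistic/control needs a compartment track", call. = FALSE)
    }
    comp_eng <- build_track_engine(scheme, track$chrom, track$bin, track$pc1)
  }
  pool <- tibble::tibble(
    chrom = c(pairs$chrom_a, pairs$chrom_b),
    first = c(ra$first_bin, rb$first_bin),
    last = c(ra$last_bin, rb$last_bin)
  )
  list(
    pairs = pairs, scheme = scheme, engine = engine, config = config,
    gene_eng = gene_eng, comp_eng = comp_eng, pool = pool,
    fa = ra$first_bin, la = ra$last_bin, wa = ra$width_bins,
    fb = rb$first_bin, lb = rb$last_bin, wb = rb$width_bins
  )
}

# vectorized per-pair statistic over parallel region vectors
ctx_pair_stat <- function(ctx, ca, fa, la, cb, fb, lb) {
  switch(ctx$config$statistic,
    proximity = {
      st <- engine_block_stats(ctx$engine, ca, fa, la, cb, fb, lb)
      ifelse(st$n > 0, st$sum / st$n, NA_real_)
    },
    gene_content = (track_range_density(ctx$gene_eng, ca, fa, la) +
      track_range_density(ctx$gene_eng, cb, fb, lb)) / 2,
    compartment = (track_range_mean(ctx$comp_eng, ca, fa, la) +
      track_range_mean(ctx$comp_eng, cb, fb, lb)) / 2
  )
}

ctx_region_sign <- function(ctx, chrom, f, l) {
  v <- track_range_mean(ctx$comp_eng, chrom, f, l)
  ifelse(is.na(v), NA_real_, ifelse(v >= 0, 1, -1))
}

# n placements of width-w regions on one chromosome, uniform over valid
# placements via rejection sampling
ctx_draw_starts <- function(ctx, n, chrom, w, target_sign = NA) {
  if (n == 0) {
    return(integer())
  }
  npl <- chrom_nbins(ctx$scheme, chrom) - w + 1
  if (npl < 1) {
    stop("chromosome ", chrom, " too short for a ", w, "-bin region", call. = FALSE)
  }
  thr <- ctx$config$validity_threshold
  out <- integer()
  attempts <- 0
  budget <- ctx$config$max_attempts * max(n, 1)
  while (length(out) < n) {
    m <- max(64L, 2L * (n - length(out)))
    cand <- sample.int(npl, m, replace = TRUE)
    ok <- masked_in_range(ctx$engine, rep(chrom, m), cand, cand + w - 1) / w < thr
    if (!is.na(target_sign)) {
      s <- ctx_region_sign(ctx, rep(chrom, m), cand, cand + w - 1)
      ok <- ok & !is.na(s) & s == target_sign
    }
    out <- c(out, cand[ok])
    attempts <- attempts + m
    if (attempts > budget && length(out) < n) {
      stop("permutation draw failure on ", chrom, " (width ", w,
        " bins): validity/compartment constraints unsatisfiable",
        call. = FALSE
      )
    }
  }
  out[seq_len(n)]
}

# n placements uniform over every (chromosome != excl, position) placement
ctx_draw_anychrom <- function(ctx, n, excl, w, target_sign = NA) {
  chs <- setdiff(ctx$scheme$chroms$chrom, excl)
  npl <- chrom_nbins(ctx$scheme, chs) - w + 1
  chs <- chs[npl >= 1]
  npl <- npl[npl >= 1]
  if (length(chs) == 0) stop("no other chromosome fits a ", w, "-bin region", call. = FALSE)
  cum <- cumsum(npl)
  thr <- ctx$config$validity_threshold
  out_ch <- character()
  out_st <- integer()
  attempts <- 0
  budget <- ctx$config$max_attempts * max(n, 1)
  while (length(out_st) < n) {
    m <- max(64L, 2L * (n - length(out_st)))
    g <- sample.int(cum[length(cum)], m, replace = TRUE)
    ci <- findInterval(g - 1, cum) + 1
    st <- g - c(0, cum)[ci]
    ch <- chs[ci]
    ok <- masked_in_range(ctx$engine, ch, st, st + w - 1) / w < thr
    if (!is.na(target_sign)) {
      s <- ctx_region_sign(ctx, ch, st, st + w - 1)
      ok <- ok & !is.na(s) & s == target_sign
    }
    out_ch <- c(out_ch, ch[ok])
    out_st <- c(out_st, st[ok])
    attempts <- attempts + m
    if (attempts > budget && length(out_st) < n) {
      stop("permutation draw failure (any-chromosome placement)", call. = FALSE)
    }
  }
  list(chrom = out_ch[seq_len(n)], start = out_st[seq_len(n)])
}

# n draws from the catalog partner pool, excluding entries on `excl`
ctx_draw_pool <- function(ctx, n, excl, target_sign = NA) {
  pool <- ctx$pool[ctx$pool$chrom != excl, ]
  if (!is.na(target_sign) && !is.null(ctx$comp_eng)) {
    s <- ctx_region_sign(ctx, pool$chrom, pool$first, pool$last)
    pool <- pool[!is.na(s) & s == target_sign, ]
  }
  thr <- ctx$config$validity_threshold
  if (nrow(pool) > 0) {
    w <- pool$last - pool$first + 1
    ok <- masked_in_range(ctx$engine, pool$chrom, pool$first, pool$last) / w < thr
    pool <- pool[ok, ]
  }
  if (nrow(pool) == 0) {
    stop("method 4: empty partner pool after constraints", call. = FALSE)
  }
  idx <- sample.int(nrow(pool), n, replace = TRUE)
  pool[idx, ]
}

# n_perms permuted versions of catalog pair `i`; returns parallel region
# vectors (chrom, first, last) x (a, b)
ctx_permute_pair <- function(ctx, i, n) {
  cfg <- ctx$config
  ca <- ctx$pairs$chrom_a[i]
  cb <- ctx$pairs$chrom_b[i]
  wa <- ctx$wa[i]
  wb <- ctx$wb[i]
  sign_a <- sign_b <- NA_real_
  if (cfg$compartment_control) {
    sign_a <- ctx_region_sign(ctx, ca, ctx$fa[i], ctx$la[i])
    sign_b <- ctx_region_sign(ctx, cb, ctx$fb[i], ctx$lb[i])
  }
  out <- list(
    ca = rep(ca, n), fa = rep(ctx$fa[i], n), la = rep(ctx$la[i], n),
    cb = rep(cb, n), fb = rep(ctx$fb[i], n), lb = rep(ctx$lb[i], n)
  )
  if (cfg$method == 1) {
    sa <- ctx_draw_starts(ctx, n, ca, wa, sign_a)
    sb <- ctx_draw_starts(ctx, n, cb, wb, sign_b)
    out$fa <- sa
    out$la <- sa + wa - 1
    out$fb <- sb
    out$lb <- sb + wb - 1
    return(out)
  }
  # methods 2-4 fix one partner per pair (chosen uniformly, seeded); fixing
  # the same side across a pair's draws keeps the observed statistic
  # exchangeable with its null draws, which per-draw re-fixing would break
  # whenever scores retain row/column structure
  fix_a <- rep(sample(c(TRUE, FALSE), 1), n)
  n_b <- sum(fix_a) # region b redrawn where a is fixed
  n_a <- n - n_b
  if (cfg$method == 2) {
    if (n_b > 0) {
      sb <- ctx_draw_starts(ctx, n_b, cb, wb, sign_b)
      out$fb[fix_a] <- sb
      out$lb[fix_a] <- sb + wb - 1
    }
    if (n_a > 0) {
      sa <- ctx_draw_starts(ctx, n_a, ca, wa, sign_a)
      out$fa[!fix_a] <- sa
      out$la[!fix_a] <- sa + wa - 1
    }
  } else if (cfg$method == 3) {
    if (n_b > 0) {
      d <- ctx_draw_anychrom(ctx, n_b, ca, wb, sign_b)
      out$cb[fix_a] <- d$chrom
      out$fb[fix_a] <- d$start
      out$lb[fix_a] <- d$start + wb - 1
    }
    if (n_a > 0) {
      d <- ctx_draw_anychrom(ctx, n_a, cb, wa, sign_a)
      out$ca[!fix_a] <- d$chrom
      out$fa[!fix_a] <- d$start
      out$la[!fix_a] <- d$start + wa - 1
    }
  } else {
    if (n_b > 0) {
      d <- ctx_draw_pool(ctx, n_b, ca, sign_b)
      out$cb[fix_a] <- d$chrom
      out$fb[fix_a] <- d$first
      out$lb[fix_a] <- d$last
    }
    if (n_a > 0) {
      d <- ctx_draw_pool(ctx, n_a, cb, sign_a)
      out$ca[!fix_a] <- d$chrom
      out$fa[!fix_a] <- d$first
      out$la[!fix_a] <- d$last
    }
  }
  out
}

#' Draw one permuted counterpart of a translocation pair
#'
#' Single-draw interface to the null constructions of [perm_config()];
#' mainly useful for inspection, the tests use the batched machinery inside
#' [perm_individual_test()] and [perm_group_test()].
#'
#' @param pair One-row pair tibble.
#' @param scores A `hic_scores` object (supplies scheme and mask).
#' @param config A [perm_config()].
#' @param track Compartment track (when `compartment_control`).
#' @param pool_pairs Catalog pairs supplying the method-4 partner pool;
#'   defaults to `pair`.
#' @return One-row tibble with the permuted regions (bp coordinates).
#' @export
draw_permuted_pair <- function(pair, scores, config, track = NULL,
                               pool_pairs = pair) {
  ctx <- perm_context(pool_pairs, scores, config, track = track)
  i <- which(
    ctx$pairs$chrom_a == pair$chrom_a[1] & ctx$pairs$start_a == pair$start_a[1] &
      ctx$pairs$chrom_b == pair$chrom_b[1] & ctx$pairs$start_b == pair$start_b[1]
  )[1]
  if (is.na(i)) stop("pair not found in pool catalog", call. = FALSE)
  d <- with_seed(config$seed, ctx_permute_pair(ctx, i, 1))
  bs <- ctx$scheme$bin_size
  tibble::tibble(
    chrom_a = d$ca, start_a = (d$fa - 1) * bs,
    end_a = pmin(d$la * bs, chrom_length(ctx$scheme, d$ca)),
    chrom_b = d$cb, start_b = (d$fb - 1) * bs,
    end_b = pmin(d$lb * bs, chrom_length(ctx$scheme, d$cb))
  )
}

# observed statistics and the full pairs x perms null matrix
perm_stat_matrix <- function(ctx) {
  n_pairs <- nrow(ctx$pairs)
  obs <- ctx_pair_stat(
    ctx, ctx$pairs$chrom_a, ctx$fa, ctx$la,
    ctx$pairs$chrom_b, ctx$fb, ctx$lb
  )
  perm <- matrix(NA_real_, n_pairs, ctx$config$n_perms)
  for (i in seq_len(n_pairs)) {
    d <- ctx_permute_pair(ctx, i, ctx$config$n_perms)
    perm[i, ] <- ctx_pair_stat(ctx, d$ca, d$fa, d$la, d$cb, d$fb, d$lb)
  }
  list(observed = obs, perm = perm)
}

#' Per-translocation permutation test
#'
#' For each pair, the p-value is the add-one fraction of permuted draws
#' whose statistic is at least the observed one,
#' \eqn{p = (1 + \#\{null \ge obs\})/(n_{perms} + 1)} (never exactly zero;
#' ties count against significance). Benjamini-Hochberg q-values are
#' computed over the pairs with defined statistics, and pairs are flagged
#' significant at `q < 0.05`.
#'
#' @param pairs Pair tibble.
#' @param scores A `hic_scores` object.
#' @param config A [perm_config()].
#' @param genes Gene intervals (for the gene-content statistic).
#' @param track Compartment track (for the compartment statistic or
#'   compartment control).
#' @return Input rows with `observed`, `p_value`, `bh_q`, `significant`.
#' @export
perm_individual_test <- function(pairs, scores, config, genes = NULL, track = NULL) {
  ctx <- perm_context(pairs, scores, config, genes, track)
  sm <- with_seed(config$seed, perm_stat_matrix(ctx))
  n <- config$n_perms
  # ties count against significance; the tolerance keeps genuine ties (same
  # placement, same value) counted even under floating-point jitter
  tol <- 1e-9 * (1 + abs(sm$observed))
  exceed <- rowSums(sweep(sm$perm, 1, sm$observed - tol, `>=`), na.rm = TRUE)
  p <- (1 + exceed) / (n + 1)
  p[is.na(sm$observed)] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- tibble::as_tibble(ctx$pairs)
  out$observed <- sm$observed
  out$p_value <- p
  out$bh_q <- q
  out$significant <- !is.na(q) & q < 0.05
  out
}

#' Group-level permutation test
#'
#' Generates `n_perms` randomized catalogs (every pair independently
#' permuted under the chosen null construction, preserving chromosome
#' pairings and region sizes), records each randomized catalog's mean
#' statistic, and compares the observed catalog mean against that null via
#' the add-one estimator. Student's t and Wilcoxon rank-sum p-values between
#' the observed per-pair statistics and the pooled permuted statistics are
#' reported alongside, to monitor whether outliers drive the permutation
#' result.
#'
#' @inheritParams perm_individual_test
#' @return A `perm_group_test` object; see [glance.perm_group_test()].
#' @export
perm_group_test <- function(pairs, scores, config, genes = NULL, track = NULL) {
  ctx <- perm_context(pairs, scores, config, genes, track)
  if (sum(!is.na(ctx_pair_stat(
    ctx, ctx$pairs$chrom_a, ctx$fa, ctx$la,
    ctx$pairs$chrom_b, ctx$fb, ctx$lb
  ))) < 2) {
    stop("need >= 2 pairs with defined statistics", call. = FALSE)
  }
  sm <- with_seed(config$seed, perm_stat_matrix(ctx))
  observed_mean <- mean(sm$observed, na.rm = TRUE)
  null_means <- colMeans(sm$perm, na.rm = TRUE)
  tol <- 1e-9 * (1 + abs(observed_mean))
  p <- (1 + sum(null_means >= observed_mean - tol)) / (config$n_perms + 1)
  pooled <- as.vector(sm$perm)
  pooled <- pooled[!is.na(pooled)]
  obs_ok <- sm$observed[!is.na(sm$observed)]
  t_p <- tryCatch(stats::t.test(obs_ok, pooled)$p.value, error = function(e) NA_real_)
  w_p <- tryCatch(
    stats::wilcox.test(obs_ok, pooled, exact = FALSE)$p.value,
    error = function(e) NA_real_
  )
  structure(
    list(
      observed_mean = observed_mean, null_means = null_means,
      p_value = p, t_test_p = t_p, rank_sum_p = w_p,
      n_pairs = length(obs_ok), observed = sm$observed, config = ctx$config
    ),
    class = "perm_group_test"
  )
}

#' @export
print.perm_group_test <- function(x, ...) {
  cat("Group permutation test (method ", x$config$method, ", ",
    x$config$n_perms, " perms, statistic ", x$config$statistic, ")\n",
    "  pairs: ", x$n_pairs, "\n",
    "  observed mean: ", signif(x$observed_mean, 4),
    "   null mean: ", signif(mean(x$null_means), 4), "\n",
    "  permutation p: ", format.pval(x$p_value, digits = 3),
    "   t: ", format.pval(x$t_test_p, digits = 3),
    "   rank-sum: ", format.pval(x$rank_sum_p, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Null-distribution draws of a group test
#'
#' @param x A `perm_group_test`.
#' @param ... Unused.
#' @return Tibble with one row per permutation replicate (`replicate`,
#'   `null_mean`).
#' @export
tidy.perm_group_test <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_means), null_mean = x$null_means)
}

#' One-row summary of a group test
#'
#' @param x A `perm_group_test`.
#' @param ... Unused.
#' @return Tibble with observed and null means and the three p-values.
#' @export
glance.perm_group_test <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, observed_mean = x$observed_mean,
    null_mean = mean(x$null_means), p_value = x$p_value,
    t_test_p = x$t_test_p, rank_sum_p = x$rank_sum_p,
    method = x$config$method, n_perms = x$config$n_perms,
    statistic = x$config$statistic
  )
}

#' Histogram of the permutation null with the observed mean
#'
#' @param object A `perm_group_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_group_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_mean, color = "red") +
    ggplot2::labs(
      x = "mean statistic of permuted catalog",
      y = "permutation replicates",
      title = sprintf(
        "observed mean %.3f, permutation p %s",
        object$observed_mean, format.pval(object$p_value, digits = 2)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement, input
#' order preserved.
#'
#' @param pvals Numeric p-values in `(0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) {
    return(numeric())
  }
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Compare proximity scores between two groups
#'
#' Two-sided Wilcoxon rank-sum comparison (normal approximation with tie
#' correction), e.g. blood versus non-blood tumor translocations.
#'
#' @param scores_1,scores_2 Numeric score vectors (NA dropped; each group
#'   needs >= 2 values).
#' @return One-row tibble: `rank_sum_p`, `median_1`, `median_2`, `n_1`,
#'   `n_2`.
#' @export
tissue_comparison <- function(scores_1, scores_2) {
  scores_1 <- scores_1[!is.na(scores_1)]
  scores_2 <- scores_2[!is.na(scores_2)]
  if (length(scores_1) < 2 || length(scores_2) < 2) {
    stop("each group needs at least 2 defined scores", call. = FALSE)
  }
  wt <- stats::wilcox.test(scores_1, scores_2, exact = FALSE)
  tibble::tibble(
    rank_sum_p = wt$p.value,
    median_1 = stats::median(scores_1), median_2 = stats::median(scores_2),
    n_1 = length(scores_1), n_2 = length(scores_2)
  )
}

#' Recurrence versus proximity correlation
#'
#' Tests whether more frequently reported translocations sit closer in the
#' nucleus: Spearman correlation between recurrence counts and proximity
#' scores, the same against the per-pair permutation p-values when present,
#' and a regression-slope t-test of ranked p-values on ranked counts.
#'
#' @param results Tibble with `recurrence_count`, `proximity_score`, and
#'   optionally `p_value`.
#' @return One-row tibble: `rho_score`, `rho_score_p`, and (when p-values
#'   are supplied) `rho_pvalue`, `slope_t_p`.
#' @export
recurrence_correlation <- function(results) {
  ok <- !is.na(results$recurrence_count) & !is.na(results$proximity_score)
  df <- results[ok, ]
  if (nrow(df) < 3) stop("need >= 3 pairs with counts and scores", call. = FALSE)
  if (stats::sd(df$recurrence_count) == 0 || stats::sd(df$proximity_score) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(df$recurrence_count, df$proximity_score,
    method = "spearman", exact = FALSE
  ))
  out <- tibble::tibble(
    rho_score = unname(ct$estimate), rho_score_p = ct$p.value,
    rho_pvalue = NA_real_, slope_t_p = NA_real_
  )
  if ("p_value" %in% names(results)) {
    dp <- results[!is.na(results$recurrence_count) & !is.na(results$p_value), ]
    if (nrow(dp) >= 3 && stats::sd(dp$p_value) > 0 && stats::sd(dp$recurrence_count) > 0) {
      cp <- suppressWarnings(stats::cor.test(dp$recurrence_count, dp$p_value,
        method = "spearman", exact = FALSE
      ))
      out$rho_pvalue <- unname(cp$estimate)
      fit <- stats::lm(rank(dp$p_value) ~ rank(dp$recurrence_count))
      out$slope_t_p <- suppressWarnings(summary(fit)$coefficients[2, 4])
    }
  }
  out
}
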