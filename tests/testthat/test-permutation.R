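# shared small study for draw-contract checks
perm_fixture <- function(seed = 1, n_null = 6, n_chrom = 3) {
  cfg <- sim_config(n_chrom = n_chrom, chrom_length = 30e6, lambda = 10, n_null = n_null, seed = seed)
  st <- simulate_study(cfg)
  mask <- build_mask(st$map, st$bands)
  sc <- hic_score(st$map, smooth_expected(expected_trans(st$map, mask)), mask)
  pairs <- ok_pairs(parse_karyotype_catalog(st$catalog, st$bands, st$assembly))
  list(st = st, sc = sc, pairs = pairs)
}

test_that("method 1 preserves chromosomes and bin widths of both regions", {
  fx <- perm_fixture()
  pair <- fx$pairs[1, ]
  cfg <- perm_config(method = 1, n_perms = 200, seed = 3)
  ctx <- hictrans:::perm_context(pair, fx$sc, cfg)
  d <- hictrans:::with_seed(3, hictrans:::ctx_permute_pair(ctx, 1, 200))
  expect_true(all(d$ca == pair$chrom_a))
  expect_true(all(d$cb == pair$chrom_b))
  expect_true(all(d$la - d$fa + 1 == ctx$wa[1]))
  expect_true(all(d$lb - d$fb + 1 == ctx$wb[1]))
})

test_that("method 3 places the moving partner on a different chromosome", {
  fx <- perm_fixture()
  pair <- fx$pairs[1, ]
  cfg <- perm_config(method = 3, n_perms = 300, seed = 5)
  ctx <- hictrans:::perm_context(pair, fx$sc, cfg)
  d <- hictrans:::with_seed(5, hictrans:::ctx_permute_pair(ctx, 1, 300))
  expect_true(all(d$ca != d$cb))
  # one side stays at the observed location
  fixed_a <- d$ca == pair$chrom_a & d$fa == ctx$fa[1] & d$la == ctx$la[1]
  fixed_b <- d$cb == pair$chrom_b & d$fb == ctx$fb[1] & d$lb == ctx$lb[1]
  expect_true(all(fixed_a | fixed_b))
})

test_that("method 4 draws partners from the catalog pool off the fixed chromosome", {
  fx <- perm_fixture(n_null = 10)
  cfg <- perm_config(method = 4, n_perms = 200, seed = 7)
  ctx <- hictrans:::perm_context(fx$pairs, fx$sc, cfg)
  pool_keys <- c(
    paste(ctx$pool$chrom, ctx$pool$first, ctx$pool$last),
    paste(fx$pairs$chrom_a, ctx$fa, ctx$la),
    paste(fx$pairs$chrom_b, ctx$fb, ctx$lb)
  )
  d <- hictrans:::with_seed(7, hictrans:::ctx_permute_pair(ctx, 2, 200))
  drawn <- unique(c(paste(d$ca, d$fa, d$la), paste(d$cb, d$fb, d$lb)))
  expect_true(all(drawn %in% pool_keys))
  expect_true(all(d$ca != d$cb))
})

test_that("rejection sampling is uniform over valid placements under masking", {
  # one chromosome with a contiguous 60%-masked block; 2-bin regions are
  # valid only when no bin is masked (masked fraction threshold 0.5)
  asm <- genome_assembly(c("chr1", "chr2"), c(10e6, 10e6))
  scheme <- bin_scheme(asm)
  mask <- mask_from_bins(scheme, rep("chr1", 6), 3:8)
  S <- matrix(0, 10, 10)
  S[hictrans:::mask_vectors(mask, scheme)$chr1, ] <- NA
  sc <- scores_from_blocks(scheme, list("chr1|chr2" = S), mask)
  pair <- make_pair("chr1", 0, 2e6, "chr2", 0, 1e6)
  cfg <- perm_config(method = 2, n_perms = 1, seed = 1)
  ctx <- hictrans:::perm_context(pair, fx_sc <- sc, cfg)
  # exact enumeration oracle: width-2 starts 1..9; a start is valid iff
  # fewer than half its bins are masked, i.e. neither bin in the block
  valid <- c(1, 9)
  n <- 10000
  draws <- hictrans:::with_seed(11, hictrans:::ctx_draw_starts(ctx, n, "chr1", 2))
  expect_setequal(unique(draws), valid)
  freq <- table(factor(draws, levels = valid)) / n
  se <- sqrt((1 / 2) * (1 / 2) / n)
  expect_true(all(abs(freq - 1 / 2) < 3 * se))
})

test_that("compartment control matches the replaced region's score sign", {
  fx <- perm_fixture(seed = 21, n_null = 8)
  genes <- fx$st$genes
  tr <- compartment_track(fx$sc, gene_content_track(fx$st$scheme, genes))
  cfg <- perm_config(method = 1, n_perms = 100, compartment_control = TRUE, seed = 9)
  ctx <- hictrans:::perm_context(fx$pairs, fx$sc, cfg, track = tr)
  for (i in c(1, 3)) {
    true_sign_a <- hictrans:::ctx_region_sign(ctx, fx$pairs$chrom_a[i], ctx$fa[i], ctx$la[i])
    d <- hictrans:::with_seed(9, hictrans:::ctx_permute_pair(ctx, i, 100))
    drawn_sign <- hictrans:::ctx_region_sign(ctx, d$ca, d$fa, d$la)
    if (!is.na(true_sign_a)) expect_true(all(drawn_sign == true_sign_a))
  }
})

test_that("per-pair p-values hit the add-one boundaries", {
  # constructed scores: the observed block far above anything reachable
  asm <- genome_assembly(c("chr1", "chr2"), c(10e6, 10e6))
  scheme <- bin_scheme(asm)
  S <- matrix(0, 10, 10)
  S[5, 5] <- 100
  sc <- scores_from_blocks(scheme, list("chr1|chr2" = S))
  hi <- make_pair("chr1", 4e6, 5e6, "chr2", 4e6, 5e6)
  lo <- make_pair("chr1", 0, 1e6, "chr2", 0, 1e6)
  cfg <- perm_config(method = 1, n_perms = 100, seed = 2)
  it <- perm_individual_test(dplyr::bind_rows(hi, lo), sc, cfg)
  # the add-one estimator is never zero and is integer-granular; draws that
  # re-hit the observed placement tie and count against significance
  expect_gte(it$p_value[1], 1 / 101)
  expect_lte(it$p_value[1], 10 / 101)
  expect_equal(round(it$p_value[1] * 101), it$p_value[1] * 101, tolerance = 1e-9)
  # at or below every draw (all ties or worse): p = 1
  expect_equal(it$p_value[2], 1.0)
})

test_that("identical seeds reproduce tests bit for bit", {
  fx <- perm_fixture(seed = 30, n_null = 8)
  cfg <- perm_config(method = 2, n_perms = 100, seed = 77)
  g1 <- perm_group_test(fx$pairs, fx$sc, cfg)
  g2 <- perm_group_test(fx$pairs, fx$sc, cfg)
  expect_identical(g1$null_means, g2$null_means)
  expect_identical(g1$p_value, g2$p_value)
  i1 <- perm_individual_test(fx$pairs, fx$sc, cfg)
  i2 <- perm_individual_test(fx$pairs, fx$sc, cfg)
  expect_identical(i1$p_value, i2$p_value)
})

test_that("Monte-Carlo p-values match exhaustive placement enumeration", {
  # toy genome: 2 chromosomes x 6 bins, single-bin regions, method 1
  # => exactly 36 equally likely placements per pair
  asm <- genome_assembly(c("chr1", "chr2"), c(6e6, 6e6))
  scheme <- bin_scheme(asm)
  set.seed(19)
  S <- matrix(rnorm(36), 6, 6)
  sc <- scores_from_blocks(scheme, list("chr1|chr2" = S))
  p1 <- make_pair("chr1", 2e6, 3e6, "chr2", 4e6, 5e6)
  p2 <- make_pair("chr1", 0e6, 1e6, "chr2", 1e6, 2e6)
  pairs <- dplyr::bind_rows(p1, p2)
  n <- 10000
  cfg <- perm_config(method = 1, n_perms = n, seed = 4)
  it <- perm_individual_test(pairs, sc, cfg)
  # individual: exact exceedance fraction over all 36 placements
  for (i in 1:2) {
    obs <- it$observed[i]
    f <- mean(S >= obs - 1e-9) # ties count as exceedances
    se <- sqrt(f * (1 - f) / n)
    expect_lt(abs(it$p_value[i] - f), 3 * se + 2 / n)
  }
  # group: exact distribution of the 2-pair mean over 36^2 joint placements
  gt <- perm_group_test(pairs, sc, cfg)
  grid <- expand.grid(a = as.vector(S), b = as.vector(S))
  f_group <- mean((grid$a + grid$b) / 2 >= gt$observed_mean - 1e-9)
  se_g <- sqrt(f_group * (1 - f_group) / n)
  expect_lt(abs(gt$p_value - f_group), 3 * se_g + 2 / n)
})

test_that("planted hotspot pairs reach individual significance", {
  hs <- tibble::tibble(
    chrom_a = "chr1", band_a = "q23", chrom_b = "chr2", band_b = "p22", fold = 3
  )
  hits <- sapply(1:10, function(s) {
    cfg <- sim_config(
      n_chrom = 2, chrom_length = 100e6, lambda = 50, hotspots = hs,
      n_true = 1, n_null = 30, seed = 400 + s
    )
    st <- simulate_study(cfg)
    mask <- build_mask(st$map, st$bands)
    sc <- hic_score(st$map, smooth_expected(expected_trans(st$map, mask)), mask)
    pairs <- parse_karyotype_catalog(st$catalog, st$bands, st$assembly)
    pairs$is_true <- st$catalog$is_true[match(pairs$source_label, st$catalog$notation)]
    pairs <- ok_pairs(pairs)
    it <- perm_individual_test(pairs, sc, perm_config(method = 1, n_perms = 1000, seed = s))
    any(it$significant[it$is_true])
  })
  expect_gte(sum(hits), 9)
})

test_that("BH adjustment equals the textbook step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(42)
  for (rep in 1:10) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    # monotone in sorted-p order and bounded by 1
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1 & q >= p / length(p)))
  }
})

test_that("rank-sum tissue comparison behaves at both extremes", {
  same <- tissue_comparison(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$rank_sum_p, 0.95)
  sep <- tissue_comparison(c(1, 2, 3), c(101, 102, 103))
  # exact enumeration for n=3,3 gives two-sided p = 0.1; the normal
  # approximation with continuity correction lands close below it
  expect_lt(sep$rank_sum_p, 0.12)
  expect_gt(sep$rank_sum_p, 0.02)
  expect_equal(sep$median_1, 2)
  expect_equal(sep$median_2, 102)
  expect_error(tissue_comparison(1, c(1, 2)), "at least 2")
})

test_that("label permutation of pooled null scores yields uniform rank-sum p", {
  set.seed(88)
  pooled <- rnorm(24)
  ps <- replicate(400, {
    lab <- sample(rep(c(1, 2), each = 12))
    tissue_comparison(pooled[lab == 1], pooled[lab == 2])$rank_sum_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("recurrence correlation recovers rank alignment and independence", {
  res_up <- tibble::tibble(
    recurrence_count = c(1, 2, 3, 5), proximity_score = c(0.1, 0.2, 0.5, 0.9)
  )
  expect_equal(recurrence_correlation(res_up)$rho_score, 1.0)
  res_dn <- tibble::tibble(
    recurrence_count = c(1, 2, 3), proximity_score = c(3, 2, 1)
  )
  expect_equal(recurrence_correlation(res_dn)$rho_score, -1.0)
  expect_error(
    recurrence_correlation(tibble::tibble(
      recurrence_count = c(2, 2, 2), proximity_score = c(1, 2, 3)
    )),
    "constant"
  )
  set.seed(6)
  hits <- replicate(40, {
    res <- tibble::tibble(
      recurrence_count = rpois(200, 3) + 1, proximity_score = rnorm(200)
    )
    abs(recurrence_correlation(res)$rho_score) < 0.2
  })
  expect_gte(mean(hits), 0.9)
  # p-value columns populated when supplied
  res_p <- tibble::tibble(
    recurrence_count = c(1, 2, 3, 4, 7), proximity_score = rnorm(5),
    p_value = c(0.9, 0.7, 0.5, 0.3, 0.1)
  )
  rc <- recurrence_correlation(res_p)
  expect_equal(rc$rho_pvalue, -1.0)
  expect_false(is.na(rc$slope_t_p))
})

test_that("group test tidiers expose the null distribution and summary", {
  fx <- perm_fixture(seed = 44, n_null = 6)
  gt <- perm_group_test(fx$pairs, fx$sc, perm_config(method = 1, n_perms = 50, seed = 1))
  td <- tidy(gt)
  expect_equal(nrow(td), 50)
  gl <- glance(gt)
  expect_equal(gl$n_perms, 50L)
  expect_true(gl$p_value > 0 && gl$p_value <= 1)
  expect_s3_class(autoplot(gt), "ggplot")
})
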