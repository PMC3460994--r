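test_that("bin scheme maps every base to exactly one bin, last bin truncated", {
  asm <- genome_assembly(c("chr1", "chr2"), c(10.5e6, 3e6))
  scheme <- bin_scheme(asm, 1e6)
  expect_equal(scheme$chroms$n_bins, c(11L, 3L))
  bins <- scheme_bins(scheme)
  expect_equal(nrow(bins), 14)
  expect_equal(bins$global_bin, 1:14)
  last1 <- bins[bins$chrom == "chr1" & bins$bin == 11, ]
  expect_equal(last1$end, 10.5e6)
  # positions map to the containing bin
  expect_equal(bin_of_position(scheme, c("chr1", "chr1"), c(0, 999999)), c(1L, 1L))
  expect_equal(bin_of_position(scheme, "chr1", 1e6), 2L)
  expect_error(bin_of_position(scheme, "chr1", 10.5e6), "out of range")
  # snapping: floor the start, ceil the end
  rr <- region_bin_range(scheme, "chr1", 1.5e6, 3.2e6)
  expect_equal(c(rr$first_bin, rr$last_bin), c(2L, 4L))
})

test_that("assembly validation rejects duplicates and non-positive lengths", {
  expect_error(genome_assembly(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_assembly(c("a", "b"), c(1, 0)), "positive")
})

test_that("cytoBand parsing validates format and band geometry", {
  bands <- parse_cytoband("chr1\t0\t2300000\tp36.33\tgneg")
  expect_equal(bands$chrom, "chr1")
  expect_equal(bands$start, 0)
  expect_equal(bands$end, 2300000)
  expect_equal(bands$band, "p36.33")
  expect_equal(bands$stain, "gneg")
  expect_equal(nrow(parse_cytoband(character())), 0)
  expect_error(parse_cytoband("chr1\t0\t100\tp11"), "5 tab-separated")
  expect_error(
    parse_cytoband(c("chr1\t0\t100\tp11\tgneg", "chr1\t50\t150\tp12\tgneg")),
    "overlapping"
  )
  expect_error(parse_cytoband("chr1\tx\t100\tp11\tgneg"), "non-numeric")
})

test_that("band labels resolve to the union of matching sub-bands", {
  bands <- parse_cytoband(c(
    "chr9\t10\t20\tq34.1\tgneg",
    "chr9\t20\t35\tq34.2\tgpos50",
    "chr9\t35\t50\tq35\tgneg"
  ))
  r <- band_to_region(bands, "chr9", "q34")
  expect_equal(c(r$start, r$end), c(10, 35))
  r1 <- band_to_region(bands, "chr9", "q34.1")
  expect_equal(c(r1$start, r1$end), c(10, 20))
  expect_error(band_to_region(bands, "chr9", "q9"), "no band matching")
  # "q3" must not match q34 or q35
  expect_error(band_to_region(bands, "chr9", "q3"), "no band matching")
})

test_that("band resolution is monotone over generated genomes", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 40e6, seed = 5)
  g <- simulate_genome(cfg)
  subbands <- g$bands[grepl("\\.", g$bands$band), ]
  for (i in seq_len(nrow(subbands))) {
    parent <- sub("\\..*$", "", subbands$band[i])
    rp <- band_to_region(g$bands, subbands$chrom[i], parent)
    rc <- band_to_region(g$bands, subbands$chrom[i], subbands$band[i])
    expect_lte(rp$start, rc$start)
    expect_gte(rp$end, rc$end)
  }
})

test_that("karyotype notation parses 2-way and decomposes 3-way records", {
  bands <- parse_cytoband(c(
    "chr9\t0\t50000000\tp13\tgneg",
    "chr9\t50000000\t140000000\tq34\tgpos50",
    "chr22\t0\t20000000\tp11\tgneg",
    "chr22\t20000000\t50000000\tq13\tgneg",
    "chr1\t0\t50000000\tp11\tgneg",
    "chr2\t0\t50000000\tq22\tgneg",
    "chr3\t0\t50000000\tq33\tgneg"
  ))
  asm <- genome_assembly(
    c("chr1", "chr2", "chr3", "chr9", "chr22"),
    c(5e7, 5e7, 5e7, 1.4e8, 5e7)
  )
  p <- parse_karyotype("t(9;22)(p13;q13)", bands, asm)
  expect_equal(nrow(p), 1)
  expect_equal(p$status, "ok")
  expect_equal(p$chrom_a, "chr9")
  expect_equal(c(p$start_a, p$end_a), c(0, 5e7))
  expect_equal(p$chrom_b, "chr22")
  expect_equal(c(p$start_b, p$end_b), c(2e7, 5e7))
  # 3-way record decomposes into its three 2-way pairs
  p3 <- parse_karyotype("t(1;2;3)(p11;q22;q33)", bands, asm)
  expect_equal(nrow(p3), 3)
  expect_setequal(
    paste(p3$chrom_a, p3$chrom_b),
    c("chr1 chr2", "chr1 chr3", "chr2 chr3")
  )
})

test_that("karyotype rejections carry reason codes and are never silent", {
  bands <- parse_cytoband(c(
    "chr4\t0\t50000000\tq21\tgneg",
    "chr10\t0\t50000000\tq11\tgneg",
    "chr5\t0\t50000000\tp15\tgneg"
  ))
  expect_equal(parse_karyotype("t(4;10)(q21;q)", bands)$status, "whole_arm")
  expect_equal(parse_karyotype("t(4;4)(q21;q21)", bands)$status, "intra_chromosomal")
  expect_equal(
    parse_karyotype("t(4;10;5;4)(q21;q11;p15;q21)", bands)$status,
    "too_many_partners"
  )
  expect_equal(parse_karyotype("nonsense", bands)$status, "parse_error")
  expect_equal(parse_karyotype("t(4;10)(q99;q11)", bands)$status, "band_not_found")
  # emitted pair counts: C(k,2) for k in {2,3}, zero otherwise
  expect_equal(sum(parse_karyotype("t(4;10)(q21;q11)", bands)$status == "ok"), 1)
})

test_that("every parsed pair is inter-chromosomal and canonically ordered", {
  cfg <- sim_config(n_chrom = 3, chrom_length = 30e6, n_null = 40, seed = 9)
  st <- simulate_study(cfg)
  pairs <- ok_pairs(parse_karyotype_catalog(st$catalog, st$bands, st$assembly))
  expect_true(all(pairs$chrom_a != pairs$chrom_b))
  ia <- match(pairs$chrom_a, st$assembly$chrom)
  ib <- match(pairs$chrom_b, st$assembly$chrom)
  expect_true(all(ia < ib))
})

test_that("breakpoint records are binned, filtered on support, and audited", {
  asm <- genome_assembly(c("chr1", "chr2"), c(10e6, 10e6))
  scheme <- bin_scheme(asm)
  rec <- tibble::tibble(
    chrom1 = c("chr1", "chr1", "chr1"),
    pos1 = c(1500000, 1500000, 2e6),
    chrom2 = c("chr2", "chr2", "chr1"),
    pos2 = c(3200000, 3200000, 5e6),
    supporting_reads = c(5, 2, 9)
  )
  out <- breakpoints_to_pairs(rec, scheme)
  expect_equal(out$status, c("ok", "low_support", "intra_chromosomal"))
  expect_equal(c(out$start_a[1], out$end_a[1]), c(1e6, 2e6))
  expect_equal(c(out$start_b[1], out$end_b[1]), c(3e6, 4e6))
  bad <- tibble::tibble(
    chrom1 = "chr1", pos1 = 99e6, chrom2 = "chr2", pos2 = 1, supporting_reads = 5
  )
  expect_error(breakpoints_to_pairs(bad, scheme), "out of range")
})

test_that("mask combines centromere overlap and zero coverage with reasons", {
  asm <- genome_assembly(c("chr1", "chr2"), c(10e6, 10e6))
  scheme <- bin_scheme(asm)
  O <- matrix(1, 10, 10)
  O[3, ] <- 0 # chr1 bin 3: no coverage anywhere
  map <- hictrans:::new_contact_map(scheme, list("chr1|chr2" = O))
  bands <- parse_cytoband(c(
    "chr1\t6000000\t8000000\tq11\tacen",
    "chr1\t2000000\t3000000\tp11\tgneg"
  ))
  mask <- build_mask(map, bands)
  m1 <- mask[mask$chrom == "chr1", ]
  expect_setequal(m1$bin[m1$reason == "centromere"], c(7L, 8L))
  expect_setequal(m1$bin[m1$reason == "no_coverage"], 3L)
  # a bin that is both acen-overlapping and zero-coverage records both reasons
  O2 <- matrix(1, 10, 10)
  O2[7, ] <- 0
  map2 <- hictrans:::new_contact_map(scheme, list("chr1|chr2" = O2))
  mask2 <- build_mask(map2, bands)
  expect_setequal(
    mask2$reason[mask2$chrom == "chr1" & mask2$bin == 7],
    c("centromere", "no_coverage")
  )
  expect_equal(nrow(build_mask(map, NULL)[build_mask(map, NULL)$reason == "centromere", ]), 0)
})

test_that("gene content is the union fraction, invariant to overlap structure", {
  region <- data.frame(chrom = "chr1", start = 0, end = 100)
  genes <- data.frame(chrom = "chr1", start = c(10, 15), end = c(20, 30))
  expect_equal(gene_content(region, genes), 0.20)
  expect_equal(gene_content(region, data.frame(chrom = "chr2", start = 1, end = 5)), 0)
  expect_equal(gene_content(region, data.frame(chrom = "chr1", start = 0, end = 100)), 1)
  # order and fragmentation of the intervals must not matter
  set.seed(4)
  for (rep in 1:5) {
    s <- sort(sample(0:90, 6))
    g1 <- data.frame(chrom = "chr1", start = s, end = s + sample(5:10, 6, TRUE))
    g2 <- g1[sample(nrow(g1)), ]
    g3 <- rbind(g1, g1[1:3, ]) # duplicated intervals
    expect_equal(gene_content(region, g2), gene_content(region, g1))
    expect_equal(gene_content(region, g3), gene_content(region, g1))
  }
  expect_error(gene_content(data.frame(chrom = "chr1", start = 5, end = 5), genes))
})

test_that("dataset coverage counts union bases and distinct trans bin pairs", {
  asm <- genome_assembly(c("chr1", "chr2"), c(10e6, 10e6))
  scheme <- bin_scheme(asm)
  pair <- make_pair("chr1", 0, 2e6, "chr2", 3e6, 6e6)
  cov <- dataset_coverage(pair, scheme)
  expect_equal(cov$trans_bin_fraction, 6 / 100)
  expect_equal(cov$genome_fraction, 5e6 / 20e6)
  # duplicates do not change the union
  cov2 <- dataset_coverage(dplyr::bind_rows(pair, pair), scheme)
  expect_equal(cov2, cov)
  # tiling regions cover the genome
  tiles <- make_pair("chr1", 0, 10e6, "chr2", 0, 10e6)
  expect_equal(dataset_coverage(tiles, scheme)$genome_fraction, 1.0)
  expect_equal(dataset_coverage(tiles, scheme)$trans_bin_fraction, 1.0)
})
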