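finemap_assembly <- function() {
  genome_assembly(c("chrA", "chrB"), c(30e6, 30e6))
}

# reads filling one quadrant with power-law decay from a known corner
planted_window <- function(seed, orientation = "++", n_reads = 2000,
                           alpha = 1, bx = 200, by = 300, bg = 500) {
  set.seed(seed)
  fb <- 5e4
  x0 <- bx * fb + runif(1, 0.2, 0.8) * fb
  y0 <- by * fb + runif(1, 0.2, 0.8) * fb
  reads <- simulate_translocation_reads("chrA", x0, "chrB", y0, orientation, n_reads, alpha = alpha)
  out <- dplyr::bind_rows(reads, simulate_uniform_reads(finemap_assembly(), "chrA", "chrB", bg))
  attr(out, "corner") <- c(bx * fb, by * fb)
  attr(out, "orientation") <- orientation
  out
}

test_that("the maximal trans bin is found with lexicographic tie-breaking", {
  asm <- finemap_assembly()
  scheme <- bin_scheme(asm)
  O <- matrix(0, 30, 30)
  O[7, 9] <- 5
  map <- hictrans:::new_contact_map(scheme, list("chrA|chrB" = O))
  mx <- max_trans_bin(map, "chrA", "chrB")
  expect_equal(c(mx$bin1, mx$bin2), c(7L, 9L))
  expect_equal(mx$count, 5)
  # equal maxima: lowest (bin1, bin2) wins
  O[3, 20] <- 5
  map2 <- hictrans:::new_contact_map(scheme, list("chrA|chrB" = O))
  mx2 <- max_trans_bin(map2, "chrA", "chrB")
  expect_equal(c(mx2$bin1, mx2$bin2), c(3L, 20L))
  expect_error(
    max_trans_bin(hictrans:::new_contact_map(scheme, list("chrA|chrB" = matrix(0, 30, 30))), "chrA", "chrB"),
    "no trans signal"
  )
})

test_that("window extraction keeps reads with both ends inside, partitioning the pair", {
  asm <- finemap_assembly()
  scheme <- bin_scheme(asm)
  center <- tibble::tibble(chrom1 = "chrA", bin1 = 11L, chrom2 = "chrB", bin2 = 16L)
  # window: chrA [9,12) Mb x chrB [14,17) Mb
  reads <- tibble::tibble(
    chrom1 = c("chrA", "chrA", "chrA", "chrB"),
    pos1 = c(10.5e6, 10.5e6, 8.9e6, 15e6),
    chrom2 = c("chrB", "chrB", "chrB", "chrA"),
    pos2 = c(15.5e6, 13.9e6, 15.5e6, 10.0e6)
  )
  win <- window_reads(reads, scheme, center)
  expect_equal(nrow(win), 2) # center read + the swapped-orientation read
  expect_equal(attr(win, "x_range"), c(9e6, 12e6))
  expect_equal(attr(win, "y_range"), c(14e6, 17e6))
  # partition: in-window plus out-of-window equals all pair reads
  expect_equal(nrow(win) + 2, nrow(reads))
  # clipped at chromosome start
  center_edge <- tibble::tibble(chrom1 = "chrA", bin1 = 1L, chrom2 = "chrB", bin2 = 1L)
  win_edge <- window_reads(reads, scheme, center_edge)
  expect_equal(attr(win_edge, "x_range"), c(0, 2e6))
})

test_that("a decaying single-quadrant pattern is called with its orientation", {
  for (ori in c("++", "+-", "-+", "--")) {
    win_reads <- planted_window(17, ori)
    calls <- finemap_breakpoints(win_reads, bin_scheme(finemap_assembly()))
    expect_equal(nrow(calls), 1)
    expect_equal(calls$status, "ok")
    expect_equal(calls$orientation, ori)
    expect_equal(calls$start1, attr(win_reads, "corner")[1])
    expect_equal(calls$start2, attr(win_reads, "corner")[2])
    expect_gt(calls$signature_score, 0.9)
  }
})

test_that("uniform windows are never called and a central corner scores 1/4", {
  set.seed(23)
  asm <- finemap_assembly()
  scheme <- bin_scheme(asm)
  center <- tibble::tibble(chrom1 = "chrA", bin1 = 11L, chrom2 = "chrB", bin2 = 16L)
  for (rep in 1:5) {
    n <- 5000
    reads <- tibble::tibble(
      chrom1 = "chrA", pos1 = runif(n, 9e6, 12e6),
      chrom2 = "chrB", pos2 = runif(n, 14e6, 17e6)
    )
    cd <- corner_detect(window_reads(reads, scheme, center))
    # no unbalanced call on uniform data (the decay gate rejects it even
    # when the argmax corner happens to open a large quadrant)
    expect_equal(cd$status, "no_call")
  }
  # with the corner pinned to the window center, the quadrant fraction of
  # uniform reads converges to the 1/4 area baseline
  n <- 50000
  reads <- tibble::tibble(
    chrom1 = "chrA", pos1 = runif(n, 9e6, 12e6),
    chrom2 = "chrB", pos2 = runif(n, 14e6, 17e6)
  )
  # pin the argmax by planting a small excess in the central 50-kb bin
  spike <- tibble::tibble(
    chrom1 = "chrA", pos1 = runif(100, 10.5e6, 10.55e6),
    chrom2 = "chrB", pos2 = runif(100, 15.5e6, 15.55e6)
  )
  cd <- corner_detect(window_reads(dplyr::bind_rows(reads, spike), scheme, center))
  expect_equal(cd$corner_start1, 10.5e6)
  # quadrant area from the central corner is (1.5/3)^2 = 1/4 of the window;
  # corner-bin inclusion can stretch one axis to 1.55/3, so the winning
  # fraction sits just above 1/4 and far below the 0.6 call threshold
  expect_gt(cd$signature_score, 0.22)
  expect_lt(cd$signature_score, 0.30)
  expect_equal(cd$status, "no_call")
})

test_that("balanced two-quadrant patterns are not called unbalanced", {
  set.seed(29)
  fb <- 5e4
  x0 <- 200 * fb
  y0 <- 300 * fb
  half1 <- simulate_translocation_reads("chrA", x0 + 0.5 * fb, "chrB", y0 + 0.5 * fb, "++", 1000)
  half2 <- simulate_translocation_reads("chrA", x0 - 0.5 * fb, "chrB", y0 - 0.5 * fb, "--", 1000)
  reads <- dplyr::bind_rows(half1, half2)
  calls <- finemap_breakpoints(reads, bin_scheme(finemap_assembly()))
  if (nrow(calls) > 0) {
    expect_true(all(calls$status != "ok" | calls$signature_score < 0.6))
  } else {
    succeed()
  }
})

test_that("insufficient window coverage is reported, not called", {
  set.seed(31)
  asm <- finemap_assembly()
  scheme <- bin_scheme(asm)
  reads <- tibble::tibble(
    chrom1 = "chrA", pos1 = runif(100, 10e6, 11e6),
    chrom2 = "chrB", pos2 = runif(100, 15e6, 16e6)
  )
  center <- tibble::tibble(chrom1 = "chrA", bin1 = 11L, chrom2 = "chrB", bin2 = 16L)
  cd <- corner_detect(window_reads(reads, scheme, center))
  expect_equal(cd$status, "insufficient_coverage")
})

test_that("1-kb refinement requires the coverage floor, boundary inclusive", {
  corner <- tibble::tibble(
    corner_start1 = 10e6, corner_end1 = 10.05e6,
    corner_start2 = 15e6, corner_end2 = 15.05e6
  )
  mkwin <- function(n_in_bin, n_spread) {
    w <- tibble::tibble(
      x = c(rep(10.0123e6 + 200, n_in_bin), runif(n_spread, 10e6, 10.05e6)),
      y = c(rep(15.0321e6 + 100, n_in_bin), runif(n_spread, 15e6, 15.05e6))
    )
    attr(w, "x_range") <- c(9e6, 12e6)
    attr(w, "y_range") <- c(14e6, 17e6)
    w
  }
  set.seed(2)
  r <- refine_1kb(mkwin(25, 5), corner)
  expect_equal(r$refinement_status, "refined")
  expect_equal(r$refined_start1, 10e6 + 12e3)
  expect_equal(r$refined_start2, 15e6 + 32e3)
  # below the floor: sparse
  r2 <- refine_1kb(mkwin(3, 2), corner)
  expect_equal(r2$refinement_status, "sparse")
  # exactly at the floor: refinement attempted
  r3 <- refine_1kb(mkwin(20, 0), corner, finemap_config(min_refine_reads = 20))
  expect_equal(r3$refinement_status, "refined")
})

test_that("the genome scan flags planted translocations and nothing in noise", {
  asm <- finemap_assembly()
  scheme <- bin_scheme(asm)
  empty <- hictrans:::new_contact_map(scheme, hictrans:::empty_blocks(scheme))
  expect_equal(nrow(scan_genome(empty)), 0)
  # planted signal: exactly the right pair flagged
  reads <- planted_window(37)
  map <- bin_read_pairs(reads, scheme)
  flags <- scan_genome(map, build_mask(map, NULL))
  expect_equal(nrow(flags), 1)
  expect_equal(flags$bin1, 11L) # 200 * 50 kb sits in the 11th 1-Mb bin
  expect_equal(flags$bin2, 16L)
  # background-only maps stay quiet at the default threshold
  quiet <- sapply(1:20, function(s) {
    cfg <- sim_config(
      n_chrom = 2, chrom_length = 30e6, lambda = 5, bias_sigma = 0.3,
      seed = 600 + s
    )
    st <- simulate_trans_map(cfg)
    nrow(scan_genome(st$map, build_mask(st$map, st$bands)))
  })
  expect_gte(mean(quiet == 0), 0.95)
})

test_that("calls respect the containment hierarchy of the zoom levels", {
  reads <- planted_window(41, "-+")
  scheme <- bin_scheme(finemap_assembly())
  calls <- finemap_breakpoints(reads, scheme)
  expect_equal(calls$status, "ok")
  bs <- 1e6
  # 50-kb corner inside the 3-Mb window around the coarse bin
  expect_gte(calls$start1, (calls$coarse_bin1 - 1) * bs - 1e6)
  expect_lte(calls$end1, calls$coarse_bin1 * bs + 1e6)
  # 1-kb refinement (when present) inside the corner bin
  if (calls$refinement_status == "refined") {
    expect_gte(calls$refined_start1, calls$start1)
    expect_lte(calls$refined_end1, calls$end1)
    expect_gte(calls$refined_start2, calls$start2)
    expect_lte(calls$refined_end2, calls$end2)
  }
})
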