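#' Synthetic study configuration
#'
#' Describes the generative model behind every synthetic input: a genome of
#' equal-length chromosomes; Poisson trans contact counts with
#' multiplicative log-normal per-bin biases (subsuming coverage, mappability
#' and restriction-site effects in one factor); block-structured A/B
#' compartments with contact multipliers; optional multi-megabase proximity
#' hotspots between band pairs; gene intervals enriched in the A
#' compartment (the PC1 orientation anchor); and labelled translocation
#' catalogs.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Chromosome length(s) in bp (default 100 Mb, i.e. 100
#'   one-megabase bins).
#' @param bin_size Bin width (default 1 Mb).
#' @param lambda Expected reads per unbiased trans bin pair (default 50).
#' @param bias_sigma Log-normal SD of per-bin biases (default 0.3).
#' @param block_bins Mean compartment block length in bins (default 10).
#' @param m_aa,m_bb,m_ab Compartment contact multipliers (defaults 1.4,
#'   1.2, 0.7: both homotypic contacts enriched, A-A strongest).
#' @param gene_frac_a,gene_frac_b Gene coverage fraction per bin in the A
#'   and B compartments (defaults 0.5, 0.1).
#' @param band_bins Range of cytogenetic band widths in bins
#'   (default `c(2, 5)`; use `c(1, 1)` for single-bin bands).
#' @param hotspots Tibble of planted proximity hotspots: `chrom_a`,
#'   `band_a`, `chrom_b`, `band_b`, `fold`.
#' @param translocations Tibble of planted unbalanced translocations for
#'   read-level simulation: `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `orientation` (`"++"` etc.), `n_reads`, `alpha`, `delta`.
#' @param background_reads Uniform background read pairs added per
#'   chromosome pair to the read-level output (default 0; use a few hundred
#'   so read-derived maps have genome-wide coverage like real libraries).
#' @param n_true,n_null Catalog composition: pairs sampled from hotspot
#'   band pairs vs uniformly random inter-chromosomal band pairs.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 100e6, bin_size = 1e6,
                       lambda = 50, bias_sigma = 0.3, block_bins = 10,
                       m_aa = 1.4, m_bb = 1.2, m_ab = 0.7,
                       gene_frac_a = 0.5, gene_frac_b = 0.1,
                       band_bins = c(2, 5), hotspots = NULL,
                       translocations = NULL, background_reads = 0,
                       n_true = 0, n_null = 0, seed = 1) {
  stopifnot(
    lambda >= 0, bias_sigma >= 0, m_aa > 0, m_bb > 0, m_ab > 0,
    n_chrom >= 2, all(band_bins >= 1)
  )
  if (!is.null(hotspots)) stopifnot(all(hotspots$fold > 0))
  if (!is.null(translocations)) stopifnot(all(translocations$alpha > 0))
  structure(
    list(
      n_chrom = n_chrom,
      chrom_length = rep_len(chrom_length, n_chrom), bin_size = bin_size,
      lambda = lambda, bias_sigma = bias_sigma, block_bins = block_bins,
      m_aa = m_aa, m_bb = m_bb, m_ab = m_ab,
      gene_frac_a = gene_frac_a, gene_frac_b = gene_frac_b,
      band_bins = band_bins, hotspots = hotspots,
      translocations = translocations, background_reads = background_reads,
      n_true = n_true, n_null = n_null, seed = seed
    ),
    class = "sim_config"
  )
}

# split an arm's bins into named bands; every other multi-bin band is
# emitted as .1/.2 sub-bands so prefix matching gets exercised
sim_arm_bands <- function(chrom, arm, first_bin, last_bin, bin_size, chrom_len,
                          band_bins) {
  n <- last_bin - first_bin + 1
  widths <- integer()
  while (sum(widths) < n) {
    w <- if (band_bins[1] == band_bins[2]) {
      band_bins[1]
    } else {
      sample(seq(band_bins[1], band_bins[2]), 1)
    }
    widths <- c(widths, w)
  }
  widths[length(widths)] <- widths[length(widths)] - (sum(widths) - n)
  widths <- widths[widths > 0]
  starts <- first_bin - 1 + cumsum(c(0, widths[-length(widths)]))
  out <- purrr::map_dfr(seq_along(widths), function(k) {
    name <- paste0(arm, 20 + k)
    s <- starts[k] * bin_size
    e <- min((starts[k] + widths[k]) * bin_size, chrom_len)
    stain <- if (k %% 2 == 1) "gneg" else "gpos50"
    if (widths[k] >= 2 && k %% 2 == 0) {
      mid <- s + floor(widths[k] / 2) * bin_size
      tibble::tibble(
        chrom = chrom, start = c(s, mid), end = c(mid, e),
        band = paste0(name, c(".1", ".2")), stain = stain
      )
    } else {
      tibble::tibble(chrom = chrom, start = s, end = e, band = name, stain = stain)
    }
  })
  out
}

#' Simulate a genome assembly with cytogenetic bands
#'
#' Builds the assembly and a cytoBand table with one centromeric (`acen`)
#' band per chromosome (a single bin at mid-chromosome, named `q11`) and
#' alternating named p/q bands whose unions are exactly recoverable by
#' [band_to_region()].
#'
#' @param config A [sim_config()].
#' @return List with `assembly`, `scheme`, and `bands`.
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, {
    assembly <- genome_assembly(
      paste0("chr", seq_len(config$n_chrom)),
      config$chrom_length
    )
    scheme <- bin_scheme(assembly, config$bin_size)
    bands <- purrr::map_dfr(seq_len(config$n_chrom), function(ci) {
      ch <- assembly$chrom[ci]
      n <- scheme$chroms$n_bins[ci]
      len <- assembly$length[ci]
      cen <- ceiling(n / 2)
      dplyr::bind_rows(
        sim_arm_bands(ch, "p", 1, cen - 1, config$bin_size, len, config$band_bins),
        tibble::tibble(
          chrom = ch, start = (cen - 1) * config$bin_size,
          end = min(cen * config$bin_size, len), band = "q11", stain = "acen"
        ),
        sim_arm_bands(ch, "q", cen + 1, n, config$bin_size, len, config$band_bins)
      )
    })
    list(assembly = assembly, scheme = scheme, bands = bands)
  })
}

# per-bin truth: biases and compartment labels
sim_truth_tracks <- function(config, scheme) {
  bins <- scheme_bins(scheme)
  bias <- stats::rlnorm(nrow(bins), 0, config$bias_sigma)
  label <- character(nrow(bins))
  for (ch in scheme$chroms$chrom) {
    sel <- which(bins$chrom == ch)
    lab <- character(0)
    cur <- sample(c("A", "B"), 1)
    while (length(lab) < length(sel)) {
      len <- stats::rgeom(1, 1 / config$block_bins) + 1
      lab <- c(lab, rep(cur, len))
      cur <- if (cur == "A") "B" else "A"
    }
    label[sel] <- lab[seq_along(sel)]
  }
  tibble::tibble(chrom = bins$chrom, bin = bins$bin, bias = bias, label = label)
}

# resolve hotspot band pairs to bin blocks
sim_hotspot_blocks <- function(config, scheme, bands) {
  if (is.null(config$hotspots) || nrow(config$hotspots) == 0) {
    return(NULL)
  }
  purrr::map_dfr(seq_len(nrow(config$hotspots)), function(i) {
    h <- config$hotspots[i, ]
    ra <- band_to_region(bands, h$chrom_a, h$band_a)
    rb <- band_to_region(bands, h$chrom_b, h$band_b)
    ba <- region_bin_range(scheme, ra$chrom, ra$start, ra$end)
    bb <- region_bin_range(scheme, rb$chrom, rb$start, rb$end)
    tibble::tibble(
      chrom_a = ra$chrom, first_a = ba$first_bin, last_a = ba$last_bin,
      chrom_b = rb$chrom, first_b = bb$first_bin, last_b = bb$last_bin,
      fold = h$fold
    )
  })
}

#' Simulate a trans contact map
#'
#' Draws every trans bin-pair count independently as
#' \eqn{O(i,j) \sim Poisson(\lambda b_i b_j m(l_i, l_j) f(i,j))} with
#' log-normal biases \eqn{b}, compartment multipliers \eqn{m} and hotspot
#' folds \eqn{f}.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()] (generated if `NULL`).
#' @return List: `map` (a `contact_map`), `truth` (per-bin `bias`, `label`;
#'   `hotspots` as bin blocks), plus the genome pieces.
#' @export
simulate_trans_map <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  scheme <- genome$scheme
  with_seed(config$seed + 1L, {
    tracks <- sim_truth_tracks(config, scheme)
    hot <- sim_hotspot_blocks(config, scheme, genome$bands)
    mult <- matrix(
      c(config$m_aa, config$m_ab, config$m_ab, config$m_bb), 2, 2,
      dimnames = list(c("A", "B"), c("A", "B"))
    )
    blocks <- lapply(canonical_pairs(scheme), function(k) {
      p <- strsplit(k, "|", fixed = TRUE)[[1]]
      ta <- tracks[tracks$chrom == p[1], ]
      tb <- tracks[tracks$chrom == p[2], ]
      rate <- config$lambda * outer(ta$bias, tb$bias) *
        mult[match(ta$label, c("A", "B")), match(tb$label, c("A", "B")), drop = FALSE]
      if (!is.null(hot)) {
        for (i in seq_len(nrow(hot))) {
          h <- hot[i, ]
          if (h$chrom_a == p[1] && h$chrom_b == p[2]) {
            rate[h$first_a:h$last_a, h$first_b:h$last_b] <-
              rate[h$first_a:h$last_a, h$first_b:h$last_b] * h$fold
          } else if (h$chrom_a == p[2] && h$chrom_b == p[1]) {
            rate[h$first_b:h$last_b, h$first_a:h$last_a] <-
              rate[h$first_b:h$last_b, h$first_a:h$last_a] * h$fold
          }
        }
      }
      matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
    })
    names(blocks) <- canonical_pairs(scheme)
    c(
      genome,
      list(
        map = new_contact_map(scheme, blocks),
        truth = list(tracks = tracks, hotspots = hot)
      )
    )
  })
}

#' Simulate gene intervals anchored to the A compartment
#'
#' Emits one interval per bin covering `gene_frac_a` of A-compartment bins
#' and `gene_frac_b` of B-compartment bins, so gene content correlates with
#' the open compartment and anchors the PC1 sign.
#'
#' @param config A [sim_config()].
#' @param scheme A [bin_scheme()].
#' @param tracks Truth tracks from [simulate_trans_map()].
#' @return Tibble of gene intervals (`chrom`, `start`, `end`).
#' @export
simulate_genes <- function(config, scheme, tracks) {
  bins <- scheme_bins(scheme)
  frac <- ifelse(tracks$label == "A", config$gene_frac_a, config$gene_frac_b)
  keep <- frac > 0
  tibble::tibble(
    chrom = bins$chrom[keep],
    start = bins$start[keep],
    end = bins$start[keep] + frac[keep] * (bins$end[keep] - bins$start[keep])
  )
}

#' Simulate reads from an unbalanced translocation
#'
#' Reads emanate from the breakpoint corner `(x0, y0)` into the single
#' quadrant fixed by `orientation`; the summed distance from the corner
#' \eqn{s = d_1 + d_2} follows the truncated power law
#' \eqn{f(s) \propto (s + \delta)^{-\alpha}} on `[0, span]` (inverse-CDF
#' sampling) and is split uniformly between the two chromosomes, giving the
#' one-corner decay pattern an unbalanced fusion imprints on trans maps.
#'
#' @param chrom1,x0,chrom2,y0 Breakpoint position.
#' @param orientation Quadrant code `"++"`, `"+-"`, `"-+"`, `"--"` (`+`
#'   opens toward increasing coordinates).
#' @param n_reads Number of read pairs.
#' @param alpha Decay exponent (default 1, the classic ~1/s contact decay).
#' @param delta Decay offset in bp avoiding the singularity (default 1 kb).
#' @param span Maximum summed distance (default 1.4 Mb, keeping reads
#'   inside a 3-Mb fine-mapping window).
#' @return Read-pair tibble (`chrom1`, `pos1`, `chrom2`, `pos2`).
#' @export
simulate_translocation_reads <- function(chrom1, x0, chrom2, y0, orientation,
                                         n_reads, alpha = 1, delta = 1e3,
                                         span = 1.4e6) {
  stopifnot(n_reads >= 1, alpha > 0, delta > 0)
  u <- stats::runif(n_reads)
  if (abs(alpha - 1) < 1e-12) {
    s <- delta * ((1 + span / delta)^u - 1)
  } else {
    a1 <- 1 - alpha
    s <- (u * ((span + delta)^a1 - delta^a1) + delta^a1)^(1 / a1) - delta
  }
  d1 <- stats::runif(n_reads) * s
  d2 <- s - d1
  sx <- if (substr(orientation, 1, 1) == "+") 1 else -1
  sy <- if (substr(orientation, 2, 2) == "+") 1 else -1
  tibble::tibble(
    chrom1 = chrom1, pos1 = x0 + sx * d1,
    chrom2 = chrom2, pos2 = y0 + sy * d2
  )
}

#' Uniform background read pairs on a chromosome pair
#'
#' @param assembly A [genome_assembly()].
#' @param chrom1,chrom2 Chromosome pair.
#' @param n Number of read pairs.
#' @return Read-pair tibble.
#' @export
simulate_uniform_reads <- function(assembly, chrom1, chrom2, n) {
  l1 <- assembly$length[match(chrom1, assembly$chrom)]
  l2 <- assembly$length[match(chrom2, assembly$chrom)]
  tibble::tibble(
    chrom1 = chrom1, pos1 = stats::runif(n, 0, l1),
    chrom2 = chrom2, pos2 = stats::runif(n, 0, l2)
  )
}

# one non-acen band per draw, uniformly over a chromosome's bands
sim_sample_band <- function(bands, chrom, n) {
  cand <- bands[bands$chrom == chrom & bands$stain != "acen", ]
  cand[sample.int(nrow(cand), n, replace = TRUE), ]
}

#' Simulate a labelled translocation catalog
#'
#' Samples `n_true` pairs from the configured hotspot band pairs and
#' `n_null` pairs from uniformly random inter-chromosomal band pairs, and
#' emits both a karyotype-notation catalog and a breakpoint catalog
#' (positions at band midpoints, supporting reads >= 3).
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List: `catalog` (karyotype TSV columns plus the truth flag
#'   `is_true`), `breakpoints` (breakpoint TSV columns plus `is_true`).
#' @export
simulate_catalog <- function(config, genome) {
  bands <- genome$bands
  assembly <- genome$assembly
  if (config$n_true > 0 &&
    (is.null(config$hotspots) || nrow(config$hotspots) == 0)) {
    stop("n_true > 0 requires configured hotspots", call. = FALSE)
  }
  with_seed(config$seed + 2L, {
    rows <- list()
    if (config$n_true > 0) {
      idx <- sample.int(nrow(config$hotspots), config$n_true, replace = TRUE)
      rows$true <- config$hotspots[idx, c("chrom_a", "band_a", "chrom_b", "band_b")]
      rows$true$is_true <- TRUE
    }
    if (config$n_null > 0) {
      cpair <- t(vapply(
        seq_len(config$n_null),
        function(i) sample(assembly$chrom, 2),
        character(2)
      ))
      ba <- purrr::map_chr(cpair[, 1], function(ch) sim_sample_band(bands, ch, 1)$band)
      bb <- purrr::map_chr(cpair[, 2], function(ch) sim_sample_band(bands, ch, 1)$band)
      rows$null <- tibble::tibble(
        chrom_a = cpair[, 1], band_a = ba,
        chrom_b = cpair[, 2], band_b = bb, is_true = FALSE
      )
    }
    sel <- dplyr::bind_rows(rows)
    if (nrow(sel) == 0) stop("empty catalog configuration", call. = FALSE)
    # band labels in notation carry the parent label (sub-band names as-is)
    notation <- sprintf(
      "t(%s;%s)(%s;%s)",
      sub("^chr", "", sel$chrom_a), sub("^chr", "", sel$chrom_b),
      sel$band_a, sel$band_b
    )
    catalog <- tibble::tibble(
      notation = notation,
      dataset_id = "synthetic",
      tissue_class = sample(c("blood", "non_blood"), nrow(sel), replace = TRUE),
      recurrence_count = 1L + stats::rpois(nrow(sel), 2),
      is_true = sel$is_true
    )
    mid <- function(chrom, band) {
      r <- band_to_region(bands, chrom, band)
      floor((r$start + r$end) / 2)
    }
    breakpoints <- tibble::tibble(
      chrom1 = sel$chrom_a,
      pos1 = purrr::map2_dbl(sel$chrom_a, sel$band_a, mid),
      chrom2 = sel$chrom_b,
      pos2 = purrr::map2_dbl(sel$chrom_b, sel$band_b, mid),
      supporting_reads = 3L + stats::rpois(nrow(sel), 5),
      dataset_id = "synthetic",
      is_true = sel$is_true
    )
    list(catalog = catalog, breakpoints = breakpoints)
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates genome, contact map, genes, catalog, and read-level
#' translocation simulation from one configuration; byte-identical outputs
#' for identical seeds.
#'
#' @param config A [sim_config()].
#' @return List with `assembly`, `scheme`, `bands`, `map`, `truth`,
#'   `genes`, `catalog`, `breakpoints`, `reads` (planted translocation
#'   reads, `NULL` when none are configured).
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  sim <- simulate_trans_map(config, genome)
  genes <- simulate_genes(config, sim$scheme, sim$truth$tracks)
  cat_parts <- if (config$n_true + config$n_null > 0) {
    simulate_catalog(config, genome)
  } else {
    list(catalog = NULL, breakpoints = NULL)
  }
  reads <- NULL
  has_tr <- !is.null(config$translocations) && nrow(config$translocations) > 0
  if (has_tr || config$background_reads > 0) {
    reads <- with_seed(config$seed + 3L, {
      tr_reads <- if (has_tr) {
        purrr::map_dfr(seq_len(nrow(config$translocations)), function(i) {
          tr <- config$translocations[i, ]
          simulate_translocation_reads(
            tr$chrom1, tr$pos1, tr$chrom2, tr$pos2, tr$orientation,
            tr$n_reads, tr$alpha, tr$delta
          )
        })
      } else {
        NULL
      }
      bg_reads <- NULL
      if (config$background_reads > 0) {
        cp <- utils::combn(sim$assembly$chrom, 2)
        bg_reads <- purrr::map_dfr(seq_len(ncol(cp)), function(i) {
          simulate_uniform_reads(
            sim$assembly, cp[1, i], cp[2, i], config$background_reads
          )
        })
      }
      dplyr::bind_rows(tr_reads, bg_reads)
    })
  }
  c(sim, list(
    genes = genes, catalog = cat_parts$catalog,
    breakpoints = cat_parts$breakpoints, reads = reads
  ))
}

#' Write all synthetic inputs as plain-text files
#'
#' Emits the file kinds every reader in the package consumes: cytoBand TSV,
#' contact triplets, gene BED, karyotype catalog TSV, breakpoint TSV,
#' read-pair TSV, and per-bin truth tracks.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sim_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cytoband = file.path(dir, "cytoBand.tsv"),
    contacts = file.path(dir, "contacts.tsv"),
    genes = file.path(dir, "genes.bed"),
    catalog = file.path(dir, "catalog.tsv"),
    breakpoints = file.path(dir, "breakpoints.tsv"),
    reads = file.path(dir, "reads.tsv"),
    truth = file.path(dir, "truth_tracks.tsv")
  )
  readr::write_lines(sprintf(
    "%s\t%d\t%d\t%s\t%s", study$bands$chrom, as.integer(study$bands$start),
    as.integer(study$bands$end), study$bands$band, study$bands$stain
  ), paths["cytoband"])
  write_contact_triplets(study$map, paths["contacts"])
  readr::write_lines(sprintf(
    "%s\t%d\t%d", study$genes$chrom, as.integer(study$genes$start),
    as.integer(study$genes$end)
  ), paths["genes"])
  if (!is.null(study$catalog)) readr::write_tsv(study$catalog, paths["catalog"])
  if (!is.null(study$breakpoints)) readr::write_tsv(study$breakpoints, paths["breakpoints"])
  if (!is.null(study$reads)) {
    readr::write_lines(sprintf(
      "%s\t%d\t%s\t%d", study$reads$chrom1, as.integer(study$reads$pos1),
      study$reads$chrom2, as.integer(study$reads$pos2)
    ), paths["reads"])
  }
  readr::write_tsv(study$truth$tracks, paths["truth"])
  invisible(paths[file.exists(paths)])
}

#' Read a read-pair file
#'
#' Tab-separated `chrom1 pos1 chrom2 pos2 [strand1 strand2]`; strands are
#' ignored.
#'
#' @param file Path or character vector of lines.
#' @return Read-pair tibble.
#' @export
read_read_pairs <- function(file) {
  if (length(file) == 1 && !grepl("\t", file) && file.exists(file)) {
    lines <- readr::read_lines(file)
  } else {
    lines <- file
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom1 = character(), pos1 = numeric(),
      chrom2 = character(), pos2 = numeric()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop("read-pair parse error: fewer than 4 columns", call. = FALSE)
  }
  tibble::tibble(
    chrom1 = vapply(fields, `[`, character(1), 1),
    pos1 = as.numeric(vapply(fields, `[`, character(1), 2)),
    chrom2 = vapply(fields, `[`, character(1), 3),
    pos2 = as.numeric(vapply(fields, `[`, character(1), 4))
  )
}
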