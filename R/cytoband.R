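#' Read and validate a cytogenetic band table
#'
#' Parses UCSC-style cytoBand text: five tab-separated columns (chrom, start,
#' end, band name, Giemsa stain), 0-based half-open coordinates. Centromeric
#' bands carry stain `"acen"`.
#'
#' @param file Path to a cytoBand file, or a character vector of lines.
#' @return Tibble with columns `chrom`, `start`, `end`, `band`, `stain`,
#'   sorted by chromosome and start. Bands on a chromosome must be
#'   non-overlapping.
#' @export
#' @examples
#' parse_cytoband(c("chr1\t0\t2300000\tp36.33\tgneg"))
parse_cytoband <- function(file) {
  if (length(file) == 1 && !grepl("\t", file) && file.exists(file)) {
    lines <- readr::read_lines(file)
  } else {
    lines <- file
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      band = character(), stain = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop("cytoBand parse error at line ", bad, ": expected 5 tab-separated columns, got ",
      nf[bad],
      call. = FALSE
    )
  }
  m <- matrix(unlist(fields), ncol = 5, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("cytoBand parse error at line ", bad, ": non-numeric coordinates", call. = FALSE)
  }
  out <- tibble::tibble(chrom = m[, 1], start = start, end = end, band = m[, 4], stain = m[, 5])
  if (any(out$start < 0 | out$start >= out$end)) {
    stop("cytoBand validation error: need 0 <= start < end", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  overlap <- out |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()] & dplyr::n() > 1)) |>
    dplyr::filter(.data$bad)
  if (nrow(overlap) > 0) {
    stop("cytoBand validation error: overlapping bands on ",
      paste(overlap$chrom, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# does band name `name` match prefix-complete label `label`?
# exact match, or extension by sub-band digits after a "."
band_label_matches <- function(name, label) {
  name == label | startsWith(name, paste0(label, "."))
}

#' Map a cytogenetic band label to genomic coordinates
#'
#' Resolves a band label such as `"q34"` to the union (minimum start, maximum
#' end) of all bands on the chromosome whose name is the label itself or a
#' sub-band refinement of it (`q34` matches `q34`, `q34.1`, `q34.11`, but
#' never `q3` matching `q34`, nor `q34` matching `q341`).
#'
#' @param bands Cytoband tibble from [parse_cytoband()].
#' @param chrom Chromosome label.
#' @param label Band label, e.g. `"q34"` or `"q34.1"`.
#' @return One-row tibble with `chrom`, `start`, `end`.
#' @export
band_to_region <- function(bands, chrom, label) {
  hit <- bands[bands$chrom == chrom & band_label_matches(bands$band, label), ]
  if (nrow(hit) == 0) {
    stop("no band matching '", label, "' on ", chrom, call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start = min(hit$start), end = max(hit$end))
}

# strip an optional "chr" prefix for karyotype chromosome tokens
karyotype_chrom <- function(token, chroms) {
  cand <- c(token, paste0("chr", token))
  hit <- cand[cand %in% chroms]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Parse karyotype translocation notation into region pairs
#'
#' Parses standard `t(c1;c2)(b1;b2)` notation against a band table. A 3-way
#' translocation `t(c1;c2;c3)(b1;b2;b3)` is decomposed into its three 2-way
#' pairs. Records are rejected (with a reason code, never silently) when they
#' have more than three partners, involve a whole chromosomal arm (band label
#' exactly `"p"` or `"q"`), repeat a chromosome (intra-chromosomal), fail to
#' parse, or name a band that does not exist.
#'
#' @param notation Character vector of karyotype strings.
#' @param bands Cytoband tibble from [parse_cytoband()].
#' @param assembly Optional [genome_assembly()] fixing the chromosome order
#'   used for canonical pair orientation; defaults to the order of first
#'   appearance in `bands`.
#' @return Tibble with one row per emitted pair (or per rejected record):
#'   `source_label`, `status` (`"ok"` or a reason code among `whole_arm`,
#'   `too_many_partners`, `intra_chromosomal`, `parse_error`,
#'   `band_not_found`), and for `"ok"` rows the two regions `chrom_a`,
#'   `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b` in canonical order
#'   (lower chromosome index first).
#' @export
#' @examples
#' bands <- parse_cytoband(c(
#'   "chr9\t0\t50000000\tp13\tgneg",
#'   "chr9\t50000000\t140000000\tq34\tgpos",
#'   "chr22\t0\t20000000\tp11\tgneg",
#'   "chr22\t20000000\t50000000\tq13\tgneg"
#' ))
#' parse_karyotype("t(9;22)(p13;q13)", bands)
parse_karyotype <- function(notation, bands, assembly = NULL) {
  chrom_order <- if (is.null(assembly)) unique(bands$chrom) else assembly$chrom
  one <- function(nt) {
    reject <- function(status) {
      tibble::tibble(
        source_label = nt, status = status,
        chrom_a = NA_character_, start_a = NA_real_, end_a = NA_real_,
        chrom_b = NA_character_, start_b = NA_real_, end_b = NA_real_
      )
    }
    m <- regmatches(nt, regexec("^t\\(([^)]*)\\)\\(([^)]*)\\)$", nt))[[1]]
    if (length(m) != 3) {
      return(reject("parse_error"))
    }
    chroms <- strsplit(m[2], ";", fixed = TRUE)[[1]]
    labels <- strsplit(m[3], ";", fixed = TRUE)[[1]]
    k <- length(chroms)
    if (k != length(labels) || k < 2 || any(!nzchar(chroms)) || any(!nzchar(labels))) {
      return(reject("parse_error"))
    }
    if (k > 3) {
      return(reject("too_many_partners"))
    }
    if (any(labels %in% c("p", "q"))) {
      return(reject("whole_arm"))
    }
    resolved <- unname(vapply(chroms, karyotype_chrom, character(1), chroms = chrom_order))
    if (anyNA(resolved)) {
      return(reject("band_not_found"))
    }
    if (anyDuplicated(resolved)) {
      return(reject("intra_chromosomal"))
    }
    if (!all(grepl("^[pq][0-9]+(\\.[0-9]+)?$", labels))) {
      return(reject("parse_error"))
    }
    regions <- vector("list", k)
    for (i in seq_len(k)) {
      regions[[i]] <- tryCatch(
        band_to_region(bands, resolved[i], labels[i]),
        error = function(e) NULL
      )
      if (is.null(regions[[i]])) {
        return(reject("band_not_found"))
      }
    }
    combos <- utils::combn(k, 2)
    purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
      a <- regions[[combos[1, ci]]]
      b <- regions[[combos[2, ci]]]
      # canonical orientation: lower chromosome index first
      if (match(a$chrom, chrom_order) > match(b$chrom, chrom_order)) {
        tmp <- a
        a <- b
        b <- tmp
      }
      tibble::tibble(
        source_label = nt, status = "ok",
        chrom_a = a$chrom, start_a = a$start, end_a = a$end,
        chrom_b = b$chrom, start_b = b$start, end_b = b$end
      )
    })
  }
  purrr::map_dfr(notation, one)
}

#' Parse a karyotype-notation catalog
#'
#' Applies [parse_karyotype()] to a catalog table (columns `notation`,
#' optionally `dataset_id`, `tissue_class`, `recurrence_count`), carrying the
#' metadata onto every emitted pair.
#'
#' @param catalog Data frame with a `notation` column.
#' @param bands Cytoband tibble.
#' @param assembly Optional [genome_assembly()].
#' @return Tibble of pairs as in [parse_karyotype()], with the catalog's
#'   metadata columns joined on.
#' @export
parse_karyotype_catalog <- function(catalog, bands, assembly = NULL) {
  stopifnot("notation" %in% names(catalog))
  meta <- catalog
  meta$source_label <- meta$notation
  meta$notation <- NULL
  if (!"dataset_id" %in% names(meta)) meta$dataset_id <- "catalog"
  if (!"tissue_class" %in% names(meta)) meta$tissue_class <- "unspecified"
  if (!"recurrence_count" %in% names(meta)) meta$recurrence_count <- 1L
  pairs <- parse_karyotype(catalog$notation, bands, assembly)
  dplyr::left_join(pairs, dplyr::distinct(meta, .data$source_label, .keep_all = TRUE),
    by = "source_label"
  )
}

#' Convert breakpoint records to bin-level translocation pairs
#'
#' Maps sequencing-derived breakpoints to the bin containing each position.
#' Records with fewer than `min_supporting_reads` supporting reads are
#' dropped (status `low_support`), as are intra-chromosomal records
#' (`intra_chromosomal`). Positions outside the assembly are an error.
#'
#' @param records Data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `supporting_reads`, and optionally `dataset_id`.
#' @param scheme A [bin_scheme()].
#' @param min_supporting_reads Minimum read support to keep a record
#'   (default 3).
#' @return Tibble with `source_label`, `status`, and for kept records the
#'   bin-snapped regions in canonical chromosome order.
#' @export
breakpoints_to_pairs <- function(records, scheme, min_supporting_reads = 3) {
  req <- c("chrom1", "pos1", "chrom2", "pos2", "supporting_reads")
  if (!all(req %in% names(records))) {
    stop("breakpoint records need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0) {
    return(tibble::tibble(
      source_label = character(), status = character(),
      chrom_a = character(), start_a = numeric(), end_a = numeric(),
      chrom_b = character(), start_b = numeric(), end_b = numeric()
    ))
  }
  b1 <- bin_of_position(scheme, records$chrom1, records$pos1)
  b2 <- bin_of_position(scheme, records$chrom2, records$pos2)
  bs <- scheme$bin_size
  label <- sprintf(
    "%s:%d-%s:%d", records$chrom1, as.integer(records$pos1),
    records$chrom2, as.integer(records$pos2)
  )
  status <- rep("ok", n)
  status[records$supporting_reads < min_supporting_reads] <- "low_support"
  status[status == "ok" & records$chrom1 == records$chrom2] <- "intra_chromosomal"
  i1 <- chrom_index(scheme, records$chrom1)
  i2 <- chrom_index(scheme, records$chrom2)
  swap <- i1 > i2
  ca <- ifelse(swap, records$chrom2, records$chrom1)
  cb <- ifelse(swap, records$chrom1, records$chrom2)
  ba <- ifelse(swap, b2, b1)
  bb <- ifelse(swap, b1, b2)
  out <- tibble::tibble(
    source_label = label, status = status,
    chrom_a = ca, start_a = (ba - 1) * bs,
    end_a = pmin(ba * bs, chrom_length(scheme, ca)),
    chrom_b = cb, start_b = (bb - 1) * bs,
    end_b = pmin(bb * bs, chrom_length(scheme, cb))
  )
  drop <- out$status != "ok"
  out$chrom_a[drop] <- NA
  out$start_a[drop] <- NA
  out$end_a[drop] <- NA
  out$chrom_b[drop] <- NA
  out$start_b[drop] <- NA
  out$end_b[drop] <- NA
  if ("dataset_id" %in% names(records)) out$dataset_id <- records$dataset_id
  out
}

#' Keep successfully parsed pairs
#'
#' Convenience filter for catalogs produced by [parse_karyotype()],
#' [parse_karyotype_catalog()] or [breakpoints_to_pairs()]: retains rows with
#' `status == "ok"`.
#'
#' @param pairs Pair tibble with a `status` column.
#' @return The `"ok"` rows.
#' @export
ok_pairs <- function(pairs) {
  if (!"status" %in% names(pairs)) {
    return(pairs)
  }
  dplyr::filter(pairs, .data$status == "ok")
}

#' Deduplicate a catalog to unique region pairs
#'
#' @param pairs Pair tibble.
#' @return Unique rows on the two regions (first occurrence kept), the view
#'   used for per-dataset summaries.
#' @export
unique_pairs <- function(pairs) {
  dplyr::distinct(
    pairs, .data$chrom_a, .data$start_a, .data$end_a,
    .data$chrom_b, .data$start_b, .data$end_b,
    .keep_all = TRUE
  )
}
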