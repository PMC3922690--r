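#' Read a BED6+ region file
#'
#' Parses a tab-separated BED file (0-based half-open coordinates) into a
#' `GRanges` in file order — the row order of the signal matrix depends on
#' it. Track/browser/comment lines are skipped; 3-column records receive
#' generated names `locus_<i>`; duplicate names are made unique by
#' suffixing. Records whose coordinates do not parse, or with start >= end,
#' are rejected with a diagnostic naming the offending line.
#'
#' @param path Path to a BED file with >= 3 tab-separated columns.
#' @return A `GRanges` (1-based internally, as usual for Bioconductor) with
#'   locus names, optional `score`, and strand; attribute `source_path`
#'   records provenance. Errors if the file is empty or no valid record
#'   remains.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty BED file: ", path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  recs <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      warning("line ", i, ": fewer than 3 columns, rejected")
      next
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      warning("line ", i, ": coordinates do not parse as integers, rejected")
      next
    }
    if (start < 0L || start >= end) {
      warning("line ", i, ": malformed coordinates (start ", start,
              " >= end ", end, " or negative), rejected")
      next
    }
    recs[[length(recs) + 1L]] <- list(
      chrom = f[1L], start = start, end = end,
      name = if (length(f) >= 4L && nzchar(f[4L])) f[4L] else NA_character_,
      score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_,
      strand = if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*")
  }
  if (length(recs) == 0L) stop("no valid BED records in ", path)
  nm <- vapply(recs, `[[`, character(1), "name")
  nm[is.na(nm)] <- paste0("locus_", which(is.na(nm)))
  nm <- make.unique(nm)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(recs, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(recs, function(r) r$start + 1L, integer(1)),  # to 1-based
      end = vapply(recs, `[[`, integer(1), "end")),
    strand = vapply(recs, `[[`, character(1), "strand"))
  names(gr) <- nm
  gr$score <- vapply(recs, `[[`, numeric(1), "score")
  attr(gr, "source_path") <- path
  gr
}

# Shared read-loading: mapped, primary, non-supplementary, QC-pass reads as
# a GRanges of aligned reference spans (start to end, including deletions
# and splices). Duplicates are kept unless filter_dup.
.load_reads <- function(bam, filter_dup = FALSE, min_mapq = 0L) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    ok <- tryCatch({ Rsamtools::indexBam(bam); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("BAM index missing and could not be built for ", bam)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
    isDuplicate = if (filter_dup) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   mapqFilter = as.integer(min_mapq))
  GenomicRanges::granges(GenomicAlignments::readGAlignments(bam, param = param))
}

# Counts reads overlapping each query range by >= 1 base; a read spanning
# several queries contributes to each of them.
.overlap_counts <- function(reads, query) {
  missing <- setdiff(as.character(unique(GenomicRanges::seqnames(query))),
                     GenomeInfoDb::seqlevels(reads))
  if (length(missing) > 0L)
    warning("chromosome(s) absent from BAM: ",
            paste(missing, collapse = ", "), "; counting 0 there")
  suppressWarnings(GenomicRanges::countOverlaps(query, reads,
                                               ignore.strand = TRUE))
}

#' Count reads overlapping each locus
#'
#' A read is counted towards a locus if its aligned reference span overlaps
#' at least one base of the locus; unmapped, secondary, supplementary and
#' QC-fail records are excluded, duplicates kept by default, and strand is
#' ignored. A read overlapping several loci contributes to each.
#'
#' @param bam Path to a coordinate-sorted BAM file (an index is built if
#'   missing).
#' @param regions `GRanges` from [read_regions()].
#' @param filter_dup Exclude duplicate-flagged reads (default FALSE).
#' @param min_mapq Minimum mapping quality (default 0 = keep all).
#' @return Named integer vector of per-locus counts, in region order.
#'   Chromosomes present in the regions but absent from the BAM header yield
#'   0 with a warning.
#' @export
count_reads <- function(bam, regions, filter_dup = FALSE, min_mapq = 0L) {
  reads <- .load_reads(bam, filter_dup, min_mapq)
  counts <- .overlap_counts(reads, regions)
  names(counts) <- names(regions)
  counts
}

#' Build the loci x marks count matrix
#'
#' Stacks [count_reads()] vectors for one BAM file per epigenetic mark into
#' the integer matrix underlying the "absolute" signal matrix V.
#'
#' @param bams Character vector of BAM paths (>= 1).
#' @param regions `GRanges` from [read_regions()].
#' @param labels Mark labels, one per BAM; defaults to file names without
#'   the .bam extension. Duplicates are an error.
#' @inheritParams count_reads
#' @return Integer matrix, rows named by locus, columns by mark.
#' @export
build_count_matrix <- function(bams, regions, labels = NULL,
                               filter_dup = FALSE, min_mapq = 0L) {
  if (length(bams) < 1L) stop("need at least one BAM file")
  if (is.null(labels)) labels <- sub("\\.bam$", "", basename(bams))
  if (length(labels) != length(bams)) stop("one label per BAM required")
  if (anyDuplicated(labels)) stop("duplicate mark labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  M <- vapply(bams, count_reads, integer(length(regions)),
              regions = regions, filter_dup = filter_dup, min_mapq = min_mapq)
  dimnames(M) <- list(names(regions), labels)
  M
}

#' Per-window read counts within each locus
#'
#' Tiles every locus left-to-right into non-overlapping windows of the given
#' width (the last window may be shorter) and counts reads per window under
#' the same overlap rule as [count_reads()]; a read straddling a window
#' boundary is counted in every window it touches.
#'
#' @param bam BAM path.
#' @param regions `GRanges`.
#' @param window Window width in bp (>= 1), default 100.
#' @inheritParams count_reads
#' @return Named list (one element per locus, region order) of integer
#'   per-window count vectors.
#' @export
windowed_counts <- function(bam, regions, window = 100L,
                            filter_dup = FALSE, min_mapq = 0L) {
  if (window < 1L) stop("'window' must be >= 1")
  tiles <- GenomicRanges::slidingWindows(regions, width = as.integer(window),
                                         step = as.integer(window))
  flat <- unlist(tiles, use.names = FALSE)
  reads <- .load_reads(bam, filter_dup, min_mapq)
  counts <- .overlap_counts(reads, flat)
  out <- split(counts, rep(seq_along(regions), lengths(tiles)))
  names(out) <- names(regions)
  lapply(out, unname)
}
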