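#' Validate a table of genomic intervals
#'
#' Intervals are 0-based half-open (BED convention) throughout the package:
#' `start` is inclusive, `end` exclusive, and `0 <= start < end`. A `strand`
#' column (`"+"`, `"-"` or `"."`) is carried if present but ignored by all
#' overlap operations.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly validated.
#' @export
check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)
  if (!is.character(x$chrom) || any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(paste0(what, ": chrom must be non-empty character"))
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    abort(paste0(what, ": start/end must not be NA"))
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(paste0(what, ": invalid interval at row ", bad[1],
                 " (need 0 <= start < end)"))
  }
  x
}

# tibble -> GRanges (1-based closed), strand dropped; shared seqlevels keep
# findOverlaps quiet when the two sides cover different chromosomes
as_granges <- function(x, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(x$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = levels),
    ranges = IRanges::IRanges(start = as.integer(x$start) + 1L,
                              end = as.integer(x$end))
  )
}

granges_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Sort intervals deterministically
#'
#' Orders by chromosome (C-locale lexicographic), then start, then end, so
#' every interval operation yields reproducible output.
#'
#' @inheritParams check_intervals
#' @return The sorted tibble.
#' @export
sort_intervals <- function(x) {
  x <- check_intervals(x)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Overlapping pairs between two interval sets
#'
#' A bedtools-intersect analogue: reports every pair `(a_idx, b_idx)` whose
#' intervals share at least `min_overlap` bases on the same chromosome.
#' Half-open adjacency (one interval ending where the next starts) is not an
#' overlap. Strand is ignored.
#'
#' @param a,b Interval tables (see [check_intervals()]).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A tibble with columns `a_idx`, `b_idx`, `overlap_bp`, sorted by
#'   `a_idx` then `b_idx`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = c(50, 100), end = c(150, 200))
#' intersect_intervals(a, b)
#' @export
intersect_intervals <- function(a, b, min_overlap = 1) {
  a <- check_intervals(a, "a")
  b <- check_intervals(b, "b")
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer(),
                          overlap_bp = integer()))
  }
  lev <- sort(unique(c(a$chrom, b$chrom)))
  gra <- as_granges(a, lev)
  grb <- as_granges(b, lev)
  hits <- GenomicRanges::findOverlaps(gra, grb,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  out <- tibble::tibble(a_idx = ai, b_idx = bi, overlap_bp = as.integer(ov))
  dplyr::arrange(out, .data$a_idx, .data$b_idx)
}

#' Merge intervals into a disjoint union
#'
#' Joins intervals on the same chromosome whose separation is at most `gap`
#' bases (default 0, so touching intervals are joined). The output is
#' disjoint and sorted; merging never crosses chromosomes. Idempotent.
#'
#' @param x Interval table.
#' @param gap Maximum separation (bp) across which intervals are joined.
#' @return A sorted tibble of disjoint intervals.
#' @export
merge_intervals <- function(x, gap = 0) {
  x <- check_intervals(x)
  if (gap < 0) abort("gap must be >= 0")
  if (nrow(x) == 0) return(tibble::tibble(chrom = character(),
                                          start = integer(), end = integer()))
  gr <- as_granges(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(gap) + 1L,
                               ignore.strand = TRUE)
  sort_intervals(granges_to_tbl(red))
}

#' Count fragments overlapping each region
#'
#' A bedtools-coverage analogue: for each region, the number of fragments
#' overlapping it by at least one base. Used to extract RNA signal at
#' differentially enriched regions.
#'
#' @param regions,fragments Interval tables.
#' @return An integer vector, one count per row of `regions`.
#' @export
coverage_count <- function(regions, fragments) {
  regions <- check_intervals(regions, "regions")
  fragments <- check_intervals(fragments, "fragments")
  if (nrow(regions) == 0) return(integer())
  if (nrow(fragments) == 0) return(rep(0L, nrow(regions)))
  lev <- sort(unique(c(regions$chrom, fragments$chrom)))
  as.integer(GenomicRanges::countOverlaps(as_granges(regions, lev),
                                          as_granges(fragments, lev),
                                          ignore.strand = TRUE))
}
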