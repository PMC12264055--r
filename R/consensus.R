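#' Extend narrow peaks around their summits
#'
#' Narrow peaks are re-centred to a fixed window of `2 * flank` bp around
#' the called summit before entering the consensus set; the window is
#' clamped to the chromosome. Broad peaks (H3K27me3, H3K9me2 calls) are
#' never summit-extended and must not be passed here.
#'
#' @param peaks Peak tibble (from [parse_peaks()]) with `shape == "narrow"`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param flank Flank size in bp on each side of the summit (default 250).
#' @return A tibble of extended intervals; non-coordinate peak columns are
#'   carried through.
#' @export
extend_from_summit <- function(peaks, chrom_lengths, flank = 250) {
  peaks <- check_intervals(peaks, "peaks")
  if (nrow(peaks) == 0) return(peaks)
  if (!"shape" %in% names(peaks) || any(peaks$shape != "narrow")) {
    abort("extend_from_summit applies to narrow peaks only; broad peaks enter the consensus at their called coordinates")
  }
  if (!"summit_offset" %in% names(peaks)) abort("peaks need a summit_offset column")
  missing <- setdiff(unique(peaks$chrom), names(chrom_lengths))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) absent from chrom_lengths: ",
                 paste(missing, collapse = ", ")))
  }
  clen <- unname(chrom_lengths[peaks$chrom])
  if (any(peaks$end > clen)) abort("peak end exceeds chromosome length")
  summit <- peaks$start + peaks$summit_offset
  out <- peaks
  out$start <- pmax(0L, as.integer(summit - flank))
  out$end <- pmin(as.integer(clen), as.integer(summit + flank))
  out
}

#' Keep peaks conserved across the two control types
#'
#' Peak calling against both an input and an H3 control yields two peak
#' lists per sample; only peaks conserved between the two are trusted. The
#' input-controlled list is the reference: its peaks are kept when they
#' overlap (by at least 1 bp) any peak in the H3-controlled list. The
#' result is always a subset of `peaks_input_ctrl`.
#'
#' @param peaks_input_ctrl,peaks_h3_ctrl Peak tibbles for the same
#'   (mark, timepoint, replicate) called against the input and H3 controls.
#' @return The conserved subset of `peaks_input_ctrl`.
#' @export
conserve_dual_control <- function(peaks_input_ctrl, peaks_h3_ctrl) {
  peaks_input_ctrl <- check_intervals(peaks_input_ctrl, "input-controlled peaks")
  peaks_h3_ctrl <- check_intervals(peaks_h3_ctrl, "H3-controlled peaks")
  if (nrow(peaks_input_ctrl) == 0 || nrow(peaks_h3_ctrl) == 0) {
    return(peaks_input_ctrl[0, ])
  }
  hits <- intersect_intervals(peaks_input_ctrl, peaks_h3_ctrl)
  peaks_input_ctrl[sort(unique(hits$a_idx)), ]
}

#' Build the consensus region set
#'
#' Combines conserved peaks from every mark and timepoint (narrow peaks
#' already summit-extended, broad peaks as called) into a disjoint, sorted
#' set of consensus regions by merging touching or overlapping intervals.
#' Region ids `CR000001, ...` are assigned in sorted order, and each region
#' records which (mark, timepoint) combinations contributed peaks to it.
#'
#' @param peaks A tibble of conserved peaks with interval columns plus
#'   `mark` and `timepoint`.
#' @param chrom_lengths Named integer vector of chromosome lengths; every
#'   peak chromosome must be present.
#' @return A tibble with `region_id`, `chrom`, `start`, `end` and a
#'   `provenance` list-column of contributing `"mark@timepoint"` labels.
#' @export
build_consensus <- function(peaks, chrom_lengths) {
  peaks <- check_intervals(peaks, "peaks")
  for (col in c("mark", "timepoint")) {
    if (!col %in% names(peaks)) abort(paste0("peaks need a ", col, " column"))
  }
  missing <- setdiff(unique(peaks$chrom), names(chrom_lengths))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) absent from chrom_lengths: ",
                 paste(missing, collapse = ", ")))
  }
  regions <- merge_intervals(peaks[, c("chrom", "start", "end")])
  if (nrow(regions) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          provenance = list()))
  }
  regions$region_id <- sprintf("CR%06d", seq_len(nrow(regions)))
  hits <- intersect_intervals(regions, peaks)
  labs <- paste(peaks$mark, peaks$timepoint, sep = "@")
  prov <- split(labs[hits$b_idx], factor(hits$a_idx, levels = seq_len(nrow(regions))))
  regions$provenance <- lapply(prov, function(p) sort(unique(p)))
  regions[, c("region_id", "chrom", "start", "end", "provenance")]
}

#' Curate a consensus region set from per-sample dual-control peak calls
#'
#' Full consensus curation: per (mark, timepoint), replicate peak calls are
#' pooled, the dual-control conservation rule applied, narrow peaks
#' summit-extended, and the union merged into consensus regions. With
#' `strict_replicates = TRUE` a conserved peak is additionally required to
#' overlap a conserved peak from another replicate of the same sample.
#'
#' @param peak_calls A tibble of peaks with columns `mark`, `timepoint`,
#'   `replicate`, `control` (`"input"` or `"H3"`) plus the peak columns of
#'   [parse_peaks()].
#' @param chrom_lengths Named chromosome lengths.
#' @param flank Summit flank for narrow peaks (default 250 bp).
#' @param strict_replicates Require cross-replicate support (default FALSE;
#'   replicates are pooled).
#' @return A consensus region tibble (see [build_consensus()]).
#' @export
curate_consensus <- function(peak_calls, chrom_lengths, flank = 250,
                             strict_replicates = FALSE) {
  peak_calls <- check_intervals(peak_calls, "peak_calls")
  need <- c("mark", "timepoint", "replicate", "control", "shape")
  miss <- setdiff(need, names(peak_calls))
  if (length(miss) > 0) {
    abort(paste0("peak_calls missing column(s): ", paste(miss, collapse = ", ")))
  }
  groups <- dplyr::distinct(peak_calls, .data$mark, .data$timepoint)
  conserved <- purrr::pmap(groups, function(mark, timepoint) {
    sub <- peak_calls[peak_calls$mark == mark & peak_calls$timepoint == timepoint, ]
    inp <- sub[sub$control == "input", ]
    h3 <- sub[sub$control == "H3", ]
    kept <- conserve_dual_control(inp, h3)
    if (strict_replicates && nrow(kept) > 0) {
      other <- function(i) {
        o <- kept[kept$replicate != kept$replicate[i], c("chrom", "start", "end")]
        nrow(o) > 0 && nrow(intersect_intervals(kept[i, ], o)) > 0
      }
      kept <- kept[vapply(seq_len(nrow(kept)), other, logical(1)), ]
    }
    kept
  })
  conserved <- dplyr::bind_rows(conserved)
  if (nrow(conserved) == 0) {
    empty <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), mark = character(),
                            timepoint = character())
    return(build_consensus(empty, chrom_lengths))
  }
  narrow <- conserved[conserved$shape == "narrow", ]
  broad <- conserved[conserved$shape == "broad", ]
  if (nrow(narrow) > 0) {
    narrow <- extend_from_summit(narrow, chrom_lengths, flank = flank)
  }
  build_consensus(dplyr::bind_rows(narrow, broad), chrom_lengths)
}
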