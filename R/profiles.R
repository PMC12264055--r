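#' Classify per-region temporal trajectories
#'
#' Assembles, per (region, mark), the ordered status triple over the three
#' consecutive transitions (Dark:Day1, Day1:Day4, Day4:Day7) and labels it
#' systematically as `"s1.s2.s3"` (e.g. `"ns.ns.ns"`, `"up.ns.down"`). The
#' one field-named trajectory is `"Profile5"`: H3K27ac with no significant
#' change until a significant increase at the Day4:Day7 transition, i.e.
#' the H3K27ac triple `(ns, ns, up)`.
#'
#' @param ders A DER tibble with `region_id`, `mark`, `transition`,
#'   `status` (e.g. `tidy()` of a [der_analysis()]).
#' @return A tibble with one row per (region, mark): the three statuses,
#'   the `label`, and a logical `profile5` flag.
#' @export
classify_profiles <- function(ders) {
  need <- c("region_id", "mark", "transition", "status")
  miss <- setdiff(need, names(ders))
  if (length(miss) > 0) {
    abort(paste0("ders missing column(s): ", paste(miss, collapse = ", ")))
  }
  trans <- greening_transitions()
  wide <- ders |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "transition", values_from = "status")
  miss_tr <- setdiff(trans, names(wide))
  if (length(miss_tr) > 0) {
    abort(paste0("missing transition(s): ", paste(miss_tr, collapse = ", "),
                 "; all three must be tested before classification"))
  }
  s <- as.matrix(wide[, trans])
  if (anyNA(s)) {
    abort("some (region, mark) pairs lack a status for one or more transitions")
  }
  label <- paste(s[, 1], s[, 2], s[, 3], sep = ".")
  profile5 <- wide$mark == "H3K27ac" & label == "ns.ns.up"
  label[profile5] <- "Profile5"
  out <- tibble::as_tibble(wide)
  names(out)[match(trans, names(out))] <-
    c("status_dark_day1", "status_day1_day4", "status_day4_day7")
  out$label <- label
  out$profile5 <- profile5
  out
}

#' Annotate regions to genes
#'
#' Maps each region to every gene whose body, extended `upstream_bp` on its
#' 5' side (strand-aware; unstranded genes are treated as `+`), overlaps
#' the region by at least 1 bp. All matches are retained -- there is no
#' nearest-gene collapse.
#'
#' @param regions Region tibble with `region_id` and interval columns.
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param upstream_bp Promoter-proximal extension upstream of the gene
#'   start (default 1000 bp).
#' @return A tibble with `region_id`, `gene_id`, one row per match.
#' @export
annotate_ders <- function(regions, genes, upstream_bp = 1000) {
  regions <- check_intervals(regions, "regions")
  genes <- check_intervals(genes, "genes")
  if (!"region_id" %in% names(regions)) abort("regions need a region_id column")
  if (!"gene_id" %in% names(genes)) abort("genes need a gene_id column")
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(region_id = character(), gene_id = character()))
  }
  strand <- if ("strand" %in% names(genes)) genes$strand else rep(".", nrow(genes))
  ext <- genes
  minus <- strand == "-"
  ext$start <- ifelse(minus, genes$start, pmax(0, genes$start - upstream_bp))
  ext$end <- ifelse(minus, genes$end + upstream_bp, genes$end)
  hits <- intersect_intervals(regions, ext)
  tibble::tibble(
    region_id = regions$region_id[hits$a_idx],
    gene_id = genes$gene_id[hits$b_idx]
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$region_id, .data$gene_id)
}

#' Genes switching from H3K27me3 to H3K27ac
#'
#' The headline gene set: genes with at least one annotated region showing
#' a significant H3K27me3 decrease across Day1:Day4 AND at least one
#' annotated region showing a significant H3K27ac increase across
#' Day4:Day7. Aggregation is gene-level (any supporting region counts),
#' and supporting region ids are carried as provenance.
#'
#' @param me3_ders DER tibble restricted to H3K27me3 at Day1:Day4.
#' @param ac_ders DER tibble restricted to H3K27ac at Day4:Day7.
#' @param annotation Region-to-gene mapping from [annotate_ders()].
#' @return A tibble with `gene_id`, `me3_down_regions`, `ac_up_regions`
#'   (comma-separated supporting region ids).
#' @export
switch_overlap <- function(me3_ders, ac_ders, annotation) {
  if (any(me3_ders$mark != "H3K27me3") || any(me3_ders$transition != "Day1:Day4")) {
    abort("me3_ders must contain only H3K27me3 records for Day1:Day4")
  }
  if (any(ac_ders$mark != "H3K27ac") || any(ac_ders$transition != "Day4:Day7")) {
    abort("ac_ders must contain only H3K27ac records for Day4:Day7")
  }
  gene_support <- function(ders, want) {
    ders |>
      dplyr::filter(.data$status == want) |>
      dplyr::inner_join(annotation, by = "region_id",
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(regions = paste(sort(unique(.data$region_id)),
                                       collapse = ","),
                       .groups = "drop")
  }
  down <- gene_support(me3_ders, "down")
  up <- gene_support(ac_ders, "up")
  dplyr::inner_join(down, up, by = "gene_id",
                    suffix = c("_me3", "_ac")) |>
    dplyr::rename(me3_down_regions = "regions_me3",
                  ac_up_regions = "regions_ac") |>
    dplyr::arrange(.data$gene_id)
}

#' Signal metaprofile around region anchors
#'
#' Bins a genomic signal track into a fixed window centred on each region's
#' anchor (the peak summit, or the region midpoint for broad/consensus
#' regions) and averages the signal per bin. Bases outside the track or the
#' chromosome contribute zero. The track is given as piecewise-constant
#' segments (`chrom`, `start`, `end`, `value`).
#'
#' @param track Signal segment tibble with a `value` column.
#' @param regions Region tibble; needs `summit_offset` for
#'   `anchor = "summit"`.
#' @param window_bp Total window width (must be divisible by `n_bins`).
#' @param n_bins Number of bins across the window.
#' @param anchor `"summit"` or `"midpoint"`.
#' @return A long tibble (`region_id`, `bin`, `value`) of class
#'   `metaprofile`, with `window_bp`, `bin_size` and `anchor` attributes.
#' @export
metaprofile <- function(track, regions, window_bp = 6000, n_bins = 60,
                        anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  track <- check_intervals(track, "track")
  if (!"value" %in% names(track)) abort("track needs a value column")
  regions <- check_intervals(regions, "regions")
  if (window_bp %% n_bins != 0) abort("window_bp must be divisible by n_bins")
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("R%04d", seq_len(nrow(regions)))
  }
  if (anchor == "summit") {
    if (!"summit_offset" %in% names(regions) || anyNA(regions$summit_offset)) {
      abort("anchor = \"summit\" needs a summit_offset column without NAs")
    }
    pos <- regions$start + regions$summit_offset
  } else {
    pos <- (regions$start + regions$end) %/% 2
  }
  bw <- window_bp %/% n_bins
  half <- window_bp %/% 2
  bins <- tidyr::expand_grid(i = seq_len(nrow(regions)), bin = seq_len(n_bins))
  bins$chrom <- regions$chrom[bins$i]
  bins$start <- pos[bins$i] - half + (bins$bin - 1L) * bw
  bins$end <- bins$start + bw
  # clip for the overlap query; the divisor stays the full bin width so
  # out-of-range bases average in as zero
  q <- bins
  q$start <- pmax(q$start, 0)
  keep <- q$start < q$end
  value <- numeric(nrow(bins))
  if (any(keep) && nrow(track) > 0) {
    qk <- q[keep, c("chrom", "start", "end")]
    hits <- intersect_intervals(qk, track)
    if (nrow(hits) > 0) {
      w <- hits$overlap_bp * track$value[hits$b_idx]
      sums <- tapply(w, factor(hits$a_idx, levels = seq_len(nrow(qk))), sum,
                     default = 0)
      value[keep] <- as.numeric(sums) / bw
    }
  }
  out <- tibble::tibble(region_id = regions$region_id[bins$i],
                        bin = bins$bin, value = value)
  structure(out, window_bp = window_bp, bin_size = bw, anchor = anchor,
            class = c("metaprofile", class(out)))
}

#' Column-mean summary of a metaprofile
#'
#' Averages a metaprofile over regions to a single per-bin profile,
#' optionally dividing by a reference profile (e.g. normalizing each
#' timepoint's profile to the dark-grown one).
#'
#' @param mp A `metaprofile` tibble.
#' @param reference Optional per-bin reference profile (tibble with `bin`,
#'   `value`) to divide by; zero reference bins yield `NA`.
#' @return A tibble with `bin`, `value` (and the window attributes).
#' @export
metaprofile_summary <- function(mp, reference = NULL) {
  out <- mp |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  if (!is.null(reference)) {
    ref <- reference$value[match(out$bin, reference$bin)]
    out$value <- ifelse(ref == 0, NA_real_, out$value / ref)
  }
  out
}

#' @export
autoplot.metaprofile <- function(object, ...) {
  prof <- metaprofile_summary(object)
  bw <- attr(object, "bin_size")
  half <- attr(object, "window_bp") / 2
  prof$pos <- (prof$bin - 0.5) * bw - half
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0("distance from ", attr(object, "anchor"), " (bp)"),
                  y = "mean signal")
}

#' RNA signal at regions
#'
#' Depth-normalized RNA fragment counts per region: [coverage_count()]
#' divided by a library size factor, used to overlay transcript output on
#' chromatin trajectories.
#'
#' @param regions Region tibble with `region_id`.
#' @param fragments RNA read/fragment intervals.
#' @param size_factor Positive scalar depth factor (default 1).
#' @return A tibble with `region_id` and `rna_signal`.
#' @export
rna_at_regions <- function(regions, fragments, size_factor = 1) {
  if (size_factor <= 0) abort("size_factor must be positive")
  regions <- check_intervals(regions, "regions")
  if (!"region_id" %in% names(regions)) abort("regions need a region_id column")
  tibble::tibble(
    region_id = regions$region_id,
    rna_signal = coverage_count(regions, fragments) / size_factor
  )
}
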