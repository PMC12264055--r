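#' Re-key a count table onto a new region set by overlap
#'
#' Sums counts of source regions overlapping each target region (1 bp
#' minimum), used to evaluate the simulated count table on the curated
#' consensus regions.
#'
#' @param counts Long count tibble keyed by `source_regions$region_id`.
#' @param source_regions,target_regions Region tibbles with `region_id`.
#' @return A long count tibble keyed by `target_regions$region_id`.
#' @export
aggregate_counts_to_regions <- function(counts, source_regions,
                                        target_regions) {
  counts <- check_counts(counts)
  hits <- intersect_intervals(target_regions, source_regions)
  if (nrow(hits) == 0) {
    abort("no source region overlaps any target region")
  }
  map <- tibble::tibble(
    region_id = target_regions$region_id[hits$a_idx],
    source_id = source_regions$region_id[hits$b_idx]
  )
  counts |>
    dplyr::rename(source_id = "region_id") |>
    dplyr::inner_join(map, by = "source_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$region_id, .data$mark, .data$timepoint,
                    .data$replicate) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Sensitivity and false-discovery proportion of the switch gene set
#'
#' Compares called switch genes against planted truth labels: sensitivity
#' is the fraction of truly switching genes recovered; the
#' false-discovery proportion is the fraction of called genes that are
#' not truly switching (0 when nothing is called).
#'
#' @param called_genes Character vector of called switch gene ids.
#' @param gene_classes Truth tibble with `gene_id`, `class`.
#' @return A one-row tibble with `n_truth`, `n_called`, `n_recovered`,
#'   `sensitivity`, `fdp`.
#' @export
evaluate_switch_recovery <- function(called_genes, gene_classes) {
  truth <- gene_classes$gene_id[gene_classes$class == "switch"]
  called <- unique(called_genes)
  tp <- sum(called %in% truth)
  tibble::tibble(
    n_truth = length(truth),
    n_called = length(called),
    n_recovered = tp,
    sensitivity = if (length(truth) > 0) tp / length(truth) else NA_real_,
    fdp = if (length(called) > 0) (length(called) - tp) / length(called) else 0
  )
}

#' Run the full greening chromatin pipeline on simulated data
#'
#' Chains every stage end to end: simulate the experiment, curate the
#' consensus region set from the dual-control peak calls, evaluate counts
#' on the consensus regions, test differential enrichment for every mark
#' and transition, classify temporal trajectories (including Profile5),
#' annotate regions to genes, build the H3K27me3-to-H3K27ac switch gene
#' set, test term over-representation, and score recovery against the
#' planted truth. With `outdir` set, every stage's table is written as
#' TSV/BED text; identical configurations produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param fdr_max,min_fold DER thresholds (defaults 0.05 and 2).
#' @param flank Summit flank for narrow peaks (default 250 bp).
#' @param upstream_bp Gene annotation upstream window (default 1000 bp).
#' @param strict_replicates Passed to [curate_consensus()].
#' @param outdir Optional output directory for stage TSVs.
#' @return A `greening_pipeline` list with `sim`, `consensus`, `counts`,
#'   `ders`, `profiles`, `annotation`, `switch_genes`, `enrichment`,
#'   `recovery`, `report`.
#' @export
run_greening_pipeline <- function(config = sim_config(), fdr_max = 0.05,
                                  min_fold = 2, flank = 250,
                                  upstream_bp = 1000,
                                  strict_replicates = FALSE,
                                  outdir = NULL) {
  sim <- simulate_chipseq(config)
  consensus <- curate_consensus(sim$peaks, sim$chrom_lengths, flank = flank,
                                strict_replicates = strict_replicates)
  if (nrow(consensus) == 0) {
    abort("consensus stage produced no regions; no peaks were conserved")
  }
  counts <- aggregate_counts_to_regions(sim$counts, sim$regions, consensus)
  ders <- der_analysis(counts, fdr_max = fdr_max, min_fold = min_fold)
  records <- tidy(ders)
  profiles <- classify_profiles(records)
  annotation <- annotate_ders(consensus, sim$genes, upstream_bp = upstream_bp)
  me3 <- records[records$mark == "H3K27me3" &
                   records$transition == "Day1:Day4", ]
  ac <- records[records$mark == "H3K27ac" &
                  records$transition == "Day4:Day7", ]
  switch_genes <- switch_overlap(me3, ac, annotation)
  enrichment <- enrich_terms(switch_genes$gene_id, sim$genes$gene_id,
                             sim$term_map)
  recovery <- evaluate_switch_recovery(switch_genes$gene_id,
                                       sim$truth$gene_classes)
  report <- dplyr::bind_rows(
    glance(ders) |>
      dplyr::transmute(metric = paste0("ders_", .data$mark, "_",
                                       gsub(":", "_to_", .data$transition)),
                       value = .data$n_up + .data$n_down),
    tibble::tibble(
      metric = c("consensus_regions", "profile5_regions",
                 "switch_genes", "switch_sensitivity", "switch_fdp"),
      value = c(nrow(consensus), sum(profiles$profile5),
                nrow(switch_genes), recovery$sensitivity, recovery$fdp)
    )
  )
  out <- list(sim = sim, consensus = consensus, counts = counts,
              ders = ders, profiles = profiles, annotation = annotation,
              switch_genes = switch_genes, enrichment = enrichment,
              recovery = recovery, report = report)
  class(out) <- "greening_pipeline"
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(x, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  cons <- x$consensus
  cons_flat <- tibble::tibble(chrom = cons$chrom, start = cons$start,
                              end = cons$end, name = cons$region_id,
                              score = 0, strand = ".")
  write_bed(cons_flat, path("consensus.bed"))
  counts_wide <- x$counts |>
    dplyr::mutate(key = sample_key(.data$mark, .data$timepoint,
                                   .data$replicate)) |>
    dplyr::select("region_id", "key", "count") |>
    tidyr::pivot_wider(names_from = "key", values_from = "count") |>
    dplyr::arrange(.data$region_id)
  readr::write_tsv(counts_wide, path("counts.tsv"), progress = FALSE)
  readr::write_tsv(tidy(x$ders), path("ders.tsv"), progress = FALSE)
  readr::write_tsv(x$profiles, path("profiles.tsv"), progress = FALSE)
  readr::write_tsv(x$annotation, path("annotation.tsv"), progress = FALSE)
  readr::write_tsv(x$switch_genes, path("switch_genes.tsv"), progress = FALSE)
  readr::write_tsv(x$enrichment, path("enrichment.tsv"), progress = FALSE)
  readr::write_tsv(x$report, path("report.tsv"), progress = FALSE)
  invisible(outdir)
}

#' @export
print.greening_pipeline <- function(x, ...) {
  cat("Greening chromatin pipeline (simulated data)\n")
  cat(sprintf("  seed %d, %d regions, %d consensus regions\n",
              x$sim$config$seed, nrow(x$sim$regions), nrow(x$consensus)))
  cat(sprintf("  Profile5 regions: %d; switch genes: %d\n",
              sum(x$profiles$profile5), nrow(x$switch_genes)))
  cat(sprintf("  switch recovery: sensitivity %.3f, FDP %.3f\n",
              x$recovery$sensitivity, x$recovery$fdp))
  if (nrow(x$enrichment) > 0) {
    top <- x$enrichment[1, ]
    cat(sprintf("  top enriched term: %s (ratio %.2f, adjusted p %.3g)\n",
                top$term_id, top$ratio, top$p_adjusted))
  }
  invisible(x)
}

#' @export
glance.greening_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "metric", values_from = "value")
}
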