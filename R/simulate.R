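sim_classes <- function() {
  c("switch", "profile5", "constitutive", "dark_specific",
    "silenced_repeat", "null")
}

#' Configuration for the synthetic greening ChIP-seq experiment
#'
#' Defines the study-shaped simulation: four timepoints, the four profiled
#' histone modifications plus paired H3 and input controls, two replicates,
#' and negative-binomial counts (variance `mu + dispersion * mu^2`) over
#' regions tiled on a toy genome with planted temporal classes. Planted
#' effects are defined on the H3-normalized ratio scale, so
#' `effect_log2fc` is exactly the log2 fold change the differential test
#' measures.
#'
#' @param seed Integer seed; every simulated quantity derives from it.
#' @param n_regions Number of regions on the toy genome.
#' @param n_replicates Replicates per sample (default 2).
#' @param mean_depth Expected counts per region at baseline (default 50).
#' @param nb_dispersion Negative-binomial dispersion `phi` in
#'   `var = mu + phi mu^2` (default 0.05).
#' @param effect_log2fc Planted log2 fold change of the H3-normalized
#'   ratio for non-null classes (default 2; 0 gives a global null).
#' @param class_fractions Named fractions over the six temporal classes
#'   (`switch`, `profile5`, `constitutive`, `dark_specific`,
#'   `silenced_repeat`, `null`); must sum to 1.
#' @param region_width,region_gap Region size and inter-region gap in bp
#'   (defaults 500 and 1200; the gap exceeds the 1 kb promoter-annotation
#'   window so a region never annotates to a neighbouring gene).
#' @param n_chroms Number of toy chromosomes the regions are tiled over.
#' @param peak_disagreement Probability that a peak present in the
#'   input-controlled call list is absent from the H3-controlled list.
#' @param decoy_term_fraction Probability that a non-photosynthesis gene
#'   carries the planted `"PHOTO"` term.
#' @param qpcr_noise_sd Log-scale lognormal noise sd for simulated qPCR.
#' @param image_noise_sd Grey-value noise sd for simulated seedling scans.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 7, n_regions = 1000, n_replicates = 2,
                       mean_depth = 50, nb_dispersion = 0.05,
                       effect_log2fc = 2,
                       class_fractions = c(switch = 0.06, profile5 = 0.04,
                                           constitutive = 0.40,
                                           dark_specific = 0.08,
                                           silenced_repeat = 0.07,
                                           null = 0.35),
                       region_width = 500, region_gap = 1200, n_chroms = 2,
                       peak_disagreement = 0.05,
                       decoy_term_fraction = 0.02,
                       qpcr_noise_sd = 0.1, image_noise_sd = 3) {
  if (!setequal(names(class_fractions), sim_classes())) {
    abort(paste0("class_fractions must be named exactly: ",
                 paste(sim_classes(), collapse = ", ")))
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    abort("class_fractions must sum to 1")
  }
  if (any(class_fractions < 0)) abort("class_fractions must be nonnegative")
  for (p in c(n_regions = n_regions, n_replicates = n_replicates,
              mean_depth = mean_depth, nb_dispersion = nb_dispersion,
              region_width = region_width, n_chroms = n_chroms)) {
    if (p <= 0) abort("all scale parameters must be positive")
  }
  if (region_gap < 500) abort("region_gap must be >= 500 bp")
  if (peak_disagreement < 0 || peak_disagreement >= 1) {
    abort("peak_disagreement must be in [0, 1)")
  }
  structure(list(
    seed = as.integer(seed), n_regions = as.integer(n_regions),
    n_replicates = as.integer(n_replicates), mean_depth = mean_depth,
    nb_dispersion = nb_dispersion, effect_log2fc = effect_log2fc,
    class_fractions = class_fractions[sim_classes()],
    region_width = as.integer(region_width),
    region_gap = as.integer(region_gap), n_chroms = as.integer(n_chroms),
    peak_disagreement = peak_disagreement,
    decoy_term_fraction = decoy_term_fraction,
    qpcr_noise_sd = qpcr_noise_sd, image_noise_sd = image_noise_sd
  ), class = "sim_config")
}

# per-class trajectory templates on the H3-normalized ratio scale plus a
# per-timepoint H3 occupancy multiplier; hi/lo = 2^effect_log2fc vs 1
class_templates <- function(effect_log2fc) {
  hi <- 2^effect_log2fc
  lo <- 1
  tp4 <- function(...) setNames(c(...), greening_timepoints())
  flat <- function(v) tp4(v, v, v, v)
  list(
    switch = list(
      ratio = rbind(H3K4me3 = tp4(lo, lo, lo, hi),
                    H3K27ac = tp4(lo, lo, lo, hi),
                    H3K27me3 = tp4(hi, hi, lo, lo),
                    H3K9me2 = flat(lo)),
      h3 = tp4(1, 1, 0.7, 0.7)
    ),
    profile5 = list(
      ratio = rbind(H3K4me3 = tp4(lo, lo, lo, hi),
                    H3K27ac = tp4(lo, lo, lo, hi),
                    H3K27me3 = flat(lo),
                    H3K9me2 = flat(lo)),
      h3 = flat(0.6)
    ),
    constitutive = list(
      ratio = rbind(H3K4me3 = flat(hi), H3K27ac = flat(hi),
                    H3K27me3 = flat(lo), H3K9me2 = flat(lo)),
      h3 = flat(1)
    ),
    dark_specific = list(
      ratio = rbind(H3K4me3 = tp4(hi, lo, lo, lo),
                    H3K27ac = tp4(hi, lo, lo, lo),
                    H3K27me3 = flat(lo), H3K9me2 = flat(lo)),
      h3 = flat(1)
    ),
    silenced_repeat = list(
      ratio = rbind(H3K4me3 = flat(lo), H3K27ac = flat(lo),
                    H3K27me3 = flat(lo), H3K9me2 = flat(hi)),
      h3 = flat(1)
    ),
    null = list(
      ratio = rbind(H3K4me3 = flat(1), H3K27ac = flat(1),
                    H3K27me3 = flat(1), H3K9me2 = flat(1)),
      h3 = flat(1)
    )
  )
}

deterministic_class_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate the full greening ChIP-seq experiment
#'
#' Generates every input the chromatin pipeline consumes, with truth
#' labels: regions tiled on a toy genome (>= 500 bp apart), per-sample
#' negative-binomial counts for the four modifications plus H3 and input
#' controls at all four timepoints, dual-control peak call lists (narrow
#' for H3K4me3/H3K27ac, broad for H3K27me3/H3K9me2; peaks are emitted
#' where the planted ratio exceeds background 2-fold, and the
#' H3-controlled list drops peaks at the configured disagreement rate),
#' one gene per region, and a term map planting `"PHOTO"` on switch and
#' profile5 genes plus a decoy fraction. H3 occupancy is reduced at
#' switch regions from Day4 and low throughout at profile5 regions; the
#' input control is flat. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A `chipseq_sim` list: `config`, `chrom_lengths`, `regions`
#'   (with planted `class`), `genes`, `term_map`, `counts` (long),
#'   `peaks`, and `truth` (`region_classes`, `gene_classes`,
#'   `expected_means`).
#' @export
simulate_chipseq <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  withr::with_seed(config$seed, simulate_chipseq_impl(config))
}

simulate_chipseq_impl <- function(config) {
  n <- config$n_regions
  w <- config$region_width
  gap <- config$region_gap
  per_chrom <- ceiling(n / config$n_chroms)
  chrom_of <- rep(seq_len(config$n_chroms), each = per_chrom)[seq_len(n)]
  idx_in_chrom <- unlist(lapply(split(seq_len(n), chrom_of), seq_along),
                         use.names = FALSE)
  chrom <- paste0("chr", chrom_of)
  start <- gap + (idx_in_chrom - 1L) * (w + gap)
  regions <- tibble::tibble(
    region_id = sprintf("SR%06d", seq_len(n)),
    chrom = chrom, start = start, end = start + w
  )
  chrom_lengths <- vapply(split(regions$end, regions$chrom),
                          function(e) max(e) + gap, numeric(1))
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))

  counts_per_class <- deterministic_class_counts(config$class_fractions, n)
  labels <- rep(names(config$class_fractions), counts_per_class)
  regions$class <- sample(labels)

  genes <- tibble::tibble(
    gene_id = sprintf("G%06d", seq_len(n)),
    chrom = regions$chrom, start = regions$start, end = regions$end,
    strand = "+", region_id = regions$region_id
  )

  templ <- class_templates(config$effect_log2fc)
  tps <- greening_timepoints()
  marks <- greening_marks()
  depth <- config$mean_depth

  mean_grid <- tidyr::expand_grid(region_idx = seq_len(n),
                                  mark = c(marks, "H3", "Input"),
                                  timepoint = tps)
  cls <- regions$class[mean_grid$region_idx]
  mu <- numeric(nrow(mean_grid))
  for (cl in sim_classes()) {
    sel <- which(cls == cl)
    if (length(sel) == 0) next
    tmark <- mean_grid$mark[sel]
    ttp <- mean_grid$timepoint[sel]
    h3d <- unname(templ[[cl]]$h3[ttp])
    val <- numeric(length(sel))
    is_input <- tmark == "Input"
    is_h3 <- tmark == "H3"
    is_ptm <- !is_input & !is_h3
    val[is_input] <- depth
    val[is_h3] <- depth * h3d[is_h3]
    val[is_ptm] <- depth * h3d[is_ptm] *
      templ[[cl]]$ratio[cbind(tmark[is_ptm], ttp[is_ptm])]
    mu[sel] <- val
  }
  mean_grid$mu <- mu
  mean_grid$region_id <- regions$region_id[mean_grid$region_idx]

  samples <- tidyr::expand_grid(mark = c(marks, "H3", "Input"),
                                timepoint = tps,
                                replicate = seq_len(config$n_replicates))
  samples$scale <- runif(nrow(samples), 0.75, 1.25)

  counts <- tidyr::expand_grid(
    region_idx = seq_len(n),
    dplyr::select(samples, "mark", "timepoint", "replicate")
  )
  counts <- dplyr::left_join(counts, samples,
                             by = c("mark", "timepoint", "replicate"))
  counts <- dplyr::left_join(
    counts,
    dplyr::select(mean_grid, "region_idx", "mark", "timepoint", "mu"),
    by = c("region_idx", "mark", "timepoint")
  )
  counts$count <- rnbinom(nrow(counts), mu = counts$mu * counts$scale,
                          size = 1 / config$nb_dispersion)
  counts$region_id <- regions$region_id[counts$region_idx]
  counts <- counts[, c("region_id", "mark", "timepoint", "replicate", "count")]

  # peak calls where planted signal exceeds background 2-fold
  peak_rows <- list()
  for (m in marks) {
    shape <- if (m %in% broad_marks()) "broad" else "narrow"
    dialect_cols <- function(sub, control) {
      tibble::tibble(
        chrom = sub$chrom, start = sub$start, end = sub$end,
        name = paste0(m, "_", sub$region_id), score = 100,
        strand = ".", signal = 5, pvalue = 10, qvalue = 8,
        summit_offset = as.integer((sub$end - sub$start) %/% 2L),
        shape = shape, mark = m, timepoint = sub$timepoint,
        replicate = sub$replicate, control = control
      )
    }
    for (tp in tps) {
      ratio_by_class <- vapply(sim_classes(),
                               function(cl) templ[[cl]]$ratio[m, tp],
                               numeric(1))
      enriched <- regions[ratio_by_class[regions$class] >= 2, ]
      if (nrow(enriched) == 0) next
      for (r in seq_len(config$n_replicates)) {
        sub <- enriched
        sub$timepoint <- tp
        sub$replicate <- r
        peak_rows[[length(peak_rows) + 1]] <- dialect_cols(sub, "input")
        keep <- runif(nrow(sub)) >= config$peak_disagreement
        peak_rows[[length(peak_rows) + 1]] <- dialect_cols(sub[keep, ], "H3")
      }
    }
  }
  peaks <- dplyr::bind_rows(peak_rows)
  if (nrow(peaks) == 0) {
    peaks <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character(),
      signal = double(), pvalue = double(), qvalue = double(),
      summit_offset = integer(), shape = character(), mark = character(),
      timepoint = character(), replicate = integer(), control = character()
    )
  }

  photo_genes <- genes$gene_id[regions$class %in% c("switch", "profile5")]
  decoy <- genes$gene_id[!genes$gene_id %in% photo_genes &
                           runif(nrow(genes)) < config$decoy_term_fraction]
  background_terms <- sprintf("TERM%02d", 1:8)
  bg <- tidyr::expand_grid(gene_id = genes$gene_id,
                           term_id = background_terms)
  bg <- bg[runif(nrow(bg)) < 0.05, ]
  term_map <- dplyr::bind_rows(
    tibble::tibble(gene_id = c(photo_genes, decoy), term_id = "PHOTO"),
    bg
  ) |> dplyr::arrange(.data$term_id, .data$gene_id)

  truth <- list(
    region_classes = tibble::tibble(region_id = regions$region_id,
                                    class = regions$class),
    gene_classes = tibble::tibble(gene_id = genes$gene_id,
                                  class = regions$class),
    expected_means = dplyr::select(mean_grid, "region_id", "mark",
                                   "timepoint", "mu")
  )
  structure(list(config = config, chrom_lengths = chrom_lengths,
                 regions = regions, genes = genes, term_map = term_map,
                 counts = counts, peaks = peaks, truth = truth),
            class = "chipseq_sim")
}

#' Simulate a ChIP-qPCR percent-input panel
#'
#' Emulates the seedling validation design: `n_phang` photosynthesis loci
#' plus two control targets, measured for one modification and H3 in
#' every (condition, replicate). Percent input is
#' `truth_ratio * h3_level * lognormal noise` for the modification and
#' `h3_level * lognormal noise` for H3; control targets have truth ratio
#' 1 in all conditions, while the treatment divides the photosynthesis
#' targets' ratio by `effect_fold`. At `noise_sd = 0` the full
#' normalization chain recovers the planted ratios exactly.
#'
#' @param seed Integer seed.
#' @param n_phang Number of photosynthesis loci (default 8).
#' @param n_replicates Biological replicates (default 3).
#' @param noise_sd Log-scale lognormal noise sd (default 0.1).
#' @param effect_fold Planted treatment fold effect (default 4).
#' @param baseline_ratio Untreated modification/H3 ratio at the
#'   photosynthesis loci (default 2).
#' @param conditions Condition names; the first is the reference.
#' @return A list with `panel` (columns `target`, `role`, `antibody`,
#'   `condition`, `replicate`, `percent_input`) and `truth` (planted
#'   ratios per target and condition).
#' @export
simulate_qpcr <- function(seed = 1, n_phang = 8, n_replicates = 3,
                          noise_sd = 0.1, effect_fold = 4,
                          baseline_ratio = 2,
                          conditions = c("untreated", "treated")) {
  withr::with_seed(seed, {
    targets <- tibble::tibble(
      target = c(paste0("PhANG", seq_len(n_phang)), "Control1", "Control2"),
      role = c(rep("phang", n_phang), "control", "control")
    )
    truth <- tidyr::expand_grid(targets, condition = conditions) |>
      dplyr::mutate(ratio = ifelse(.data$role == "control", 1,
                                   ifelse(.data$condition == conditions[1],
                                          baseline_ratio,
                                          baseline_ratio / effect_fold)))
    base_h3 <- setNames(runif(nrow(targets), 2, 8), targets$target)
    grid <- tidyr::expand_grid(truth, replicate = seq_len(n_replicates))
    lnoise <- function(k) exp(rnorm(k, 0, noise_sd))
    h3_level <- base_h3[grid$target] * lnoise(nrow(grid))
    panel <- dplyr::bind_rows(
      dplyr::mutate(grid, antibody = "PTM",
                    percent_input = .data$ratio * h3_level * lnoise(nrow(grid))),
      dplyr::mutate(grid, antibody = "H3",
                    percent_input = h3_level * lnoise(nrow(grid)))
    ) |>
      dplyr::select("target", "role", "antibody", "condition",
                    "replicate", "percent_input")
    list(panel = panel, truth = dplyr::select(truth, "target", "role",
                                              "condition", "ratio"))
  })
}

#' Simulate microplate absorbance records from pigment concentrations
#'
#' Inverts the pigment equations: given target chlorophyll a/b and
#' carotenoid concentrations (ug/ml), solves the linear system for the
#' corrected absorbances, un-corrects with the pathlength factor and the
#' A750 blank, and optionally adds Gaussian noise. Requested
#' concentrations whose solution would need a negative absorbance are
#' rejected.
#'
#' @param concentrations Tibble with `chla`, `chlb`, `car` (ug/ml).
#' @param a750 Blank absorbance added to every channel (default 0.05).
#' @param noise_sd Gaussian absorbance noise sd (default 0).
#' @param pathlength_factor Microplate pathlength correction (0.58).
#' @param seed Optional seed for the noise.
#' @return A tibble of absorbance records (`a470`, `a652`, `a665`,
#'   `a750`).
#' @export
simulate_absorbance <- function(concentrations, a750 = 0.05, noise_sd = 0,
                                pathlength_factor = 0.58, seed = NULL) {
  need <- c("chla", "chlb", "car")
  miss <- setdiff(need, names(concentrations))
  if (length(miss) > 0) {
    abort(paste0("concentrations missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(unlist(concentrations[need]) < 0)) {
    abort("concentrations must be nonnegative")
  }
  chl_mat <- matrix(c(-6.5079, 16.2127, 32.1228, -13.8255),
                    nrow = 2, byrow = TRUE)
  sol <- solve(chl_mat, rbind(concentrations$chla, concentrations$chlb))
  a652c <- sol[1, ]
  a665c <- sol[2, ]
  a470c <- (221 * concentrations$car + 1.63 * concentrations$chla +
              104.96 * concentrations$chlb) / 1000
  if (any(c(a652c, a665c, a470c) < -1e-12)) {
    abort("requested concentrations lie outside the invertible range (negative absorbance)")
  }
  gen <- function() {
    k <- nrow(concentrations)
    noise <- function() if (noise_sd > 0) rnorm(k, 0, noise_sd) else 0
    tibble::tibble(
      a470 = pmax(0, a470c * pathlength_factor + a750 + noise()),
      a652 = pmax(0, a652c * pathlength_factor + a750 + noise()),
      a665 = pmax(0, a665c * pathlength_factor + a750 + noise()),
      a750 = a750
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a scanned-seedling green-channel image
#'
#' Places one rectangular cotyledon per seedling on a light background:
#' each rectangle's mean grey is `255 - green_value` (darker = greener),
#' with optional Gaussian grey noise, alongside aligned ROI definitions.
#' At zero noise [greening_score()] returns the planted values exactly.
#'
#' @param green_values Numeric vector of planted green values in
#'   `[0, 255]`, one per seedling.
#' @param noise_sd Grey noise sd (default 0).
#' @param roi_size ROI edge length in pixels (default 20).
#' @param margin Spacing between ROIs and image border (default 10).
#' @param background Background grey level (default 230).
#' @param rois Optional custom ROI rectangle tibble (`seedling`, `row0`,
#'   `row1`, `col0`, `col1`); overlapping ROIs are an error.
#' @param seed Optional seed for the noise.
#' @return A list with `image` (grey matrix), `rois` (rectangle tibble)
#'   and `truth` (planted green value per seedling).
#' @export
simulate_seedling_image <- function(green_values, noise_sd = 0,
                                    roi_size = 20, margin = 10,
                                    background = 230, rois = NULL,
                                    seed = NULL) {
  if (any(green_values < 0) || any(green_values > 255)) {
    abort("green values must lie in [0, 255]")
  }
  ns <- length(green_values)
  if (is.null(rois)) {
    ncols <- ceiling(sqrt(ns))
    nrows <- ceiling(ns / ncols)
    cell <- roi_size + margin
    rois <- tibble::tibble(
      seedling = paste0("s", seq_len(ns)),
      row0 = margin + ((seq_len(ns) - 1) %/% ncols) * cell + 1,
      col0 = margin + ((seq_len(ns) - 1) %% ncols) * cell + 1
    )
    rois$row1 <- rois$row0 + roi_size - 1
    rois$col1 <- rois$col0 + roi_size - 1
  }
  if (nrow(rois) != ns) abort("need one ROI per seedling")
  if (nrow(rois) > 1) {
    for (i in seq_len(nrow(rois) - 1)) {
      for (j in seq((i + 1), nrow(rois))) {
        if (rois$row0[i] <= rois$row1[j] && rois$row0[j] <= rois$row1[i] &&
            rois$col0[i] <= rois$col1[j] && rois$col0[j] <= rois$col1[i]) {
          abort(paste0("ROIs '", rois$seedling[i], "' and '",
                       rois$seedling[j], "' overlap"))
        }
      }
    }
  }
  dims <- c(max(rois$row1) + margin, max(rois$col1) + margin)
  gen <- function() {
    img <- matrix(background, dims[1], dims[2])
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(prod(dims), 0, noise_sd), dims[1], dims[2])
    }
    for (i in seq_len(ns)) {
      block <- 255 - green_values[i]
      r <- rois$row0[i]:rois$row1[i]
      cc <- rois$col0[i]:rois$col1[i]
      vals <- matrix(block, length(r), length(cc))
      if (noise_sd > 0) {
        vals <- vals + matrix(rnorm(length(vals), 0, noise_sd),
                              length(r), length(cc))
      }
      img[r, cc] <- vals
    }
    pmin(pmax(img, 0), 255)
  }
  img <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  list(image = img, rois = rois,
       truth = tibble::tibble(seedling = rois$seedling,
                              green_value = green_values))
}
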