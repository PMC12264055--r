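#' Validate a region-by-sample count table
#'
#' Counts are held long: one row per (region, sample) with columns
#' `region_id`, `mark`, `timepoint`, `replicate`, `count`. `mark` may be a
#' histone modification, `"H3"` (the nucleosome-occupancy control) or
#' `"Input"`. Every modification sample is expected to have a paired H3
#' sample at the same (timepoint, replicate).
#'
#' @param counts A long count tibble.
#' @return The validated tibble.
#' @export
check_counts <- function(counts) {
  if (!is.data.frame(counts)) abort("counts must be a data frame")
  need <- c("region_id", "mark", "timepoint", "replicate", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("counts missing column(s): ", paste(miss, collapse = ", ")))
  }
  counts <- tibble::as_tibble(counts)
  if (any(is.na(counts$count)) || any(counts$count < 0) ||
      any(counts$count != round(counts$count))) {
    abort("counts must be nonnegative integers")
  }
  bad_tp <- setdiff(unique(counts$timepoint), greening_timepoints())
  if (length(bad_tp) > 0) {
    abort(paste0("unknown timepoint(s): ", paste(bad_tp, collapse = ", ")))
  }
  counts
}

sample_key <- function(mark, timepoint, replicate) {
  paste(mark, timepoint, paste0("rep", replicate), sep = ".")
}

counts_to_matrix <- function(counts) {
  counts <- check_counts(counts)
  key <- sample_key(counts$mark, counts$timepoint, counts$replicate)
  wide <- tidyr::pivot_wider(
    tibble::tibble(region_id = counts$region_id, key = key, count = counts$count),
    names_from = "key", values_from = "count"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$region_id
  if (anyNA(m)) abort("count table is not complete over regions x samples")
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed over regions with positive
#' counts in every sample: each sample's factor is the median of its
#' count-to-geometric-row-mean ratios, rescaled so the factors have
#' geometric mean 1. When fewer than 10 all-positive regions exist the
#' factors fall back to library sizes (rescaled the same way).
#'
#' @param counts Long count tibble (see [check_counts()]).
#' @param min_positive_regions Minimum all-positive regions before the
#'   library-size fallback is used (default 10).
#' @return A tibble with `mark`, `timepoint`, `replicate`, `size_factor`.
#' @export
size_factors <- function(counts, min_positive_regions = 10) {
  m <- counts_to_matrix(counts)
  libs <- colSums(m)
  if (any(libs == 0)) {
    abort(paste0("sample has all-zero counts: ",
                 colnames(m)[which(libs == 0)[1]]))
  }
  pos <- m[rowSums(m > 0) == ncol(m), , drop = FALSE]
  if (nrow(pos) >= min_positive_regions) {
    logm <- log(pos)
    logmeans <- rowMeans(logm)
    sf <- exp(apply(logm - logmeans, 2, median))
  } else {
    sf <- libs / mean(libs)
  }
  sf <- sf / exp(mean(log(sf)))
  keys <- strsplit(colnames(m), ".", fixed = TRUE)
  tibble::tibble(
    mark = vapply(keys, `[`, "", 1),
    timepoint = vapply(keys, `[`, "", 2),
    replicate = as.integer(sub("^rep", "", vapply(keys, `[`, "", 3))),
    size_factor = unname(sf)
  )
}

lookup_sf <- function(sf, mark, timepoint, replicate) {
  i <- which(sf$mark == mark & sf$timepoint == timepoint &
               sf$replicate == replicate)
  if (length(i) != 1) {
    abort(paste0("no size factor for sample ",
                 sample_key(mark, timepoint, replicate)))
  }
  sf$size_factor[i]
}

#' H3-normalized log ratio for one sample
#'
#' The per-region statistic on which all differential testing runs:
#' `log2((c_mark + pc) / s_mark) - log2((c_H3 + pc) / s_H3)`, the
#' depth-corrected log2 ratio of modification signal to total H3 at the
#' same (timepoint, replicate). Dividing by H3 corrects for nucleosome
#' occupancy, so occupancy changes with constant per-nucleosome
#' modification give a ratio change of zero.
#'
#' @param counts Long count tibble.
#' @param mark,timepoint,replicate The modification sample to normalize.
#' @param sf Size-factor tibble from [size_factors()]; computed from
#'   `counts` when `NULL`.
#' @param pseudocount Added to both counts before the log (default 0.5).
#' @return A tibble with `region_id` and `log_ratio`, in region order of
#'   the count table.
#' @export
h3_log_ratio <- function(counts, mark, timepoint, replicate, sf = NULL,
                         pseudocount = 0.5) {
  counts <- check_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  ptm <- counts[counts$mark == mark & counts$timepoint == timepoint &
                  counts$replicate == replicate, ]
  h3 <- counts[counts$mark == "H3" & counts$timepoint == timepoint &
                 counts$replicate == replicate, ]
  if (nrow(ptm) == 0) {
    abort(paste0("no counts for sample ", sample_key(mark, timepoint, replicate)))
  }
  if (nrow(h3) == 0) {
    abort(paste0("no paired H3 sample for ", sample_key(mark, timepoint, replicate)))
  }
  h3 <- h3[match(ptm$region_id, h3$region_id), ]
  if (anyNA(h3$count)) abort("H3 sample does not cover all regions")
  s_ptm <- lookup_sf(sf, mark, timepoint, replicate)
  s_h3 <- lookup_sf(sf, "H3", timepoint, replicate)
  tibble::tibble(
    region_id = ptm$region_id,
    log_ratio = log2((ptm$count + pseudocount) / s_ptm) -
      log2((h3$count + pseudocount) / s_h3)
  )
}

#' Moderated test for differential enrichment across one transition
#'
#' For one histone mark and one consecutive-timepoint transition, computes
#' per-replicate H3-normalized log ratios in each group, then a moderated
#' Wald test per region: the effect is the difference of group means of
#' the log ratios; the per-region pooled variance is shrunk toward a
#' common prior variance with prior weight `shrink_df`; the statistic is
#' referred to a t distribution with `n1 + n2 - 2 + shrink_df` degrees of
#' freedom (two-sided). This is the package's fully specified stand-in
#' for a generic differential-binding fit, preserving paired-H3
#' normalization and FDR/fold calling.
#'
#' With `shrink_df = "auto"` (the default) the prior weight is estimated
#' empirically from the spread of the per-region log variances (the
#' empirical-Bayes moment estimator of Smyth 2004): when variances look
#' homogeneous across regions the prior weight grows and the test
#' approaches a known-variance z test, which matters at n = 2 replicates
#' per group. A fixed numeric prior weight is accepted.
#'
#' @param counts Long count tibble.
#' @param mark Histone modification to test.
#' @param transition A transition string, e.g. `"Day1:Day4"`.
#' @param sf Optional precomputed size factors.
#' @param shrink_df Prior weight of the variance shrinkage: `"auto"`
#'   (estimated, default) or a positive number.
#' @param pseudocount Pseudocount for the log ratios (default 0.5).
#' @return A tibble with `region_id`, `mark`, `transition`, `log2fc`
#'   (H3-normalized), `p_value`.
#' @export
test_transition <- function(counts, mark, transition, sf = NULL,
                            shrink_df = "auto", pseudocount = 0.5) {
  counts <- check_counts(counts)
  tp <- split_transition(transition)
  if (is.null(sf)) sf <- size_factors(counts)
  group_ratios <- function(timepoint) {
    reps <- sort(unique(counts$replicate[counts$mark == mark &
                                           counts$timepoint == timepoint]))
    if (length(reps) < 2) {
      abort(paste0("need >= 2 replicates of ", mark, " at ", timepoint,
                   "; found ", length(reps)))
    }
    cols <- lapply(reps, function(r) {
      h3_log_ratio(counts, mark, timepoint, r, sf = sf,
                   pseudocount = pseudocount)
    })
    ids <- cols[[1]]$region_id
    m <- vapply(cols, function(x) x$log_ratio[match(ids, x$region_id)],
                numeric(length(ids)))
    list(ids = ids, m = m)
  }
  g1 <- group_ratios(tp[1])
  g2 <- group_ratios(tp[2])
  if (!identical(g1$ids, g2$ids)) {
    g2$m <- g2$m[match(g1$ids, g2$ids), , drop = FALSE]
    if (anyNA(g2$m)) abort("region sets differ between timepoints")
  }
  n1 <- ncol(g1$m); n2 <- ncol(g2$m)
  m1 <- rowMeans(g1$m); m2 <- rowMeans(g2$m)
  delta <- m2 - m1
  rss <- rowSums((g1$m - m1)^2) + rowSums((g2$m - m2)^2)
  df_resid <- n1 + n2 - 2
  s2 <- rss / df_resid
  prior <- shrink_prior(s2, df_resid, shrink_df)
  s2_shrunk <- if (is.infinite(prior$df)) {
    rep(prior$s2, length(s2))
  } else {
    (df_resid * s2 + prior$df * prior$s2) / (df_resid + prior$df)
  }
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  stat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  df <- df_resid + prior$df
  p <- 2 * pt(-abs(stat), df = df)
  tibble::tibble(
    region_id = g1$ids,
    mark = mark,
    transition = transition,
    log2fc = delta,
    p_value = p
  )
}

# Prior (df, variance) for the moderated test. Numeric shrink_df shrinks
# toward the across-region mean variance with that fixed weight; "auto"
# uses the scaled-F moment estimator on log variances: with residual df d,
# var(log s2) in excess of trigamma(d/2) determines the prior df, and an
# excess of ~0 (homogeneous variances) gives an infinite prior, i.e. a
# known-variance z test.
shrink_prior <- function(s2, df_resid, shrink_df) {
  if (is.numeric(shrink_df)) {
    if (shrink_df < 0) abort("shrink_df must be nonnegative")
    return(list(df = shrink_df, s2 = mean(s2)))
  }
  if (!identical(shrink_df, "auto")) {
    abort("shrink_df must be a number or \"auto\"")
  }
  pos <- s2[s2 > 0]
  if (length(pos) < 4) return(list(df = 10, s2 = mean(s2)))
  e <- log(pos) - digamma(df_resid / 2) + log(df_resid / 2)
  excess <- var(e) - trigamma(df_resid / 2)
  if (!is.finite(excess) || excess <= 1e-8) {
    return(list(df = Inf, s2 = exp(mean(e))))
  }
  half_d0 <- tryCatch(
    uniroot(function(x) trigamma(x) - excess,
            lower = 1e-8, upper = 1e8, tol = 1e-10)$root,
    error = function(e) NULL
  )
  if (is.null(half_d0) || 2 * half_d0 > 1e6) {
    return(list(df = Inf, s2 = exp(mean(e))))
  }
  d0 <- 2 * half_d0
  s0 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(df = d0, s2 = s0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values (monotone, capped at 1), applied per
#' (mark, transition) family throughout the package.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially enriched regions
#'
#' Assigns a status to each tested region: `up` when `fdr <= fdr_max` and
#' `log2fc >= log2(min_fold)`, `down` when `fdr <= fdr_max` and
#' `log2fc <= -log2(min_fold)`, otherwise `ns` (both boundaries inclusive).
#'
#' @param records Tibble with `log2fc` and `fdr` columns (e.g. from
#'   [test_transition()] after [bh_adjust()]).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_fold Minimum fold change on the linear scale (default 2, i.e.
#'   `|log2fc| >= 1`).
#' @return `records` with a `status` column.
#' @export
call_ders <- function(records, fdr_max = 0.05, min_fold = 2) {
  if (!all(c("log2fc", "fdr") %in% names(records))) {
    abort("records need log2fc and fdr columns")
  }
  lfc_min <- log2(min_fold)
  status <- rep("ns", nrow(records))
  sig <- records$fdr <= fdr_max
  status[sig & records$log2fc >= lfc_min] <- "up"
  status[sig & records$log2fc <= -lfc_min] <- "down"
  records$status <- status
  records
}

#' Differential enrichment across all marks and transitions
#'
#' Runs [test_transition()] for every requested (mark, transition) pair,
#' adjusts p values per family with [bh_adjust()], and calls statuses with
#' [call_ders()]. Returns a `der_analysis` object with [tidy()], [glance()]
#' and [autoplot()] methods.
#'
#' @param counts Long count tibble.
#' @param marks Marks to test (default: the four profiled modifications
#'   present in the table).
#' @param transitions Transitions to test (default all three).
#' @param fdr_max,min_fold DER calling thresholds (defaults 0.05 and 2).
#' @param shrink_df,pseudocount Moderation parameters (defaults "auto"
#'   and 0.5; see [test_transition()]).
#' @return A `der_analysis` object; `tidy()` yields one row per tested
#'   region with `log2fc`, `p_value`, `fdr`, `status`.
#' @export
der_analysis <- function(counts, marks = NULL,
                         transitions = greening_transitions(),
                         fdr_max = 0.05, min_fold = 2,
                         shrink_df = "auto", pseudocount = 0.5) {
  counts <- check_counts(counts)
  if (is.null(marks)) {
    marks <- intersect(greening_marks(), unique(counts$mark))
  }
  sf <- size_factors(counts)
  grid <- tidyr::expand_grid(mark = marks, transition = transitions)
  records <- purrr::pmap(grid, function(mark, transition) {
    rec <- test_transition(counts, mark, transition, sf = sf,
                           shrink_df = shrink_df, pseudocount = pseudocount)
    rec$fdr <- bh_adjust(rec$p_value)
    call_ders(rec, fdr_max = fdr_max, min_fold = min_fold)
  })
  out <- list(
    results = dplyr::bind_rows(records),
    size_factors = sf,
    params = list(fdr_max = fdr_max, min_fold = min_fold,
                  shrink_df = shrink_df, pseudocount = pseudocount)
  )
  class(out) <- "der_analysis"
  out
}

#' @export
tidy.der_analysis <- function(x, ...) x$results

#' @export
glance.der_analysis <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$mark, .data$transition) |>
    dplyr::summarise(
      n_regions = dplyr::n(),
      n_up = sum(.data$status == "up"),
      n_down = sum(.data$status == "down"),
      .groups = "drop"
    )
}

#' @export
print.der_analysis <- function(x, ...) {
  cat("Differential enrichment (H3-normalized moderated Wald test)\n")
  cat(sprintf("  thresholds: FDR <= %g, fold >= %g\n",
              x$params$fdr_max, x$params$min_fold))
  print(glance(x))
  invisible(x)
}

#' Bar chart of DER counts per mark and transition
#'
#' @param object A `der_analysis` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.der_analysis <- function(object, ...) {
  counts <- glance(object) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(
      direction = ifelse(.data$direction == "n_up", "up", "down"),
      transition = factor(.data$transition, levels = greening_transitions())
    )
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$transition, y = .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~mark) +
    ggplot2::scale_fill_manual(values = c(up = "#c23b22", down = "#3b6fc2")) +
    ggplot2::labs(x = "transition", y = "differentially enriched regions",
                  fill = NULL)
}
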