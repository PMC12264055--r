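#' Percent input from raw Ct values
#'
#' Helper converting IP and input Ct values to percent-of-input signal:
#' `100 * 2^(ct_input - adj - ct_ip)` where `adj = log2(1 / input_fraction)`
#' corrects for the fraction of chromatin kept as input. The normalization
#' chain itself runs from percent input onward, so panels may equally be
#' supplied with precomputed values.
#'
#' @param ct_ip,ct_input Ct values of the immunoprecipitate and the input.
#' @param input_fraction Fraction of chromatin kept as input (e.g. 0.01).
#' @return Percent input (positive real).
#' @export
percent_input_from_ct <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    abort("input_fraction must be in (0, 1]")
  }
  adj <- log2(1 / input_fraction)
  100 * 2^(ct_input - adj - ct_ip)
}

check_panel <- function(panel) {
  if (!is.data.frame(panel)) abort("panel must be a data frame")
  need <- c("target", "antibody", "condition", "replicate", "percent_input")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    abort(paste0("panel missing column(s): ", paste(miss, collapse = ", ")))
  }
  panel <- tibble::as_tibble(panel)
  if (any(is.na(panel$percent_input)) || any(panel$percent_input <= 0)) {
    abort("percent_input must be positive")
  }
  panel
}

#' ChIP-qPCR modification-to-H3 ratio
#'
#' First normalization step: at each (target, condition, replicate), the
#' percent-input signal of the histone modification of interest is divided
#' by the percent-input signal of H3, correcting for nucleosome occupancy.
#' Any common plate-level scale cancels.
#'
#' @param panel Percent-input tibble with columns `target`, `antibody`
#'   (the modification name or `"H3"`), `condition`, `replicate`,
#'   `percent_input`, and optionally `role` (`"phang"`/`"control"`).
#' @return A tibble with one row per (target, condition, replicate) and a
#'   `ratio` column.
#' @export
chip_ratio <- function(panel) {
  panel <- check_panel(panel)
  keys <- c("target", "condition", "replicate")
  if ("role" %in% names(panel)) keys <- c(keys, "role")
  wide <- panel |>
    dplyr::mutate(antibody = ifelse(.data$antibody == "H3", "H3", "PTM")) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "antibody",
                       values_from = "percent_input")
  if (!all(c("PTM", "H3") %in% names(wide)) ||
      anyNA(wide$PTM) || anyNA(wide$H3)) {
    abort("every (target, condition, replicate) needs both the modification and the H3 measurement")
  }
  wide$ratio <- wide$PTM / wide$H3
  dplyr::select(wide, -"PTM", -"H3")
}

#' Normalize ratios to the geometric mean of two control targets
#'
#' Second normalization step: within each (condition, replicate), every
#' target's modification/H3 ratio is divided by the geometric mean
#' `sqrt(ctrl1 * ctrl2)` of the two designated control targets (regions
#' with abundant, constant modification signal). After this step the two
#' controls' normalized values multiply to exactly 1.
#'
#' @param ratios Output of [chip_ratio()] (or any tibble with `target`,
#'   `condition`, `replicate`, `ratio`).
#' @param control_targets Character vector of exactly 2 control target
#'   names.
#' @return `ratios` with `ratio` replaced by the control-normalized value.
#' @export
normalize_to_controls <- function(ratios, control_targets) {
  if (length(control_targets) != 2) {
    abort("exactly 2 control targets are required")
  }
  if (!all(c("target", "condition", "replicate", "ratio") %in% names(ratios))) {
    abort("ratios need target, condition, replicate, ratio columns")
  }
  ratios |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- df$ratio[match(control_targets, df$target)]
      if (anyNA(ctrl)) {
        abort(paste0("control target(s) missing in condition ",
                     key$condition, ", replicate ", key$replicate))
      }
      if (any(ctrl <= 0)) abort("control ratios must be positive")
      df$ratio <- df$ratio / sqrt(ctrl[1] * ctrl[2])
      df
    }) |>
    dplyr::ungroup()
}

#' Express values relative to a reference condition
#'
#' Final step of the qPCR chain: within each group (target, and replicate
#' when present), values are divided by the value at the reference
#' condition, which therefore maps to exactly 1.
#'
#' @param values Tibble with `condition` and a value column.
#' @param reference_condition Condition used as the denominator.
#' @param value_col Name of the value column (default `"ratio"`).
#' @return `values` with the value column relativized.
#' @export
relativize <- function(values, reference_condition, value_col = "ratio") {
  if (!"condition" %in% names(values) || !value_col %in% names(values)) {
    abort(paste0("values need condition and ", value_col, " columns"))
  }
  keys <- intersect(c("target", "replicate"), names(values))
  values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      ref <- df[[value_col]][df$condition == reference_condition]
      if (length(ref) != 1) {
        abort(paste0("reference condition '", reference_condition,
                     "' must appear exactly once per group"))
      }
      if (ref <= 0) abort("reference value must be positive")
      df[[value_col]] <- df[[value_col]] / ref
      df
    }) |>
    dplyr::ungroup()
}

#' Relative expression by the delta-Ct method
#'
#' Relative transcript abundance `2^(mean(Ct_ref1, Ct_ref2) - Ct_target)`,
#' normalized to two reference genes: the arithmetic mean of the reference
#' Cts equals their geometric mean on the linear `2^-Ct` scale. One cycle
#' below the reference mean doubles the value.
#'
#' @param panel Tibble with `target`, `condition`, `replicate`, `ct`.
#' @param reference_targets Character vector of exactly 2 reference gene
#'   names present in every (condition, replicate).
#' @return A tibble of non-reference targets with an `expression` column.
#' @export
delta_ct_expression <- function(panel, reference_targets) {
  need <- c("target", "condition", "replicate", "ct")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    abort(paste0("panel missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (length(reference_targets) != 2) {
    abort("exactly 2 reference targets are required")
  }
  panel <- tibble::as_tibble(panel)
  panel |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      refs <- df$ct[match(reference_targets, df$target)]
      if (anyNA(refs)) {
        abort(paste0("reference target(s) missing in condition ",
                     key$condition, ", replicate ", key$replicate))
      }
      out <- df[!df$target %in% reference_targets, ]
      out$expression <- 2^(mean(refs) - out$ct)
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select("target", "condition", "replicate", "ct", "expression")
}

#' Welch's two-sample t test
#'
#' Two-sided t test with unequal variances (Satterthwaite degrees of
#' freedom), the test used for replicate-level qPCR comparisons.
#'
#' @param x,y Numeric vectors of replicate values (each of length >= 2).
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `mean_x`, `mean_y`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_test needs at least 2 values per group")
  }
  fit <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}

#' Meta-qPCR aggregation across loci
#'
#' Combines fully normalized per-locus profiles into a single
#' per-timepoint summary: across-locus mean and standard error
#' (`sd / sqrt(n_loci)`) at each timepoint, the display used to summarise
#' many photosynthesis loci at once.
#'
#' @param values Tibble with `target`, a `timepoint` (or `condition`)
#'   column, and a value column.
#' @param loci Character vector of loci to aggregate.
#' @param value_col Name of the value column (default `"ratio"`).
#' @param time_col Name of the time/condition column (default
#'   `"timepoint"`).
#' @return A tibble with `timepoint`, `mean`, `sem`, `n_loci`.
#' @export
meta_qpcr <- function(values, loci, value_col = "ratio",
                      time_col = "timepoint") {
  if (length(loci) == 0) abort("loci subset must be non-empty")
  if (!time_col %in% names(values) || !value_col %in% names(values)) {
    abort(paste0("values need ", time_col, " and ", value_col, " columns"))
  }
  sub <- values[values$target %in% loci, ]
  if (nrow(sub) == 0) abort("none of the requested loci are present")
  sub |>
    dplyr::group_by(timepoint = .data[[time_col]]) |>
    dplyr::summarise(
      mean = mean(.data[[value_col]]),
      sem = if (dplyr::n() > 1) sd(.data[[value_col]]) / sqrt(dplyr::n()) else 0,
      n_loci = dplyr::n(),
      .groups = "drop"
    )
}
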