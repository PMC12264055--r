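#' Chlorophyll and carotenoid quantification from microplate absorbances
#'
#' Methanol-extract pigment quantification. Absorbances at 470, 652 and
#' 665 nm are blank-corrected against A750 and divided by the microplate
#' pathlength factor (0.58 for 200 ul in a 96-well plate):
#' `A_c = (A - A750) / 0.58`. Pigments then follow the standard linear
#' combinations
#' `ChlA = -6.5079 A652c + 16.2127 A665c`,
#' `ChlB = 32.1228 A652c - 13.8255 A665c` (ug/ml), and
#' `Car = (1000 A470c - 1.63 ChlA - 104.96 ChlB) / 221`.
#' Amounts per mg fresh weight use the extract volume:
#' `ug/mg = ug/ml * volume_ml / weight_mg`.
#'
#' Corrected absorbances below zero (blank exceeding signal) are clamped
#' to 0; a warning is emitted when the excess is beyond `tol`.
#'
#' @param records Tibble with columns `a470`, `a652`, `a665`, `a750` and
#'   optionally `volume_ml` (default 0.5), `weight_mg` (default 25).
#' @param pathlength_factor Microplate pathlength correction (default
#'   0.58).
#' @param volume_ml,weight_mg Defaults used when the columns are absent.
#' @param tol Negative corrected absorbance tolerated silently (default
#'   1e-9).
#' @return `records` with added columns `chla_ugml`, `chlb_ugml`,
#'   `car_ugml`, `chla_ugmg`, `chlb_ugmg`, `car_ugmg`.
#' @examples
#' pigment_quant(tibble::tibble(a470 = 0.30, a652 = 0.75,
#'                              a665 = 0.92, a750 = 0.05))
#' @export
pigment_quant <- function(records, pathlength_factor = 0.58,
                          volume_ml = 0.5, weight_mg = 25, tol = 1e-9) {
  if (!is.data.frame(records)) abort("records must be a data frame")
  need <- c("a470", "a652", "a665", "a750")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  if (any(unlist(records[need]) < 0, na.rm = TRUE)) {
    abort("absorbances must be nonnegative")
  }
  if (pathlength_factor <= 0) abort("pathlength_factor must be positive")
  if (!"volume_ml" %in% names(records)) records$volume_ml <- volume_ml
  if (!"weight_mg" %in% names(records)) records$weight_mg <- weight_mg
  corr <- function(a) {
    v <- (a - records$a750) / pathlength_factor
    if (any(v < -tol)) {
      warn("blank A750 exceeds signal for some records; clamping corrected absorbance to 0")
    }
    pmax(v, 0)
  }
  a470c <- corr(records$a470)
  a652c <- corr(records$a652)
  a665c <- corr(records$a665)
  records$chla_ugml <- -6.5079 * a652c + 16.2127 * a665c
  records$chlb_ugml <- 32.1228 * a652c - 13.8255 * a665c
  records$car_ugml <- (1000 * a470c - 1.63 * records$chla_ugml -
                         104.96 * records$chlb_ugml) / 221
  scale <- records$volume_ml / records$weight_mg
  records$chla_ugmg <- records$chla_ugml * scale
  records$chlb_ugmg <- records$chlb_ugml * scale
  records$car_ugmg <- records$car_ugml * scale
  records
}

#' Green-pixel score of scanned seedlings
#'
#' Greening is scored on the 8-bit green channel of a plate scan: for each
#' region of interest (ROI) drawn over a cotyledon, the score is the
#' maximum grey value minus the ROI mean, `green_value = 255 -
#' mean(grey)`. Darker (greener) cotyledons therefore score higher; a
#' fully white ROI scores 0 and a fully black one 255.
#'
#' @param image Numeric matrix of grey values in `[0, 255]` (green
#'   channel).
#' @param rois Either a single logical mask matrix matching `image`, a
#'   list of such masks, or a rectangle tibble with columns `seedling`,
#'   `row0`, `row1`, `col0`, `col1` (inclusive pixel bounds).
#' @return A tibble with `seedling`, `n_pixels`, `roi_mean_grey`,
#'   `green_value`.
#' @export
greening_score <- function(image, rois) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("image must be a numeric matrix")
  }
  if (any(image < 0) || any(image > 255)) {
    abort("grey values must lie in [0, 255]")
  }
  masks <- rois_to_masks(rois, dim(image))
  if (length(masks) == 0) abort("at least one ROI is required")
  out <- purrr::imap(masks, function(mask, name) {
    if (!any(mask)) abort(paste0("ROI '", name, "' is empty"))
    px <- image[mask]
    tibble::tibble(seedling = name, n_pixels = length(px),
                   roi_mean_grey = mean(px), green_value = 255 - mean(px))
  })
  dplyr::bind_rows(out)
}

rois_to_masks <- function(rois, dims) {
  if (is.matrix(rois) && is.logical(rois)) {
    rois <- list(roi1 = rois)
  }
  if (is.list(rois) && !is.data.frame(rois)) {
    if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
    for (m in rois) {
      if (!is.matrix(m) || !is.logical(m) || !identical(dim(m), dims)) {
        abort("each ROI mask must be a logical matrix matching the image")
      }
    }
    return(rois)
  }
  if (is.data.frame(rois)) {
    need <- c("seedling", "row0", "row1", "col0", "col1")
    miss <- setdiff(need, names(rois))
    if (length(miss) > 0) {
      abort(paste0("ROI table missing column(s): ", paste(miss, collapse = ", ")))
    }
    masks <- purrr::pmap(rois[need], function(seedling, row0, row1, col0, col1) {
      if (row0 < 1 || col0 < 1 || row1 > dims[1] || col1 > dims[2] ||
          row0 > row1 || col0 > col1) {
        abort(paste0("ROI '", seedling, "' outside the image"))
      }
      m <- matrix(FALSE, dims[1], dims[2])
      m[row0:row1, col0:col1] <- TRUE
      m
    })
    names(masks) <- as.character(rois$seedling)
    return(masks)
  }
  abort("rois must be a logical mask, a list of masks, or a rectangle table")
}

#' One-way ANOVA with post-hoc pairwise comparisons
#'
#' Compares green-pixel scores (or pigment amounts) across conditions:
#' one-way ANOVA followed by either Tukey's HSD over all pairs or
#' Dunnett's many-to-one comparisons against a control group.
#'
#' @param data Tibble with a grouping column and a value column.
#' @param group,value Column names (defaults `"group"`, `"value"`).
#' @param posthoc `"tukey"` (all pairs) or `"dunnett"` (versus control).
#' @param control Control group for Dunnett (default: first factor level).
#' @return A `group_comparison` object; `tidy()` gives the pairwise table
#'   (`comparison`, `estimate`, `p_adjusted`), `glance()` the ANOVA
#'   `statistic` (F), `df`, `df_residual`, `p_value`.
#' @export
group_compare <- function(data, group = "group", value = "value",
                          posthoc = c("tukey", "dunnett"), control = NULL) {
  posthoc <- match.arg(posthoc)
  if (!group %in% names(data) || !value %in% names(data)) {
    abort(paste0("data needs columns '", group, "' and '", value, "'"))
  }
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) abort("at least 2 groups are required")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("every group needs n >= 2; offending group: ",
                 names(sizes)[which(sizes < 2)[1]]))
  }
  if (!is.null(control)) {
    if (!control %in% levels(g)) abort("control is not a group level")
    g <- stats::relevel(g, ref = control)
  }
  df <- data.frame(y = y, g = g)
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    statistic = an[["F value"]][1],
    df = an[["Df"]][1],
    df_residual = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1]
  )
  if (posthoc == "tukey") {
    tk <- TukeyHSD(fit)$g
    pairs <- tibble::tibble(
      comparison = rownames(tk),
      estimate = tk[, "diff"],
      p_adjusted = tk[, "p adj"]
    )
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    pairs <- tibble::tibble(
      comparison = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      p_adjusted = unname(as.numeric(sm$test$pvalues))
    )
  }
  out <- list(anova = anova_tbl, pairs = pairs, posthoc = posthoc,
              groups = levels(g))
  class(out) <- "group_comparison"
  out
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairs

#' @export
glance.group_comparison <- function(x, ...) x$anova

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA over %d groups: F(%d, %d) = %.3f, p = %.3g\n",
              length(x$groups), x$anova$df, x$anova$df_residual,
              x$anova$statistic, x$anova$p_value))
  cat(sprintf("Post-hoc (%s):\n", x$posthoc))
  print(x$pairs)
  invisible(x)
}
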