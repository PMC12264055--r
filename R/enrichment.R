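#' Term over-representation in a gene set
#'
#' One-sided hypergeometric over-representation analysis of a selected
#' gene set against a universe, for every term with at least one universe
#' gene. Reports the field's "% found vs % expected" enrichment ratio:
#' `percent_found = 100 k / n` (share of selected genes carrying the term)
#' over `percent_expected = 100 K / N` (share of the universe carrying it),
#' with the upper-tail p value `P(X >= k)` for drawing `n` genes from a
#' universe of `N` containing `K` term genes. Bonferroni correction over
#' the tested terms is the default; Benjamini-Hochberg is available.
#'
#' @param selected Character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param universe Character vector of universe gene ids.
#' @param term_map Tibble with `gene_id`, `term_id` (see [read_term_map()]).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return A tibble sorted by adjusted then raw p value with columns
#'   `term_id`, `n_universe`, `n_term`, `n_selected`, `n_overlap`,
#'   `percent_found`, `percent_expected`, `ratio`, `p_value`, `p_adjusted`.
#' @examples
#' term_map <- tibble::tibble(gene_id = paste0("g", 1:5), term_id = "T1")
#' enrich_terms(paste0("g", 1:4), paste0("g", 1:20), term_map)
#' @export
enrich_terms <- function(selected, universe, term_map,
                         correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe)) {
    abort("selected genes must be a subset of the universe")
  }
  if (!all(c("gene_id", "term_id") %in% names(term_map))) {
    abort("term_map needs gene_id and term_id columns")
  }
  N <- length(universe)
  n <- length(selected)
  tm <- term_map |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$gene_id, .data$term_id)
  if (nrow(tm) == 0 || n == 0) {
    return(tibble::tibble(term_id = character(), n_universe = integer(),
                          n_term = integer(), n_selected = integer(),
                          n_overlap = integer(), percent_found = double(),
                          percent_expected = double(), ratio = double(),
                          p_value = double(), p_adjusted = double()))
  }
  res <- tm |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      n_term = dplyr::n(),
      n_overlap = sum(.data$gene_id %in% .env$selected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_universe = N,
      n_selected = n,
      percent_found = 100 * .data$n_overlap / n,
      percent_expected = 100 * .data$n_term / N,
      ratio = .data$percent_found / .data$percent_expected,
      p_value = phyper(.data$n_overlap - 1, .data$n_term,
                       N - .data$n_term, n, lower.tail = FALSE)
    )
  m <- nrow(res)
  res$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, res$p_value * m)
  } else {
    bh_adjust(res$p_value)
  }
  res |>
    dplyr::select("term_id", "n_universe", "n_term", "n_selected",
                  "n_overlap", "percent_found", "percent_expected",
                  "ratio", "p_value", "p_adjusted") |>
    dplyr::arrange(.data$p_adjusted, .data$p_value, .data$term_id)
}
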