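peak_dialects <- c("narrowPeak", "broadPeak", "bed6")

dialect_ncol <- c(narrowPeak = 10L, broadPeak = 9L, bed6 = 6L)

#' Read peak calls in BED-family dialects
#'
#' Parses headerless tab-separated peak files: `narrowPeak` (10 columns,
#' column 10 is the summit offset from the peak start), `broadPeak`
#' (9 columns, no summit; the interval midpoint is used by convention
#' wherever a centre is required) or plain `bed6`. Coordinates are kept
#' 0-based half-open.
#'
#' @param path Path to the peak file.
#' @param dialect One of `"narrowPeak"`, `"broadPeak"`, `"bed6"`.
#' @return A tibble of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit_offset`, `shape` (plus `signal`, `pvalue`,
#'   `qvalue` for the MACS2 dialects).
#' @export
parse_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nc <- dialect_ncol[[dialect]]
  if (length(lines) == 0) return(empty_peak_tbl(dialect))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != nc)
  if (length(bad) > 0) {
    abort(paste0("malformed ", dialect, " line ", bad[1], " in ", path,
                 ": expected ", nc, " fields, found ", nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = nc, byrow = TRUE)
  num <- function(col, label) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      abort(paste0("malformed ", dialect, " line ", which(is.na(v))[1],
                   " in ", path, ": non-numeric ", label))
    }
    v
  }
  out <- tibble::tibble(
    chrom = m[, 1],
    start = as.integer(num(2, "start")),
    end = as.integer(num(3, "end")),
    name = m[, 4],
    score = num(5, "score"),
    strand = m[, 6]
  )
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    out$signal <- num(7, "signalValue")
    out$pvalue <- num(8, "pValue")
    out$qvalue <- num(9, "qValue")
  }
  width <- out$end - out$start
  if (dialect == "narrowPeak") {
    out$summit_offset <- as.integer(num(10, "summit offset"))
    out$shape <- "narrow"
  } else {
    # midpoint convention; broad peaks are never summit-extended
    out$summit_offset <- as.integer(width %/% 2L)
    out$shape <- if (dialect == "broadPeak") "broad" else "narrow"
  }
  check_intervals(out, paste0(dialect, " file ", path))
  bad <- which(out$summit_offset < 0 | out$summit_offset >= width)
  if (length(bad) > 0) {
    abort(paste0("invalid summit offset at line ", bad[1], " in ", path,
                 ": offset ", out$summit_offset[bad[1]],
                 " outside a ", width[bad[1]], " bp peak"))
  }
  out
}

empty_peak_tbl <- function(dialect) {
  out <- tibble::tibble(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = double(), strand = character())
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    out$signal <- double(); out$pvalue <- double(); out$qvalue <- double()
  }
  out$summit_offset <- integer()
  out$shape <- character()
  out
}

#' Write peaks or plain intervals as BED-family text
#'
#' Writers emit tab-separated, newline-terminated files with no header.
#' `write_peaks()` round-trips [parse_peaks()] output bit-exactly for the
#' matching dialect; `write_bed()` writes `chrom start end [name score
#' strand]` using whatever of those columns are present.
#'
#' @param x Peak or interval tibble.
#' @param path Output path.
#' @param dialect Peak dialect to emit.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, dialect = c("narrowPeak", "broadPeak", "bed6")) {
  dialect <- match.arg(dialect)
  x <- check_intervals(x, "peaks")
  cols <- list(x$chrom, x$start, x$end, x$name, x$score, x$strand)
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    cols <- c(cols, list(x$signal, x$pvalue, x$qvalue))
  }
  if (dialect == "narrowPeak") cols <- c(cols, list(x$summit_offset))
  m <- do.call(cbind, lapply(cols, format_bed_col))
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
write_bed <- function(x, path) {
  x <- check_intervals(x)
  cols <- list(x$chrom, x$start, x$end)
  if ("name" %in% names(x)) {
    cols <- c(cols, list(x$name))
    if ("score" %in% names(x)) {
      cols <- c(cols, list(x$score))
      if ("strand" %in% names(x)) cols <- c(cols, list(x$strand))
    }
  }
  m <- do.call(cbind, lapply(cols, format_bed_col))
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

format_bed_col <- function(v) {
  if (is.numeric(v)) {
    out <- format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  } else {
    out <- as.character(v)
  }
  out
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 input (1-based inclusive) is converted to the package-internal
#' 0-based half-open convention on read; only `gene` features are kept and
#' `gene_id` is taken from the `ID` attribute (falling back to `Name`).
#' BED input is read as `chrom start end gene_id [score strand]`.
#'
#' @param path Annotation file path.
#' @param format `"gff3"` or `"bed"`.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
    out <- tibble::tibble(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
    out$strand[out$strand == "*"] <- "."
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(raw) < 4) abort("BED gene file needs >= 4 columns (name holds gene_id)")
    out <- tibble::tibble(
      gene_id = as.character(raw[[4]]),
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]),
      strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else "."
    )
  }
  if (anyDuplicated(out$gene_id)) {
    abort("gene_id values must be unique within an annotation set")
  }
  check_intervals(out, "gene models")
  out
}

#' Read a gene-to-term map
#'
#' Expects a tab-separated file with columns `gene_id`, `term_id` and an
#' optional `term_name`; one row per (gene, term) assignment. Terms are
#' taken as given (no ontology-graph propagation).
#'
#' @param path TSV path.
#' @return A tibble with `gene_id`, `term_id` (and `term_name` if present).
#' @export
read_term_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(out))) {
    abort("term map needs columns gene_id, term_id")
  }
  tibble::as_tibble(out)
}

#' Read a fragment list
#'
#' Tab-separated `chrom start end` intervals (no header), e.g. RNA read
#' fragments for coverage extraction at differentially enriched regions.
#'
#' @param path TSV path.
#' @return An interval tibble.
#' @export
read_fragments <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  check_intervals(tibble::as_tibble(raw), "fragments")
}
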