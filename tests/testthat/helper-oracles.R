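# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (all-pairs loops, per-base bitmaps, exhaustive draws)
# so they cannot share a bug with the implementations they check.

rand_intervals <- function(n, chroms = c("chrT1", "chrT2"),
                           chrom_len = 10000, max_width = 400) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = pmin(start + width, chrom_len)
  )
}

bf_intersect <- function(a, b, min_overlap = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        out[[length(out) + 1]] <- c(i, j, ov)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer(),
                          overlap_bp = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_idx = m[, 1], b_idx = m[, 2], overlap_bp = m[, 3]) |>
    dplyr::arrange(a_idx, b_idx)
}

# merge via a per-base occupancy bitmap on a toy chromosome
bf_merge <- function(x, gap = 0, chrom_len = 10000) {
  pieces <- list()
  for (ch in sort(unique(x$chrom))) {
    occ <- rep(FALSE, chrom_len)
    sub <- x[x$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      occ[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    r <- rle(occ)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    iv <- data.frame(s = run_start[r$values] - 1L, e = run_end[r$values])
    cur_s <- iv$s[1]; cur_e <- iv$e[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$s[i] - cur_e <= gap) {
        cur_e <- iv$e[i]
      } else {
        pieces[[length(pieces) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                                   end = cur_e)
        cur_s <- iv$s[i]; cur_e <- iv$e[i]
      }
    }
    pieces[[length(pieces) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                               end = cur_e)
  }
  out <- tibble::as_tibble(do.call(rbind, pieces))
  dplyr::arrange(out, chrom, start, end)
}

bf_coverage <- function(regions, fragments) {
  vapply(seq_len(nrow(regions)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(fragments))) {
      if (regions$chrom[i] != fragments$chrom[j]) next
      if (min(regions$end[i], fragments$end[j]) >
          max(regions$start[i], fragments$start[j])) {
        n <- n + 1L
      }
    }
    n
  }, integer(1))
}

# exhaustive-draw hypergeometric upper tail: enumerate every size-n draw
# from a universe of N with the first K elements marked
bf_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# per-base metaprofile: expand the track to a base vector and average
bf_metaprofile <- function(track, regions, window_bp, n_bins, anchor_pos,
                           chrom_len = 10000) {
  vecs <- list()
  for (ch in unique(track$chrom)) {
    v <- numeric(chrom_len)
    sub <- track[track$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
    }
    vecs[[ch]] <- v
  }
  bw <- window_bp / n_bins
  out <- matrix(0, nrow(regions), n_bins)
  for (i in seq_len(nrow(regions))) {
    v <- vecs[[regions$chrom[i]]]
    if (is.null(v)) v <- numeric(chrom_len)
    for (b in seq_len(n_bins)) {
      bs <- anchor_pos[i] - window_bp / 2 + (b - 1) * bw
      vals <- vapply(bs:(bs + bw - 1), function(p) {
        if (p < 0 || p >= chrom_len) 0 else v[p + 1]
      }, numeric(1))
      out[i, b] <- mean(vals)
    }
  }
  out
}

# small valid long count table: two marks + H3 + Input, all timepoints
toy_counts <- function(n_regions = 20, n_reps = 2, mu = 50, seed = 42) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      region_id = sprintf("R%03d", seq_len(n_regions)),
      mark = c("H3K27ac", "H3K27me3", "H3", "Input"),
      timepoint = greening_timepoints(),
      replicate = seq_len(n_reps)
    )
    grid$count <- rnbinom(nrow(grid), mu = mu, size = 20)
    grid
  })
}

unit_sf <- function(counts) {
  dplyr::distinct(counts, mark, timepoint, replicate) |>
    dplyr::mutate(size_factor = 1)
}
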