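test_that("size factors recover depth ratios by median-of-ratios", {
  base <- tibble::tibble(
    region_id = sprintf("R%02d", 1:20),
    mark = "H3K27ac", timepoint = "Dark", replicate = 1L,
    count = 5L * (1:20)
  )
  twice <- dplyr::mutate(base, replicate = 2L, count = 2L * count)
  sf <- size_factors(dplyr::bind_rows(base, twice))
  expect_equal(sort(sf$size_factor), c(2^-0.5, 2^0.5))
  # identical samples get unit factors
  same <- dplyr::mutate(base, replicate = 2L)
  sf2 <- size_factors(dplyr::bind_rows(base, same))
  expect_equal(sf2$size_factor, c(1, 1))
})

test_that("size factors fall back to library sizes on degenerate tables", {
  one <- tibble::tibble(
    region_id = "R1",
    mark = "H3K27ac", timepoint = "Dark", replicate = c(1L, 2L),
    count = c(10L, 40L)
  )
  sf <- size_factors(one)
  expect_equal(sf$size_factor, c(0.5, 2))  # proportional to library size
  allzero <- dplyr::mutate(one, count = c(10L, 0L))
  expect_error(size_factors(allzero), "all-zero")
})

test_that("H3 log ratio matches hand evaluation and cancels scale", {
  counts <- tibble::tibble(
    region_id = "R1",
    mark = c("H3K27ac", "H3"), timepoint = "Dark", replicate = 1L,
    count = c(15L, 3L)
  )
  sf1 <- unit_sf(counts)
  r <- h3_log_ratio(counts, "H3K27ac", "Dark", 1L, sf = sf1)
  expect_equal(r$log_ratio, log2(15.5 / 3.5), tolerance = 1e-12)

  # identical counts and factors give zero
  eq <- dplyr::mutate(counts, count = 10L)
  expect_equal(h3_log_ratio(eq, "H3K27ac", "Dark", 1L,
                            sf = unit_sf(eq))$log_ratio, 0)

  # doubling both size factors leaves the ratio unchanged
  sf2 <- dplyr::mutate(sf1, size_factor = 2)
  expect_equal(h3_log_ratio(counts, "H3K27ac", "Dark", 1L, sf = sf2),
               r)
  expect_error(h3_log_ratio(counts[1, ], "H3K27ac", "Dark", 1L, sf = sf1),
               "H3")
})

test_that("a region with identical group ratios gets delta 0 and p 1", {
  counts <- toy_counts(n_regions = 30)
  flat <- counts$region_id == "R001" & counts$mark %in% c("H3K27ac", "H3")
  counts$count[flat] <- 40L
  rec <- test_transition(counts, "H3K27ac", "Dark:Day1", sf = unit_sf(counts),
                         shrink_df = 10)
  r1 <- rec[rec$region_id == "R001", ]
  expect_equal(r1$log2fc, 0)
  expect_equal(r1$p_value, 1, tolerance = 1e-12)
})

test_that("swapping timepoint labels negates log2fc and keeps p", {
  counts <- toy_counts(n_regions = 40, seed = 7)
  fwd <- test_transition(counts, "H3K27ac", "Dark:Day1", sf = unit_sf(counts),
                         shrink_df = 10)
  swapped <- dplyr::mutate(counts, timepoint = dplyr::case_match(
    timepoint, "Dark" ~ "Day1", "Day1" ~ "Dark", .default = timepoint))
  rev <- test_transition(swapped, "H3K27ac", "Dark:Day1",
                         sf = dplyr::mutate(unit_sf(swapped)),
                         shrink_df = 10)
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("raw p values are calibrated on null negative-binomial counts", {
  withr::with_seed(1, {
    n <- 1000
    grid <- tidyr::expand_grid(
      region_id = sprintf("R%04d", seq_len(n)),
      mark = c("H3K27ac", "H3"),
      timepoint = c("Dark", "Day1"),
      replicate = 1:2
    )
    grid$count <- rnbinom(nrow(grid), mu = 50, size = 1 / 0.05)
    rec10 <- test_transition(grid, "H3K27ac", "Dark:Day1",
                             sf = unit_sf(grid), shrink_df = 10)
    expect_gt(mean(rec10$p_value < 0.05), 0.03)
    expect_lt(mean(rec10$p_value < 0.05), 0.07)
    reca <- test_transition(grid, "H3K27ac", "Dark:Day1",
                            sf = unit_sf(grid), shrink_df = "auto")
    expect_gt(mean(reca$p_value < 0.05), 0.03)
    expect_lt(mean(reca$p_value < 0.05), 0.07)
  })
})

test_that("detection rate is monotone in the planted fold change", {
  withr::with_seed(31, {
    n <- 300; planted <- 1:60
    rates <- vapply(c(0, 1, 2, 3), function(lfc) {
      grid <- tidyr::expand_grid(
        region_id = sprintf("R%04d", seq_len(n)),
        mark = c("H3K27ac", "H3"),
        timepoint = c("Day4", "Day7"),
        replicate = 1:2
      )
      mu <- rep(50, nrow(grid))
      boost <- grid$mark == "H3K27ac" & grid$timepoint == "Day7" &
        grid$region_id %in% sprintf("R%04d", planted)
      mu[boost] <- 50 * 2^lfc
      grid$count <- rnbinom(nrow(grid), mu = mu, size = 1 / 0.05)
      rec <- test_transition(grid, "H3K27ac", "Day4:Day7", sf = unit_sf(grid))
      rec$fdr <- bh_adjust(rec$p_value)
      rec <- call_ders(rec)
      mean(rec$status[rec$region_id %in% sprintf("R%04d", planted)] == "up")
    }, numeric(1))
    expect_true(all(diff(rates) >= -0.02))  # non-decreasing up to noise
    expect_gt(rates[4], rates[1])
  })
})

test_that("joint H3 and modification shifts (constant ratio) stay non-significant", {
  withr::with_seed(32, {
    n <- 400; shifted <- sprintf("R%04d", 1:100)
    grid <- tidyr::expand_grid(
      region_id = sprintf("R%04d", seq_len(n)),
      mark = c("H3K27ac", "H3"),
      timepoint = c("Day4", "Day7"),
      replicate = 1:2
    )
    mu <- rep(50, nrow(grid))
    idx <- grid$timepoint == "Day7" & grid$region_id %in% shifted
    mu[idx] <- 200  # 4x in both the modification and H3
    grid$count <- rnbinom(nrow(grid), mu = mu, size = 1 / 0.05)
    rec <- test_transition(grid, "H3K27ac", "Day4:Day7", sf = unit_sf(grid))
    rec$fdr <- bh_adjust(rec$p_value)
    rec <- call_ders(rec)
    frac_ns <- mean(rec$status[rec$region_id %in% shifted] == "ns")
    expect_gte(frac_ns, 0.95)
  })
})

test_that("moderated p values rank-agree with exact permutation p", {
  withr::with_seed(1, {
    n <- 50
    grid <- tidyr::expand_grid(
      region_id = sprintf("R%03d", seq_len(n)),
      mark = c("H3K27ac", "H3"),
      timepoint = c("Day1", "Day4"),
      replicate = 1:3
    )
    mu <- rep(50, nrow(grid))
    mu[grid$mark == "H3K27ac" & grid$timepoint == "Day4" &
         grid$region_id %in% sprintf("R%03d", 1:15)] <- 150
    grid$count <- rnbinom(nrow(grid), mu = mu, size = 1 / 0.05)
    rec <- test_transition(grid, "H3K27ac", "Day1:Day4", sf = unit_sf(grid),
                           shrink_df = 10)

    # exact permutation of the six per-replicate log ratios per region,
    # permuting the same moderated statistic recomputed from scratch
    r_of <- function(tp, rep) {
      p <- grid[grid$mark == "H3K27ac" & grid$timepoint == tp &
                  grid$replicate == rep, ]
      h <- grid[grid$mark == "H3" & grid$timepoint == tp &
                  grid$replicate == rep, ]
      log2((p$count[match(rec$region_id, p$region_id)] + 0.5) /
             (h$count[match(rec$region_id, h$region_id)] + 0.5))
    }
    rmat <- cbind(r_of("Day1", 1), r_of("Day1", 2), r_of("Day1", 3),
                  r_of("Day4", 1), r_of("Day4", 2), r_of("Day4", 3))
    s2_obs <- apply(rmat, 1, function(v) {
      (sum((v[1:3] - mean(v[1:3]))^2) + sum((v[4:6] - mean(v[4:6]))^2)) / 4
    })
    prior <- mean(s2_obs)
    tstat <- function(v, g) {
      a <- v[g]; b <- v[setdiff(1:6, g)]
      s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
      abs(mean(b) - mean(a)) /
        sqrt((4 * s2 + 10 * prior) / 14 * (2 / 3))
    }
    combos <- utils::combn(6, 3)
    perm_p <- apply(rmat, 1, function(v) {
      obs <- tstat(v, 1:3)
      stats <- apply(combos, 2, function(g) tstat(v, g))
      mean(stats >= obs - 1e-12)
    })
    expect_gte(suppressWarnings(cor(rec$p_value, perm_p, method = "spearman")),
               0.9)
  })
})

test_that("BH adjustment follows the step-up rule and dominates raw p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  withr::with_seed(34, {
    p <- runif(50)
    expect_true(all(bh_adjust(p) >= p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DER calling applies the FDR and fold thresholds inclusively", {
  rec <- tibble::tibble(
    log2fc = c(1.5, 0.9, 3, -1, 1),
    fdr = c(0.04, 0.04, 0.06, 0.05, 0.05)
  )
  out <- call_ders(rec)
  expect_equal(out$status, c("up", "ns", "ns", "down", "up"))
})

test_that("der_analysis adjusts per family and summarises counts", {
  counts <- toy_counts(n_regions = 25, seed = 9)
  fit <- der_analysis(counts, marks = c("H3K27ac", "H3K27me3"))
  out <- tidy(fit)
  expect_equal(nrow(out), 25 * 2 * 3)
  one <- out[out$mark == "H3K27ac" & out$transition == "Dark:Day1", ]
  expect_equal(one$fdr, bh_adjust(one$p_value))
  gl <- glance(fit)
  expect_equal(nrow(gl), 6)
  expect_true(all(gl$n_up + gl$n_down <= gl$n_regions))
})
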