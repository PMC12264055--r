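mk_ders <- function(region_id, mark, statuses) {
  tibble::tibble(
    region_id = region_id, mark = mark,
    transition = greening_transitions(),
    status = statuses,
    log2fc = ifelse(statuses == "up", 2, ifelse(statuses == "down", -2, 0)),
    p_value = 0.5, fdr = 0.5
  )
}

test_that("Profile5 is the H3K27ac (ns, ns, up) triple and labels are systematic", {
  ders <- dplyr::bind_rows(
    mk_ders("R1", "H3K27ac", c("ns", "ns", "up")),
    mk_ders("R2", "H3K27ac", c("ns", "ns", "ns")),
    mk_ders("R3", "H3K27me3", c("ns", "ns", "up")),
    mk_ders("R4", "H3K27ac", c("up", "ns", "down"))
  )
  prof <- classify_profiles(ders)
  get <- function(id) prof$label[prof$region_id == id]
  expect_equal(get("R1"), "Profile5")
  expect_equal(get("R2"), "ns.ns.ns")
  expect_equal(get("R3"), "ns.ns.up")  # not H3K27ac, not Profile5
  expect_equal(get("R4"), "up.ns.down")
  expect_equal(prof$profile5, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("classification matches rule enumeration over all 27 triples", {
  st <- c("up", "down", "ns")
  triples <- expand.grid(s1 = st, s2 = st, s3 = st,
                         stringsAsFactors = FALSE)
  for (mk in c("H3K27ac", "H3K27me3")) {
    ders <- dplyr::bind_rows(lapply(seq_len(nrow(triples)), function(i) {
      mk_ders(sprintf("T%02d", i), mk, unlist(triples[i, ]))
    }))
    prof <- classify_profiles(ders)
    want <- vapply(seq_len(nrow(triples)), function(i) {
      s <- unlist(triples[i, ])
      if (mk == "H3K27ac" && s[1] == "ns" && s[2] == "ns" && s[3] == "up") {
        "Profile5"
      } else {
        paste(s, collapse = ".")
      }
    }, character(1))
    expect_equal(prof$label[match(sprintf("T%02d", seq_len(nrow(triples))),
                                  prof$region_id)], want)
  }
})

test_that("classification requires all three transitions", {
  ders <- mk_ders("R1", "H3K27ac", c("ns", "ns", "up"))[1:2, ]
  expect_error(classify_profiles(ders), "transition")
})

test_that("region annotation keeps all matches within the promoter window", {
  genes <- tibble::tibble(
    gene_id = c("A", "B"),
    chrom = "chr1", start = c(2000, 3100), end = c(3000, 4000),
    strand = c("+", "+")
  )
  inside <- tibble::tibble(region_id = "r1", chrom = "chr1",
                           start = 2200, end = 2400)
  expect_equal(annotate_ders(inside, genes, upstream_bp = 100)$gene_id, "A")
  # with the default 1 kb window the region also reaches B's promoter
  expect_equal(sort(annotate_ders(inside, genes)$gene_id), c("A", "B"))
  spanning <- tibble::tibble(region_id = "r2", chrom = "chr1",
                             start = 2900, end = 3200)
  expect_equal(sort(annotate_ders(spanning, genes, upstream_bp = 100)$gene_id),
               c("A", "B"))
  # upstream window is strand-aware
  minus <- dplyr::mutate(genes, strand = "-")
  downstream <- tibble::tibble(region_id = "r3", chrom = "chr1",
                               start = 4050, end = 4080)
  expect_equal(annotate_ders(downstream, minus, upstream_bp = 100)$gene_id,
               "B")
  expect_equal(nrow(annotate_ders(downstream, genes, upstream_bp = 100)), 0L)
})

test_that("annotation equals the brute-force overlap of extended gene bodies", {
  withr::with_seed(41, {
    regions <- rand_intervals(60)
    regions$region_id <- sprintf("r%03d", seq_len(nrow(regions)))
    genes <- rand_intervals(40)
    genes$gene_id <- sprintf("g%03d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-", "."), nrow(genes), replace = TRUE)
    up <- 300
    ext <- genes
    ext$start <- ifelse(genes$strand == "-", genes$start,
                        pmax(0, genes$start - up))
    ext$end <- ifelse(genes$strand == "-", genes$end + up, genes$end)
    want <- bf_intersect(regions, ext)
    got <- annotate_ders(regions, genes, upstream_bp = up)
    want_tbl <- dplyr::arrange(
      tibble::tibble(region_id = regions$region_id[want$a_idx],
                     gene_id = genes$gene_id[want$b_idx]),
      region_id, gene_id)
    expect_equal(got, want_tbl)
  })
})

test_that("switch overlap is the gene-level intersection with provenance", {
  ann <- tibble::tibble(
    region_id = c("m1", "m2", "m3", "a1", "a2", "a3"),
    gene_id = c("A", "B", "C", "B", "C", "D")
  )
  me3 <- tibble::tibble(region_id = c("m1", "m2", "m3"), mark = "H3K27me3",
                        transition = "Day1:Day4", status = "down")
  ac <- tibble::tibble(region_id = c("a1", "a2", "a3"), mark = "H3K27ac",
                       transition = "Day4:Day7", status = "up")
  sw <- switch_overlap(me3, ac, ann)
  expect_equal(sw$gene_id, c("B", "C"))
  expect_equal(sw$me3_down_regions, c("m2", "m3"))
  expect_equal(sw$ac_up_regions, c("a1", "a2"))
  expect_true(all(sw$gene_id %in% ann$gene_id[ann$region_id %in% me3$region_id]))

  # disjoint gene sets give an empty switch set
  ann2 <- dplyr::mutate(ann, gene_id = c("A", "B", "C", "D", "E", "F"))
  expect_equal(nrow(switch_overlap(me3, ac, ann2)), 0L)

  # transition mismatch is an error
  bad <- dplyr::mutate(me3, transition = "Dark:Day1")
  expect_error(switch_overlap(bad, ac, ann), "Day1:Day4")
})

test_that("metaprofile averages bins correctly against the per-base oracle", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chrT1",
                            start = c(4000, 6000), end = c(4500, 6500))
  const <- tibble::tibble(chrom = "chrT1", start = 0, end = 10000, value = 2)
  mp <- metaprofile(const, regions, window_bp = 1000, n_bins = 10,
                    anchor = "midpoint")
  expect_true(all(mp$value == 2))

  withr::with_seed(42, {
    bnd <- sort(sample(500:9500, 30))
    segs <- tibble::tibble(chrom = "chrT1", start = c(0, bnd),
                           end = c(bnd, 10000))
    segs$value <- round(runif(nrow(segs), 0, 5), 3)
    mp <- metaprofile(segs, regions, window_bp = 2000, n_bins = 20,
                      anchor = "midpoint")
    anchor_pos <- (regions$start + regions$end) %/% 2
    want <- bf_metaprofile(segs, regions, 2000, 20, anchor_pos)
    got <- matrix(mp$value, nrow = 2, byrow = TRUE)
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
  })

  # out-of-chromosome window bases average in as zero
  edge <- tibble::tibble(region_id = "e", chrom = "chrT1",
                         start = 0, end = 100)
  mp <- metaprofile(const, edge, window_bp = 1000, n_bins = 10,
                    anchor = "midpoint")
  expect_equal(mp$value[1], 0)   # bin entirely before base 0
  expect_true(all(mp$value <= 2))
})

test_that("metaprofile row means are stable under bin refinement", {
  regions <- tibble::tibble(region_id = "r1", chrom = "chrT1",
                            start = 5000, end = 5400,
                            summit_offset = 200L)
  # piecewise-constant track aligned to 100 bp boundaries
  segs <- tibble::tibble(chrom = "chrT1",
                         start = seq(4000, 6900, by = 100),
                         end = seq(4100, 7000, by = 100))
  withr::with_seed(43, segs$value <- sample(0:5, nrow(segs), replace = TRUE))
  coarse <- metaprofile(segs, regions, 2000, 20, anchor = "summit")
  fine <- metaprofile(segs, regions, 2000, 100, anchor = "summit")
  expect_equal(mean(coarse$value), mean(fine$value), tolerance = 1e-12)
})

test_that("metaprofile summary normalizes to a reference profile", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chrT1",
                            start = c(4000, 6000), end = c(4500, 6500))
  t1 <- tibble::tibble(chrom = "chrT1", start = 0, end = 10000, value = 4)
  t0 <- tibble::tibble(chrom = "chrT1", start = 0, end = 10000, value = 2)
  p1 <- metaprofile_summary(metaprofile(t1, regions, 1000, 10, "midpoint"))
  p0 <- metaprofile_summary(metaprofile(t0, regions, 1000, 10, "midpoint"))
  norm <- metaprofile_summary(metaprofile(t1, regions, 1000, 10, "midpoint"),
                              reference = p0)
  expect_true(all(norm$value == 2))
  expect_true(all(p1$value == 4))
})

test_that("RNA signal at regions composes coverage and depth scaling", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chrT1",
                            start = c(100, 500), end = c(200, 600))
  frags <- tibble::tibble(chrom = "chrT1", start = c(150, 160, 550),
                          end = c(250, 170, 560))
  out <- rna_at_regions(regions, frags, size_factor = 2)
  expect_equal(out$rna_signal, c(1, 0.5))
  expect_equal(rna_at_regions(regions, frags[0, ])$rna_signal, c(0, 0))
  expect_equal(rna_at_regions(regions, dplyr::bind_rows(frags, frags))$rna_signal,
               2 * coverage_count(regions, frags))
})
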