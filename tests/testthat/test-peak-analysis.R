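test_that("peak-gene association uses >= 1 bp overlap with half-open edges", {
  # BED-style [100,300) peak and [250,900) gene overlap
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 900),
                                 strand = "+")
  names(gene) <- "g1"
  expect_equal(associate_peaks_genes(peak, gene)[[1]], "g1")
  # [100,200) vs [200,900): touching half-open intervals do not overlap
  peak2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  gene2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 900),
                                  strand = "+")
  names(gene2) <- "g2"
  expect_equal(associate_peaks_genes(peak2, gene2)[[1]], character(0))
  # a promoter extension picks up the upstream peak
  expect_equal(associate_peaks_genes(peak2, gene2,
                                     promoter = 1000)[[1]], "g2")
})

test_that("association equals the all-pairs overlap oracle", {
  set.seed(77)
  peaks <- GenomicRanges::GRanges("chr1",
             IRanges::IRanges(start = sample(1:50000, 100), width = 500))
  genes <- GenomicRanges::GRanges("chr1",
             IRanges::IRanges(start = sample(1:50000, 100), width = 1500),
             strand = sample(c("+", "-"), 100, replace = TRUE))
  names(genes) <- sprintf("g%03d", 1:100)
  got <- associate_peaks_genes(peaks, genes)
  for (i in seq_along(peaks)) {
    brute <- names(genes)[GenomicRanges::start(genes) <=
                            GenomicRanges::end(peaks[i]) &
                          GenomicRanges::end(genes) >=
                            GenomicRanges::start(peaks[i])]
    expect_setequal(got[[i]], brute)
  }
})

test_that("peak grouping conserves peaks and reports integer percentages", {
  set.seed(8)
  q <- GenomicRanges::GRanges("chr1",
         IRanges::IRanges(start = seq(1, 20000, by = 400), width = 200))
  r <- q[seq(1, length(q), by = 3)]
  pg <- group_by_overlap(q, r)
  expect_equal(pg$n_group1 + pg$n_group2, pg$total)
  expect_equal(pg$n_group1, length(r))

  expect_equal(group_by_overlap(q, q)$unique_fraction, 0)
  disjoint <- GenomicRanges::shift(q, 100000)
  expect_equal(group_by_overlap(q, disjoint)$unique_fraction, 1)

  # reported unique-peak arithmetic from tabulated counts
  pg2 <- group_by_overlap(total = 1936, unique = 1848)
  expect_equal(pg2$unique_percent, 95L)
})

test_that("region enrichment is zero at identity and antisymmetric", {
  world <- small_world()
  tags <- small_tags("control")
  regions <- world$genes[1:30]
  expect_true(all(region_enrichment(regions, tags, tags) == 0))

  other <- small_tags("H31_like")
  ab <- region_enrichment(regions, other, tags)
  ba <- region_enrichment(regions, tags, other)
  expect_equal(ab, -ba)

  # a region empty in both libraries sits at log2(eps/eps) = 0
  desert <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5))
  empty_val <- region_enrichment(desert,
                                 tags[GenomicRanges::start(tags) > 1000],
                                 tags[GenomicRanges::start(tags) > 1000])
  expect_equal(empty_val, 0)
  expect_error(region_enrichment(regions, tags, GenomicRanges::GRanges()),
               "empty")
})

test_that("an active mark reads higher over expression-linked peaks", {
  world <- study_world()
  ctl <- study_tags("control")
  # peaks from each archetype; the H3.3-like mark law doubles as an
  # active histone modification over an H3-like uniform denominator
  isl33 <- call_islands(window_grid(study_tags("H33_like"), ctl,
                                    world$genome))
  isl31 <- call_islands(window_grid(study_tags("H31_like"), ctl,
                                    world$genome))
  mark <- study_tags("H33_like")
  e33 <- region_enrichment(isl33[isl33$significant], mark, ctl)
  e31 <- region_enrichment(isl31[isl31$significant], mark, ctl)
  expect_gt(mean(e33), mean(e31))
})

test_that("expression summaries use log10(FPKM + 1) exactly", {
  expr <- data.frame(gene_id = c("a", "b", "c"), FPKM = c(0, 99, 9))
  s <- expression_summary(c("a", "b", "c"), expr)
  expect_equal(unname(s$values), c(0, 2, 1))
  expect_equal(s$median, 1)
  expect_error(expression_summary("zz", expr), "absent")

  # genes under expression-linked peaks express above the genome median
  world <- study_world()
  isl33 <- call_islands(window_grid(study_tags("H33_like"),
                                    study_tags("control"), world$genome))
  assoc <- unique(unlist(associate_peaks_genes(isl33[isl33$significant],
                                               world$genes)))
  s_assoc <- expression_summary(assoc, world$expression)
  s_all <- expression_summary(world$expression$gene_id, world$expression)
  expect_gt(s_assoc$median, s_all$median)
})

test_that("state and housekeeping enrichment recover the planted contrasts", {
  world <- study_world()
  ctl <- study_tags("control")
  st31 <- state_enrichment(study_tags("H31_like"), ctl, world$states)
  expect_gt(st31[["silent"]], st31[["active"]])
  expect_true(all(state_enrichment(ctl, ctl, world$states) == 0))

  hk33 <- housekeeping_enrichment(study_tags("H33_like"), ctl,
                                  world$genes, world$housekeeping)
  hk31 <- housekeeping_enrichment(study_tags("H31_like"), ctl,
                                  world$genes, world$housekeeping)
  expect_length(hk33, length(world$housekeeping))
  expect_gt(median(hk33), 0)
  expect_lt(median(hk31), 0)
  expect_true(all(housekeeping_enrichment(ctl, ctl, world$genes,
                                          world$housekeeping) == 0))
})

test_that("nuclei proportions round to integer percent with exact CIs", {
  p1 <- nuclei_proportion(39, 49)
  expect_equal(p1$percent, 80L)
  p2 <- nuclei_proportion(36, 47)
  expect_equal(p2$percent, 77L)
  expect_equal(nuclei_proportion(0, 10)$percent, 0L)
  expect_true(p1$ci[1] < 100 * p1$fraction && p1$ci[2] > 100 * p1$fraction)
  # Clopper-Pearson bounds agree with the beta-quantile closed form
  expect_equal(p1$ci[1], 100 * qbeta(0.025, 39, 49 - 39 + 1),
               tolerance = 1e-8)
  expect_equal(p1$ci[2], 100 * qbeta(0.975, 39 + 1, 49 - 39),
               tolerance = 1e-8)
  expect_error(nuclei_proportion(5, 0), "total")
  expect_error(nuclei_proportion(11, 10), "positive")
})
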