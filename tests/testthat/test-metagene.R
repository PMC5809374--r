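test_that("quintile assignment splits genes evenly with deterministic ties", {
  expr10 <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       FPKM = c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10))
  q <- assign_quintiles(expr10)
  expect_equal(unname(table(q$quintile)), rep(2L, 5), ignore_attr = TRUE)
  expect_equal(q$quintile[q$FPKM == 1], 1L)
  expect_equal(q$quintile[q$FPKM == 10], 5L)

  # 28,000 genes split into five groups of 5,600
  big <- data.frame(gene_id = sprintf("g%05d", 1:28000),
                    FPKM = rlnorm(28000))
  qb <- assign_quintiles(big)
  expect_equal(unname(table(qb$quintile)), rep(5600L, 5),
               ignore_attr = TRUE)

  # remainder goes to the lowest groups
  q7 <- assign_quintiles(data.frame(gene_id = letters[1:7], FPKM = 1:7))
  expect_equal(unname(table(q7$quintile)), c(2L, 2L, 1L, 1L, 1L),
               ignore_attr = TRUE)

  expect_warning(assign_quintiles(data.frame(gene_id = letters[1:6],
                                             FPKM = rep(0, 6))),
                 "tie-break")
  expect_error(assign_quintiles(data.frame(gene_id = "a", FPKM = 1)),
               "at least 5")
})

test_that("gene binning partitions the body exactly and handles rounding", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 7000),
                              strand = "+")
  bins <- bin_gene(g)
  expect_length(bins, 60)
  body <- bins[21:40]
  expect_true(all(GenomicRanges::width(body) == 100))
  expect_equal(GenomicRanges::start(body)[1], 5001)
  expect_equal(GenomicRanges::end(body)[20], 7000)
  expect_true(all(GenomicRanges::width(bins[1:20]) == 100))
  expect_equal(GenomicRanges::start(bins)[1], 5001 - 2000)
  expect_equal(GenomicRanges::end(bins)[60], 7000 + 2000)

  g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5001 + 2009),
                               strand = "+")
  w2 <- GenomicRanges::width(bin_gene(g2)[21:40])
  expect_true(all(w2 %in% c(100, 101)))
  expect_equal(sum(w2), 2010)

  expect_error(bin_gene(GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(1, 10),
                                               strand = "+")),
               "shorter")
})

test_that("minus-strand bins mirror plus-strand bins within the gene frame", {
  for (len in c(2000, 2010, 1999, 777)) {
    a <- 10001
    b <- a + len - 1
    gp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(a, b), strand = "+")
    gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(a, b), strand = "-")
    bp <- bin_gene(gp)
    bm <- bin_gene(gm)
    # reflecting bin k of the + gene about the gene frame gives bin k of -
    expect_equal(GenomicRanges::start(bm), a + b - GenomicRanges::end(bp))
    expect_equal(GenomicRanges::end(bm), a + b - GenomicRanges::start(bp))
  }
})

test_that("body bin widths always sum to the gene length", {
  world <- small_world()
  bins <- h3varscan:::bin_genes(world$genes, genome = world$genome)
  body <- bins[bins$bin > 20 & bins$bin <= 40]
  sums <- tapply(GenomicRanges::width(body), body$gene_id, sum)
  expect_equal(as.vector(sums[names(world$genes)]),
               as.vector(GenomicRanges::width(world$genes)))
})

test_that("vectorized binning agrees with per-gene binning", {
  world <- small_world()
  genes <- world$genes[1:15]
  all_bins <- h3varscan:::bin_genes(genes, genome = world$genome)
  for (k in seq_along(genes)) {
    one <- bin_gene(genes[k], chrom_length =
                      world$genome[[as.character(
                        GenomicRanges::seqnames(genes[k]))]])
    sel <- all_bins[all_bins$gene_id == names(genes)[k]]
    expect_equal(GenomicRanges::start(sel), GenomicRanges::start(one))
    expect_equal(GenomicRanges::end(sel), GenomicRanges::end(one))
    expect_equal(sel$bin, one$bin)
  }
})

test_that("a sample profiled against itself is exactly zero everywhere", {
  world <- small_world()
  tags <- small_tags("control")
  prof <- metagene_profile(tags, tags, world$genes, world$expression,
                           genome = world$genome)
  expect_true(all(prof$per_gene == 0))
  expect_true(all(prof$group_means == 0))

  # library duplication cancels under RPM scaling (pre-dedup libraries)
  raw <- simulate_reads(world, "H33_like")
  doubled <- c(raw, raw)
  p1 <- metagene_profile(raw, tags, world$genes, world$expression,
                         genome = world$genome)
  p2 <- metagene_profile(doubled, tags, world$genes, world$expression,
                         genome = world$genome)
  expect_equal(p1$per_gene, p2$per_gene)

  # read order does not matter
  p3 <- metagene_profile(rev(raw), tags, world$genes, world$expression,
                         genome = world$genome)
  expect_equal(p1$per_gene, p3$per_gene)
})

test_that("group curves are invariant under mirroring the whole dataset", {
  world <- small_world()
  s <- small_tags("H33_like")
  ctl <- small_tags("control")
  prof <- metagene_profile(s, ctl, world$genes, world$expression,
                           genome = world$genome)
  m_genes <- mirror_granges(world$genes, world$genome)
  prof_m <- metagene_profile(mirror_granges(s, world$genome),
                             mirror_granges(ctl, world$genome),
                             m_genes, world$expression,
                             genome = world$genome)
  expect_equal(prof_m$per_gene, prof$per_gene)
  expect_equal(prof_m$group_means, prof$group_means)
})

test_that("an empty control is rejected", {
  world <- small_world()
  expect_error(metagene_profile(small_tags("control"),
                                GenomicRanges::GRanges(),
                                world$genes, world$expression),
               "control")
})
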