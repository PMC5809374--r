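test_that("the generator is deterministic and emits exact read counts", {
  cfg <- synthetic_config(genome_length = 2e5, n_genes = 30,
                          n_reads = 5000, seed = 3)
  w1 <- simulate_genome(cfg)
  w2 <- simulate_genome(cfg)
  expect_identical(w1$expression, w2$expression)
  expect_equal(GenomicRanges::start(w1$genes), GenomicRanges::start(w2$genes))

  r1 <- simulate_reads(w1, "H31_like")
  r2 <- simulate_reads(w2, "H31_like")
  expect_length(r1, 5000)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # byte-identical BED output under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(r1, p1)
  write_reads_bed(simulate_reads(simulate_genome(cfg), "H31_like"), p2)
  expect_identical(readLines(p1), readLines(p2))

  # per-sample RNG streams: archetypes are reproducible in any order
  a <- simulate_reads(w1, "control")
  invisible(simulate_reads(w1, "H33_like"))
  b <- simulate_reads(w1, "control")
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("genes are non-overlapping and the het fraction sets silent genes", {
  cfg <- synthetic_config(genome_length = 1e6, n_genes = 200,
                          het_fraction = 0.3, n_reads = 1000, seed = 9)
  world <- simulate_genome(cfg)
  expect_length(world$genes, 200)
  expect_true(IRanges::isDisjoint(world$genes, ignore.strand = TRUE))
  frac_silent <- mean(world$expression$FPKM == 0)
  expect_gt(frac_silent, 0.2)   # ~30% of genes fall in the het block
  expect_lt(frac_silent, 0.4)
  # housekeeping list: expressed, euchromatic, top of the distribution
  hk_fpkm <- world$expression$FPKM[match(world$housekeeping,
                                         world$expression$gene_id)]
  expect_true(all(hk_fpkm >= sort(world$expression$FPKM,
                                  decreasing = TRUE)[length(hk_fpkm)]))
  expect_error(simulate_genome(synthetic_config(genome_length = 1e4,
                                                n_genes = 50, seed = 1)),
               "packing")
})

test_that("control reads are uniform: window counts match Poisson", {
  world <- small_world()
  reads <- simulate_reads(world, "control", n_reads = 10000)
  cnt <- count_windows(reads, world$genome)[[1]]
  lambda <- 10000 * 200 / sum(world$genome)
  # categories 0..kpool-1 plus a pooled upper tail
  kpool <- qpois(0.995, lambda)
  obs <- tabulate(pmin(cnt, kpool) + 1, nbins = kpool + 1)
  probs <- c(dpois(0:(kpool - 1), lambda),
             ppois(kpool - 1, lambda, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("H3.3-like positions are uniform within genes when bias is zero", {
  cfg <- synthetic_config(genome_length = 4e5, n_genes = 80, n_reads = 3e4,
                          three_prime_bias = 0, background_fraction = 0,
                          seed = 7)
  world <- simulate_genome(cfg)
  reads <- simulate_reads(world, "H33_like")
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
               IRanges::IRanges(h3varscan:::tag_midpoints(reads, 200) + 1,
                                width = 1))
  hits <- GenomicRanges::findOverlaps(centers, world$genes,
                                      ignore.strand = TRUE,
                                      select = "first")
  ok <- !is.na(hits)
  g <- world$genes[hits[ok]]
  u <- (GenomicRanges::start(centers)[ok] - GenomicRanges::start(g) +
          runif(sum(ok))) / GenomicRanges::width(g)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("H3.3-like mass tilts 3' and follows log expression", {
  world <- small_world()
  reads <- small_tags("H33_like")
  centers <- h3varscan:::tag_midpoints(reads, 200) + 1
  cgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                IRanges::IRanges(centers, width = 1))
  per_gene <- GenomicRanges::countOverlaps(world$genes, cgr,
                                           ignore.strand = TRUE)
  lw <- log(world$expression$FPKM + 1)
  expect_gt(cor(per_gene, lw, method = "spearman"), 0.8)

  # 3' tilt: transcription-oriented relative position has mean > 1/2
  hits <- GenomicRanges::findOverlaps(cgr, world$genes,
                                      ignore.strand = TRUE, select = "first")
  ok <- !is.na(hits)
  g <- world$genes[hits[ok]]
  u <- (GenomicRanges::start(cgr)[ok] - GenomicRanges::start(g)) /
    GenomicRanges::width(g)
  minus <- as.character(GenomicRanges::strand(g)) == "-"
  u[minus] <- 1 - u[minus]
  expect_gt(mean(u), 0.55)
})

test_that("H3.1-like heterochromatin coverage matches the configured fold", {
  world <- study_world()
  reads <- simulate_reads(world, "H31_like")   # pre-dedup generator law
  centers <- h3varscan:::tag_midpoints(reads, 200) + 1
  cgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                IRanges::IRanges(centers, width = 1))
  het <- world$states[world$states$state == "silent"]
  genic <- GenomicRanges::reduce(GenomicRanges::granges(world$genes),
                                 ignore.strand = TRUE)
  genome_gr <- GenomicRanges::GRanges(names(world$genome),
                                      IRanges::IRanges(1, world$genome))
  bg <- GenomicRanges::setdiff(GenomicRanges::setdiff(genome_gr, het,
                                                      ignore.strand = TRUE),
                               genic, ignore.strand = TRUE)
  dens <- function(regions)
    sum(IRanges::overlapsAny(cgr, regions, ignore.strand = TRUE)) /
      sum(GenomicRanges::width(regions))
  ratio <- dens(het) / dens(bg)
  fold <- world$config$enrichment_fold
  expect_lt(abs(ratio - fold) / fold, 0.1)
})

test_that("an expressionless genome cannot source an H3.3-like sample", {
  cfg <- synthetic_config(genome_length = 1e5, n_genes = 10,
                          het_fraction = 0.9, n_reads = 100, seed = 2)
  world <- simulate_genome(cfg)
  world$expression$FPKM[] <- 0
  expect_error(simulate_reads(world, "H33_like"), "expressed")
})

test_that("mark scores correlate with expression and het membership", {
  world <- small_world()
  marks <- simulate_mark_scores(world)
  lw <- log(world$expression$FPKM + 1)
  het <- world$expression$FPKM == 0
  expect_gt(cor(marks$active, lw), 0.5)
  expect_gt(mean(marks$silent[het]), mean(marks$silent[!het]))
})
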