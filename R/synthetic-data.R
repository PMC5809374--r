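## Miniature-genome simulator. Plants the deposition contrasts the real
## analysis is designed to detect: an H3.1-like sample concentrated in
## heterochromatin and silent genes (declining with expression), an
## H3.3-like sample whose per-gene read mass tracks expression with a 3'
## positional bias, a 50/50 mixed sample, and a uniform mock control.
## Reads are emitted as 200 bp fragment centers sequenced as 50 bp
## single-end tags on a random strand, so that fragment-midpoint shifting
## downstream recovers the planted signal position exactly.

ARCHETYPES <- c("control", "H31_like", "H33_like", "mixed")

#' Configuration for the synthetic genome and read simulator
#'
#' Defaults describe the desk-scale study system: one 2 Mb chromosome with
#' a 200 kb pericentromeric heterochromatin block, 400 non-overlapping
#' genes, log-normal FPKM for euchromatic genes, and 2e5 reads per sample.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chroms Number of chromosomes (equal lengths).
#' @param n_genes Number of genes to place.
#' @param het_fraction Fraction of each chromosome covered by a single
#'   centered heterochromatin block (ignored when `het_blocks` given).
#' @param het_blocks Optional `GRanges` of heterochromatin blocks.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal FPKM parameters for genes
#'   outside heterochromatin.
#' @param gene_length_range Range gene lengths are drawn from (bp).
#' @param read_length Read length in bp (single-end tags).
#' @param fragment_size Nominal ChIP fragment size in bp; reads are the 5'
#'   `read_length` bp of a fragment centered on the sampled signal point.
#' @param n_reads Reads per sample.
#' @param enrichment_fold Heterochromatin/silent-gene enrichment of the
#'   H3.1-like archetype over background (> 1).
#' @param three_prime_bias Within-gene 3' tilt of the H3.3-like archetype,
#'   in [0, 1]; 0 means uniform along the gene body.
#' @param background_fraction Fraction of H3.3-like reads drawn from the
#'   genome-wide uniform background (nonspecific pulldown).
#' @param seed Base seed; per-sample streams are derived from it and the
#'   sample name, so archetypes can be generated in any order.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 2e6, n_chroms = 1,
                             n_genes = 400, het_fraction = 0.1,
                             het_blocks = NULL,
                             fpkm_meanlog = 1, fpkm_sdlog = 1.5,
                             gene_length_range = c(1000, 3000),
                             read_length = 50, fragment_size = 200,
                             n_reads = 2e5, enrichment_fold = 8,
                             three_prime_bias = 0.6,
                             background_fraction = 0.3, seed = 1) {
  cfg <- list(genome_length = as.numeric(genome_length),
              n_chroms = as.integer(n_chroms),
              n_genes = as.integer(n_genes), het_fraction = het_fraction,
              het_blocks = het_blocks, fpkm_meanlog = fpkm_meanlog,
              fpkm_sdlog = fpkm_sdlog, gene_length_range = gene_length_range,
              read_length = as.integer(read_length),
              fragment_size = as.integer(fragment_size),
              n_reads = as.integer(n_reads),
              enrichment_fold = enrichment_fold,
              three_prime_bias = three_prime_bias,
              background_fraction = background_fraction,
              seed = as.integer(seed))
  stopifnot_scalar_number(cfg$genome_length, "genome_length", positive = TRUE)
  if (cfg$n_chroms < 1) stop("n_chroms must be >= 1", call. = FALSE)
  if (cfg$enrichment_fold <= 1)
    stop("enrichment_fold must be > 1", call. = FALSE)
  if (cfg$three_prime_bias < 0 || cfg$three_prime_bias > 1)
    stop("three_prime_bias must lie in [0, 1]", call. = FALSE)
  if (cfg$het_fraction < 0 || cfg$het_fraction >= 1)
    stop("het_fraction must lie in [0, 1)", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

chrom_lengths <- function(config) {
  len <- floor(config$genome_length / config$n_chroms)
  setNames(rep(len, config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

default_het_blocks <- function(config) {
  lens <- chrom_lengths(config)
  w <- floor(lens * config$het_fraction)
  start <- floor((lens - w) / 2) + 1
  keep <- w > 0
  GenomicRanges::GRanges(names(lens)[keep],
                         IRanges::IRanges(start = start[keep],
                                          width = w[keep]))
}

#' Simulate a miniature annotated genome
#'
#' Places non-overlapping genes with random strand, assigns log-normal
#' FPKM to genes outside the heterochromatin blocks and FPKM 0 to genes
#' inside them, derives a binary active/silent chromatin-state
#' segmentation (silent = heterochromatin), and picks the top-expressed
#' euchromatic genes as the housekeeping set. Deterministic under the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @param n_housekeeping Size of the housekeeping gene list (default 100).
#' @return List with `genes` (`GRanges` named by gene id), `expression`
#'   (data.frame gene_id/FPKM), `states` (`GRanges` with a `state`
#'   column), `housekeeping` (character vector), `genome` (named vector of
#'   chromosome lengths) and `config`.
#' @export
simulate_genome <- function(config, n_housekeeping = 100) {
  lens <- chrom_lengths(config)
  het <- config$het_blocks %||% default_het_blocks(config)
  if (length(het) &&
      any(!as.character(GenomicRanges::seqnames(het)) %in% names(lens)))
    stop("het_blocks reference unknown chromosomes", call. = FALSE)
  with_seed(config$seed, {
    n_per <- table(factor(sample(names(lens), config$n_genes, replace = TRUE),
                          levels = names(lens)))
    glens <- round(runif(config$n_genes, config$gene_length_range[1],
                         config$gene_length_range[2]))
    gene_chrom <- rep(names(lens), n_per)
    starts <- integer(config$n_genes)
    idx0 <- 0L
    for (chr in names(lens)) {
      k <- n_per[[chr]]
      if (k == 0L) next
      li <- glens[idx0 + seq_len(k)]
      free <- lens[[chr]] - sum(li)
      if (free < k + 1)
        stop("infeasible packing: genes do not fit on ", chr, call. = FALSE)
      # random gaps before each gene and after the last one
      gaps <- floor(diff(c(0, sort(runif(k)), 1)) * free)
      starts[idx0 + seq_len(k)] <- cumsum(gaps[seq_len(k)]) +
        cumsum(c(0, li[-k])) + 1
      idx0 <- idx0 + k
    }
    genes <- GenomicRanges::GRanges(gene_chrom,
                                    IRanges::IRanges(start = starts,
                                                     width = glens),
                                    strand = sample(c("+", "-"),
                                                    config$n_genes,
                                                    replace = TRUE))
    ids <- sprintf("gene%04d", seq_len(config$n_genes))
    names(genes) <- ids
    genes$gene_id <- ids
    in_het <- IRanges::overlapsAny(genes, het, ignore.strand = TRUE)
    fpkm <- rlnorm(config$n_genes, config$fpkm_meanlog, config$fpkm_sdlog)
    fpkm[in_het] <- 0
    expression <- data.frame(gene_id = ids, FPKM = fpkm)
    # binarized gene-scale state track, as published state maps are used
    # here: silent = heterochromatin blocks, active = euchromatic gene
    # bodies; featureless intergenic space carries no state label
    silent <- GenomicRanges::granges(het)
    active <- GenomicRanges::granges(genes[!in_het])
    GenomicRanges::strand(active) <- "*"
    silent$state <- rep("silent", length(silent))
    active$state <- rep("active", length(active))
    states <- GenomicRanges::sort(c(silent, active), ignore.strand = TRUE)
    eu <- which(!in_het)
    hk <- ids[eu[order(fpkm[eu], decreasing = TRUE)]]
    hk <- head(hk, n_housekeeping)
    list(genes = genes, expression = expression, states = states,
         housekeeping = hk, genome = lens, config = config)
  })
}

## Inverse-CDF sampler for the linearly tilted unit density
## f(u) = 1 - b + 2bu on [0, 1]; b = 0 is uniform, b = 1 puts all mass
## proportional to u (strong 3' bias).
sample_tilted_unit <- function(n, bias) {
  x <- runif(n)
  if (bias == 0) return(x)
  ((bias - 1) + sqrt((1 - bias)^2 + 4 * bias * x)) / (2 * bias)
}

## Piecewise-constant fragment-center density for the H3.1-like law:
## baseline 1, heterochromatin blocks x fold, gene bodies
## x (1 + (fold - 1) * (1 - r)^2) where r is the gene's expression
## percentile rank -- silent genes get the full fold, the most expressed
## genes essentially none, mimicking the negative correlation between
## canonical H3.1 occupancy and transcription.
h31_segments <- function(world) {
  cfg <- world$config
  fold <- cfg$enrichment_fold
  het <- cfg$het_blocks %||% default_het_blocks(cfg)
  lens <- world$genome
  fpkm <- setNames(world$expression$FPKM, world$expression$gene_id)
  lw <- log(fpkm + 1)
  rel <- (rank(lw, ties.method = "min") - 1) / max(length(lw) - 1, 1)
  names(rel) <- names(lw)
  segs <- list()
  for (chr in names(lens)) {
    L <- lens[[chr]]
    sel_h <- het[as.character(GenomicRanges::seqnames(het)) == chr]
    sel_g <- world$genes[
      as.character(GenomicRanges::seqnames(world$genes)) == chr]
    brk <- sort(unique(c(1, L + 1,
                         GenomicRanges::start(sel_h),
                         GenomicRanges::end(sel_h) + 1,
                         GenomicRanges::start(sel_g),
                         GenomicRanges::end(sel_g) + 1)))
    brk <- brk[brk >= 1 & brk <= L + 1]
    gr <- GenomicRanges::GRanges(chr,
            IRanges::IRanges(start = brk[-length(brk)],
                             end = brk[-1] - 1))
    dens <- rep(1, length(gr))
    hit_g <- GenomicRanges::findOverlaps(gr, sel_g, ignore.strand = TRUE,
                                         select = "first")
    in_gene <- !is.na(hit_g)
    gmult <- 1 + (fold - 1) * (1 - rel[names(sel_g)[hit_g[in_gene]]])^2
    dens[in_gene] <- gmult
    dens[IRanges::overlapsAny(gr, sel_h, ignore.strand = TRUE)] <- fold
    gr$density <- dens
    segs[[chr]] <- gr
  }
  do.call(c, unname(segs))
}

## Draw n fragment centers (chrom, 1-based pos) from weighted segments.
sample_segment_centers <- function(segs, n) {
  w <- GenomicRanges::width(segs) * segs$density
  idx <- sample.int(length(segs), n, replace = TRUE, prob = w)
  pos <- GenomicRanges::start(segs)[idx] +
    floor(runif(n) * GenomicRanges::width(segs)[idx])
  data.frame(chrom = as.character(GenomicRanges::seqnames(segs))[idx],
             pos = pos)
}

#' Ground-truth planted-enrichment regions of an archetype
#'
#' Returns the genomic regions where the generator's fragment-center
#' density is at least `min_fold` times the baseline -- the reference
#' against which planted-signal recovery of the island caller is
#' measured. For `H31_like` this is the heterochromatin blocks plus the
#' gene bodies whose expression-graded multiplier reaches `min_fold`;
#' for `H33_like` / `mixed` the expressed gene bodies are included.
#'
#' @param world Output of [simulate_genome()].
#' @param archetype Archetype whose planted law to report.
#' @param min_fold Minimum planted fold-over-baseline to count as
#'   planted signal (default 2).
#' @return Reduced `GRanges` of planted regions.
#' @export
planted_regions <- function(world, archetype = "H31_like", min_fold = 2) {
  if (archetype == "control")
    return(GenomicRanges::GRanges())
  het <- world$config$het_blocks %||% default_het_blocks(world$config)
  out <- GenomicRanges::GRanges()
  if (archetype %in% c("H31_like", "mixed")) {
    segs <- h31_segments(world)
    out <- c(out, GenomicRanges::granges(segs[segs$density >= min_fold]))
  }
  if (archetype %in% c("H33_like", "mixed")) {
    expressed <- world$genes[world$expression$FPKM > 0]
    out <- c(out, GenomicRanges::granges(expressed))
  }
  GenomicRanges::reduce(out, ignore.strand = TRUE)
}

sample_centers <- function(world, archetype, n) {
  cfg <- world$config
  lens <- world$genome
  uniform_centers <- function(m) {
    chr <- sample(names(lens), m, replace = TRUE, prob = lens)
    data.frame(chrom = chr, pos = 1 + floor(runif(m) * lens[chr]))
  }
  if (archetype == "control") return(uniform_centers(n))
  if (archetype == "H31_like")
    return(sample_segment_centers(h31_segments(world), n))
  if (archetype == "H33_like") {
    lw <- log(world$expression$FPKM + 1)
    if (all(lw == 0))
      stop("H33_like archetype needs expressed genes (all FPKM are 0)",
           call. = FALSE)
    n_bg <- rbinom(1, n, cfg$background_fraction)
    bg <- uniform_centers(n_bg)
    gidx <- sample.int(length(lw), n - n_bg, replace = TRUE, prob = lw)
    g <- world$genes[gidx]
    u <- sample_tilted_unit(n - n_bg, cfg$three_prime_bias)
    plus <- as.character(GenomicRanges::strand(g)) == "+"
    off <- floor(u * GenomicRanges::width(g))
    pos <- ifelse(plus, GenomicRanges::start(g) + off,
                  GenomicRanges::end(g) - off)
    rbind(bg, data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                         pos = pos))
  } else if (archetype == "mixed") {
    n1 <- rbinom(1, n, 0.5)
    rbind(sample_centers(world, "H31_like", n1),
          sample_centers(world, "H33_like", n - n1))
  } else stop("unknown archetype: ", archetype, call. = FALSE)
}

#' Simulate a ChIP-seq read sample with a planted deposition archetype
#'
#' Draws `n_reads` fragment centers from the archetype's spatial law
#' (see [synthetic_config()]), then emits each as a `read_length` bp
#' single-end tag: the 5' end of a `fragment_size` fragment centered on
#' the sampled point, on a fair-coin strand. Shifting a tag by half the
#' fragment size in read direction therefore recovers the center exactly.
#'
#' @param world Output of [simulate_genome()].
#' @param archetype One of `"control"` (uniform mock), `"H31_like"`
#'   (heterochromatin/silent enriched), `"H33_like"`
#'   (expression-correlated, 3'-biased), `"mixed"` (50/50 of the two).
#' @param n_reads Number of reads (default from the config).
#' @param name Sample name used to derive the RNG stream (defaults to the
#'   archetype); pass a different name to draw an independent replicate
#'   of the same archetype.
#' @return `GRanges` of exactly `n_reads` stranded read tags.
#' @export
simulate_reads <- function(world, archetype = ARCHETYPES,
                           n_reads = NULL, name = NULL) {
  archetype <- match.arg(archetype)
  cfg <- world$config
  n <- as.integer(n_reads %||% cfg$n_reads)
  half <- cfg$fragment_size %/% 2L
  lens <- world$genome
  with_seed(derive_seed(cfg$seed, name %||% archetype), {
    ctr <- sample_centers(world, archetype, n)
    pos <- pmin(pmax(ctr$pos, half + 1), lens[ctr$chrom] - half)
    plus <- runif(n) < 0.5
    start <- ifelse(plus, pos - half,
                    pos + half - cfg$read_length + 1)
    gr <- GenomicRanges::GRanges(ctr$chrom,
            IRanges::IRanges(start = start, width = cfg$read_length),
            strand = ifelse(plus, "+", "-"),
            name = sprintf("%s_read%06d", archetype, seq_len(n)))
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    gr
  })
}

#' Simulate per-gene H3-normalized histone-mark scores
#'
#' Emits log2(mark/H3)-style per-gene scores for one active-type mark
#' (tracking expression, like H3K36me2/H3K9ac) and one silent-type mark
#' (tracking heterochromatin membership, like H3K9me2/H3K27me1).
#'
#' @param world Output of [simulate_genome()].
#' @param noise_sd Gaussian noise added to each score.
#' @return data.frame with `gene_id`, `active`, `silent` columns.
#' @export
simulate_mark_scores <- function(world, noise_sd = 0.3) {
  cfg <- world$config
  lw <- log(world$expression$FPKM + 1)
  rel <- if (max(lw) > 0) lw / max(lw) else lw
  het <- world$expression$FPKM == 0
  with_seed(derive_seed(cfg$seed, "marks"), {
    n <- nrow(world$expression)
    data.frame(gene_id = world$expression$gene_id,
               active = -1 + 3 * rel + rnorm(n, 0, noise_sd),
               silent = ifelse(het, 1.5, -0.5) + rnorm(n, 0, noise_sd))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the annotation (`genes.gff3`), expression table
#' (`expression.tsv`), chromatin states (`states.bed`), housekeeping list
#' (`housekeeping.txt`), chromosome sizes (`genome.sizes.tsv`) and one
#' BED6 read file per requested archetype. Byte-identical across reruns
#' with the same config.
#'
#' @param world Output of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param archetypes Archetypes to emit read sets for.
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(world, dir,
                                    archetypes = ARCHETYPES) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genes = write_genes_gff3(world$genes, file.path(dir, "genes.gff3")),
    expression = write_expression(world$expression,
                                  file.path(dir, "expression.tsv")),
    genome = file.path(dir, "genome.sizes.tsv"),
    housekeeping = file.path(dir, "housekeeping.txt"))
  write.table(data.frame(names(world$genome), world$genome),
              paths$genome, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(world$housekeeping, paths$housekeeping)
  st <- world$states
  states_df <- data.frame(as.character(GenomicRanges::seqnames(st)),
                          GenomicRanges::start(st) - 1L,
                          GenomicRanges::end(st), st$state)
  paths$states <- file.path(dir, "states.bed")
  write.table(states_df, paths$states, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (a in archetypes) {
    p <- file.path(dir, paste0(a, ".bed"))
    write_reads_bed(simulate_reads(world, a), p)
    paths[[a]] <- p
  }
  invisible(paths)
}
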