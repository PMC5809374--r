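# Shared fixtures, built once per run and memoized. The "study" world is
# the generator's default desk-scale configuration (2 Mb, 400 genes,
# 200 kb heterochromatin block, 2e5 reads/sample); the "small" world is a
# cheaper genome for unit-scale checks.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

study_world <- function() {
  memo("study_world", simulate_genome(synthetic_config(seed = 42)))
}

# deduplicated tag sets for the study world; "control_rep2" is an
# independent uniform replicate for control-vs-control baselines
study_tags <- function(name) {
  memo(paste0("tags_", name), {
    w <- study_world()
    arch <- if (name == "control_rep2") "control" else name
    collapse_duplicates(simulate_reads(w, arch, name = name))
  })
}

small_world <- function() {
  memo("small_world",
       simulate_genome(synthetic_config(genome_length = 4e5, n_genes = 80,
                                        n_reads = 3e4, seed = 7)))
}

small_tags <- function(name) {
  memo(paste0("small_tags_", name), {
    w <- small_world()
    arch <- if (name == "control_rep2") "control" else name
    collapse_duplicates(simulate_reads(w, arch, name = name))
  })
}

# mirror a stranded GRanges dataset through the genome (x -> L - x + 1),
# flipping strands; used for the strand-symmetry invariant
mirror_granges <- function(gr, genome) {
  L <- genome[as.character(GenomicRanges::seqnames(gr))]
  new_start <- L - GenomicRanges::end(gr) + 1
  new_end <- L - GenomicRanges::start(gr) + 1
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(new_start, new_end))
  st <- as.character(GenomicRanges::strand(gr))
  GenomicRanges::strand(out) <- ifelse(st == "+", "-",
                                       ifelse(st == "-", "+", "*"))
  names(out) <- names(gr)
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

# Poisson upper tail by direct series summation, independent of ppois
direct_poisson_tail <- function(k, lambda, terms = 400) {
  if (k == 0) return(1)
  i <- seq(k, k + terms)
  sum(exp(i * log(lambda) - lambda - lgamma(i + 1)))
}

# independent island enumerator: explicit scan over windows, direct-series
# eligibility, closed-form -log pmf scores
enumerate_islands_oracle <- function(cnt_s, lambda_s, eligibility_p, gap_w) {
  elig <- vapply(cnt_s, function(k) direct_poisson_tail(k, lambda_s),
                 0) < eligibility_p
  spans <- list()
  cur <- NULL
  gap <- 0
  for (i in seq_along(elig)) {
    if (elig[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
      gap <- 0
    } else if (!is.null(cur)) {
      gap <- gap + 1
      if (gap > gap_w) {
        spans[[length(spans) + 1]] <- cur
        cur <- NULL
        gap <- 0
      }
    }
  }
  if (!is.null(cur)) spans[[length(spans) + 1]] <- cur
  lapply(spans, function(sp) {
    win <- sp[1]:sp[2]
    e <- win[elig[win]]
    list(first = sp[1], last = sp[2],
         score = sum(-(cnt_s[e] * log(lambda_s) - lambda_s -
                         lgamma(cnt_s[e] + 1))))
  })
}

bed_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
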