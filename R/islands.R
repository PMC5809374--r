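## Broad-domain enrichment caller against a mock control, in the SICER
## parameterization (window size 200, fragment size 200, gap size 200):
## tags are shifted by half a fragment to their midpoint, counted in
## non-overlapping windows, windows are marked eligible by a Poisson tail
## test against the genome background, eligible runs separated by at most
## gap/window ineligible windows are merged into islands, and each island
## is tested against the library-size-scaled control count (floored at
## the control background) with a Poisson upper tail.

#' Poisson upper-tail probability P(X >= k)
#'
#' Thin, argument-checked wrapper over the regularized-gamma tail
#' ([stats::ppois]); vectorized and monotone decreasing in `k`.
#'
#' @param k Observed count(s), >= 0.
#' @param lambda Poisson rate(s), > 0.
#' @return P(X >= k), in (0, 1].
#' @examples
#' poisson_sf(0, 5)        # 1
#' poisson_sf(2, 1)        # 1 - 2/e
#' @export
poisson_sf <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  ppois(k - 1, lambda, lower.tail = FALSE)
}

## Fragment-midpoint position of each tag, 0-based: reads are shifted by
## fragment_size/2 in read direction (start + f/2 on +, end - 1 - f/2 on
## -), then clipped into [0, L).
tag_midpoints <- function(tags, fragment_size) {
  half <- fragment_size %/% 2L
  plus <- as.character(GenomicRanges::strand(tags)) == "+"
  ifelse(plus, GenomicRanges::start(tags) - 1L + half,
         GenomicRanges::end(tags) - 1L - half)
}

#' Count fragment midpoints in fixed windows
#'
#' @param tags `GRanges` of (deduplicated) read tags.
#' @param genome Named vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 200).
#' @param fragment_size Nominal fragment size; tags are shifted by half of
#'   it toward their fragment midpoint before counting (default 200).
#' @return Named list of per-chromosome integer count vectors (one entry
#'   per window), with attribute `total` = number of assigned tags.
#' @export
count_windows <- function(tags, genome, window_size = 200,
                          fragment_size = 200) {
  if (window_size <= 0) stop("window_size must be > 0", call. = FALSE)
  pos <- tag_midpoints(tags, fragment_size)
  chrom <- as.character(GenomicRanges::seqnames(tags))
  keep <- chrom %in% names(genome)
  pos <- pmin(pmax(pos[keep], 0), genome[chrom[keep]] - 1)
  chrom <- chrom[keep]
  counts <- lapply(names(genome), function(chr) {
    nw <- ceiling(genome[[chr]] / window_size)
    tabulate(pos[chrom == chr] %/% window_size + 1, nbins = nw)
  })
  names(counts) <- names(genome)
  attr(counts, "total") <- sum(keep)
  counts
}

#' Build the sample/control window grid for island calling
#'
#' Either from read tags (`sample`, `control` as `GRanges`) or directly
#' from per-chromosome count vectors (lists of integer vectors), for
#' testing and for grids constructed elsewhere.
#'
#' @param sample,control Read tags (`GRanges`) or named lists of
#'   per-chromosome window counts.
#' @param genome Named vector of chromosome lengths. When counts are given
#'   and `genome` is omitted, lengths are taken as `n_windows *
#'   window_size`.
#' @param window_size,fragment_size See [count_windows()].
#' @return Object of class `window_grid`: window size, genome, per-chrom
#'   sample/control counts, library totals and background rates
#'   `lambda_s`, `lambda_c` (expected tags per window genome-wide).
#' @export
window_grid <- function(sample, control, genome = NULL,
                        window_size = 200, fragment_size = 200) {
  as_counts <- function(x, label) {
    if (is(x, "GRanges")) {
      if (is.null(genome))
        stop("genome lengths are required when counting from tags",
             call. = FALSE)
      count_windows(x, genome, window_size, fragment_size)
    } else if (is.list(x)) {
      x <- lapply(x, as.integer)
      attr(x, "total") <- sum(unlist(x))
      x
    } else if (is.numeric(x)) {
      x <- list(chr1 = as.integer(x))
      attr(x, "total") <- sum(unlist(x))
      x
    } else stop("cannot interpret ", label, " input", call. = FALSE)
  }
  s <- as_counts(sample, "sample")
  ctl <- as_counts(control, "control")
  if (!identical(lengths(s), lengths(ctl)))
    stop("sample and control grids disagree in window counts", call. = FALSE)
  if (is.null(genome))
    genome <- setNames(lengths(s) * window_size, names(s))
  L <- sum(genome)
  ns <- attr(s, "total")
  nc <- attr(ctl, "total")
  structure(list(window_size = window_size, genome = genome,
                 sample = s, control = ctl,
                 n_sample = ns, n_control = nc,
                 lambda_s = ns * window_size / L,
                 lambda_c = nc * window_size / L),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid:", sum(lengths(x$sample)), "windows of", x$window_size,
      "bp over", length(x$genome), "chromosome(s)\n")
  cat(sprintf("  sample %d tags (lambda %.3f), control %d tags (lambda %.3f)\n",
              x$n_sample, x$lambda_s, x$n_control, x$lambda_c))
  invisible(x)
}

#' Call enrichment islands from a window grid
#'
#' A window is eligible when its Poisson tail probability against the
#' sample background `lambda_s` is below `eligibility_p`. Islands are
#' maximal runs of eligible windows in which consecutive eligible windows
#' are separated by at most `gap / window_size` ineligible windows (the
#' ineligible interior is included in the span but contributes nothing to
#' the score). The island score is the sum of -ln Poisson probabilities
#' of its eligible windows; significance is a Poisson upper-tail test of
#' the island's total sample count against the library-size-scaled
#' control count, floored at the control background rate.
#'
#' @param grid A [window_grid()].
#' @param gap Maximum ineligible gap bridged within an island, in bp
#'   (default 200, i.e. one window).
#' @param eligibility_p Per-window Poisson tail threshold (default 0.2).
#' @param p0 Island significance threshold (default 1e-3).
#' @param fdr Apply a Benjamini-Hochberg layer and call significance on
#'   adjusted p-values? Default `FALSE` (raw p, as reported).
#' @return `GRanges` of islands sorted by coordinate, with metadata
#'   columns `score`, `sample_count`, `control_count`, `p_value`
#'   (`p_adjust` when `fdr`) and `significant`.
#' @export
call_islands <- function(grid, gap = 200, eligibility_p = 0.2,
                         p0 = 1e-3, fdr = FALSE) {
  stopifnot(inherits(grid, "window_grid"))
  if (grid$n_control == 0)
    stop("control library is empty; normalization undefined", call. = FALSE)
  if (grid$n_sample == 0)
    stop("sample library is empty", call. = FALSE)
  w <- grid$window_size
  gap_w <- floor(gap / w)
  scale <- grid$n_sample / grid$n_control
  res <- lapply(names(grid$sample), function(chr) {
    cnt_s <- grid$sample[[chr]]
    cnt_c <- grid$control[[chr]]
    elig <- poisson_sf(cnt_s, grid$lambda_s) < eligibility_p
    idx <- which(elig)
    if (length(idx) == 0L) return(NULL)
    grp <- cumsum(c(1L, diff(idx) > gap_w + 1L))
    i1 <- vapply(split(idx, grp), min, 0L)
    i2 <- vapply(split(idx, grp), max, 0L)
    cs_s <- c(0, cumsum(cnt_s))
    cs_c <- c(0, cumsum(cnt_c))
    nll <- ifelse(elig, -dpois(cnt_s, grid$lambda_s, log = TRUE), 0)
    cs_nll <- c(0, cumsum(nll))
    n_win <- i2 - i1 + 1L
    sample_count <- cs_s[i2 + 1L] - cs_s[i1]
    control_count <- cs_c[i2 + 1L] - cs_c[i1]
    expected <- pmax(control_count, grid$lambda_c * n_win) * scale
    gr <- GenomicRanges::GRanges(chr,
            IRanges::IRanges(start = (i1 - 1L) * w + 1L,
                             end = pmin(i2 * w, grid$genome[[chr]])))
    gr$score <- cs_nll[i2 + 1L] - cs_nll[i1]
    gr$sample_count <- as.integer(sample_count)
    gr$control_count <- as.integer(control_count)
    # floor at the smallest subnormal so extreme islands keep p in (0, 1]
    gr$p_value <- pmax(poisson_sf(sample_count, expected),
                       .Machine$double.xmin * .Machine$double.eps)
    gr
  })
  islands <- do.call(c, c(Filter(Negate(is.null), res),
                          list(GenomicRanges::GRanges(
                            score = numeric(0), sample_count = integer(0),
                            control_count = integer(0),
                            p_value = numeric(0)))))
  GenomeInfoDb::seqlevels(islands) <-
    intersect(names(grid$genome), GenomeInfoDb::seqlevels(islands))
  islands <- GenomicRanges::sort(islands, ignore.strand = TRUE)
  if (fdr) {
    islands$p_adjust <- p.adjust(islands$p_value, "BH")
    islands$significant <- islands$p_adjust < p0
  } else {
    islands$significant <- islands$p_value < p0
  }
  islands
}

#' Write called islands as a BED6 peak file
#'
#' @param islands Output of [call_islands()].
#' @param path Output path.
#' @param all Write all islands rather than significant ones only?
#' @return `path`, invisibly.
#' @export
write_peaks <- function(islands, path, all = FALSE) {
  if (!all) islands <- islands[islands$significant]
  out <- GenomicRanges::granges(islands)
  out$name <- sprintf("island_%d", seq_along(out))
  out$score <- round(islands$score, 3)
  write_reads_bed(out, path)
}

#' Read a BED peak file back as plain ranges
#'
#' @param path BED file with >= 3 columns.
#' @return `GRanges` of peaks.
#' @export
read_peaks_bed <- function(path) {
  tab <- read_text_table(path, 3L, "BED")
  if (is.null(tab$fields)) return(GenomicRanges::GRanges())
  f <- tab$fields
  start0 <- suppressWarnings(as.numeric(f[, 2L]))
  end0 <- suppressWarnings(as.numeric(f[, 3L]))
  check_coords(path, "BED", start0, end0, tab$lineno)
  GenomicRanges::GRanges(f[, 1L],
                         IRanges::IRanges(start = start0 + 1, end = end0))
}
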