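## Downstream summaries over called islands and genes: peak-gene
## association, shared/unique peak grouping between two peak sets,
## H3-normalized mark enrichment over regions, expression summaries,
## chromatin-state and housekeeping-gene enrichment, and the
## integer-percent arithmetic used for nuclei counts.

#' Associate peaks with genes by overlap
#'
#' A gene is associated with a peak when the peak overlaps the gene body
#' by at least 1 bp; optionally the gene is extended upstream by
#' `promoter` bp first.
#'
#' @param islands `GRanges` of peaks.
#' @param genes `GRanges` of gene bodies named by gene id.
#' @param promoter Upstream extension in bp (default 0).
#' @return List, one character vector of gene ids per peak.
#' @export
associate_peaks_genes <- function(islands, genes, promoter = 0) {
  ids <- names(genes) %||% genes$gene_id
  ext <- genes
  if (promoter > 0) {
    minus <- as.character(GenomicRanges::strand(ext)) == "-"
    GenomicRanges::start(ext)[!minus] <-
      pmax(GenomicRanges::start(ext)[!minus] - promoter, 1)
    GenomicRanges::end(ext)[minus] <-
      GenomicRanges::end(ext)[minus] + promoter
  }
  hits <- GenomicRanges::findOverlaps(islands, ext, ignore.strand = TRUE)
  out <- rep(list(character(0)), length(islands))
  per <- split(ids[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_along(islands)))
  out[] <- unname(per)
  out
}

#' Split query peaks into shared (Group 1) and unique (Group 2) sets
#'
#' Query peaks that overlap a reference peak by >= 1 bp form Group 1;
#' peaks with no overlap form Group 2 ("unique" peaks). Also supports the
#' count-only form `group_by_overlap(total =, unique =)` for reporting a
#' unique percentage from tabulated counts.
#'
#' @param query,reference `GRanges` peak sets.
#' @param total,unique Alternative count-only input.
#' @return Object of class `peak_groups`: list with `total`, `group1`,
#'   `group2`, `n_group1`, `n_group2`, `unique_fraction`, and
#'   `unique_percent` (nearest integer).
#' @export
group_by_overlap <- function(query = NULL, reference = NULL,
                             total = NULL, unique = NULL) {
  if (is.null(query)) {
    stopifnot(!is.null(total), !is.null(unique), unique <= total)
    n2 <- unique
    n_total <- total
    g1 <- g2 <- NULL
  } else {
    ov <- IRanges::overlapsAny(query, reference, ignore.strand = TRUE)
    g1 <- query[ov]
    g2 <- query[!ov]
    n2 <- length(g2)
    n_total <- length(query)
  }
  uf <- if (n_total > 0) n2 / n_total else NA_real_
  structure(list(total = n_total, group1 = g1, group2 = g2,
                 n_group1 = n_total - n2, n_group2 = n2,
                 unique_fraction = uf,
                 unique_percent = as.integer(round(100 * uf))),
            class = "peak_groups")
}

#' @export
print.peak_groups <- function(x, ...) {
  cat(sprintf("peak_groups: %d peaks; Group 1 (shared) %d, Group 2 (unique) %d (%d%%)\n",
              x$total, x$n_group1, x$n_group2, x$unique_percent))
  invisible(x)
}

#' Per-region log2 enrichment of one library over another
#'
#' For each region, fragment midpoints of the numerator and denominator
#' libraries are counted, RPM-scaled, and combined as
#' `log2((num + eps)/(den + eps))`. With an H3 ChIP as denominator this
#' is the H3-normalized mark enrichment used for peak/gene boxplots; with
#' the mock control as denominator it is the deposition enrichment.
#'
#' @param regions `GRanges` of peaks or gene bodies.
#' @param numerator_tags,h3_tags Deduplicated read tags.
#' @param fragment_size Fragment size for midpoint shifting (default 200).
#' @param pseudocount Pseudocount in RPM units (default 1).
#' @return Numeric vector of log2 enrichment, one value per region.
#' @export
region_enrichment <- function(regions, numerator_tags, h3_tags,
                              fragment_size = 200, pseudocount = 1) {
  if (length(h3_tags) == 0L)
    stop("denominator (H3/control) library is empty", call. = FALSE)
  if (length(numerator_tags) == 0L)
    stop("numerator library is empty", call. = FALSE)
  n <- count_in_bins(regions, numerator_tags, fragment_size) *
    1e6 / length(numerator_tags)
  h <- count_in_bins(regions, h3_tags, fragment_size) *
    1e6 / length(h3_tags)
  log2((n + pseudocount) / (h + pseudocount))
}

#' Summary of log10(FPKM + 1) over a gene set
#'
#' @param gene_ids Character vector of gene ids.
#' @param expression data.frame with `gene_id`, `FPKM`.
#' @return List with `values` (the transformed vector, violin-ready),
#'   `median`, `quartiles` and `n`.
#' @export
expression_summary <- function(gene_ids, expression) {
  fpkm <- expression$FPKM[match(gene_ids, expression$gene_id)]
  if (anyNA(fpkm))
    stop("gene id(s) absent from the expression table: ",
         paste(head(gene_ids[is.na(fpkm)], 3), collapse = ", "),
         call. = FALSE)
  v <- log10(fpkm + 1)
  list(values = setNames(v, gene_ids), median = median(v),
       quartiles = quantile(v, c(0.25, 0.75), names = FALSE), n = length(v))
}

#' Mean log2 enrichment per chromatin state
#'
#' @param sample_tags,control_tags Deduplicated read tags.
#' @param states `GRanges` with a `state` label column.
#' @inheritParams region_enrichment
#' @return Named numeric vector, one mean log2(sample/control) per state.
#' @export
state_enrichment <- function(sample_tags, control_tags, states,
                             fragment_size = 200, pseudocount = 1) {
  v <- region_enrichment(states, sample_tags, control_tags,
                         fragment_size, pseudocount)
  tapply(v, states$state, mean)
}

#' Gene-body log2 enrichment over a housekeeping gene list
#'
#' @param sample_tags,control_tags Deduplicated read tags.
#' @param genes `GRanges` of gene bodies named by gene id.
#' @param top_list Character vector of housekeeping gene ids.
#' @inheritParams region_enrichment
#' @return Named numeric vector of per-gene log2(sample/control).
#' @export
housekeeping_enrichment <- function(sample_tags, control_tags, genes,
                                    top_list, fragment_size = 200,
                                    pseudocount = 1) {
  sel <- genes[names(genes) %in% top_list]
  if (length(sel) == 0L)
    stop("none of the listed genes are in the annotation", call. = FALSE)
  setNames(region_enrichment(sel, sample_tags, control_tags,
                             fragment_size, pseudocount),
           names(sel))
}

#' Integer percentage of positive nuclei, with an exact binomial interval
#'
#' @param positive Number of nuclei showing the pattern.
#' @param total Total nuclei examined (> 0).
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @return List with `percent` (nearest integer), `fraction`, `ci`
#'   (two-sided exact binomial interval on the percentage scale),
#'   `positive`, `total`.
#' @examples
#' nuclei_proportion(39, 49)$percent   # 80
#' nuclei_proportion(36, 47)$percent   # 77
#' @export
nuclei_proportion <- function(positive, total, conf_level = 0.95) {
  if (total <= 0) stop("total must be > 0", call. = FALSE)
  if (positive < 0 || positive > total)
    stop("need 0 <= positive <= total", call. = FALSE)
  ci <- binom.test(positive, total, conf.level = conf_level)$conf.int
  list(percent = as.integer(round(100 * positive / total)),
       fraction = positive / total,
       ci = 100 * as.numeric(ci),
       positive = positive, total = total)
}
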