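## Readers and writers for the plain-text formats the pipeline touches:
## BED6 reads and states, GFF3 gene models, TSV expression tables, bedGraph
## tracks, chromosome size tables. Everything downstream works on GRanges
## (1-based, closed); BED's 0-based half-open coordinates are converted here
## and nowhere else.

read_text_table <- function(path, min_fields, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) == 0L)
    return(list(fields = NULL, lineno = integer(0)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < min_fields)) {
    bad <- lineno[which(nf < min_fields)[1L]]
    stop(sprintf("%s: malformed %s line %d (expected >= %d tab-separated fields)",
                 path, what, bad, min_fields), call. = FALSE)
  }
  fields <- matrix("", nrow = length(parts), ncol = min_fields)
  for (j in seq_len(min_fields))
    fields[, j] <- vapply(parts, `[[`, "", j)
  list(fields = fields, lineno = lineno)
}

check_coords <- function(path, what, start0, end0, lineno) {
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("%s: non-numeric coordinates at line %d", path, lineno[bad[1L]]),
         call. = FALSE)
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop(sprintf("%s: invalid interval (need 0 <= start < end) at %s line %d",
                 path, what, lineno[bad[1L]]), call. = FALSE)
  invisible(NULL)
}

#' Read single-end ChIP-seq read tags from a BED6 file
#'
#' Parses a BED file with at least six columns (strand in column 6) into a
#' stranded [GenomicRanges::GRanges] of read tags. BED's 0-based half-open
#' coordinates are converted to the 1-based closed convention GRanges uses,
#' so a BED line `chr1 100 150` becomes the range 101--150 (width 50).
#'
#' @param path Path to a BED file with >= 6 tab-separated columns.
#' @return A `GRanges` of read tags, in file order, with a `name` metadata
#'   column taken from BED column 4.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t150\tr1\t0\t+", bed)
#' read_reads_bed(bed)
#' @export
read_reads_bed <- function(path) {
  tab <- read_text_table(path, 6L, "BED")
  if (is.null(tab$fields))
    return(GenomicRanges::GRanges())
  f <- tab$fields
  start0 <- suppressWarnings(as.numeric(f[, 2L]))
  end0 <- suppressWarnings(as.numeric(f[, 3L]))
  check_coords(path, "BED", start0, end0, tab$lineno)
  strand <- f[, 6L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("%s: missing or invalid strand ('%s') at line %d",
                 path, strand[bad[1L]], tab$lineno[bad[1L]]), call. = FALSE)
  GenomicRanges::GRanges(f[, 1L],
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         strand = strand,
                         name = f[, 4L])
}

#' Write read tags (or any stranded ranges) as BED6
#'
#' @param gr A `GRanges`; a `score` metadata column is used for BED column 5
#'   if present, and `name` for column 4.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", n)
  score <- if (!is.null(gr$score)) gr$score else rep(0L, n)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3/GTF
#'
#' Imports features of type `gene` via [rtracklayer::import] and returns
#' them as a `GRanges` named by gene id. GFF's 1-based inclusive coordinates
#' are kept as-is in GRanges (the two conventions agree); exporting through
#' [write_reads_bed] yields the 0-based half-open equivalent, e.g. a 1 bp
#' gene at GFF position n..n becomes BED `n-1 n`.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return `GRanges` of gene bodies with a `gene_id` metadata column
#'   (also used as names). Non-gene features are skipped with a message.
#' @export
read_genes_gff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gff <- rtracklayer::import(path)
  is_gene <- !is.na(gff$type) & as.character(gff$type) == "gene"
  n_skip <- sum(!is_gene)
  if (n_skip > 0)
    message("read_genes_gff: skipped ", n_skip, " non-gene feature(s)")
  genes <- gff[is_gene]
  ids <- genes$ID %||% genes$gene_id
  if (is.null(ids) || anyNA(ids))
    stop(path, ": gene feature(s) without an ID/gene_id attribute",
         call. = FALSE)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop(path, ": duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out <- GenomicRanges::granges(genes)
  names(out) <- ids
  out$gene_id <- ids
  out
}

#' Write gene models as GFF3
#'
#' @param genes `GRanges` named by gene id (as from [read_genes_gff]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  ids <- names(genes) %||% genes$gene_id
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(genes)),
                   source = "h3varscan", type = "gene",
                   start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes),
                   score = ".", strand = as.character(GenomicRanges::strand(genes)),
                   phase = ".",
                   attributes = paste0("ID=", ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Expects a TSV with header `gene_id<TAB>FPKM`. If `genes` is supplied,
#' ids that do not resolve against the annotation are dropped with a
#' message, per-gene expression being meaningless without a gene body.
#'
#' @param path Path to the TSV.
#' @param genes Optional `GRanges` annotation to validate ids against.
#' @return `data.frame` with columns `gene_id`, `FPKM`.
#' @export
read_expression <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "FPKM") %in% names(df)))
    stop(path, ": expected header 'gene_id\\tFPKM'", call. = FALSE)
  if (any(is.na(df$FPKM) | df$FPKM < 0))
    stop(path, ": FPKM values must be non-negative", call. = FALSE)
  if (!is.null(genes)) {
    known <- names(genes) %||% genes$gene_id
    drop <- !df$gene_id %in% known
    if (any(drop)) {
      message("read_expression: dropped ", sum(drop),
              " id(s) absent from the annotation")
      df <- df[!drop, , drop = FALSE]
    }
  }
  df[c("gene_id", "FPKM")]
}

#' @rdname read_expression
#' @param expression `data.frame` with `gene_id` and `FPKM` columns.
#' @export
write_expression <- function(expression, path) {
  write.table(expression[c("gene_id", "FPKM")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled interval set (e.g. chromatin states) from BED
#'
#' BED with >= 4 columns; column 4 carries the label (e.g. `active`,
#' `silent`).
#'
#' @param path Path to the BED file.
#' @return `GRanges` with a `state` metadata column.
#' @export
read_states_bed <- function(path) {
  tab <- read_text_table(path, 4L, "BED")
  if (is.null(tab$fields))
    return(GenomicRanges::GRanges(state = character(0)))
  f <- tab$fields
  start0 <- suppressWarnings(as.numeric(f[, 2L]))
  end0 <- suppressWarnings(as.numeric(f[, 3L]))
  check_coords(path, "BED", start0, end0, tab$lineno)
  GenomicRanges::GRanges(f[, 1L],
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         state = f[, 4L])
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path TSV with columns chrom, length (no header).
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
read_genome_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Collapse duplicate read tags
#'
#' Reads mapping to identical positions in the genome are collapsed into
#' one read: at most one tag is kept per (chrom, start, strand) key --
#' or per (chrom, start) when `ignore_strand = TRUE`. Output is sorted by
#' (chrom, start). Idempotent.
#'
#' @param tags `GRanges` of read tags.
#' @param ignore_strand Collapse tags on opposite strands at the same
#'   position into one? Default `FALSE`.
#' @return Sorted, deduplicated `GRanges`.
#' @export
collapse_duplicates <- function(tags, ignore_strand = FALSE) {
  if (length(tags) == 0L) return(tags)
  key <- paste(GenomicRanges::seqnames(tags), GenomicRanges::start(tags),
               if (ignore_strand) "" else GenomicRanges::strand(tags))
  out <- tags[!duplicated(key)]
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Write a per-window value track as bedGraph
#'
#' @param track `GRanges` with a numeric `score` metadata column; windows
#'   must be sorted and non-overlapping.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (is.null(track$score)) stop("track needs a 'score' column", call. = FALSE)
  if (!IRanges::isDisjoint(track))
    stop("bedGraph windows must be non-overlapping", call. = FALSE)
  ord <- order(as.factor(GenomicRanges::seqnames(track)),
               GenomicRanges::start(track))
  if (!identical(ord, seq_along(track)))
    stop("bedGraph windows must be sorted", call. = FALSE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                   start = GenomicRanges::start(track) - 1L,
                   end = GenomicRanges::end(track),
                   value = format(track$score, trim = TRUE, digits = 10,
                                  scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  tab <- read_text_table(path, 4L, "bedGraph")
  if (is.null(tab$fields))
    return(GenomicRanges::GRanges(score = numeric(0)))
  f <- tab$fields
  start0 <- suppressWarnings(as.numeric(f[, 2L]))
  end0 <- suppressWarnings(as.numeric(f[, 3L]))
  check_coords(path, "bedGraph", start0, end0, tab$lineno)
  GenomicRanges::GRanges(f[, 1L],
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         score = as.numeric(f[, 4L]))
}
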