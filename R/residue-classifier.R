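## Diagnostic-residue classification of H3 protein sequences. Plant H3.1
## and H3.3 typically differ at mature-protein positions 31, 41, 87 and
## 90 (Ala/Thr31, Phe/Tyr41, Ser/His87, Ala/Leu90); animal variants
## differ at 31, 87, 89 and 90 (A31-S87-V89-M90 in H3.1 versus
## S31-A87-I89-G90 in H3.3), position 41 being Tyr in all animal H3.
## Numbering follows histone convention: the initiator methionine is
## removed, so "position 41" is the 41st residue of the mature protein
## (as in H3K9, H3Y41).

#' Diagnostic residue rule tables
#'
#' @param scheme `"plant"` (positions 31/41/87/90) or `"animal"`
#'   (positions 31/87/89/90).
#' @return List with `name`, `positions`, and per-variant expected
#'   residues (named character vectors keyed by position).
#' @export
variant_rules <- function(scheme = c("plant", "animal")) {
  scheme <- match.arg(scheme)
  if (scheme == "plant")
    list(name = "plant", positions = c(31L, 41L, 87L, 90L),
         H3.1 = c(`31` = "A", `41` = "F", `87` = "S", `90` = "A"),
         H3.3 = c(`31` = "T", `41` = "Y", `87` = "H", `90` = "L"))
  else
    list(name = "animal", positions = c(31L, 87L, 89L, 90L),
         H3.1 = c(`31` = "A", `87` = "S", `89` = "V", `90` = "M"),
         H3.3 = c(`31` = "S", `87` = "A", `89` = "I", `90` = "G"))
}

#' Bundled H3 reference sequences
#'
#' Mature (Met-stripped) consensus reference sequences for plant
#' (Arabidopsis-type) and animal (human-type) H3.1 and H3.3, shipped
#' with the package for alignment anchoring and self-tests. These are
#' consensus constructs assembled in-package (synthetic), anchored at
#' the diagnostic positions, not database records.
#'
#' @return A [Biostrings::AAStringSet] with four named sequences
#'   (`plant_H3.1`, `plant_H3.3`, `animal_H3.1`, `animal_H3.3`).
#' @export
h3_references <- function() {
  seqs <- Biostrings::readAAStringSet(
    system.file("extdata", "h3_references_consensus_synthetic.faa",
                package = "h3varscan", mustWork = TRUE))
  names(seqs) <- sub(" .*", "", names(seqs))
  seqs
}

strip_met <- function(seq) sub("^M", "", as.character(seq))

#' Map mature-H3 reference positions onto a query sequence
#'
#' Globally aligns the query against a canonical H3 reference
#' (Needleman-Wunsch via [Biostrings::pairwiseAlignment], match 1,
#' mismatch -1, gap open 5, gap extend 1 by default) and returns, for
#' each mature reference position, the corresponding mature query
#' position, or `NA` where the query has a gap. Leading methionines are
#' stripped from both sequences before aligning.
#'
#' @param query,reference Amino-acid sequences (character or
#'   `AAString`-like).
#' @param match,mismatch,gap_open,gap_extend Alignment scores/penalties.
#' @param min_length Minimum query length (default 50 aa).
#' @param min_identity Identity gate against the reference (default 0.4);
#'   queries below it are rejected as not H3-like.
#' @return Integer vector of length `nchar(reference)` (mature), mapping
#'   reference position -> query position (`NA` = unalignable), with the
#'   percent identity as attribute `identity`.
#' @export
map_to_reference <- function(query, reference, match = 1, mismatch = -1,
                             gap_open = 5, gap_extend = 1,
                             min_length = 50, min_identity = 0.4) {
  q <- strip_met(query)
  r <- strip_met(reference)
  if (nchar(q) < min_length)
    stop("not an H3-like sequence: query shorter than ", min_length, " aa",
         call. = FALSE)
  alpha <- Biostrings::AA_ALPHABET
  mat <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(r), subject = Biostrings::AAString(q),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  identity <- Biostrings::pid(aln) / 100
  if (identity < min_identity)
    stop(sprintf("not an H3-like sequence: identity %.1f%% below the %.0f%% gate",
                 100 * identity, 100 * min_identity), call. = FALSE)
  ref_aln <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  qry_aln <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  mapping <- rep(NA_integer_, nchar(r))
  ri <- qi <- 0L
  for (k in seq_along(ref_aln)) {
    if (qry_aln[k] != "-") qi <- qi + 1L
    if (ref_aln[k] != "-") {
      ri <- ri + 1L
      if (qry_aln[k] != "-") mapping[ri] <- qi
    }
  }
  attr(mapping, "identity") <- identity
  mapping
}

#' Read residues at diagnostic positions off a query sequence
#'
#' @param query Amino-acid sequence.
#' @param reference Canonical H3 reference to align against (default: the
#'   bundled plant H3.1).
#' @param positions Mature-H3 positions to extract (default: the plant
#'   scheme's 31/41/87/90).
#' @param seq_id Identifier to attach to the profile.
#' @param ... Passed to [map_to_reference()].
#' @return Object of class `residue_profile`: list with `seq_id`,
#'   `residues` (named character, `NA` = unalignable) and `identity`.
#' @export
extract_profile <- function(query, reference = NULL,
                            positions = c(31L, 41L, 87L, 90L),
                            seq_id = "query", ...) {
  reference <- reference %||% as.character(h3_references()[["plant_H3.1"]])
  mapping <- map_to_reference(query, reference, ...)
  q <- strip_met(query)
  qpos <- mapping[positions]
  res <- ifelse(is.na(qpos), NA_character_,
                substring(q, qpos, qpos))
  structure(list(seq_id = seq_id,
                 residues = setNames(res, positions),
                 identity = attr(mapping, "identity")),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  res <- ifelse(is.na(x$residues), "?", x$residues)
  cat(sprintf("residue_profile %s: %s (identity %.0f%%)\n", x$seq_id,
              paste0(res, names(x$residues), collapse = "-"),
              100 * x$identity))
  invisible(x)
}

#' Classify an H3 residue profile as H3.1-like or H3.3-like
#'
#' Majority vote over the diagnostic positions: each position votes for
#' the variant whose expected residue it carries (positions matching
#' neither rule, or unalignable positions, abstain). Ties and
#' majority-unalignable profiles are called `ambiguous`.
#'
#' @param profile A `residue_profile` (or named character vector of
#'   residues keyed by position).
#' @param rule A rule table from [variant_rules()].
#' @return List with `call` (`"H3.1"`, `"H3.3"` or `"ambiguous"`) and
#'   `votes` (per-position: `"H3.1"`, `"H3.3"`, `"neither"` or
#'   `"unalignable"`).
#' @export
classify_h3 <- function(profile, rule = variant_rules("plant")) {
  residues <- if (inherits(profile, "residue_profile")) profile$residues
              else profile
  pos <- as.character(rule$positions)
  res <- residues[pos]
  votes <- ifelse(is.na(res), "unalignable",
           ifelse(res == rule$H3.1[pos], "H3.1",
           ifelse(res == rule$H3.3[pos], "H3.3", "neither")))
  names(votes) <- pos
  n1 <- sum(votes == "H3.1")
  n3 <- sum(votes == "H3.3")
  call <- if (sum(votes == "unalignable") > length(votes) / 2) "ambiguous"
          else if (n1 > n3) "H3.1"
          else if (n3 > n1) "H3.3"
          else "ambiguous"
  list(call = call, votes = votes)
}

#' Tabulate variant calls and diagnostic residues for a FASTA of H3s
#'
#' @param fasta Path to a protein FASTA, or an `AAStringSet`.
#' @param scheme Rule scheme (see [variant_rules()]).
#' @param reference Reference sequence to align against; defaults to the
#'   bundled H3.1 of the chosen scheme's kingdom.
#' @param ... Passed to [map_to_reference()].
#' @return data.frame with one row per sequence: `seq_id`, `call`,
#'   `identity`, and one residue column per diagnostic position
#'   (`pos31`, ...). Sequences failing the H3 identity gate are called
#'   `not_H3` with `NA` residues.
#' @export
species_table <- function(fasta, scheme = "plant", reference = NULL, ...) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    Biostrings::readAAStringSet(fasta) else fasta
  rule <- variant_rules(scheme)
  reference <- reference %||% as.character(
    h3_references()[[paste0(rule$name, "_H3.1")]])
  rows <- lapply(seq_along(seqs), function(k) {
    id <- names(seqs)[k] %||% paste0("seq", k)
    out <- tryCatch({
      prof <- extract_profile(as.character(seqs[[k]]), reference,
                              positions = rule$positions, seq_id = id, ...)
      c(list(seq_id = id, call = classify_h3(prof, rule)$call,
             identity = round(prof$identity, 3)),
        as.list(prof$residues))
    }, error = function(e)
      c(list(seq_id = id, call = "not_H3", identity = NA_real_),
        setNames(as.list(rep(NA_character_, length(rule$positions))),
                 as.character(rule$positions))))
    out
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  names(df) <- c("seq_id", "call", "identity",
                 paste0("pos", rule$positions))
  df
}
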