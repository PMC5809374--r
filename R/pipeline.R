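## End-to-end orchestration: one YAML config drives
## simulate -> dedup -> callpeaks -> metagene -> summaries, writing a
## deterministic run directory (peaks/, metagene/, tables/, log.txt).
## Every TSV carries a header comment with the config hash so outputs can
## be traced back to the configuration that produced them.

run_config_defaults <- function() {
  list(
    synthetic = NULL,
    inputs = NULL,
    caller = list(window_size = 200, gap = 200, fragment_size = 200,
                  eligibility_p = 0.2, p0 = 1e-3),
    metagene = list(flank = 2000, n_bins = 20, pseudocount = 1),
    seed = 1
  )
}

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level blocks `synthetic:` (passed to
#' [synthetic_config()]) or `inputs:` (paths: `control`, `samples` (named
#' list of BEDs), `genes`, `expression`, `states`, `housekeeping`,
#' `genome`), plus optional `caller:`, `metagene:` and `seed`. Unknown
#' keys are rejected before any stage runs.
#'
#' @param path YAML file, or a list with the same structure.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in c("caller", "metagene")) {
    extra <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(extra))
      stop("unknown ", blk, " key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    defaults[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  }
  defaults$seed <- cfg$seed %||% defaults$seed
  defaults$inputs <- cfg$inputs
  if (!is.null(cfg$synthetic)) {
    syn_args <- cfg$synthetic
    syn_args$seed <- syn_args$seed %||% defaults$seed
    defaults$synthetic <- do.call(synthetic_config, syn_args)
  }
  if (is.null(defaults$synthetic) && is.null(defaults$inputs))
    stop("config needs either a 'synthetic' or an 'inputs' block",
         call. = FALSE)
  with(defaults$caller, {
    stopifnot_scalar_number(window_size, "window_size", positive = TRUE)
    stopifnot_scalar_number(fragment_size, "fragment_size", positive = TRUE)
    stopifnot_scalar_number(p0, "p0", positive = TRUE)
  })
  class(defaults) <- c("run_config", "list")
  defaults
}

write_tsv_stamped <- function(df, path, hash, row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config ", hash), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = row_names, col.names = TRUE))
  invisible(path)
}

run_stage <- function(name, input, log, expr) {
  log(paste0("stage ", name, ": start"))
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for ", input, ": ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full deposition-analysis pipeline
#'
#' Synthesizes (or loads) the dataset, collapses duplicate reads, calls
#' enrichment islands for each sample against the control, computes
#' quintile-stratified metagene profiles, groups sample peaks against
#' the first sample's peaks, and writes chromatin-state and
#' housekeeping-gene enrichment summaries.
#'
#' @param config A `run_config` (or path/list accepted by
#'   [read_run_config()]).
#' @param out_dir Output run directory (created; reruns overwrite).
#' @return Invisibly, a list with the run directory, per-sample island
#'   calls, metagene profiles and the summary table.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  hash <- config_hash(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "metagene", "tables"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(paste0("config ", hash))

  if (!is.null(config$synthetic)) {
    data_dir <- file.path(out_dir, "data")
    paths <- run_stage("simulate", "synthetic config", log, {
      world <- simulate_genome(config$synthetic)
      write_synthetic_dataset(world, data_dir)
    })
    inputs <- list(control = paths$control,
                   samples = paths[c("H31_like", "H33_like", "mixed")],
                   genes = paths$genes, expression = paths$expression,
                   states = paths$states,
                   housekeeping = paths$housekeeping,
                   genome = paths$genome)
  } else inputs <- config$inputs

  genome <- run_stage("genome", inputs$genome, log, {
    if (!file.exists(inputs$genome))
      stop("file not found: ", inputs$genome)
    read_genome_sizes(inputs$genome)
  })
  genes <- run_stage("annotation", inputs$genes, log,
                     read_genes_gff(inputs$genes))
  expr <- run_stage("expression", inputs$expression, log,
                    assign_quintiles(read_expression(inputs$expression,
                                                     genes)))
  states <- read_states_bed(inputs$states)
  hk <- readLines(inputs$housekeeping)

  read_dedup <- function(path, label) run_stage("dedup", path, log, {
    raw <- read_reads_bed(path)
    tags <- collapse_duplicates(raw)
    log(sprintf("%s: %d reads, %d after dedup", label, length(raw),
                length(tags)))
    tags
  })
  control <- read_dedup(inputs$control, "control")
  samples <- lapply(names(inputs$samples), function(s)
    read_dedup(inputs$samples[[s]], s))
  names(samples) <- names(inputs$samples)

  cl <- config$caller
  mg <- config$metagene
  islands <- list()
  profiles <- list()
  summary_rows <- list()
  for (s in names(samples)) {
    islands[[s]] <- run_stage("callpeaks", s, log, {
      grid <- window_grid(samples[[s]], control, genome,
                          cl$window_size, cl$fragment_size)
      isl <- call_islands(grid, cl$gap, cl$eligibility_p, cl$p0)
      write_peaks(isl, file.path(out_dir, "peaks", paste0(s, ".bed")))
      df <- as.data.frame(isl)
      write_tsv_stamped(df, file.path(out_dir, "tables",
                                      paste0(s, "_islands.tsv")), hash)
      log(sprintf("%s: %d islands (%d significant)", s, length(isl),
                  sum(isl$significant)))
      isl
    })
    profiles[[s]] <- run_stage("metagene", s, log, {
      prof <- metagene_profile(samples[[s]], control, genes, expr,
                               mg$flank, mg$n_bins, cl$fragment_size,
                               mg$pseudocount, genome)
      write_metagene_tsv(prof,
                         file.path(out_dir, "metagene",
                                   paste0(s, "_groups.tsv")))
      log(sprintf("%s: %d genes profiled", s, nrow(prof$per_gene)))
      prof
    })
    st <- state_enrichment(samples[[s]], control, states,
                           cl$fragment_size, mg$pseudocount)
    hk_med <- median(housekeeping_enrichment(samples[[s]], control, genes,
                                             hk, cl$fragment_size,
                                             mg$pseudocount))
    summary_rows[[s]] <- data.frame(
      sample = s, n_islands = length(islands[[s]]),
      n_significant = sum(islands[[s]]$significant),
      active_state = unname(st["active"]),
      silent_state = unname(st["silent"]),
      housekeeping_median = hk_med)
  }

  # shared/unique grouping of every other sample against the first
  ref_name <- names(samples)[1]
  ref_peaks <- islands[[ref_name]][islands[[ref_name]]$significant]
  group_rows <- lapply(setdiff(names(samples), ref_name), function(s) {
    pg <- group_by_overlap(islands[[s]][islands[[s]]$significant],
                           ref_peaks)
    write_peaks(pg$group2, file.path(out_dir, "peaks",
                                     paste0(s, "_unique.bed")), all = TRUE)
    data.frame(sample = s, reference = ref_name, total = pg$total,
               shared = pg$n_group1, unique = pg$n_group2,
               unique_percent = pg$unique_percent)
  })

  summary_df <- do.call(rbind, summary_rows)
  write_tsv_stamped(summary_df, file.path(out_dir, "tables", "summary.tsv"),
                    hash)
  if (length(group_rows))
    write_tsv_stamped(do.call(rbind, group_rows),
                      file.path(out_dir, "tables", "peak_groups.tsv"), hash)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(dir = out_dir, islands = islands, profiles = profiles,
                 summary = summary_df, config = config, hash = hash))
}
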