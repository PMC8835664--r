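# Pipeline orchestration: simulate -> detect -> cohort -> clinical as
# composable stage commands sharing one serialized configuration. Each
# stage writes its outputs (and the config) into the output directory and
# appends a structured entry to run_log.json; downstream stages check for
# their upstream files and fail with the missing path named.

#' Build a pipeline configuration
#'
#' @param out_dir output directory for all stages.
#' @param seed master seed (overrides the simulator config's seed).
#' @param sim a [sim_config()] (or list of its arguments).
#' @param aligner an [aligner_params()] (or list of its arguments).
#' @param min_coverage per-mate alignment coverage threshold.
#' @param exclude_repeats drop repeat-overlapping candidates.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = NULL, sim = sim_config(),
                            aligner = aligner_params(),
                            min_coverage = 0.9, exclude_repeats = TRUE) {
  if (is.list(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, sim)
  if (is.list(aligner) && !inherits(aligner, "aligner_params"))
    aligner <- do.call(aligner_params, aligner)
  if (!is.null(seed)) {
    args <- unclass(sim)
    args$seed <- as.integer(seed)
    args$insert_mean <- args$insert_mean  # keep remaining fields as-is
    sim <- do.call(sim_config, args)
  }
  check_number(min_coverage, "min_coverage", min = 0, max = 1)
  structure(list(out_dir = out_dir, sim = sim, aligner = aligner,
                 min_coverage = min_coverage,
                 exclude_repeats = isTRUE(exclude_repeats)),
            class = "pipeline_config")
}

write_pipeline_config <- function(config, dir) {
  x <- list(out_dir = config$out_dir, sim = unclass(config$sim),
            aligner = unclass(config$aligner),
            min_coverage = config$min_coverage,
            exclude_repeats = config$exclude_repeats)
  jsonlite::write_json(x, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
}

#' Read a pipeline configuration from JSON
#' @param path path to a config JSON written by the pipeline (or by hand).
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- x$sim
  if (!is.null(sim_args$marker_probs)) {
    sim_args$marker_probs$rai <- matrix(unlist(sim_args$marker_probs$rai),
                                        nrow = 2, byrow = FALSE,
                                        dimnames = list(NULL,
                                          c("0", "I", "II", "III", "IV")))
  } else {
    sim_args$marker_probs <- default_marker_probs()
  }
  pipeline_config(out_dir = x$out_dir, sim = sim_args, aligner = x$aligner,
                  min_coverage = x$min_coverage,
                  exclude_repeats = x$exclude_repeats)
}

log_stage <- function(dir, stage, info) {
  path <- file.path(dir, "run_log.json")
  log <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  log[[length(log) + 1L]] <- c(list(stage = stage,
                                    time = format(Sys.time())), info)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  message(sprintf("[lgtscan] %s: %s", stage,
                  paste(names(info), unlist(info), sep = "=",
                        collapse = " ")))
}

require_upstream <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_config("missing upstream output: %s (run the earlier stage first)",
                missing[1])
}

#' Pipeline stage commands
#'
#' \code{cmd_simulate()} generates references and the read-level cohort;
#' \code{cmd_detect()} runs LGT detection on every simulated sample;
#' \code{cmd_cohort()} computes burdens, the cohort comparison, the genus
#' matrix and the MDS grouping; \code{cmd_clinical()} associates the
#' grouping and burdens with the clinical table; \code{cmd_all()} runs the
#' four stages in order. Every stage is a pure function of its inputs and
#' the config; re-running with the same config reproduces outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the directory (or list of key results for analysis
#'   stages).
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, config$out_dir)
  refs <- generate_references(config$sim)
  write_references(refs, file.path(config$out_dir, "refs"))
  cohort <- simulate_cohort(config$sim, refs)
  write_cohort(cohort, file.path(config$out_dir, "sim"))
  log_stage(config$out_dir, "simulate",
            list(samples = length(cohort$samples),
                 pairs_per_sample = config$sim$n_pairs_per_sample,
                 seconds = round(as.numeric(Sys.time() - t0, "secs"), 2)))
  invisible(config$out_dir)
}

#' @rdname cmd_simulate
#' @export
cmd_detect <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  refs_dir <- file.path(config$out_dir, "refs")
  sim_dir <- file.path(config$out_dir, "sim")
  require_upstream(c(file.path(refs_dir, "host.fa"),
                     file.path(sim_dir, "truth_counts.tsv")))
  refs <- read_references(refs_dir)
  counts <- read.table(file.path(sim_dir, "truth_counts.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  events <- list(); reports <- list()
  for (sid in counts$sample_id) {
    r1 <- file.path(sim_dir, "reads", paste0(sid, "_R1.fastq"))
    r2 <- file.path(sim_dir, "reads", paste0(sid, "_R2.fastq"))
    require_upstream(c(r1, r2))
    det <- run_detection(c(r1, r2), refs, config$aligner,
                         min_coverage = config$min_coverage,
                         exclude_repeats = config$exclude_repeats,
                         sample_id = sid)
    events[[sid]] <- det$events
    reports[[sid]] <- as.list(det$report)
  }
  all_events <- do.call(rbind, events)
  all_events <- annotate_events(all_events, refs$genes)
  write_events_tsv(all_events, file.path(config$out_dir, "events.tsv"))
  jsonlite::write_json(reports, file.path(config$out_dir,
                                          "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(config$out_dir, "detect",
            list(samples = nrow(counts), events = nrow(all_events),
                 seconds = round(as.numeric(Sys.time() - t0, "secs"), 2)))
  invisible(config$out_dir)
}

#' @rdname cmd_simulate
#' @export
cmd_cohort <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  ev_path <- file.path(config$out_dir, "events.tsv")
  tc_path <- file.path(config$out_dir, "sim", "truth_counts.tsv")
  require_upstream(c(ev_path, tc_path))
  events <- read_events_tsv(ev_path)
  counts <- read.table(tc_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  cohorts <- data.frame(sample_id = counts$sample_id,
                        cohort = paste0("group", counts$group),
                        stringsAsFactors = FALSE)
  burdens <- compute_burden(events,
                            setNames(counts$n_pairs, counts$sample_id),
                            cohorts)
  test <- compare_cohorts(burdens)
  mat <- build_genus_matrix(events, sample_ids = counts$sample_id)
  grouping <- mds_group(mat, burdens)
  write.table(burdens, file.path(config$out_dir, "burden.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(mat, file.path(config$out_dir, "genus_matrix.tsv"))
  mds_df <- data.frame(sample_id = rownames(grouping$coordinates),
                       mds1 = grouping$coordinates[, 1],
                       mds2 = grouping$coordinates[, 2],
                       group = grouping$group, stringsAsFactors = FALSE)
  write.table(mds_df, file.path(config$out_dir, "mds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fold_mean = test$fold_mean, fold_median = test$fold_median,
         t = test$t, df = test$df, p = test$p,
         mds_fold_difference = grouping$fold_difference),
    file.path(config$out_dir, "cohort_test.json"), auto_unbox = TRUE,
    digits = NA)
  log_stage(config$out_dir, "cohort",
            list(fold_mean = round(test$fold_mean, 4),
                 p = signif(test$p, 4),
                 mds_fold = round(grouping$fold_difference, 4),
                 seconds = round(as.numeric(Sys.time() - t0, "secs"), 2)))
  invisible(list(burdens = burdens, test = test, matrix = mat,
                 grouping = grouping))
}

#' @rdname cmd_simulate
#' @export
cmd_clinical <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  mds_path <- file.path(config$out_dir, "mds.tsv")
  cl_path <- file.path(config$out_dir, "sim", "clinical.tsv")
  b_path <- file.path(config$out_dir, "burden.tsv")
  require_upstream(c(mds_path, cl_path, b_path))
  mds_df <- read.table(mds_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  clinical <- read_clinical_tsv(cl_path)
  burdens <- read.table(b_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  group <- setNames(mds_df$group, mds_df$sample_id)
  assoc <- associate_groups(group, clinical, burdens)
  out <- list(
    n_samples = assoc$n_samples,
    markers = assoc$markers,
    logrank = lapply(assoc$survival, function(s) s$logrank),
    cutpoints = lapply(assoc$cutpoints %||% list(), function(cp)
      list(cutoff = cp$cutpoint$cutoff, n_low = cp$cutpoint$n_low,
           n_high = cp$cutpoint$n_high, logrank_p = cp$logrank$p)),
    n_dropped = as.list(assoc$n_dropped))
  jsonlite::write_json(out, file.path(config$out_dir, "association.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(config$out_dir, "clinical",
            list(n_markers = if (is.null(assoc$markers)) 0L
                 else nrow(assoc$markers),
                 seconds = round(as.numeric(Sys.time() - t0, "secs"), 2)))
  invisible(assoc)
}

#' @rdname cmd_simulate
#' @export
cmd_all <- function(config) {
  cmd_simulate(config)
  cmd_detect(config)
  cmd_cohort(config)
  cmd_clinical(config)
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' Thin argument parser behind the \code{lgtscan} script
#' (\code{inst/scripts/lgtscan}): subcommands \code{simulate},
#' \code{detect}, \code{cohort}, \code{clinical}, \code{all} with
#' \code{--config}, \code{--seed} and \code{--out-dir} overrides.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the stage result.
#' @export
run_lgtscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) ||
      !args[1] %in% c("simulate", "detect", "cohort", "clinical", "all")) {
    cat("usage: lgtscan <simulate|detect|cohort|clinical|all>",
        "[--config FILE] [--seed N] [--out-dir DIR]\n")
    return(invisible(NULL))
  }
  stage <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  cfg_path <- opt("--config")
  out_dir <- opt("--out-dir", "lgtscan_out")
  seed <- opt("--seed")
  config <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path)
            else pipeline_config(out_dir)
  if (!is.null(opt("--out-dir"))) config$out_dir <- out_dir
  if (!is.null(seed))
    config <- pipeline_config(config$out_dir, seed = as.integer(seed),
                              sim = config$sim, aligner = config$aligner,
                              min_coverage = config$min_coverage,
                              exclude_repeats = config$exclude_repeats)
  fn <- switch(stage, simulate = cmd_simulate, detect = cmd_detect,
               cohort = cmd_cohort, clinical = cmd_clinical, all = cmd_all)
  invisible(fn(config))
}
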