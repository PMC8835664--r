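# Two-group cohort simulation: group 2 carries a configurable fold-increase
# in LGT rate; clinical covariates (survival endpoints, IGHV/FISH/CD38/RAI
# markers) are drawn per group from the configured distributions.

#' Simulate a two-group cohort with planted LGT ground truth
#'
#' Group 1 samples use \code{config$lgt_rate}; group 2 samples use
#' \code{config$lgt_rate * config$group2_lgt_fold}. Each sample is generated
#' by [simulate_sample()] under a seed derived from \code{config$seed} and
#' the sample index, so the cohort is fully reproducible. A clinical table
#' is drawn alongside: exponential survival times for OS and PFS (group-2
#' hazard multiplied by \code{hazard_ratio_group2}), uniform administrative
#' censoring on \code{(0, censor_horizon]}, and categorical markers with the
#' configured per-group probabilities.
#'
#' With \code{counts_only = TRUE} no reads are generated: per-sample truth
#' class counts are drawn directly from the multinomial class distribution
#' (the same law the read-level generator follows), which is sufficient for
#' burden-level statistics and orders of magnitude faster.
#'
#' @param config a [sim_config()].
#' @param references an \code{lgt_references}; may be \code{NULL} when
#'   \code{counts_only = TRUE}.
#' @param counts_only logical; skip read generation and return truth counts.
#' @return A list of class \code{lgt_cohort}: \code{samples} (named list of
#'   \code{lgt_sample} objects, or \code{NULL}), \code{truth_counts} (data
#'   frame sample_id, group, n_pairs and per-class counts), \code{clinical}
#'   (data frame, one row per sample).
#' @examples
#' cfg <- sim_config(seed = 5, n_samples_group1 = 3, n_samples_group2 = 3,
#'                   n_pairs_per_sample = 5000)
#' coh <- simulate_cohort(cfg, counts_only = TRUE)
#' coh$truth_counts
#' @export
simulate_cohort <- function(config, references = NULL, counts_only = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!counts_only && !inherits(references, "lgt_references"))
    stop_config("read-level simulation requires references; see generate_references()")
  n1 <- config$n_samples_group1
  n2 <- config$n_samples_group2
  group <- rep(1:2, c(n1, n2))
  sample_id <- sprintf("G%dS%02d", group,
                       c(seq_len(n1), seq_len(n2)))
  lgt_rate <- ifelse(group == 2L, config$lgt_rate * config$group2_lgt_fold,
                     config$lgt_rate)

  if (counts_only) {
    counts <- draw_truth_counts(config, sample_id, lgt_rate)
    samples <- NULL
  } else {
    samples <- vector("list", length(sample_id))
    names(samples) <- sample_id
    for (i in seq_along(sample_id)) {
      samples[[i]] <- simulate_sample(
        config, references, sample_id[i], lgt_rate = lgt_rate[i],
        seed = derive_seed(config$seed, 1000L + i))
    }
    counts <- do.call(rbind, lapply(samples, function(s) {
      tab <- table(factor(s$truth$truth_class,
                          levels = c("host", "lgt", "bacterial",
                                     "lowcomplex", "duplicate")))
      data.frame(sample_id = s$sample_id, n_pairs = nrow(s$pairs),
                 n_host = as.integer(tab["host"]),
                 n_lgt = as.integer(tab["lgt"]),
                 n_bacterial = as.integer(tab["bacterial"]),
                 n_lowcomplex = as.integer(tab["lowcomplex"]),
                 n_duplicate = as.integer(tab["duplicate"]),
                 stringsAsFactors = FALSE)
    }))
    rownames(counts) <- NULL
    counts$group <- group
  }

  clinical <- simulate_clinical(config, sample_id, group)
  structure(list(samples = samples, truth_counts = counts,
                 clinical = clinical, group = setNames(group, sample_id),
                 config = config),
            class = "lgt_cohort")
}

# Multinomial truth-class counts per sample; the same distribution the
# per-pair categorical draw in simulate_sample induces.
draw_truth_counts <- function(config, sample_id, lgt_rate) {
  with_seed(derive_seed(config$seed, 77L), {
    out <- lapply(seq_along(sample_id), function(i) {
      p <- c(lgt = lgt_rate[i], bacterial = config$microbiome_rate,
             lowcomplex = config$lowcomplexity_rate,
             duplicate = config$duplicate_rate)
      p <- c(p, host = 1 - sum(p))
      k <- rmultinom(1, config$n_pairs_per_sample, p)[, 1]
      data.frame(sample_id = sample_id[i],
                 n_pairs = config$n_pairs_per_sample,
                 n_host = k[["host"]], n_lgt = k[["lgt"]],
                 n_bacterial = k[["bacterial"]],
                 n_lowcomplex = k[["lowcomplex"]],
                 n_duplicate = k[["duplicate"]], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$group <- as.integer(sub("^G(\\d).*", "\\1", out$sample_id))
    out
  })
}

# Clinical covariates: exponential survival with uniform censoring, binary
# markers and RAI stage per group.
simulate_clinical <- function(config, sample_id, group) {
  mp <- config$marker_probs
  with_seed(derive_seed(config$seed, 88L), {
    n <- length(sample_id)
    hr <- ifelse(group == 2L, config$hazard_ratio_group2, 1)
    draw_endpoint <- function(base_hazard) {
      t_event <- rexp(n, rate = base_hazard * hr)
      t_cens <- runif(n, 0, config$censor_horizon)
      list(time = round(pmin(t_event, t_cens), 3),
           event = as.integer(t_event <= t_cens))
    }
    os <- draw_endpoint(config$os_hazard)
    pfs <- draw_endpoint(config$pfs_hazard)
    yn <- function(m) {
      p <- mp[[m]][group]
      ifelse(runif(n) < p, "yes", "no")
    }
    cd38 <- ifelse(runif(n) < mp$cd38_high[group], "high", "low")
    rai <- vapply(seq_len(n), function(i)
      sample(colnames(mp$rai), 1L, prob = mp$rai[group[i], ]), character(1))
    data.frame(sample_id = sample_id,
               os_time = os$time, os_event = os$event,
               pfs_time = pfs$time, pfs_event = pfs$event,
               ighv_mutated = yn("ighv_mutated"),
               del11q = yn("del11q"), del17q = yn("del17q"),
               tri12 = yn("tri12"), del13q = yn("del13q"),
               cd38 = cd38, rai_stage = rai, stringsAsFactors = FALSE)
  })
}

#' @export
print.lgt_cohort <- function(x, ...) {
  n <- table(x$group)
  cat(sprintf("Synthetic LGT cohort: %d + %d samples%s\n", n[["1"]], n[["2"]],
              if (is.null(x$samples)) " (truth counts only)" else ""))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample FASTQ pairs and truth tables (when reads were
#' generated), the clinical TSV and the truth-count table under \code{dir}.
#'
#' @param cohort an \code{lgt_cohort}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lgt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$samples))
    for (s in cohort$samples) write_sample(s, file.path(dir, "reads"))
  write_clinical_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write.table(cohort$truth_counts, file.path(dir, "truth_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
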