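#' Configuration for the synthetic LGT cohort generator
#'
#' Collects every parameter of the synthetic-data generator: reference
#' geometry, read-pair geometry, per-class rates, sequencing error, cohort
#' structure and clinical covariate distributions. The seed fully determines
#' every output derived from a config.
#'
#' The generator emits read pairs of five truth classes: host-only pairs,
#' pure-bacterial ("microbiome") pairs, LGT-junction-spanning pairs,
#' low-complexity artifact pairs (one homopolymer mate) and PCR duplicates
#' (byte-copies of an LGT pair). For an LGT pair one mate lies entirely in
#' the host sequence and the other entirely in a bacterial sequence, with
#' the planted junction falling in the unsequenced insert between them —
#' hence the constraint \code{insert_mean >= 2 * read_length}.
#'
#' @param seed integer seed; identical configs produce byte-identical output.
#' @param host_length host reference length in bp.
#' @param n_host_genes number of non-overlapping gene models to place.
#' @param n_bacterial_refs number of bacterial reference sequences.
#' @param bacterial_length length of each bacterial reference in bp.
#' @param read_length mate length in bp.
#' @param insert_mean,insert_sd fragment-length distribution (truncated
#'   normal, resampled until \code{>= 2 * read_length}).
#' @param n_pairs_per_sample read pairs simulated per sample.
#' @param lgt_rate fraction of pairs spanning a planted host-bacterial
#'   junction.
#' @param microbiome_rate fraction of pure-bacterial pairs.
#' @param duplicate_rate fraction of pairs that are byte-copies of an LGT
#'   pair from the same sample.
#' @param lowcomplexity_rate fraction of pairs with one homopolymer mate.
#' @param error_rate per-base substitution probability.
#' @param n_samples_group1,n_samples_group2 cohort group sizes.
#' @param group2_lgt_fold multiplier applied to \code{lgt_rate} in group 2.
#' @param gc expected G+C fraction of generated references.
#' @param noncoding_frac fraction of gene models without a CDS (ncRNA).
#' @param os_hazard,pfs_hazard baseline exponential hazards for overall and
#'   progression-free survival (per month).
#' @param hazard_ratio_group2 hazard multiplier for group-2 samples (both
#'   endpoints).
#' @param censor_horizon administrative censoring horizon (months); censoring
#'   times are uniform on (0, horizon].
#' @param marker_probs named list of per-group marker probabilities; see
#'   [default_marker_probs()].
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_pairs_per_sample = 1000)
#' cfg$lgt_rate
#' @export
sim_config <- function(seed = 1L,
                       host_length = 100000L,
                       n_host_genes = 30L,
                       n_bacterial_refs = 24L,
                       bacterial_length = 5000L,
                       read_length = 100L,
                       insert_mean = 300L,
                       insert_sd = 30L,
                       n_pairs_per_sample = 10000L,
                       lgt_rate = 0.001,
                       microbiome_rate = 0.01,
                       duplicate_rate = 5e-4,
                       lowcomplexity_rate = 5e-4,
                       error_rate = 0.002,
                       n_samples_group1 = 20L,
                       n_samples_group2 = 20L,
                       group2_lgt_fold = 2.8,
                       gc = 0.5,
                       noncoding_frac = 0.2,
                       os_hazard = 0.006,
                       pfs_hazard = 0.017,
                       hazard_ratio_group2 = 1,
                       censor_horizon = 120,
                       marker_probs = default_marker_probs()) {
  check_number(seed, "seed", integer = TRUE)
  check_number(host_length, "host_length", min = 1000, integer = TRUE)
  check_number(n_host_genes, "n_host_genes", min = 0, integer = TRUE)
  check_number(n_bacterial_refs, "n_bacterial_refs", min = 1, integer = TRUE)
  check_number(bacterial_length, "bacterial_length", min = 500, integer = TRUE)
  check_number(read_length, "read_length", min = 20, integer = TRUE)
  check_number(insert_mean, "insert_mean", min = 1)
  check_number(insert_sd, "insert_sd", min = 0)
  check_number(n_pairs_per_sample, "n_pairs_per_sample", min = 1,
               integer = TRUE)
  for (r in c("lgt_rate", "microbiome_rate", "duplicate_rate",
              "lowcomplexity_rate", "error_rate")) {
    check_number(get(r), r, min = 0, max = 1)
  }
  if (lgt_rate + microbiome_rate + duplicate_rate + lowcomplexity_rate > 1)
    stop_config("class rates must sum to at most 1")
  if (lgt_rate * group2_lgt_fold + microbiome_rate + duplicate_rate +
        lowcomplexity_rate > 1)
    stop_config("group-2 class rates (lgt_rate * group2_lgt_fold) exceed 1")
  if (insert_mean < 2 * read_length)
    stop_config(
      "insert_mean (%s) must be >= 2 * read_length (%s) so the junction can lie in the unsequenced insert",
      insert_mean, 2 * read_length)
  check_number(n_samples_group1, "n_samples_group1", min = 1, integer = TRUE)
  check_number(n_samples_group2, "n_samples_group2", min = 1, integer = TRUE)
  check_number(group2_lgt_fold, "group2_lgt_fold", min = 0)
  check_number(gc, "gc", min = 0.05, max = 0.95)
  check_number(noncoding_frac, "noncoding_frac", min = 0, max = 1)
  check_number(os_hazard, "os_hazard", min = 1e-6)
  check_number(pfs_hazard, "pfs_hazard", min = 1e-6)
  check_number(hazard_ratio_group2, "hazard_ratio_group2", min = 1e-6)
  check_number(censor_horizon, "censor_horizon", min = 1)

  structure(list(
    seed = as.integer(seed),
    host_length = as.integer(host_length),
    n_host_genes = as.integer(n_host_genes),
    n_bacterial_refs = as.integer(n_bacterial_refs),
    bacterial_length = as.integer(bacterial_length),
    read_length = as.integer(read_length),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    n_pairs_per_sample = as.integer(n_pairs_per_sample),
    lgt_rate = lgt_rate,
    microbiome_rate = microbiome_rate,
    duplicate_rate = duplicate_rate,
    lowcomplexity_rate = lowcomplexity_rate,
    error_rate = error_rate,
    n_samples_group1 = as.integer(n_samples_group1),
    n_samples_group2 = as.integer(n_samples_group2),
    group2_lgt_fold = group2_lgt_fold,
    gc = gc,
    noncoding_frac = noncoding_frac,
    os_hazard = os_hazard,
    pfs_hazard = pfs_hazard,
    hazard_ratio_group2 = hazard_ratio_group2,
    censor_horizon = censor_horizon,
    marker_probs = validate_marker_probs(marker_probs)
  ), class = "sim_config")
}

#' Default per-group clinical marker probabilities
#'
#' Frequencies typical for an untreated CLL cohort: IGHV mutated ~40%,
#' del(11q) ~20%, del(17p) ~10%, trisomy 12 ~15%, del(13q) ~55%, CD38-high
#' ~30%, and a RAI stage mix spanning 0-IV. Both groups share the same
#' probabilities by default (no configured marker-group association).
#'
#' @return Named list; each binary marker maps to \code{c(group1, group2)}
#'   success probabilities, and \code{rai} to a 2 x 5 matrix of stage
#'   probabilities (rows = groups, columns = stages 0, I, II, III, IV).
#' @export
default_marker_probs <- function() {
  rai <- rbind(c(0.25, 0.25, 0.20, 0.15, 0.15),
               c(0.25, 0.25, 0.20, 0.15, 0.15))
  colnames(rai) <- c("0", "I", "II", "III", "IV")
  list(ighv_mutated = c(0.4, 0.4),
       del11q = c(0.2, 0.2),
       del17q = c(0.1, 0.1),
       tri12 = c(0.15, 0.15),
       del13q = c(0.55, 0.55),
       cd38_high = c(0.3, 0.3),
       rai = rai)
}

validate_marker_probs <- function(mp) {
  needed <- c("ighv_mutated", "del11q", "del17q", "tri12", "del13q",
              "cd38_high", "rai")
  if (!is.list(mp) || !all(needed %in% names(mp)))
    stop_config("marker_probs must contain: %s", paste(needed, collapse = ", "))
  for (m in setdiff(needed, "rai")) {
    p <- mp[[m]]
    if (!is.numeric(p) || length(p) != 2L || any(p < 0) || any(p > 1))
      stop_config("marker_probs$%s must be two probabilities (group1, group2)", m)
  }
  r <- mp$rai
  if (!is.matrix(r) || nrow(r) != 2L || ncol(r) != 5L ||
      any(abs(rowSums(r) - 1) > 1e-8))
    stop_config("marker_probs$rai must be a 2 x 5 matrix with rows summing to 1")
  mp
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic LGT cohort configuration\n")
  cat(sprintf("  seed %d | host %d bp, %d genes | %d bacterial refs x %d bp\n",
              x$seed, x$host_length, x$n_host_genes, x$n_bacterial_refs,
              x$bacterial_length))
  cat(sprintf("  %d pairs/sample, read %d bp, insert %g +/- %g bp\n",
              x$n_pairs_per_sample, x$read_length, x$insert_mean, x$insert_sd))
  cat(sprintf("  rates: lgt %g, microbiome %g, duplicate %g, lowcomplexity %g, error %g\n",
              x$lgt_rate, x$microbiome_rate, x$duplicate_rate,
              x$lowcomplexity_rate, x$error_rate))
  cat(sprintf("  cohort: %d + %d samples, group-2 LGT fold %g\n",
              x$n_samples_group1, x$n_samples_group2, x$group2_lgt_fold))
  invisible(x)
}
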