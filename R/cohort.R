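# Cohort-level statistics: read-normalised LGT burden, cohort enrichment
# test, genus count matrix and MDS-based patient stratification.

#' Compute read-normalised LGT burden per sample
#'
#' Burden is the number of unique LGT events normalised to the total
#' read-pair count: \code{pct_lgt = 100 * n_events / total_pairs}.
#'
#' @param events event data frame (or list of \code{lgt_detection}
#'   results).
#' @param total_pairs named numeric vector of total read pairs per sample
#'   (ignored when \code{events} is a detection list, which carries its own
#'   totals). Every named sample appears in the output, with zero events if
#'   absent from the table.
#' @param cohorts optional data frame \code{sample_id}, \code{cohort}.
#' @return Data frame \code{sample_id}, \code{cohort} (NA when unknown),
#'   \code{n_events}, \code{total_pairs}, \code{pct_lgt}.
#' @export
compute_burden <- function(events, total_pairs, cohorts = NULL) {
  if (is.list(events) && !is.data.frame(events) &&
      all(vapply(events, inherits, logical(1), "lgt_detection"))) {
    total_pairs <- setNames(vapply(events, `[[`, numeric(1), "total_pairs"),
                            vapply(events, `[[`, character(1), "sample_id"))
    events <- do.call(rbind, lapply(events, `[[`, "events"))
  }
  if (is.null(names(total_pairs)))
    stop_config("total_pairs must be a named vector of per-sample totals")
  if (any(total_pairs <= 0))
    stop_config("total_pairs must be positive for every sample")
  n_events <- table(factor(events$sample_id, levels = names(total_pairs)))
  out <- data.frame(sample_id = names(total_pairs),
                    cohort = NA_character_,
                    n_events = as.integer(n_events),
                    total_pairs = as.numeric(total_pairs),
                    stringsAsFactors = FALSE)
  out$pct_lgt <- 100 * out$n_events / out$total_pairs
  if (!is.null(cohorts))
    out$cohort <- cohorts$cohort[match(out$sample_id, cohorts$sample_id)]
  rownames(out) <- NULL
  out
}

#' Compare LGT burden between two cohorts
#'
#' Unpaired two-tailed t-test on per-sample \code{pct_lgt} (classic
#' pooled-variance by default; Welch behind \code{welch = TRUE}), plus
#' mean- and median-based fold changes (first-listed cohort in the
#' numerator when its mean is larger, otherwise cohorts are reported as
#' given: fold changes are \code{mean(a)/mean(b)} with \code{a} the first
#' cohort level).
#'
#' @param burdens burden data frame from [compute_burden()] with a
#'   non-missing \code{cohort} column containing exactly two levels.
#' @param welch use the Welch (unequal-variance) variant.
#' @return List of class \code{lgt_cohort_test}: \code{fold_mean},
#'   \code{fold_median}, \code{t}, \code{df}, \code{p}, \code{means},
#'   \code{cohort_levels}, \code{n}.
#' @examples
#' b <- data.frame(sample_id = letters[1:8],
#'                 cohort = rep(c("CLL", "healthy"), each = 4),
#'                 pct_lgt = c(4, 5, 6, 5, 2, 3, 2, 3))
#' compare_cohorts(b)
#' @export
compare_cohorts <- function(burdens, welch = FALSE) {
  lv <- unique(burdens$cohort[!is.na(burdens$cohort)])
  if (length(lv) != 2L)
    stop_config("compare_cohorts() needs exactly two cohorts, got %d",
                length(lv))
  a <- burdens$pct_lgt[burdens$cohort == lv[1]]
  b <- burdens$pct_lgt[burdens$cohort == lv[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop_config("each cohort needs at least two samples")
  tt <- t.test(a, b, var.equal = !welch)
  structure(list(
    fold_mean = mean(a) / mean(b),
    fold_median = median(a) / median(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    means = setNames(c(mean(a), mean(b)), lv),
    cohort_levels = lv, n = setNames(c(length(a), length(b)), lv)),
    class = "lgt_cohort_test")
}

#' @export
print.lgt_cohort_test <- function(x, ...) {
  cat(sprintf(
    "LGT burden: %s (n=%d, mean %.4g%%) vs %s (n=%d, mean %.4g%%)\n",
    x$cohort_levels[1], x$n[1], x$means[1],
    x$cohort_levels[2], x$n[2], x$means[2]))
  cat(sprintf("  fold change: %.3g (means), %.3g (medians)\n",
              x$fold_mean, x$fold_median))
  cat(sprintf("  t = %.4g on %.4g df, two-sided p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Build the samples-by-genera count matrix of unique LGT events
#'
#' @param events event data frame with \code{sample_id} and
#'   \code{bact_genus}.
#' @param sample_ids optional character vector fixing row order (samples
#'   without events get zero rows).
#' @return Integer matrix, rows = samples, columns = genera (alphabetical).
#' @export
build_genus_matrix <- function(events, sample_ids = NULL) {
  sample_ids <- sample_ids %||% sort(unique(events$sample_id))
  genera <- sort(unique(events$bact_genus))
  tab <- table(factor(events$sample_id, levels = sample_ids),
               factor(events$bact_genus, levels = genera))
  mat <- matrix(as.integer(tab), nrow = length(sample_ids),
                dimnames = list(sample_ids, genera))
  mat
}

#' Restrict a genus matrix to the most abundant genera
#'
#' @param mat genus count matrix.
#' @param n number of genera to keep (by descending total count,
#'   alphabetical tie-break).
#' @return The restricted matrix.
#' @export
top_genera <- function(mat, n = 20L) {
  totals <- colSums(mat)
  ord <- order(-totals, colnames(mat))
  mat[, ord[seq_len(min(n, ncol(mat)))], drop = FALSE]
}

#' Stratify samples by classical MDS of genus-level LGT counts
#'
#' Counts are damped as \code{log2(count + 1)} so a single hyper-abundant
#' genus cannot dominate the distances; classical (Torgerson) MDS of the
#' Euclidean distance matrix embeds samples in two dimensions; a 2-means
#' split with deterministic initialisation at the two most distant samples
#' partitions the embedding. The group with the higher mean burden is
#' labelled group 2, so \code{fold_difference >= 1} by convention.
#'
#' @param mat genus count matrix (rows = samples).
#' @param burdens burden data frame from [compute_burden()] covering the
#'   matrix's samples.
#' @return Object of class \code{lgt_mds}: \code{coordinates} (n x 2),
#'   \code{group} (named 1/2 vector), \code{fold_difference},
#'   \code{group_means}.
#' @export
mds_group <- function(mat, burdens) {
  n <- nrow(mat)
  if (n < 4L) stop_config("mds_group() needs at least 4 samples, got %d", n)
  x <- log2(mat + 1)
  d <- dist(x)
  coords <- cmdscale(d, k = 2L)
  if (ncol(coords) < 2L)  # degenerate input collapses to fewer dimensions
    coords <- cbind(coords, matrix(0, n, 2L - ncol(coords)))
  rownames(coords) <- rownames(mat)

  # deterministic 2-means: initialise at the farthest pair of samples
  dm <- as.matrix(dist(coords))
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  centers <- coords[c(far[1], far[2]), , drop = FALSE]
  km <- kmeans(coords, centers = centers)
  cl <- km$cluster

  pct <- burdens$pct_lgt[match(rownames(mat), burdens$sample_id)]
  if (anyNA(pct))
    stop_config("burdens are missing for some samples in the matrix")
  m1 <- mean(pct[cl == 1]); m2 <- mean(pct[cl == 2])
  group <- if (m2 >= m1) cl else 3L - cl
  gm <- c(mean(pct[group == 1]), mean(pct[group == 2]))
  structure(list(coordinates = coords,
                 group = setNames(as.integer(group), rownames(mat)),
                 fold_difference = gm[2] / gm[1],
                 group_means = setNames(gm, c("group1", "group2"))),
            class = "lgt_mds")
}

#' @export
print.lgt_mds <- function(x, ...) {
  n <- table(x$group)
  cat(sprintf(
    "MDS grouping: group 1 n=%d (mean %.4g%%), group 2 n=%d (mean %.4g%%); fold difference %.3g\n",
    n[["1"]], x$group_means[1], n[["2"]], x$group_means[2],
    x$fold_difference))
  invisible(x)
}

#' @export
plot.lgt_mds <- function(x, ...) {
  graphics::plot(x$coordinates, col = x$group, pch = 19,
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = "MDS of genus-level LGT counts", ...)
  graphics::legend("topright", legend = c("group 1", "group 2"),
                   col = 1:2, pch = 19, bty = "n")
  invisible(x)
}

#' Heat-map of the genus count matrix (cosmetic helper)
#'
#' @param mat genus count matrix.
#' @param n_genera number of top genera to display.
#' @param ... passed to [graphics::image()].
#' @return The displayed (log-damped) matrix, invisibly.
#' @export
plot_genus_heatmap <- function(mat, n_genera = 20L, ...) {
  m <- log2(top_genera(mat, n_genera) + 1)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "genus", ylab = "sample", axes = FALSE,
                  main = "LGT events per genus (log2 counts)", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(m)
}
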