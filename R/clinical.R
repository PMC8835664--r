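# Survival and categorical-marker association of LGT groupings.
#
# Survival machinery (product-limit estimate, log-rank test) is delegated
# to the survival package; the maximally selected cutpoint scan and the
# association report are implemented here.

#' Kaplan-Meier (product-limit) survival estimate
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return Data frame of class \code{lgt_km}: \code{time} (ascending unique
#'   follow-up times), \code{n_risk}, \code{n_event}, \code{surv}
#'   (non-increasing, starting from 1 before the first time).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_config("km_estimate() needs at least one subject")
  if (any(times < 0)) stop_config("negative survival times")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survfit(Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("lgt_km", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' @param group two-level group labels.
#' @param times,events survival data as in [km_estimate()].
#' @return List: \code{chisq} (the sum over event times of
#'   \eqn{(O-E)^2/V}), \code{df} (1), \code{p} (two-sided, from
#'   chi-square(1)).
#' @export
logrank_test <- function(group, times, events) {
  g <- as.factor(group)
  if (nlevels(g) != 2L)
    stop_config("logrank_test() needs exactly two groups, got %d", nlevels(g))
  if (sum(events) < 1) stop_config("logrank_test() needs at least one event")
  sd <- survdiff(Surv(times, events) ~ g)
  list(chisq = unname(sd$chisq), df = 1L,
       p = pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Maximally selected survival cutpoint on LGT burden
#'
#' Scans every midpoint between consecutive sorted unique burden values
#' whose induced low/high split leaves at least \code{min_group_frac} of
#' subjects on each side, computes the two-group log-rank statistic at
#' each, and returns the cutoff maximising it (ties resolved toward the
#' smaller cutoff). This is the standard maximally-selected-statistic
#' operationalisation of a regression-derived cutoff; being a rank-based
#' scan, the selected split is invariant to monotone transforms of the
#' burden.
#'
#' @param values per-subject burden (e.g. \code{pct_lgt}).
#' @param times,events survival data.
#' @param min_group_frac minimum fraction of subjects per side (default
#'   0.1).
#' @return List of class \code{lgt_cutpoint}: \code{cutoff}, \code{n_low},
#'   \code{n_high}, \code{statistic} (log-rank chi-square at the cutoff),
#'   \code{p} (unadjusted), \code{scan} (data frame of every admissible
#'   cutoff and its statistic).
#' @export
cox_cutpoint <- function(values, times, events, min_group_frac = 0.1) {
  n <- length(values)
  if (n < 10L) stop_config("cox_cutpoint() needs at least 10 subjects")
  stopifnot(length(times) == n, length(events) == n)
  u <- sort(unique(values))
  if (length(u) < 2L) stop_config("no admissible split: all values tied")
  cuts <- (u[-1] + u[-length(u)]) / 2
  min_n <- max(1L, ceiling(min_group_frac * n))
  adm <- vapply(cuts, function(cc) {
    nl <- sum(values < cc)
    nl >= min_n && (n - nl) >= min_n
  }, logical(1))
  cuts <- cuts[adm]
  if (!length(cuts)) stop_config("no admissible split under min_group_frac")
  stat <- vapply(cuts, function(cc) {
    logrank_test(values < cc, times, events)$chisq
  }, numeric(1))
  best <- which.max(stat)  # which.max takes the first, i.e. smaller cutoff
  cutoff <- cuts[best]
  structure(list(cutoff = cutoff,
                 n_low = sum(values < cutoff),
                 n_high = sum(values >= cutoff),
                 statistic = stat[best],
                 p = pchisq(stat[best], 1L, lower.tail = FALSE),
                 scan = data.frame(cutoff = cuts, chisq = stat)),
            class = "lgt_cutpoint")
}

#' @export
print.lgt_cutpoint <- function(x, ...) {
  cat(sprintf(
    "Maximally selected cutpoint: %.6g (low n=%d, high n=%d), log-rank chisq %.4g (unadjusted p %.4g)\n",
    x$cutoff, x$n_low, x$n_high, x$statistic, x$p))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return Two-sided p-value.
#' @examples
#' fisher_2x2(5, 0, 0, 5)  # 2/choose(10, 5)
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_config("fisher_2x2() needs non-negative integer counts")
  if (sum(cells) == 0) stop_config("all-zero table")
  fisher.test(matrix(cells, 2L, byrow = TRUE))$p.value
}

#' Pearson's chi-squared test for a contingency table
#'
#' Statistic \eqn{\sum (O-E)^2/E} without continuity correction; p from
#' chi-square with (r-1)(c-1) degrees of freedom.
#'
#' @param table matrix of non-negative counts (at least 2x2).
#' @return List: \code{statistic}, \code{df}, \code{p}.
#' @export
chisq_contingency <- function(table) {
  if (!is.matrix(table) || nrow(table) < 2L || ncol(table) < 2L)
    stop_config("chisq_contingency() needs at least a 2x2 matrix")
  if (sum(table) == 0) stop_config("all-zero table")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

CLINICAL_BINARY_MARKERS <- c(ighv_mutated = "yes", del11q = "yes",
                             del17q = "yes", tri12 = "yes", del13q = "yes",
                             cd38 = "high")

#' Associate an LGT grouping with clinical markers and survival
#'
#' For each binary marker (IGHV mutation, del11q, del17q, tri12, del13q,
#' CD38) a 2x2 table against the grouping is tested with a two-sided
#' Fisher's exact test; RAI stage against the grouping with Pearson's
#' chi-squared; OS and PFS are compared between groups by Kaplan-Meier
#' estimation and a log-rank test, both for the supplied grouping and for
#' the low/high dichotomy at the maximally selected burden cutpoint of each
#' endpoint. Subjects with a missing value are dropped for that marker only
#' and counted in the report. Raw per-marker p-values are reported; a
#' Benjamini-Hochberg column is added alongside for transparency.
#'
#' @param grouping an \code{lgt_mds} (or a named vector of 1/2 labels).
#' @param clinical clinical data frame (see [read_clinical_tsv()]).
#' @param burdens optional burden data frame; when given, burden cutpoint
#'   dichotomies for OS and PFS are included.
#' @return Object of class \code{lgt_assoc}: \code{markers} (data frame of
#'   marker tests), \code{survival} (list of per-comparison log-rank
#'   results with KM curves), \code{cutpoints} (per endpoint, when burdens
#'   were given), \code{n_dropped} (named vector of NA-dropped counts).
#' @export
associate_groups <- function(grouping, clinical, burdens = NULL) {
  group <- if (inherits(grouping, "lgt_mds")) grouping$group else grouping
  common <- intersect(names(group), clinical$sample_id)
  if (!length(common))
    stop_config("no overlapping samples between grouping and clinical table")
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  g <- group[common]

  markers <- list()
  n_dropped <- integer(0)
  for (m in names(CLINICAL_BINARY_MARKERS)) {
    v <- cl[[m]]
    ok <- !is.na(v) & v != "NA"
    n_dropped[m] <- sum(!ok)
    if (sum(ok) == 0L) next  # marker entirely missing: skipped, logged
    pos <- CLINICAL_BINARY_MARKERS[[m]]
    tab <- table(factor(v[ok] == pos, levels = c(TRUE, FALSE)),
                 factor(g[ok], levels = c(1L, 2L)))
    markers[[m]] <- data.frame(
      marker = m, test = "fisher",
      n = sum(ok),
      p = fisher_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      stringsAsFactors = FALSE)
  }
  ok <- !is.na(cl$rai_stage) & cl$rai_stage != "NA"
  n_dropped["rai_stage"] <- sum(!ok)
  if (sum(ok) > 0L && length(unique(cl$rai_stage[ok])) >= 2L) {
    tab <- table(factor(g[ok], levels = c(1L, 2L)), cl$rai_stage[ok])
    markers[["rai_stage"]] <- data.frame(
      marker = "rai_stage", test = "chisq", n = sum(ok),
      p = chisq_contingency(tab)$p, stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, markers)
  if (!is.null(markers)) {
    markers$p_bh <- p.adjust(markers$p, method = "BH")
    rownames(markers) <- NULL
  }

  surv_out <- list()
  for (ep in c("os", "pfs")) {
    tm <- cl[[paste0(ep, "_time")]]
    evt <- cl[[paste0(ep, "_event")]]
    ok <- !is.na(tm) & !is.na(evt)
    if (sum(evt[ok]) >= 1 && length(unique(g[ok])) == 2L) {
      lr <- logrank_test(g[ok], tm[ok], evt[ok])
      surv_out[[ep]] <- list(
        logrank = lr,
        km = lapply(split(seq_along(tm[ok]), g[ok]), function(i)
          km_estimate(tm[ok][i], evt[ok][i])))
    }
  }

  cutpoints <- NULL
  if (!is.null(burdens)) {
    pct <- burdens$pct_lgt[match(common, burdens$sample_id)]
    cutpoints <- list()
    for (ep in c("os", "pfs")) {
      tm <- cl[[paste0(ep, "_time")]]
      evt <- cl[[paste0(ep, "_event")]]
      ok <- !is.na(tm) & !is.na(evt) & !is.na(pct)
      cp <- try(cox_cutpoint(pct[ok], tm[ok], evt[ok]), silent = TRUE)
      if (!inherits(cp, "try-error")) {
        dich <- ifelse(pct[ok] < cp$cutoff, "low", "high")
        cutpoints[[ep]] <- list(
          cutpoint = cp,
          logrank = logrank_test(dich, tm[ok], evt[ok]))
      }
    }
  }

  structure(list(markers = markers, survival = surv_out,
                 cutpoints = cutpoints, n_dropped = n_dropped,
                 n_samples = length(common)),
            class = "lgt_assoc")
}

#' @export
print.lgt_assoc <- function(x, ...) {
  cat(sprintf("Clinical association over %d samples\n", x$n_samples))
  if (!is.null(x$markers)) {
    cat("Marker tests (raw and BH-adjusted p):\n")
    print(x$markers, row.names = FALSE, digits = 4)
  }
  for (ep in names(x$survival))
    cat(sprintf("  %s log-rank: chisq %.4g, p %.4g\n", toupper(ep),
                x$survival[[ep]]$logrank$chisq, x$survival[[ep]]$logrank$p))
  if (!is.null(x$cutpoints)) {
    for (ep in names(x$cutpoints))
      cat(sprintf("  %s burden cutpoint %.6g: log-rank p %.4g\n",
                  toupper(ep), x$cutpoints[[ep]]$cutpoint$cutoff,
                  x$cutpoints[[ep]]$logrank$p))
  }
  if (any(x$n_dropped > 0)) {
    d <- x$n_dropped[x$n_dropped > 0]
    cat(sprintf("  NA subjects dropped per marker: %s\n",
                paste(names(d), d, sep = "=", collapse = ", ")))
  }
  invisible(x)
}
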