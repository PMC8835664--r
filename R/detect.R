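# LGT detection: realignment of half-mapped pairs to bacterial references,
# the exclusivity rule, the filtering cascade and junction deduplication.

#' Detect LGT candidate pairs among half-mapped pairs
#'
#' Realigns both mates of every half-mapped pair to the bacterial reference
#' set. A pair becomes a candidate iff the host-unmapped mate maps to a
#' bacterial reference AND the host-mapped mate maps to no bacterial
#' reference — the two-sided exclusivity rule: one mate exclusively host,
#' one mate exclusively bacterial, with the putative junction lying in the
#' unsequenced insert between them.
#'
#' @param half an extraction result from [extract_half_mapped()].
#' @param bact_refs named character vector of bacterial references.
#' @param genus_map data frame with columns \code{accession}, \code{genus}.
#' @param params an [aligner_params()].
#' @param sample_id sample identifier stamped on candidates.
#' @return A candidate data frame (possibly 0-row) with host- and
#'   bacterial-hit coordinates, genus, mate sequences and an attribute
#'   \code{counts} recording the \code{bacterial_mapped} and
#'   \code{exclusive} tallies.
#' @export
detect_candidates <- function(half, bact_refs, genus_map,
                              params = aligner_params(),
                              sample_id = "sample") {
  pairs <- half$pairs
  n <- nrow(pairs)
  free_seq <- ifelse(half$host_mate_index == 1L, pairs$mate2, pairs$mate1)
  host_seq <- ifelse(half$host_mate_index == 1L, pairs$mate1, pairs$mate2)
  if (n == 0L) {
    out <- empty_candidates()
    attr(out, "counts") <- c(bacterial_mapped = 0L, exclusive = 0L)
    return(out)
  }
  free_hit <- align_batch(free_seq, bact_refs, params)
  host_mate_bact <- align_batch(host_seq, bact_refs, params)
  bacterial_mapped <- sum(free_hit$mapped)
  is_cand <- free_hit$mapped & !host_mate_bact$mapped
  idx <- which(is_cand)
  acc <- free_hit$ref_id[idx]
  genus <- genus_map$genus[match(acc, genus_map$accession)]
  if (anyNA(genus))
    stop_config("bacterial accession(s) missing from genus metadata: %s",
                paste(unique(acc[is.na(genus)]), collapse = ", "))
  hh <- half$host_hit[idx, , drop = FALSE]
  out <- data.frame(
    sample_id = rep(sample_id, length(idx)), pair_id = pairs$pair_id[idx],
    host_mate_index = half$host_mate_index[idx],
    host_chrom = hh$ref_id, host_start = hh$start, host_end = hh$end,
    host_strand = hh$strand, host_aligned = hh$aligned_read_bases,
    host_score = hh$score,
    bact_accession = acc, bact_genus = genus,
    bact_start = free_hit$start[idx], bact_end = free_hit$end[idx],
    bact_strand = free_hit$strand[idx],
    bact_aligned = free_hit$aligned_read_bases[idx],
    bact_score = free_hit$score[idx],
    host_mate_seq = host_seq[idx], bact_mate_seq = free_seq[idx],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- c(bacterial_mapped = bacterial_mapped,
                           exclusive = nrow(out))
  out
}

empty_candidates <- function() {
  data.frame(sample_id = character(), pair_id = character(),
             host_mate_index = integer(), host_chrom = character(),
             host_start = integer(), host_end = integer(),
             host_strand = character(), host_aligned = integer(),
             host_score = integer(), bact_accession = character(),
             bact_genus = character(), bact_start = integer(),
             bact_end = integer(), bact_strand = character(),
             bact_aligned = integer(), bact_score = integer(),
             host_mate_seq = character(), bact_mate_seq = character(),
             stringsAsFactors = FALSE)
}

#' Alignment-coverage filter
#'
#' A candidate is kept iff, for BOTH its host hit and its bacterial hit,
#' the fraction of read bases in match/mismatch columns is at least
#' \code{min_coverage} (default 0.90, i.e. reads with <90\% alignment
#' coverage are excluded).
#'
#' @param candidates candidate data frame from [detect_candidates()].
#' @param min_coverage minimum aligned-base fraction per mate.
#' @return Logical keep vector.
#' @export
filter_coverage <- function(candidates, min_coverage = 0.9) {
  host_cov <- candidates$host_aligned / nchar(candidates$host_mate_seq)
  bact_cov <- candidates$bact_aligned / nchar(candidates$bact_mate_seq)
  host_cov >= min_coverage & bact_cov >= min_coverage
}

#' Low-complexity read filter
#'
#' Drops a candidate iff either mate contains a homopolymer run of at least
#' \code{max_run} bases (long poly-A/-T/-G/-C stretches) or any single base
#' makes up more than \code{max_frac} of the mate.
#'
#' @param candidates candidate data frame.
#' @param max_run homopolymer run length triggering exclusion.
#' @param max_frac single-base composition fraction triggering exclusion
#'   (strictly greater than).
#' @return Logical keep vector.
#' @export
filter_low_complexity <- function(candidates, max_run = 20L,
                                  max_frac = 0.8) {
  keep1 <- !is_low_complexity(candidates$host_mate_seq, max_run, max_frac)
  keep2 <- !is_low_complexity(candidates$bact_mate_seq, max_run, max_frac)
  keep1 & keep2
}

is_low_complexity <- function(seqs, max_run = 20L, max_frac = 0.8) {
  if (!length(seqs)) return(logical(0))
  pat <- paste(sprintf("%s{%d}", c("A", "C", "G", "T"), max_run),
               collapse = "|")
  has_run <- grepl(pat, seqs)
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                      c("A", "C", "G", "T"))
  skewed <- apply(freq, 1L, max) / nchar(seqs) > max_frac
  has_run | skewed
}

#' Repeat-region overlap filter
#'
#' Flags a candidate iff its host hit interval overlaps any repeat interval
#' by at least one base (0-based half-open semantics: an interval ending
#' where a repeat starts does not overlap).
#'
#' @param candidates candidate data frame.
#' @param repeats repeat intervals (data frame \code{chrom}, \code{start},
#'   \code{end}).
#' @return Logical vector, \code{TRUE} where the candidate is flagged as
#'   repeat-overlapping.
#' @export
filter_repeat_overlap <- function(candidates, repeats) {
  n <- nrow(candidates)
  if (n == 0L || is.null(repeats) || nrow(repeats) == 0L)
    return(rep(FALSE, n))
  flagged <- rep(FALSE, n)
  for (chrom in unique(candidates$host_chrom)) {
    ci <- which(candidates$host_chrom == chrom)
    rr <- repeats[repeats$chrom == chrom, , drop = FALSE]
    if (!nrow(rr)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(candidates$host_start[ci] + 1L,
                       candidates$host_end[ci]),
      IRanges::IRanges(rr$start + 1L, rr$end))
    flagged[ci[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  flagged
}

#' Deduplicate junctions into LGT events
#'
#' Junction key: (host_chrom, host_start, bact_accession, bact_start) —
#' integrations of the same bacterial region at the same genomic position
#' count once; the representative candidate is the first in pair-id
#' lexicographic order. Output is sorted by key. Idempotent.
#'
#' @param candidates candidate data frame (one sample).
#' @return Event data frame with the standard event columns (gene_name and
#'   region_class are \code{"."} until annotation).
#' @export
dedup_junctions <- function(candidates) {
  if (nrow(candidates) == 0L) {
    ev <- empty_candidates()
    ev$gene_name <- character(0)
    ev$region_class <- character(0)
    return(ev[, EVENT_COLUMNS])
  }
  ord <- order(candidates$host_chrom, candidates$host_start,
               candidates$bact_accession, candidates$bact_start,
               candidates$pair_id, method = "radix")
  x <- candidates[ord, , drop = FALSE]
  key <- paste(x$host_chrom, x$host_start, x$bact_accession, x$bact_start,
               sep = "\r")
  keep <- !duplicated(key)
  ev <- x[keep, , drop = FALSE]
  ev$gene_name <- "."
  ev$region_class <- "."
  rownames(ev) <- NULL
  ev[, EVENT_COLUMNS]
}

#' Run the full LGT detection cascade on one sample
#'
#' Composes host alignment and half-mapped extraction, bacterial
#' realignment with the exclusivity rule, the coverage, low-complexity and
#' repeat filters, and junction deduplication. Per-stage counters are
#' recorded in a filter report.
#'
#' @param x input reads: an \code{lgt_sample}, a pair data frame
#'   (\code{pair_id}, \code{mate1}, \code{mate2}), or a length-2 character
#'   vector of FASTQ paths (R1, R2).
#' @param references an \code{lgt_references} (host, bacterial, genus_map,
#'   repeats).
#' @param params an [aligner_params()].
#' @param min_coverage minimum per-mate alignment coverage (default 0.90).
#' @param exclude_repeats drop repeat-flagged candidates (default TRUE);
#'   when FALSE candidates are only flagged.
#' @param sample_id sample identifier; defaults to the sample's own id or
#'   \code{"sample"}.
#' @return An object of class \code{lgt_detection}: \code{events} (event
#'   data frame), \code{report} (named integer vector of stage counters),
#'   \code{candidates} (pre-dedup candidates with filter flags),
#'   \code{sample_id}, \code{total_pairs}.
#' @examples
#' cfg <- sim_config(seed = 11, n_pairs_per_sample = 300,
#'                   host_length = 20000, n_host_genes = 3,
#'                   n_bacterial_refs = 4, lgt_rate = 0.02)
#' refs <- generate_references(cfg)
#' det <- run_detection(simulate_sample(cfg, refs, "S1"), refs)
#' det$report
#' @export
run_detection <- function(x, references, params = aligner_params(),
                          min_coverage = 0.9, exclude_repeats = TRUE,
                          sample_id = NULL) {
  stopifnot(inherits(references, "lgt_references"))
  if (inherits(x, "lgt_sample")) {
    pairs <- x$pairs
    sample_id <- sample_id %||% x$sample_id
  } else if (is.data.frame(x)) {
    pairs <- x
    sample_id <- sample_id %||% "sample"
  } else if (is.character(x) && length(x) == 2L) {
    pairs <- read_fastq_pairs(x[1], x[2])
    sample_id <- sample_id %||% sub("_R1.*$", "", basename(x[1]))
  } else {
    stop_config("unsupported input type for run_detection()")
  }

  report <- c(input_pairs = nrow(pairs))
  half <- extract_half_mapped(pairs, references$host, params)
  report["half_mapped"] <- nrow(half$pairs)

  cand <- detect_candidates(half, references$bacterial, references$genus_map,
                            params, sample_id = sample_id)
  cnt <- attr(cand, "counts")
  report["bacterial_mapped"] <- cnt[["bacterial_mapped"]]
  report["exclusive"] <- cnt[["exclusive"]]

  keep_cov <- filter_coverage(cand, min_coverage)
  cand$coverage_pass <- keep_cov
  cand2 <- cand[keep_cov, , drop = FALSE]
  report["coverage_pass"] <- nrow(cand2)

  keep_cpx <- filter_low_complexity(cand2)
  cand2$complexity_pass <- keep_cpx
  cand3 <- cand2[keep_cpx, , drop = FALSE]
  report["complexity_pass"] <- nrow(cand3)

  flagged <- filter_repeat_overlap(cand3, references$repeats)
  cand3$repeat_flagged <- flagged
  cand4 <- if (exclude_repeats) cand3[!flagged, , drop = FALSE] else cand3
  report["repeat_pass"] <- nrow(cand4)

  events <- dedup_junctions(cand4)
  report["deduplicated"] <- nrow(events)

  structure(list(events = events, report = report, candidates = cand3,
                 fate_counts = half$fate_counts, sample_id = sample_id,
                 total_pairs = nrow(pairs)),
            class = "lgt_detection")
}

#' @export
print.lgt_detection <- function(x, ...) {
  cat(sprintf("LGT detection for sample '%s': %d events from %d read pairs\n",
              x$sample_id, nrow(x$events), x$total_pairs))
  cat("Filter cascade:\n")
  for (nm in names(x$report))
    cat(sprintf("  %-16s %d\n", nm, x$report[[nm]]))
  invisible(x)
}

#' @export
summary.lgt_detection <- function(object, ...) {
  ev <- object$events
  cat(sprintf("Sample '%s': %d unique LGT events (%.3g%% of %d pairs)\n",
              object$sample_id, nrow(ev),
              100 * nrow(ev) / object$total_pairs, object$total_pairs))
  if (nrow(ev)) {
    cat("Events per genus:\n")
    print(sort(table(ev$bact_genus), decreasing = TRUE))
  }
  invisible(object)
}
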