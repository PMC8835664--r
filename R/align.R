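# Alignment module: parameters, batch alignment against a reference set,
# pair-fate classification and half-mapped pair extraction.

#' Parameters of the built-in seed-and-extend local aligner
#'
#' Defaults follow common short-read local-alignment practice: 15-mer exact
#' seeds, +1 match, -4 mismatch, affine gaps (a gap of length g scores
#' \code{gap_open + g * gap_extend}), and a mapped threshold of 30. A read
#' shorter than \code{seed_k} is unmapped by definition.
#'
#' @param seed_k exact-seed k-mer length (>= 8).
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0); N bases always score as mismatches.
#' @param gap_open gap opening score (< 0).
#' @param gap_extend gap extension score (< 0).
#' @param min_score minimum local alignment score to call a read mapped.
#' @return An object of class \code{aligner_params}.
#' @export
aligner_params <- function(seed_k = 15L, match = 1L, mismatch = -4L,
                           gap_open = -6L, gap_extend = -1L,
                           min_score = 30L) {
  check_number(seed_k, "seed_k", min = 8, max = 32, integer = TRUE)
  check_number(match, "match", min = 1, integer = TRUE)
  check_number(mismatch, "mismatch", max = -1, integer = TRUE)
  check_number(gap_open, "gap_open", max = 0, integer = TRUE)
  check_number(gap_extend, "gap_extend", max = -1, integer = TRUE)
  check_number(min_score, "min_score", min = 1, integer = TRUE)
  structure(list(seed_k = as.integer(seed_k), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score)),
            class = "aligner_params")
}

#' Align a batch of reads against a reference set
#'
#' For each read, both strands are seeded with exact k-mers and candidate
#' loci extended under affine-gap local scoring; the single best (primary)
#' hit is reported when its score reaches \code{min_score}. Ties break
#' deterministically: highest score, then lexicographically smallest
#' reference id, then smallest start, then \code{+} strand. Reported
#' intervals are 0-based half-open on the forward reference strand and
#' never cross a reference boundary.
#'
#' @param reads character vector of read sequences.
#' @param references named character vector of reference sequences.
#' @param params an [aligner_params()].
#' @return Data frame with one row per read: \code{mapped}, \code{ref_id},
#'   \code{start}, \code{end}, \code{strand}, \code{aligned_read_bases},
#'   \code{score}.
#' @examples
#' ref <- c(chrT = paste(rep("ACGTTGCA", 50), collapse = ""))
#' align_batch(substr(ref, 101, 180), ref, aligner_params())
#' @export
align_batch <- function(reads, references, params = aligner_params()) {
  stopifnot(inherits(params, "aligner_params"))
  if (length(references) == 0L)
    stop_config("empty reference set")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop_config("references must be named")
  cpp_align_batch(as.character(reads), unname(as.character(references)),
                  names(references), params$seed_k, params$match,
                  params$mismatch, params$gap_open, params$gap_extend,
                  params$min_score)
}

#' Align a single mate, returning a primary hit or an unmapped record
#'
#' @param sequence read sequence (single string).
#' @param references named character vector of reference sequences.
#' @param params an [aligner_params()].
#' @param read_id,mate_index identifiers carried into the hit record.
#' @return A one-row data frame as in [align_batch()], with \code{read_id}
#'   and \code{mate_index} prepended and \code{is_primary = TRUE}.
#' @export
align_mate <- function(sequence, references, params = aligner_params(),
                       read_id = "read", mate_index = 1L) {
  hit <- align_batch(sequence, references, params)
  cbind(data.frame(read_id = read_id, mate_index = as.integer(mate_index),
                   stringsAsFactors = FALSE),
        hit, data.frame(is_primary = TRUE))
}

#' Classify the fate of a read pair against one reference set
#'
#' Derived solely from the primary-hit mapped status of the two mates;
#' secondary/supplementary alignments are never consulted.
#'
#' @param mapped1,mapped2 logical vectors (or hit data frames with a
#'   \code{mapped} column) for mate 1 and mate 2.
#' @return Character vector over \code{"BOTH"}, \code{"MATE1_ONLY"},
#'   \code{"MATE2_ONLY"}, \code{"NEITHER"}.
#' @export
classify_pair_fate <- function(mapped1, mapped2) {
  if (is.data.frame(mapped1)) mapped1 <- mapped1$mapped
  if (is.data.frame(mapped2)) mapped2 <- mapped2$mapped
  stopifnot(is.logical(mapped1), is.logical(mapped2),
            length(mapped1) == length(mapped2))
  ifelse(mapped1 & mapped2, "BOTH",
         ifelse(mapped1, "MATE1_ONLY",
                ifelse(mapped2, "MATE2_ONLY", "NEITHER")))
}

#' Extract half-mapped pairs from a pair table
#'
#' Aligns both mates of every pair to the host reference set and keeps
#' exactly the pairs with fate \code{MATE1_ONLY} or \code{MATE2_ONLY},
#' retaining the host-side hit.
#'
#' @param pairs data frame with \code{pair_id}, \code{mate1}, \code{mate2}.
#' @param host_refs named character vector (host reference set).
#' @param params an [aligner_params()].
#' @return A list: \code{pairs} (the retained rows of the input),
#'   \code{host_hit} (hit data frame for the host-mapped mate),
#'   \code{host_mate_index} (1 or 2 per retained pair), \code{fate_counts}
#'   (named integer vector over the four fates).
#' @export
extract_half_mapped <- function(pairs, host_refs, params = aligner_params()) {
  hit1 <- align_batch(pairs$mate1, host_refs, params)
  hit2 <- align_batch(pairs$mate2, host_refs, params)
  fate <- classify_pair_fate(hit1$mapped, hit2$mapped)
  fate_counts <- table(factor(fate, levels = c("BOTH", "MATE1_ONLY",
                                               "MATE2_ONLY", "NEITHER")))
  keep <- fate %in% c("MATE1_ONLY", "MATE2_ONLY")
  host_mate_index <- ifelse(fate[keep] == "MATE1_ONLY", 1L, 2L)
  host_hit <- hit1[keep, , drop = FALSE]
  m2 <- which(host_mate_index == 2L)
  host_hit[m2, ] <- hit2[keep, , drop = FALSE][m2, ]
  rownames(host_hit) <- NULL
  list(pairs = pairs[keep, , drop = FALSE],
       host_hit = host_hit,
       host_mate_index = host_mate_index,
       fate_counts = setNames(as.integer(fate_counts), names(fate_counts)))
}

#' Read pair fates from a SAM file
#'
#' Thin import path for substituting an external aligner: accepts a
#' coordinate-unsorted SAM of paired reads and derives per-pair mate mapped
#' status from the FLAG field. Supplementary records (flag 2048) are
#' discarded; flag 4 marks the record's own mate unmapped and flag 8 the
#' other mate unmapped, matching the usual extraction semantics.
#'
#' @param path SAM file path.
#' @return Data frame with \code{pair_id}, \code{mate1_mapped},
#'   \code{mate2_mapped}, \code{fate}.
#' @export
read_sam_fates <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) stop_config("SAM file '%s' has no alignment records", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  keep <- bitwAnd(flag, 2048L) == 0L  # drop supplementary records
  qname <- qname[keep]; flag <- flag[keep]
  first <- bitwAnd(flag, 64L) != 0L
  self_mapped <- bitwAnd(flag, 4L) == 0L
  ids <- unique(qname)
  m1 <- m2 <- setNames(rep(NA, length(ids)), ids)
  m1[qname[first]] <- self_mapped[first]
  m2[qname[!first]] <- self_mapped[!first]
  if (anyNA(m1) || anyNA(m2))
    stop_config("SAM file '%s' is missing a mate record for some pairs", path)
  data.frame(pair_id = ids, mate1_mapped = unname(m1),
             mate2_mapped = unname(m2),
             fate = classify_pair_fate(unname(m1), unname(m2)),
             stringsAsFactors = FALSE)
}
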