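# Gene and gene-structure annotation of LGT events.
#
# Classification is anchored at the midpoint of the host-side interval and
# returns exactly one region class per event. Overlapping genes are
# resolved by a fixed precedence (exonic first, intergenic last), then by
# alphabetical gene name.

REGION_PRECEDENCE <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                       "ncRNA_exonic", "ncRNA_intronic", "upstream",
                       "downstream", "intergenic")

#' Annotate one genomic position against a single gene model
#'
#' Returns the region class of \code{pos} relative to the gene, or
#' \code{NA} when the position is farther than the upstream/downstream
#' window from the transcript. UTR classes are strand-aware (a position
#' before the CDS on the coding strand is UTR5). Positions in an intron of
#' a coding gene within \code{splice_window} bases of an exon boundary are
#' \code{splicing}. Genes without a CDS yield the \code{ncRNA_} classes.
#'
#' @param pos 0-based position.
#' @param gene one-row slice of a gene model data frame.
#' @param flank_window upstream/downstream window in bp (default 1000).
#' @param splice_window intronic distance from an exon boundary classified
#'   as splicing (default 2).
#' @return A region class string or \code{NA_character_}.
#' @keywords internal
classify_position_gene <- function(pos, gene, flank_window = 1000L,
                                   splice_window = 2L) {
  ex_s <- gene$exon_starts[[1]]
  ex_e <- gene$exon_ends[[1]]
  coding <- gene$cds_start != gene$cds_end
  if (pos >= gene$tx_start && pos < gene$tx_end) {
    in_exon <- any(pos >= ex_s & pos < ex_e)
    if (in_exon) {
      if (!coding) return("ncRNA_exonic")
      if (pos < gene$cds_start)
        return(if (gene$strand == "+") "UTR5" else "UTR3")
      if (pos >= gene$cds_end)
        return(if (gene$strand == "+") "UTR3" else "UTR5")
      return("exonic")
    }
    # intronic; exon boundaries adjacent to this intron are the ends of the
    # previous exon and the start of the next
    if (!coding) return("ncRNA_intronic")
    d_prev <- pos - max(ex_e[ex_e <= pos]) # 0 means first intron base
    d_next <- min(ex_s[ex_s > pos]) - pos - 1L
    if (min(d_prev, d_next) < splice_window) return("splicing")
    return("intronic")
  }
  if (gene$strand == "+") {
    if (pos >= gene$tx_start - flank_window && pos < gene$tx_start)
      return("upstream")
    if (pos >= gene$tx_end && pos < gene$tx_end + flank_window)
      return("downstream")
  } else {
    if (pos >= gene$tx_end && pos < gene$tx_end + flank_window)
      return("upstream")
    if (pos >= gene$tx_start - flank_window && pos < gene$tx_start)
      return("downstream")
  }
  NA_character_
}

#' Annotate LGT events with gene and region class
#'
#' The midpoint of each event's host interval is classified against every
#' gene model on its chromosome; the winning (gene, class) pair is chosen
#' by region-class precedence (exonic > splicing > UTR5 > UTR3 > intronic >
#' ncRNA_exonic > ncRNA_intronic > upstream > downstream), then by
#' alphabetical gene name. Events hitting no gene within the flank window
#' are \code{intergenic} with gene name \code{"."}.
#'
#' @param events event data frame (host_chrom, host_start, host_end).
#' @param genes gene model data frame (see [read_gene_models()]).
#' @param flank_window,splice_window see [classify_position_gene()].
#' @return The event data frame with \code{gene_name} and
#'   \code{region_class} filled in.
#' @export
annotate_events <- function(events, genes, flank_window = 1000L,
                            splice_window = 2L) {
  if (nrow(events) == 0L) return(events)
  mid <- (events$host_start + events$host_end) %/% 2L
  ann <- vapply(seq_len(nrow(events)), function(i) {
    annotate_position(mid[i], events$host_chrom[i], genes,
                      flank_window, splice_window)
  }, character(2))
  events$gene_name <- ann[1, ]
  events$region_class <- ann[2, ]
  events
}

# Best (gene, class) for one position; returns c(gene_name, region_class).
annotate_position <- function(pos, chrom, genes, flank_window = 1000L,
                              splice_window = 2L) {
  best <- c(".", "intergenic")
  best_rank <- match("intergenic", REGION_PRECEDENCE)
  if (nrow(genes)) {
    gi <- which(genes$chrom == chrom &
                  pos >= genes$tx_start - flank_window &
                  pos < genes$tx_end + flank_window)
    for (g in gi) {
      cls <- classify_position_gene(pos, genes[g, , drop = FALSE],
                                    flank_window, splice_window)
      if (is.na(cls)) next
      rank <- match(cls, REGION_PRECEDENCE)
      if (rank < best_rank ||
          (rank == best_rank && genes$gene_name[g] < best[1])) {
        best <- c(genes$gene_name[g], cls)
        best_rank <- rank
      }
    }
  }
  best
}

#' Region-class distribution of annotated events
#'
#' @param events annotated event data frame.
#' @return Named numeric vector of fractions over the observed region
#'   classes, summing to 1 (empty for an empty event set).
#' @examples
#' ev <- data.frame(region_class = c("intronic", "intronic", "exonic"))
#' region_distribution(ev)
#' @export
region_distribution <- function(events) {
  if (nrow(events) == 0L) return(setNames(numeric(0), character(0)))
  tab <- table(factor(events$region_class, levels = REGION_PRECEDENCE))
  tab <- tab[tab > 0]
  out <- as.numeric(tab) / nrow(events)
  setNames(out, names(tab))
}

#' Per-gene patient recurrence across cohorts
#'
#' For every gene hit by at least one event, the percentage of distinct
#' patients per cohort with at least one event in that gene (a patient
#' counts once per gene regardless of event count). Intergenic events
#' (gene \code{"."}) are excluded.
#'
#' @param events annotated event data frame (with \code{sample_id}).
#' @param cohorts data frame \code{sample_id}, \code{cohort}; cohort labels
#'   are typically \code{"CLL"} and \code{"healthy"}. Every cohort sample
#'   counts in the denominator, with or without events.
#' @param top_n keep the top \code{top_n} genes by descending first-cohort
#'   percentage, alphabetical tie-break (default 30; \code{Inf} for all).
#' @return Data frame \code{gene_name} plus one \code{pct_<cohort>} column
#'   per cohort.
#' @export
gene_recurrence <- function(events, cohorts, top_n = 30L) {
  stopifnot(all(c("sample_id", "cohort") %in% names(cohorts)))
  cohort_names <- unique(cohorts$cohort)
  ev <- events[events$gene_name != ".", , drop = FALSE]
  ev$cohort <- cohorts$cohort[match(ev$sample_id, cohorts$sample_id)]
  genes <- sort(unique(ev$gene_name))
  out <- data.frame(gene_name = genes, stringsAsFactors = FALSE)
  for (co in cohort_names) {
    denom <- sum(cohorts$cohort == co)
    sub <- ev[!is.na(ev$cohort) & ev$cohort == co, , drop = FALSE]
    hits <- tapply(sub$sample_id, sub$gene_name,
                   function(s) length(unique(s)))
    n_pat <- as.integer(hits[genes])
    n_pat[is.na(n_pat)] <- 0L
    out[[paste0("pct_", co)]] <-
      if (denom > 0) 100 * n_pat / denom else rep(0, length(genes))
  }
  first <- paste0("pct_", cohort_names[1])
  out <- out[order(-out[[first]], out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}
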