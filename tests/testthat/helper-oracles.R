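# Independent oracles used to check pipeline computations. These are kept
# deliberately naive (loops, enumeration, external reference
# implementations) and share no code with the package internals.

# --- alignment: full Smith-Waterman via Biostrings ------------------------
# Gap of length g costs |gap_open| + g * |gap_extend| in both conventions.
sw_oracle_score <- function(read, ref, params) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  s_fwd <- Biostrings::pairwiseAlignment(
    read, ref, type = "local", substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    scoreOnly = TRUE)
  s_rev <- Biostrings::pairwiseAlignment(
    revcomp_chr(read), ref, type = "local", substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    scoreOnly = TRUE)
  max(s_fwd, s_rev)
}

# Plant a (possibly mutated) substring of ref into a read and return both;
# substitution positions are spaced so an exact seed_k-mer survives.
plant_read <- function(ref, read_len, n_sub, seed_k) {
  pos <- sample.int(nchar(ref) - read_len + 1L, 1L)
  read <- substr(ref, pos, pos + read_len - 1L)
  if (n_sub > 0) {
    repeat {
      at <- sort(sample.int(read_len, n_sub))
      gaps <- diff(c(0L, at, read_len + 1L)) - 1L
      if (max(gaps) >= seed_k) break
    }
    s <- strsplit(read, "")[[1]]
    for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    read <- paste(s, collapse = "")
  }
  read
}

# --- filters: brute-force per-candidate recomputation ---------------------
oracle_coverage_keep <- function(cand_row, min_coverage) {
  hc <- cand_row$host_aligned / nchar(cand_row$host_mate_seq)
  bc <- cand_row$bact_aligned / nchar(cand_row$bact_mate_seq)
  (hc >= min_coverage) && (bc >= min_coverage)
}

oracle_lowcomplex_drop_one <- function(seq, max_run, max_frac) {
  s <- strsplit(seq, "")[[1]]
  run <- 1L; longest <- 1L
  for (i in seq_along(s)[-1]) {
    run <- if (s[i] == s[i - 1L]) run + 1L else 1L
    longest <- max(longest, run)
  }
  comp <- max(table(factor(s, levels = c("A", "C", "G", "T")))) / length(s)
  longest >= max_run || comp > max_frac
}

oracle_lowcomplex_keep <- function(cand_row, max_run = 20L, max_frac = 0.8) {
  !oracle_lowcomplex_drop_one(cand_row$host_mate_seq, max_run, max_frac) &&
    !oracle_lowcomplex_drop_one(cand_row$bact_mate_seq, max_run, max_frac)
}

oracle_repeat_flag <- function(cand_row, repeats) {
  flag <- FALSE
  for (j in seq_len(nrow(repeats))) {
    if (repeats$chrom[j] == cand_row$host_chrom &&
        cand_row$host_start < repeats$end[j] &&
        repeats$start[j] < cand_row$host_end) flag <- TRUE
  }
  flag
}

# --- dedup: set-based junction count --------------------------------------
oracle_unique_junctions <- function(cand) {
  length(unique(paste(cand$host_chrom, cand$host_start,
                      cand$bact_accession, cand$bact_start, sep = "|")))
}

# --- annotation: exhaustive position-set containment ----------------------
# Expands each gene into explicit position sets and classifies by
# membership, then applies the precedence order over all genes.
oracle_annotate <- function(pos, genes, flank = 1000L, splice = 2L) {
  precedence <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                  "ncRNA_exonic", "ncRNA_intronic", "upstream",
                  "downstream", "intergenic")
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    ex <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                     genes$exon_starts[[i]], genes$exon_ends[[i]]))
    tx <- seq.int(genes$tx_start[i], genes$tx_end[i] - 1L)
    coding <- genes$cds_start[i] != genes$cds_end[i]
    strand <- genes$strand[i]
    cls <- NULL
    if (pos %in% ex) {
      if (!coding) cls <- "ncRNA_exonic"
      else if (pos < genes$cds_start[i])
        cls <- if (strand == "+") "UTR5" else "UTR3"
      else if (pos >= genes$cds_end[i])
        cls <- if (strand == "+") "UTR3" else "UTR5"
      else cls <- "exonic"
    } else if (pos %in% tx) {
      near <- FALSE
      for (b in c(genes$exon_ends[[i]])) # first intron bases after an exon
        if (pos - b >= 0 && pos - b < splice) near <- TRUE
      for (b in c(genes$exon_starts[[i]])) # last intron bases before an exon
        if (b - 1L - pos >= 0 && b - 1L - pos < splice) near <- TRUE
      if (!coding) cls <- "ncRNA_intronic"
      else cls <- if (near) "splicing" else "intronic"
    } else {
      up <- if (strand == "+")
        seq.int(genes$tx_start[i] - flank, genes$tx_start[i] - 1L)
      else seq.int(genes$tx_end[i], genes$tx_end[i] + flank - 1L)
      dn <- if (strand == "+")
        seq.int(genes$tx_end[i], genes$tx_end[i] + flank - 1L)
      else seq.int(genes$tx_start[i] - flank, genes$tx_start[i] - 1L)
      if (pos %in% up) cls <- "upstream"
      else if (pos %in% dn) cls <- "downstream"
    }
    if (!is.null(cls))
      hits[[length(hits) + 1L]] <- c(genes$gene_name[i], cls)
  }
  if (!length(hits)) return(c(".", "intergenic"))
  ranks <- vapply(hits, function(h) match(h[2], precedence), integer(1))
  best <- which(ranks == min(ranks))
  names_best <- vapply(hits[best], `[`, character(1), 1L)
  hits[best][[order(names_best)[1]]]
}

# --- statistics -----------------------------------------------------------
oracle_t_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

# two-sided Fisher p by full hypergeometric enumeration (fixed margins);
# same relative tolerance for "as extreme" as the standard definition
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat,
       p = pchisq(stat, (nrow(tab) - 1) * (ncol(tab) - 1),
                  lower.tail = FALSE))
}

# hand product-limit estimator
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# direct sum over event times of (O-E)^2 / V
oracle_logrank_chisq <- function(group, times, events) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exhaustive cutpoint scan using survival::survdiff directly
oracle_cutpoint <- function(values, times, events, min_group_frac = 0.1) {
  u <- sort(unique(values))
  cuts <- (u[-1] + u[-length(u)]) / 2
  min_n <- max(1L, ceiling(min_group_frac * length(values)))
  best <- NULL
  for (cc in cuts) {
    low <- values < cc
    if (sum(low) < min_n || sum(!low) < min_n) next
    sd <- survival::survdiff(survival::Surv(times, events) ~ low)
    if (is.null(best) || sd$chisq > best$chisq + 1e-12)
      best <- list(cutoff = cc, chisq = sd$chisq)
  }
  best
}

# Exhaustive whole-chromosome annotation map: per gene, position sets for
# every class are materialised vectorially, then merged across genes by
# precedence (ties to the alphabetically smaller gene). Position i of the
# returned vectors corresponds to 0-based coordinate i - 1.
oracle_annotation_map <- function(genes, chrom_len, flank = 1000L,
                                  splice = 2L) {
  precedence <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                  "ncRNA_exonic", "ncRNA_intronic", "upstream",
                  "downstream", "intergenic")
  best_rank <- rep.int(match("intergenic", precedence), chrom_len)
  best_gene <- rep.int(".", chrom_len)
  best_cls <- rep.int("intergenic", chrom_len)
  clip <- function(p) p[p >= 0 & p < chrom_len]
  for (i in seq_len(nrow(genes))) {
    ex <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                     genes$exon_starts[[i]], genes$exon_ends[[i]]))
    tx <- seq.int(genes$tx_start[i], genes$tx_end[i] - 1L)
    intr <- setdiff(tx, ex)
    coding <- genes$cds_start[i] != genes$cds_end[i]
    strand <- genes$strand[i]
    sets <- list()
    if (coding) {
      before <- ex[ex < genes$cds_start[i]]
      after <- ex[ex >= genes$cds_end[i]]
      sets[[if (strand == "+") "UTR5" else "UTR3"]] <- before
      sets[[if (strand == "+") "UTR3" else "UTR5"]] <- after
      sets[["exonic"]] <- setdiff(ex, c(before, after))
      spl <- intr[vapply(intr, function(p) {
        any(p - genes$exon_ends[[i]] >= 0 & p - genes$exon_ends[[i]] < splice) ||
          any(genes$exon_starts[[i]] - 1L - p >= 0 &
                genes$exon_starts[[i]] - 1L - p < splice)
      }, logical(1))]
      sets[["splicing"]] <- spl
      sets[["intronic"]] <- setdiff(intr, spl)
    } else {
      sets[["ncRNA_exonic"]] <- ex
      sets[["ncRNA_intronic"]] <- intr
    }
    left <- seq.int(genes$tx_start[i] - flank, genes$tx_start[i] - 1L)
    right <- seq.int(genes$tx_end[i], genes$tx_end[i] + flank - 1L)
    sets[[if (strand == "+") "upstream" else "downstream"]] <- clip(left)
    sets[[if (strand == "+") "downstream" else "upstream"]] <- clip(right)
    for (cls in names(sets)) {
      p <- sets[[cls]]
      if (!length(p)) next
      r <- match(cls, precedence)
      at <- p + 1L
      win <- r < best_rank[at] |
        (r == best_rank[at] & genes$gene_name[i] < best_gene[at])
      at <- at[win]
      best_rank[at] <- r
      best_gene[at] <- genes$gene_name[i]
      best_cls[at] <- cls
    }
  }
  list(gene = best_gene, class = best_cls)
}
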