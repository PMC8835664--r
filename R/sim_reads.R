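# Read-pair simulation with planted ground truth.
#
# Each pair belongs to one truth class: host (both mates from the host),
# bacterial (both mates from one bacterial reference), lgt (one mate host,
# one mate bacterial, flanking a planted junction inside the unsequenced
# insert), lowcomplex (one homopolymer mate, one host mate) or duplicate
# (byte-copy of an lgt pair from the same sample). Planted LGT host
# positions avoid repeat intervals so every planted junction is in
# detectable, unmasked sequence; the repeat filter's behaviour is exercised
# on constructed candidates instead.

#' Simulate one paired-end RNA-seq sample with planted LGT junctions
#'
#' Draws the truth class of each pair from the configured rates, builds
#' fragments of truncated-normal length (resampled until at least twice the
#' read length, so the junction of an LGT pair always falls in the
#' unsequenced insert), cuts the two mates from the fragment ends (mate 2
#' reverse-complemented), applies per-base substitution errors, and returns
#' the reads together with a truth table recording, for every LGT pair, the
#' planted junction and the exact placement of both mates.
#'
#' The whole host locus is treated as expressed, unspliced transcript
#' sequence: mates are contiguous substrings of the references.
#'
#' @param config a [sim_config()].
#' @param references an \code{lgt_references} from [generate_references()].
#' @param sample_id sample identifier (used in pair ids).
#' @param n_pairs optional override of \code{config$n_pairs_per_sample}.
#' @param lgt_rate optional override of \code{config$lgt_rate} (used by the
#'   cohort generator for group-2 samples).
#' @param seed optional override of the derived per-sample seed.
#' @return A list of class \code{lgt_sample}: \code{sample_id},
#'   \code{pairs} (data frame \code{pair_id}, \code{mate1}, \code{mate2})
#'   and \code{truth} (one row per pair; \code{truth_class}, planted
#'   junction coordinates and mate placements, \code{duplicate_of}).
#' @examples
#' cfg <- sim_config(seed = 3, n_pairs_per_sample = 200, host_length = 20000,
#'                   n_host_genes = 3, n_bacterial_refs = 4)
#' refs <- generate_references(cfg)
#' smp <- simulate_sample(cfg, refs, "S01")
#' table(smp$truth$truth_class)
#' @export
simulate_sample <- function(config, references, sample_id,
                            n_pairs = NULL, lgt_rate = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(references, "lgt_references"))
  n <- as.integer(n_pairs %||% config$n_pairs_per_sample)
  p_lgt <- lgt_rate %||% config$lgt_rate
  id_hash <- sum(utf8ToInt(sample_id) * seq_len(nchar(sample_id))) %% 65521
  seed <- seed %||% derive_seed(config$seed, 100L + id_hash)
  L <- config$read_length
  host <- unname(references$host)
  host_chrom <- names(references$host)
  bact <- references$bacterial

  with_seed(seed, {
    probs <- c(host = 1 - p_lgt - config$microbiome_rate -
                 config$duplicate_rate - config$lowcomplexity_rate,
               lgt = p_lgt, bacterial = config$microbiome_rate,
               lowcomplex = config$lowcomplexity_rate,
               duplicate = config$duplicate_rate)
    classes <- sample(names(probs), n, replace = TRUE, prob = probs)
    # a duplicate needs an lgt pair in the same sample to copy
    if (any(classes == "duplicate") && !any(classes == "lgt"))
      classes[which(classes == "duplicate")[1]] <- "lgt"

    frag_len <- draw_fragment_lengths(n, config)
    pair_id <- sprintf("%s:p%07d", sample_id, seq_len(n))
    mate1 <- character(n); mate2 <- character(n)
    truth <- data.frame(
      pair_id = pair_id, truth_class = classes,
      host_chrom = NA_character_, junction_host_pos = NA_integer_,
      bact_accession = NA_character_, junction_bact_pos = NA_integer_,
      host_mate_index = NA_integer_,
      host_mate_start = NA_integer_, host_mate_end = NA_integer_,
      bact_mate_start = NA_integer_, bact_mate_end = NA_integer_,
      duplicate_of = NA_character_, stringsAsFactors = FALSE)

    ## host pairs: fragment fully inside the host sequence
    idx <- which(classes == "host")
    if (length(idx)) {
      st <- floor(runif(length(idx)) * (nchar(host) - frag_len[idx] + 1))
      m <- cut_mates(host, st, frag_len[idx], L)
      mate1[idx] <- m$mate1; mate2[idx] <- m$mate2
    }

    ## bacterial ("microbiome") pairs: fragment inside one bacterial ref
    idx <- which(classes == "bacterial")
    if (length(idx)) {
      ref_i <- sample.int(length(bact), length(idx), replace = TRUE)
      st <- floor(runif(length(idx)) *
                    (nchar(bact[ref_i]) - frag_len[idx] + 1))
      m <- cut_mates_multi(bact, ref_i, st, frag_len[idx], L)
      mate1[idx] <- m$mate1; mate2[idx] <- m$mate2
      truth$bact_accession[idx] <- names(bact)[ref_i]
    }

    ## lgt pairs: chimeric fragment host-part + bacterial-part
    idx <- which(classes == "lgt")
    if (length(idx)) {
      lg <- build_lgt_pairs(idx, frag_len[idx], host, host_chrom, bact, L,
                            references$repeats)
      mate1[idx] <- lg$mate1; mate2[idx] <- lg$mate2
      for (col in c("host_chrom", "junction_host_pos", "bact_accession",
                    "junction_bact_pos", "host_mate_index",
                    "host_mate_start", "host_mate_end",
                    "bact_mate_start", "bact_mate_end"))
        truth[[col]][idx] <- lg$truth[[col]]
    }

    ## low-complexity artifacts: one homopolymer mate, one host mate
    idx <- which(classes == "lowcomplex")
    if (length(idx)) {
      st <- floor(runif(length(idx)) * (nchar(host) - L + 1))
      host_mate <- substring(host, st + 1, st + L)
      homo <- strrep(sample(c("A", "C", "G", "T"), length(idx),
                            replace = TRUE), L)
      which1 <- runif(length(idx)) < 0.5
      mate1[idx] <- ifelse(which1, host_mate, homo)
      mate2[idx] <- ifelse(which1, homo,
                           as.character(reverse_complement(host_mate)))
      truth$host_mate_index[idx] <- ifelse(which1, 1L, 2L)
    }

    ## sequencing errors on every non-homopolymer mate
    if (config$error_rate > 0) {
      skip2 <- classes == "lowcomplex" & truth$host_mate_index == 1L
      skip1 <- classes == "lowcomplex" & truth$host_mate_index == 2L
      mate1[!skip1] <- inject_errors(mate1[!skip1], config$error_rate)
      mate2[!skip2] <- inject_errors(mate2[!skip2], config$error_rate)
    }

    ## duplicates: byte-copies of a random lgt pair (errors included)
    idx <- which(classes == "duplicate")
    if (length(idx)) {
      lgt_idx <- which(classes == "lgt")
      src <- lgt_idx[sample.int(length(lgt_idx), length(idx), replace = TRUE)]
      mate1[idx] <- mate1[src]; mate2[idx] <- mate2[src]
      keep <- c("host_chrom", "junction_host_pos", "bact_accession",
                "junction_bact_pos", "host_mate_index", "host_mate_start",
                "host_mate_end", "bact_mate_start", "bact_mate_end")
      truth[idx, keep] <- truth[src, keep]
      truth$duplicate_of[idx] <- pair_id[src]
    }

    structure(list(sample_id = sample_id,
                   pairs = data.frame(pair_id = pair_id, mate1 = mate1,
                                      mate2 = mate2,
                                      stringsAsFactors = FALSE),
                   truth = truth),
              class = "lgt_sample")
  })
}

# Truncated-normal fragment lengths, resampled until >= 2 * read_length and
# short enough to fit the smallest reference.
draw_fragment_lengths <- function(n, config) {
  lo <- 2L * config$read_length
  hi <- min(config$bacterial_length, config$host_length) - 1L
  f <- round(rnorm(n, config$insert_mean, config$insert_sd))
  bad <- which(f < lo | f > hi)
  while (length(bad)) {
    f[bad] <- round(rnorm(length(bad), config$insert_mean, config$insert_sd))
    bad <- bad[f[bad] < lo | f[bad] > hi]
  }
  as.integer(f)
}

# Cut the two mates from fragments of one reference string. st is 0-based.
cut_mates <- function(ref, st, frag_len, L) {
  fwd <- substring(ref, st + 1, st + L)
  rev <- reverse_complement(substring(ref, st + frag_len - L + 1,
                                      st + frag_len))
  list(mate1 = fwd, mate2 = rev)
}

cut_mates_multi <- function(refs, ref_i, st, frag_len, L) {
  fwd <- substring(refs[ref_i], st + 1, st + L)
  rev <- reverse_complement(substring(refs[ref_i], st + frag_len - L + 1,
                                      st + frag_len))
  list(mate1 = fwd, mate2 = rev)
}

# Build chimeric LGT fragments. The host part always precedes the bacterial
# part in the fragment; a per-pair mate swap randomises whether mate 1 or
# mate 2 carries the host sequence. Host-side placement is resampled until
# the host mate avoids every repeat interval.
build_lgt_pairs <- function(idx, frag_len, host, host_chrom, bact, L,
                            repeats) {
  k <- length(idx)
  host_len <- nchar(host)
  h_len <- L + floor(runif(k) * (frag_len - 2L * L + 1))
  b_len <- frag_len - h_len
  # junction position on the host (end of the host part, 0-based)
  hpos <- integer(k)
  for (i in seq_len(k)) {
    repeat {
      p <- h_len[i] + sample.int(host_len - h_len[i], 1L) - 1L
      m_start <- p - h_len[i]          # host mate covers [m_start, m_start+L)
      if (!overlaps_any(m_start, m_start + L, repeats)) break
    }
    hpos[i] <- p
  }
  ref_i <- sample.int(length(bact), k, replace = TRUE)
  bpos <- vapply(seq_len(k), function(i)
    sample.int(nchar(bact[ref_i[i]]) - b_len[i], 1L) - 1L, integer(1))

  host_part <- substring(host, hpos - h_len + 1, hpos)
  bact_part <- substring(bact[ref_i], bpos + 1, bpos + b_len)
  frag <- paste0(host_part, bact_part)
  m1 <- substring(frag, 1, L)                       # host side, forward
  m2 <- reverse_complement(substring(frag, frag_len - L + 1, frag_len))

  swap <- runif(k) < 0.5
  mate1 <- ifelse(swap, m2, m1)
  mate2 <- ifelse(swap, m1, m2)
  list(mate1 = mate1, mate2 = mate2,
       truth = data.frame(
         host_chrom = host_chrom,
         junction_host_pos = hpos,
         bact_accession = names(bact)[ref_i],
         junction_bact_pos = bpos,
         host_mate_index = ifelse(swap, 2L, 1L),
         host_mate_start = hpos - h_len,
         host_mate_end = hpos - h_len + L,
         bact_mate_start = bpos + b_len - L,
         bact_mate_end = bpos + b_len,
         stringsAsFactors = FALSE))
}

overlaps_any <- function(start, end, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(FALSE)
  any(intervals$start < end & start < intervals$end)
}

# Vectorised substitution errors: per-read error counts are binomial, error
# positions uniform, substituted base drawn from the three alternatives.
inject_errors <- function(seqs, rate) {
  if (!length(seqs) || rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' @export
print.lgt_sample <- function(x, ...) {
  tab <- table(x$truth$truth_class)
  cat(sprintf("Synthetic sample '%s': %d read pairs (%s)\n", x$sample_id,
              nrow(x$pairs),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a simulated sample as paired FASTQ plus truth table
#'
#' @param sample an \code{lgt_sample} from [simulate_sample()].
#' @param dir output directory; files are named
#'   \code{<sample_id>_R1.fastq}, \code{<sample_id>_R2.fastq} and
#'   \code{<sample_id>_truth.tsv}.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "lgt_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- file.path(dir, paste0(sample$sample_id, "_R1.fastq"))
  r2 <- file.path(dir, paste0(sample$sample_id, "_R2.fastq"))
  tt <- file.path(dir, paste0(sample$sample_id, "_truth.tsv"))
  write_fastq_pairs(sample$pairs, r1, r2)
  write.table(sample$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(r1 = r1, r2 = r2, truth = tt))
}
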