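# On-disk formats. All internal coordinates are 0-based half-open
# (BED-native); nothing in this file converts coordinate systems except the
# FASTA/FASTQ substring helpers in the simulator, which work 1-based as R's
# substring does.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; record order is preserved. Duplicate ids and
#' empty files are format errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop_config("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop_config("duplicate FASTA ids in '%s': %s", path,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(x))
  names(out) <- ids
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

strip_mate_suffix <- function(ids) sub("/[12]$", "", ids)

#' Read paired FASTQ files into a pair table
#'
#' Mate ids must match after stripping \code{/1} and \code{/2} suffixes
#' (bare duplicated ids are also accepted); a count or id mismatch is a
#' format error. Base qualities are ignored by the pipeline and therefore
#' not retained.
#'
#' @param path_r1,path_r2 FASTQ files for mate 1 and mate 2.
#' @return Data frame with columns \code{pair_id}, \code{mate1}, \code{mate2}.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- Biostrings::readDNAStringSet(path_r1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path_r2, format = "fastq")
  if (length(r1) != length(r2))
    stop_config("mate file record counts differ: %d vs %d",
                length(r1), length(r2))
  id1 <- strip_mate_suffix(sub("\\s.*$", "", names(r1)))
  id2 <- strip_mate_suffix(sub("\\s.*$", "", names(r2)))
  if (!identical(id1, id2)) {
    bad <- which(id1 != id2)[1]
    stop_config("mate id mismatch at record %d: '%s' vs '%s'",
                bad, id1[bad], id2[bad])
  }
  data.frame(pair_id = unname(id1),
             mate1 = unname(toupper(as.character(r1))),
             mate2 = unname(toupper(as.character(r2))),
             stringsAsFactors = FALSE)
}

#' Write a pair table as two FASTQ files
#'
#' Quality strings are constant \code{'I'}; mate ids carry \code{/1} and
#' \code{/2} suffixes.
#'
#' @param pairs data frame with \code{pair_id}, \code{mate1}, \code{mate2}.
#' @param path_r1,path_r2 output FASTQ paths.
#' @return Invisibly, \code{c(path_r1, path_r2)}.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_fastq_one(pairs$mate1, paste0(pairs$pair_id, "/1"), path_r1)
  write_fastq_one(pairs$mate2, paste0(pairs$pair_id, "/2"), path_r2)
  invisible(c(path_r1, path_r2))
}

write_fastq_one <- function(seqs, ids, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", qual)
  writeLines(rec, path)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' Coordinates stay 0-based half-open, matching the package's internal
#' convention. A strand column (column 6) is honoured when present,
#' otherwise strand is \code{"."}.
#'
#' @param path BED file path.
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop_config("BED file '%s' has fewer than 3 columns", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    strand = if (ncol(df) >= 6L) as.character(df[[6]]) else ".",
                    stringsAsFactors = FALSE)
  if (any(out$start < 0L) || any(out$start >= out$end))
    stop_config("BED file '%s' contains an interval with start >= end", path)
  out
}

#' Write intervals as BED
#' @param intervals data frame with \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{name}, \code{score}, \code{strand}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- data.frame(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$strand)) {
    cols$name <- intervals$name %||% "."
    cols$score <- 0L
    cols$strand <- intervals$strand
  }
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene model table
#'
#' Tab-separated with header columns \code{gene_name}, \code{chrom},
#' \code{strand}, \code{tx_start}, \code{tx_end}, \code{cds_start},
#' \code{cds_end}, \code{exon_starts}, \code{exon_ends} (comma-joined),
#' all 0-based half-open. A gene with \code{cds_start == cds_end} is
#' non-coding. Exons must be sorted, non-overlapping and contained in the
#' transcript; the CDS must be contained in the transcript.
#'
#' @param path TSV path.
#' @return Gene model data frame with list columns \code{exon_starts} and
#'   \code{exon_ends}.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(exon_starts = "character",
                                  exon_ends = "character"))
  df$exon_starts <- lapply(strsplit(df$exon_starts, ","), as.integer)
  df$exon_ends <- lapply(strsplit(df$exon_ends, ","), as.integer)
  validate_gene_models(df)
  df
}

validate_gene_models <- function(df) {
  for (i in seq_len(nrow(df))) {
    s <- df$exon_starts[[i]]; e <- df$exon_ends[[i]]
    g <- df$gene_name[i]
    if (length(s) != length(e) || length(s) == 0L)
      stop_config("gene '%s': exon start/end lists malformed", g)
    if (any(s >= e)) stop_config("gene '%s': exon with start >= end", g)
    if (is.unsorted(s, strictly = TRUE) || any(e[-length(e)] > s[-1]))
      stop_config("gene '%s': exons not sorted/non-overlapping", g)
    if (s[1] < df$tx_start[i] || e[length(e)] > df$tx_end[i])
      stop_config("gene '%s': exon outside transcript bounds", g)
    if (df$cds_start[i] != df$cds_end[i] &&
        (df$cds_start[i] < df$tx_start[i] || df$cds_end[i] > df$tx_end[i]))
      stop_config("gene '%s': CDS outside transcript bounds", g)
  }
  invisible(df)
}

#' Write a gene model table
#' @param genes gene model data frame (see [read_gene_models()]).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- genes
  out$exon_starts <- vapply(genes$exon_starts, paste, character(1),
                            collapse = ",")
  out$exon_ends <- vapply(genes$exon_ends, paste, character(1),
                          collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

EVENT_COLUMNS <- c("sample_id", "pair_id", "host_chrom", "host_start",
                   "host_end", "host_strand", "bact_accession", "bact_genus",
                   "bact_start", "bact_end", "gene_name", "region_class")

#' Write / read an LGT event table
#'
#' Columns: sample_id, pair_id, host_chrom, host_start, host_end,
#' host_strand, bact_accession, bact_genus, bact_start, bact_end, gene_name,
#' region_class. Reading back a written table reproduces it exactly.
#'
#' @param events event data frame.
#' @param path TSV path.
#' @return \code{path} (writer, invisibly) or the event data frame (reader).
#' @export
write_events_tsv <- function(events, path) {
  missing <- setdiff(EVENT_COLUMNS, names(events))
  for (m in missing) events[[m]] <- if (m %in% c("gene_name", "region_class"))
    "." else NA
  write.table(events[, EVENT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(host_chrom = "character",
                                  bact_accession = "character",
                                  gene_name = "character",
                                  region_class = "character"))
  df
}

#' Write / read a samples-by-genera count matrix
#' @param mat integer matrix with sample-id rownames and genus colnames.
#' @param path TSV path.
#' @return \code{path} (writer, invisibly) or the matrix (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  mat
}

#' Read / write a per-sample clinical table
#'
#' Columns: sample_id, os_time, os_event, pfs_time, pfs_event, ighv_mutated,
#' del11q, del17q, tri12, del13q, cd38, rai_stage. Missing values are
#' serialized as \code{NA}.
#'
#' @param clinical clinical data frame.
#' @param path TSV path.
#' @return \code{path} (writer, invisibly) or the clinical data frame
#'   (reader).
#' @export
write_clinical_tsv <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  rai_stage = "character"))
  if (any(df$os_time < 0, na.rm = TRUE) || any(df$pfs_time < 0, na.rm = TRUE))
    stop_config("clinical table '%s' contains negative survival times", path)
  df
}
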