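# Reference simulation: host chromosome with gene models and repeat
# intervals, plus a set of bacterial reference sequences with genus metadata.

# Genus pool for bacterial references; recycled so several accessions share
# a genus, as in real reference sets.
GENUS_POOL <- c("Pseudomonas", "Mesorhizobium", "Acinetobacter",
                "Sphingomonas", "Bradyrhizobium", "Streptococcus",
                "Escherichia", "Bacillus", "Staphylococcus",
                "Burkholderia", "Ralstonia", "Cutibacterium")

#' Generate synthetic host and bacterial references
#'
#' Builds a single host chromosome of length \code{host_length} with
#' \code{n_host_genes} non-overlapping gene models (each with at least two
#' exons; coding genes carry UTR5/UTR3 flanks inside their terminal exons, a
#' configurable fraction are non-coding), a repeat-interval track, and
#' \code{n_bacterial_refs} bacterial sequences each with a distinct accession
#' and an assigned genus. Base composition is i.i.d. with the configured GC
#' fraction. Fully deterministic given \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @return An object of class \code{lgt_references}: a list with elements
#'   \code{host} (named character vector of length 1), \code{genes} (gene
#'   model data frame, 0-based half-open coordinates, list columns
#'   \code{exon_starts}/\code{exon_ends}), \code{repeats} (BED-like data
#'   frame), \code{bacterial} (named character vector), \code{genus_map}
#'   (data frame accession -> genus).
#' @examples
#' refs <- generate_references(sim_config(seed = 1, host_length = 20000,
#'                                        n_host_genes = 4))
#' nchar(refs$host)
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    host <- random_dna(config$host_length, config$gc)
    genes <- place_gene_models(config)
    repeats <- place_repeats(config)
    bact <- vapply(seq_len(config$n_bacterial_refs),
                   function(i) random_dna(config$bacterial_length, config$gc),
                   character(1))
    acc <- sprintf("NC_9%05d.1", seq_len(config$n_bacterial_refs))
    names(bact) <- acc
    genus_map <- data.frame(
      accession = acc,
      genus = rep_len(GENUS_POOL, config$n_bacterial_refs),
      stringsAsFactors = FALSE)
    structure(list(host = c(chr1 = host), genes = genes, repeats = repeats,
                   bacterial = bact, genus_map = genus_map,
                   config = config),
              class = "lgt_references")
  })
}

# Lay out n non-overlapping gene models in equal slots along the host, with
# >= 1 kb clearance to the slot borders so intergenic space always exists.
place_gene_models <- function(config) {
  empty <- data.frame(gene_name = character(), chrom = character(),
                      strand = character(), tx_start = integer(),
                      tx_end = integer(), cds_start = integer(),
                      cds_end = integer(), stringsAsFactors = FALSE)
  empty$exon_starts <- list()
  empty$exon_ends <- list()
  n <- config$n_host_genes
  if (n == 0L) return(empty)
  slot <- config$host_length %/% n
  # smallest gene: 2 exons of 150 bp + 1 intron of 200 bp, plus 300 bp
  # clearance to each slot border
  if (slot < 500L + 2L * 300L)
    stop_config("cannot place %d non-overlapping gene models in %d bp",
                n, config$host_length)
  coding <- runif(n) >= config$noncoding_frac
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    slot_lo <- (i - 1L) * slot + 300L
    slot_hi <- i * slot - 300L
    avail <- slot_hi - slot_lo
    for (try in 1:50) {
      n_ex <- sample(2:4, 1L)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(200:600, n_ex - 1L, replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      if (span <= avail) break
    }
    if (span > avail) {  # fall back to the smallest admissible gene
      n_ex <- 2L; ex_len <- c(150L, 150L); in_len <- 200L
      span <- 500L
    }
    tx_start <- slot_lo + sample.int(avail - span + 1L, 1L) - 1L
    starts <- tx_start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    tx_end <- ends[n_ex]
    if (coding[i]) {
      u5 <- sample(40:(ex_len[1] - 40), 1L)
      u3 <- sample(40:(ex_len[n_ex] - 40), 1L)
      cds_start <- tx_start + u5
      cds_end <- tx_end - u3
    } else {
      cds_start <- cds_end <- tx_start  # empty CDS marks a non-coding gene
    }
    rows[[i]] <- list(gene_name = sprintf("GENE%03d", i), chrom = "chr1",
                      strand = sample(c("+", "-"), 1L),
                      tx_start = tx_start, tx_end = tx_end,
                      cds_start = cds_start, cds_end = cds_end,
                      exon_starts = starts, exon_ends = ends)
  }
  df <- data.frame(
    gene_name = vapply(rows, `[[`, character(1), "gene_name"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    tx_start = vapply(rows, `[[`, integer(1), "tx_start"),
    tx_end = vapply(rows, `[[`, integer(1), "tx_end"),
    cds_start = vapply(rows, `[[`, integer(1), "cds_start"),
    cds_end = vapply(rows, `[[`, integer(1), "cds_end"),
    stringsAsFactors = FALSE)
  df$exon_starts <- lapply(rows, `[[`, "exon_starts")
  df$exon_ends <- lapply(rows, `[[`, "exon_ends")
  df
}

place_repeats <- function(config) {
  n_rep <- max(1L, config$host_length %/% 20000L)
  len <- sample(200:500, n_rep, replace = TRUE)
  start <- vapply(len, function(l)
    sample.int(config$host_length - l, 1L) - 1L, integer(1))
  df <- data.frame(chrom = "chr1", start = start, end = start + len,
                   strand = ".", stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.lgt_references <- function(x, ...) {
  cat(sprintf(
    "Synthetic LGT references: host %s (%d bp, %d genes, %d repeat intervals); %d bacterial refs (%d genera)\n",
    names(x$host), nchar(x$host), nrow(x$genes), nrow(x$repeats),
    length(x$bacterial), length(unique(x$genus_map$genus))))
  invisible(x)
}

#' Write a reference set to disk
#'
#' Emits \code{host.fa}, \code{bacteria.fa}, \code{genes.tsv},
#' \code{repeats.bed} and \code{genus_map.tsv} under \code{dir}.
#'
#' @param refs an \code{lgt_references} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_references <- function(refs, dir) {
  stopifnot(inherits(refs, "lgt_references"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(refs$host, file.path(dir, "host.fa"))
  write_fasta(refs$bacterial, file.path(dir, "bacteria.fa"))
  write_gene_models(refs$genes, file.path(dir, "genes.tsv"))
  write_bed(refs$repeats, file.path(dir, "repeats.bed"))
  write.table(refs$genus_map, file.path(dir, "genus_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a reference set written by [write_references()]
#' @param dir directory containing the reference files.
#' @return An \code{lgt_references} object (without the generating config).
#' @export
read_references <- function(dir) {
  host <- read_fasta(file.path(dir, "host.fa"))
  bact <- read_fasta(file.path(dir, "bacteria.fa"))
  structure(list(
    host = host,
    genes = read_gene_models(file.path(dir, "genes.tsv")),
    repeats = read_bed(file.path(dir, "repeats.bed")),
    bacterial = bact,
    genus_map = read.table(file.path(dir, "genus_map.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE),
    config = NULL), class = "lgt_references")
}
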