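# Shared fixtures: one small reference set reused across test files.

small_config <- function(seed = 101L, ...) {
  args <- list(seed = seed, host_length = 30000L, n_host_genes = 6L,
               n_bacterial_refs = 6L, bacterial_length = 3000L,
               n_pairs_per_sample = 500L, lgt_rate = 0.02,
               microbiome_rate = 0.02, duplicate_rate = 0.002,
               lowcomplexity_rate = 0.002, error_rate = 0)
  do.call(sim_config, modifyList(args, list(...)))
}

.fixture_env <- new.env()

small_refs <- function() {
  if (is.null(.fixture_env$refs))
    .fixture_env$refs <- generate_references(small_config())
  .fixture_env$refs
}

# random DNA helper independent of the package's generator
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp_chr <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))
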