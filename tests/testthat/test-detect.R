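# Candidate detection, the filtering cascade and junction deduplication.

make_candidate <- function(host_seq = rand_seq(100), bact_seq = rand_seq(100),
                           host_aligned = 100L, bact_aligned = 100L,
                           host_start = 1000L, host_chrom = "chr1",
                           bact_start = 50L, pair_id = "p1",
                           bact_accession = "NC_900001.1") {
  data.frame(sample_id = "S", pair_id = pair_id, host_mate_index = 1L,
             host_chrom = host_chrom, host_start = host_start,
             host_end = host_start + 100L, host_strand = "+",
             host_aligned = host_aligned, host_score = host_aligned,
             bact_accession = bact_accession, bact_genus = "Pseudomonas",
             bact_start = bact_start, bact_end = bact_start + 100L,
             bact_strand = "-", bact_aligned = bact_aligned,
             bact_score = bact_aligned, host_mate_seq = host_seq,
             bact_mate_seq = bact_seq, stringsAsFactors = FALSE)
}

test_that("clean planted LGT pairs yield one candidate with the planted accession", {
  cfg <- small_config(seed = 88, n_pairs_per_sample = 300L, lgt_rate = 0.05,
                      duplicate_rate = 0, lowcomplexity_rate = 0)
  refs <- small_refs()
  smp <- simulate_sample(cfg, refs, "S1")
  half <- extract_half_mapped(smp$pairs, refs$host, aligner_params())
  cand <- detect_candidates(half, refs$bacterial, refs$genus_map,
                            sample_id = "S1")
  truth <- smp$truth[smp$truth$truth_class == "lgt", ]
  expect_setequal(cand$pair_id, truth$pair_id)
  m <- match(cand$pair_id, truth$pair_id)
  expect_equal(cand$bact_accession, truth$bact_accession[m])
  expect_equal(cand$host_start, truth$host_mate_start[m])
  expect_equal(cand$bact_start, truth$bact_mate_start[m])
})

test_that("exclusivity: a host mate that also maps to bacteria kills the candidate", {
  set.seed(9)
  # build tiny references sharing a homologous segment
  shared <- rand_seq(300)
  host <- c(chr1 = paste0(rand_seq(500), shared, rand_seq(500)))
  bact <- c(NC_1.1 = paste0(rand_seq(200), shared, rand_seq(200)),
            NC_2.1 = rand_seq(700))
  gm <- data.frame(accession = names(bact), genus = c("Ga", "Gb"))
  # host mate from the shared (homologous) region, free mate from NC_2.1
  pairs <- data.frame(pair_id = "h1",
                      mate1 = substr(host, 601, 700),
                      mate2 = revcomp_chr(substr(bact[["NC_2.1"]], 101, 200)),
                      stringsAsFactors = FALSE)
  half <- extract_half_mapped(pairs, host, aligner_params())
  expect_equal(nrow(half$pairs), 1L)
  cand <- detect_candidates(half, bact, gm)
  expect_equal(nrow(cand), 0L)  # host mate maps to NC_1.1 too -> excluded

  # control: host mate outside the shared region is kept
  pairs2 <- data.frame(pair_id = "h2",
                       mate1 = substr(host, 101, 200),
                       mate2 = revcomp_chr(substr(bact[["NC_2.1"]], 101, 200)),
                       stringsAsFactors = FALSE)
  half2 <- extract_half_mapped(pairs2, host, aligner_params())
  cand2 <- detect_candidates(half2, bact, gm)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$bact_accession, "NC_2.1")

  # free mate mapping nowhere bacterial -> no candidate
  pairs3 <- data.frame(pair_id = "h3",
                       mate1 = substr(host, 101, 200),
                       mate2 = rand_seq(100), stringsAsFactors = FALSE)
  half3 <- extract_half_mapped(pairs3, host, aligner_params())
  expect_equal(nrow(detect_candidates(half3, bact, gm)), 0L)
})

test_that("missing genus metadata is a configuration error", {
  cfg <- small_config(seed = 88, n_pairs_per_sample = 200L, lgt_rate = 0.05)
  refs <- small_refs()
  smp <- simulate_sample(cfg, refs, "S1")
  half <- extract_half_mapped(smp$pairs, refs$host, aligner_params())
  gm <- refs$genus_map[1:2, ]
  expect_error(detect_candidates(half, refs$bacterial, gm),
               "missing from genus metadata")
})

test_that("coverage filter applies the threshold to both mates", {
  expect_true(filter_coverage(make_candidate(host_aligned = 95L,
                                             bact_aligned = 95L)))
  expect_false(filter_coverage(make_candidate(host_aligned = 89L,
                                              bact_aligned = 100L)))
  expect_false(filter_coverage(make_candidate(host_aligned = 100L,
                                              bact_aligned = 89L)))
  expect_true(filter_coverage(make_candidate(host_aligned = 90L,
                                             bact_aligned = 90L)))
  # min_coverage = 0 keeps everything
  expect_true(filter_coverage(make_candidate(host_aligned = 1L,
                                             bact_aligned = 1L),
                              min_coverage = 0))
})

test_that("low-complexity filter drops homopolymer and skewed mates", {
  expect_false(filter_low_complexity(
    make_candidate(bact_seq = strrep("A", 100))))
  # 81 C's among 100 exceeds the 80% composition rule even without a run
  skew <- paste(sample(c(rep("C", 81), rep(c("A", "G", "T"), length.out = 19))),
                collapse = "")
  expect_false(filter_low_complexity(make_candidate(host_seq = skew)))
  set.seed(10)
  expect_true(all(filter_low_complexity(
    do.call(rbind, lapply(1:20, function(i) make_candidate())))))
  # run of exactly 20 inside an otherwise random read triggers exclusion
  seq20 <- paste0(rand_seq(40), strrep("G", 20), rand_seq(40))
  expect_false(filter_low_complexity(make_candidate(host_seq = seq20)))
  seq19 <- paste0(rand_seq(40), strrep("G", 19), rand_seq(41))
  expect_true(filter_low_complexity(make_candidate(host_seq = seq19)))
})

test_that("repeat overlap uses half-open semantics", {
  reps <- data.frame(chrom = "chr1", start = c(150L, 200L),
                     end = c(160L, 300L))
  c1 <- make_candidate(host_start = 100L)          # interval [100, 200)
  expect_true(filter_repeat_overlap(c1, reps[1, ]))   # overlaps [150,160)
  expect_false(filter_repeat_overlap(c1, reps[2, ]))  # adjacent [200,300)
  expect_false(filter_repeat_overlap(c1, reps[0, ]))  # empty set
  c2 <- make_candidate(host_start = 100L, host_chrom = "chr2")
  expect_false(filter_repeat_overlap(c2, reps))       # other chromosome
})

test_that("deduplication collapses identical junctions and is idempotent", {
  base <- make_candidate(pair_id = "p5")
  dups <- do.call(rbind, lapply(sprintf("p%d", 1:5), function(id) {
    x <- base; x$pair_id <- id; x
  }))
  ev <- dedup_junctions(dups)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pair_id, "p1")  # first in lexicographic pair order

  two <- rbind(make_candidate(pair_id = "a"),
               make_candidate(pair_id = "b", bact_accession = "NC_900002.1"))
  ev2 <- dedup_junctions(two)
  expect_equal(nrow(ev2), 2L)

  # idempotence: feeding events back through dedup changes nothing
  ev3 <- dedup_junctions(cbind(ev2,
    host_mate_index = 1L, host_aligned = 100L, host_score = 100L,
    bact_strand = "-", bact_aligned = 100L, bact_score = 100L,
    host_mate_seq = "A", bact_mate_seq = "C"))
  expect_equal(ev3[, c("host_chrom", "host_start", "bact_accession",
                       "bact_start")],
               ev2[, c("host_chrom", "host_start", "bact_accession",
                       "bact_start")])
})

test_that("filter decisions match brute-force recomputation on randomized candidates", {
  set.seed(11)
  n <- 400
  cands <- do.call(rbind, lapply(seq_len(n), function(i) {
    seq_type <- sample(c("random", "homo", "skew", "runny"), 1,
                       prob = c(0.7, 0.1, 0.1, 0.1))
    mk_seq <- function() switch(seq_type,
      random = rand_seq(100),
      homo = strrep(sample(c("A", "C", "G", "T"), 1), 100),
      skew = paste(sample(c(rep("C", sample(75:90, 1)), rep("A", 100)),
                          100), collapse = ""),
      runny = paste0(rand_seq(30), strrep("T", sample(15:25, 1)),
                     rand_seq(55)))
    make_candidate(host_seq = mk_seq(), bact_seq = mk_seq(),
                   host_aligned = sample(80:100, 1),
                   bact_aligned = sample(80:100, 1),
                   host_start = sample(0:2000, 1),
                   pair_id = sprintf("p%04d", i))
  }))
  reps <- data.frame(chrom = "chr1",
                     start = sort(sample(0:2000, 15)))
  reps$end <- reps$start + sample(20:200, 15, replace = TRUE)

  keep_cov <- filter_coverage(cands, 0.9)
  keep_cpx <- filter_low_complexity(cands)
  flag_rep <- filter_repeat_overlap(cands, reps)
  for (i in seq_len(n)) {
    expect_identical(keep_cov[i], oracle_coverage_keep(cands[i, ], 0.9))
    expect_identical(keep_cpx[i], oracle_lowcomplex_keep(cands[i, ]))
    expect_identical(flag_rep[i], oracle_repeat_flag(cands[i, ], reps))
  }
})

test_that("run_detection: no planted LGT and no errors means zero events", {
  cfg <- small_config(seed = 90, lgt_rate = 0, duplicate_rate = 0,
                      lowcomplexity_rate = 0, n_pairs_per_sample = 400L)
  refs <- small_refs()
  det <- run_detection(simulate_sample(cfg, refs, "S0"), refs)
  expect_equal(nrow(det$events), 0L)
  expect_true(all(diff(det$report[c("input_pairs", "half_mapped",
                                    "bacterial_mapped", "exclusive",
                                    "coverage_pass", "complexity_pass",
                                    "repeat_pass", "deduplicated")]) <= 0))
})

test_that("run_detection recovers planted junctions and reports a sane cascade", {
  cfg <- small_config(seed = 91, n_pairs_per_sample = 2000L,
                      lgt_rate = 0.03, duplicate_rate = 0.01)
  refs <- small_refs()
  smp <- simulate_sample(cfg, refs, "S1")
  det <- run_detection(smp, refs)
  truth <- smp$truth[smp$truth$truth_class == "lgt", ]
  truth_keys <- unique(paste(truth$host_mate_start, truth$bact_accession,
                             truth$bact_mate_start))
  event_keys <- paste(det$events$host_start, det$events$bact_accession,
                      det$events$bact_start)
  expect_gte(mean(truth_keys %in% event_keys), 0.95)
  # no event originates from a host-only or bacteria-only pair
  cls <- smp$truth$truth_class[match(det$events$pair_id, smp$truth$pair_id)]
  expect_true(all(cls %in% c("lgt", "duplicate")))
  # counters weakly decreasing along the cascade
  expect_true(all(diff(det$report) <= 0))
})
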