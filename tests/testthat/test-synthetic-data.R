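# Synthetic-data generator: determinism, configured rates, geometry.

test_that("identical configs give byte-identical references and reads", {
  cfg <- small_config(seed = 202)
  r1 <- generate_references(cfg)
  r2 <- generate_references(cfg)
  expect_identical(r1$host, r2$host)
  expect_identical(r1$bacterial, r2$bacterial)
  expect_identical(r1$repeats, r2$repeats)
  expect_identical(r1$genes, r2$genes)
  s1 <- simulate_sample(cfg, r1, "SX")
  s2 <- simulate_sample(cfg, r2, "SX")
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$truth, s2$truth)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(lgt_rate = 0.8, microbiome_rate = 0.3),
               "sum to at most 1")
  expect_error(sim_config(insert_mean = 150, read_length = 100),
               "insert_mean")
  expect_error(sim_config(lgt_rate = -0.1), "lgt_rate")
  # too many genes for the host
  expect_error(generate_references(sim_config(host_length = 2000,
                                              n_host_genes = 10)),
               "cannot place")
})

test_that("degenerate config: zero genes gives empty gene table, valid FASTA", {
  cfg <- small_config(n_host_genes = 0L)
  refs <- generate_references(cfg)
  expect_equal(nrow(refs$genes), 0L)
  expect_equal(unname(nchar(refs$host)), cfg$host_length)
  expect_true(grepl("^[ACGT]+$", refs$host))
  expect_gte(nrow(refs$repeats), 1L)
})

test_that("host base composition matches the configured GC within 3 sd", {
  cfg <- sim_config(seed = 7, host_length = 100000L, gc = 0.5)
  refs <- generate_references(cfg)
  gc_count <- sum(strsplit(refs$host, "")[[1]] %in% c("G", "C"))
  # binomial oracle for the i.i.d. base model
  expect_lt(abs(gc_count - cfg$host_length * cfg$gc),
            3 * sqrt(cfg$host_length * cfg$gc * (1 - cfg$gc)))
  cfg2 <- sim_config(seed = 7, host_length = 100000L, gc = 0.3)
  refs2 <- generate_references(cfg2)
  gc2 <- sum(strsplit(refs2$host, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc2 - cfg2$host_length * cfg2$gc),
            3 * sqrt(cfg2$host_length * cfg2$gc * (1 - cfg2$gc)))
})

test_that("truth classes follow the configured rates", {
  cfg <- small_config(seed = 33, n_pairs_per_sample = 10000L,
                      lgt_rate = 0.01, microbiome_rate = 0.02,
                      duplicate_rate = 0.005, lowcomplexity_rate = 0.005)
  refs <- small_refs()
  smp <- simulate_sample(cfg, refs, "S1")
  tab <- table(factor(smp$truth$truth_class,
                      levels = c("host", "lgt", "bacterial", "lowcomplex",
                                 "duplicate")))
  # binomial 99% interval around the expected lgt count of 100
  expect_gte(tab[["lgt"]], qbinom(0.005, 10000, 0.01))
  expect_lte(tab[["lgt"]], qbinom(0.995, 10000, 0.01))
  # chi-squared goodness of fit over all five classes
  p <- c(host = 1 - 0.04, lgt = 0.01, bacterial = 0.02,
         lowcomplex = 0.005, duplicate = 0.005)
  gof <- chisq.test(as.integer(tab), p = p[names(tab)])
  expect_gt(gof$p.value, 0.001)
})

test_that("pure-host config yields only host truth records", {
  cfg <- small_config(lgt_rate = 0, microbiome_rate = 0,
                      duplicate_rate = 0, lowcomplexity_rate = 0)
  smp <- simulate_sample(cfg, small_refs(), "S1")
  expect_true(all(smp$truth$truth_class == "host"))
})

test_that("duplicate pairs are byte-identical copies of their source", {
  cfg <- small_config(seed = 55, n_pairs_per_sample = 2000L,
                      lgt_rate = 0.02, duplicate_rate = 0.01,
                      error_rate = 0.005)
  smp <- simulate_sample(cfg, small_refs(), "S1")
  dup <- smp$truth[smp$truth$truth_class == "duplicate", ]
  expect_gt(nrow(dup), 0L)
  for (i in seq_len(nrow(dup))) {
    src <- which(smp$pairs$pair_id == dup$duplicate_of[i])
    cur <- which(smp$pairs$pair_id == dup$pair_id[i])
    expect_identical(smp$pairs$mate1[cur], smp$pairs$mate1[src])
    expect_identical(smp$pairs$mate2[cur], smp$pairs$mate2[src])
  }
  # planted junction present iff lgt or duplicate-of-lgt
  has_junc <- !is.na(smp$truth$junction_host_pos)
  expect_identical(has_junc,
                   smp$truth$truth_class %in% c("lgt", "duplicate"))
})

test_that("planted junctions lie within reference bounds and insert geometry holds", {
  cfg <- small_config(seed = 66, lgt_rate = 0.05, n_pairs_per_sample = 2000L)
  refs <- small_refs()
  smp <- simulate_sample(cfg, refs, "S1")
  tr <- smp$truth[smp$truth$truth_class == "lgt", ]
  expect_gt(nrow(tr), 0L)
  expect_true(all(tr$junction_host_pos >= 0 &
                    tr$junction_host_pos <= nchar(refs$host)))
  blen <- nchar(refs$bacterial)[tr$bact_accession]
  expect_true(all(tr$junction_bact_pos >= 0 & tr$junction_bact_pos < blen))
  # host mate ends at or before the junction; bacterial mate starts at or
  # after the bacterial junction position: junction in the unsequenced insert
  expect_true(all(tr$host_mate_end <= tr$junction_host_pos))
  expect_true(all(tr$bact_mate_start >= tr$junction_bact_pos))
  # every mate is a clean substring of its reference (error_rate = 0)
  for (i in head(seq_len(nrow(tr)), 5)) {
    host_mate <- ifelse(tr$host_mate_index[i] == 1L,
                        smp$pairs$mate1[smp$pairs$pair_id == tr$pair_id[i]],
                        smp$pairs$mate2[smp$pairs$pair_id == tr$pair_id[i]])
    expect_identical(unname(host_mate),
                     unname(substr(refs$host, tr$host_mate_start[i] + 1L,
                                   tr$host_mate_end[i])))
  }
})

test_that("cohort truth counts reflect the configured group fold", {
  cfg <- sim_config(seed = 12, n_pairs_per_sample = 100000L,
                    lgt_rate = 0.001, group2_lgt_fold = 2.8,
                    n_samples_group1 = 20L, n_samples_group2 = 20L)
  coh <- simulate_cohort(cfg, counts_only = TRUE)
  m <- tapply(coh$truth_counts$n_lgt, coh$truth_counts$group, mean)
  ratio <- m[["2"]] / m[["1"]]
  expect_gte(ratio, 2.4)
  expect_lte(ratio, 3.2)
})

test_that("equal-group config plants no group effect", {
  cfg <- small_config(group2_lgt_fold = 1, n_samples_group1 = 4L,
                      n_samples_group2 = 4L,
                      n_pairs_per_sample = 20000L, lgt_rate = 0.005)
  coh <- simulate_cohort(cfg, counts_only = TRUE)
  m <- tapply(coh$truth_counts$n_lgt, coh$truth_counts$group, mean)
  # no configured effect: means within sampling noise of each other
  expect_lt(abs(m[["2"]] - m[["1"]]),
            5 * sqrt(2 * 20000 * 0.005 / 4))
  expect_true(all(c("os_time", "pfs_time", "ighv_mutated", "rai_stage")
                  %in% names(coh$clinical)))
})

test_that("null hazard ratio gives uniform log-rank p over replicates", {
  cfg <- small_config(hazard_ratio_group2 = 1, n_samples_group1 = 20L,
                      n_samples_group2 = 20L)
  ps <- vapply(1:200, function(r) {
    cfg_r <- small_config(seed = 5000L + r, hazard_ratio_group2 = 1,
                          n_samples_group1 = 20L, n_samples_group2 = 20L)
    coh <- simulate_cohort(cfg_r, counts_only = TRUE)
    cl <- coh$clinical
    g <- coh$group[cl$sample_id]
    logrank_test(g, cl$os_time, cl$os_event)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("written sample round-trips through FASTQ", {
  cfg <- small_config(n_pairs_per_sample = 50L)
  smp <- simulate_sample(cfg, small_refs(), "RT")
  dir <- withr::local_tempdir()
  paths <- write_sample(smp, dir)
  back <- read_fastq_pairs(paths[["r1"]], paths[["r2"]])
  expect_identical(back, smp$pairs)
})
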