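test_that("primer location round-trips the simulator and flags orientation", {
  sim <- fx_sim_clean()
  pre <- preprocess_reads(sim_pairs(sim))
  ann <- locate_primers(pre$merged, sim$spec)
  ok <- is.na(ann$reason)
  expect_true(all(ok))
  tr <- sim$truth[match(ann$read_id, sim$truth$read_id), ]
  expect_identical(ann$fwd_umi, tr$fwd_umi)
  expect_identical(ann$rev_umi, tr$rev_umi)
  expect_identical(ann$insert, tr$true_insert)
  su <- sim$templates$synthetic_umi[match(tr$template_id,
                                          sim$templates$template_id)]
  expect_identical(ann$synthetic_umi, su)

  # a reverse-complemented read yields the same annotation, flagged
  rc1 <- locate_primers(revcomp(pre$merged$sequence[1]), sim$spec)
  expect_true(rc1$was_reverse_complemented)
  expect_identical(rc1$insert, ann$insert[1])
  expect_identical(rc1$fwd_umi, ann$fwd_umi[1])
})

test_that("primer mismatch budget and conserved-base checks reject reads", {
  sim <- fx_sim_clean()
  spec <- sim$spec
  tpl <- sim$templates$sequence[1]
  full <- paste0(spec$fwd_malbac, "ACGTACGT", tpl,
                 revcomp("TTTTCCCC"), revcomp(spec$rev_malbac))
  base <- locate_primers(full, spec)
  expect_true(is.na(base$reason))
  expect_equal(base$fwd_umi, "ACGTACGT")
  expect_equal(base$rev_umi, "TTTTCCCC")

  # 3 mismatches in the forward gene-specific region, budget 2
  gs_start <- nchar(spec$fwd_malbac) + spec$umi_length + 1
  mut <- full
  for (p in gs_start + c(1, 6, 11)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p, p))[1]
  }
  expect_equal(locate_primers(mut, spec)$reason, "no_primer")

  # conserved base adjacent to the forward UMI altered: structure failure
  cons <- full
  p <- nchar(spec$fwd_malbac)
  substr(cons, p, p) <- setdiff(c("A", "C", "G", "T"), substr(cons, p, p))[1]
  expect_equal(locate_primers(cons, spec)$reason, "barcode_structure")
})

test_that("UMI grouping is exact, lexicographic and conserving", {
  ann <- data.frame(
    read_id = c("a", "b", "c"),
    insert = c("AAA", "AAT", "CCC"),
    fwd_umi = c("AA", "AA", "CC"), rev_umi = c("BB", "BB", "DD"),
    synthetic_umi = NA, sample = NA, fwd_primer = "x", rev_primer = "y",
    was_reverse_complemented = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE)
  g <- group_by_umi(ann)
  expect_length(g, 2)
  expect_equal(vapply(g, function(x) length(x$sequences), numeric(1)),
               c(2, 1))
  expect_equal(sum(lengths(lapply(g, `[[`, "sequences"))), 3)
  expect_length(group_by_umi(ann[0, ]), 0)

  # loop-free, error-free simulation: one group per priming event
  cfg <- sim_config(n_templates = 25, loop_reamp_prob = 0,
                    sequencing_depth = 1200, seq_error_rate = 0,
                    qual_pass_fraction = 1, seed = 30)
  sim <- simulate_sumi_experiment(cfg)
  res <- sumi_process(sim_pairs(sim), sim$spec)
  observed_events <- length(unique(paste(sim$truth$fwd_umi,
                                         sim$truth$rev_umi)))
  expect_equal(length(res$groups), observed_events)
})

test_that("consensus thresholds: small-group unanimity and the 80% rule", {
  one <- call_consensus("ACGTACGT")
  expect_equal(one$consensus, "ACGTACGT")
  expect_equal(one$support, 1)
  expect_equal(one$agreement, 1)

  trio <- c("ACGTACGT", "ACGTACGT", "ACGAACGT")
  expect_equal(call_consensus(trio)$reason, "disagreement")

  base <- strrep("ACGT", 8)
  g10 <- rep(base, 10)
  for (i in 1:2) substr(g10[i], 5, 5) <- "T"   # 8/10 agree at one position
  r <- call_consensus(g10)
  expect_equal(r$consensus, base)
  expect_equal(r$agreement, 0.8)
  expect_true(is.na(r$reason))

  g7 <- rep(base, 10)
  for (i in 1:3) substr(g7[i], 5, 5) <- "T"    # 7/10 < 0.8
  expect_equal(call_consensus(g7)$reason, "disagreement")
})

test_that("length heterogeneity: plurality class resolves, ties discard", {
  long <- strrep("AC", 20)
  short <- substr(long, 1, 39)
  r <- call_consensus(c(rep(long, 3), rep(short, 2)))
  expect_equal(r$consensus, long)
  expect_equal(r$support, 3)
  expect_equal(call_consensus(c(long, long, short, short))$reason,
               "length_tie")
})

test_that("consensus caller agrees with the brute-force oracle on random groups", {
  set.seed(31)
  for (i in seq_len(200)) {
    g <- random_group(size = sample(1:30, 1), len = sample(20:60, 1),
                      error = runif(1, 0, 0.05))
    a <- call_consensus(g)
    b <- consensus_oracle(g)
    expect_identical(a[c("consensus", "support", "reason")],
                     b[c("consensus", "support", "reason")])
    if (is.na(a$reason)) expect_equal(a$agreement, b$agreement)
  }
})

test_that("standard filtering keeps primer-bearing reads and only those", {
  sim <- fx_sim_clean()
  pre <- preprocess_reads(sim_pairs(sim))
  std <- standard_filter(pre$merged, sim$spec)
  expect_true(all(is.na(std$reason)))
  tr <- sim$truth$true_insert[match(std$read_id, sim$truth$read_id)]
  expect_identical(std$insert, tr)

  # remove the reverse gene-specific region: read discarded
  cut <- substr(pre$merged$sequence[1], 1,
                nchar(pre$merged$sequence[1]) - 60)
  expect_equal(standard_filter(cut, sim$spec)$reason, "no_primer")

  # many-to-one contract: standard output count >= consensus count
  res <- sumi_process(sim_pairs(sim), sim$spec)
  expect_gte(sum(is.na(std$reason)), nrow(res$consensus$records))
})

test_that("consensus calling corrects sequencing errors in well-supported groups", {
  cfg <- sim_config(n_templates = 25, sequencing_depth = 4000,
                    seq_error_rate = 0.005, qual_pass_fraction = 1,
                    priming_prob = 0.5, efficiency_range = c(0.85, 0.95),
                    seed = 32)
  sim <- simulate_sumi_experiment(cfg)
  res <- sumi_process(sim_pairs(sim), sim$spec)
  ann <- res$annotated[is.na(res$annotated$reason), ]
  tr <- sim$truth$true_insert[match(ann$read_id, sim$truth$read_id)]
  same <- nchar(ann$insert) == nchar(tr)
  raw_rate <- sum(hamming(ann$insert[same], tr[same])) / sum(nchar(tr[same]))
  expect_gt(raw_rate, 0.001)

  rec <- res$consensus$records
  key <- vapply(res$groups, function(g) paste(g$fwd_umi, g$rev_umi), "")
  truth_by_read <- setNames(sim$truth$true_insert, sim$truth$read_id)
  gi <- match(paste(rec$fwd_umi, rec$rev_umi), key)
  ctruth <- vapply(res$groups[gi], function(g) {
    ti <- truth_by_read[g$read_ids]
    names(sort(table(ti), decreasing = TRUE))[1]
  }, "")
  sup <- rec$support >= 5 & nchar(rec$consensus) == nchar(ctruth)
  expect_gt(sum(sup), 20)
  cons_rate <- sum(hamming(rec$consensus[sup], ctruth[sup])) /
    sum(nchar(ctruth[sup]))
  expect_lte(cons_rate, 0.1 * raw_rate)
})

test_that("consensus molecules count once regardless of read support", {
  sim <- fx_sim_clean()
  res <- sumi_process(sim_pairs(sim), sim$spec)
  rec <- res$consensus$records
  # group sizes partition annotated reads; each retained record is one row
  expect_equal(sum(vapply(res$groups, function(g) length(g$sequences),
                          numeric(1))),
               sum(is.na(res$annotated$reason)))
  expect_equal(anyDuplicated(paste(rec$fwd_umi, rec$rev_umi)), 0)
})

test_that("sample barcodes are demultiplexed with a one-mismatch budget", {
  g <- synthetic_germline()
  bcs <- c(S1 = "ACACAC", S2 = "GTGTGT", S3 = "TCTCTC")
  spec <- default_primer_spec(g, synthetic_umi_length = 8,
                              sample_barcodes = bcs)
  sims <- lapply(names(bcs), function(s) {
    cfg <- sim_config(n_templates = 10, sequencing_depth = 150,
                      seq_error_rate = 0, qual_pass_fraction = 1,
                      sample_barcode = bcs[[s]],
                      seed = derive_seed(50, s))
    simulate_sumi_experiment(cfg, g, spec = spec)
  })
  pairs <- do.call(rbind, lapply(seq_along(sims), function(i) {
    p <- sim_pairs(sims[[i]])
    p$read_id <- paste0(names(bcs)[i], "_", p$read_id)
    p
  }))
  pre <- preprocess_reads(pairs)
  ann <- locate_primers(pre$merged, spec)
  ok <- is.na(ann$reason)
  origin <- sub("_.*", "", ann$read_id)
  expect_true(all(ann$sample[ok] == origin[ok]))
  expect_equal(sort(unique(ann$sample[ok])), c("S1", "S2", "S3"))
})
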