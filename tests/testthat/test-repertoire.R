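germ <- synthetic_germline()

# unmutated inserts (primer regions excised) for a set of clones
clone_inserts <- function(n_clones, seed) {
  tt <- generate_templates(sim_config(n_templates = n_clones,
                                      n_clones = n_clones, shm_rate = 0,
                                      synthetic_umi_length = 0,
                                      seed = seed), germ)
  list(templates = tt,
       inserts = substr(tt$sequence, 22, nchar(tt$sequence) - 21))
}

test_that("germline annotation round-trips unmutated templates", {
  ci <- clone_inserts(6, 60)
  bcr <- filter_bcr(ci$inserts, germ)
  expect_equal(nrow(bcr$annotated), 6)
  m <- match(bcr$annotated$sequence, ci$inserts)
  expect_identical(bcr$annotated$v_gene, ci$templates$v_gene[m])
  expect_identical(bcr$annotated$j_gene, ci$templates$j_gene[m])
  expect_identical(bcr$annotated$cdr3_nt, ci$templates$cdr3_nt[m])
  expect_true(all(bcr$annotated$v_mismatches == 0))
  expect_true(all(bcr$annotated$in_frame))
  # CDR3 amino-acid length follows the nucleotide length
  expect_equal(nchar(bcr$annotated$cdr3_aa),
               nchar(bcr$annotated$cdr3_nt) / 3)
})

test_that("non-immunoglobulin and broken-frame sequences are rejected", {
  ci <- clone_inserts(2, 61)
  set.seed(62)
  junk <- vapply(1:5, function(i) random_seq(nchar(ci$inserts[1])), "")
  bcr <- filter_bcr(c(ci$inserts, junk), germ)
  expect_equal(nrow(bcr$annotated), 2)
  expect_true(all(bcr$rejects$reason[bcr$rejects$sequence %in% junk] ==
                  "low_v_identity"))

  stopseq <- ci$inserts[1]
  substr(stopseq, 4, 6) <- "TAA"  # internal stop in the V frame
  bcr2 <- filter_bcr(stopseq, germ)
  expect_equal(nrow(bcr2$annotated), 0)
  expect_equal(bcr2$rejects$reason, "incomplete_orf")
})

test_that("mutation classification: silent vs non-silent, CDR vs FWR", {
  ci <- clone_inserts(1, 63)
  s <- ci$inserts[1]
  # find a V FWR3 codon where a third-base change is synonymous
  gc <- Biostrings::GENETIC_CODE
  vseq <- germ$genes$sequence[germ$genes$gene_id == ci$templates$v_gene[1]]
  found <- FALSE
  for (ci3 in seq(13, 37)) {            # codons within FWR3 (37..117)
    gpos <- (ci3 - 1) * 3 + 1
    codon <- substr(vseq, gpos, gpos + 2)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      alt <- paste0(substr(codon, 1, 2), b)
      if (gc[[alt]] == gc[[codon]] && gc[[alt]] != "*") {
        ipos <- gpos + 2 - 21           # insert coordinate of third base
        substr(s, ipos, ipos) <- b
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  bcr <- filter_bcr(s, germ)
  expect_equal(nrow(bcr$mutations), 1)
  expect_equal(bcr$mutations$effect, "silent")
  expect_equal(bcr$mutations$region, "FWR")
  st <- shm_stats(bcr)
  expect_true(is.na(st$silent_to_nonsilent_ratio))  # zero denominator
  expect_equal(st$prop_unmutated, 1)                # 1 mismatch counts
})

test_that("Hamming-1 networks: abundance, indel exclusion, oracle equivalence", {
  net <- build_network(c("ACGT", "ACGT", "ACGT", "ACGA"))
  expect_length(net$sequences, 2)
  expect_equal(sort(net$abundance), c(1, 3))
  expect_equal(nrow(net$edges), 1)
  expect_equal(max(net$membership), 1)

  ins <- build_network(c("ACGTACGT", "ACGTTACGT"))  # insertion: no edge
  expect_equal(nrow(ins$edges), 0)
  expect_equal(max(ins$membership), 2)

  set.seed(64)
  for (i in 1:5) {
    centers <- vapply(1:12, function(k) random_seq(30), "")
    seqs <- unlist(lapply(centers, function(cs) {
      v <- vapply(1:8, function(k) {
        p <- sample(30, 1)
        substr(cs, p, p) <- sample(c("A", "C", "G", "T"), 1)
        cs
      }, "")
      c(cs, v)
    }))
    net <- build_network(seqs)
    expect_identical(edge_key(net$edges),
                     edge_key(hamming_oracle_edges(net$sequences)))
  }
})

test_that("clones merge disconnected components sharing CDR3 and gene usage", {
  ci <- clone_inserts(1, 65)
  a <- ci$inserts[1]
  b <- a
  # two silent-ish FWR changes far apart: Hamming distance 2, same CDR3
  for (p in c(5, 50)) {
    repeat {
      cand <- sample(c("A", "C", "G", "T"), 1)
      if (cand != substr(b, p, p)) { substr(b, p, p) <- cand; break }
    }
  }
  bcr <- filter_bcr(c(a, b), germ)
  if (nrow(bcr$annotated) == 2) {  # mutations could break the frame check
    net <- build_network(bcr$annotated$sequence, bcr$annotated$abundance)
    expect_equal(nrow(net$edges), 0)
    cl <- define_clones(net, bcr$annotated)
    expect_equal(nrow(cl$clones), 1)
  }

  single <- filter_bcr(a, germ)
  net1 <- build_network(single$annotated$sequence)
  expect_equal(nrow(define_clones(net1, single$annotated)$clones), 1)
})

test_that("an error-free simulation recovers exactly the simulated clones", {
  k <- 4
  cfg <- sim_config(n_templates = 40, n_clones = k, shm_rate = 0,
                    synthetic_umi_length = 0, sequencing_depth = 1500,
                    seq_error_rate = 0, qual_pass_fraction = 1, seed = 66)
  sim <- simulate_sumi_experiment(cfg)
  res <- sumi_process(sim_pairs(sim), sim$spec)
  bcr <- filter_bcr(res$consensus$records$consensus, germ)
  net <- build_network(bcr$annotated$sequence, bcr$annotated$abundance)
  cl <- define_clones(net, bcr$annotated)
  expect_equal(nrow(cl$clones), k)
})

test_that("Renyi index: closed forms and the Shannon limit", {
  expect_equal(renyi_index(1, 2), 0)
  for (alpha in c(0.5, 1, 2, 3)) {
    expect_equal(renyi_index(rep(3, 7), alpha), log(7))
  }
  set.seed(67)
  w <- runif(20)
  shannon <- -sum((w / sum(w)) * log(w / sum(w)))
  expect_lt(abs(renyi_index(w, 1 - 1e-6) - shannon), 1e-5)
  expect_equal(renyi_index(w, 1), shannon)
})

test_that("clonal diversification index: degenerate repertoires", {
  one <- data.frame(sequence = "AAAA", abundance = 50, cluster = 1,
                    clone_id = "CL0001", stringsAsFactors = FALSE)
  for (alpha in c(0.5, 2)) {
    expect_equal(clonal_diversification_index(one, repeats = 3,
                                              alpha = alpha, seed = 1), 0)
  }
  k <- 6
  eq <- data.frame(sequence = paste0("S", 1:k), abundance = 10,
                   cluster = 1:k, clone_id = sprintf("CL%04d", 1:k),
                   stringsAsFactors = FALSE)
  expect_equal(clonal_diversification_index(eq, repeats = 3, alpha = 2,
                                            seed = 1), log(k))
  # read-level subsampling agrees on the uniform case
  expect_equal(clonal_diversification_index(eq, depth = 30, repeats = 5,
                                            alpha = 2, seed = 1,
                                            unit = "reads"), log(k),
               tolerance = 0.2)
})

test_that("matched-depth intraclonal diversity follows the occupancy law", {
  same <- intraclonal_diversity(list(A = rep("x", 40), B = rep("x", 40)),
                                seed = 2)
  expect_equal(same[["A"]], same[["B"]])
  expect_equal(unname(intraclonal_diversity(list(A = rep("x", 100)),
                                            seed = 3)[["A"]]), 1)

  a <- rep(paste0("u", 1:20), each = 5)    # 100 reads, 20 uniques
  b <- rep(paste0("v", 1:5), each = 16)    # 80 reads, 5 uniques
  d <- floor(0.75 * 80)
  occ <- function(k, n, d) k * (1 - choose(n - n / k, d) / choose(n, d))
  div <- intraclonal_diversity(list(A = a, B = b), repeats = 200, seed = 4)
  expect_gt(div[["A"]], div[["B"]])
  expect_lt(abs(div[["A"]] - occ(20, 100, d)), 0.35)
  expect_lt(abs(div[["B"]] - occ(5, 80, d)), 0.1)

  expect_null(suppressMessages(
    intraclonal_diversity(list(A = "x", B = "y"))))
})

test_that("error-free repertoires have unit proportion of unmutated molecules", {
  cfg <- sim_config(n_templates = 20, n_clones = 2, shm_rate = 0,
                    synthetic_umi_length = 0, sequencing_depth = 600,
                    seq_error_rate = 0, qual_pass_fraction = 1, seed = 68)
  sim <- simulate_sumi_experiment(cfg)
  res <- sumi_process(sim_pairs(sim), sim$spec)
  st <- shm_stats(filter_bcr(res$consensus$records$consensus, germ))
  expect_equal(st$prop_unmutated, 1)
})

test_that("visual subsampling preserves clonal architecture and is seeded", {
  mk_assign <- function(clone_sizes, seed) {
    set.seed(seed)
    rows <- lapply(seq_along(clone_sizes), function(k) {
      center <- random_seq(40)
      n_var <- max(1, clone_sizes[k] %/% 4)
      seqs <- c(center, vapply(seq_len(n_var - 1), function(i) {
        p <- sample(40, 1)
        s <- center
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
        s
      }, ""))
      seqs <- unique(seqs)
      ab <- rep(clone_sizes[k] %/% length(seqs), length(seqs))
      ab[1] <- ab[1] + clone_sizes[k] - sum(ab)
      data.frame(sequence = seqs, abundance = ab, cluster = k,
                 clone_id = sprintf("CL%04d", k), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  one <- mk_assign(120, 70)
  v1 <- viz_subsample(one, n_bcrs = 50, repeats = 5, seed = 5)
  expect_lte(sum(v1$graph$abundance), 50)
  v2 <- viz_subsample(one, n_bcrs = 50, repeats = 5, seed = 5)
  expect_identical(v1$graph, v2$graph)

  # a dominant clone yields a dominant component more often than not
  share <- function(assign, seed) {
    v <- viz_subsample(assign, n_clones = 1000, repeats = 10,
                       n_bcrs = 200, seed = seed)
    comp_ab <- tapply(v$graph$abundance, v$graph$membership, sum)
    max(comp_ab) / sum(comp_ab)
  }
  clonal <- mk_assign(c(600, rep(10, 40)), 71)
  diverse <- mk_assign(rep(10, 100), 72)
  wins <- sum(vapply(1:10, function(s)
    share(clonal, s) > share(diverse, s), logical(1)))
  expect_gte(wins, 9)
})
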