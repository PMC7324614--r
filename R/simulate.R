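#' Simulation configuration
#'
#' Parameters of the generative model of a barcoded amplicon sequencing
#' experiment: a pool of template molecules (optionally structured into
#' clones with specified pool fractions and an internal synthetic DNA-UMI
#' per molecule), a near-linear first PCR in which each template is primed
#' with probability `priming_prob` per cycle (acquiring a fresh primer-UMI
#' pair) and each existing looped amplicon escapes and is re-amplified with
#' probability `loop_reamp_prob` per cycle, an exponential second PCR with
#' per-molecule efficiency drawn from a rescaled Beta law, and paired-end
#' sequencing with iid substitution errors and a two-component quality
#' model.
#'
#' @param n_templates Number of template molecules in the pool.
#' @param n_clones Number of distinct V(D)J rearrangements (clones) among
#'   the templates.
#' @param clone_fractions Pool fractions per clone (sum 1); uniform when
#'   `NULL`. Molecules are apportioned deterministically (largest
#'   remainder) so input fractions are exact.
#' @param pcr1_cycles Cycles of the near-linear barcoding PCR.
#' @param priming_prob Per-cycle probability that a template molecule is
#'   primed (produces one new barcoded amplicon).
#' @param loop_reamp_prob Per-cycle probability that an existing looped
#'   amplicon is re-primed (copy with a NEW primer-UMI pair but the same
#'   template content; flagged `loop_reamplified`).
#' @param pcr2_cycles Cycles of the exponential second PCR; an amplicon's
#'   relative read weight is `(1 + efficiency)^pcr2_cycles`.
#' @param efficiency_shape1,efficiency_shape2 Beta shape parameters of the
#'   per-molecule amplification efficiency.
#' @param efficiency_range Interval to which the Beta draw is rescaled
#'   (default `c(0.6, 1)`); set to `c(x, x)` for homogeneous efficiency.
#' @param length_efficiency Per-base penalty on efficiency for amplicons
#'   longer than the pool mean (0 disables length bias).
#' @param seq_error_rate Per-base substitution error rate of sequencing.
#' @param read_length Read length of each mate. The default (170) gives
#'   the simulated amplicons (roughly 250-280 bp) a designed mate overlap
#'   of about 60-90 identical bases, comfortably above the >50 bp merge
#'   requirement while keeping the overlap-to-length ratio realistic.
#' @param sequencing_depth Number of read pairs drawn.
#' @param umi_length Primer UMI length (default 8).
#' @param synthetic_umi_length Length of the internal synthetic DNA-UMI in
#'   each template molecule (0 for clinical-style templates without one).
#' @param shm_rate Per-base somatic hypermutation rate applied per
#'   molecule relative to its clone's germline sequence.
#' @param cdr_weight,fwr_weight Relative SHM weights of CDR vs FWR
#'   positions (`cdr_weight >= fwr_weight`).
#' @param junction_codons Candidate junction lengths, in codons.
#' @param qual_pass_fraction Fraction of read pairs drawn from the
#'   high-quality component (the rest fail the median-Phred filter).
#' @param standard_cycles Cycle count of the standard (non-barcoded)
#'   exponential PCR; defaults to `pcr1_cycles`.
#' @param sample_barcode Optional sample barcode appended beyond the
#'   reverse MALBAC tail (demultiplexing experiments).
#' @param seed Master seed; stage seeds are derived deterministically so a
#'   fixed seed yields bit-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_templates = 1000L, n_clones = 1L,
                       clone_fractions = NULL,
                       pcr1_cycles = 5L, priming_prob = 0.9,
                       loop_reamp_prob = 0.005, pcr2_cycles = 20L,
                       efficiency_shape1 = 2, efficiency_shape2 = 2,
                       efficiency_range = c(0.6, 1),
                       length_efficiency = 0,
                       seq_error_rate = 0.005, read_length = 170L,
                       sequencing_depth = 10000L, umi_length = 8L,
                       synthetic_umi_length = 8L,
                       shm_rate = 0, cdr_weight = 3, fwr_weight = 1,
                       junction_codons = 7:16,
                       qual_pass_fraction = 0.95,
                       standard_cycles = NULL,
                       sample_barcode = NULL, seed = NULL) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_templates >= 1, n_clones >= 1, pcr1_cycles >= 1,
              priming_prob >= 0, priming_prob <= 1,
              loop_reamp_prob >= 0, loop_reamp_prob <= 1,
              seq_error_rate >= 0, seq_error_rate <= 1,
              umi_length >= 1, sequencing_depth >= 1,
              synthetic_umi_length >= 0,
              qual_pass_fraction >= 0, qual_pass_fraction <= 1,
              cdr_weight >= fwr_weight,
              length(efficiency_range) == 2,
              efficiency_range[1] <= efficiency_range[2])
    if (!is.null(clone_fractions)) {
      stopifnot(length(clone_fractions) == n_clones,
                abs(sum(clone_fractions) - 1) < 1e-8,
                all(clone_fractions >= 0))
    }
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_templates, "templates /", x$n_clones, "clone(s);",
      "PCR1", x$pcr1_cycles, "cycles (p =", x$priming_prob,
      ", q =", x$loop_reamp_prob, "); depth", x$sequencing_depth,
      "; error", x$seq_error_rate, "\n")
  invisible(x)
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys mirror the arguments of [sim_config()].
#' @return A [sim_config] object.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  keep <- intersect(names(y), names(formals(sim_config)))
  do.call(sim_config, y[keep])
}

stage_seed <- function(config, stage) {
  if (is.null(config$seed)) NULL else derive_seed(config$seed, stage)
}

#' Generate a pool of template molecules
#'
#' Builds `n_clones` distinct V(D)J rearrangements (random V and J choice,
#' random stop-free in-frame junction) and apportions `n_templates`
#' molecules over them. Each molecule receives somatic hypermutation at
#' `shm_rate` per base with CDR positions up-weighted by
#' `cdr_weight / fwr_weight` (the two 21 bp primer-annealing sites are kept
#' intact so primer identification stays well-defined), and, when
#' `synthetic_umi_length > 0`, a unique internal synthetic DNA-UMI placed
#' directly after the forward primer site. Synthetic-UMI collisions are
#' re-drawn so molecule identity is unambiguous; primer-UMI collisions
#' downstream are deliberately not.
#'
#' @param config A [sim_config].
#' @param germline A [germline_db] with at least one V and one J segment.
#' @return data.frame of template molecules (one row per molecule) with a
#'   `clones` attribute describing the clone pool.
#' @export
generate_templates <- function(config, germline = synthetic_germline()) {
  v <- germline_genes(germline, "V")
  j <- germline_genes(germline, "J")
  if (nrow(v) == 0 || nrow(j) == 0)
    stop("empty germline reference: need at least one V and one J gene")
  with_seed(stage_seed(config, "templates"), {
    k <- config$n_clones
    codons <- stopfree_codons()
    junc <- character(k)
    repeat {
      nc <- sample(config$junction_codons, k, replace = TRUE)
      junc <- vapply(nc, function(m)
        paste(sample(codons, m, replace = TRUE), collapse = ""),
        character(1))
      if (!anyDuplicated(junc)) break
    }
    clones <- data.frame(
      clone_id = sprintf("C%03d", seq_len(k)),
      v_gene = sample(v$gene_id, k, replace = TRUE),
      j_gene = sample(j$gene_id, k, replace = TRUE),
      junction = junc,
      fraction = config$clone_fractions %||% rep(1 / k, k),
      stringsAsFactors = FALSE)
    clones$sequence <- paste0(
      v$sequence[match(clones$v_gene, v$gene_id)],
      clones$junction,
      j$sequence[match(clones$j_gene, j$gene_id)])
    counts <- apportion(config$n_templates, clones$fraction)
    idx <- rep(seq_len(k), counts)
    n <- length(idx)

    # per-molecule SHM over the clone sequence, sparing the primer sites
    seqs <- clones$sequence[idx]
    nshm <- integer(n)
    if (config$shm_rate > 0) {
      for (ki in seq_len(k)) {
        rows <- which(idx == ki)
        if (!length(rows)) next
        cs <- clones$sequence[ki]
        len <- nchar(cs)
        vlab <- region_labels(germline, clones$v_gene[ki])
        jlab <- region_labels(germline, clones$j_gene[ki])
        lab <- c(vlab, rep("CDR3", nchar(clones$junction[ki])), jlab)
        prob <- ifelse(startsWith(lab, "CDR"),
                       config$shm_rate * config$cdr_weight,
                       config$shm_rate * config$fwr_weight)
        prob <- pmin(prob, 1)
        prob[c(1:21, (len - 20):len)] <- 0  # primer annealing sites
        bases <- c("A", "C", "G", "T")
        for (r in rows) {
          hit <- which(runif(len) < prob)
          s <- cs
          for (p in hit) {
            substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1)
          }
          seqs[r] <- s
          nshm[r] <- length(hit)
        }
      }
    }

    jl <- nchar(clones$junction)[idx]
    cdr3 <- substr(seqs, 118, 123 + jl)

    su <- rep(NA_character_, n)
    if (config$synthetic_umi_length > 0) {
      su <- random_dna(n, config$synthetic_umi_length)
      while (anyDuplicated(su)) {
        dup <- which(duplicated(su))
        su[dup] <- random_dna(length(dup), config$synthetic_umi_length)
      }
      seqs <- paste0(substr(seqs, 1, 21), su, substring(seqs, 22))
    }

    templates <- data.frame(
      template_id = sprintf("T%05d", seq_len(n)),
      clone_id = clones$clone_id[idx],
      v_gene = clones$v_gene[idx],
      j_gene = clones$j_gene[idx],
      junction = clones$junction[idx],
      cdr3_nt = cdr3,
      synthetic_umi = su,
      sequence = seqs,
      n_shm = nshm,
      stringsAsFactors = FALSE)
    attr(templates, "clones") <- clones
    templates
  })
}

#' Simulate the near-linear barcoding PCR (PCR1)
#'
#' Per cycle, each template molecule is primed with probability
#' `priming_prob`, creating one amplicon with a new random primer-UMI pair
#' (linear growth in cycle number); each amplicon existing at the start of
#' the cycle escapes its loop and is re-primed with probability
#' `loop_reamp_prob`, creating a copy with a new primer-UMI pair but the
#' same template content, flagged `loop_reamplified`.
#'
#' @param templates Output of [generate_templates()].
#' @param config A [sim_config] with `pcr1_cycles >= 1`.
#' @return data.frame of barcoded amplicons.
#' @export
simulate_pcr1 <- function(templates, config) {
  stopifnot(config$pcr1_cycles >= 1)
  with_seed(stage_seed(config, "pcr1"), {
    n_t <- nrow(templates)
    tid <- character(0); lineage <- character(0); cycle <- integer(0)
    for (cyc in seq_len(config$pcr1_cycles)) {
      n_existing <- length(tid)
      if (n_existing > 0 && config$loop_reamp_prob > 0) {
        loop <- which(runif(n_existing) < config$loop_reamp_prob)
        if (length(loop)) {
          tid <- c(tid, tid[loop])
          lineage <- c(lineage, rep("loop_reamplified", length(loop)))
          cycle <- c(cycle, rep(cyc, length(loop)))
        }
      }
      primed <- which(runif(n_t) < config$priming_prob)
      if (length(primed)) {
        tid <- c(tid, templates$template_id[primed])
        lineage <- c(lineage, rep("template_primed", length(primed)))
        cycle <- c(cycle, rep(cyc, length(primed)))
      }
    }
    n <- length(tid)
    data.frame(
      amplicon_id = sprintf("A%06d", seq_len(n)),
      template_id = tid,
      fwd_umi = random_dna(n, config$umi_length),
      rev_umi = random_dna(n, config$umi_length),
      lineage = lineage,
      cycle = cycle,
      stringsAsFactors = FALSE)
  })
}

# Full top-strand sequence of each barcoded amplicon.
amplicon_sequences <- function(amplicons, templates, config, spec) {
  tseq <- templates$sequence[match(amplicons$template_id,
                                   templates$template_id)]
  out <- paste0(spec$fwd_malbac, amplicons$fwd_umi, tseq,
                revcomp(amplicons$rev_umi), revcomp(spec$rev_malbac))
  if (!is.null(config$sample_barcode))
    out <- paste0(out, config$sample_barcode)
  out
}

draw_efficiency <- function(n, config) {
  r <- config$efficiency_range
  if (r[1] == r[2]) return(rep(r[1], n))
  r[1] + (r[2] - r[1]) * rbeta(n, config$efficiency_shape1,
                               config$efficiency_shape2)
}

random_quals <- function(widths, pass) {
  lo <- c(20L, 31L); hi <- c(35L, 40L)
  vapply(seq_along(widths), function(i) {
    rng <- if (pass[i]) hi else lo
    intToUtf8(sample(rng[1]:rng[2], widths[i], replace = TRUE) + 33L)
  }, character(1))
}

sequence_molecules <- function(full, weights, source_idx, config, stage) {
  with_seed(stage_seed(config, stage), {
    if (sum(weights) <= 0) stop("zero total amplification weight")
    depth <- config$sequencing_depth
    draw <- sample.int(length(full), depth, replace = TRUE, prob = weights)
    fs <- full[draw]
    L <- nchar(fs)
    rl <- config$read_length
    r1 <- substr(fs, 1, pmin(rl, L))
    r2 <- revcomp(substr(fs, pmax(1, L - rl + 1), L))
    r1 <- mutate_bases(r1, config$seq_error_rate)
    r2 <- mutate_bases(r2, config$seq_error_rate)
    pass <- runif(depth) < config$qual_pass_fraction
    reads <- data.frame(
      read_id = sprintf("R%07d", seq_len(depth)),
      r1_seq = r1, r1_qual = random_quals(nchar(r1), pass),
      r2_seq = r2, r2_qual = random_quals(nchar(r2), pass),
      stringsAsFactors = FALSE)
    list(reads = reads, draw = draw, source = source_idx[draw])
  })
}

#' Simulate the exponential second PCR and paired-end sequencing
#'
#' Each amplicon from PCR1 receives a per-molecule efficiency from the
#' configured rescaled Beta law (optionally penalised by amplicon length),
#' compounded over `pcr2_cycles` into a relative weight
#' `(1 + efficiency)^pcr2_cycles`. Read pairs are drawn multinomially at
#' `sequencing_depth`, substitution errors applied iid at
#' `seq_error_rate`, and quality strings drawn from a two-component model
#' so that about `1 - qual_pass_fraction` of pairs fail a median-Phred
#' filter. Paired reads overlap over most of the amplicon, exercising the
#' exact-overlap merge.
#'
#' @param amplicons Output of [simulate_pcr1()].
#' @param templates Output of [generate_templates()].
#' @param config A [sim_config].
#' @param spec A [primer_spec]; defaults to the layout used by the
#'   simulator for the given synthetic-UMI length.
#' @return list with `reads` (paired FASTQ records as a data.frame) and
#'   `truth` (one ground-truth row per read pair).
#' @export
simulate_pcr2_and_sequencing <- function(amplicons, templates, config,
                                         spec = NULL) {
  if (nrow(amplicons) == 0) stop("no amplicons to amplify")
  spec <- spec %||% default_primer_spec(
    synthetic_germline(), synthetic_umi_length = config$synthetic_umi_length,
    umi_length = config$umi_length)
  full <- amplicon_sequences(amplicons, templates, config, spec)
  eff <- with_seed(stage_seed(config, "efficiency"),
                   draw_efficiency(length(full), config))
  if (config$length_efficiency > 0) {
    L <- nchar(full)
    eff <- pmin(pmax(eff * exp(-config$length_efficiency * (L - mean(L))),
                     0.01), 1)
  }
  w <- (1 + eff)^config$pcr2_cycles
  sq <- sequence_molecules(full, w, seq_len(nrow(amplicons)), config, "pcr2")
  amp <- amplicons[sq$source, ]
  tseq <- templates$sequence[match(amp$template_id, templates$template_id)]
  truth <- data.frame(
    read_id = sq$reads$read_id,
    template_id = amp$template_id,
    fwd_umi = amp$fwd_umi,
    rev_umi = amp$rev_umi,
    lineage = amp$lineage,
    true_insert = substr(tseq, .GS_LEN + 1, nchar(tseq) - .GS_LEN),
    stringsAsFactors = FALSE, row.names = NULL)
  list(reads = sq$reads, truth = truth, efficiency = eff)
}

#' Simulate a standard (non-barcoded) exponential PCR and sequencing
#'
#' Every template molecule is duplicated each cycle with its per-template
#' efficiency (Binomial branching of molecule counts), over
#' `standard_cycles` cycles (default `pcr1_cycles`), then weighted through
#' the second PCR exactly as the barcoded arm; no primer UMIs exist.
#'
#' @inheritParams simulate_pcr2_and_sequencing
#' @return list with `reads`, `truth` (UMI fields `NA`) and
#'   `molecule_counts`, the per-template molecule count after the
#'   exponential PCR.
#' @export
simulate_standard_pcr <- function(templates, config) {
  stopifnot(nrow(templates) >= 1)
  cycles <- config$standard_cycles %||% config$pcr1_cycles
  n <- nrow(templates)
  eff <- with_seed(stage_seed(config, "standard_efficiency"),
                   draw_efficiency(n, config))
  N <- with_seed(stage_seed(config, "standard_branching"), {
    N <- rep(1L, n)
    for (cyc in seq_len(cycles)) N <- N + rbinom(n, N, eff)
    N
  })
  w <- N * (1 + eff)^config$pcr2_cycles
  sq <- sequence_molecules(templates$sequence, w, seq_len(n), config,
                           "standard_seq")
  tpl <- templates[sq$source, ]
  truth <- data.frame(
    read_id = sq$reads$read_id,
    template_id = tpl$template_id,
    fwd_umi = NA_character_,
    rev_umi = NA_character_,
    lineage = NA_character_,
    true_insert = substr(tpl$sequence, .GS_LEN + 1,
                         nchar(tpl$sequence) - .GS_LEN),
    stringsAsFactors = FALSE, row.names = NULL)
  list(reads = sq$reads, truth = truth, molecule_counts = N,
       efficiency = eff)
}

#' Run a complete barcoded-PCR simulation
#'
#' Convenience wrapper: template generation, PCR1, PCR2 and sequencing,
#' optionally writing paired FASTQ, the truth table and the template table
#' to a directory.
#'
#' @inheritParams generate_templates
#' @param spec Optional [primer_spec]; built from the germline by default.
#' @param out_dir Optional output directory (created if needed).
#' @return list with `config`, `spec`, `templates`, `amplicons`, `reads`,
#'   `truth`.
#' @export
simulate_sumi_experiment <- function(config, germline = synthetic_germline(),
                                     spec = NULL, out_dir = NULL) {
  spec <- spec %||% default_primer_spec(
    germline, synthetic_umi_length = config$synthetic_umi_length,
    umi_length = config$umi_length)
  templates <- generate_templates(config, germline)
  amplicons <- simulate_pcr1(templates, config)
  sq <- simulate_pcr2_and_sequencing(amplicons, templates, config, spec)
  sim <- list(config = config, spec = spec, templates = templates,
              amplicons = amplicons, reads = sq$reads, truth = sq$truth)
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' Run a complete standard (non-barcoded) simulation
#' @inheritParams simulate_sumi_experiment
#' @return list with `config`, `templates`, `reads`, `truth`,
#'   `molecule_counts`.
#' @export
simulate_standard_experiment <- function(config,
                                         germline = synthetic_germline(),
                                         out_dir = NULL) {
  templates <- generate_templates(config, germline)
  sq <- simulate_standard_pcr(templates, config)
  sim <- list(config = config, templates = templates, reads = sq$reads,
              truth = sq$truth, molecule_counts = sq$molecule_counts)
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' Write simulator output to disk
#'
#' Writes `reads_R1.fastq`, `reads_R2.fastq`, `truth.tsv` and
#' `templates.tsv` under `out_dir`.
#'
#' @param sim Result of [simulate_sumi_experiment()] or
#'   [simulate_standard_experiment()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  r <- sim$reads
  write_fastq(r$read_id, r$r1_seq, r$r1_qual,
              file.path(out_dir, "reads_R1.fastq"))
  write_fastq(r$read_id, r$r2_seq, r$r2_qual,
              file.path(out_dir, "reads_R2.fastq"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(sim$templates, file.path(out_dir, "templates.tsv"))
  invisible(out_dir)
}

#' Assign sequences to simulated clones by junction identity
#'
#' Classifies sequences (reads, inserts or consensus molecules) by exact
#' occurrence of each simulated clone's junction, giving the observed
#' fraction of the pool attributable to each clone (used in titration
#' analyses).
#'
#' @param seqs Character vector of sequences.
#' @param templates Output of [generate_templates()] (its `clones`
#'   attribute supplies the junctions).
#' @return Named numeric vector of fractions, one per clone plus
#'   `unassigned`, summing to 1.
#' @export
clone_read_fractions <- function(seqs, templates) {
  clones <- attr(templates, "clones")
  stopifnot(!is.null(clones))
  n <- length(seqs)
  if (n == 0) stop("no sequences to classify")
  assigned <- rep(FALSE, n)
  out <- numeric(nrow(clones))
  names(out) <- clones$clone_id
  for (i in seq_len(nrow(clones))) {
    hit <- !assigned & grepl(clones$junction[i], seqs, fixed = TRUE)
    out[i] <- sum(hit) / n
    assigned <- assigned | hit
  }
  c(out, unassigned = sum(!assigned) / n)
}
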