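run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Process read pairs through the barcode-aware filtering pipeline
#'
#' Quality filter, exact-overlap merge, primer/UMI identification,
#' UMI grouping and consensus calling, entirely in memory.
#'
#' @param pairs data.frame of read pairs (see [read_paired_fastq()]).
#' @param spec A [primer_spec].
#' @param min_median_phred,min_overlap Preprocessing thresholds.
#' @param min_agreement,small_group_max Consensus thresholds.
#' @return list with `merged`, `annotated`, `consensus` (records and
#'   rejects) and `counts` (per-stage read/molecule counts).
#' @export
sumi_process <- function(pairs, spec, min_median_phred = 32,
                         min_overlap = 51L, min_agreement = 0.8,
                         small_group_max = 4L) {
  pre <- run_stage("preprocess",
                   preprocess_reads(pairs, min_median_phred, min_overlap))
  ann <- run_stage("locate_primers", locate_primers(pre$merged, spec))
  groups <- run_stage("group_by_umi", group_by_umi(ann))
  cons <- run_stage("call_consensus",
                    consensus_from_groups(groups, min_agreement,
                                          small_group_max))
  reject_counts <- as.list(table(ann$reason, useNA = "no"))
  counts <- c(pre$counts,
              list(annotated = sum(is.na(ann$reason)),
                   primer_rejects = reject_counts,
                   umi_groups = length(groups),
                   consensus = nrow(cons$records),
                   consensus_rejects = as.list(table(cons$rejects$reason))))
  list(merged = pre$merged, annotated = ann, groups = groups,
       consensus = cons, counts = counts)
}

#' Process read pairs through the standard (barcode-ignoring) pipeline
#'
#' Identical preprocessing, then gene-specific primer filtering only:
#' every surviving read contributes one insert sequence.
#'
#' @inheritParams sumi_process
#' @return list with `merged`, `inserts` (data.frame) and `counts`.
#' @export
standard_process <- function(pairs, spec, min_median_phred = 32,
                             min_overlap = 51L) {
  pre <- run_stage("preprocess",
                   preprocess_reads(pairs, min_median_phred, min_overlap))
  std <- run_stage("standard_filter", standard_filter(pre$merged, spec))
  keep <- std[is.na(std$reason), , drop = FALSE]
  counts <- c(pre$counts, list(retained = nrow(keep),
                               primer_rejects = sum(!is.na(std$reason))))
  list(merged = pre$merged, inserts = keep, counts = counts)
}

#' Run the complete barcoded filtering pipeline from FASTQ to consensus
#'
#' End-to-end orchestration: paired FASTQ in, consensus molecules (and,
#' when a germline is supplied, annotated BCRs and clone assignments) out,
#' with a run manifest recording configuration, seed and per-stage counts.
#' Any stage failure aborts with the stage name in the error.
#'
#' @param r1,r2 Paths to paired FASTQ files, or a `pairs` data.frame in
#'   `r1` with `r2` missing.
#' @param spec A [primer_spec].
#' @param germline Optional [germline_db]; when given, consensus
#'   molecules are annotated and clones defined.
#' @inheritParams sumi_process
#' @param min_identity Minimum V identity for BCR filtering.
#' @param seed Master seed recorded in the manifest and used for any
#'   seeded downstream statistics.
#' @param out_dir Optional directory: writes `consensus.fasta` (header
#'   fields `umi_fwd`, `umi_rev`, `support`), `rejections.tsv` and
#'   `manifest.json`.
#' @return list with the [sumi_process()] results, optional `repertoire`
#'   (annotation, graph, clones), and `manifest`.
#' @export
run_sumi_pipeline <- function(r1, r2 = NULL, spec, germline = NULL,
                              min_median_phred = 32, min_overlap = 51L,
                              min_agreement = 0.8, small_group_max = 4L,
                              min_identity = 0.8, seed = NULL,
                              out_dir = NULL) {
  pairs <- if (is.data.frame(r1)) r1 else
    run_stage("preprocess", read_paired_fastq(r1, r2))
  res <- sumi_process(pairs, spec, min_median_phred, min_overlap,
                      min_agreement, small_group_max)
  repertoire <- NULL
  if (!is.null(germline) && nrow(res$consensus$records) > 0) {
    repertoire <- run_stage("filter_bcr", {
      bcr <- filter_bcr(res$consensus$records$consensus, germline,
                        min_identity)
      if (nrow(bcr$annotated) > 0) {
        g <- build_network(bcr$annotated$sequence, bcr$annotated$abundance)
        cl <- define_clones(g, bcr$annotated)
        list(annotation = bcr, graph = g, clones = cl,
             shm = shm_stats(bcr))
      } else list(annotation = bcr, graph = NULL, clones = NULL,
                  shm = NULL)
    })
    res$counts$bcr_retained <- sum(repertoire$annotation$annotated$abundance)
  }
  manifest <- list(
    tool = "sumiseq",
    version = as.character(packageVersion("sumiseq")),
    seed = seed,
    params = list(min_median_phred = min_median_phred,
                  min_overlap = min_overlap,
                  min_agreement = min_agreement,
                  small_group_max = small_group_max,
                  min_identity = min_identity),
    counts = res$counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rec <- res$consensus$records
    if (nrow(rec) > 0) {
      x <- Biostrings::DNAStringSet(rec$consensus)
      names(x) <- sprintf("M%05d umi_fwd=%s umi_rev=%s support=%d",
                          seq_len(nrow(rec)), rec$fwd_umi, rec$rev_umi,
                          as.integer(rec$support))
      Biostrings::writeXStringSet(x, file.path(out_dir, "consensus.fasta"))
    }
    rej <- res$annotated[!is.na(res$annotated$reason),
                         c("read_id", "reason")]
    write_tsv(rej, file.path(out_dir, "rejections.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  c(res, list(repertoire = repertoire, manifest = manifest))
}

#' Compare manifests for reproducibility, ignoring timestamps
#' @param m1,m2 Manifests from [run_sumi_pipeline()].
#' @return `TRUE` if identical apart from the timestamp.
#' @export
manifest_identical <- function(m1, m2) {
  m1$timestamp <- m2$timestamp <- NULL
  identical(m1, m2)
}

# Abundance-weighted modal CDR3 of a clone's member sequences.
clone_dominant_cdr3 <- function(members, annotation) {
  m <- annotation[annotation$sequence %in% members, , drop = FALSE]
  if (nrow(m) == 0) return(NA_character_)
  w <- tapply(m$abundance, m$cdr3_nt, sum)
  names(w)[which.max(w)]
}

#' Paired comparison of barcode-aware and barcode-ignoring filtering
#'
#' Processes one set of read pairs both ways (consensus molecules vs all
#' primer-bearing reads), annotates both against the germline, defines
#' clones, and reports: matched-depth intraclonal diversity per clone
#' (clones above `min_clone_frac` of the barcode-corrected repertoire,
#' matched across methods by dominant CDR3), somatic-hypermutation
#' summaries, and a one-sided Wilcoxon signed-rank test of the
#' diversity reduction.
#'
#' @inheritParams run_sumi_pipeline
#' @param frac,repeats Matched-depth subsampling parameters of
#'   [intraclonal_diversity()].
#' @param min_clone_frac Minimum clone share of the corrected repertoire
#'   for inclusion (default 0.01).
#' @return list with `corrected`, `uncorrected` (each: counts, shm,
#'   clones), `clone_diversity` (per-clone matched-depth means) and
#'   `p_diversity` (one-sided Wilcoxon, corrected < uncorrected; `NA`
#'   with fewer than 2 matched clones).
#' @export
run_comparison <- function(r1, r2 = NULL, spec, germline,
                           min_median_phred = 32, min_overlap = 51L,
                           min_agreement = 0.8, small_group_max = 4L,
                           min_identity = 0.8, frac = 0.75, repeats = 50L,
                           min_clone_frac = 0.01, seed = NULL) {
  pairs <- if (is.data.frame(r1)) r1 else
    run_stage("preprocess", read_paired_fastq(r1, r2))
  pre <- run_stage("preprocess",
                   preprocess_reads(pairs, min_median_phred, min_overlap))
  ann <- run_stage("locate_primers", locate_primers(pre$merged, spec))
  cons <- run_stage("call_consensus",
                    consensus_from_groups(group_by_umi(ann), min_agreement,
                                          small_group_max))
  std <- run_stage("standard_filter", standard_filter(pre$merged, spec))
  std_keep <- std$insert[is.na(std$reason)]

  analyse <- function(seqs) {
    bcr <- filter_bcr(seqs, germline, min_identity)
    g <- build_network(bcr$annotated$sequence, bcr$annotated$abundance)
    cl <- define_clones(g, bcr$annotated)
    list(bcr = bcr, graph = g, clones = cl, shm = shm_stats(bcr))
  }
  corr <- run_stage("filter_bcr", analyse(cons$records$consensus))
  unco <- run_stage("filter_bcr", analyse(std_keep))

  # match clones across methods by the corrected clones' dominant CDR3
  total_corr <- sum(corr$clones$clones$total_reads)
  big <- corr$clones$clones[
    corr$clones$clones$total_reads >= min_clone_frac * total_corr, ,
    drop = FALSE]
  rows <- list()
  for (cl_id in big$clone_id) {
    mem_c <- corr$clones$assignments$sequence[
      corr$clones$assignments$clone_id == cl_id]
    cdr3 <- clone_dominant_cdr3(mem_c, corr$bcr$annotated)
    if (is.na(cdr3)) next
    u_seqs <- unco$bcr$annotated$sequence[unco$bcr$annotated$cdr3_nt == cdr3]
    u_clones <- unique(unco$clones$assignments$clone_id[
      unco$clones$assignments$sequence %in% u_seqs])
    if (length(u_clones) == 0) next
    mem_u <- unco$clones$assignments$sequence[
      unco$clones$assignments$clone_id %in% u_clones]
    reads_c <- rep(mem_c, corr$bcr$annotated$abundance[
      match(mem_c, corr$bcr$annotated$sequence)])
    reads_u <- rep(mem_u, unco$bcr$annotated$abundance[
      match(mem_u, unco$bcr$annotated$sequence)])
    div <- intraclonal_diversity(
      list(corrected = reads_c, uncorrected = reads_u),
      frac = frac, repeats = repeats,
      seed = if (is.null(seed)) NULL else derive_seed(seed, cl_id))
    if (is.null(div)) next
    rows[[cl_id]] <- data.frame(clone_id = cl_id,
                                corrected = div[["corrected"]],
                                uncorrected = div[["uncorrected"]],
                                stringsAsFactors = FALSE)
  }
  clone_div <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clone_id = character(0), corrected = numeric(0),
               uncorrected = numeric(0))
  row.names(clone_div) <- NULL
  p_div <- if (nrow(clone_div) >= 2) {
    if (all(clone_div$corrected == clone_div$uncorrected)) 1 else
      suppressWarnings(wilcox.test(clone_div$corrected,
                                   clone_div$uncorrected, paired = TRUE,
                                   alternative = "less")$p.value)
  } else NA_real_

  list(
    corrected = list(n_molecules = nrow(cons$records), shm = corr$shm,
                     clones = corr$clones$clones, bcr = corr$bcr),
    uncorrected = list(n_molecules = length(std_keep), shm = unco$shm,
                       clones = unco$clones$clones, bcr = unco$bcr),
    clone_diversity = clone_div,
    p_diversity = p_div)
}
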