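# Best local alignment of each sequence against the V (or J) germline
# segments. Patterns are aligned once per germline gene (vectorised in C),
# then the best-scoring gene is chosen per sequence.
align_to_germline <- function(seqs, germline, class) {
  genes <- germline_genes(germline, class)
  if (nrow(genes) == 0) stop("germline reference has no ", class, " genes")
  pat <- Biostrings::DNAStringSet(seqs)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  ng <- nrow(genes)
  n <- length(seqs)
  alns <- vector("list", ng)
  mk <- function() matrix(NA_real_, n, ng)
  score <- mk(); pid <- mk(); mism <- mk(); indl <- mk()
  pstart <- mk(); sstart <- mk(); send <- mk()
  for (k in seq_len(ng)) {
    a <- Biostrings::pairwiseAlignment(
      pat, Biostrings::DNAString(genes$sequence[k]), type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    alns[[k]] <- a
    score[, k] <- Biostrings::score(a)
    pid[, k] <- Biostrings::pid(a)
    mism[, k] <- Biostrings::nmismatch(a)
    ni <- Biostrings::nindel(a)
    indl[, k] <- ni@insertion[, "WidthSum"] + ni@deletion[, "WidthSum"]
    pstart[, k] <- Biostrings::start(Biostrings::pattern(a))
    sstart[, k] <- Biostrings::start(Biostrings::subject(a))
    send[, k] <- Biostrings::end(Biostrings::subject(a))
  }
  pick <- max.col(score, ties.method = "first")
  at <- cbind(seq_len(n), pick)
  mut <- do.call(rbind, lapply(seq_len(ng), function(k) {
    rows <- which(pick == k)
    if (!length(rows)) return(NULL)
    mt <- Biostrings::mismatchTable(alns[[k]][rows])
    if (nrow(mt) == 0) return(NULL)
    data.frame(seq_index = rows[mt$PatternId],
               gene = genes$gene_id[k],
               subject_pos = mt$SubjectStart,
               pattern_pos = mt$PatternStart,
               from = as.character(mt$SubjectSubstring),
               to = as.character(mt$PatternSubstring),
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(
    gene = genes$gene_id[pick],
    score = score[at],
    pid = pid[at],
    mismatches = mism[at],
    indels = indl[at],
    p_start = pstart[at],
    s_start = sstart[at],
    s_end = send[at],
    stringsAsFactors = FALSE)
  attr(out, "mutations") <- mut
  out
}

# 1-based germline position of the start of a gene's CDR3 interval.
cdr3_anchor <- function(germline, gene_id) {
  r <- germline$regions
  hit <- r$gene_id == gene_id & r$region == "CDR3"
  if (!any(hit)) return(NA_integer_)
  r$start[hit][1] + 1L
}

#' Filter and annotate B-cell receptor sequences against a germline
#'
#' Aligns every unique sequence locally against all V and all J germline
#' segments, rejects sequences whose best V identity falls below
#' `min_identity` (non-immunoglobulin sequences), whose alignment carries
#' indels, whose CDR3 anchors (the conserved V-end cysteine codon and
#' J-start tryptophan codon given by the germline region map) cannot be
#' located, or whose V-frame translation through the junction contains a
#' stop codon or a frameshift (incomplete reading frame). Retained
#' sequences are annotated with gene usage, V mismatch count, CDR3
#' (nucleotide and, when in frame, amino acid) and a per-mutation table
#' with region (CDR vs FWR) and effect (silent vs non-silent).
#'
#' @param seqs Character vector of sequences (consensus molecules or plain
#'   reads); duplicates are collapsed with summed abundance.
#' @param germline A [germline_db].
#' @param min_identity Minimum V identity (default 0.80).
#' @param abundance Optional per-sequence abundance (molecule counts);
#'   defaults to the multiplicity of each sequence in `seqs`.
#' @return list with `annotated` (one row per retained unique sequence),
#'   `mutations` (one row per V/J substitution of a retained sequence) and
#'   `rejects` (unique sequence, reason).
#' @export
filter_bcr <- function(seqs, germline, min_identity = 0.8,
                       abundance = NULL) {
  stopifnot(length(seqs) >= 1)
  if (is.null(abundance)) {
    tab <- table(seqs)
    uniq <- names(tab)
    ab <- as.integer(tab)
  } else {
    stopifnot(length(abundance) == length(seqs))
    ab <- as.integer(tapply(abundance, seqs, sum))
    uniq <- names(ab)
    ab <- unname(ab)
  }
  v <- align_to_germline(uniq, germline, "V")
  j <- align_to_germline(uniq, germline, "J")
  vmut <- attr(v, "mutations")
  jmut <- attr(j, "mutations")

  # identity alone is meaningless for a short local hit: require the
  # alignment to cover at least half of the germline V segment as well
  vlen <- nchar(germline$genes$sequence[
    match(v$gene, germline$genes$gene_id)])
  v_cover <- (v$s_end - v$s_start + 1) / vlen
  reason <- rep(NA_character_, length(uniq))
  reason[v$pid / 100 < min_identity | v_cover < 0.5] <- "low_v_identity"
  reason[is.na(reason) & (v$indels > 0 | j$indels > 0)] <- "indel"

  vcys <- vapply(v$gene, function(g) cdr3_anchor(germline, g), integer(1))
  jtrp <- vapply(j$gene, function(g) cdr3_anchor(germline, g), integer(1))
  cys_read <- v$p_start + (vcys - v$s_start)
  trp_read <- j$p_start + (jtrp - j$s_start)
  len <- nchar(uniq)
  anchored <- !is.na(cys_read) & !is.na(trp_read) &
    cys_read >= 1 & trp_read > cys_read & trp_read + 2 <= len
  reason[is.na(reason) & !anchored] <- "no_cdr3"

  in_frame <- anchored & ((trp_read - cys_read) %% 3 == 0)
  cdr3_nt <- ifelse(anchored, substr(uniq, cys_read, trp_read + 2), NA)

  # translate in the V frame from the first codon-aligned position
  orf_ok <- rep(FALSE, length(uniq))
  for (i in which(is.na(reason))) {
    s0 <- v$p_start[i] - v$s_start[i] + 1  # read position of germline pos 1
    while (s0 < 1) s0 <- s0 + 3
    e0 <- min(len[i], (j$p_start[i] - j$s_start[i]) + j$s_end[i])
    if (e0 - s0 + 1 < 3) next
    aa <- translate_dna(substr(uniq[i], s0, e0))
    orf_ok[i] <- in_frame[i] && !is.na(aa) && !grepl("*", aa, fixed = TRUE)
  }
  reason[is.na(reason) & !orf_ok] <- "incomplete_orf"

  keep <- is.na(reason)
  cdr3_aa <- rep(NA_character_, length(uniq))
  cdr3_aa[keep] <- translate_dna(cdr3_nt[keep])

  annotated <- data.frame(
    sequence = uniq[keep], abundance = ab[keep],
    v_gene = v$gene[keep], j_gene = j$gene[keep],
    v_identity = v$pid[keep] / 100,
    v_mismatches = v$mismatches[keep],
    j_mismatches = j$mismatches[keep],
    cdr3_nt = cdr3_nt[keep], cdr3_aa = cdr3_aa[keep],
    in_frame = in_frame[keep],
    stringsAsFactors = FALSE, row.names = NULL)

  mutations <- classify_mutations(rbind(vmut, jmut), uniq, germline)
  if (!is.null(mutations)) {
    mutations <- mutations[keep[mutations$seq_index], , drop = FALSE]
    mutations$sequence <- uniq[mutations$seq_index]
    mutations$abundance <- ab[mutations$seq_index]
    row.names(mutations) <- NULL
  } else {
    mutations <- data.frame(seq_index = integer(0), gene = character(0),
                            position = integer(0), from = character(0),
                            to = character(0), region = character(0),
                            effect = character(0), sequence = character(0),
                            abundance = integer(0))
  }
  rejects <- data.frame(sequence = uniq[!keep], abundance = ab[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE,
                        row.names = NULL)
  list(annotated = annotated, mutations = mutations, rejects = rejects)
}

# Attach region (CDR/FWR) and effect (silent/non-silent) labels to a raw
# substitution table from the germline alignments.
classify_mutations <- function(mut, uniq, germline) {
  if (is.null(mut) || nrow(mut) == 0) return(NULL)
  genes <- germline$genes
  lab <- vapply(seq_len(nrow(mut)), function(i) {
    rl <- region_labels(germline, mut$gene[i])
    l <- rl[mut$subject_pos[i]]
    if (is.na(l) || l == "") "FWR" else if (startsWith(l, "CDR")) "CDR"
    else "FWR"
  }, character(1))
  effect <- vapply(seq_len(nrow(mut)), function(i) {
    gseq <- genes$sequence[match(mut$gene[i], genes$gene_id)]
    ci <- (mut$subject_pos[i] - 1) %/% 3
    gcodon <- substr(gseq, ci * 3 + 1, ci * 3 + 3)
    off <- mut$pattern_pos[i] - mut$subject_pos[i]
    rstart <- off + ci * 3 + 1
    rcodon <- substr(uniq[mut$seq_index[i]], rstart, rstart + 2)
    if (nchar(rcodon) < 3 || rstart < 1) return(NA_character_)
    ga <- translate_dna(gcodon); ra <- translate_dna(rcodon)
    if (is.na(ga) || is.na(ra)) NA_character_
    else if (ga == ra) "silent" else "non_silent"
  }, character(1))
  data.frame(seq_index = mut$seq_index, gene = mut$gene,
             position = mut$subject_pos, from = mut$from, to = mut$to,
             region = lab, effect = effect, stringsAsFactors = FALSE)
}

#' Build a Hamming-1 sequence network
#'
#' Vertices are unique sequences (abundance = number of identical reads or
#' molecules); edges join vertices of equal length differing by exactly
#' one substitution (indel differences never create edges); clusters are
#' connected components. Candidate neighbours are found by position-masked
#' hashing (linear in total sequence length), not by all-pairs comparison.
#'
#' @param sequences Character vector of sequences (duplicates collapsed).
#' @param abundance Optional per-sequence abundance; defaults to the
#'   multiplicity of each sequence.
#' @return Object of class `repertoire_graph`: list with `sequences`,
#'   `abundance`, `edges` (two-column index data.frame) and `membership`
#'   (connected-component id per vertex).
#' @export
build_network <- function(sequences, abundance = NULL) {
  stopifnot(length(sequences) >= 1)
  if (is.null(abundance)) {
    tab <- table(sequences)
    uniq <- names(tab); ab <- as.integer(tab)
  } else {
    stopifnot(length(abundance) == length(sequences))
    s <- tapply(abundance, sequences, sum)
    uniq <- names(s); ab <- as.integer(s)
  }
  n <- length(uniq)
  ei <- integer(0); ej <- integer(0)
  for (len in unique(nchar(uniq))) {
    idx <- which(nchar(uniq) == len)
    if (length(idx) < 2) next
    ss <- uniq[idx]
    for (pos in seq_len(len)) {
      key <- paste0(substr(ss, 1, pos - 1), ".", substring(ss, pos + 1))
      grp <- split(idx, key)
      grp <- grp[lengths(grp) > 1]
      for (g in grp) {
        pr <- utils::combn(sort(g), 2)
        ei <- c(ei, pr[1, ]); ej <- c(ej, pr[2, ])
      }
    }
  }
  edges <- data.frame(from = ei, to = ej)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  membership <- igraph::components(g)$membership
  structure(list(sequences = uniq, abundance = ab, edges = edges,
                 membership = as.integer(membership)),
            class = "repertoire_graph")
}

#' @export
print.repertoire_graph <- function(x, ...) {
  cat("repertoire_graph:", length(x$sequences), "vertices,",
      nrow(x$edges), "edges,", max(x$membership), "cluster(s)\n")
  invisible(x)
}

#' Assign clones from a repertoire network
#'
#' Clones start as the connected components of the Hamming-1 network;
#' components are then merged when they share an identical
#' (CDR3, V gene, J gene) combination, so clonally related sequences
#' split by more than one mutation still form one clone.
#'
#' @param graph A [build_network()] result.
#' @param annotated `annotated` data.frame from [filter_bcr()] covering
#'   the graph's sequences (sequences without annotation keep their
#'   component as their clone).
#' @return list with `assignments` (sequence, abundance, cluster,
#'   clone_id) and `clones` (clone_id, unique_sequences, total_reads),
#'   clones ordered by size.
#' @export
define_clones <- function(graph, annotated) {
  m <- match(graph$sequences, annotated$sequence)
  key <- ifelse(is.na(m), NA,
                paste(annotated$cdr3_nt[m], annotated$v_gene[m],
                      annotated$j_gene[m], sep = "|"))
  comp <- graph$membership
  parent <- seq_len(max(comp))
  findr <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in unique(key[!is.na(key)])) {
    comps <- unique(comp[which(!is.na(key) & key == k)])
    if (length(comps) > 1) {
      r0 <- findr(comps[1])
      for (c2 in comps[-1]) parent[findr(c2)] <- r0
    }
  }
  root <- vapply(comp, findr, integer(1))
  sizes <- tapply(graph$abundance, root, sum)
  ord <- order(-as.numeric(sizes))
  clone_map <- stats::setNames(sprintf("CL%04d", seq_along(ord)),
                               names(sizes)[ord])
  clone_id <- clone_map[as.character(root)]
  assignments <- data.frame(
    sequence = graph$sequences, abundance = graph$abundance,
    cluster = comp, clone_id = unname(clone_id),
    stringsAsFactors = FALSE, row.names = NULL)
  clones <- data.frame(
    clone_id = unname(clone_map),
    unique_sequences = as.integer(tapply(rep(1, nrow(assignments)),
                                         assignments$clone_id, sum)[clone_map]),
    total_reads = as.integer(tapply(assignments$abundance,
                                    assignments$clone_id, sum)[clone_map]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(assignments = assignments, clones = clones)
}

#' Rényi index of a weight distribution
#'
#' Order-`alpha` generalised entropy; `alpha = 1` (or values numerically
#' approaching 1) recovers Shannon entropy by continuity.
#'
#' @param weights Non-negative weights (normalised internally).
#' @param alpha Rényi order (default 2).
#' @return The Rényi index (natural log).
#' @export
renyi_index <- function(weights, alpha = 2) {
  w <- weights[weights > 0]
  w <- w / sum(w)
  if (alpha == 1) return(-sum(w * log(w)))
  log(sum(w^alpha)) / (1 - alpha)
}

#' Clonal diversification index
#'
#' Rényi index of the distribution of unique-sequence counts per clone,
#' computed on repeated subsamples of the repertoire and averaged.
#' Subsampling is clone-level by default (a fixed number of clones drawn
#' without replacement, matching a "specified depth of clones");
#' read-level subsampling (a fixed number of reads, clones recomputed on
#' the subsample) is available via `unit = "reads"`.
#'
#' @param assignments `assignments` data.frame from [define_clones()].
#' @param depth Subsample depth: clones (default 1000) or reads.
#' @param repeats Number of subsamples (default 100).
#' @param alpha Rényi order (default 2).
#' @param seed Optional seed.
#' @param unit `"clones"` (default) or `"reads"`.
#' @return Mean Rényi clonal diversification index over repeats.
#' @export
clonal_diversification_index <- function(assignments, depth = 1000L,
                                         repeats = 100L, alpha = 2,
                                         seed = NULL,
                                         unit = c("clones", "reads")) {
  unit <- match.arg(unit)
  stopifnot(nrow(assignments) >= 1)
  with_seed(seed, {
    if (unit == "clones") {
      u_by_clone <- tapply(rep(1, nrow(assignments)), assignments$clone_id,
                           sum)
      k <- length(u_by_clone)
      d <- min(depth, k)
      vals <- vapply(seq_len(repeats), function(r) {
        pick <- sample.int(k, d)
        renyi_index(as.numeric(u_by_clone[pick]), alpha)
      }, numeric(1))
    } else {
      reads_clone <- rep(assignments$clone_id, assignments$abundance)
      reads_seq <- rep(assignments$sequence, assignments$abundance)
      total <- length(reads_clone)
      if (total < depth)
        stop("only ", total, " reads; read-level depth ", depth,
             " not reachable")
      vals <- vapply(seq_len(repeats), function(r) {
        pick <- sample.int(total, depth)
        u <- tapply(reads_seq[pick], reads_clone[pick],
                    function(s) length(unique(s)))
        renyi_index(as.numeric(u), alpha)
      }, numeric(1))
    }
    mean(vals)
  })
}

#' Intraclonal diversity at matched depth
#'
#' For one clone observed under several filtering methods, subsamples each
#' method's reads to the same depth (`frac` times the smallest per-method
#' read count, floored) and counts unique sequences, averaging over
#' repeats. Matched-depth subsampling removes the read-depth advantage of
#' unfiltered data.
#'
#' @param clone_reads_by_method Named list: method name to character
#'   vector of the clone's reads (sequences, one element per read).
#' @param frac Depth fraction of the smallest method (default 0.75).
#' @param repeats Subsample repeats (default 50).
#' @param seed Optional seed.
#' @return Named numeric vector of mean unique-sequence counts per method,
#'   or `NULL` (with a message) when the matched depth is below 1.
#' @export
intraclonal_diversity <- function(clone_reads_by_method, frac = 0.75,
                                  repeats = 50L, seed = NULL) {
  stopifnot(is.list(clone_reads_by_method),
            length(clone_reads_by_method) >= 1,
            !is.null(names(clone_reads_by_method)))
  d <- floor(frac * min(lengths(clone_reads_by_method)))
  if (d < 1) {
    message("matched subsample depth < 1 read; clone skipped")
    return(NULL)
  }
  # common random numbers across methods: a paired comparison, and equal
  # read sets then give exactly equal means
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  vapply(clone_reads_by_method, function(reads) {
    with_seed(seed, mean(vapply(seq_len(repeats), function(r)
      length(unique(sample(reads, d))), numeric(1))))
  }, numeric(1))
}

#' Somatic hypermutation summary statistics
#'
#' Abundance-weighted repertoire features: the proportion of unmutated
#' sequences (V segment within 1 mismatch of the closest germline gene),
#' the silent-to-non-silent mutation ratio, the CDR/FWR mutation-location
#' ratio, and the mean CDR3 length in amino acids (in-frame sequences).
#' Ratios with a zero denominator are reported as `NA`.
#'
#' @param annotation Result of [filter_bcr()] (or its `annotated`
#'   data.frame plus a `mutations` argument).
#' @param mutations Mutation table when `annotation` is a data.frame.
#' @return list with `prop_unmutated`, `silent_to_nonsilent_ratio`,
#'   `cdr_fwr_mutation_ratio`, `mean_cdr3_aa_length`, `n_molecules`.
#' @export
shm_stats <- function(annotation, mutations = NULL) {
  if (is.list(annotation) && !is.data.frame(annotation)) {
    mutations <- annotation$mutations
    annotation <- annotation$annotated
  }
  stopifnot(is.data.frame(annotation))
  ab <- annotation$abundance
  total <- sum(ab)
  prop_unmutated <- if (total == 0) NA_real_ else
    sum(ab[annotation$v_mismatches <= 1]) / total
  sil <- nsil <- cdr <- fwr <- 0
  if (!is.null(mutations) && nrow(mutations) > 0) {
    w <- mutations$abundance %||% rep(1, nrow(mutations))
    sil <- sum(w[mutations$effect %in% "silent"])
    nsil <- sum(w[mutations$effect %in% "non_silent"])
    cdr <- sum(w[mutations$region %in% "CDR"])
    fwr <- sum(w[mutations$region %in% "FWR"])
  }
  infr <- annotation$in_frame & !is.na(annotation$cdr3_aa)
  mean_len <- if (sum(ab[infr]) == 0) NA_real_ else
    sum(nchar(annotation$cdr3_aa[infr]) * ab[infr]) / sum(ab[infr])
  list(prop_unmutated = prop_unmutated,
       silent_to_nonsilent_ratio = if (nsil == 0) NA_real_ else sil / nsil,
       cdr_fwr_mutation_ratio = if (fwr == 0) NA_real_ else cdr / fwr,
       mean_cdr3_aa_length = mean_len,
       n_molecules = total)
}

#' Representative network subsample for visualisation
#'
#' Draws `repeats` clone-level subsamples of up to `n_clones` clones,
#' records each subsample's maximum clone size, selects the subsample
#' whose maximum is closest to the median of the recorded maxima (ties go
#' to the lowest repeat index), then subsamples `n_bcrs` reads from the
#' selected clones and rebuilds the network — preserving the relative
#' clonal architecture at a drawable size.
#'
#' @param assignments `assignments` data.frame from [define_clones()].
#' @param n_clones Clones per subsample (default 1000).
#' @param repeats Number of subsamples scored (default 100).
#' @param n_bcrs Reads drawn from the selected clone set (default 500).
#' @param seed Optional seed.
#' @return list with `graph` (the rebuilt [build_network()] object),
#'   `selected_clones`, `selected_repeat` and `max_sizes`.
#' @export
viz_subsample <- function(assignments, n_clones = 1000L, repeats = 100L,
                          n_bcrs = 500L, seed = NULL) {
  stopifnot(nrow(assignments) >= 1)
  clone_ids <- unique(assignments$clone_id)
  k <- length(clone_ids)
  size <- tapply(assignments$abundance, assignments$clone_id, sum)
  with_seed(seed, {
    d <- min(n_clones, k)
    picks <- lapply(seq_len(repeats), function(r) sample(clone_ids, d))
    max_sizes <- vapply(picks, function(p) max(size[p]), numeric(1))
    med <- median(max_sizes)
    sel <- which.min(abs(max_sizes - med))  # lowest index on ties
    chosen <- picks[[sel]]
    sub <- assignments[assignments$clone_id %in% chosen, , drop = FALSE]
    reads <- rep(sub$sequence, sub$abundance)
    reads <- sample(reads, min(n_bcrs, length(reads)))
    list(graph = build_network(reads), selected_clones = chosen,
         selected_repeat = sel, max_sizes = max_sizes)
  })
}
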