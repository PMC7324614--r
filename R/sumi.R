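first_match <- function(seqs, pattern, mm) {
  idx <- Biostrings::startIndex(Biostrings::vmatchPattern(
    pattern, Biostrings::DNAStringSet(seqs), max.mismatch = mm,
    fixed = "subject"))
  vapply(idx, function(x) if (length(x)) min(x) else NA_integer_,
         integer(1))
}

last_match <- function(seqs, pattern, mm) {
  idx <- Biostrings::startIndex(Biostrings::vmatchPattern(
    pattern, Biostrings::DNAStringSet(seqs), max.mismatch = mm,
    fixed = "subject"))
  vapply(idx, function(x) if (length(x)) max(x) else NA_integer_,
         integer(1))
}

# Best (fewest-mismatch) primer for fixed-width windows; ties go to the
# first primer in the spec.
best_primer <- function(windows, primers) {
  mm <- vapply(primers, function(p) count_mismatches(windows, p),
               numeric(length(windows)))
  mm <- matrix(mm, nrow = length(windows))
  best <- max.col(-mm, ties.method = "first")
  list(primer = names(primers)[best],
       mismatches = mm[cbind(seq_along(windows), best)])
}

#' Identify primers and extract UMIs from merged reads
#'
#' Searches each read and its reverse complement for the forward MALBAC
#' tail and the (reverse-complemented) reverse MALBAC tail, orients the
#' read forward-primer 5', extracts the two primer UMIs at their layout
#' offsets, verifies the gene-specific regions (IUPAC-aware, at most
#' `max_primer_mismatches` mismatches each) and the conserved bases
#' flanking the UMIs, and excises all primer segments to yield the insert.
#' When the spec declares a synthetic-UMI window or sample barcodes, those
#' are extracted as well.
#'
#' @param seqs Character vector of merged read sequences.
#' @param spec A [primer_spec].
#' @param ids Optional read identifiers.
#' @return data.frame with one row per read: `read_id`, `insert`,
#'   `fwd_umi`, `rev_umi`, `fwd_primer`, `rev_primer`, `synthetic_umi`,
#'   `sample`, `was_reverse_complemented`, and `reason` (`NA` for accepted
#'   reads, `"no_primer"` or `"barcode_structure"` otherwise).
#' @export
locate_primers <- function(seqs, spec, ids = NULL) {
  if (is.data.frame(seqs)) {
    ids <- ids %||% seqs$read_id
    seqs <- seqs$sequence
  }
  ids <- ids %||% sprintf("S%06d", seq_along(seqs))
  n <- length(seqs)
  mm <- spec$max_primer_mismatches
  rc_rev_malbac <- revcomp(spec$rev_malbac)

  scan <- function(s) list(m1 = first_match(s, spec$fwd_malbac, mm),
                           m2 = last_match(s, rc_rev_malbac, mm))
  o1 <- scan(seqs)
  rcs <- revcomp(seqs)
  o2 <- scan(rcs)
  ok1 <- !is.na(o1$m1) & !is.na(o1$m2) & o1$m2 > o1$m1
  ok2 <- !is.na(o2$m1) & !is.na(o2$m2) & o2$m2 > o2$m1
  use_rc <- !ok1 & ok2
  s <- ifelse(use_rc, rcs, seqs)
  m1 <- ifelse(use_rc, o2$m1, o1$m1)
  m2 <- ifelse(use_rc, o2$m2, o1$m2)
  found <- ok1 | ok2

  lf <- nchar(spec$fwd_malbac); lr <- nchar(spec$rev_malbac)
  u <- spec$umi_length
  gf <- nchar(spec$fwd_gs[1]); gr <- nchar(spec$rev_gs[1])
  e1 <- m1 + lf - 1
  layout_ok <- found & !is.na(m2) &
    (m2 - u - gr - 1) >= (e1 + u + gf + 1) &  # non-empty insert
    (m2 - u - gr) >= 1

  fwd_umi <- ifelse(layout_ok, substr(s, e1 + 1, e1 + u), NA)
  rev_umi <- ifelse(layout_ok, revcomp0(substr(s, m2 - u, m2 - 1)), NA)
  gs_f <- ifelse(layout_ok, substr(s, e1 + u + 1, e1 + u + gf), NA)
  gs_r <- ifelse(layout_ok, substr(s, m2 - u - gr, m2 - u - 1), NA)

  bf <- best_primer(gs_f, spec$fwd_gs)
  rc_rev_gs <- revcomp(spec$rev_gs)
  names(rc_rev_gs) <- names(spec$rev_gs)
  br <- best_primer(gs_r, rc_rev_gs)
  gs_ok <- layout_ok & bf$mismatches <= mm & br$mismatches <= mm

  cons_ok <- rep(TRUE, n)
  if (length(spec$conserved_fwd)) {
    win <- substr(s, m1, m1 + lf - 1)
    for (off in spec$conserved_fwd)
      cons_ok <- cons_ok &
        substr(win, off, off) == substr(spec$fwd_malbac, off, off)
  }
  if (length(spec$conserved_rev)) {
    win <- substr(s, m2, m2 + lr - 1)
    for (off in spec$conserved_rev)
      cons_ok <- cons_ok &
        substr(win, off, off) == substr(rc_rev_malbac, off, off)
  }
  cons_ok[is.na(cons_ok)] <- FALSE

  reason <- rep(NA_character_, n)
  reason[!gs_ok] <- "no_primer"
  reason[gs_ok & !cons_ok] <- "barcode_structure"
  accept <- is.na(reason)

  insert <- rep(NA_character_, n)
  insert[accept] <- substr(s[accept], e1[accept] + u + gf + 1,
                           m2[accept] - u - gr - 1)

  su <- rep(NA_character_, n)
  if (!is.na(spec$synthetic_umi_offset) && spec$synthetic_umi_length > 0) {
    o <- spec$synthetic_umi_offset
    w <- spec$synthetic_umi_length
    su[accept] <- substr(insert[accept], o + 1, o + w)
    su[!is.na(su) & nchar(su) != w] <- NA
  }

  sample_name <- rep(NA_character_, n)
  if (!is.null(spec$sample_barcodes)) {
    bl <- nchar(spec$sample_barcodes[1])
    win <- ifelse(accept, substr(s, m2 + lr, m2 + lr + bl - 1), NA)
    bb <- best_primer(win, spec$sample_barcodes)
    hit <- accept & bb$mismatches <= 1
    sample_name[hit] <- bb$primer[hit]
  }

  data.frame(
    read_id = ids,
    insert = insert,
    fwd_umi = ifelse(accept, fwd_umi, NA),
    rev_umi = ifelse(accept, rev_umi, NA),
    fwd_primer = ifelse(accept, bf$primer, NA),
    rev_primer = ifelse(accept, br$primer, NA),
    synthetic_umi = su,
    sample = sample_name,
    was_reverse_complemented = use_rc,
    reason = reason,
    stringsAsFactors = FALSE, row.names = NULL)
}

# revcomp that passes NA through
revcomp0 <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- revcomp(x[ok])
  out
}

#' Group annotated reads by their primer-UMI pair
#'
#' Exact-match grouping on the (forward UMI, reverse UMI) pair; groups are
#' returned in lexicographic key order. Reads rejected during primer
#' identification are excluded.
#'
#' @param annotated Output of [locate_primers()].
#' @return list of groups, each a list with `fwd_umi`, `rev_umi`,
#'   `read_ids` and `sequences` (the member inserts).
#' @export
group_by_umi <- function(annotated) {
  ok <- which(is.na(annotated$reason))
  if (!length(ok)) return(list())
  key <- paste(annotated$fwd_umi[ok], annotated$rev_umi[ok], sep = "+")
  idx <- split(ok, key)
  idx <- idx[order(names(idx), method = "radix")]
  lapply(names(idx), function(k) {
    i <- idx[[k]]
    list(fwd_umi = annotated$fwd_umi[i[1]],
         rev_umi = annotated$rev_umi[i[1]],
         read_ids = annotated$read_id[i],
         sequences = annotated$insert[i])
  })
}

#' Call a consensus sequence for one UMI group
#'
#' Members are sub-grouped by length and the plurality-length sub-group is
#' compared positionally (a tie between length classes discards the
#' group). For groups of `small_group_max` or fewer retained reads, all
#' must be identical; for larger groups the consensus base at each
#' position is the plurality base, and the group is retained only if every
#' position's plurality fraction is at least `min_agreement`. The reported
#' agreement is the minimum positional plurality fraction.
#'
#' @param sequences Character vector of member inserts (or a group from
#'   [group_by_umi()]).
#' @param min_agreement Per-position plurality fraction required for
#'   groups larger than `small_group_max` (default 0.8).
#' @param small_group_max Largest group size required to agree completely
#'   (default 4).
#' @return list with `consensus`, `support`, `agreement` and `reason`
#'   (`NA` when retained; `"length_tie"` or `"disagreement"` when the
#'   group is discarded, with `consensus = NA`).
#' @export
call_consensus <- function(sequences, min_agreement = 0.8,
                           small_group_max = 4L) {
  if (is.list(sequences)) sequences <- sequences$sequences
  stopifnot(length(sequences) >= 1)
  lens <- nchar(sequences)
  tab <- table(lens)
  top <- max(tab)
  if (sum(tab == top) > 1)
    return(list(consensus = NA_character_, support = length(sequences),
                agreement = NA_real_, reason = "length_tie"))
  keep_len <- as.integer(names(tab)[which.max(tab)])
  members <- sequences[lens == keep_len]
  support <- length(members)
  if (length(unique(members)) == 1)
    return(list(consensus = members[1], support = support,
                agreement = 1, reason = NA_character_))
  if (support <= small_group_max)
    return(list(consensus = NA_character_, support = support,
                agreement = NA_real_, reason = "disagreement"))
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(members))
  frac <- apply(cm, 2, max) / support
  agreement <- min(frac)
  if (agreement < min_agreement)
    return(list(consensus = NA_character_, support = support,
                agreement = agreement, reason = "disagreement"))
  cons <- paste(rownames(cm)[apply(cm, 2, which.max)], collapse = "")
  list(consensus = cons, support = support, agreement = agreement,
       reason = NA_character_)
}

#' Call consensus sequences for all UMI groups
#'
#' @param groups Output of [group_by_umi()].
#' @inheritParams call_consensus
#' @return list with `records` (data.frame of retained consensus
#'   molecules: `fwd_umi`, `rev_umi`, `consensus`, `support`,
#'   `agreement`) and `rejects` (data.frame of discarded groups with the
#'   discard `reason`).
#' @export
consensus_from_groups <- function(groups, min_agreement = 0.8,
                                  small_group_max = 4L) {
  res <- lapply(groups, function(g)
    call_consensus(g$sequences, min_agreement, small_group_max))
  keep <- vapply(res, function(r) is.na(r$reason), logical(1))
  fwd <- vapply(groups, `[[`, character(1), "fwd_umi")
  rev <- vapply(groups, `[[`, character(1), "rev_umi")
  records <- data.frame(
    fwd_umi = fwd[keep], rev_umi = rev[keep],
    consensus = vapply(res[keep], `[[`, character(1), "consensus"),
    support = vapply(res[keep], `[[`, numeric(1), "support"),
    agreement = vapply(res[keep], `[[`, numeric(1), "agreement"),
    stringsAsFactors = FALSE, row.names = NULL)
  rejects <- data.frame(
    fwd_umi = fwd[!keep], rev_umi = rev[!keep],
    n_members = vapply(groups[!keep], function(g) length(g$sequences),
                       numeric(1)),
    reason = vapply(res[!keep], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(records = records, rejects = rejects)
}

#' Standard (non-barcoded) filtering
#'
#' Locates the gene-specific primer annealing regions at both ends of each
#' read (in either orientation), discards reads lacking either, and
#' returns the primer-excised insert of every surviving read. No UMI
#' extraction, grouping or consensus: every read contributes one sequence,
#' which is what "ignoring the barcode information" means downstream.
#'
#' @param seqs Character vector of merged reads (or a data.frame with
#'   `read_id` and `sequence` columns).
#' @param spec A [primer_spec].
#' @param ids Optional read identifiers.
#' @return data.frame with `read_id`, `insert`, `fwd_primer`,
#'   `rev_primer`, `was_reverse_complemented`, `reason` (`NA` if
#'   retained).
#' @export
standard_filter <- function(seqs, spec, ids = NULL) {
  if (is.data.frame(seqs)) {
    ids <- ids %||% seqs$read_id
    seqs <- seqs$sequence
  }
  ids <- ids %||% sprintf("S%06d", seq_along(seqs))
  n <- length(seqs)
  mm <- spec$max_primer_mismatches
  gf <- nchar(spec$fwd_gs[1]); gr <- nchar(spec$rev_gs[1])
  rc_rev_gs <- revcomp(spec$rev_gs)
  names(rc_rev_gs) <- names(spec$rev_gs)

  scan <- function(s) {
    m1 <- rep(NA_integer_, length(s)); p1 <- rep(NA_character_, length(s))
    for (k in seq_along(spec$fwd_gs)) {
      cand <- first_match(s, spec$fwd_gs[k], mm)
      upd <- !is.na(cand) & (is.na(m1) | cand < m1)
      m1[upd] <- cand[upd]; p1[upd] <- names(spec$fwd_gs)[k]
    }
    m2 <- rep(NA_integer_, length(s)); p2 <- rep(NA_character_, length(s))
    for (k in seq_along(rc_rev_gs)) {
      cand <- last_match(s, rc_rev_gs[k], mm)
      upd <- !is.na(cand) & (is.na(m2) | cand > m2)
      m2[upd] <- cand[upd]; p2[upd] <- names(rc_rev_gs)[k]
    }
    list(m1 = m1, m2 = m2, p1 = p1, p2 = p2)
  }
  o1 <- scan(seqs)
  rcs <- revcomp(seqs)
  o2 <- scan(rcs)
  valid <- function(o) !is.na(o$m1) & !is.na(o$m2) & o$m2 > o$m1 + gf
  use_rc <- !valid(o1) & valid(o2)
  s <- ifelse(use_rc, rcs, seqs)
  o <- lapply(names(o1), function(f) ifelse(use_rc, o2[[f]], o1[[f]]))
  names(o) <- names(o1)
  ok <- valid(o1) | valid(o2)

  insert <- rep(NA_character_, n)
  insert[ok] <- substr(s[ok], o$m1[ok] + gf, o$m2[ok] - 1)
  data.frame(
    read_id = ids, insert = insert,
    fwd_primer = ifelse(ok, o$p1, NA), rev_primer = ifelse(ok, o$p2, NA),
    was_reverse_complemented = use_rc,
    reason = ifelse(ok, NA_character_, "no_primer"),
    stringsAsFactors = FALSE, row.names = NULL)
}
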