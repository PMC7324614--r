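#' Read paired FASTQ files
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files (Phred+33).
#' @return data.frame with columns `read_id`, `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`.
#' @export
read_paired_fastq <- function(r1, r2) {
  f <- read_fastq(r1)
  r <- read_fastq(r2)
  if (nrow(f) != nrow(r))
    stop("R1 and R2 differ in record count (", nrow(f), " vs ", nrow(r), ")")
  if (!all(f$read_id == r$read_id))
    stop("R1/R2 read identifiers do not match at record ",
         which(f$read_id != r$read_id)[1])
  data.frame(read_id = f$read_id,
             fwd_seq = f$seq, fwd_qual = f$qual,
             rev_seq = r$seq, rev_qual = r$qual,
             stringsAsFactors = FALSE)
}

# data.frame of pairs from in-memory simulator output
pairs_from_sim <- function(sim) {
  data.frame(read_id = sim$reads$read_id,
             fwd_seq = sim$reads$r1_seq, fwd_qual = sim$reads$r1_qual,
             rev_seq = sim$reads$r2_seq, rev_qual = sim$reads$r2_qual,
             stringsAsFactors = FALSE)
}

#' Median base-quality filter
#'
#' A pair survives only if BOTH mates have median Phred quality strictly
#' greater than `min_median_phred`. The median of an even-length vector is
#' the lower of the two central values (conservative convention applied
#' everywhere in the package). Survivors pass through unmodified.
#'
#' @param pairs data.frame as returned by [read_paired_fastq()].
#' @param min_median_phred Threshold (default 32; strict inequality).
#' @return The surviving rows of `pairs`.
#' @export
quality_filter <- function(pairs, min_median_phred = 32) {
  if (nrow(pairs) == 0) return(pairs)
  med <- function(q) vapply(q, function(s) lower_median(phred_values(s)),
                            numeric(1), USE.NAMES = FALSE)
  keep <- med(pairs$fwd_qual) > min_median_phred &
          med(pairs$rev_qual) > min_median_phred
  pairs[keep, , drop = FALSE]
}

#' Merge read pairs over an exact overlap
#'
#' Scans overlap offsets between the forward read and the reverse
#' complement of the reverse read, longest first, and merges at the first
#' (hence longest) offset where the overlap is exactly identical and at
#' least `min_overlap` bases long; pairs with no such overlap are
#' discarded. The merged sequence is the forward read followed by the
#' non-overlapping tail of the reverse-complemented mate.
#'
#' @param pairs data.frame of read pairs (normally after
#'   [quality_filter()]).
#' @param min_overlap Minimum identical overlap (default 51, i.e. strictly
#'   more than 50 bases).
#' @return data.frame with columns `read_id`, `sequence`,
#'   `overlap_length`, one row per merged pair.
#' @export
merge_pairs <- function(pairs, min_overlap = 51L) {
  n <- nrow(pairs)
  if (n == 0)
    return(data.frame(read_id = character(0), sequence = character(0),
                      overlap_length = integer(0)))
  rcrev <- revcomp(pairs$rev_seq)
  fwd <- pairs$fwd_seq
  la <- nchar(fwd); lb <- nchar(rcrev)
  seqs <- character(n); ovl <- integer(n); merged <- logical(n)
  # any candidate overlap contains the first k bases of rc(rev), so exact
  # occurrences of that seed in fwd enumerate all possible offsets
  k <- min(12L, min_overlap)
  for (i in seq_len(n)) {
    hi <- min(la[i], lb[i])
    if (hi < min_overlap) next
    seed <- substr(rcrev[i], 1, k)
    pos <- gregexpr(seed, fwd[i], fixed = TRUE)[[1]]
    if (pos[1] == -1) next
    for (p in pos) {  # ascending p = descending overlap (longest first)
      ov <- la[i] - p + 1
      if (ov > hi || ov < min_overlap) next
      if (substring(fwd[i], p) == substr(rcrev[i], 1, ov)) {
        seqs[i] <- paste0(fwd[i], substring(rcrev[i], ov + 1))
        ovl[i] <- ov
        merged[i] <- TRUE
        break
      }
    }
  }
  data.frame(read_id = pairs$read_id[merged], sequence = seqs[merged],
             overlap_length = ovl[merged], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Quality-filter and merge paired reads
#'
#' @param pairs data.frame of read pairs, or a length-2 character vector
#'   of FASTQ paths `c(r1, r2)`.
#' @inheritParams quality_filter
#' @inheritParams merge_pairs
#' @return list with `merged` (data.frame) and `counts` (per-stage read
#'   counts: input, quality_pass, merged).
#' @export
preprocess_reads <- function(pairs, min_median_phred = 32,
                             min_overlap = 51L) {
  if (is.character(pairs)) {
    stopifnot(length(pairs) == 2)
    pairs <- read_paired_fastq(pairs[1], pairs[2])
  }
  n_in <- nrow(pairs)
  qc <- quality_filter(pairs, min_median_phred)
  merged <- merge_pairs(qc, min_overlap)
  list(merged = merged,
       counts = list(input = n_in, quality_pass = nrow(qc),
                     merged = nrow(merged)))
}
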