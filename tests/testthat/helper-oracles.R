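# Independent brute-force oracles used to cross-check the implementation.

# Consensus caller written from the rules directly: explicit position
# loops and base tabulation, no shared code with call_consensus().
consensus_oracle <- function(seqs, min_agreement = 0.8,
                             small_group_max = 4L) {
  lens <- nchar(seqs)
  cnt <- table(lens)
  best <- max(cnt)
  if (sum(cnt == best) > 1)
    return(list(consensus = NA_character_, support = length(seqs),
                agreement = NA_real_, reason = "length_tie"))
  members <- seqs[lens == as.integer(names(cnt)[which.max(cnt)])]
  n <- length(members)
  if (n <= small_group_max) {
    if (all(members == members[1]))
      return(list(consensus = members[1], support = n, agreement = 1,
                  reason = NA_character_))
    return(list(consensus = NA_character_, support = n,
                agreement = NA_real_, reason = "disagreement"))
  }
  chars <- do.call(rbind, strsplit(members, ""))
  cons <- character(ncol(chars))
  fracs <- numeric(ncol(chars))
  for (p in seq_len(ncol(chars))) {
    tt <- sort(table(chars[, p]), decreasing = TRUE)
    cons[p] <- names(tt)[1]
    fracs[p] <- tt[1] / n
  }
  if (min(fracs) < min_agreement)
    return(list(consensus = NA_character_, support = n,
                agreement = min(fracs), reason = "disagreement"))
  list(consensus = paste(cons, collapse = ""), support = n,
       agreement = min(fracs), reason = NA_character_)
}

# O(n^2) Hamming-1 oracle via position-wise accumulation of a full
# pairwise distance matrix (independent of the hashed implementation).
hamming_oracle_edges_matrix <- function(uniq) {
  ei <- integer(0); ej <- integer(0)
  for (len in unique(nchar(uniq))) {
    idx <- which(nchar(uniq) == len)
    if (length(idx) < 2) next
    m <- do.call(rbind, strsplit(uniq[idx], ""))
    D <- matrix(0L, length(idx), length(idx))
    for (p in seq_len(len)) D <- D + outer(m[, p], m[, p], "!=")
    hit <- which(D == 1 & upper.tri(D), arr.ind = TRUE)
    if (nrow(hit)) {
      ei <- c(ei, idx[hit[, 1]])
      ej <- c(ej, idx[hit[, 2]])
    }
  }
  data.frame(from = pmin(ei, ej), to = pmax(ei, ej))
}

# O(n^2) Hamming-1 edge enumeration over unique sequences.
hamming_oracle_edges <- function(uniq) {
  ei <- integer(0); ej <- integer(0)
  for (len in unique(nchar(uniq))) {
    idx <- which(nchar(uniq) == len)
    if (length(idx) < 2) next
    m <- do.call(rbind, strsplit(uniq[idx], ""))
    for (a in seq_len(length(idx) - 1)) {
      for (b in seq(a + 1, length(idx))) {
        if (sum(m[a, ] != m[b, ]) == 1) {
          ei <- c(ei, min(idx[a], idx[b]))
          ej <- c(ej, max(idx[a], idx[b]))
        }
      }
    }
  }
  ord <- order(ei, ej)
  data.frame(from = ei[ord], to = ej[ord])
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to)))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A group of reads around one true sequence, with iid substitution errors
# and occasional length-variant members (truncation/extension).
random_group <- function(size, len, error) {
  truth <- random_seq(len)
  seqs <- vapply(seq_len(size), function(i) {
    s <- truth
    nerr <- rbinom(1, len, error)
    if (nerr > 0) {
      for (p in sample.int(len, nerr)) {
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, p, p)), 1)
      }
    }
    if (runif(1) < 0.08) {  # occasional indel-bearing minority read
      if (runif(1) < 0.5) s <- substr(s, 1, nchar(s) - 1)
      else s <- paste0(s, sample(c("A", "C", "G", "T"), 1))
    }
    s
  }, character(1))
  seqs
}

# Shared small error-free simulation, built once per test run.
.fx <- new.env()
fx_sim_clean <- function() {
  if (is.null(.fx$clean)) {
    cfg <- sim_config(n_templates = 40, sequencing_depth = 1500,
                      seq_error_rate = 0, qual_pass_fraction = 1,
                      seed = 424242)
    .fx$clean <- simulate_sumi_experiment(cfg)
  }
  .fx$clean
}

sim_pairs <- function(sim) {
  data.frame(read_id = sim$reads$read_id,
             fwd_seq = sim$reads$r1_seq, fwd_qual = sim$reads$r1_qual,
             rev_seq = sim$reads$r2_seq, rev_qual = sim$reads$r2_qual,
             stringsAsFactors = FALSE)
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

qual_string <- function(phreds) intToUtf8(phreds + 33L)
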