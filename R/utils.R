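#' @importFrom stats median rbeta rbinom runif lm coef residuals wilcox.test setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's RNG stream. A `NULL` seed evaluates the expression
#' with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic hash of a master seed and a stage label, kept below
#' 2^31 so it is a valid R integer seed. Distinct stages of a pipeline run
#' get independent, individually reproducible streams.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (abs(seed) %% m) * 7919) %% m)
}

#' Random DNA sequences
#' @param n Number of sequences.
#' @param width Length of each sequence.
#' @return Character vector of length `n`.
#' @keywords internal
random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * width, replace = TRUE)
  apply(matrix(chars, nrow = width), 2, paste, collapse = "")
}

#' Reverse complement of character DNA sequences
#' @param x Character vector of DNA sequences (IUPAC codes allowed).
#' @return Character vector.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Lower median: for an even-length vector, the lower of the two central
# values. Applied identically to all quality filtering.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[(n + 1L) %/% 2L]
}

phred_values <- function(qual) utf8ToInt(qual) - 33L

# Apply iid substitution errors at per-base `rate` to each sequence.
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  widths <- nchar(seqs)
  n_err <- rbinom(length(seqs), widths, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Write a FASTQ file (Phred+33)
#' @param ids Read identifiers.
#' @param seqs DNA sequences.
#' @param quals Quality strings (Phred+33), same widths as `seqs`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qs <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ path.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  out <- tryCatch({
    # Biostrings warns about dropped metadata columns on every FASTQ read
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    data.frame(
      read_id = sub("\\s.*$", "", names(x)),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x)),
      stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  bad <- which(nchar(out$seq, type = "bytes") !=
               nchar(out$qual, type = "bytes"))
  if (length(bad))
    stop("malformed FASTQ '", path, "': sequence/quality length mismatch ",
         "at record ", bad[1], call. = FALSE)
  out
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Largest-remainder apportionment of n items over fractions summing to 1.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Codons that do not encode a stop.
stopfree_codons <- function() {
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

# Codon-table translation ("*" = stop, "X" = untranslatable codon).
translate_dna <- function(x) {
  gc <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) < 3) return(NA_character_)
    n <- nchar(s) - nchar(s) %% 3
    aa <- gc[substring(s, seq(1, n, 3), seq(3, n, 3))]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
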