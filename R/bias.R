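#' Build a synthetic-UMI / primer-barcode link table
#'
#' One row per retained read linking its internal synthetic DNA-UMI to the
#' primer-UMI pair that captured it.
#'
#' @param annotated Output of [locate_primers()] on a synthetic-UMI
#'   library (the primer spec must declare the synthetic-UMI window).
#' @return data.frame with columns `read_id`, `synthetic_umi`, `fwd_umi`,
#'   `rev_umi`.
#' @export
umi_link_table <- function(annotated) {
  ok <- is.na(annotated$reason) & !is.na(annotated$synthetic_umi)
  out <- annotated[ok, c("read_id", "synthetic_umi", "fwd_umi", "rev_umi")]
  row.names(out) <- NULL
  out
}

#' Loop re-amplification rate per 1000 reads
#'
#' The proportion of reads whose synthetic DNA-UMI is associated with more
#' than one distinct primer-barcode pair, normalised to the total read
#' count and reported per 1000 reads. This quantifies how often looped
#' first-PCR products escaped and were re-barcoded (plus re-priming of the
#' same template molecule, which the metric cannot distinguish).
#'
#' @param link_table Output of [umi_link_table()].
#' @return Rate per 1000 reads.
#' @export
loop_reamp_rate <- function(link_table) {
  n <- nrow(link_table)
  if (n == 0) stop("empty link table: rate undefined")
  pair <- paste(link_table$fwd_umi, link_table$rev_umi, sep = "+")
  n_pairs <- tapply(pair, link_table$synthetic_umi,
                    function(p) length(unique(p)))
  multi <- names(n_pairs)[n_pairs > 1]
  1000 * sum(link_table$synthetic_umi %in% multi) / n
}

#' Subsampled relative amplification bias
#'
#' Repeatedly subsamples the read set to a fixed depth without replacement
#' and records, per subsample, the maximum number of reads carrying the
#' same synthetic DNA-UMI; the mean over repeats is the relative
#' amplification bias. Equal-depth subsampling makes the statistic
#' comparable across filtering methods and samples.
#'
#' @param read_umi_counts Integer vector of read counts per synthetic
#'   DNA-UMI (a `table` works), or a character vector of per-read
#'   synthetic-UMI labels.
#' @param depth Subsample depth in reads (default 3000).
#' @param repeats Number of subsamples (default 500).
#' @param seed Optional seed for reproducible subsampling.
#' @return Object of class `bias_result`: list with `mean_bias`, `depth`,
#'   `repeats`, `seed` and `per_repeat` (the per-subsample maxima).
#' @export
amplification_bias <- function(read_umi_counts, depth = 3000L,
                               repeats = 500L, seed = NULL) {
  if (is.character(read_umi_counts) || is.factor(read_umi_counts)) {
    read_umi_counts <- table(read_umi_counts)
  }
  counts <- as.integer(read_umi_counts)
  stopifnot(all(counts >= 0), repeats >= 1, depth >= 1)
  total <- sum(counts)
  if (total < depth)
    stop("only ", total, " reads available; subsample depth ", depth,
         " requires at least that many")
  labels <- rep.int(seq_along(counts), counts)
  nbins <- length(counts)
  per_repeat <- with_seed(seed, vapply(seq_len(repeats), function(r) {
    max(tabulate(labels[sample.int(total, depth)], nbins = nbins))
  }, numeric(1)))
  structure(list(mean_bias = mean(per_repeat), depth = depth,
                 repeats = repeats, seed = seed, per_repeat = per_repeat),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat("amplification bias: mean max reads per synthetic UMI =",
      format(x$mean_bias), "(depth", x$depth, ",", x$repeats, "repeats)\n")
  invisible(x)
}

#' Compare amplification bias between filtering methods
#'
#' Applies [amplification_bias()] to each method and sample and tests
#' pairwise differences between methods with a Wilcoxon signed-rank test
#' paired by sample name (or an unpaired rank-sum test when
#' `paired = FALSE`). With a single sample the test is skipped and only
#' descriptive output is returned. All-zero paired differences are
#' reported as p = 1 (non-significant), the degenerate case the signed-rank
#' statistic cannot rank.
#'
#' @param methods Named list: one element per method, itself a named list
#'   of per-sample read-UMI count vectors (see [amplification_bias()]);
#'   sample names must match across methods when `paired = TRUE`.
#' @inheritParams amplification_bias
#' @param paired Pair samples by name (default) or compare unpaired.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return list with `results` (data.frame of method, sample, mean_bias)
#'   and `p_values` (matrix of pairwise p-values, `NA` where skipped).
#' @export
compare_bias <- function(methods, depth = 3000L, repeats = 500L,
                         seed = NULL, paired = TRUE,
                         alternative = "two.sided") {
  stopifnot(is.list(methods), length(methods) >= 2,
            !is.null(names(methods)))
  samples <- lapply(methods, names)
  if (paired) {
    ref <- samples[[1]]
    if (!all(vapply(samples, function(s) identical(sort(s), sort(ref)),
                    logical(1))))
      stop("paired comparison requires identical sample names per method")
  }
  rows <- list()
  mb <- list()
  for (m in names(methods)) {
    # seeds derived per sample (not per method): identical count tables
    # then give identical subsamples, and comparisons share randomness
    vals <- vapply(names(methods[[m]]), function(s) {
      amplification_bias(methods[[m]][[s]], depth, repeats,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, s))$mean_bias
    }, numeric(1))
    mb[[m]] <- vals
    rows[[m]] <- data.frame(method = m, sample = names(vals),
                            mean_bias = unname(vals),
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  row.names(results) <- NULL
  nm <- names(methods)
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  n_samples <- length(methods[[1]])
  if (n_samples >= 2) {
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i >= j) next
      x <- mb[[nm[i]]]
      y <- if (paired) mb[[nm[j]]][names(x)] else mb[[nm[j]]]
      pv <- if (paired && all(x - y == 0)) 1 else
        suppressWarnings(wilcox.test(x, y, paired = paired,
                                     alternative = alternative)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  list(results = results, p_values = p)
}

#' Ordinary least-squares fit of a titration series
#'
#' Fits observed variant fractions against known input fractions; a
#' quantitative barcoding method should give slope 1, intercept 0 and
#' r-squared near 1.
#'
#' @param input_fractions Known input fractions (at least 3 points).
#' @param observed_fractions Observed fractions, same length.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
titration_fit <- function(input_fractions, observed_fractions) {
  stopifnot(length(input_fractions) == length(observed_fractions))
  if (length(input_fractions) < 3)
    stop("titration fit needs at least 3 points")
  fit <- lm(observed_fractions ~ input_fractions)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((observed_fractions - mean(observed_fractions))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = max(0, min(1, r2)))
}
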