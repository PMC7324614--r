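#' Primer layout specification
#'
#' Describes the architecture of the barcoded amplification primers: a
#' common self-annealing (MALBAC-style) tail, an 8 bp UMI, and a
#' gene-specific annealing region, on both the forward (V-side) and reverse
#' (J-side) primers. Conserved-base offsets (always outside the UMI
#' segment) are checked during read annotation to confirm the barcode
#' structure. An optional synthetic-UMI window describes where an internal
#' molecule barcode sits within the insert of synthetic template libraries,
#' and optional sample barcodes (appended 3' of the reverse MALBAC tail
#' during the second PCR) support demultiplexing.
#'
#' @param fwd_malbac,rev_malbac Common primer tails (primer orientation).
#' @param fwd_gs Named character vector of forward gene-specific regions
#'   (one per V family; IUPAC codes allowed).
#' @param rev_gs Named character vector of reverse gene-specific regions
#'   (primer orientation, i.e. reverse complement of the J template site).
#' @param umi_length UMI length in bases (default 8).
#' @param max_primer_mismatches Mismatches tolerated in each of the MALBAC
#'   and gene-specific segments (default 2).
#' @param conserved_fwd,conserved_rev Integer offsets (1-based, within the
#'   respective MALBAC segment as it appears in the oriented read) that must
#'   match exactly; reads failing this are rejected as `barcode_structure`.
#' @param synthetic_umi_offset 0-based offset of the synthetic DNA-UMI
#'   window within the insert (`NA` if the library carries none).
#' @param synthetic_umi_length Length of that window (0 = none).
#' @param sample_barcodes Optional named character vector of barcode
#'   sequences, named by sample.
#' @return An object of class `primer_spec`.
#' @export
primer_spec <- function(fwd_malbac, rev_malbac, fwd_gs, rev_gs,
                        umi_length = 8L, max_primer_mismatches = 2L,
                        conserved_fwd = integer(0),
                        conserved_rev = integer(0),
                        synthetic_umi_offset = NA_integer_,
                        synthetic_umi_length = 0L,
                        sample_barcodes = NULL) {
  stopifnot(is.character(fwd_malbac), length(fwd_malbac) == 1,
            is.character(rev_malbac), length(rev_malbac) == 1,
            is.character(fwd_gs), length(fwd_gs) >= 1,
            is.character(rev_gs), length(rev_gs) >= 1,
            umi_length >= 1)
  if (length(unique(nchar(fwd_gs))) != 1 || length(unique(nchar(rev_gs))) != 1)
    stop("gene-specific regions must share one length per side")
  if (any(conserved_fwd > nchar(fwd_malbac)) ||
      any(conserved_rev > nchar(rev_malbac)))
    stop("conserved offsets must lie within the MALBAC segments")
  if (!is.null(sample_barcodes)) {
    stopifnot(is.character(sample_barcodes), !is.null(names(sample_barcodes)))
    if (length(unique(nchar(sample_barcodes))) != 1)
      stop("sample barcodes must share one length")
  }
  structure(list(
    fwd_malbac = fwd_malbac, rev_malbac = rev_malbac,
    fwd_gs = fwd_gs, rev_gs = rev_gs,
    umi_length = as.integer(umi_length),
    max_primer_mismatches = as.integer(max_primer_mismatches),
    conserved_fwd = as.integer(conserved_fwd),
    conserved_rev = as.integer(conserved_rev),
    synthetic_umi_offset = as.integer(synthetic_umi_offset),
    synthetic_umi_length = as.integer(synthetic_umi_length),
    sample_barcodes = sample_barcodes), class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat("primer_spec:", length(x$fwd_gs), "fwd /", length(x$rev_gs),
      "rev gene-specific primers; UMI", x$umi_length, "bp;",
      "MALBAC tails", nchar(x$fwd_malbac), "/", nchar(x$rev_malbac), "bp\n")
  invisible(x)
}

# Fixed synthetic MALBAC-style common tails (20 nt each).
.FWD_MALBAC <- "GTGAGTGATGGTTGAGGTAG"
.REV_MALBAC <- "TGAGTGGTAGTGTGGAGTGA"
.GS_LEN <- 21L

#' Default primer specification for a germline reference
#'
#' Builds one forward primer per V segment (its first 21 bases, the
#' FR3-side annealing site) and one reverse primer per J segment (reverse
#' complement of its last 21 bases), with the package's fixed MALBAC tails.
#' Conserved-base checks cover the two MALBAC bases flanking each UMI.
#'
#' @param germline A [germline_db].
#' @inheritParams primer_spec
#' @return A [primer_spec].
#' @export
default_primer_spec <- function(germline,
                                synthetic_umi_length = 0L,
                                sample_barcodes = NULL,
                                umi_length = 8L) {
  v <- germline_genes(germline, "V")
  j <- germline_genes(germline, "J")
  if (nrow(v) == 0 || nrow(j) == 0)
    stop("germline reference must contain at least one V and one J gene")
  fwd_gs <- substr(v$sequence, 1, .GS_LEN)
  names(fwd_gs) <- v$gene_id
  rev_gs <- revcomp(substr(j$sequence, nchar(j$sequence) - .GS_LEN + 1,
                           nchar(j$sequence)))
  names(rev_gs) <- j$gene_id
  nf <- nchar(.FWD_MALBAC)
  primer_spec(
    fwd_malbac = .FWD_MALBAC, rev_malbac = .REV_MALBAC,
    fwd_gs = fwd_gs, rev_gs = rev_gs,
    umi_length = umi_length,
    conserved_fwd = c(nf - 1L, nf),  # last two bases before the fwd UMI
    conserved_rev = c(1L, 2L),       # first two bases after the rev UMI
    synthetic_umi_offset = if (synthetic_umi_length > 0) 0L else NA_integer_,
    synthetic_umi_length = as.integer(synthetic_umi_length),
    sample_barcodes = sample_barcodes)
}

#' Read a primer specification from YAML
#' @param path YAML file whose keys mirror the arguments of [primer_spec()].
#' @return A [primer_spec].
#' @export
primer_spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(primer_spec, c(
    y[intersect(names(y), names(formals(primer_spec)))],
    list()))
}

#' Write a primer specification to YAML
#' @param spec A [primer_spec].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
primer_spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

# IUPAC-aware per-position mismatch counting of fixed-width windows
# against one primer. Windows of the wrong width (or NA) count as Inf.
count_mismatches <- function(windows, primer) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  w <- nchar(primer)
  ok <- !is.na(windows) & nchar(windows) == w
  mm <- rep(Inf, length(windows))
  if (!any(ok)) return(mm)
  acc <- integer(sum(ok))
  win <- windows[ok]
  for (i in seq_len(w)) {
    allowed <- iupac[[substr(primer, i, i)]]
    if (is.null(allowed)) allowed <- character(0)
    acc <- acc + !(substr(win, i, i) %in% allowed)
  }
  mm[ok] <- acc
  mm
}
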