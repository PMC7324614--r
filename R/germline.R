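#' Germline reference database
#'
#' Container for V and J germline gene segments together with a region map
#' (FWR/CDR intervals in 0-based half-open coordinates). The region map
#' drives CDR3 extraction, mutation-location classes (CDR vs FWR) and the
#' region-weighted somatic hypermutation model of the simulator.
#'
#' @param genes data.frame with columns `gene_id`, `segment_class`
#'   (`"V"` or `"J"`) and `sequence`.
#' @param regions data.frame with columns `gene_id`, `region`
#'   (one of FWR1..FWR4, CDR1..CDR3), `start`, `end` (0-based half-open).
#' @return An object of class `germline_db`.
#' @export
germline_db <- function(genes, regions) {
  stopifnot(is.data.frame(genes), is.data.frame(regions),
            all(c("gene_id", "segment_class", "sequence") %in% names(genes)),
            all(c("gene_id", "region", "start", "end") %in% names(regions)))
  if (!all(genes$segment_class %in% c("V", "J")))
    stop("segment_class must be 'V' or 'J'")
  allowed <- c(paste0("FWR", 1:4), paste0("CDR", 1:3))
  if (!all(regions$region %in% allowed))
    stop("unknown region name(s): ",
         paste(setdiff(regions$region, allowed), collapse = ", "))
  for (g in unique(regions$gene_id)) {
    r <- regions[regions$gene_id == g, ]
    r <- r[order(r$start), ]
    len <- nchar(genes$sequence[match(g, genes$gene_id)])
    if (is.na(len)) stop("region map refers to unknown gene: ", g)
    if (any(r$start < 0) || any(r$end > len) || any(r$end <= r$start))
      stop("region interval out of bounds for gene ", g)
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping region intervals for gene ", g)
  }
  structure(list(genes = genes, regions = regions), class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat("germline_db:", sum(x$genes$segment_class == "V"), "V gene(s),",
      sum(x$genes$segment_class == "J"), "J gene(s)\n")
  invisible(x)
}

#' Bundled synthetic germline reference
#'
#' A small synthetic IGHV/IGHJ-like reference used by the simulator and the
#' worked examples. It is NOT derived from IMGT: the four V segments
#' (120 nt, stop-free in frame, ending in the conserved CDR3 cysteine codon
#' TGT) and two J segments (48 nt, starting with the conserved tryptophan
#' codon TGG) were generated once at random under those structural
#' constraints. Region intervals mark the forward-primer annealing site
#' (labelled FWR2), a CDR2-like interval, FWR3, and the CDR3 anchors.
#'
#' @return A [germline_db] object.
#' @export
synthetic_germline <- function() {
  v <- c(
    SYNV1 = "CCGAACAGTACGTCTCCGTTAGTTTCAACTTTGCCGTCCCCAAACGGCGGGGGCTACAGCCTGCTAAACTCTAGCGTTACCGTTAGTGGACTCCACCTACTTACTCCTGGTGCGGTTTGT",
    SYNV2 = "AAATTCGCCCCATTCAACGCAGTCATCGTAAGAGTACAGAGTAGTGCCACAGGCTTTCTACCCCACTACTACTTAATCGGGATAGAAATGATTGCTTTAGGATCTGTTTCGGGCGTATGT",
    SYNV3 = "CGGGGAAGAGCGCAGCTAGACAGAGGGTTATCTGTGAAGCTAGCTTATTTCTGTCCGCCTAATAGTGGCGTGCTCGTGCACGGGCCAATGTGGGTGCCCATCCATATCCTTCTATTGTGT",
    SYNV4 = "TTGGCCACGATGCACTACACCACACGGACGGCACAAAGTAGCGTGGTGAGGCGCCATAAACTGCGGTATGTGATCATTGGCCTCAATGTCACAGAGATCCTCCATCGCTCCGCCGAGTGT")
  j <- c(
    SYNJ1 = "TGGGTACGGCAATTTGCCACCATCCCGACGTTGTTGTATCGACAGGAA",
    SYNJ2 = "TGGCTCTACGGCAAACTGCCCCACTTTGTTAAGGGGTACAGGGCAGTC")
  genes <- data.frame(
    gene_id = c(names(v), names(j)),
    segment_class = c(rep("V", length(v)), rep("J", length(j))),
    sequence = unname(c(v, j)),
    stringsAsFactors = FALSE)
  regions <- rbind(
    do.call(rbind, lapply(names(v), function(g) data.frame(
      gene_id = g,
      region = c("FWR2", "CDR2", "FWR3", "CDR3"),
      start = c(0L, 21L, 36L, 117L),
      end = c(21L, 36L, 117L, 120L),
      stringsAsFactors = FALSE))),
    do.call(rbind, lapply(names(j), function(g) data.frame(
      gene_id = g,
      region = c("CDR3", "FWR4"),
      start = c(0L, 3L),
      end = c(3L, 48L),
      stringsAsFactors = FALSE))))
  germline_db(genes, regions)
}

#' Read a germline reference from FASTA plus a region-map TSV
#'
#' @param fasta FASTA of germline segments; record names of the form
#'   `gene_id` with the segment class taken from the region TSV.
#' @param regions_tsv TSV with columns `gene_id`, `segment_class`,
#'   `region`, `start`, `end` (0-based half-open).
#' @return A [germline_db] object.
#' @export
read_germline <- function(fasta, regions_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  reg <- read_tsv(regions_tsv)
  stopifnot(all(c("gene_id", "segment_class", "region", "start", "end")
                %in% names(reg)))
  cls <- reg$segment_class[match(names(seqs), reg$gene_id)]
  if (anyNA(cls)) stop("FASTA gene(s) missing from region map: ",
                       paste(names(seqs)[is.na(cls)], collapse = ", "))
  genes <- data.frame(gene_id = names(seqs), segment_class = cls,
                      sequence = as.character(seqs), stringsAsFactors = FALSE)
  germline_db(genes, reg[c("gene_id", "region", "start", "end")])
}

#' Write a germline reference as FASTA plus a region-map TSV
#' @param db A [germline_db].
#' @param fasta,regions_tsv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_germline <- function(db, fasta, regions_tsv) {
  x <- Biostrings::DNAStringSet(db$genes$sequence)
  names(x) <- db$genes$gene_id
  Biostrings::writeXStringSet(x, fasta)
  reg <- db$regions
  reg$segment_class <- db$genes$segment_class[match(reg$gene_id,
                                                    db$genes$gene_id)]
  write_tsv(reg[c("gene_id", "segment_class", "region", "start", "end")],
            regions_tsv)
  invisible(c(fasta, regions_tsv))
}

germline_genes <- function(db, class) {
  db$genes[db$genes$segment_class == class, , drop = FALSE]
}

# Per-position region labels for one gene ("" where unannotated).
region_labels <- function(db, gene_id) {
  seq <- db$genes$sequence[match(gene_id, db$genes$gene_id)]
  lab <- rep("", nchar(seq))
  r <- db$regions[db$regions$gene_id == gene_id, ]
  for (i in seq_len(nrow(r))) lab[(r$start[i] + 1):r$end[i]] <- r$region[i]
  lab
}
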