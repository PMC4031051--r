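#' Aligned mtDNA sequence panel
#'
#' A set of (putatively rCRS-aligned) mtDNA sequences plus the reference they
#' are compared against and an optional exclusion list of pathogenic
#' variants. Sequences must use bases in {A, C, G, T, N, -}; N and the gap
#' character are treated as missing when calling variants.
#'
#' @param records named character vector of uppercase sequences.
#' @param reference reference sequence string (full length).
#' @param exclusion_variants optional data.frame with columns \code{pos}
#'   (1-based) and \code{allele}: sequences carrying any listed allele are
#'   removed by \code{\link{filter_sequences}}.
#' @return an object of class \code{sequence_panel}.
#' @export
sequence_panel <- function(records, reference, exclusion_variants = NULL) {
  if (is.null(names(records)) || anyDuplicated(names(records)))
    abort("records must have unique names")
  records <- toupper(records)
  if (is.null(reference) || !nzchar(reference)) abort("reference is required")
  bad <- grepl("[^ACGTN-]", records)
  if (any(bad)) abort("sequence '%s' contains non-ACGTN- characters",
                      names(records)[bad][1])
  if (!is.null(exclusion_variants)) {
    stopifnot(all(c("pos", "allele") %in% names(exclusion_variants)))
    exclusion_variants$pos <- as.integer(exclusion_variants$pos)
  }
  structure(list(records = records, reference = toupper(reference),
                 exclusion_variants = exclusion_variants),
            class = "sequence_panel")
}

#' @export
print.sequence_panel <- function(x, ...) {
  cat(sprintf("sequence_panel: %d sequences, reference length %d, %d exclusion variants\n",
              length(x$records), nchar(x$reference),
              if (is.null(x$exclusion_variants)) 0L else nrow(x$exclusion_variants)))
  invisible(x)
}

#' Read / write a sequence panel as FASTA
#'
#' @param path FASTA file.
#' @param reference reference sequence string (required on read).
#' @param exclusion_variants see \code{\link{sequence_panel}}.
#' @return \code{read_panel_fasta}: a \code{sequence_panel};
#'   \code{write_panel_fasta}: invisibly, \code{path}.
#' @export
read_panel_fasta <- function(path, reference, exclusion_variants = NULL) {
  ss <- Biostrings::readBStringSet(path)
  sequence_panel(stats::setNames(as.character(ss), names(ss)),
                 reference = reference,
                 exclusion_variants = exclusion_variants)
}

#' @rdname read_panel_fasta
#' @param panel a \code{sequence_panel}.
#' @export
write_panel_fasta <- function(panel, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(panel$records), path)
  invisible(path)
}

#' Read a two-column pathogenic-variant exclusion list (TSV: pos, allele)
#' @param path TSV file with header columns \code{pos} and \code{allele}.
#' @return data.frame with integer \code{pos} and character \code{allele}.
#' @export
read_exclusion_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character"))
  stopifnot(all(c("pos", "allele") %in% names(df)))
  df
}

# base of sequence s at position pos, or NA if beyond its length
base_at <- function(s, pos) {
  ifelse(pos <= nchar(s), substr(s, pos, pos), NA_character_)
}

#' Filter a sequence panel for reference-panel construction
#'
#' Removals are applied in order: (1) sequences carrying any listed
#' pathogenic variant; (2) non-European sequences (an individual is kept only
#' if every diagnostic position within its length carries the European allele
#' m.8701A / m.8540T / m.10873T); (3) truncated sequences shorter than
#' \code{min_length}. A sequence is counted once, in the first category that
#' removes it. The filter is idempotent.
#'
#' @param panel a \code{\link{sequence_panel}}.
#' @param min_length minimum retained sequence length (default 16500).
#' @return list with \code{panel} (filtered) and \code{ledger} (counts:
#'   input, pathogenic, non_european, truncated, retained).
#' @export
filter_sequences <- function(panel, min_length = 16500L) {
  seqs <- panel$records
  n_in <- length(seqs)
  # 1: pathogenic variants
  patho <- rep(FALSE, length(seqs))
  ev <- panel$exclusion_variants
  if (!is.null(ev) && nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      b <- base_at(seqs, ev$pos[i])
      patho <- patho | (!is.na(b) & b == toupper(ev$allele[i]))
    }
  }
  seqs <- seqs[!patho]
  # 2: non-European (diagnostic triplet; positions beyond a truncated
  # sequence's end are untestable for it)
  euro <- rep(TRUE, length(seqs))
  for (k in seq_len(nrow(EURO_DIAGNOSTIC))) {
    b <- base_at(seqs, EURO_DIAGNOSTIC$pos[k])
    euro <- euro & (is.na(b) | b == EURO_DIAGNOSTIC$allele[k])
  }
  non_euro <- sum(!euro)
  seqs <- seqs[euro]
  # 3: truncated
  trunc <- nchar(seqs) < min_length
  n_trunc <- sum(trunc)
  seqs <- seqs[!trunc]
  list(panel = sequence_panel(seqs, panel$reference,
                              panel$exclusion_variants),
       ledger = c(input = n_in, pathogenic = sum(patho),
                  non_european = non_euro, truncated = n_trunc,
                  retained = length(seqs)))
}

#' Call biallelic variants from an aligned panel
#'
#' All sequences must equal the reference length (the
#' \code{\link{filter_sequences}} post-condition when the panel was aligned).
#' Per position, N and "-" are missing; the alternate allele is the most
#' frequent non-reference base. Positions where more than two distinct bases
#' are observed are flagged multi-allelic and excluded from the biallelic
#' table. MAF is the folded alternate frequency over non-missing calls.
#'
#' @param panel a \code{\link{sequence_panel}}.
#' @return list with \code{variants} (data.frame: pos, ref, alt, alt_count,
#'   n_called, maf) and \code{multiallelic} (excluded positions).
#' @export
call_variants <- function(panel) {
  L <- nchar(panel$reference)
  lens <- nchar(panel$records)
  if (any(lens != L))
    abort("sequence '%s' length %d != reference length %d",
          names(panel$records)[lens != L][1], lens[lens != L][1], L)
  n <- length(panel$records)
  mat <- matrix(unlist(strsplit(panel$records, ""), use.names = FALSE),
                nrow = n, byrow = TRUE)
  refv <- strsplit(panel$reference, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  counts <- vapply(acgt, function(b) colSums(mat == b), numeric(L))
  n_called <- rowSums(counts)
  ref_idx <- match(refv, acgt)
  ref_count <- counts[cbind(seq_len(L), ref_idx)]
  nonref <- counts
  nonref[cbind(seq_len(L), ref_idx)] <- 0
  n_distinct <- rowSums(counts > 0)
  alt_total <- rowSums(nonref)
  seg <- alt_total > 0 & ref_count > 0  # segregating vs reference
  fixed_diff <- alt_total > 0 & ref_count == 0
  variant <- seg | fixed_diff
  multi <- variant & n_distinct > 2
  keep <- variant & !multi
  alt_idx <- max.col(nonref, ties.method = "first")
  alt <- acgt[alt_idx]
  alt_count <- nonref[cbind(seq_len(L), alt_idx)]
  f <- ifelse(n_called > 0, alt_count / n_called, NA_real_)
  list(variants = data.frame(pos = which(keep), ref = refv[keep],
                             alt = alt[keep],
                             alt_count = as.integer(alt_count[keep]),
                             n_called = as.integer(n_called[keep]),
                             maf = pmin(f[keep], 1 - f[keep]),
                             stringsAsFactors = FALSE),
       multiallelic = which(multi))
}

#' Fraction of variants above a MAF threshold
#'
#' The quantity behind a variation-capture summary: the fraction of panel
#' variants with MAF strictly greater than \code{threshold}.
#'
#' @param variants the \code{variants} data.frame of
#'   \code{\link{call_variants}} (needs a \code{maf} column).
#' @param threshold MAF threshold (default 0.01).
#' @return a fraction in [0, 1].
#' @export
maf_spectrum <- function(variants, threshold = 0.01) {
  if (nrow(variants) == 0) abort("empty variant table")
  mean(variants$maf > threshold)
}
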