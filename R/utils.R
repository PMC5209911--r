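# Small shared helpers. Sequences are kept as plain uppercase character
# strings at module boundaries; Biostrings objects are used internally
# wherever real sequence work (revcomp, alignment, I/O) happens.

#' Load a genome as a named DNAStringSet
#'
#' Accepts a FASTA path or an already-loaded `DNAStringSet` / named character
#' vector and returns a named `DNAStringSet`. Sequence names are truncated at
#' the first whitespace, matching common chromosome-name usage.
#'
#' @param genome FASTA file path, `DNAStringSet`, or named character vector.
#' @return A named `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gs <- readDNAStringSet(genome)
  } else if (is.character(genome) && !is.null(names(genome))) {
    gs <- DNAStringSet(genome)
  } else {
    stop("genome must be a FASTA path, a DNAStringSet or a named character vector")
  }
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

# fetch genome subsequence [start, end] 1-based inclusive; NULL if out of range
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) return(NULL)
  n <- length(genome[[chrom]])
  if (start < 1L || end > n || start > end) return(NULL)
  s <- subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- reverseComplement(s)
  as.character(s)
}

revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# deterministic random DNA string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# harmonic mean of sensitivity and precision; NA propagates
f1_score <- function(sn, pr) {
  if (is.na(sn) || is.na(pr)) return(NA_real_)
  if (sn + pr == 0) return(0)
  2 * sn * pr / (sn + pr)
}

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

#' Junction identifier string
#'
#' Formats donor/acceptor coordinates as
#' `donchr_donpos_donstr:accchr_accpos_accstr`.
#'
#' @param don_chrom,don_pos,don_strand Donor side (last exonic base, 5').
#' @param acc_chrom,acc_pos,acc_strand Acceptor side (first exonic base, 3').
#' @return Character vector of junction IDs.
#' @export
junction_id <- function(don_chrom, don_pos, don_strand,
                        acc_chrom, acc_pos, acc_strand) {
  paste0(don_chrom, "_", don_pos, "_", don_strand, ":",
         acc_chrom, "_", acc_pos, "_", acc_strand)
}
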