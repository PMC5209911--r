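# SAM/BAM ingestion: converts alignment records into the two evidence
# streams of the pipeline (split reads, mate pairs), applying the
# multimapping cap. 1-based inclusive coordinates from here on; Rsamtools
# already reports 1-based positions.

# query-space coordinates of the aligned portion, in the orientation of the
# stored SEQ: c(qstart, qend, qlen) where qlen includes clipped bases
cigar_query_span <- function(ops, lens) {
  qlen <- sum(lens[ops %in% c("M", "I", "S", "H", "=", "X")])
  nonclip <- which(!ops %in% c("S", "H"))
  lead <- if (min(nonclip) > 1L) sum(lens[seq_len(min(nonclip) - 1L)]) else 0L
  trail <- if (max(nonclip) < length(ops)) {
    sum(lens[(max(nonclip) + 1L):length(ops)])
  } else 0L
  c(qstart = lead + 1L, qend = qlen - trail, qlen = qlen)
}

# read-local range of an alignment piece in original-read orientation
piece_read_range <- function(ops, lens, strand) {
  sp <- cigar_query_span(ops, lens)
  if (strand == "+") {
    c(sp[["qstart"]], sp[["qend"]])
  } else {
    c(sp[["qlen"]] - sp[["qend"]] + 1L, sp[["qlen"]] - sp[["qstart"]] + 1L)
  }
}

# open a SAM or BAM for scanBam; SAM text is converted on the fly
as_bamfile <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    asBam(path, destination = dest, overwrite = TRUE, indexDestination = TRUE)
  } else {
    path
  }
}

empty_splits <- function() data.table(
  read_id = character(), mate = integer(),
  chromA = character(), startA = integer(), endA = integer(),
  strandA = character(), qstartA = integer(), qendA = integer(),
  chromB = character(), startB = integer(), endB = integer(),
  strandB = character(), qstartB = integer(), qendB = integer(),
  nh = integer())

#' Ingest aligned paired-end reads into split-read and mate-pair streams
#'
#' Reads primary alignment records from SAM/BAM and emits:
#' * **split reads** — for each primary alignment whose CIGAR contains
#'   exactly one `N` gap (two same-chromosome, same-strand segments), and for
#'   each primary + `SA`-tag pair describing a two-piece chimeric alignment
#'   (any chromosomes, strands or order). Segments are reported in read order
#'   (5' to 3' of the read as sequenced).
#' * **mate pairs** — per-mate aligned blocks for every read pair with both
#'   mates mapped.
#'
#' Read pairs in which any mate reports more than `max_hits` mapping
#' positions (`NH` tag; a missing NH is treated as 1) are dropped from both
#' streams. CIGARs with two or more `N` gaps are skipped for the split
#' stream (the record still contributes to the mate stream) and counted in
#' the skip report, as are chimeric alignments with more than one `SA` entry.
#'
#' @param path SAM or BAM file. SAM input is converted in a temporary
#'   directory via [Rsamtools::asBam()].
#' @param max_hits Maximum reported mapping positions per mate (default 10).
#' @return list with elements
#'   `splits` (data.table: read_id, mate, chromA..strandA, qstartA, qendA,
#'   chromB..qendB, nh),
#'   `mate_blocks` (data.table: read_id, mate, chrom, strand, start, end),
#'   `pairs` (data.table: read_id, both_mapped), and `skipped` (named counts).
#' @export
ingest_alignments <- function(path, max_hits = 10L) {
  bam <- as_bamfile(path)
  res <- scanBam(bam, param = ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = c("NH", "SA"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE)
  ))[[1L]]
  rec <- data.table(
    read_id = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    strand = as.character(res$strand),
    pos = res$pos,
    cigar = res$cigar,
    nh = if (is.null(res$tag$NH)) NA_integer_ else res$tag$NH,
    sa = if (is.null(res$tag$SA)) NA_character_ else res$tag$SA
  )
  rec[is.na(nh), nh := 1L]
  rec[, mate := fifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)]

  skipped <- c(multi_gap = 0L, multi_sa = 0L, over_max_hits = 0L)
  over <- unique(rec[nh > max_hits, read_id])
  skipped[["over_max_hits"]] <- length(over)
  if (length(over)) rec <- rec[!read_id %in% over]

  if (!nrow(rec)) {
    return(list(splits = empty_splits(),
                mate_blocks = data.table(read_id = character(), mate = integer(),
                                         chrom = character(), strand = character(),
                                         start = integer(), end = integer()),
                pairs = data.table(read_id = character(), both_mapped = logical()),
                skipped = skipped))
  }

  ops_l <- explodeCigarOps(rec$cigar)
  lens_l <- explodeCigarOpLengths(rec$cigar)
  n_gaps <- vapply(ops_l, function(o) sum(o == "N"), integer(1))
  has_sa <- !is.na(rec$sa) & nzchar(rec$sa)

  # mate-pair stream: M blocks of every primary record
  mranges <- cigarRangesAlongReferenceSpace(rec$cigar, pos = rec$pos, ops = "M")
  nb <- S4Vectors::elementNROWS(mranges)
  flat <- unlist(mranges, use.names = FALSE)
  mate_blocks <- data.table(
    read_id = rep(rec$read_id, nb), mate = rep(rec$mate, nb),
    chrom = rep(rec$chrom, nb), strand = rep(rec$strand, nb),
    start = BiocGenerics::start(flat), end = BiocGenerics::end(flat))

  split_list <- list()

  # (a) spliced primaries with exactly one N gap (no SA): same chrom/strand
  idx_gap <- which(n_gaps == 1L & !has_sa)
  if (length(idx_gap)) {
    gapr <- unlist(cigarRangesAlongReferenceSpace(rec$cigar[idx_gap],
                                                  pos = rec$pos[idx_gap],
                                                  ops = "N"), use.names = FALSE)
    refw <- cigarWidthAlongReferenceSpace(rec$cigar[idx_gap])
    s1 <- rec$pos[idx_gap]; e1 <- BiocGenerics::start(gapr) - 1L
    s2 <- BiocGenerics::end(gapr) + 1L; e2 <- rec$pos[idx_gap] + refw - 1L
    qsplit <- t(vapply(idx_gap, function(i) {
      ops <- ops_l[[i]]; lens <- lens_l[[i]]
      sp <- cigar_query_span(ops, lens)
      gap_at <- which(ops == "N")
      before <- seq_len(gap_at - 1L)
      w1 <- sum(lens[before][ops[before] %in% c("M", "I")])
      c(sp[["qstart"]], sp[["qstart"]] + w1 - 1L,
        sp[["qstart"]] + w1, sp[["qend"]], sp[["qlen"]])
    }, numeric(5)))
    q1s <- as.integer(qsplit[, 1L]); q1e <- as.integer(qsplit[, 2L])
    q2s <- as.integer(qsplit[, 3L]); q2e <- as.integer(qsplit[, 4L])
    qlen <- as.integer(qsplit[, 5L])
    minus <- rec$strand[idx_gap] == "-"
    # on '-', the genomically-second flank comes first in the read; flip
    # query coordinates into original-read orientation
    fq1s <- fifelse(minus, qlen - q2e + 1L, q1s)
    fq1e <- fifelse(minus, qlen - q2s + 1L, q1e)
    fq2s <- fifelse(minus, qlen - q1e + 1L, q2s)
    fq2e <- fifelse(minus, qlen - q1s + 1L, q2e)
    split_list[[length(split_list) + 1L]] <- data.table(
      read_id = rec$read_id[idx_gap], mate = rec$mate[idx_gap],
      chromA = rec$chrom[idx_gap],
      startA = fifelse(minus, s2, s1), endA = fifelse(minus, e2, e1),
      strandA = rec$strand[idx_gap], qstartA = fq1s, qendA = fq1e,
      chromB = rec$chrom[idx_gap],
      startB = fifelse(minus, s1, s2), endB = fifelse(minus, e1, e2),
      strandB = rec$strand[idx_gap], qstartB = fq2s, qendB = fq2e,
      nh = rec$nh[idx_gap])
  }
  skipped[["multi_gap"]] <- sum(n_gaps > 1L & !has_sa)

  # (b) chimeric primaries carrying a single SA entry
  sa_blocks <- list()
  for (i in which(has_sa)) {
    sa_entries <- strsplit(rec$sa[i], ";", fixed = TRUE)[[1L]]
    sa_entries <- sa_entries[nzchar(sa_entries)]
    if (length(sa_entries) != 1L || n_gaps[i] > 0L) {
      skipped[["multi_sa"]] <- skipped[["multi_sa"]] + 1L
      next
    }
    f <- strsplit(sa_entries, ",", fixed = TRUE)[[1L]]
    if (length(f) < 4L) {
      warning("malformed SA tag for read ", rec$read_id[i], "; record skipped")
      next
    }
    sa_chrom <- f[1L]; sa_pos <- as.integer(f[2L])
    sa_strand <- f[3L]; sa_cigar <- f[4L]
    sa_ops <- explodeCigarOps(sa_cigar)[[1L]]
    sa_lens <- explodeCigarOpLengths(sa_cigar)[[1L]]
    sa_refw <- cigarWidthAlongReferenceSpace(sa_cigar)
    p1 <- list(chrom = rec$chrom[i], strand = rec$strand[i],
               start = rec$pos[i],
               end = rec$pos[i] + cigarWidthAlongReferenceSpace(rec$cigar[i]) - 1L,
               rr = piece_read_range(ops_l[[i]], lens_l[[i]], rec$strand[i]))
    p2 <- list(chrom = sa_chrom, strand = sa_strand,
               start = sa_pos, end = sa_pos + sa_refw - 1L,
               rr = piece_read_range(sa_ops, sa_lens, sa_strand))
    pieces <- if (p1$rr[1L] <= p2$rr[1L]) list(p1, p2) else list(p2, p1)
    a <- pieces[[1L]]; b <- pieces[[2L]]
    split_list[[length(split_list) + 1L]] <- data.table(
      read_id = rec$read_id[i], mate = rec$mate[i],
      chromA = a$chrom, startA = a$start, endA = a$end,
      strandA = a$strand, qstartA = a$rr[1L], qendA = a$rr[2L],
      chromB = b$chrom, startB = b$start, endB = b$end,
      strandB = b$strand, qstartB = b$rr[1L], qendB = b$rr[2L],
      nh = rec$nh[i])
    # the SA piece is not a separate primary record: add its span to the
    # mate-pair stream so gene assignment sees the whole chimeric mate
    sa_blocks[[length(sa_blocks) + 1L]] <- data.table(
      read_id = rec$read_id[i], mate = rec$mate[i], chrom = sa_chrom,
      strand = sa_strand, start = sa_pos, end = sa_pos + sa_refw - 1L)
  }
  if (length(sa_blocks)) {
    mate_blocks <- rbindlist(list(mate_blocks, rbindlist(sa_blocks)))
  }

  splits <- if (length(split_list)) rbindlist(split_list) else empty_splits()
  pairs <- mate_blocks[, .(both_mapped = uniqueN(mate) == 2L), by = read_id]
  list(splits = splits, mate_blocks = mate_blocks, pairs = pairs,
       skipped = skipped)
}
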