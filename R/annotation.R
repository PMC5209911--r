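# Gene annotation model: exon table, gene table, interval index and the
# catalogue of annotated splice sites (internal exon boundaries).
#
# Coordinates are 1-based inclusive throughout (GTF native). Alignment
# records are converted at ingestion and never leak 0-based coordinates here.

#' Build an annotation index from an exon table
#'
#' Core constructor behind [read_gtf()]. Takes a data.frame of exon records
#' and derives the gene table, the per-chromosome interval index used for
#' overlap queries, and the donor/acceptor splice-site catalogues. Splice
#' sites come from exon boundaries that are internal to some transcript:
#' a transcript's non-last exon contributes a donor at its transcript-end
#' and a non-first exon contributes an acceptor at its transcript-start
#' (genomic start/end swap roles on the minus strand). Single-exon
#' transcripts contribute no sites.
#'
#' @param exons data.frame with columns chrom, start, end, strand, gene_id,
#'   transcript_id and optionally gene_name and biotype.
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(exons) {
  ex <- as.data.table(exons)
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(need, names(ex))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(ex)) stop("empty exon table")
  if (!"gene_name" %in% names(ex)) ex[, gene_name := gene_id]
  if (!"biotype" %in% names(ex)) ex[, biotype := "unknown"]
  ex[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), strand = as.character(strand),
            gene_id = as.character(gene_id),
            transcript_id = as.character(transcript_id))]
  ex[is.na(biotype) | biotype == "", biotype := "unknown"]
  if (any(ex$start > ex$end)) stop("exon with start > end")
  if (!all(ex$strand %in% c("+", "-"))) stop("exon strand must be + or -")

  genes <- ex[, .(
    gene_name = gene_name[1L],
    chrom = chrom[1L],
    strand = strand[1L],
    start = min(start),
    end = max(end),
    biotype = biotype[1L]
  ), by = gene_id]

  # union of exons over transcripts, duplicates collapsed, for overlap accounting
  uex <- unique(ex[, .(chrom, start, end, strand, gene_id)])
  gr <- GRanges(uex$chrom, IRanges(uex$start, uex$end), strand = uex$strand)

  sites <- splice_sites(ex)

  structure(list(
    exons = ex,
    uexons = uex,
    gr = gr,
    genes = genes,
    donors = sites$donors,
    acceptors = sites$acceptors,
    donor_keys = unique(site_key(sites$donors$chrom, sites$donors$pos, sites$donors$strand)),
    acceptor_keys = unique(site_key(sites$acceptors$chrom, sites$acceptors$pos, sites$acceptors$strand))
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", nrow(x$exons), "exon records,",
      nrow(x$genes), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts\n")
  cat("  annotated donor sites:", length(x$donor_keys),
      " acceptor sites:", length(x$acceptor_keys), "\n")
  invisible(x)
}

# enumerate annotated splice sites from internal exon boundaries
splice_sites <- function(ex) {
  ex <- copy(ex)[order(transcript_id, start)]
  don <- list(); acc <- list()
  byt <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (tx in names(byt)) {
    rows <- ex[byt[[tx]]]
    n <- nrow(rows)
    if (n < 2L) next
    if (rows$strand[1L] == "+") {
      # transcript order == genomic order
      don[[tx]] <- rows[seq_len(n - 1L), .(chrom, pos = end, strand, gene_id, transcript_id = tx)]
      acc[[tx]] <- rows[2L:n, .(chrom, pos = start, strand, gene_id, transcript_id = tx)]
    } else {
      # transcript order is descending genomic order: donors at genomic starts
      # of all but the genomically-first exon, acceptors at genomic ends of
      # all but the genomically-last exon
      don[[tx]] <- rows[2L:n, .(chrom, pos = start, strand, gene_id, transcript_id = tx)]
      acc[[tx]] <- rows[seq_len(n - 1L), .(chrom, pos = end, strand, gene_id, transcript_id = tx)]
    }
  }
  empty <- data.table(chrom = character(), pos = integer(), strand = character(),
                      gene_id = character(), transcript_id = character())
  list(
    donors = if (length(don)) unique(rbindlist(don)) else empty,
    acceptors = if (length(acc)) unique(rbindlist(acc)) else empty
  )
}

# parse one GTF attribute from the attribute string, NA when absent
gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0('(^|; ?)', key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_, character(1))
}

#' Read a GTF gene annotation
#'
#' Parses exon lines of a GTF (GFF2 dialect, `key "value"` attributes) into
#' an [annotation_index()]. Gzip input is handled transparently. Gene biotype
#' is taken from the `gene_type` attribute, falling back to `gene_biotype`,
#' else `"unknown"`; `gene_name` falls back to `gene_id`.
#'
#' Malformed exon lines (missing gene_id/transcript_id, non-numeric or
#' inverted coordinates, wrong field count) are rejected with their line
#' numbers.
#'
#' @param path Path to a GTF file (optionally gzipped).
#' @return An `annotation_index`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no feature lines in GTF: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("GTF line ", lineno[which(nf != 9L)[1L]], ": expected 9 tab-separated fields, got ",
         nf[which(nf != 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  is_exon <- m[, 3L] == "exon"
  if (!any(is_exon)) stop("GTF contains no exon features: ", path)
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]

  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("GTF line ", lineno[bad[1L]], ": non-numeric exon coordinates")
  bad <- which(start > end)
  if (length(bad)) {
    stop("GTF line ", lineno[bad[1L]], ": exon start (", start[bad[1L]],
         ") > end (", end[bad[1L]], ")")
  }
  strand <- m[, 7L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("GTF line ", lineno[bad[1L]], ": exon strand must be + or -")

  attrs <- m[, 9L]
  gene_id <- gtf_attr(attrs, "gene_id")
  transcript_id <- gtf_attr(attrs, "transcript_id")
  bad <- which(is.na(gene_id) | is.na(transcript_id))
  if (length(bad)) {
    stop("GTF line ", lineno[bad[1L]],
         ": exon lacks gene_id or transcript_id attribute")
  }
  biotype <- gtf_attr(attrs, "gene_type")
  alt <- gtf_attr(attrs, "gene_biotype")
  biotype[is.na(biotype)] <- alt[is.na(biotype)]
  biotype[is.na(biotype) | biotype == ""] <- "unknown"
  gene_name <- gtf_attr(attrs, "gene_name")
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]

  annotation_index(data.table(
    chrom = m[, 1L], start = start, end = end, strand = strand,
    gene_id = gene_id, transcript_id = transcript_id,
    gene_name = gene_name, biotype = biotype
  ))
}

#' Exon overlap query
#'
#' Returns all (collapsed) exons intersecting `[start, end]` on `chrom`,
#' optionally restricted to one strand, each with its intersection length.
#' Unknown chromosomes yield an empty result.
#'
#' @param index An `annotation_index`.
#' @param chrom Chromosome name.
#' @param start,end Query interval, 1-based inclusive.
#' @param strand `"+"`, `"-"` or `NULL` (both strands).
#' @return data.table with columns chrom, start, end, strand, gene_id,
#'   overlap_bp, ordered by genomic position.
#' @export
overlap_exons <- function(index, chrom, start, end, strand = NULL) {
  stopifnot(inherits(index, "annotation_index"), start <= end)
  q <- GRanges(chrom, IRanges(start, end))
  hits <- suppressWarnings(findOverlaps(q, index$gr, ignore.strand = TRUE))
  res <- index$uexons[subjectHits(hits)]
  qstrand <- strand
  if (!is.null(qstrand)) res <- res[res$strand == qstrand]
  if (!nrow(res)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      overlap_bp = integer()))
  }
  qs <- start; qe <- end
  res <- copy(res)
  res[, overlap_bp := pmin(end, qe) - pmax(start, qs) + 1L]
  res[order(start, end, gene_id)]
}

# Best-gene assignment for a batch of query intervals.
# q: data.table(qid, chrom, start, end, strand) where strand may be NA to
# ignore strand. Overlap is summed per gene over collapsed exons; ties are
# broken by protein_coding biotype first, then lexicographically smallest
# gene_id. Returns data.table(qid, gene_id, overlap_bp), one row per qid
# that overlaps any exon.
best_gene <- function(index, q) {
  stopifnot(is.data.table(q))
  if (!nrow(q)) return(data.table(qid = integer(), gene_id = character(),
                                  overlap_bp = integer()))
  qr <- GRanges(q$chrom, IRanges(q$start, q$end))
  hits <- suppressWarnings(findOverlaps(qr, index$gr, ignore.strand = TRUE))
  if (!length(hits)) return(data.table(qid = q$qid[0], gene_id = character(),
                                       overlap_bp = integer()))
  dt <- data.table(
    qid = q$qid[queryHits(hits)],
    qstart = q$start[queryHits(hits)],
    qend = q$end[queryHits(hits)],
    qstrand = q$strand[queryHits(hits)],
    index$uexons[subjectHits(hits), .(chrom, start, end, strand, gene_id)]
  )
  dt <- dt[is.na(qstrand) | qstrand == strand]
  if (!nrow(dt)) return(data.table(qid = q$qid[0], gene_id = character(),
                                   overlap_bp = integer()))
  dt[, ov := pmin(end, qend) - pmax(start, qstart) + 1L]
  agg <- dt[, .(overlap_bp = sum(ov)), by = .(qid, gene_id)]
  agg <- merge(agg, index$genes[, .(gene_id, biotype)], by = "gene_id")
  agg[, biotype_rank := ifelse(biotype == "protein_coding", 0L, 1L)]
  setorder(agg, qid, -overlap_bp, biotype_rank, gene_id)
  agg[, .SD[1L], by = qid][, .(qid, gene_id, overlap_bp)]
}

# is (chrom,pos,strand) an annotated donor / acceptor site?
is_annotated_donor <- function(index, chrom, pos, strand) {
  site_key(chrom, pos, strand) %chin% index$donor_keys
}
is_annotated_acceptor <- function(index, chrom, pos, strand) {
  site_key(chrom, pos, strand) %chin% index$acceptor_keys
}
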