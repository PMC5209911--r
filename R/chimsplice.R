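# Split-read junction calling: orient split reads into donor/acceptor splice-site pairs using
# the extended consensus motifs, cluster them into candidate junctions, and
# annotate each side with its parent gene.
#
# Donor coordinate = last exonic base of the 5' segment; acceptor = first
# exonic base of the 3' segment (both 1-based, on the oriented strand). The
# four accepted motif classes are GT-AG, GC-AG, ATATC-A. and GTATC-AT
# (donor motif immediately 3' of the donor site, acceptor motif immediately
# 5' of the acceptor site, "." = any base).

# transcript-direction endpoints of a mapped segment
seg_t_start <- function(start, end, strand) fifelse(strand == "+", start, end)
seg_t_end <- function(start, end, strand) fifelse(strand == "+", end, start)

# intron-side flanks: 5 bases after the donor, 2 bases before the acceptor,
# both in transcript direction. Returns NA when the chromosome edge is hit.
donor_flank <- function(genome, chrom, pos, strand) {
  if (strand == "+") fetch_seq(genome, chrom, pos + 1L, pos + 5L, "+")
  else fetch_seq(genome, chrom, pos - 5L, pos - 1L, "-")
}
acceptor_flank <- function(genome, chrom, pos, strand) {
  if (strand == "+") fetch_seq(genome, chrom, pos - 2L, pos - 1L, "+")
  else fetch_seq(genome, chrom, pos + 1L, pos + 2L, "-")
}

# match the extended splice-site consensus classes; NA when none match
match_motif <- function(don5, acc2) {
  if (is.null(don5) || is.null(acc2)) return(NA_character_)
  d2 <- substr(don5, 1L, 2L)
  if (d2 == "GT" && acc2 == "AG") return("GT-AG")
  if (d2 == "GC" && acc2 == "AG") return("GC-AG")
  if (don5 == "GTATC" && acc2 == "AT") return("GTATC-AT")
  if (don5 == "ATATC" && substr(acc2, 1L, 1L) == "A") return("ATATC-A.")
  NA_character_
}

#' Orient split reads into donor/acceptor splice-site pairs
#'
#' Examines the intron-side flanking sequence of each split read's candidate
#' junction in both possible transcript orientations and keeps the unique
#' orientation whose flanks match an extended splice-site consensus motif.
#' This fixes a definite strand for both junction sides even for unstranded
#' libraries. Reads where neither orientation matches are rejected
#' (`no_consensus`), as are reads where both match (`ambiguous`) or where a
#' segment sits too close to a chromosome edge for the flanks to be read
#' (`edge`).
#'
#' @param splits Split-read table from [ingest_alignments()].
#' @param genome Genome as accepted by [load_genome()].
#' @param stranded If `TRUE`, reads are assumed to be in transcript
#'   orientation already and only that orientation is motif-checked; the
#'   default `FALSE` (unstranded library) lets the motif decide.
#' @return list with `oriented` (data.table: read_id, mate, don_chrom,
#'   don_pos, don_strand, acc_chrom, acc_pos, acc_strand, don_outer,
#'   acc_outer, motif) and `rejected` (data.table: read_id, mate, reason).
#' @export
orient_splits <- function(splits, genome, stranded = FALSE) {
  genome <- load_genome(genome)
  # plain-string genome access: orientation touches millions of tiny flanks,
  # so substr on character vectors beats XString subsetting here
  gstr <- as.character(genome)
  glen <- nchar(gstr)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }
  flank <- function(chrom, s, e, strand) {
    if (!chrom %in% names(gstr)) return(NULL)
    if (s < 1L || e > glen[[chrom]]) return(NULL)
    x <- substr(gstr[[chrom]], s, e)
    if (strand == "-") rc(x) else x
  }
  don_flank <- function(chrom, pos, strand) {
    if (strand == "+") flank(chrom, pos + 1L, pos + 5L, "+")
    else flank(chrom, pos - 5L, pos - 1L, "-")
  }
  acc_flank <- function(chrom, pos, strand) {
    if (strand == "+") flank(chrom, pos - 2L, pos - 1L, "+")
    else flank(chrom, pos + 1L, pos + 2L, "-")
  }
  n <- nrow(splits)
  out <- vector("list", n)
  rej <- vector("list", n)
  cols <- lapply(splits, identity)
  for (i in seq_len(n)) {
    s <- list(read_id = cols$read_id[i], mate = cols$mate[i],
              chromA = cols$chromA[i], startA = cols$startA[i],
              endA = cols$endA[i], strandA = cols$strandA[i],
              chromB = cols$chromB[i], startB = cols$startB[i],
              endB = cols$endB[i], strandB = cols$strandB[i])
    # orientation 1: the read as sequenced is the transcript 5'->3'
    o1 <- list(
      don_chrom = s$chromA, don_strand = s$strandA,
      don_pos = seg_t_end(s$startA, s$endA, s$strandA),
      don_outer = seg_t_start(s$startA, s$endA, s$strandA),
      acc_chrom = s$chromB, acc_strand = s$strandB,
      acc_pos = seg_t_start(s$startB, s$endB, s$strandB),
      acc_outer = seg_t_end(s$startB, s$endB, s$strandB))
    # orientation 2: the read is the reverse complement of the transcript
    fA <- flip_strand(s$strandA); fB <- flip_strand(s$strandB)
    o2 <- list(
      don_chrom = s$chromB, don_strand = fB,
      don_pos = seg_t_end(s$startB, s$endB, fB),
      don_outer = seg_t_start(s$startB, s$endB, fB),
      acc_chrom = s$chromA, acc_strand = fA,
      acc_pos = seg_t_start(s$startA, s$endA, fA),
      acc_outer = seg_t_end(s$startA, s$endA, fA))

    edge_seen <- FALSE
    motif_of <- function(o) {
      d <- don_flank(o$don_chrom, o$don_pos, o$don_strand)
      a <- acc_flank(o$acc_chrom, o$acc_pos, o$acc_strand)
      if (is.null(d) || is.null(a)) {
        edge_seen <<- TRUE
        return(NA_character_)
      }
      match_motif(d, a)
    }
    m1 <- motif_of(o1)
    m2 <- if (stranded) NA_character_ else motif_of(o2)

    if (!is.na(m1) && !is.na(m2)) {
      rej[[i]] <- data.table(read_id = s$read_id, mate = s$mate,
                             reason = "ambiguous")
    } else if (!is.na(m1) || !is.na(m2)) {
      o <- if (!is.na(m1)) o1 else o2
      m <- if (!is.na(m1)) m1 else m2
      out[[i]] <- data.table(
        read_id = s$read_id, mate = s$mate,
        don_chrom = o$don_chrom, don_pos = o$don_pos, don_strand = o$don_strand,
        acc_chrom = o$acc_chrom, acc_pos = o$acc_pos, acc_strand = o$acc_strand,
        don_outer = o$don_outer, acc_outer = o$acc_outer, motif = m)
    } else {
      rej[[i]] <- data.table(read_id = s$read_id, mate = s$mate,
                             reason = if (edge_seen) "edge" else "no_consensus")
    }
  }
  empty_or <- data.table(
    read_id = character(), mate = integer(), don_chrom = character(),
    don_pos = integer(), don_strand = character(), acc_chrom = character(),
    acc_pos = integer(), acc_strand = character(), don_outer = integer(),
    acc_outer = integer(), motif = character())
  oriented <- if (any(!vapply(out, is.null, logical(1)))) {
    rbindlist(out[!vapply(out, is.null, logical(1))])
  } else empty_or
  rejected <- if (any(!vapply(rej, is.null, logical(1)))) {
    rbindlist(rej[!vapply(rej, is.null, logical(1))])
  } else data.table(read_id = character(), mate = integer(), reason = character())
  list(oriented = oriented, rejected = rejected)
}

#' Cluster oriented split reads into consensus junctions
#'
#' One cluster per distinct (donor, acceptor) site pair. `nb_split` is the
#' member count; `nb_staggered` counts distinct (donor-side outer, acceptor-
#' side outer) coordinate pairs among members — the ladder pattern of
#' staggered split reads. External boundaries are the most-distal member
#' coordinates on each side.
#'
#' @param oriented Oriented split reads from [orient_splits()].
#' @return data.table with one row per junction: junction_id, site columns,
#'   nb_split, nb_staggered, ext_don, ext_acc, motif, reads (comma-separated
#'   supporting read ids).
#' @export
cluster_splits <- function(oriented) {
  if (!nrow(oriented)) {
    return(data.table(
      junction_id = character(), don_chrom = character(), don_pos = integer(),
      don_strand = character(), acc_chrom = character(), acc_pos = integer(),
      acc_strand = character(), nb_split = integer(), nb_staggered = integer(),
      ext_don = integer(), ext_acc = integer(), motif = character(),
      reads = character()))
  }
  cl <- oriented[, .(
    nb_split = .N,
    nb_staggered = uniqueN(paste(don_outer, acc_outer)),
    ext_don = if (don_strand[1L] == "+") min(don_outer) else max(don_outer),
    ext_acc = if (acc_strand[1L] == "+") max(acc_outer) else min(acc_outer),
    motif = motif[1L],
    reads = paste(unique(read_id), collapse = ",")
  ), by = .(don_chrom, don_pos, don_strand, acc_chrom, acc_pos, acc_strand)]
  cl[, junction_id := junction_id(don_chrom, don_pos, don_strand,
                                  acc_chrom, acc_pos, acc_strand)]
  setcolorder(cl, "junction_id")
  cl[]
}

#' Annotate junction sides with parent genes and splice-site status
#'
#' For each side, the segment span (junction position to external boundary)
#' is overlapped against annotated exons on the matching strand (both strands
#' with `both_strands = TRUE`); the parent gene is the one with the largest
#' summed exonic overlap, ties broken by protein_coding biotype first, then
#' smallest gene_id. Each side also gets a flag saying whether its splice
#' site coincides with an annotated donor (5' side) or acceptor (3' side).
#'
#' @param clusters Junction clusters from [cluster_splits()].
#' @param index An `annotation_index`.
#' @param both_strands Overlap exons on both strands regardless of the
#'   oriented junction strand (default `FALSE`).
#' @return The cluster table with added columns gene5, gene3, overlap5,
#'   overlap3, ann5, ann3.
#' @export
annotate_junctions <- function(clusters, index, both_strands = FALSE) {
  cl <- copy(clusters)
  if (!nrow(cl)) {
    cl[, `:=`(gene5 = character(), gene3 = character(),
              overlap5 = integer(), overlap3 = integer(),
              ann5 = logical(), ann3 = logical())]
    return(cl[])
  }
  q5 <- data.table(qid = seq_len(nrow(cl)), chrom = cl$don_chrom,
                   start = pmin(cl$don_pos, cl$ext_don),
                   end = pmax(cl$don_pos, cl$ext_don),
                   strand = if (both_strands) NA_character_ else cl$don_strand)
  q3 <- data.table(qid = seq_len(nrow(cl)), chrom = cl$acc_chrom,
                   start = pmin(cl$acc_pos, cl$ext_acc),
                   end = pmax(cl$acc_pos, cl$ext_acc),
                   strand = if (both_strands) NA_character_ else cl$acc_strand)
  b5 <- best_gene(index, q5)
  b3 <- best_gene(index, q3)
  cl[, `:=`(gene5 = NA_character_, gene3 = NA_character_,
            overlap5 = NA_integer_, overlap3 = NA_integer_)]
  if (nrow(b5)) {
    cl[b5$qid, `:=`(gene5 = b5$gene_id, overlap5 = b5$overlap_bp)]
  }
  if (nrow(b3)) {
    cl[b3$qid, `:=`(gene3 = b3$gene_id, overlap3 = b3$overlap_bp)]
  }
  cl[, ann5 := is_annotated_donor(index, don_chrom, don_pos, don_strand)]
  cl[, ann3 := is_annotated_acceptor(index, acc_chrom, acc_pos, acc_strand)]
  cl[]
}

#' Select chimeric junction candidates
#'
#' Keeps junctions whose two sides are assigned to two different genes.
#' Same-gene junctions (ordinary splice junctions) and junctions with an
#' unassigned side are dropped; their counts are attached as the
#' `"dropped"` attribute.
#'
#' @param junctions Annotated junctions from [annotate_junctions()].
#' @return The chimeric-candidate subset, with attribute `dropped` =
#'   c(same_gene = n, unannotated_side = n).
#' @export
select_chimeric <- function(junctions) {
  has_both <- !is.na(junctions$gene5) & !is.na(junctions$gene3)
  same <- has_both & junctions$gene5 == junctions$gene3
  keep <- has_both & !same
  out <- junctions[keep]
  setattr(out, "dropped",
          c(same_gene = sum(same), unannotated_side = sum(!has_both)))
  out
}
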