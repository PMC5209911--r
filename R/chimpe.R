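# Discordant-pair evidence: attach paired-end support to candidate junctions.
# A discordant pair has its two mates assigned (by largest exonic overlap)
# to two different genes; for a junction connecting those genes the pair is
# judged consistent when its geometry fits the implied chimeric transcript.

#' Find discordant mate pairs
#'
#' Assigns each mate of every both-mates-mapped pair to its highest-overlap
#' gene (summed exonic overlap over the mate's aligned blocks, strand
#' ignored; same tie-break as junction annotation) and returns pairs whose
#' two mates land in different genes.
#'
#' @param ingested Result of [ingest_alignments()] (uses `mate_blocks`).
#' @param index An `annotation_index`.
#' @return data.table: read_id, gene_a (mate 1 gene), gene_b (mate 2 gene).
#' @export
find_discordant <- function(ingested, index) {
  mb <- ingested$mate_blocks
  if (!nrow(mb)) {
    return(data.table(read_id = character(), gene_a = character(),
                      gene_b = character()))
  }
  both <- ingested$pairs[both_mapped == TRUE, read_id]
  mb <- mb[read_id %in% both]
  q <- mb[, .(read_id, mate, chrom, start, end)]
  q[, qid := .GRP, by = .(read_id, mate)]
  key <- unique(q[, .(qid, read_id, mate)])
  bg <- best_gene(index, q[, .(qid, chrom, start, end, strand = NA_character_)])
  asg <- merge(key, bg, by = "qid")
  wide <- dcast(asg, read_id ~ mate, value.var = "gene_id")
  if (!all(c("1", "2") %in% names(wide))) {
    return(data.table(read_id = character(), gene_a = character(),
                      gene_b = character()))
  }
  setnames(wide, c("1", "2"), c("gene_a", "gene_b"))
  out <- wide[!is.na(gene_a) & !is.na(gene_b) & gene_a != gene_b,
              .(read_id, gene_a, gene_b)]
  setkey(out, NULL)
  out[]
}

# exonic-space distance within a gene between two genomic coordinates:
# summed overlap of the gene's collapsed exons with the closed interval
exonic_span <- function(index, gene, chr, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  ex <- index$uexons[gene_id == gene & chrom == chr]
  if (!nrow(ex)) return(0L)
  sum(pmax(0L, pmin(ex$end, hi) - pmax(ex$start, lo) + 1L))
}

#' Judge a discordant pair against a junction
#'
#' Lays the chimeric transcript implied by the junction out 5' to 3' and
#' checks that the mate assigned to the 5' gene lies upstream of (or abuts)
#' the donor on the donor strand, the mate in the 3' gene lies downstream of
#' (or abuts) the acceptor on the opposite of the acceptor strand (inward
#' facing), and that the implied transcript-space insert — measured as the
#' exonic span between each mate's far end and its junction side — does not
#' exceed `max_insert`.
#'
#' @param junction One junction (list or single-row data.table with
#'   don_chrom, don_pos, don_strand, acc_chrom, acc_pos, acc_strand,
#'   gene5, gene3).
#' @param pair_blocks Aligned blocks of the pair's two mates (data.table with
#'   mate, chrom, strand, start, end) as in `mate_blocks`.
#' @param mate5,mate3 Which mate (1 or 2) is assigned to gene5 / gene3.
#' @param index An `annotation_index`.
#' @param max_insert Maximum implied insert in bp (default 1000).
#' @return `"consistent"` or `"inconsistent"`.
#' @export
assess_consistency <- function(junction, pair_blocks, mate5, mate3, index,
                               max_insert = 1000L) {
  j <- junction
  g5 <- index$genes[gene_id == j$gene5]
  g3 <- index$genes[gene_id == j$gene3]
  if (!nrow(g5) || !nrow(g3)) stop("junction parent genes not in the index")

  b5 <- pair_blocks[mate == mate5 & chrom == j$don_chrom &
                      start <= g5$end & end >= g5$start]
  b3 <- pair_blocks[mate == mate3 & chrom == j$acc_chrom &
                      start <= g3$end & end >= g3$start]
  if (!nrow(b5) || !nrow(b3)) return("inconsistent")

  # inward orientation along the chimeric transcript
  if (!all(b5$strand == j$don_strand)) return("inconsistent")
  if (!all(b3$strand == flip_strand(j$acc_strand))) return("inconsistent")

  if (j$don_strand == "+") {
    near5 <- max(b5$end); far5 <- min(b5$start)
    if (near5 > j$don_pos) return("inconsistent")
  } else {
    near5 <- min(b5$start); far5 <- max(b5$end)
    if (near5 < j$don_pos) return("inconsistent")
  }
  if (j$acc_strand == "+") {
    near3 <- min(b3$start); far3 <- max(b3$end)
    if (near3 < j$acc_pos) return("inconsistent")
  } else {
    near3 <- max(b3$end); far3 <- min(b3$start)
    if (near3 > j$acc_pos) return("inconsistent")
  }

  d5 <- exonic_span(index, j$gene5, j$don_chrom, far5, j$don_pos)
  d3 <- exonic_span(index, j$gene3, j$acc_chrom, j$acc_pos, far3)
  if (d5 + d3 > max_insert) return("inconsistent")
  "consistent"
}

#' Attach paired-end support to candidate junctions
#'
#' For each junction, discordant pairs connecting its two parent genes (in
#' either mate order) are assessed with [assess_consistency()] and counted.
#' A pair may support several junctions of the same gene pair (isoforms);
#' it is counted once per junction. `nb_total = nb_split + nb_consistent_pe`.
#'
#' @param junctions Chimeric candidates from [select_chimeric()].
#' @param discordant Output of [find_discordant()].
#' @param ingested Result of [ingest_alignments()] (for mate blocks).
#' @param index An `annotation_index`.
#' @param max_insert Maximum implied insert in bp (default 1000).
#' @return The junction table with nb_consistent_pe, nb_inconsistent_pe,
#'   nb_total and pe_reads (comma-separated consistent pair ids) columns.
#' @export
attach_support <- function(junctions, discordant, ingested, index,
                           max_insert = 1000L) {
  jn <- copy(junctions)
  jn[, `:=`(nb_consistent_pe = 0L, nb_inconsistent_pe = 0L,
            pe_reads = "")]
  if (nrow(jn) && nrow(discordant)) {
    mb <- ingested$mate_blocks
    setkey(mb, read_id)
    for (i in seq_len(nrow(jn))) {
      j <- jn[i]
      m <- discordant[(gene_a == j$gene5 & gene_b == j$gene3) |
                        (gene_a == j$gene3 & gene_b == j$gene5)]
      if (!nrow(m)) next
      ncon <- 0L; nincon <- 0L; con_ids <- character()
      for (k in seq_len(nrow(m))) {
        p <- m[k]
        mate5 <- if (p$gene_a == j$gene5) 1L else 2L
        verdict <- assess_consistency(j, mb[J(p$read_id)], mate5,
                                      3L - mate5, index, max_insert)
        if (verdict == "consistent") {
          ncon <- ncon + 1L
          con_ids <- c(con_ids, p$read_id)
        } else {
          nincon <- nincon + 1L
        }
      }
      jn[i, `:=`(nb_consistent_pe = ncon, nb_inconsistent_pe = nincon,
                 pe_reads = paste(con_ids, collapse = ","))]
    }
  }
  jn[, nb_total := nb_split + nb_consistent_pe]
  jn[]
}
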