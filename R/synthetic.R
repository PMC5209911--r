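# Synthetic genome + annotation generator used by the simulator examples,
# the test-suite and the acceptance runs. Gene structures are planted with
# canonical splice motifs (GT..AG introns on +, appearing as CT..AC in
# forward genome sense on -) so that every annotated splice site carries a
# consensus motif the detector can orient against.

#' Generate a random genome with a gene annotation
#'
#' Builds `n_chrom` chromosomes of random sequence, each carrying
#' `genes_per_chrom` non-overlapping multi-exon genes on random strands.
#' Every intron starts with GT and ends with AG in transcript sense, so all
#' annotated splice sites are motif-compatible. One transcript per gene;
#' all genes are `protein_coding` with ids of the form `G<chrom>.<n>`.
#'
#' Intergenic spacing controls which chimera classes have candidate gene
#' pairs: with the defaults each chromosome spans roughly 140 kb so both
#' read-through pairs (< 100 kb apart) and intrachromosomal pairs
#' (>= 100 kb apart) exist.
#'
#' @param n_chrom Number of chromosomes (default 3).
#' @param genes_per_chrom Genes per chromosome (default 16).
#' @param exons_per_gene Range of exon counts per gene (default 3:5).
#' @param exon_len Range of exon lengths in bp (default 120:200).
#' @param intron_len Range of intron lengths in bp (default 150:350).
#' @param intergenic Range of intergenic gaps in bp (default 5000:9000).
#' @param seed Optional seed; when given, `set.seed(seed)` is called.
#' @return list with `genome` (named `DNAStringSet`), `exons` (data.table)
#'   and `index` (an `annotation_index`).
#' @export
synth_genome <- function(n_chrom = 3L, genes_per_chrom = 16L,
                         exons_per_gene = 3:5, exon_len = 120:200,
                         intron_len = 150:350, intergenic = 5000:9000,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- function(rng) if (length(rng) == 1L) rng else sample(rng, 1L)
  chroms <- character(n_chrom)
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  exon_rows <- list()
  for (ci in seq_len(n_chrom)) {
    chrom <- paste0("chr", ci)
    parts <- list(random_dna(pick(intergenic)))
    cursor <- nchar(parts[[1L]])
    for (gi in seq_len(genes_per_chrom)) {
      strand <- sample(c("+", "-"), 1L)
      nex <- pick(exons_per_gene)
      gene_id <- sprintf("G%d.%02d", ci, gi)
      gstart <- cursor + 1L
      for (e in seq_len(nex)) {
        elen <- pick(exon_len)
        parts[[length(parts) + 1L]] <- random_dna(elen)
        exon_rows[[length(exon_rows) + 1L]] <- data.table(
          chrom = chrom, start = cursor + 1L, end = cursor + elen,
          strand = strand, gene_id = gene_id,
          transcript_id = paste0(gene_id, ".t1"),
          gene_name = gene_id, biotype = "protein_coding")
        cursor <- cursor + elen
        if (e < nex) {
          ilen <- pick(intron_len)
          mid <- random_dna(ilen - 4L)
          intron <- if (strand == "+") paste0("GT", mid, "AG")
                    else paste0("CT", mid, "AC")
          parts[[length(parts) + 1L]] <- intron
          cursor <- cursor + ilen
        }
      }
      gap <- random_dna(pick(intergenic))
      parts[[length(parts) + 1L]] <- gap
      cursor <- cursor + nchar(gap)
    }
    chroms[[chrom]] <- paste(unlist(parts), collapse = "")
  }
  exons <- rbindlist(exon_rows)
  list(genome = DNAStringSet(chroms), exons = exons,
       index = annotation_index(exons))
}

#' Write an exon table as GTF
#'
#' Emits one `exon` feature line per exon with `gene_id`, `transcript_id`,
#' `gene_name` and `gene_type` attributes, round-trippable through
#' [read_gtf()].
#'
#' @param exons Exon data.table (as in `synth_genome()$exons` or
#'   `annotation_index$exons`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(exons, path) {
  ex <- as.data.table(exons)
  if (!"gene_name" %in% names(ex)) ex[, gene_name := gene_id]
  if (!"biotype" %in% names(ex)) ex[, biotype := "unknown"]
  lines <- sprintf(
    "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\"; gene_type \"%s\";",
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    ex$gene_name, ex$biotype)
  writeLines(lines, path)
  invisible(path)
}
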