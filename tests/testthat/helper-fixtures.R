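# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

library(data.table)

# hand-made two-gene annotation: geneA (+, 3 exons) and geneB (+, 2 exons)
# on chr1, geneC (-, 2 exons) on chr2
tiny_exons <- function() {
  rbindlist(list(
    data.table(chrom = "chr1", start = c(101L, 301L, 501L),
               end = c(180L, 380L, 580L), strand = "+",
               gene_id = "geneA", transcript_id = "geneA.t1",
               gene_name = "geneA", biotype = "protein_coding"),
    data.table(chrom = "chr1", start = c(2001L, 2301L),
               end = c(2100L, 2400L), strand = "+",
               gene_id = "geneB", transcript_id = "geneB.t1",
               gene_name = "geneB", biotype = "protein_coding"),
    data.table(chrom = "chr2", start = c(101L, 401L),
               end = c(200L, 500L), strand = "-",
               gene_id = "geneC", transcript_id = "geneC.t1",
               gene_name = "geneC", biotype = "protein_coding")
  ))
}

# genome with a planted GT..AG intron between two 80 bp exons on chr1 (+)
# and the reverse-complement construct (CT..AC in forward sense) on chr2,
# plus a motif-less chr3
motif_genome <- function() {
  set.seed(424242)
  exA <- random_dna_str(80)
  exB <- random_dna_str(80)
  mid <- random_dna_str(96)
  chr1 <- paste0(exA, "GT", mid, "AG", exB)        # exons 1-80, 181-260
  chr2 <- paste0(exB, "CT", mid, "AC", exA)        # '-' transcript construct
  chr3 <- paste0(strrep("A", 80), strrep("A", 100), strrep("T", 80))
  c(chr1 = chr1, chr2 = chr2, chr3 = chr3)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a SAM file from record lines, with @SQ headers
write_sam <- function(records, sq = c(chr1 = 100000L, chr7 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(sq), "\tLN:", sq))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos, cigar, seq,
                       rnext = "*", pnext = 0L, tags = "NH:i:1") {
  paste(qname, flag, chrom, pos, 60L, cigar, rnext, pnext, 0L, seq,
        strrep("I", nchar(seq)), tags, sep = "\t")
}

# O(n) brute-force exon overlap oracle over the collapsed exon table
brute_overlap <- function(index, chrom, start, end, strand = NULL) {
  ex <- index$uexons
  hit <- ex$chrom == chrom & ex$start <= end & ex$end >= start
  if (!is.null(strand)) hit <- hit & ex$strand == strand
  res <- ex[hit]
  if (!nrow(res)) return(res[, overlap_bp := integer()])
  res <- copy(res)
  res[, overlap_bp := pmin(end, ..e) - pmax(start, ..s) + 1L,
      env = list(..e = end, ..s = start)]
  res[order(start, end, gene_id)]
}

# two-gene index + genome whose genes share an exonic block of configurable
# length/identity (mismatching flanks prevent local-alignment extension)
similarity_fixture <- function(block_a, block_b) {
  gA <- paste0(strrep("A", 60), block_a, strrep("A", 60))
  gB <- paste0(strrep("C", 60), block_b, strrep("C", 60))
  genome <- c(chr1 = paste0(gA, strrep("T", 30), gB))
  ex <- data.table(
    chrom = "chr1",
    start = c(1L, nchar(gA) + 31L),
    end = c(nchar(gA), nchar(gA) + 30L + nchar(gB)),
    strand = "+", gene_id = c("simA", "simB"),
    transcript_id = c("simA.t", "simB.t"))
  list(index = annotation_index(ex), genome = genome)
}

# graded-identity copy of a block: k substitutions placed >= 4 bp from the
# ends and apart, so the full block stays the optimal local alignment
substitute_block <- function(block, k) {
  if (k == 0L) return(block)
  v <- strsplit(block, "")[[1L]]
  pos <- unique(round(seq(5, length(v) - 4, length.out = k)))
  stopifnot(length(pos) == k)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1L]
  paste(v, collapse = "")
}

# small simulation on a synthetic genome, reused by several test files
small_sim <- function(seed = 11, coverage = 12, bg_fraction = 0.3,
                      n_per_class = 2L, out_dir = tempfile()) {
  sg <- synth_genome(n_chrom = 3, genes_per_chrom = 16, seed = 7)
  cfg <- sim_config(
    n_readthrough = n_per_class, n_intrachromosomal = n_per_class,
    n_inverted = n_per_class, n_interstrand = n_per_class,
    n_interchromosomal = n_per_class, bg_fraction = bg_fraction,
    coverage = coverage, seed = seed)
  sim <- simulate_dataset(sg$genome, sg$index, cfg, out_dir)
  list(sg = sg, cfg = cfg, sim = sim, out_dir = out_dir)
}
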