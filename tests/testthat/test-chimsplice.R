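# motif_genome(): chr1 = exonA(1-80) GT..AG intron(81-180) exonB(181-260),
# chr2 the reverse-complement construct, chr3 motif-less.

split_row <- function(chromA, startA, endA, strandA,
                      chromB, startB, endB, strandB, id = "s1") {
  data.table(read_id = id, mate = 1L,
             chromA = chromA, startA = startA, endA = endA, strandA = strandA,
             qstartA = 1L, qendA = 30L,
             chromB = chromB, startB = startB, endB = endB, strandB = strandB,
             qstartB = 31L, qendB = 60L, nh = 1L)
}

test_that("orientation finds the unique consensus-motif direction", {
  g <- motif_genome()
  # forward construct: donor at end of exonA, acceptor at start of exonB
  o <- orient_splits(split_row("chr1", 51L, 80L, "+", "chr1", 181L, 210L, "+"), g)
  expect_equal(nrow(o$oriented), 1L)
  j <- o$oriented[1]
  expect_equal(c(j$don_chrom, j$don_pos, j$don_strand), c("chr1", "80", "+"))
  expect_equal(c(j$acc_chrom, j$acc_pos, j$acc_strand), c("chr1", "181", "+"))
  expect_equal(j$motif, "GT-AG")
  expect_equal(c(j$don_outer, j$acc_outer), c(51L, 210L))

  # reverse-strand construct: genome shows CT..AC in forward sense
  o2 <- orient_splits(split_row("chr2", 181L, 210L, "-", "chr2", 51L, 80L, "-"), g)
  j2 <- o2$oriented[1]
  expect_equal(c(j2$don_pos, j2$don_strand), c("181", "-"))
  expect_equal(c(j2$acc_pos, j2$acc_strand), c("80", "-"))
  expect_equal(j2$motif, "GT-AG")

  # motif-less flanks are rejected
  o3 <- orient_splits(split_row("chr3", 51L, 80L, "+", "chr3", 181L, 210L, "+"), g)
  expect_equal(nrow(o3$oriented), 0L)
  expect_equal(o3$rejected$reason, "no_consensus")
})

test_that("orientation is idempotent under read reversal", {
  g <- motif_genome()
  fwd <- split_row("chr1", 51L, 80L, "+", "chr1", 181L, 210L, "+")
  # the same molecule sequenced from the other end: segments swapped and
  # strands flipped
  rev <- split_row("chr1", 181L, 210L, "-", "chr1", 51L, 80L, "-")
  jf <- orient_splits(fwd, g)$oriented[1]
  jr <- orient_splits(rev, g)$oriented[1]
  cols <- c("don_chrom", "don_pos", "don_strand",
            "acc_chrom", "acc_pos", "acc_strand", "motif")
  expect_equal(jf[, cols, with = FALSE], jr[, cols, with = FALSE])
})

test_that("chromosome-edge segments are rejected with reason edge", {
  g <- motif_genome()
  # donor flank would start beyond position 1 on the acceptor side
  o <- orient_splits(split_row("chr3", 1L, 30L, "-", "chr3", 231L, 260L, "-"), g)
  expect_equal(nrow(o$oriented), 0L)
  expect_equal(o$rejected$reason, "edge")
})

test_that("clusters key on exact sites and count staggered offsets", {
  base <- data.table(
    read_id = paste0("r", 1:5), mate = 1L,
    don_chrom = "chr1", don_pos = 80L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 181L, acc_strand = "+",
    don_outer = c(51L, 46L, 41L, 36L, 31L),
    acc_outer = c(210L, 215L, 220L, 225L, 230L), motif = "GT-AG")
  cl <- cluster_splits(base)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$nb_split, 5L)
  expect_equal(cl$nb_staggered, 5L)
  expect_equal(c(cl$ext_don, cl$ext_acc), c(31L, 230L))
  expect_equal(cl$junction_id, "chr1_80_+:chr1_181_+")

  # PCR duplicates: identical offsets count once
  dup <- copy(base)[, `:=`(don_outer = 51L, acc_outer = 210L)]
  cl2 <- cluster_splits(dup)
  expect_equal(c(cl2$nb_split, cl2$nb_staggered), c(5L, 1L))

  # a second acceptor position makes a second cluster
  two <- rbind(base, copy(base)[1][, acc_pos := 190L])
  expect_equal(nrow(cluster_splits(two)), 2L)
})

test_that("cluster partition preserves every oriented read once", {
  set.seed(5)
  n <- 200L
  reads <- data.table(
    read_id = paste0("r", seq_len(n)), mate = 1L,
    don_chrom = "chr1", don_pos = sample(c(80L, 380L, 1000L), n, TRUE),
    don_strand = "+", acc_chrom = "chr1",
    acc_pos = sample(c(181L, 481L), n, TRUE), acc_strand = "+",
    don_outer = sample(31L:60L, n, TRUE),
    acc_outer = sample(200L:230L, n, TRUE), motif = "GT-AG")
  cl <- cluster_splits(reads)
  expect_equal(sum(cl$nb_split), n)
  expect_true(all(cl$nb_staggered <= cl$nb_split))
})

test_that("junction sides take the gene with the larger exonic overlap", {
  # two + genes overlap the donor-side span by 40 bp (gx) and 12 bp (gy)
  idx <- annotation_index(data.table(
    chrom = "chr1",
    start = c(41L, 69L, 181L), end = c(80L, 80L, 260L), strand = "+",
    gene_id = c("gx", "gy", "gz"),
    transcript_id = c("gx.t", "gy.t", "gz.t")))
  cl <- data.table(
    junction_id = "chr1_80_+:chr1_181_+",
    don_chrom = "chr1", don_pos = 80L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 181L, acc_strand = "+",
    nb_split = 1L, nb_staggered = 1L, ext_don = 41L, ext_acc = 210L,
    motif = "GT-AG", reads = "r1")
  ann <- annotate_junctions(cl, idx)
  expect_equal(ann$gene5, "gx")
  expect_equal(ann$overlap5, 40L)
  expect_equal(ann$gene3, "gz")
})

test_that("gene ties break by biotype then lexicographic gene id", {
  mk <- function(biotypes) annotation_index(data.table(
    chrom = "chr1", start = c(41L, 41L, 181L), end = c(80L, 80L, 260L),
    strand = "+", gene_id = c("gb", "ga", "gz"),
    transcript_id = c("gb.t", "ga.t", "gz.t"),
    biotype = c(biotypes, "protein_coding")))
  cl <- data.table(
    junction_id = "chr1_80_+:chr1_181_+",
    don_chrom = "chr1", don_pos = 80L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 181L, acc_strand = "+",
    nb_split = 1L, nb_staggered = 1L, ext_don = 41L, ext_acc = 210L,
    motif = "GT-AG", reads = "r1")
  # equal overlap: protein_coding outranks lincRNA
  ann <- annotate_junctions(cl, mk(c("protein_coding", "lincRNA")))
  expect_equal(ann$gene5, "gb")
  # both protein_coding: smaller gene_id wins
  ann2 <- annotate_junctions(cl, mk(c("protein_coding", "protein_coding")))
  expect_equal(ann2$gene5, "ga")
})

test_that("annotated-splice-site flags use positional stranded membership", {
  idx <- annotation_index(tiny_exons())
  cl <- data.table(
    junction_id = "chr1_180_+:chr1_2301_+",
    don_chrom = "chr1", don_pos = 180L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 2301L, acc_strand = "+",
    nb_split = 1L, nb_staggered = 1L, ext_don = 150L, ext_acc = 2330L,
    motif = "GT-AG", reads = "r1")
  ann <- annotate_junctions(cl, idx)
  expect_true(ann$ann5)   # end of geneA exon1 is an annotated donor
  expect_true(ann$ann3)   # start of geneB exon2 is an annotated acceptor
  off <- copy(cl)[, `:=`(don_pos = 179L, ext_don = 150L)]
  expect_false(annotate_junctions(off, idx)$ann5)
})

test_that("only junctions connecting two different genes are selected", {
  jn <- data.table(
    junction_id = c("a", "b", "c"),
    gene5 = c("geneA", "geneA", "geneA"),
    gene3 = c("geneB", "geneA", NA_character_))
  sel <- select_chimeric(jn)
  expect_equal(sel$junction_id, "a")
  expect_equal(attr(sel, "dropped"),
               c(same_gene = 1L, unannotated_side = 1L))
})
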