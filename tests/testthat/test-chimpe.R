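# Gene layout for consistency tests: geneU (+, chr1:1000-3000) and
# geneD (+, chr1:10000-12000), each one long exon, junction joining
# donor 2500 (+) to acceptor 10500 (+).

pe_index <- function() {
  annotation_index(data.table(
    chrom = "chr1", start = c(1000L, 10000L), end = c(3000L, 12000L),
    strand = "+", gene_id = c("geneU", "geneD"),
    transcript_id = c("geneU.t", "geneD.t")))
}

pe_junction <- function() {
  list(don_chrom = "chr1", don_pos = 2500L, don_strand = "+",
       acc_chrom = "chr1", acc_pos = 10500L, acc_strand = "+",
       gene5 = "geneU", gene3 = "geneD")
}

blocks <- function(m1, m2) {
  rbind(
    data.table(mate = 1L, chrom = "chr1", strand = m1[[3]],
               start = m1[[1]], end = m1[[2]]),
    data.table(mate = 2L, chrom = "chr1", strand = m2[[3]],
               start = m2[[1]], end = m2[[2]]))
}

test_that("discordant pairs require mates in two different genes", {
  idx <- pe_index()
  mk <- function(c1, s1, e1, c2, s2, e2) {
    list(mate_blocks = rbind(
      data.table(read_id = "p", mate = 1L, chrom = c1, strand = "+",
                 start = s1, end = e1),
      data.table(read_id = "p", mate = 2L, chrom = c2, strand = "-",
                 start = s2, end = e2)),
      pairs = data.table(read_id = "p", both_mapped = TRUE))
  }
  # mate1 in geneU, mate2 in geneD
  d <- find_discordant(mk("chr1", 1100L, 1174L, "chr1", 10600L, 10674L), idx)
  expect_equal(d, data.table(read_id = "p", gene_a = "geneU", gene_b = "geneD"))
  # both mates in geneU
  expect_equal(nrow(find_discordant(
    mk("chr1", 1100L, 1174L, "chr1", 2000L, 2074L), idx)), 0L)
  # mate2 intergenic
  expect_equal(nrow(find_discordant(
    mk("chr1", 1100L, 1174L, "chr1", 5000L, 5074L), idx)), 0L)
})

test_that("consistency requires flanking positions, inward orientation and insert", {
  idx <- pe_index()
  j <- pe_junction()
  # mate ends 200 bp before the donor, mate starts 150 bp after the acceptor
  expect_equal(assess_consistency(
    j, blocks(list(2226L, 2300L, "+"), list(10650L, 10724L, "-")),
    1L, 2L, idx), "consistent")
  # abutting the junction on both sides is still consistent
  expect_equal(assess_consistency(
    j, blocks(list(2426L, 2500L, "+"), list(10500L, 10574L, "-")),
    1L, 2L, idx), "consistent")
  # gene5 mate mapped downstream of the donor (past the junction)
  expect_equal(assess_consistency(
    j, blocks(list(2600L, 2674L, "+"), list(10650L, 10724L, "-")),
    1L, 2L, idx), "inconsistent")
  # outward-facing gene5 mate
  expect_equal(assess_consistency(
    j, blocks(list(2226L, 2300L, "-"), list(10650L, 10724L, "-")),
    1L, 2L, idx), "inconsistent")
  # both mates on the acceptor side of the junction in transcript space
  expect_equal(assess_consistency(
    j, blocks(list(10650L, 10724L, "+"), list(10900L, 10974L, "-")),
    1L, 2L, idx), "inconsistent")
  # insert beyond max_insert
  expect_equal(assess_consistency(
    j, blocks(list(1000L, 1074L, "+"), list(11900L, 11974L, "-")),
    1L, 2L, idx, max_insert = 1000L), "inconsistent")
  expect_equal(assess_consistency(
    j, blocks(list(1000L, 1074L, "+"), list(11900L, 11974L, "-")),
    1L, 2L, idx, max_insert = 5000L), "consistent")
})

test_that("the implied insert is measured in exonic space", {
  # donor-side gene with a 5 kb intron between its exons: a mate upstream of
  # the intron is close to the junction in transcript space even though it
  # is far in genomic space
  idx <- annotation_index(data.table(
    chrom = "chr1", start = c(1000L, 7000L, 10000L),
    end = c(1500L, 7500L, 12000L), strand = "+",
    gene_id = c("geneU", "geneU", "geneD"),
    transcript_id = c("geneU.t", "geneU.t", "geneD.t")))
  j <- list(don_chrom = "chr1", don_pos = 7500L, don_strand = "+",
            acc_chrom = "chr1", acc_pos = 10500L, acc_strand = "+",
            gene5 = "geneU", gene3 = "geneD")
  pb <- blocks(list(1100L, 1174L, "+"), list(10600L, 10674L, "-"))
  # genomic gap is ~9.5 kb but exonic distance is ~1 kb
  expect_equal(assess_consistency(j, pb, 1L, 2L, idx, max_insert = 1200L),
               "consistent")
  expect_equal(assess_consistency(j, pb, 1L, 2L, idx, max_insert = 800L),
               "inconsistent")
})

test_that("support attachment counts each matching pair once per junction", {
  idx <- pe_index()
  jn <- data.table(
    junction_id = "chr1_2500_+:chr1_10500_+",
    don_chrom = "chr1", don_pos = 2500L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 10500L, acc_strand = "+",
    gene5 = "geneU", gene3 = "geneD",
    nb_split = 4L, nb_staggered = 3L)
  mb <- rbind(
    blocks(list(2226L, 2300L, "+"), list(10650L, 10724L, "-"))[, read_id := "c1"],
    blocks(list(2300L, 2374L, "+"), list(10700L, 10774L, "-"))[, read_id := "c2"],
    blocks(list(2600L, 2674L, "+"), list(10650L, 10724L, "-"))[, read_id := "i1"])
  ing <- list(mate_blocks = mb,
              pairs = data.table(read_id = c("c1", "c2", "i1"),
                                 both_mapped = TRUE))
  disc <- data.table(read_id = c("c1", "c2", "i1"),
                     gene_a = "geneU", gene_b = "geneD")
  sup <- attach_support(jn, disc, ing, idx)
  expect_equal(sup$nb_consistent_pe, 2L)
  expect_equal(sup$nb_inconsistent_pe, 1L)
  expect_equal(sup$nb_total, 6L)   # 4 split + 2 consistent PE
  expect_setequal(strsplit(sup$pe_reads, ",")[[1]], c("c1", "c2"))

  # no matching pairs: totals fall back to the split support
  sup0 <- attach_support(jn, disc[0], ing, idx)
  expect_equal(c(sup0$nb_consistent_pe, sup0$nb_inconsistent_pe), c(0L, 0L))
  expect_equal(sup0$nb_total, 4L)

  # one pair may support two isoform junctions of the same gene pair
  jn2 <- rbind(jn, copy(jn)[, `:=`(junction_id = "chr1_2400_+:chr1_10500_+",
                                   don_pos = 2400L)])
  sup2 <- attach_support(jn2, disc[read_id == "c1"], ing, idx)
  expect_equal(sup2$nb_consistent_pe, c(1L, 1L))
})

test_that("a pair is never both consistent and inconsistent for one junction", {
  idx <- pe_index()
  j <- pe_junction()
  set.seed(77)
  for (i in 1:50) {
    s1 <- sample(1000L:2900L, 1L); s2 <- sample(10000L:11900L, 1L)
    pb <- blocks(list(s1, s1 + 74L, sample(c("+", "-"), 1L)),
                 list(s2, s2 + 74L, sample(c("+", "-"), 1L)))
    v <- assess_consistency(j, pb, 1L, 2L, idx)
    expect_true(v %in% c("consistent", "inconsistent"))
  }
})
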