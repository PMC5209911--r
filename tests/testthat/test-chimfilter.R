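support_row <- function(tier, split, pe, stag = split) {
  data.table(tier = tier, nb_split = split, nb_staggered = stag,
             nb_consistent_pe = pe, nb_total = split + pe)
}

test_that("tier assignment follows the annotated-sides rule", {
  expect_equal(tier_of(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)),
               c("annotated", "novel", "novel"))
  expect_equal(tier_of(c(TRUE, FALSE), c(FALSE, FALSE), rule = "either"),
               c("annotated", "novel"))
})

test_that("two-tier support thresholds are enforced at their boundaries", {
  cfg <- filter_config()
  # annotated: 1 consistent PE + 1 split + 3 total
  expect_true(is.na(support_filter(support_row("annotated", 2L, 1L), cfg)))
  expect_match(support_filter(support_row("annotated", 1L, 1L), cfg),
               "total_support")
  expect_match(support_filter(support_row("annotated", 3L, 0L), cfg),
               "pe_support")
  # novel: 3 + 3 + 6
  expect_true(is.na(support_filter(support_row("novel", 3L, 3L), cfg)))
  expect_match(support_filter(support_row("novel", 2L, 4L), cfg),
               "split_support")
  expect_match(support_filter(support_row("novel", 2L, 2L), cfg),
               "split_support.*total_support")
})

test_that("mitochondrial and pseudogene junctions are removed", {
  idx <- annotation_index(data.table(
    chrom = c("chr1", "chrM", "chr2"),
    start = c(100L, 100L, 100L), end = c(500L, 500L, 500L), strand = "+",
    gene_id = c("gA", "gM", "gP"),
    transcript_id = c("gA.t", "gM.t", "gP.t"),
    biotype = c("protein_coding", "protein_coding", "processed_pseudogene")))
  cfg <- filter_config()
  jn <- data.table(
    gene5 = c("gA", "gA", "gA"), gene3 = c("gM", "gP", "gA"),
    don_chrom = "chr1", acc_chrom = c("chrM", "chr2", "chr1"))
  r <- identity_filters(jn, cfg, idx)
  expect_equal(r, c("mitochondrial", "pseudogene", NA))
  # pseudogene filter can be switched off
  r2 <- identity_filters(jn, filter_config(keep_pseudogenes = TRUE), idx)
  expect_equal(r2, c("mitochondrial", NA, NA))
})

test_that("exonic similarity filter applies inclusive 30 bp / 90% thresholds", {
  set.seed(8)
  block50 <- random_dna_str(50)
  cfg <- filter_config()
  jn <- data.table(gene5 = "simA", gene3 = "simB")
  # identical 50 bp exonic block -> discarded
  f <- similarity_fixture(block50, block50)
  expect_equal(similarity_filter(jn, cfg, f$index, f$genome), "similarity")
  # 40 bp at exactly 90% identity -> discarded (boundary inclusive)
  b40 <- substr(block50, 1, 40)
  f <- similarity_fixture(b40, substitute_block(b40, 4L))
  expect_equal(similarity_filter(jn, cfg, f$index, f$genome), "similarity")
  # 40 bp below 90% -> kept
  f <- similarity_fixture(b40, substitute_block(b40, 5L))
  expect_true(is.na(similarity_filter(jn, cfg, f$index, f$genome)))
  # 25 bp at 100% -> kept (below the length threshold)
  b25 <- substr(block50, 1, 25)
  f <- similarity_fixture(b25, b25)
  expect_true(is.na(similarity_filter(jn, cfg, f$index, f$genome)))
})

test_that("classification covers the five categories with a strict 100 kb boundary", {
  jn <- data.table(
    don_chrom = c("chr1", "chr1", "chr19", "chr1", "chr1", "chr2"),
    don_pos = c(1000L, 1000L, 5000L, 1000L, 200000L, 200000L),
    don_strand = c("+", "+", "+", "+", "+", "-"),
    acc_chrom = c("chr1", "chr1", "chr7", "chr1", "chr1", "chr2"),
    acc_pos = c(51000L, 251000L, 9000L, 2000L, 100000L, 150001L),
    acc_strand = c("+", "+", "-", "-", "+", "-"))
  cl <- classify_junctions(jn)
  expect_equal(cl$category,
               c("readthrough", "intrachromosomal", "interchromosomal",
                 "interstrand", "inverted", "readthrough"))
  expect_equal(cl$length[1:2], c(50000L, 250000L))
  expect_true(is.na(cl$length[3]))
  # exactly 100,000 bp is intrachromosomal ("closer than" is exclusive)
  b <- data.table(don_chrom = "chr1", don_pos = 1000L, don_strand = "+",
                  acc_chrom = "chr1", acc_pos = c(100999L, 101000L),
                  acc_strand = "+")
  expect_equal(classify_junctions(b)$category,
               c("readthrough", "intrachromosomal"))
})

test_that("classification depends on orientation, not segment input order", {
  # the same physical junction seen from the two read directions: donor and
  # acceptor swap AND strands flip; category must not change
  a <- data.table(don_chrom = "chr1", don_pos = 1000L, don_strand = "+",
                  acc_chrom = "chr1", acc_pos = 51000L, acc_strand = "+")
  b <- data.table(don_chrom = "chr1", don_pos = 51000L, don_strand = "-",
                  acc_chrom = "chr1", acc_pos = 1000L, acc_strand = "-")
  expect_equal(classify_junctions(a)$category, classify_junctions(b)$category)
})

test_that("apply_filters partitions candidates and lists every reason", {
  idx <- annotation_index(data.table(
    chrom = "chr1", start = c(100L, 10000L), end = c(500L, 10500L),
    strand = "+", gene_id = c("gA", "gB"),
    transcript_id = c("gA.t", "gB.t"),
    biotype = c("protein_coding", "processed_pseudogene")))
  genome <- c(chr1 = random_dna_str(11000))
  jn <- data.table(
    junction_id = c("j1", "j2"),
    don_chrom = "chr1", don_pos = 500L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 10000L, acc_strand = "+",
    gene5 = "gA", gene3 = "gB",
    ann5 = c(TRUE, TRUE), ann3 = c(TRUE, TRUE),
    nb_split = c(2L, 0L), nb_staggered = c(2L, 0L),
    nb_consistent_pe = c(1L, 0L), nb_inconsistent_pe = 0L,
    nb_total = c(3L, 0L))
  out <- apply_filters(jn, filter_config(), idx, genome)
  expect_setequal(out$filter_status, "discarded")
  # j1 fails only the pseudogene rule; j2 additionally lacks support
  expect_equal(out[junction_id == "j1", reasons], "pseudogene")
  r2 <- strsplit(out[junction_id == "j2", reasons], ",")[[1]]
  expect_true(all(c("pe_support", "split_support", "total_support",
                    "pseudogene") %in% r2))
  # keeping pseudogenes rescues j1
  out2 <- apply_filters(jn, filter_config(keep_pseudogenes = TRUE), idx, genome)
  expect_equal(out2[junction_id == "j1", filter_status], "kept")
})

test_that("output files partition candidates into kept and discarded", {
  dir <- tempfile()
  jn <- data.table(
    junction_id = paste0("j", 1:10),
    don_chrom = "chr1", don_pos = 1000L, don_strand = "+",
    acc_chrom = "chr1", acc_pos = 2000L, acc_strand = "+",
    category = "readthrough", length = 1000L,
    gene5 = "gA", gene3 = "gB",
    nb_split = 5L, nb_staggered = 4L, nb_consistent_pe = 2L,
    nb_inconsistent_pe = 0L, nb_total = 7L, tier = "annotated",
    filter_status = rep(c("kept", "discarded"), c(4L, 6L)),
    reasons = rep(c("", "mitochondrial,similarity"), c(4L, 6L)))
  paths <- write_outputs(jn, dir)
  kept <- fread(paths[1]); all_c <- fread(paths[2]); disc <- fread(paths[3])
  expect_equal(nrow(kept), 4L)
  expect_equal(nrow(all_c), 10L)
  expect_equal(nrow(disc), 6L)
  expect_length(intersect(kept$junction_id, disc$junction_id), 0L)
  expect_equal(names(kept)[1], "junction_id")
  expect_true(all(disc$reasons == "mitochondrial,similarity"))
})

test_that("raising support thresholds never enlarges the kept set", {
  set.seed(21)
  jn <- data.table(
    tier = sample(c("annotated", "novel"), 200L, TRUE),
    nb_split = sample(0:8, 200L, TRUE),
    nb_consistent_pe = sample(0:8, 200L, TRUE))
  jn[, nb_total := nb_split + nb_consistent_pe]
  pass_n <- function(cfg) sum(is.na(support_filter(jn, cfg)))
  base <- filter_config()
  knobs <- c("annotated_min_pe", "annotated_min_split", "annotated_min_total",
             "novel_min_pe", "novel_min_split", "novel_min_total")
  for (arg in knobs) {
    for (delta in 1:3) {
      params <- base[knobs]
      params[[arg]] <- params[[arg]] + delta
      # keep the config invariant: tier totals >= component minima
      params$annotated_min_total <- max(params$annotated_min_total,
                                        params$annotated_min_pe,
                                        params$annotated_min_split)
      params$novel_min_total <- max(params$novel_min_total,
                                    params$novel_min_pe,
                                    params$novel_min_split)
      stricter <- do.call(filter_config, params)
      expect_lte(pass_n(stricter), pass_n(base))
    }
  }
})
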