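# Junction filtering and reporting: two-tier support thresholds, mitochondrial/pseudogene
# removal, exonic sequence-similarity filter, five-way classification and
# the three output files.

#' Filter configuration
#'
#' Defaults implement the standard rule set: junctions with both splice
#' sites annotated need at least 1 consistent PE read, 1 split read and 3
#' total (consistent PE + split) reads; junctions involving novel splice
#' sites need at least 3, 3 and 6. Junctions touching the mitochondrial
#' chromosome or a pseudogene are removed, as are junctions whose parent
#' genes share an exonic local alignment of at least 30 bp at 90% identity
#' or more. The read-through vs intrachromosomal boundary is 100 kb
#' (strictly closer than 100,000 bp is read-through).
#'
#' @param annotated_min_pe,annotated_min_split,annotated_min_total Support
#'   minima for the annotated tier (defaults 1, 1, 3).
#' @param novel_min_pe,novel_min_split,novel_min_total Support minima for
#'   the novel tier (defaults 3, 3, 6).
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @param pseudogene_pattern Substring identifying pseudogene biotypes.
#' @param keep_pseudogenes Disable the pseudogene filter.
#' @param similarity_min_len Minimum shared alignment length in bp (30).
#' @param similarity_min_ident Minimum percent identity (90).
#' @param readthrough_max_dist Read-through distance boundary in bp (1e5).
#' @param annotated_tier_rule `"both"` (default: both sides must be
#'   annotated for the lenient tier) or `"either"`.
#' @param max_insert Maximum implied PE insert in bp (1000).
#' @param max_inconsistent_frac Optional veto: discard junctions whose
#'   inconsistent fraction of PE reads exceeds this value (default `NULL`,
#'   off).
#' @param max_hits Multimapping cap applied at ingestion (10).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(annotated_min_pe = 1L, annotated_min_split = 1L,
                          annotated_min_total = 3L,
                          novel_min_pe = 3L, novel_min_split = 3L,
                          novel_min_total = 6L,
                          mito_chroms = c("chrM", "MT"),
                          pseudogene_pattern = "pseudogene",
                          keep_pseudogenes = FALSE,
                          similarity_min_len = 30L,
                          similarity_min_ident = 90,
                          readthrough_max_dist = 100000L,
                          annotated_tier_rule = c("both", "either"),
                          max_insert = 1000L,
                          max_inconsistent_frac = NULL,
                          max_hits = 10L) {
  annotated_tier_rule <- match.arg(annotated_tier_rule)
  cfg <- list(
    annotated_min_pe = annotated_min_pe,
    annotated_min_split = annotated_min_split,
    annotated_min_total = annotated_min_total,
    novel_min_pe = novel_min_pe, novel_min_split = novel_min_split,
    novel_min_total = novel_min_total,
    mito_chroms = mito_chroms,
    pseudogene_pattern = pseudogene_pattern,
    keep_pseudogenes = keep_pseudogenes,
    similarity_min_len = similarity_min_len,
    similarity_min_ident = similarity_min_ident,
    readthrough_max_dist = readthrough_max_dist,
    annotated_tier_rule = annotated_tier_rule,
    max_insert = max_insert,
    max_inconsistent_frac = max_inconsistent_frac,
    max_hits = max_hits)
  stopifnot(all(vapply(cfg[c(1:6, 10:12, 14, 16)], function(x)
    is.numeric(x) && x >= 0, logical(1))))
  stopifnot(annotated_min_total >= max(annotated_min_pe, annotated_min_split),
            novel_min_total >= max(novel_min_pe, novel_min_split))
  structure(cfg, class = "filter_config")
}

#' Support tier of a junction
#'
#' `"annotated"` when the junction's splice sites are annotated (both sides
#' under the default rule, at least one side under `"either"`), else
#' `"novel"`.
#'
#' @param ann5,ann3 Logical vectors: is the donor / acceptor side at an
#'   annotated splice site?
#' @param rule `"both"` or `"either"`.
#' @return Character vector `"annotated"`/`"novel"`.
#' @export
tier_of <- function(ann5, ann3, rule = c("both", "either")) {
  rule <- match.arg(rule)
  ok <- if (rule == "both") ann5 & ann3 else ann5 | ann3
  fifelse(ok, "annotated", "novel")
}

#' Two-tier read-support filter
#'
#' @param junctions Junction table with nb_split, nb_consistent_pe,
#'   nb_total, tier columns.
#' @param cfg A [filter_config()].
#' @return Character vector: `NA` for pass, else the failure reason.
#' @export
support_filter <- function(junctions, cfg = filter_config()) {
  min_pe <- fifelse(junctions$tier == "annotated",
                    cfg$annotated_min_pe, cfg$novel_min_pe)
  min_split <- fifelse(junctions$tier == "annotated",
                       cfg$annotated_min_split, cfg$novel_min_split)
  min_total <- fifelse(junctions$tier == "annotated",
                       cfg$annotated_min_total, cfg$novel_min_total)
  fail_pe <- junctions$nb_consistent_pe < min_pe
  fail_split <- junctions$nb_split < min_split
  fail_total <- junctions$nb_total < min_total
  reason <- vapply(seq_len(nrow(junctions)), function(i) {
    r <- c(if (fail_pe[i]) "pe_support", if (fail_split[i]) "split_support",
           if (fail_total[i]) "total_support")
    if (length(r)) paste(r, collapse = ",") else NA_character_
  }, character(1))
  reason
}

#' Mitochondrial and pseudogene filters
#'
#' @param junctions Junction table with gene5/gene3 columns.
#' @param cfg A [filter_config()].
#' @param index An `annotation_index`.
#' @return Character vector per junction: `NA` for pass, else a
#'   comma-separated reason list (`mitochondrial`, `pseudogene`).
#' @export
identity_filters <- function(junctions, cfg, index) {
  g <- index$genes
  g5 <- g[match(junctions$gene5, gene_id)]
  g3 <- g[match(junctions$gene3, gene_id)]
  mito <- g5$chrom %in% cfg$mito_chroms | g3$chrom %in% cfg$mito_chroms |
    junctions$don_chrom %in% cfg$mito_chroms |
    junctions$acc_chrom %in% cfg$mito_chroms
  pseudo <- if (cfg$keep_pseudogenes) rep(FALSE, nrow(junctions)) else {
    grepl(cfg$pseudogene_pattern, g5$biotype, fixed = TRUE) |
      grepl(cfg$pseudogene_pattern, g3$biotype, fixed = TRUE)
  }
  out <- rep(NA_character_, nrow(junctions))
  out[mito] <- "mitochondrial"
  out[pseudo & !mito] <- "pseudogene"
  out[pseudo & mito] <- "mitochondrial,pseudogene"
  out
}

# strand-oriented exonic sequence of a gene: collapsed exons concatenated in
# transcript order (ascending on +, descending with revcomp on -)
gene_exonic_seq <- function(index, genome, gene) {
  ex <- index$uexons[gene_id == gene]
  if (!nrow(ex)) return(NULL)
  ex <- ex[order(start)]
  if (ex$strand[1L] == "-") ex <- ex[rev(seq_len(nrow(ex)))]
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    s <- fetch_seq(genome, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[i])
    if (is.null(s)) "" else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Best exonic local alignment between two genes
#'
#' Aligns the concatenated, strand-oriented exonic sequences of the two
#' genes with a local alignment (match +1, mismatch -2, gap of length k
#' costs 2 + k) and reports the alignment length in columns and the percent
#' identity (matches / aligned columns x 100).
#'
#' @param index An `annotation_index`.
#' @param genome Genome as accepted by [load_genome()].
#' @param gene_a,gene_b Gene ids.
#' @return list(len = aligned columns, ident = percent identity), or
#'   `NULL` when either sequence is unavailable.
#' @export
exonic_similarity <- function(index, genome, gene_a, gene_b) {
  genome <- load_genome(genome)
  sa <- gene_exonic_seq(index, genome, gene_a)
  sb <- gene_exonic_seq(index, genome, gene_b)
  if (is.null(sa) || is.null(sb) || !nzchar(sa) || !nzchar(sb)) return(NULL)
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- pairwiseAlignment(DNAString(sa), DNAString(sb), type = "local",
                           substitutionMatrix = mat,
                           gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (cols == 0L) return(list(len = 0L, ident = 0))
  list(len = cols, ident = 100 * nmatch(aln) / cols)
}

#' Exonic sequence-similarity filter
#'
#' Discards a junction when its parent genes share an exonic local alignment
#' of at least `similarity_min_len` bp at `similarity_min_ident` percent
#' identity or more (both boundaries inclusive). When a sequence cannot be
#' extracted the filter is skipped with a warning and the junction passes.
#'
#' @param junctions Junction table with gene5/gene3.
#' @param cfg A [filter_config()].
#' @param index An `annotation_index`.
#' @param genome Genome as accepted by [load_genome()].
#' @return Character vector: `NA` for pass, `"similarity"` for fail.
#' @export
similarity_filter <- function(junctions, cfg, index, genome) {
  genome <- load_genome(genome)
  out <- rep(NA_character_, nrow(junctions))
  if (!nrow(junctions)) return(out)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(junctions))) {
    ga <- junctions$gene5[i]; gb <- junctions$gene3[i]
    key <- paste(sort(c(ga, gb)), collapse = "|")
    if (!is.null(cache[[key]])) {
      sim <- cache[[key]]
    } else {
      sim <- exonic_similarity(index, genome, ga, gb)
      if (is.null(sim)) {
        warning("exonic sequence unavailable for ", ga, "/", gb,
                "; similarity filter skipped")
        sim <- list(len = 0L, ident = 0)
      }
      cache[[key]] <- sim
    }
    if (sim$len >= cfg$similarity_min_len &&
        sim$ident >= cfg$similarity_min_ident) {
      out[i] <- "similarity"
    }
  }
  out
}

#' Classify junctions into the five chimera categories
#'
#' * `readthrough` — same chromosome, same strand, acceptor downstream of
#'   the donor in transcription direction (expected order), closer than
#'   `readthrough_max_dist`;
#' * `intrachromosomal` — same geometry at that distance or beyond;
#' * `inverted` — same chromosome and strand, unexpected order;
#' * `interstrand` — same chromosome, different strands;
#' * `interchromosomal` — different chromosomes.
#'
#' The distance (reported as `length`) is `|acceptor - donor|` and is `NA`
#' across chromosomes.
#'
#' @param junctions Junction table with donor/acceptor site columns.
#' @param readthrough_max_dist Boundary in bp (default 100000; exactly this
#'   distance is intrachromosomal).
#' @return The table with `category` and `length` columns added.
#' @export
classify_junctions <- function(junctions, readthrough_max_dist = 100000L) {
  jn <- copy(as.data.table(junctions))
  if (!nrow(jn)) {
    jn[, `:=`(category = character(), length = integer())]
    return(jn[])
  }
  jn[, length := fifelse(don_chrom == acc_chrom,
                         abs(acc_pos - don_pos), NA_integer_)]
  expected <- with(jn, fifelse(don_strand == "+",
                               acc_pos > don_pos, acc_pos < don_pos))
  jn[, category := fcase(
    don_chrom != acc_chrom, "interchromosomal",
    don_strand != acc_strand, "interstrand",
    !expected, "inverted",
    !is.na(length) & length < readthrough_max_dist, "readthrough",
    default = "intrachromosomal")]
  jn[]
}

#' Apply the full filter set
#'
#' Evaluates every enabled filter on every junction (no short-circuiting,
#' so the discard report can list all applicable reasons), adds `tier`,
#' `category`, `length`, `filter_status` (`"kept"`/`"discarded"`) and
#' `reasons` columns.
#'
#' @param junctions Supported junctions from [attach_support()].
#' @param cfg A [filter_config()].
#' @param index An `annotation_index`.
#' @param genome Genome as accepted by [load_genome()].
#' @return The annotated, classified, filtered junction table.
#' @export
apply_filters <- function(junctions, cfg, index, genome) {
  jn <- classify_junctions(junctions, cfg$readthrough_max_dist)
  if (!nrow(jn)) {
    jn[, `:=`(tier = character(), filter_status = character(),
              reasons = character())]
    return(jn[])
  }
  jn[, tier := tier_of(ann5, ann3, cfg$annotated_tier_rule)]
  r1 <- support_filter(jn, cfg)
  r2 <- identity_filters(jn, cfg, index)
  r3 <- similarity_filter(jn, cfg, index, genome)
  r4 <- rep(NA_character_, nrow(jn))
  if (!is.null(cfg$max_inconsistent_frac)) {
    npe <- jn$nb_consistent_pe + jn$nb_inconsistent_pe
    frac <- ifelse(npe > 0, jn$nb_inconsistent_pe / npe, 0)
    r4[frac > cfg$max_inconsistent_frac] <- "inconsistent_pe"
  }
  reasons <- vapply(seq_len(nrow(jn)), function(i) {
    r <- c(r1[i], r2[i], r3[i], r4[i])
    paste(r[!is.na(r)], collapse = ",")
  }, character(1))
  jn[, reasons := reasons]
  jn[, filter_status := fifelse(reasons == "", "kept", "discarded")]
  jn[]
}

output_columns <- c(
  "junction_id", "category", "length", "gene5", "gene3",
  "nb_split", "nb_staggered", "nb_consistent_pe", "nb_inconsistent_pe",
  "nb_total", "tier", "motif", "don_chrom", "don_pos", "don_strand",
  "acc_chrom", "acc_pos", "acc_strand", "ext_don", "ext_acc",
  "filter_status", "reasons", "reads", "pe_reads", "schema_version")

#' Write the three junction report files
#'
#' Writes headered TSVs: `chimeric_junctions.tsv` (kept junctions),
#' `chimeric_junctions_candidates.tsv` (all pre-filter candidates) and
#' `chimeric_junctions_discarded.tsv` (discarded junctions with their
#' comma-separated reason list). All three share the same schema, led by
#' the junction ID column, plus a `schema_version` column.
#'
#' @param junctions Filtered junction table from [apply_filters()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(junctions, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  jn <- copy(as.data.table(junctions))
  jn[, schema_version := "1"]
  for (col in setdiff(output_columns, names(jn))) jn[, (col) := NA]
  jn <- jn[, output_columns, with = FALSE]
  paths <- file.path(out_dir, c("chimeric_junctions.tsv",
                                "chimeric_junctions_candidates.tsv",
                                "chimeric_junctions_discarded.tsv"))
  tryCatch({
    fwrite(jn[filter_status == "kept"], paths[1L], sep = "\t")
    fwrite(jn, paths[2L], sep = "\t")
    fwrite(jn[filter_status == "discarded"], paths[3L], sep = "\t")
  }, error = function(e) stop("cannot write outputs under ", out_dir, ": ",
                              conditionMessage(e)))
  invisible(paths)
}
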