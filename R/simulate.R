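# Chimera simulator: builds chimeric transcripts of the five classes from a
# genome + annotation, samples co-expressed background transcripts, emits
# non-directional paired-end reads and projects them back to genomic truth
# alignments so the detector can be exercised without an external mapper.

chimera_classes <- c("readthrough", "intrachromosomal", "inverted",
                     "interstrand", "interchromosomal")

#' Simulation configuration
#'
#' Defaults mirror the standard simulated benchmark conditions: 50 chimeric
#' transcripts per class and 60% of annotation transcripts as co-expressed
#' background, with the parent transcripts of every chimera forcibly
#' included. Reads are non-directional paired-end with constant high base
#' quality; the base error rate defaults to 0.
#'
#' @param n_readthrough,n_intrachromosomal,n_inverted,n_interstrand,n_interchromosomal
#'   Chimeric transcripts to create per class (default 50 each).
#' @param bg_fraction Fraction of annotation transcripts sampled as
#'   background (default 0.6).
#' @param read_len Read length in bp (default 75).
#' @param insert_mean,insert_sd Fragment (insert) size mean and sd in bp
#'   (defaults 250 and 50); fragments are clamped to
#'   `[read_len, transcript length]`.
#' @param coverage Per-transcript read coverage (default 10).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Random seed fixing all sampling (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_readthrough = 50L, n_intrachromosomal = 50L,
                       n_inverted = 50L, n_interstrand = 50L,
                       n_interchromosomal = 50L, bg_fraction = 0.6,
                       read_len = 75L, insert_mean = 250, insert_sd = 50,
                       coverage = 10, error_rate = 0, seed = 1L) {
  counts <- c(readthrough = n_readthrough,
              intrachromosomal = n_intrachromosomal,
              inverted = n_inverted, interstrand = n_interstrand,
              interchromosomal = n_interchromosomal)
  stopifnot(all(counts >= 0), bg_fraction >= 0, bg_fraction <= 1,
            read_len > 0, coverage >= 0, error_rate >= 0, error_rate <= 1)
  structure(list(counts = counts, bg_fraction = bg_fraction,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# transcript model: exon blocks in transcript order with transcript-space
# coordinates, plus the spliced sequence
build_model <- function(blocks, genome, id, gene_id = NA_character_) {
  w <- blocks$end - blocks$start + 1L
  tend <- cumsum(w)
  blocks <- copy(blocks)
  blocks[, `:=`(tstart = tend - w + 1L, tend = tend)]
  seq <- paste(vapply(seq_len(nrow(blocks)), function(i) {
    fetch_seq(genome, blocks$chrom[i], blocks$start[i], blocks$end[i],
              blocks$strand[i])
  }, character(1)), collapse = "")
  list(id = id, gene_id = gene_id, blocks = blocks, seq = seq,
       len = nchar(seq))
}

# annotation transcript -> model (exons in transcript order)
transcript_model <- function(index, genome, tx) {
  ex <- index$exons[transcript_id == tx][order(start)]
  if (!nrow(ex)) stop("unknown transcript: ", tx)
  if (ex$strand[1L] == "-") ex <- ex[rev(seq_len(nrow(ex)))]
  build_model(ex[, .(chrom, start, end, strand)], genome, tx, ex$gene_id[1L])
}

# gene-level candidate pair pool for one chimera class, using gene spans
class_pair_pool <- function(genes, class_label, readthrough_max_dist = 100000L) {
  g <- copy(genes)
  pairs <- CJ(a = g$gene_id, b = g$gene_id)[a != b]
  pairs <- merge(pairs, g[, .(a = gene_id, chrom_a = chrom, strand_a = strand,
                              start_a = start, end_a = end)], by = "a")
  pairs <- merge(pairs, g[, .(b = gene_id, chrom_b = chrom, strand_b = strand,
                              start_b = start, end_b = end)], by = "b")
  same_chrom <- pairs$chrom_a == pairs$chrom_b
  same_strand <- pairs$strand_a == pairs$strand_b
  # "a upstream of b" in transcription direction of the shared strand
  a_before_b <- fifelse(pairs$strand_a == "+",
                        pairs$end_a < pairs$start_b,
                        pairs$start_a > pairs$end_b)
  outer_span <- pmax(pairs$end_a, pairs$end_b) -
    pmin(pairs$start_a, pairs$start_b)
  inner_gap <- pmax(pairs$start_a, pairs$start_b) -
    pmin(pairs$end_a, pairs$end_b)
  switch(class_label,
    readthrough = pairs[same_chrom & same_strand & a_before_b &
                          outer_span < readthrough_max_dist],
    intrachromosomal = pairs[same_chrom & same_strand & a_before_b &
                               inner_gap >= readthrough_max_dist],
    inverted = pairs[same_chrom & same_strand & !a_before_b &
                       (pairs$end_a < pairs$start_b | pairs$end_b < pairs$start_a)],
    interstrand = pairs[same_chrom & !same_strand &
                          (pairs$end_a < pairs$start_b | pairs$end_b < pairs$start_a)],
    interchromosomal = pairs[!same_chrom],
    stop("unknown chimera class: ", class_label))
}

#' Simulate chimeric transcripts
#'
#' For each class, samples parent gene pairs whose geometry admits the
#' class, joins a uniformly-sampled annotated internal exon end (donor) of
#' the 5' gene to an annotated internal exon start (acceptor) of the 3'
#' gene, and emits the chimeric sequence (full 5' part through the donor +
#' full 3' part from the acceptor) with its truth junction. Every emitted
#' junction re-classifies to its own class and junctions are unique.
#' Sampling is deterministic under the caller's RNG state (see
#' [simulate_dataset()] for the seeded entry point).
#'
#' @param index An `annotation_index`.
#' @param genome Genome as accepted by [load_genome()].
#' @param cfg A [sim_config()].
#' @return list with `models` (list of chimeric transcript models) and
#'   `truth` (data.table: chim_id, class, gene5, gene3, tx5, tx3, donor and
#'   acceptor site columns).
#' @export
simulate_chimeras <- function(index, genome, cfg = sim_config()) {
  genome <- load_genome(genome)
  truth <- list()
  models <- list()
  used <- character()
  for (cl in chimera_classes) {
    n <- cfg$counts[[cl]]
    if (n == 0L) next
    pool <- class_pair_pool(index$genes, cl)
    # both roles need internal splice sites
    pool <- pool[a %in% index$donors$gene_id & b %in% index$acceptors$gene_id]
    if (!nrow(pool)) {
      stop("no candidate gene pairs for chimera class '", cl,
           "' (pool size 0)")
    }
    made <- 0L
    attempts <- 0L
    max_attempts <- 1000L * n
    while (made < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not assemble ", n, " '", cl, "' chimeras after ",
             max_attempts, " attempts (pool size ", nrow(pool), ")")
      }
      pr <- pool[sample(.N, 1L)]
      dn <- index$donors[gene_id == pr$a][sample(.N, 1L)]
      ac <- index$acceptors[gene_id == pr$b][sample(.N, 1L)]
      jid <- junction_id(dn$chrom, dn$pos, dn$strand,
                         ac$chrom, ac$pos, ac$strand)
      if (jid %in% used) next
      got <- classify_junctions(data.table(
        don_chrom = dn$chrom, don_pos = dn$pos, don_strand = dn$strand,
        acc_chrom = ac$chrom, acc_pos = ac$pos, acc_strand = ac$strand))
      if (got$category != cl) next

      mod5 <- transcript_model(index, genome, dn$transcript_id)
      mod3 <- transcript_model(index, genome, ac$transcript_id)
      k <- which(seg_t_end(mod5$blocks$start, mod5$blocks$end,
                           mod5$blocks$strand) == dn$pos)
      j <- which(seg_t_start(mod3$blocks$start, mod3$blocks$end,
                             mod3$blocks$strand) == ac$pos)
      if (length(k) != 1L || length(j) != 1L) next
      if (k == nrow(mod5$blocks) || j == 1L) next  # sites must be internal
      blocks <- rbind(
        mod5$blocks[seq_len(k), .(chrom, start, end, strand)],
        mod3$blocks[j:nrow(mod3$blocks), .(chrom, start, end, strand)])
      made <- made + 1L
      used <- c(used, jid)
      chim_id <- sprintf("chimera_%s_%03d", cl, made)
      models[[chim_id]] <- build_model(blocks, genome, chim_id)
      truth[[length(truth) + 1L]] <- data.table(
        chim_id = chim_id, class = cl, gene5 = pr$a, gene3 = pr$b,
        tx5 = dn$transcript_id, tx3 = ac$transcript_id,
        don_chrom = dn$chrom, don_pos = dn$pos, don_strand = dn$strand,
        acc_chrom = ac$chrom, acc_pos = ac$pos, acc_strand = ac$strand)
    }
  }
  truth <- if (length(truth)) rbindlist(truth) else data.table(
    chim_id = character(), class = character(), gene5 = character(),
    gene3 = character(), tx5 = character(), tx3 = character(),
    don_chrom = character(), don_pos = integer(), don_strand = character(),
    acc_chrom = character(), acc_pos = integer(), acc_strand = character())
  list(models = models, truth = truth)
}

#' Sample background transcripts
#'
#' Uniform sample of `bg_fraction` of all annotation transcripts, with the
#' chimera parent transcripts forcibly included (union, no duplicates).
#'
#' @param index An `annotation_index`.
#' @param cfg A [sim_config()].
#' @param parent_tx Parent transcript ids of the simulated chimeras.
#' @return Character vector of transcript ids, sorted.
#' @export
sample_background <- function(index, cfg, parent_tx = character()) {
  all_tx <- sort(unique(index$exons$transcript_id))
  n <- round(cfg$bg_fraction * length(all_tx))
  samp <- if (n > 0L) sample(all_tx, n) else character()
  sort(union(samp, parent_tx))
}

# uniform substitution errors at the configured per-base rate
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    v <- strsplit(s, "")[[1L]]
    for (i in hit) {
      v[i] <- sample(setdiff(bases, v[i]), 1L)
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate non-directional paired-end reads
#'
#' Per transcript, `round(coverage x length / (2 x read_len))` fragments are
#' drawn with normal(insert_mean, insert_sd) lengths clamped to
#' `[read_len, transcript length]` and uniform start positions; the two
#' mates are the fragment ends (the downstream one reverse-complemented),
#' assigned to mate 1 / mate 2 in random order (non-directional protocol).
#' Uniform substitution errors are applied at `error_rate`. Transcripts
#' shorter than the read length are skipped with a warning.
#'
#' @param models List of transcript models (see [simulate_dataset()]).
#' @param cfg A [sim_config()].
#' @return data.table: read_id, tx_id, frag_start, frag_end, swap (mate 1
#'   is the downstream fragment end), seq1, seq2.
#' @export
generate_reads <- function(models, cfg) {
  rl <- cfg$read_len
  out <- list()
  for (id in names(models)) {
    m <- models[[id]]
    if (m$len < rl) {
      warning("transcript ", id, " (", m$len, " bp) shorter than read length; skipped")
      next
    }
    n <- round(cfg$coverage * m$len / (2 * rl))
    if (n <= 0L) next
    fl <- as.integer(pmin(pmax(round(rnorm(n, cfg$insert_mean, cfg$insert_sd)),
                               rl), m$len))
    fs <- as.integer(floor(runif(n) * (m$len - fl + 1L)) + 1L)
    fe <- fs + fl - 1L
    fwd <- substring(m$seq, fs, fs + rl - 1L)
    rev <- revcomp(substring(m$seq, fe - rl + 1L, fe))
    swap <- runif(n) < 0.5
    out[[id]] <- data.table(
      read_id = sprintf("%s_p%04d", id, seq_len(n)),
      tx_id = id, frag_start = fs, frag_end = fe, swap = swap,
      seq1 = fifelse(swap, rev, fwd), seq2 = fifelse(swap, fwd, rev))
  }
  reads <- if (length(out)) rbindlist(out) else data.table(
    read_id = character(), tx_id = character(), frag_start = integer(),
    frag_end = integer(), swap = logical(), seq1 = character(),
    seq2 = character())
  if (nrow(reads) && cfg$error_rate > 0) {
    reads[, `:=`(seq1 = apply_errors(seq1, cfg$error_rate),
                 seq2 = apply_errors(seq2, cfg$error_rate))]
  }
  reads[]
}

# project a transcript interval [s, e] through the exon blocks into genomic
# portions, one per overlapped block, in transcript order
project_interval <- function(blocks, s, e) {
  hit <- blocks[tend >= s & tstart <= e]
  hit[, `:=`(ps = pmax(tstart, s), pe = pmin(tend, e))]
  hit[, `:=`(
    gstart = fifelse(strand == "+", start + (ps - tstart), end - (pe - tstart)),
    gend = fifelse(strand == "+", start + (pe - tstart), end - (ps - tstart)))]
  hit[, .(chrom, strand, ps, pe, gstart, gend)]
}

# group projected portions into alignment pieces: consecutive portions on
# the same chromosome and strand, colinear in genomic space
group_pieces <- function(portions) {
  n <- nrow(portions)
  grp <- integer(n)
  g <- 1L
  grp[1L] <- 1L
  for (i in seq_len(n - 1L)) {
    p <- portions[i]; q <- portions[i + 1L]
    colinear <- p$chrom == q$chrom && p$strand == q$strand &&
      ((p$strand == "+" && q$gstart > p$gend) ||
         (p$strand == "-" && q$gend < p$gstart))
    if (!colinear) g <- g + 1L
    grp[i + 1L] <- g
  }
  split(portions, grp)
}

# CIGAR (M/N) plus POS for one piece; sub-blocks in ascending genomic order
piece_cigar <- function(piece) {
  pb <- piece[order(gstart)]
  ops <- character()
  for (i in seq_len(nrow(pb))) {
    if (i > 1L) {
      gap <- pb$gstart[i] - pb$gend[i - 1L] - 1L
      ops <- c(ops, paste0(gap, "N"))
    }
    ops <- c(ops, paste0(pb$gend[i] - pb$gstart[i] + 1L, "M"))
  }
  list(pos = pb$gstart[1L], cigar = paste(ops, collapse = ""),
       chrom = pb$chrom[1L])
}

#' Project simulated reads to genomic truth alignments (SAM)
#'
#' Each mate is mapped through its transcript's exon structure to genomic
#' coordinates: colinear same-chromosome, same-strand stretches become
#' `N`-gapped CIGARs; junctions joining different chromosomes, strands or
#' inverted order are emitted as a primary + supplementary record pair with
#' mutual `SA` tags and soft-clips. Mate pairing flags and `NH:i:1` are set.
#' Reads that would need more than two pieces are skipped with a count.
#'
#' @param models Transcript models (chimeric and background).
#' @param reads Read table from [generate_reads()].
#' @param genome Genome (for `@SQ` header lines).
#' @param path Output SAM path.
#' @return Invisibly, list(path, n_skipped).
#' @export
generate_truth_alignments <- function(models, reads, genome, path) {
  genome <- load_genome(genome)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(genome), "\tLN:",
                     BiocGenerics::width(genome)))
  lines <- vector("list", nrow(reads))
  n_skipped <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i]
    m <- models[[r$tx_id]]
    rl <- nchar(r$seq1)
    # transcript intervals and orientations of the two mates
    up <- c(r$frag_start, r$frag_start + rl - 1L)
    dn <- c(r$frag_end - rl + 1L, r$frag_end)
    if (!r$swap) {
      iv1 <- up; o1 <- "+"; iv2 <- dn; o2 <- "-"
    } else {
      iv1 <- dn; o1 <- "-"; iv2 <- up; o2 <- "+"
    }
    mk <- function(iv, o) {
      portions <- project_interval(m$blocks, iv[1L], iv[2L])
      pieces <- group_pieces(portions)
      lapply(pieces, function(p) {
        pc <- piece_cigar(p)
        mstrand <- if (o == "+") p$strand[1L] else flip_strand(p$strand[1L])
        # read-local range in original-read orientation
        rr <- if (o == "+") c(min(p$ps) - iv[1L] + 1L, max(p$pe) - iv[1L] + 1L)
              else c(iv[2L] - max(p$pe) + 1L, iv[2L] - min(p$ps) + 1L)
        c(pc, list(mstrand = mstrand, rs = rr[1L], re = rr[2L]))
      })
    }
    p1 <- mk(iv1, o1)
    p2 <- mk(iv2, o2)
    if (length(p1) > 2L || length(p2) > 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    recs <- list()
    mate_recs <- function(pieces, seq, mate_flag, other) {
      # order pieces by read-local start: first is the primary
      ord <- order(vapply(pieces, function(p) p$rs, numeric(1)))
      pieces <- pieces[ord]
      prim_other <- other[[which.min(vapply(other, function(p) p$rs, numeric(1)))]]
      out <- list()
      for (pi in seq_along(pieces)) {
        p <- pieces[[pi]]
        supp <- pi > 1L
        flag <- 1L + 2L + mate_flag +
          (if (p$mstrand == "-") 16L else 0L) +
          (if (prim_other$mstrand == "-") 32L else 0L) +
          (if (supp) 2048L else 0L)
        sq <- if (p$mstrand == "+") seq else revcomp(seq)
        lclip <- if (p$mstrand == "+") p$rs - 1L else nchar(seq) - p$re
        rclip <- if (p$mstrand == "+") nchar(seq) - p$re else p$rs - 1L
        cig <- paste0(if (lclip > 0L) paste0(lclip, "S"), p$cigar,
                      if (rclip > 0L) paste0(rclip, "S"))
        rnext <- if (prim_other$chrom == p$chrom) "=" else prim_other$chrom
        tags <- "NH:i:1"
        if (length(pieces) == 2L) {
          q <- pieces[[3L - pi]]
          qlclip <- if (q$mstrand == "+") q$rs - 1L else nchar(seq) - q$re
          qrclip <- if (q$mstrand == "+") nchar(seq) - q$re else q$rs - 1L
          qcig <- paste0(if (qlclip > 0L) paste0(qlclip, "S"), q$cigar,
                         if (qrclip > 0L) paste0(qrclip, "S"))
          tags <- paste0(tags, "\tSA:Z:", q$chrom, ",", q$pos, ",",
                         q$mstrand, ",", qcig, ",60,0;")
        }
        out[[pi]] <- paste(r$read_id, flag, p$chrom, p$pos, 60L, cig,
                           rnext, prim_other$pos, 0L, sq,
                           strrep("I", nchar(sq)), tags, sep = "\t")
      }
      out
    }
    recs <- c(mate_recs(p1, r$seq1, 64L, p2), mate_recs(p2, r$seq2, 128L, p1))
    lines[[i]] <- unlist(recs)
  }
  keep <- !vapply(lines, is.null, logical(1))
  writeLines(c(header, unlist(lines[keep])), path)
  invisible(list(path = path, n_skipped = n_skipped))
}

#' Run the full simulation and write all outputs
#'
#' Seeds the RNG from the configuration, simulates the chimeric
#' transcripts, samples background transcripts (parents forced in),
#' generates paired reads and truth alignments, and writes:
#' `transcripts.fa`, `truth_junctions.tsv`, `truth_reads.tsv`,
#' `reads_1.fastq`, `reads_2.fastq` and `alignments.sam`. Identical
#' configurations produce byte-identical outputs.
#'
#' @param genome Genome as accepted by [load_genome()].
#' @param index An `annotation_index`.
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the truth table, models, reads and file
#'   paths.
#' @export
simulate_dataset <- function(genome, index, cfg = sim_config(), out_dir) {
  genome <- load_genome(genome)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)

  sim <- simulate_chimeras(index, genome, cfg)
  parents <- unique(c(sim$truth$tx5, sim$truth$tx3))
  bg_tx <- sample_background(index, cfg, parents)
  bg_models <- lapply(bg_tx, function(tx) transcript_model(index, genome, tx))
  names(bg_models) <- bg_tx
  models <- c(sim$models, bg_models)
  models <- models[order(names(models))]

  reads <- generate_reads(models, cfg)

  paths <- list(
    transcripts = file.path(out_dir, "transcripts.fa"),
    truth_junctions = file.path(out_dir, "truth_junctions.tsv"),
    truth_reads = file.path(out_dir, "truth_reads.tsv"),
    fastq1 = file.path(out_dir, "reads_1.fastq"),
    fastq2 = file.path(out_dir, "reads_2.fastq"),
    sam = file.path(out_dir, "alignments.sam"))

  txseq <- DNAStringSet(vapply(models, `[[`, character(1), "seq"))
  names(txseq) <- names(models)
  writeXStringSet(txseq, paths$transcripts)
  fwrite(sim$truth, paths$truth_junctions, sep = "\t")
  fwrite(reads[, .(read_id, tx_id, frag_start, frag_end, swap)],
         paths$truth_reads, sep = "\t")
  writeLines(as.vector(rbind(paste0("@", reads$read_id, "/1"), reads$seq1,
                             "+", strrep("I", nchar(reads$seq1)))),
             paths$fastq1)
  writeLines(as.vector(rbind(paste0("@", reads$read_id, "/2"), reads$seq2,
                             "+", strrep("I", nchar(reads$seq2)))),
             paths$fastq2)
  aln <- generate_truth_alignments(models, reads, genome, paths$sam)

  invisible(list(truth = sim$truth, models = models, reads = reads,
                 background = bg_tx, paths = paths,
                 n_alignment_skipped = aln$n_skipped))
}
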