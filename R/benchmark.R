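# Benchmark module: scores a predicted chimera set against a reference at
# the gene-pair and junction level. A junction true positive requires exact
# equality of all six coordinates (donor chrom/pos/strand, acceptor
# chrom/pos/strand); the junction distance is the sum of the per-side
# absolute coordinate differences.

new_eval_result <- function(level, tp, fp, fn) {
  sn <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  pr <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  structure(list(level = level, tp = tp, fp = fp, fn = fn,
                 sn = sn, pr = pr, f1 = f1_score(sn, pr)),
            class = "chim_eval")
}

#' @export
print.chim_eval <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("chimera evaluation (%s level): TP=%d FP=%d FN=%d\n",
              x$level, x$tp, x$fp, x$fn))
  cat(sprintf("  Sn=%s Pr=%s F1=%s\n", fmt(x$sn), fmt(x$pr), fmt(x$f1)))
  invisible(x)
}

#' Evaluate predictions at the gene-pair level
#'
#' Compares the deduplicated sets of (gene5, gene3) pairs. Ordered (5'->3')
#' comparison by default; `ordered = FALSE` compares unordered pairs, for
#' callers that do not orient their junctions.
#'
#' @param reference,predictions Tables with gene5 and gene3 columns.
#' @param ordered Compare pairs respecting 5'/3' orientation (default TRUE).
#' @return A `chim_eval` with tp, fp, fn, sn, pr, f1 (0/0 ratios are `NA`).
#' @export
eval_gene_pairs <- function(reference, predictions, ordered = TRUE) {
  key <- function(x) {
    x <- as.data.table(x)
    if (!nrow(x)) return(character())
    if (ordered) unique(paste(x$gene5, x$gene3, sep = "|"))
    else unique(paste(pmin(x$gene5, x$gene3), pmax(x$gene5, x$gene3),
                      sep = "|"))
  }
  r <- key(reference); p <- key(predictions)
  new_eval_result("gene_pair", length(intersect(r, p)),
                  length(setdiff(p, r)), length(setdiff(r, p)))
}

#' Evaluate predictions at the junction level
#'
#' A predicted junction is a true positive only when all six coordinates
#' (donor chrom, pos, strand; acceptor chrom, pos, strand) exactly equal a
#' reference junction's. Isoforms of one gene pair count independently.
#'
#' @param reference,predictions Tables with don_chrom, don_pos, don_strand,
#'   acc_chrom, acc_pos, acc_strand columns.
#' @return A `chim_eval`.
#' @export
eval_junctions <- function(reference, predictions) {
  key <- function(x) {
    x <- as.data.table(x)
    if (!nrow(x)) return(character())
    unique(junction_id(x$don_chrom, x$don_pos, x$don_strand,
                       x$acc_chrom, x$acc_pos, x$acc_strand))
  }
  r <- key(reference); p <- key(predictions)
  new_eval_result("junction", length(intersect(r, p)),
                  length(setdiff(p, r)), length(setdiff(r, p)))
}

#' Distance between two junctions
#'
#' Sum of the distance between the donor (upstream/5') splice sites and the
#' distance between the acceptor (downstream/3') splice sites. A side on
#' different chromosomes has infinite distance. The raw distance is
#' returned; any pseudocount for log-scale plotting is the caller's
#' business.
#'
#' @param a,b Junctions (lists or single-row tables with the six site
#'   columns).
#' @return list(donor = bp, acceptor = bp, total = bp).
#' @export
junction_distance <- function(a, b) {
  side <- function(ca, pa, cb, pb) {
    if (ca != cb) Inf else abs(pa - pb)
  }
  d <- side(a$don_chrom, a$don_pos, b$don_chrom, b$don_pos)
  ac <- side(a$acc_chrom, a$acc_pos, b$acc_chrom, b$acc_pos)
  list(donor = d, acceptor = ac, total = d + ac)
}

#' Remove read-through events from a prediction set
#'
#' Drops junctions on the same chromosome and strand, in expected genomic
#' order, with a donor-acceptor distance smaller than `max_dist` — the
#' standard preprocessing when comparing against fusion-gene-only
#' references.
#'
#' @param predictions Junction table with the six site columns.
#' @param max_dist Distance boundary in bp (default 100000).
#' @return The filtered table.
#' @export
strip_readthrough <- function(predictions, max_dist = 100000L) {
  p <- as.data.table(predictions)
  if (!nrow(p)) return(p)
  cl <- classify_junctions(p[, .(don_chrom, don_pos, don_strand,
                                 acc_chrom, acc_pos, acc_strand)],
                           readthrough_max_dist = max_dist)
  p[cl$category != "readthrough"]
}
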