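#' Detect chimeric junctions from aligned paired-end RNA-seq
#'
#' Runs the full post-mapping pipeline: alignment ingestion (split reads and
#' mate pairs, multimapping cap), split-read orientation by splice-motif
#' consensus, junction clustering and annotation, selection of junctions
#' connecting two different genes, discordant paired-end evidence split into
#' consistent/inconsistent support, filtering and five-way classification.
#'
#' @param alignments SAM/BAM path or a pre-ingested list from
#'   [ingest_alignments()].
#' @param genome Genome FASTA path or `DNAStringSet`.
#' @param annotation GTF path or an `annotation_index`.
#' @param cfg A [filter_config()].
#' @param stranded Library strandedness (default `FALSE`; see
#'   [orient_splits()]).
#' @param both_strands Annotate junction sides against exons of both strands
#'   (default `FALSE`: use the oriented strand).
#' @param out_dir If non-`NULL`, the three report files are written there
#'   with [write_outputs()].
#' @return list with `kept`, `candidates` (all pre-filter, with filter
#'   status), `discarded` junction tables, and a `report` list of counts
#'   (ingestion skips, orientation rejections, non-chimeric junctions).
#' @export
detect_chimeras <- function(alignments, genome, annotation,
                            cfg = filter_config(), stranded = FALSE,
                            both_strands = FALSE, out_dir = NULL) {
  genome <- load_genome(genome)
  index <- if (inherits(annotation, "annotation_index")) annotation
           else read_gtf(annotation)
  ingested <- if (is.list(alignments) && !is.null(alignments$splits)) alignments
              else ingest_alignments(alignments, max_hits = cfg$max_hits)

  ori <- orient_splits(ingested$splits, genome, stranded = stranded)
  clusters <- cluster_splits(ori$oriented)
  annotated <- annotate_junctions(clusters, index, both_strands = both_strands)
  candidates <- select_chimeric(annotated)
  dropped <- attr(candidates, "dropped")

  discordant <- find_discordant(ingested, index)
  supported <- attach_support(candidates, discordant, ingested, index,
                              max_insert = cfg$max_insert)
  filtered <- apply_filters(supported, cfg, index, genome)

  if (!is.null(out_dir)) write_outputs(filtered, out_dir)

  list(
    kept = filtered[filter_status == "kept"],
    candidates = filtered,
    discarded = filtered[filter_status == "discarded"],
    report = list(
      n_records_skipped = ingested$skipped,
      n_split_reads = nrow(ingested$splits),
      n_oriented = nrow(ori$oriented),
      orientation_rejections = if (nrow(ori$rejected))
        table(ori$rejected$reason) else table(character()),
      n_junction_clusters = nrow(clusters),
      n_non_chimeric = dropped,
      n_discordant_pairs = nrow(discordant),
      n_candidates = nrow(filtered),
      n_kept = sum(filtered$filter_status == "kept")
    )
  )
}
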