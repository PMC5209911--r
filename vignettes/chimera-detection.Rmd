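---
title: "Detecting chimeric RNA junctions: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chimeric RNA junctions: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeradetect)
library(data.table)
```

# The detection model

A chimeric transcript joins exonic sequence from two different genes. In
paired-end RNA-seq it leaves two complementary footprints:

* **split reads** crossing the chimeric junction, whose two segments map
  to the two parent loci and pin the junction to the base pair, and
* **discordant mate pairs**, whose mates map to the two parent genes and
  corroborate a junction without localising it.

`chimeradetect` treats the two streams independently: junctions are
*defined* by split reads (the more precise but more error-prone signal)
and *corroborated* by mate pairs (less precise, but largely independent of
the alignment artefacts that create spurious splits). A junction must in
the end be supported by both. The package starts from existing alignments;
read mapping itself is out of scope, though spliced `N`-gap alignments in
the input let intra-chromosomal chimeras be detected from any standard
spliced aligner's output, and `SA`-tagged chimeric alignments cover the
inter-chromosomal, inter-strand and inverted cases.

## Orientation by splice-motif consensus

The biological junction is directional: a donor (5') site is spliced to an
acceptor (3') site. A split read from an unstranded library could a priori
represent either direction, so both are checked against the extended
splice-site consensus classes `GT+AG`, `GC+AG`, `ATATC+A.` and `GTATC+AT`
(donor motif immediately intron-ward of the donor site, acceptor motif
immediately intron-ward of the acceptor site, `.` = any base). Exactly one
direction must match:

* neither matches → the read is rejected (`no_consensus`);
* both match → the read is rejected as `ambiguous`. This is the
  conservative resolution of a case the consensus rule itself cannot
  decide; with real intron boundaries the reverse direction would have to
  show a reverse-complement motif by chance, so losses are rare.
* a flank falling off a chromosome end is rejected as `edge`.

For stranded libraries (`stranded = TRUE`) the read's own orientation is
taken as the transcript orientation and the motif check merely validates
it. After orientation every junction side has a definite strand, which is
why downstream exon overlap is strand-matched by default even for
unstranded data (`both_strands = TRUE` relaxes this).

## Clustering, annotation and candidate selection

Oriented reads sharing the exact (donor, acceptor) coordinate pair form
one cluster. Two support statistics are kept: `nb_split`, the raw member
count, and `nb_staggered`, the number of distinct (donor-side outer
coordinate, acceptor-side outer coordinate) pairs. Staggering is counted
on coordinate *pairs*, not single sides: the ladder pattern characteristic
of genuine junctions is two-dimensional, and pairing makes the statistic
strictly harder to inflate with PCR duplicates.

Each side's span (junction position to the cluster's most distal member
coordinate) is compared with annotated exons; the parent gene is the one
with the largest summed exonic overlap. Ties are broken deterministically:
`protein_coding` biotype first, then the lexicographically smallest gene
id. Junctions whose two sides land in two different genes are the chimeric
candidates; same-gene junctions are ordinary splicing, and junctions with
an unassigned side are dropped but counted in the run report — keeping
them would leave the tier rule and the parent-gene filters undefined.

## Paired-end consistency

A discordant pair matches a junction when its two mates' genes equal the
junction's parent genes (either mate order). It is *consistent* when,
laying the implied chimeric transcript 5'→3':

* the mate in the 5' gene lies upstream of (or abuts) the donor, on the
  donor strand;
* the mate in the 3' gene lies downstream of (or abuts) the acceptor, on
  the strand opposite the acceptor strand (the two mates face inward);
* the implied insert does not exceed `max_insert` (default 1000 bp).

The insert is measured in *exonic space*: the summed overlap of the parent
gene's collapsed exons with the interval between the mate's far end and
the junction side. A genomic distance would spuriously fail mates
separated from the junction by a long intron; the exonic measure is the
closest annotation-informed proxy for the fragment length a sequencer
actually saw. Inconsistent pairs are counted and reported but do not veto
a junction by default, because they have benign explanations (another
isoform of the same gene pair, or mate misalignment); a
`max_inconsistent_frac` veto can be enabled. A pair may support several
isoform junctions of one gene pair and is counted for each.

## Filtering and classification

Support thresholds are two-tiered (`filter_config()` defaults):

| tier | consistent PE | split | total (PE + split) |
|---|---|---|---|
| annotated splice sites | ≥ 1 | ≥ 1 | ≥ 3 |
| novel splice sites | ≥ 3 | ≥ 3 | ≥ 6 |

A junction is in the annotated tier only when **both** sides coincide with
annotated splice sites (positional, stranded membership: donors with
donors, acceptors with acceptors). Requiring both sides is the strict
reading of "involves annotated splice sites" and the default; the
`annotated_tier_rule = "either"` switch implements the lenient reading.

Junctions touching the mitochondrial chromosome (`chrM`/`MT`,
configurable) or a gene whose biotype contains `pseudogene` are discarded
as probable mapping artefacts. Finally, if the two parent genes share an
exonic local alignment of at least 30 bp at ≥ 90% identity (both
boundaries inclusive), the junction is discarded, since reads are prone to
misalign between such paralogous sequences. The local alignment scores
match +1, mismatch −2, and a gap of length *k* costs 2 + *k* (affine −3
open, −1 extend in the usual notation); identity is matches over aligned
columns. The thresholds are the filter's contract; the scoring scheme
itself is a fixed implementation choice, picked as a standard scheme and
frozen for reproducibility. Each gene's exonic sequence is its collapsed
exons concatenated in transcript orientation; a single local alignment of
the concatenations is used rather than all exon-versus-exon pairs, which
is faster and can only make the filter stricter (alignments may bridge
adjacent exons).

All filters are evaluated on every junction — no short-circuiting — so the
discard report lists every applicable reason.

Categories are a total function of the oriented sites: different
chromosomes → `interchromosomal`; same chromosome, different strands →
`interstrand`; same strand but acceptor upstream of the donor in
transcription direction → `inverted`; otherwise `readthrough` when
|acceptor − donor| is strictly less than 100 kb and `intrachromosomal`
from 100,000 bp on ("closer than 100 kb" is read as exclusive, so the
boundary value itself is intrachromosomal).

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_hits` | 10 | mapping positions | pairs reported at more positions are treated as unmapped; removes repeat-driven evidence |
| `max_insert` | 1000 | bp (exonic space) | upper bound on the implied fragment; rules out pairs flanking a different, distant isoform |
| tier minima | 1/1/3 and 3/3/6 | reads | see table above; novel sites need stronger evidence |
| `similarity_min_len` / `similarity_min_ident` | 30 bp / 90% | — | paralog-homology filter boundaries, inclusive |
| `readthrough_max_dist` | 100,000 | bp | read-through vs intrachromosomal category boundary, exclusive |
| `mito_chroms` | chrM, MT | — | mitochondrial junction removal |
| `pseudogene_pattern` | "pseudogene" | substring | biotype rule for pseudogene removal |

# The simulator

`simulate_dataset()` emulates the conditions under which such detectors
are normally assessed: a configurable number of chimeric transcripts per
class (default 50 per class, 250 in total), built by joining an annotated
internal exon end of a 5' parent gene to an annotated internal exon start
of a 3' parent gene, on a background of 60% of the annotation's
transcripts (uniformly sampled) plus the chimeras' parent transcripts —
reflecting that an expressed chimera usually comes with expressed parents.
Defaults for the read layer are fixture-scale choices: 75 bp
non-directional paired-end reads, fragment length normal(250, 50) clamped
to `[read_len, transcript length]`, 10× per-transcript coverage
(`round(coverage × length / (2 × read_len))` pairs), constant high base
quality, and error rate 0.

Design choices made where the construction was genuinely open:

* **Junction placement** — the donor is drawn uniformly among the 5'
  gene's annotated internal exon ends and the acceptor among the 3'
  gene's internal exon starts, taking the full 5' part through the donor
  and the full 3' part from the acceptor. This is the least-assumption
  rule; the read-through literature's preference for penultimate/second
  exons is deliberately not imposed.
* **Truth alignments** — every read is projected through its transcript's
  exon blocks to genomic CIGARs: colinear same-chromosome, same-strand
  stretches become `N` gaps, anything else becomes a primary +
  supplementary pair with mutual `SA` tags. This replaces the external
  mapper for testing, which is exactly the point: detector behaviour can
  be assessed against alignments that are correct by construction.
* **Determinism** — one seed in `sim_config()` fixes every sampling step;
  identical configurations give byte-identical outputs.

What the simulator does *not* emulate: empirically learnt quality and
error profiles, indels, intron-spanning mis-splicing, expression-level
heterogeneity between transcripts, multi-mapping ambiguity, and alignment
errors in general. Passing the end-to-end tests therefore shows the
pipeline's logic is correct on clean evidence; it does not bound
performance on real libraries, where mapping noise dominates.

The companion `synth_genome()` builds random multi-exon gene annotations
whose introns carry canonical `GT..AG` boundaries, so every annotated
splice site is motif-compatible with the detector's orientation step.

# The benchmark module

Evaluation is done at two levels. At the *gene-pair* level the
deduplicated (gene5, gene3) sets are intersected — ordered by default,
since this pipeline orients its junctions; an unordered switch
accommodates callers that do not. At the *junction* level a true positive
requires exact equality of all six coordinates, so a prediction shifted by
a single base on either side is a false positive. Sensitivity is
TP/(TP+FN), precision TP/(TP+FP), F1 their harmonic mean; 0/0 ratios are
reported as undefined (`NA`), never coerced to 0 or 1, so empty sets do
not silently score perfectly or terribly. `junction_distance()` sums the
per-side absolute coordinate differences (donor-side + acceptor-side);
`strip_readthrough()` removes junctions meeting the read-through geometry
at < 100 kb, the usual preprocessing when a reference contains only fusion
genes.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere in the domain model (GTF
  native); 0-based half-open alignment coordinates are converted once at
  ingestion.
* A gene's exon set is the union over its transcripts with duplicate
  intervals collapsed, so overlap accounting does not multiply-count
  shared exons.
* Single-exon transcripts have no internal boundaries and contribute no
  annotated splice sites.
* Missing `NH` tags are treated as 1 (common in deduplicated BAMs);
  missing biotypes become `"unknown"`; an unknown chromosome in an
  overlap query returns an empty result rather than an error.
* CIGARs with two or more `N` gaps are not usable as two-segment split
  reads and are skipped for the split stream (still used as mates), as
  are chimeric alignments with more than one `SA` entry.
* Exactly-boundary values: 100,000 bp classifies as intrachromosomal
  (exclusive "closer than"); 30 bp / 90% identity discards (inclusive "at
  least").

# Problem sizes used by the test-suite

The end-to-end recovery test runs on a ~1 Mb synthetic genome (4
chromosomes × 20 multi-exon genes on both strands), two simulated
chimeras per class at 15× coverage, and requires junction-level
sensitivity and precision of exactly 1 at exact coordinates. Oracle
equivalence of the interval queries and the clustering is checked against
brute-force reimplementations on 1000+ randomized instances. These sizes
were chosen to exercise every class and code path while keeping the suite
comfortably fast on a laptop.

# Known limitations

* Junctions with one side in unannotated territory are dropped from the
  candidate set (logged), so fully novel genes cannot nominate chimeras.
* The consistency check uses annotation exonic space; for genes whose
  true expressed isoform differs wildly from the annotation the implied
  insert is misestimated.
* Reads split into three or more pieces are not represented.
* The detector's precision on real data depends on the upstream mapper's
  chimeric-alignment quality, which is outside this package's control.
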