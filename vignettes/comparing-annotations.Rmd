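---
title: "Comparing gene structure annotation sets with annomatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene structure annotation sets with annomatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annomatch)
```

## The problem

Distinct gene structure annotation sets for the same genomic sequences
accumulate constantly: successive releases of a community annotation,
predictions from a new gene finder against a curated standard, or
annotations from two independent providers. Assessing what is common and
what differs between two such sets — at whole-genome scale but with
gene-by-gene detail — is the task this package addresses. The two inputs
are called *reference* and *prediction*, but these are role labels only:
every step of the method treats them symmetrically, and no assumption is
made about their relative quality.

## Gene loci from the joint interval graph

The first question is which annotations should be compared with which,
and over which coordinates. Using only one set's gene coordinates to
define comparison windows discards signal from the other set (genes that
extend beyond the window, or exist only in the other set) and silently
imposes a quality judgment. Instead, both sets jointly define the
comparison units: every gene from either source is a node of an interval
graph, with an edge whenever two gene spans share at least one position
(1-based inclusive coordinates; abutting genes — `end == other$start - 1`
— do not overlap). Each connected component becomes one *gene locus*,
spanning the smallest genomic region that contains every member gene.

Three design points deserve mention:

* **Strand is ignored when building the graph.** Two genes on opposite
  strands that share positions belong to one locus; strand is treated as
  a display and interpretation property, not a separator. Whether
  cross-strand edges should be suppressed is genuinely open; joining them
  is the more conservative choice because it never splits related
  evidence apart.
* **Overlap is evaluated on gene spans** (the outermost transcript
  extent), not exon-by-exon, because the graph's nodes are gene
  annotations.
* Loci are mutually non-overlapping by construction, partition the genes,
  and are **independent** of one another — which is what makes a
  per-locus parallel map safe.

## Model vectors and transcript cliques

At a locus, each transcript is flattened to one symbol per genomic
position over the alphabet

| symbol | meaning |
|--------|---------------------|
| `C` | coding sequence |
| `F` | 5'-UTR |
| `T` | 3'-UTR |
| `I` | intron |
| `G` | intergenic |

Strand has no channel in this alphabet: a minus-strand transcript's `F`
still marks its biological 5'-UTR, which lies at the high-coordinate end.

Several transcripts of one source can share a single *model vector*
provided they do not overlap. Finding the groupings is a maximal clique
enumeration problem on the transcript *non-overlap* graph (an edge joins
two transcripts with disjoint spans — the complement of an interval
graph). The package enumerates all maximal cliques with the
Bron–Kerbosch algorithm with pivot selection; no degeneracy ordering is
used because per-locus transcript counts are small, so the worst-case
exponential behavior is immaterial. Disjointness is evaluated at the
transcript level, not the gene level, so transcripts of overlapping genes
can still share a vector if the transcripts themselves are disjoint. A
transcript may appear in several maximal cliques; all cliques are carried
forward, and the pairing step's at-most-once rule resolves the
redundancy.

## Inferring implicit structure from GFF3

Comparison requires every position to be classifiable, but real GFF3
files rarely annotate UTRs or introns explicitly. From `exon` and `CDS`
features the package infers:

* **introns** — the gaps between consecutive exons;
* **UTR segments** — exonic positions outside the CDS, labeled 5' or 3'
  by their position relative to the CDS span, mirrored on the minus
  strand.

Two degenerate situations need a rule. A transcript with exons but no
CDS uses the limiting form of the same rule — every exonic position is
"upstream of the (absent) CDS", hence 5'-UTR on the plus strand and
3'-UTR on the minus strand. Exonic non-CDS islands strictly *inside* the
CDS span (they arise only from pathological or fused models) are
assigned to a UTR side by comparing their midpoint with the CDS span
midpoint; the choice affects only the `F`/`T` display split, never the
pooled UTR statistics. Explicit UTR or intron features in the input are
checked against the inferred segments; on conflict a warning is issued
and the inferred version is kept, so both inputs are always measured by
the same yardstick.

Other parsing policies: mRNAs with CDS but no exons get exons
synthesized from the CDS segments; standalone mRNAs are wrapped in a
synthetic single-mRNA gene; non-mRNA transcript types (tRNA, ncRNA, ...)
are skipped with a warning — how the comparison should treat them is
undefined, and silently coercing them to coding models would distort the
UTR and CDS panels; CDS phase is read but ignored (no statistic uses
it); feature line order and coordinate sortedness are irrelevant.

## Similarity statistics

Every reference vector is compared against every prediction vector at
the locus. With TP/FP/FN/TN confusion counts (the reference defines the
condition, the prediction the call):

* sensitivity $Sn = TP/(TP+FN)$
* specificity $Sp = TP/(TP+FP)$ — this is *precision*; the name follows
  the gene-prediction literature's convention
* $F1 = 2\,TP/(2\,TP+FP+FN)$
* annotation edit distance $AED = 1 - (Sn+Sp)/2$
* simple matching coefficient $SMC = (TP+TN)/(TP+FP+FN+TN)$
* correlation coefficient
  $CC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$

Counts are taken at two resolutions:

* **nucleotide level**, for the coding class (symbol `C`) and the UTR
  class (`F` and `T` pooled — one UTR panel is reported, not two), plus
  the *overall identity*: the fraction of positions with the identical
  symbol over the full five-letter alphabet. $SMC$ and $CC$ are
  nucleotide-level only ($TN$ is undefined at feature resolution).
* **feature level**, for exons, CDS segments, and UTR segments: a
  prediction feature is a true positive only when both its start and end
  exactly match a reference feature, each reference feature being
  consumable once. A one-base boundary shift is a miss by design — the
  statistics quantify *exact* structural agreement; near-misses surface
  in the nucleotide panels instead.

Any statistic whose denominator vanishes is *undefined*: it propagates
as `NA`, renders as `--`, and is excluded from aggregation rather than
coerced to zero (zero would bias pooled summaries toward disagreement).

## Classification

Each compared pair is placed in a strict exact-agreement hierarchy:

1. **perfect match** — identical symbol strings (equivalently, overall
   identity 1);
2. **CDS structure match** — CDS segment coordinates agree exactly;
3. **exon structure match** — exon coordinates agree while the CDS
   differs (e.g. alternative start/stop codons);
4. **UTR structure match** — UTR segment coordinates agree (5' and 3'
   kept separate) while CDS and exon structure differ;
5. **non-match** — everything else.

Segment coordinates are taken from the cliques' member transcripts, not
re-derived from symbol runs, so two abutting transcripts cannot fuse
into one apparent exon run.

## Pairing cliques and the ranking key

When a locus carries several vectors per source, all $|R| \times |P|$
comparisons are computed, ranked, and greedily accepted so that each
clique is used at most once. The ranking key is: descending overall
identity, then ascending nucleotide CDS AED, then ascending feature-level
exon AED, then clique labels for full determinism. Overall identity
leads because it is the only single scalar defined over the entire
vector; the tie-breaks prefer coding agreement, which is what most users
of these comparisons care about first. Leftover cliques are reported as
*unmatched* (reference) or *novel* (prediction). They receive an
informational panel against the all-`G` vector in the locus report — so
the reader can see how much annotated structure went uncompared — but
they contribute nothing to the counted statistics: a locus annotated by
a single source yields no classified comparison. This keeps the
aggregate classification table a statement about loci where both sources
actually annotated something, rather than being dominated by presence /
absence differences, which the locus breakdown already quantifies.

## Splice complexity

As a per-source measure of isoform diversity at a locus, the package
reports the mean pairwise structural AED over all unordered transcript
pairs of one source: each transcript is encoded alone across the locus,
and for a pair $(a, b)$ the congruence sensitivity is the number of
positions labeled identically and non-`G` in both, divided by $a$'s
non-`G` positions (specificity: divided by $b$'s); $AED = 1-(Sn+Sp)/2$,
averaged over the $\binom{n}{2}$ pairs, and 0 when $n \le 1$. Pairs are
taken within a source across the whole locus and are unweighted by
transcript length; the published definitions leave both choices open,
and the unweighted within-source mean is the simplest statistic that is
0 exactly for structurally identical isoform sets.

## Aggregation

Running totals of every confusion cell, the identity tallies, and the
classification counts are maintained across loci; the summary panels are
then *recomputed from the pooled counts* — never averaged over per-locus
panels, which would weight a 200 bp locus equally with a 2 Mb one.
Pooling is exactly equivalent to a single confusion pass over the
concatenation of all compared vector pairs, and the tests assert this
equivalence.

Gene-level sensitivity and specificity are reported as the number of
perfect-match comparisons divided by the total number of reference
(respectively prediction) transcript cliques across unfiltered loci.
The "gene level" has no established definition in this setting; this
interpretation makes a dropped or unmatched gene count against
sensitivity, which matches how the numbers are read in practice.

## Filtering and reports

An optional flat `Key=Value` configuration excludes loci from the
analysis by locus length, gene count, transcript count, transcripts per
gene, exon count, or CDS length (`Min`/`Max` prefixes; unknown keys are
an error). Filtered loci are tallied in the summary for transparency
but contribute nothing else — no comparison is computed for them.

Reports are plain text with stable labels and ordering: one aggregate
summary (locus breakdown, classification table with counts and
one-decimal percentages, gene-level values, pooled panels to four
decimals) and one report per locus (`<seqid>_<start>-<end>.txt` under an
output directory, or streamed to stdout). A GFF3 track with one `locus`
feature per locus supports genome-browser integration. Rendering is
deterministic: identical inputs produce byte-identical reports, and
per-locus results are independent of the worker count because the
parallel map collects results in locus order. HTML output and embedded
graphics are out of scope; the text grammar is the single source of
truth.

## The synthetic data generator

`simulate_annotation_pair()` generates a reference set of non-overlapping
multi-exon protein-coding genes and derives the prediction gene-by-gene
through a perturbation program. Each perturbation class is constructed
to map onto exactly one classification outcome:

| edit | prediction change | expected outcome |
|------|-------------------|------------------|
| identical | verbatim copy | perfect match |
| utr | terminal exon extended outward; CDS untouched | CDS structure match |
| cds | start codon moved 1–2 codons in; exons untouched | exon structure match |
| splice | internal (coding) exon boundary pushed into its intron | UTR structure match |
| drop | gene absent | locus unique to reference |
| add | novel gene in the next intergenic gap | locus unique to prediction |
| merge | fused with the following gene | CDS structure match (two reference genes, one prediction gene) |

Defaults: 100 genes over 2 sequences, 2–6 exons of 60–300 bp, introns
40–200 bp, UTRs 20–90 bp (5') and 30–150 bp (3') clamped so every
internal exon boundary is coding, intergenic gaps 500–1500 bp (wide
enough that no perturbation can touch a neighboring locus), and a
mixed program of 55% identical copies with 10% each of UTR/CDS/splice
edits and 5% each of drop/add/merge. Length distributions are uniform
over these bounds: the generator aims at controlled structure for exact
ground truth, not at biological realism — no empirical exon-length
distributions, no alternative isoforms in the reference, no
transcription evidence or sequence content at all. Consequently, the
passing ground-truth tests demonstrate correctness of the comparison
machinery, not robustness to the messiness of real annotations (broken
parent links, partial genes, non-coding biotypes), which the parser
handles through its own explicit policies.

Generated GFF3 carries only exon and CDS features by default, so UTR
and intron inference is always exercised; `explicit_utrs = TRUE` adds
UTR features to test the consistency-checking path.
`expected_confusion()` derives the pooled nucleotide confusion counts
and identity tallies implied by the edits through interval arithmetic
over the generator's own coordinate records — an independent route that
the pipeline's running totals must reproduce exactly.

## Numerical and determinism choices

* All reported coordinates are 1-based inclusive (GFF3 convention).
* Undefined statistics are `NA`/`--`, never 0; aggregation skips them.
* All orderings that reach the output (seqids, gene and clique labels,
  locus order, clique enumeration order) use locale-independent radix
  sorting, so reports are byte-stable across platforms.
* The generator consumes randomness only inside `with_seed()`, restoring
  the caller's RNG state; the same seed yields byte-identical GFF3.
* Statistics are computed in double precision from integer counts;
  displayed values round to four decimals (percentages to one), matching
  the precision at which such comparisons are conventionally reported.

Verification runs use deliberately moderate problem sizes — e.g. 500
random graphs of up to 10 nodes against a brute-force clique oracle,
200 loci per single-edit program, and a 1000-locus genome for the
worker-count determinism check — chosen so the full suite exercises
every stage end to end while remaining quick to run routinely.

## Known limitations

* GTF input is not supported; convert to GFF3 first.
* Only `gene → mRNA` hierarchies are compared; non-mRNA transcript
  types are skipped, not evaluated separately.
* CDS phase is ignored; comparison is purely positional, so a frame
  error with identical coordinates is invisible.
* Feature matching is exact-coordinate only; no fuzzy (e.g. reciprocal
  overlap) matching mode exists.
* Nearby but non-overlapping genes are never joined into one locus; no
  distance-based merging is offered.

## A worked example

```{r example}
sim <- simulate_annotation_pair(sim_params(n_genes = 20, seed = 7))
ref <- read_annotations_text(sim$reference, "reference")
pred <- read_annotations_text(sim$prediction, "prediction")
res <- compare_annotations(ref, pred)
res
```

```{r locus-report}
cat(render_locus_report(res$comparisons[[1]]), sep = "\n")
```
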