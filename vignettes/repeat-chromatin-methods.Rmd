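---
title: "Reference-free repeat identification and ChIP enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free repeat identification and ChIP enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Repeat-rich regions — satellite arrays of centromeres, pericentromeric
heterochromatin, high-copy retrotransposons — are exactly the regions that
genome assemblies collapse or drop. Asking "which repeats carry CenH3
(centromeric) or H3K9me2 (heterochromatic) chromatin?" against such an
assembly systematically understates the answer. The alternative implemented
here works reference-free: unassembled genomic shotgun reads are clustered
by all-vs-all similarity into *repeat clusters*, each cluster's share of the
analysed reads is read off as its genome proportion, clusters are annotated
against a repeat database, and ChIP and input reads are assigned to
clusters by best similarity so that a per-cluster ChIP/input count ratio
identifies the chromatin-associated repeats. A ratio of at least 1.5 calls
a cluster enriched.

`repeatchip` implements this pipeline as testable components plus a
synthetic-genome simulator that plants repeat families with *known*
proportions and enrichment factors, so every downstream stage can be
validated against ground truth without any external data.

# The synthetic genome generator

`build_synthetic_genome()` emits the study conditions, not a tunable toy:

* **Satellites** are single contiguous tandem arrays of `copies`
  independently mutated monomers (monomer lengths of a few tens to a few
  hundred bp, like the classical plant centromeric satellites with
  monomers around 60–330 bp).
* **LTR retrotransposons** get family-specific terminal repeats (15% of
  the element length each, by default) flanking an internal domain shared
  across the genome's LTR families at ~1% divergence — mimicking conserved
  *gag-pol* domains with family-specific LTRs.
* **DNA-transposon-like** and **plastid-like** segments are dispersed
  mutated copies on random strands.
* **Background** is uniform random single-copy sequence; dispersed copies
  are interleaved with background chunks at random cut points, so planted
  intervals never overlap and `planted + background = genome length`
  exactly.

Mutation is substitution-only by default (each base flips to one of the
three other bases with probability `divergence`), which keeps identity
arithmetic exact: a copy-vs-consensus comparison has expected identity
exactly $1-d$ (a substitution never restores the original base), and two
copies at divergence $d$ differ at $\approx 2d$ of positions for small $d$.
An indel mode exists behind `indel_rate` but is off by default so that
clustering thresholds are tested separately from alignment gaps.

Reads:

* `simulate_shotgun_pairs()` draws `round(coverage * L / (2 * read_length))`
  fragment positions uniformly; mates sit at a fixed insert size on
  opposite strands. Reads are error-free with constant quality `I`
  (Phred 40) unless `error_rate` is set. Each read records its true origin:
  the family of the contiguous planted segment that wholly contains it,
  `"junction"` if it spans a segment boundary, else `"background"`.
  Labelling is per *segment*, not per monomer — with monomers shorter than
  the read length every satellite read straddles monomer boundaries, and
  marking those as junctions would void the notion of family of origin.
* `simulate_chip_reads()` draws input read start positions uniformly and
  ChIP start positions with per-position weight equal to the enrichment
  factor $f$ of the family covering the position (background $f = 1$),
  renormalised. The implied closed forms are returned with the reads: a
  family occupying start-position fraction $q_i$ with factor $f_i$ has
  expected ChIP fraction $f_i q_i / \sum_j f_j q_j$ and expected
  ChIP/input ratio
  $$ r_i = \frac{f_i}{\textstyle\sum_j f_j q_j}
         = \frac{f_i}{1 + \sum_j (f_j - 1) q_j}, $$
  which is what the enrichment tests compare against. With all $f \equiv 1$
  the ChIP sample is statistically identical to the input — the null used
  for calibration.

All randomness in each operation flows from its single integer `seed`;
identical seeds give byte-identical FASTQ output.

# Read clustering

Two reads are joined by a similarity edge when a local alignment on either
strand reaches **90% identity over at least 55% of the shorter read**
(the conventional defaults of read-clustering practice). On
substitution-only data qualifying alignments are gapless, so the edge test
is implemented as: does any diagonal of the (possibly reverse-complemented)
read pair carry a window of length $\ge \lceil 0.55\,m\rceil$ (with $m$ the
shorter read length) whose identity is $\ge 90\%$? Writing per-column
weights $1-p$ for a match and $-p$ for a mismatch ($p = 0.9$), a window
qualifies iff its weight sum is $\ge 0$, and the best window of bounded
minimum length is found in one prefix-sum/sliding-minimum pass per
diagonal.

**Seeding is provably lossless here.** Candidate (pair, strand, diagonal)
triples come from shared k-mers with $k = 8$: any qualifying window of
length $L \ge 55$ has at most $\lfloor L/10 \rfloor$ mismatches splitting
the matches into at most $\lfloor L/10\rfloor + 1$ runs, so some exact run
has length $\ge \lceil (L - \lfloor L/10\rfloor) / (\lfloor L/10\rfloor +
1)\rceil$, whose minimum over $L \ge 55$ is 8 (attained near $L = 60$ with
6 mismatches; $k = 9$ would *not* be safe there). Every qualifying pair
therefore shares an 8-mer on the qualifying diagonal and is examined.

Clusters are the connected components with $\ge 2$ reads of this graph,
ranked by descending read count (ties: lexicographically smallest member
id); all other reads are singletons. Components rather than a community
detection step keep the partition deterministic and checkable against an
exhaustive oracle: the test suite and the acceptance script compare the
seeded graph against an unseeded all-pairs, all-diagonals scan followed by
an independently written union-find. `cluster_reads()` additionally skips
verifying candidate pairs whose endpoints are already connected — omitted
edges lie inside components, so the partition is provably unchanged.

Genome proportion is plain read accounting:
$100 \cdot n_\text{reads} / N$ with $N$ the post-filter analysed reads
(clustered + singletons); the denominator convention is stated here because
"analysed reads" could also be read as pre-filter input. Clusters at
$\ge 0.01\%$ (inclusive) form the *reference clusters* used for ChIP
mapping — the bundled demo raises this to 0.5% because 0.01% of a
thousand-read demo is below one read. Mate pairs whose ends fall in two
different clusters are counted by `link_clusters_by_pairs()` (default
min. 5 pairs) as hints that one element split across clusters, e.g. LTRs
versus the internal domain of one retrotransposon family.

Quality filtering (mean Phred $\ge 20$, N fraction $\le 5\%$) applies
conventional defaults; the method itself does not prescribe them.

# Contig assembly and annotation

Contigs exist to serve as mapping and annotation references, so assembly is
deliberately the simplest deterministic choice: greedy merging of the
longest exact suffix–prefix overlap $\ge 31$ nt, strand-aware, until no
qualifying overlap remains; unmerged reads remain single-read contigs, so
contigs cover every read. Exact overlaps mean merged columns agree by
construction (the majority vote over a merged column is trivially the
shared base). Known limitations: reads properly contained inside a longer
contig are not recognised as redundant, and at low coverage a family
fragments into several contigs — harmless for mapping, which unions contig
hits by cluster.

Annotation queries each contig against a repeat database (FASTA headers
`>id group|clade|family`) by Smith–Waterman on both strands. A best hit
qualifies at $\ge 80\%$ identity over $\ge 50$ aligned nt; qualifying
contigs vote with weight equal to their read count (read-abundance
semantics, matching how clusters are quantified), and the cluster label is
assigned at the deepest level — family, then clade, then group — where a
strict majority ($> 50\%$) of voting weight agrees. No qualifying hit
means group `unknown`. Ties in best-hit selection break by alignment
score, then database record *id* (never record position), so permuting the
database cannot change an annotation.

# ChIP/input enrichment

ChIP and input reads are trimmed to their first 50 nt (shorter reads
dropped) and subsampled without replacement to one common depth, so raw
counts are directly comparable between the two samples — the ratio needs no
further normalisation, though a per-mapped-sample normalised ratio is
reported alongside.

Mapping uses BLASTN-style scoring (+2 match, −3 mismatch, gap open 5,
extend 2, no masking) and accepts a read's best hit iff its e-value is
$\le 10^{-12}$; ties break by cluster then contig id. E-values follow
Karlin–Altschul statistics $E = K m n e^{-\lambda S}$ with $\lambda$
solved from $\tfrac14 e^{2\lambda} + \tfrac34 e^{-3\lambda} = 1$
($\lambda \approx 0.634$ ungapped, uniform base composition), $K = 0.41$
(the tabulated value for this scheme with gap costs 5/2), $m$ the read
length and $n$ the total contig length. The mapped/unmapped decision is
insensitive to $K$ within an order of magnitude: a 50 nt read needs a score
around 63, and true hits score near 100 while the best random hit scores
in the twenties.

By default every read × contig × strand combination is scored exactly, so
best-hit assignment coincides with an exhaustive dynamic-programming oracle
— this is the property the test suite asserts. A word-size-9 prefilter
(`word_size = 9`) restricts scoring to combinations sharing an exact 9-mer;
the pipeline uses it for speed. Unlike the $k = 8$ clustering seed, this
trigger carries no losslessness guarantee (a borderline hit with ~7
scattered mismatches in 50 nt can lack any exact 9-mer), which is why
exactness, not seeding, is the default.

Enrichment records report, for every reference cluster, ChIP count, input
count and their plain ratio. Clusters with fewer than `min_input = 20`
input reads are flagged *indeterminate* instead of getting a ratio: the
ratio statistic is kept exactly as defined (no pseudocounts), and a floor
avoids divisions by near-zero input counts that would otherwise produce
arbitrarily wild ratios; flagged clusters are reported, never dropped.
`call_enriched()` applies the inclusive threshold ratio $\ge 1.5$;
indeterminate clusters are never called.

Composition summaries of the enriched fraction are computed per hierarchy
level with the enriched-cluster ChIP total as the primary denominator
(shares sum to 100% within a level); because "normalised to the overall
read amount" is also a defensible denominator, a secondary column against
the full sample size is emitted alongside. Enriched clusters annotated
`unknown` appear as `uncharacterized`.

# Reporting

`proportion_to_megabases()` converts percent proportions to physical sizes
(`pct/100 × genome Mb`), rounding half-up to two decimals, and
`compare_to_assembly()` joins cluster-based and assembly-based tables by
case-insensitive label (absent side = 0) with
`delta = cluster_mb − assembly_mb` computed *after* rounding each side —
published comparison tables are consistent with differencing the printed,
rounded sizes. Defaults of 758 Mb (genome estimate) and 567 Mb (assembly)
reflect the sugar beet convention and are configurable. A transcription of
the published sugar beet repeat-content table ships under
`extdata/beta_repeat_content.tsv`; a handful of its rows are internally
inconsistent at the last printed decimal, which is why round-trip tests
assert the package's arithmetic, not every printed digit.

# Calibration and validation scales

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen once as sizes where the statistics are decisive:

* **Clustering oracle**: 20 seeded 200-read sets (two satellite families
  plus background) — seeded graph vs exhaustive-scan single linkage.
* **Proportion recovery**: four satellite families planted at 10/5/2/0.5%
  of a 400 kb genome, 1× coverage (4,000 reads), 10 seeds; the
  seed-averaged matched-cluster estimate must sit within ±20% relative
  error. Monomers are kept ≤ 90 nt so that any two reads from one family
  overlap by at least 55 nt regardless of phase, making intra-family
  connectivity a property of the array, not of coverage luck.
* **Enrichment calibration**: 50 families of 1.8 kb in a 120 kb genome,
  $10^5$ reads per sample. Under the null, expected input count per
  cluster is ~1,500 and the ratio's standard deviation ~0.037, so 1.5 is a
  ≳13σ event — zero enriched calls expected. With one family at $f = 5$
  (planted fraction ~1.5%) the closed-form ratio is ~4.72 and the call is
  certain. These runs use the simulator's truth labels as the read–cluster
  assignment (reads are error-free, so alignment could only reproduce the
  labels); the aligner itself is validated separately by the mapping
  oracle.
* **Mapping oracle**: 300 single-end 50 nt reads against five planted
  element consensi, compared read-by-read against
  `Biostrings::pairwiseAlignment` local alignment under the same scoring.
* **Determinism**: the bundled demo configuration run twice must produce
  byte-identical output trees (md5 over every file).

# What the simulator does not emulate

Uniform fragment starts (no GC or chromatin bias), a fixed insert size,
no sequencing-error or quality profiles, no PCR duplicates, substitution-
only divergence by default, and a background with no low-complexity or
segmentally duplicated sequence. Passing tests therefore demonstrate the
pipeline's correctness under its stated model — planted proportions are
recovered, the ratio statistic is calibrated, mapping matches exhaustive
alignment — not robustness to every artefact of real libraries. Real-data
concerns (duplication rates, error-tolerant clustering thresholds,
community structure inside superclusters) are exactly the knobs exposed as
parameters (`error_rate`, `min_identity`, `min_coverage`, `word_size`).

# Known limitations

* Connected components cannot split chimeric superclusters the way the
  published community-detection pipelines do; shared internal domains can
  bridge LTR families at low divergence.
* Greedy exact-overlap assembly requires error-free overlaps; with
  `error_rate > 0` contigs fragment (annotation still works through
  single-read contigs, at reduced support).
* The all-pairs stage is quadratic per candidate family; the intended
  scale is the bundled desk-scale study sizes (≤ a few times $10^4$
  reads), not millions of reads.
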