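# repeatchip

Reference-free repeat identification and ChIP-Seq enrichment scoring over
repeat clusters, for chromatin biologists working on genomes whose
repeat-rich regions — centromeric satellite arrays, pericentromeric
heterochromatin, high-copy LTR retrotransposons — are collapsed or missing
from the assembly. Instead of mapping ChIP reads to an assembly, the
pipeline clusters unassembled genomic shotgun reads into repeat clusters,
quantifies each cluster directly from read counts, annotates it against a
repeat database, and scores per-cluster ChIP/input enrichment. Typical use
cases are CenH3 (centromere) and H3K9me2 (heterochromatin) profiling.

## Method

1. **Read clustering.** An undirected similarity graph joins two reads
   when a local alignment on either strand reaches ≥ 90% identity over
   ≥ 55% of the shorter read. Candidate pairs come from shared 8-mers — a
   prefilter that is provably lossless for substitution-only data at these
   thresholds. Repeat clusters are the connected components with ≥ 2 reads,
   ranked by size; everything else is a singleton.
2. **Quantification.** A cluster containing *n* of the *N* analysed reads
   occupies `100 · n / N` percent of the genome. Clusters at ≥ 0.01% form
   the *reference clusters* carried into ChIP analysis.
3. **Annotation.** Greedy exact-overlap contigs are assembled per cluster;
   each contig's best database hit (Smith–Waterman, both strands, ≥ 80%
   identity over ≥ 50 nt) votes with its read count, and the cluster is
   labelled at the deepest hierarchy level (group → clade → family) with a
   strict majority.
4. **Enrichment.** ChIP and input reads are trimmed to 50 nt and sampled
   to a common depth, each read is assigned to at most one cluster by best
   local alignment (+2/−3 scoring, gap 5/2, e-value ≤ 1e−12), and each
   reference cluster gets the ratio `chip_count / input_count`; clusters
   with ratio ≥ 1.5 are called enriched (input counts below 20 are flagged
   indeterminate instead of producing wild ratios).
5. **Reporting.** Percent proportions convert to physical sizes via
   `pct/100 × genome Mb` (half-up, 2 decimals), enabling cluster-based
   vs assembly-based repeat content comparisons (defaults 758 Mb genome
   estimate vs 567 Mb assembly).

A synthetic-data module generates repeat-rich genomes (tandem satellites,
LTR retrotransposons with shared internal domains, dispersed elements,
unique background) together with shotgun pairs and ChIP/input read sets
whose per-family enrichment factors are known, so every stage is testable
against planted ground truth. A family at start-position fraction *q* with
factor *f* has expected ChIP/input ratio `f / (1 + Σ (f_j − 1) q_j)` — the
closed form the calibration tests verify.

## Worked example

```r
library(repeatchip)

spec <- genome_spec(list(
    repeat_family("cenSat", "satellite", 60, 300, divergence = 0.02),
    repeat_family("gypsy1", "ltr_retrotransposon", 1000, 8, divergence = 0.02)
  ), background_length = 32000, seed = 101)
genome <- build_synthetic_genome(spec)
genome
#> Synthetic genome: 58000 nt; 9 planted segments from 2 families
#>      family                kind proportion
#>      cenSat           satellite     0.3103
#>      gypsy1 ltr_retrotransposon     0.1379
#>  background          background     0.5517

reads    <- simulate_shotgun_pairs(genome, coverage = 2, seed = 102)
clusters <- add_proportions(cluster_reads(quality_filter(reads)))
summary(clusters)
#> Reads analysed:    1160
#> Reads in clusters: 1071 (92.3%)
#> Singletons:        89
#> Clusters:          157

reference <- select_annotatable_clusters(clusters, threshold = 0.5)
contigs   <- assemble_clusters(reference, reads)
head(annotate_clusters(contigs, reference_db_from_truth(genome),
                       clusters = reference), 2)
#>   cluster_id n_reads proportion_pct     group       clade family support n_hits
#> 1        CL1     358      30.862069 satellite cenSat-like cenSat       1     41
#> 2        CL2     147      12.672414 Ty3-gypsy gypsy1-like gypsy1       1     33

sim   <- simulate_chip_reads(genome, chip_profile(cenSat = 6),
                             n_reads = 20000, seed = 103)
chip  <- prepare_chip_reads(sim$chip,  n_sample = 8000, seed = 104)
input <- prepare_chip_reads(sim$input, n_sample = 8000, seed = 105)
cm  <- map_reads_to_clusters(chip,  contigs, word_size = 9, details = FALSE)
im  <- map_reads_to_clusters(input, contigs, word_size = 9, details = FALSE)
rec <- call_enriched(compute_enrichment(cm, im,
         reference_clusters = reference$table$cluster_id))
head(rec[, c("cluster_id", "chip_count", "input_count", "ratio", "enriched")], 3)
#>   cluster_id chip_count input_count     ratio enriched
#> 1        CL1       5830        2435 2.3942505     TRUE
#> 2        CL2        462        1102 0.4192377    FALSE
#> 3        CL3         32          89 0.3595506    FALSE
```

The satellite simulated with enrichment factor 6 over 31% of the genome is
the single enriched cluster; its observed ratio 2.39 sits on the
renormalised expectation `6 / (1 + 5 · 0.31) ≈ 2.35`, not on 6 — ChIP read
fractions compete for a fixed sequencing depth. Converting a cluster
proportion to physical size:

```r
proportion_to_megabases(3.58, 758)
#> [1] 27.14
```

A full run (simulate → filter → cluster → annotate → enrich → report) with
TSV/FASTA outputs and a reproducibility manifest:

```r
run_pipeline(demo_config(), "demo_out")
```

or from a shell, stage by stage:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "repeatchip.R", package = "repeatchip"))')" \
  all --config path/to/config.yaml --outdir out/
```

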