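# kzfpclust

Analysis toolkit for KRAB-containing poly-zinc-finger protein (KZFP)
genes and related genetic units — the pseudogenes, retrocopies and
unannotated KZFP-like loci that share their repeat-anchored zinc-finger
arrays. These units sit in dense genomic clusters enriched for ERVK/ERV1
endogenous retroviruses and are held under KAP1-mediated repression;
studying them requires a pipeline that spans motif annotation, interval
statistics, phylogenetics and regulatory-signal profiling. `kzfpclust`
provides that pipeline for computational biologists working on KZFP
biology, transposable-element regulation, or gene-family evolution, plus
a fully seeded synthetic-genome generator with ground truth so every
stage can be validated end to end.

## What it computes

- **ZNF/KRAB/ORF annotation** — C2H2 motifs by shortest-match scanning of
  `C-X(2,4)-C-X(12)-H-X(3,4)-H` (21–24 aa); zinc fingerprints (the helix
  −1/+3/+6 specificity triplets, i.e. spacer positions 6/9/12); KRAB-A
  domains by a packaged 42-column log-odds PSSM over six frames; unit
  ORFs as KRAB → ≥3 fingers in one frame with no intervening stop.
- **Clustering** — single-linkage chaining of units with adjacent gaps
  < 500 kb, clusters at ≥ 8 members (≥ 10 for the receptor-gene
  comparator rule); strand-aware upstream-KRAB association within 30 kb;
  positional-correlation histograms over symmetric windows; exact Fisher
  tests of peak association against within-chromosome shuffled controls.
- **Enrichment statistics** — permutation nulls with the add-one
  empirical p-value `(1 + #{null ≥ obs}) / (n + 1)`; exact hypergeometric
  TE-subfamily over-representation (α = 0.01); peak composition with the
  KZFP/rGU > selected-TE > other priority; KO-only acetylation fractions
  and per-subfamily KO/WT ratios.
- **Consensus phylogenetics** — progressive alignment, majority
  consensus per cluster, p-distances, and Saitou–Nei neighbor joining
  with declared tie-breaks.
- **Fingerprint evolution** — tandem triplet duplications, repeated
  blocks of 2–7 triplets (maximality rule), shared and strand-reversed
  blocks between paralogs, Dollo single-gain emergence ordering of
  paralogs from segment presence, and retrocopy calls (intronless +
  3'-proximal poly-A + donor homology).
- **Coverage metaprofiles** — strand-oriented aggregate profiles with
  1.5 kb/3.5 kb flanks, length-normalised bodies and 95% confidence
  bands; fold-change response classes; per-cluster category summaries;
  distance-to-peak stratification.

## Worked example

Extract a zinc fingerprint from the canonical Zif268 first finger:

```r
library(kzfpclust)
m <- findC2H2Motifs("CPVESCDRRFSRSDELTRHIRIH")
m
#>   start end c1 c2 h1 h2       spacer linker
#> 1     1  23  1  6 19 23 DRRFSRSDELTR
extractFingerprint(m)
#> [1] "RER"
```

The motif spans residues 1–23 with zinc-coordinating cysteines at 1 and 6
and histidines at 19 and 23; the triplet `RER` is the DNA-contacting
residues at helix positions −1, +3, +6 — the canonical Zif268 finger-1
contacts.

Chain repeat-anchored units into clusters (eight elements, every gap
400 kb, i.e. under the 500 kb rule):

```r
x <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
  start = seq(1, by = 401000, length.out = 8), width = 1000))
cl <- buildClusters(x)
cl
#> KzfpClusters: 1 cluster(s) from 8 element(s) (0 isolated)
#>   rule: >= 8 members, adjacent gap < 500000 bp
clusterTable(cl)
#>   cluster_id chrom start     end n_members         members
#> 1          1  chr1     1 2808000         8 1,2,3,4,5,6,7,8
```

Run the full pipeline on the packaged synthetic conditions (3 clusters of
10 units, 20 isolated units, 5 retrocopies) and inspect the summary it
writes:

```r
res <- runDemoPipeline("demo_out", seed = 3)
str(res$summary)
#> $ orf_sensitivity          : num 1
#> $ orf_precision            : num 1
#> $ n_clusters_found         : int 3
#> $ cluster_recovery         : num 1
#> $ n_significant_subfamilies: int 4
#> $ top_enrichment_is_erv    : num 1
#> $ peak_shuffle_p           : num 0.0099
#> $ retrocopy_sensitivity    : num 1
#> $ retrocopy_false_positives: int 0
#> $ mean_log2fc_cluster_units: num 2.1
#> $ cluster_vs_isolated_p    : num 8.77e-09
#> $ ko_only_fraction         : num 0.0754
```

Every planted ORF is recovered with no false calls; the three planted
clusters are found with exactly their planted members; the most enriched
TE subfamilies inside clusters are the planted ERVK/ERV1 ones; WT peaks
are enriched in clusters at the permutation floor p = 1/101; all five
retrocopies are called with zero false positives among intron-containing
genes; cluster units recover the planted 4× KO upregulation
(mean log2 fold change ≈ 2) while isolated units do not (rank-sum
p ≈ 9e-09); and 7.5% of cluster bases gain KO-only acetylation peaks.
`demo_out/` additionally holds every intermediate as BED/FASTA/TSV/
bedGraph/Newick, byte-identical across runs at a fixed seed.

## Layout

- `R/` — implementation (I/O, synthetic genome, ZNF/KRAB annotation,
  clustering, enrichment, phylogenetics, fingerprint evolution, coverage).
- `tests/testthat/` — unit, property and end-to-end tests with
  brute-force oracles.
- `vignettes/kzfpclust-methods.Rmd` — models, parameter choices and
  design decisions in detail.
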