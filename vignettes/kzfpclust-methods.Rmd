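---
title: "Methods: models, parameters and design choices in kzfpclust"
author: "kzfpclust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in kzfpclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

KRAB-containing poly-zinc-finger protein (KZFP) genes and their relatives —
pseudogenes, retrocopies and unannotated KZFP-like loci, collectively
"KZFP-related genetic units" — occur in dense genomic clusters enriched for
endogenous retroviruses, and are kept under KAP1/SETDB1-mediated repression.
`kzfpclust` implements the computational workflow for studying this system:
annotation of zinc-finger arrays, KRAB domains and in-frame KRAB-to-ZNF
ORFs; clustering of units along chromosomes; permutation-based enrichment
statistics; per-cluster consensus phylogenetics; zinc-fingerprint
diversification analysis; retrocopy detection; and strand-aware coverage
metaprofiles. A seeded synthetic-genome generator with complete ground
truth stands in for the mouse genome so every stage is testable at desk
scale; reproducing genome-scale counts from real annotation databases is
out of scope.

All genomic data live in Bioconductor containers: intervals are `GRanges`
(1-based closed), sequences are `Biostrings` objects and coverage is
run-length encoded. BED (0-based half-open) and GTF/RepeatMasker (1-based
inclusive) conventions are converted only at the I/O boundary, preserving
interval length. Chromosome names are matched verbatim — no "chr"
aliasing — so mixed naming surfaces as an error rather than silent data
loss.

# Motif and ORF annotation

**C2H2 motif scanning.** The zinc-finger motif is `C-X(2,4)-C-X(12)-
H-X(3,4)-H`, 21–24 residues. The inner gap ranges make the pattern
ambiguous, so the scanner is defined operationally: left-to-right, at each
candidate cysteine the *shortest* match is taken (tied lengths resolve to
the smaller C–C gap) and scanning resumes after the final histidine, so
motifs never overlap. Shortest-match reproduces the canonical 21-residue
finger and makes the scan deterministic; `X` never satisfies an anchor
position. Fingers with mutated C/H anchors are skipped entirely rather
than reported as degenerate — a deliberate simplification, since a
degenerate-finger class would need its own calling rules.

**Fingerprints.** The specificity triplet of a finger is the residues at
alpha-helix positions −1, +3 and +6, which map to positions 6, 9 and 12 of
the 12-residue spacer between the second cysteine and the first histidine.
The mapping was fixed against the canonical Zif268 finger-1 contacts
(spacer `DRRFSRSDELTR` gives `RER`) and is asserted in the test suite.

**KRAB detection.** No public annotation pipeline for KRAB-coding
sequence is bundled with the data this package emulates, so detection is
defined transparently: a 42-column position-specific scoring matrix over
the KRAB-A box (consensus residue probability 0.9, the remainder uniform,
log2-odds against a uniform background), slid over all six translation
frames. Hits are above-threshold local maxima; overlapping hits within a
frame merge keeping the maximum. The default threshold is 60% of the
maximum attainable score (about 105 of 175 bits), far above anything
random sequence reaches, and both the matrix and threshold are arguments,
so a user-supplied profile can replace the packaged one.

**ORF rule.** A reported unit ORF is a KRAB hit whose translation, extended
to the first stop codon in the same frame, contains at least `minZnf = 3`
C2H2 motifs. Three is the number of (incomplete) fingers spanned by the
repeat consensus that anchors these units. Because the scanned segment
ends at the first stop, the no-stop-between-KRAB-and-fingers constraint
holds by construction, and a single stop-gain mutation in the spacer
abolishes the call — the behaviour expected for pseudogenized copies.

# Clustering and positional statistics

**Cluster rule.** Units chain by single linkage: sorted by start, adjacent
elements link when the end-to-start gap is strictly below `maxGap`
(default 500 kb; a gap of exactly 500 kb does not link), and chains of at
least `minSize = 8` become clusters. `minSize = 10` reproduces the
comparator rule used for olfactory/vomeronasal receptor gene clusters.
"Apart" could also be read as midpoint-to-midpoint; end-to-start is the
strictest natural reading and matches interval-merging conventions, and a
running-maximum end makes chaining exact even for nested intervals (the
test suite proves equivalence to exhaustive union-find over the pairwise
gap relation). Cluster spans run from the first member's start to the last
member's end, without flanks; per-nucleotide normalisations use this span
length.

**Upstream association.** A KRAB hit is associated with a unit when its
3'-most coordinate (in the unit's orientation) lies within 30 kb upstream
of the unit's 5' end, inclusive; ties break by distance, then leftmost
coordinate. Unstranded input is treated as "+" with a warning rather than
an error, so degenerate annotations degrade predictably.

**Positional correlation.** Offsets from anchor points to feature points
accumulate into half-open bins over a symmetric window (±15 kb for the
KRAB/repeat correlation, ±10 kb for peak correlation); offsets flip sign
for minus-strand anchors, and an offset exactly on a bin edge falls into
the right-hand bin. A strand-aware 3'-extension helper (`extend3prime`,
e.g. 1 kb) covers the gene-extension preprocessing used before anchoring.

**Fisher overlap test.** The 2×2 table contrasts real elements with a
within-chromosome shuffled control of identical counts and lengths: rows
real/control, columns has/has-not a peak within the window. The exact
two-sided p comes from `fisher.test`; the odds ratio is the sample odds
ratio with a Haldane correction (0.5 per cell) when a cell is zero. The
contingency construction is not stated by the analyses this mirrors;
shuffling is chosen because it matches the permutation logic used
elsewhere in the same workflow.

# Permutation nulls and composition summaries

Shuffles reposition each interval uniformly within its chromosome, keeping
length and chromosome; overlaps among shuffled intervals are allowed,
since rejection sampling would bias the placement of long objects. The
empirical p-value is the add-one estimator
$(1 + \#\{null \ge obs\}) / (n + 1)$, which cannot reach zero — 100
shuffles cannot support p < 1/101, and the estimator's discreteness makes
rejection at small α slightly conservative, which the calibration test
accounts for. Typical shuffle counts follow the source analyses: 100 for
cluster shuffles, 10,000 for peak shuffles.

TE subfamily over-representation uses a one-sided exact hypergeometric
test on (inside/outside clusters) × (this subfamily/other repeats), with
raw p-values compared to α = 0.01. No multiple-testing correction is
applied by default, matching the raw-threshold convention of the analyses
this reproduces; `adjust = TRUE` switches to Benjamini–Hochberg and is
documented as a deviation.

Peak composition assigns each peak to exactly one category by priority:
unit overlap first, then the selected-TE subfamily with the largest
overlap (ties to the leftmost TE), then "other". Selected TEs exclude
Satellite, Simple_repeat, Low_complexity and Unknown classes and
subfamilies with fewer than 100 members in the supplied (cluster-
restricted) repeat set.

Differential-acetylation summaries merge each peak set before interval
arithmetic, so base conservation |KO| = |KO∩WT| + |KO\\WT| holds exactly;
per-subfamily KO/WT ratios require at least 3 members and report `NA`
when the denominator is zero rather than inventing a value.

# Consensus phylogenetics

Within-cluster alignment is progressive: guide order from 6-mer profile
distances (closest pair first, then nearest remaining sequence), each new
sequence aligned globally against the running alignment's majority
consensus with affine gaps. Alignment scoring is match 1, mismatch −1, gap
open −4, gap extend −1, in the convention where a gap of length L costs
open + (L−1)·extend; `N` scores 0 against everything. These defaults are
exposed because the source analyses state no alignment parameters.
Consensus columns where gaps hold a strict majority are dropped rather
than written as gaps, because consensuses feed pairwise realignment and
internal gap characters would distort p-distances; residues must reach a
0.5 majority among non-gap characters or the column is called `N`, with
ties resolved by alphabet order.

Between-cluster distances are p-distances (mismatches over aligned,
non-gap, non-N columns) and the tree is canonical Saitou–Nei neighbor
joining, implemented in-package so tie-breaking (lexicographically
smallest label pair) and negative-branch clamping (to zero, deficit
recorded) are fully specified; `ape::nj` serves as an independent
cross-check in the tests, never as the implementation. NJ on p-distances
was chosen over likelihood methods because the tree method of the figures
this mirrors is unstated and NJ is deterministic and exactly testable
against additive matrices. Distances default to nucleotide mode; protein
sequences can be compared by aligning externally and supplying
pre-aligned consensuses.

# Fingerprint diversification and retrocopies

Tandem runs are maximal runs of identical consecutive triplets. Repeated
blocks of 2–7 triplets are reported longest-first, and positions consumed
by a reported block are not re-reported inside shorter blocks — without
this maximality rule every k-block repetition would spawn a combinatorial
family of sub-block reports. Shared blocks between two fingerprints are
maximal common contiguous substrings, optionally also against the
reversed second fingerprint (arrays encoded on the opposite strand read
backwards), flagged as reversed.

Segment homology calls use local affine alignment in place of BLAT: a
segment is present in a region when the best local alignment covers ≥ 80%
of the segment at ≥ 80% identity, thresholds exposed since the source
states none. An interrupted homology still counts as present while
coverage holds. Segment boundaries are user input, not inferred — they
were fixed by hand in the analyses this reproduces.

Emergence ordering treats segments as Dollo characters: gained once,
never regained, so each segment's gene-set must form one clade and all
gene-sets must be pairwise nested or disjoint (violations raise an error
naming the conflicting segment pair and the gene pattern). Under the
additional requirement that every gene's segment set equals the union of
gains on its root-to-leaf path, the laminar family determines the
topology uniquely, so the mismatch-minimisation tie-break in the original
formulation never has to choose; children order deterministically by
smallest leaf label, making the output invariant to input order.

A retrocopy call requires all three criteria: exactly one exon; a
genomically encoded poly-A run (≥ 10 adenines at ≥ 90% purity, i.e. one
non-adenine tolerated per ten positions, ending within 200 bp of the 3'
end); and ≥ 80% global identity with the concatenated exonic sequence of
the best-matching multi-exon donor. The poly-A thresholds quantify a
qualitative description and are all configurable.

# Coverage metaprofiles and response classes

Metaprofiles sample a counts-per-million-normalised track over
strand-oriented windows: 1.5 kb upstream and 3.5 kb downstream at 1 bp
resolution, with the element body length-normalised to 100 bins (the
common plotting axis requires some rescaling; flanks stay at native
resolution, bodies are averaged per bin, and bodies shorter than the bin
count are sampled at the nearest position). Windows running off a
chromosome are masked, not errors. The 95% confidence band is the normal
approximation mean ± 1.96·SE per grid position, matching the
"confidence interval around the mean" convention; a bootstrap band was
considered and rejected as needlessly expensive for the n involved.

Response classification is a declared stand-in for differential-expression
testing, which is out of scope: log2((b + 1)/(a + 1)) against a fixed
threshold of 1 with a minimum-signal filter. It is antisymmetric under
condition swap by construction. Per-cluster category summaries omit
categories with fewer than 5 elements; distance-to-peak stratification
assigns each element to exactly one bin (overlap, < 5 kb, < 20 kb,
≥ 20 kb) with strict bounds, so a gap of exactly 5000 bp falls in the
"< 20 kb" bin; the in-cluster versus isolated comparison uses a rank-sum
test on log2 fold changes.

# The synthetic genome

The generator plants, with full ground truth: three clusters of ten
KRAB-anchored units each on 400 kb chromosomes (inter-gene gaps 3–8 kb,
far below the 500 kb chaining bound), twenty isolated units on a fourth
chromosome in runs of at most seven separated by 600 kb (above the bound,
so no spurious cluster can form), and five intronless, poly-A-tailed
retrocopies of cluster donor genes on that same other chromosome. Unit
anatomy follows the annotated model: a KRAB-A segment (the packaged
consensus — the same model used for detection, which keeps sensitivity
tests self-consistent), an in-frame stop-free spacer of 300–1500 bp, then
4–8 C2H2 fingers with TGEKPY linkers. Filler residues avoid cysteine and
histidine so the planted finger count and fingerprint are exact;
consequently planted fingerprint triplets never contain C or H, a
restriction real fingerprints do not share. Units within a cluster share
a spacer template, mimicking common ancestry. Donor genes carry the
spacer as an annotated intron; the intron is frame-neutral and stop-free,
a simplification that keeps genomic ORF detection over donors intact
where a real intron would break it. Retrocopies are the spliced
KRAB+array copy with a 16-adenine genomic tail.

TE composition is ERVK/ERV1-biased inside clusters (65% LTR,
ERVK-heavy) against a LINE/SINE-dominated background (12% LTR), with 40
TEs per cluster and 300 background TEs — densities chosen to make the
bias detectable at this scale, not to match any published figure, which
reports proportions only graphically. Signal follows the KO model:
repressive WT peaks over unit 3' ends and 30% of cluster ERVK/ERV1
elements; in KO these disappear and 40% of cluster TEs gain
activation-style peaks. Per-element coverage is negative-binomial
(dispersion 0.1; dispersion 0 gives noise-free means), the standard count
model for sequencing signal; cluster units are planted 4× up in KO
(30→120), isolated units and retrocopies unchanged — the planted form of
the observation that upregulation is confined to clusters. The default
mutation rate is 0: the reference conditions are noise-free, and noise is
applied explicitly where an analysis studies robustness.

What the generator does not emulate: realistic chromosome sizes and gene
densities, TE sequence content (TE intervals carry random sequence),
transcriptional isoform structure, mappability artefacts, and any 3D
chromatin organisation. Tests passing on this generator therefore
demonstrate algorithmic correctness against a known truth, not
performance on real annotation pipelines.

All randomness flows from a single integer seed through separate
sub-streams for annotations, sequences and signal; the full demo pipeline
is byte-identical across runs at a fixed seed.

# Problem sizes and determinism

The packaged demo conditions (3 × 10 + 20 units, 5 retrocopies, ~3 Mb of
genome) run the full pipeline in about a minute. Validation uses 1,000
random interval sets against the union-find oracle, 1,000 replicate
null datasets for shuffle calibration (the null experiment uses 600
features against 30 regions covering half a 3 Mb chromosome, sized so the
overlap statistic is fine-grained enough for the add-one estimator's
discreteness not to dominate), 500 random fingerprints against
brute-force enumeration, 50 seeded lineage replicates for tree recovery
(per-branch divergence 6% versus 2% within-cluster diversity, a 3×
separation), and 200 random single-gain histories for emergence ordering.

# Known limitations

Progressive alignment against a majority consensus is a greedy heuristic:
adequate for the closely related sequences clusters contain, but not a
substitute for a full MSA program on divergent inputs. P-distances ignore
multiple substitutions, so deep divergences compress. The PSSM KRAB
detector is a transparent stand-in for whatever produced the original
KRAB track; sensitivity on real degenerate KRAB boxes will differ. The
poly-A and identity thresholds for retrocopy calling quantify qualitative
criteria and should be tuned against known processed pseudogenes before
use on real genomes.
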