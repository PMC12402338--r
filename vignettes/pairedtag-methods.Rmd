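---
title: "Methods: joint single-nucleus histone and transcriptome processing with pairedtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint single-nucleus histone and transcriptome processing with pairedtag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedtag)
```

## The problem

Paired-Tag is a split-pool combinatorial barcoding assay that profiles one
histone modification (via antibody-guided tagmentation) together with the
transcriptome of the same single nucleus. Each nucleus passes through three
barcoding rounds (12, 96 and 96 wells by default), so a read's cellular
identity is the triple of round barcodes carried on Read 2, and its molecular
identity is the UMI plus the PCR sub-library index. This package implements
the complete downstream computation for such experiments — demultiplexing,
trimming, deduplication, matrix construction, joint clustering, differential
testing, genomic annotation, and promoter bivalency analysis — together with
a deterministic synthetic-data generator that plants known answers for every
stage. The biological setting it emulates is a two-capture design (H3K4me1
and H3K27me3) across four sample groups (female/male x control/exposed),
where an exposure perturbs both expression and the H3K4me1/H3K27me3
"bivalency" state of gene promoters.

## Read 2 layout and demultiplexing

Read 2 carries `[pad][BC3][linker][BC2][linker][UMI][BC1]`. A per-read start
jitter of 0-3 bp shifts the cassette, so the first bases of BC1, BC2 and BC3
fall in the 1-based windows 84-87, 47-50 and 10-13. Barcode and linker
lengths are not fixed by the assay description, so the defaults are chosen to
reproduce those window positions exactly: 8-bp barcodes and UMI with 21-bp
and 29-bp linkers (`barcode_layout()`); everything is configurable.

Demultiplexing anchors each barcode by locating the adjacent linker (exact
match first, then one substitution), rejects reads whose barcode first base
falls outside its window, and resolves each round against its whitelist under
a Hamming distance <= 1, unique-hit rule: no entry within distance 1 discards
the read (`no_match`), two or more entries at the minimal distance discard it
(`ambiguous`), and `N` counts as a mismatch. Matching is substitution-only
and forward-strand-only, mirroring alignment with one permitted mismatch and
multi-hit discarding. The demultiplexing report partitions the input exactly:
every read is assigned or carries one failure reason.

The simulator's whitelists are drawn with a minimum pairwise Hamming distance
of 3 (`sim_whitelists()`), as real split-pool whitelists are designed to be,
and its barcode error model substitutes at most one base per round at the
configured rate. Under those two conditions a corrupted barcode is always
either corrected to its true well or discarded — never mis-assigned — which
the tests assert exactly on 100,000 simulated reads.

Read 1 is trimmed in the standard order: 3' adapter (>= 10 bp overlap,
<= 10% mismatches), then for RNA a terminal poly-dT/poly-dA run of >= 6
bases, then 3' bases below Phred 30. Reads shorter than 30 bases after
trimming are dropped. A minimum base-call quality of Q = 30 can be read
either as a per-base 3' trim or as a mean-quality filter; the 3'-trimming
reading was chosen because it composes with the length filter the way
read-cleaning tools normally do.

## Quantification conventions

* **Position** for deduplication and pileup filtering is (chromosome,
  5' start, strand); a bare mapped position would ignore strand, so the
  inclusion of strand is an explicit, configurable convention.
* **Deduplication** keeps one record per (position, cell barcode, PCR index,
  UMI) and is idempotent and order-independent.
* **High-pileup removal** pools counts over all cells, UMIs and indices per
  position and removes positions with depth strictly greater than the cutoff
  (default 10). "Cutoff = 10" could also be read as `>=`; strict-greater was
  chosen so that a depth exactly at the cutoff survives, and the reading is a
  parameter, not a constant.
* **Bin matrices** tile the genome with 5-kb bins and count each fragment in
  the bin containing its 5' start (not its midpoint). Matrix totals equal
  fragment counts exactly, which the pipeline ledger exploits.
* **Gene matrices** count a record for every gene span it overlaps
  (`ties = "all"`, naive union counting); `ties = "drop"` discards ambiguous
  records instead. Toy gene models are non-overlapping, so the two agree in
  every simulated test.
* **Cell filtering** keeps nuclei with >= 200 nonzero RNA features and
  >= 500 nonzero DNA bins (both conditions; matched profiles), and the DNA
  matrix then loses its top 2% highest-covered bins, ties broken by genomic
  coordinate. CI-scaled synthetic runs reduce per-cell depth ~50-fold, so
  pipeline-level tests scale these two thresholds proportionally while the
  200/500 boundary behaviour (199 removed / 200 kept, 499/500) is asserted
  verbatim on constructed matrices.

Every pipeline run carries an exact count ledger:
`reads_in = linker_not_found + out_of_window + no_match + ambiguous +
dropped_length + unaligned + mapq_removed + duplicates_collapsed +
pileup_removed + unassigned + in_matrix`, and matrix totals decompose into
kept counts plus cell-filter and top-bin losses. `check_ledger()` errors on
any imbalance.

Alignment itself is out of scope: the pipeline consumes tagged fragment
records, and the simulator either emits them directly (`emit_fragments()`)
or emits FASTQ whose Read 1 is placed back on the toy genome by exact
matching of a 30-bp seed with full-length verification (`locate_reads()`,
forward strand only — the simulator emits plus-strand reads).

## Embedding and clustering

RNA counts are normalized per cell to 10,000 and log1p-transformed; variable
genes are ranked by a mean-binned standardized dispersion. DNA bin matrices
are binarized and TF-IDF weighted. "TF-IDF" names a family; the variant here
is `log(1 + 1e4 * tf * idf)` with `tf` the bin's share of its cell total and
`idf = n_cells / n_cells_with_bin` — the form in common use for single-cell
chromatin data. RNA uses components 1-30 of a centered, scaled PCA; DNA uses
components 2-30 of an uncentered truncated SVD of the TF-IDF matrix (LSI),
dropping component 1 because it tracks per-cell depth. Component signs follow
the largest-|loading|-positive convention, so embeddings are bit-reproducible.

Neighbour graphs are shared-nearest-neighbour graphs (k = 20, weights
`|shared| / (2k - |shared|)`, pruned below 1/15). The two modalities are
blended with a fixed global weight (`joint_graph()`, default 0.5), which
reduces exactly to either modality at the weight limits; per-cell
weighted-nearest-neighbour integration is deliberately out of scope, so the
blend is the documented simplification. Clustering is Louvain modularity
optimization at a given resolution with a fixed seed; clusters under 50 cells
are flagged excluded. `search_resolution()` scans a resolution grid to match
a target cluster count, the procedure used when a reference clustering fixes
the number of clusters.

Cluster labels come from marker scoring on cluster centroids: each marker
gene's mean expression per cluster is z-scored *across clusters* and averaged
within each type's marker set. Centroid scoring (rather than per-cell
z-scores) keeps scores independent of cluster sizes — with a 55% excitatory
majority, per-cell z-scores compress the majority type's signal toward zero.
A cluster scoring above the doublet threshold (0.4) on two or more types is
flagged as a doublet cluster.

## Bivalency analysis

Promoter signal is the count of fragment 5' starts in `[TSS - 1000,
TSS + 1000)` (half-open, so the 50-bp metagene grid of 40 bins sums exactly
to the promoter count), normalized to RPM (`count / total x 1e6`) and FPKM
(window length 2 kb). Metagene profiles flip minus-strand genes so positive
positions are downstream in gene orientation, and aggregate as the unweighted
mean over genes. Fragment membership is by 5' start, consistent with
quantification; "signal intensity" is read as fragment-count coverage, not
base-pair coverage.

A mark is called *present* at a promoter when its RPM reaches
`min_fold x quantile(background RPM, 0.95)`, with the background measured on
random intergenic windows (`background_windows()`). The percentile alone has
a built-in ~5% false-positive rate per unmarked gene, which would make exact
recovery of planted states impossible for any caller, so a multiplicative
margin (`min_fold`, default 2) is applied; `min_fold = 1` restores the plain
percentile. States are bivalent / K4-only / K27-only / unmarked, transitions
are a pure function of the state pair ("K27 resolved" for bivalent to
K4-only), and the thresholds used are recorded with every call so calls are
recomputable.

For genomic annotation the promoter is the *inclusive* TSS +/- 1 kb interval
(2001 bp): an inclusive window is symmetric around the TSS base, which makes
annotation exactly invariant under coordinate reflection with strand flip — a
property the tests check on 1,000 random peaks. Category precedence is
Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream (<= 3 kb past the 3'
end) > DistalIntergenic, membership by any-overlap; without exon models the
gene span counts as exonic. The precedence order follows common annotation
practice and is configurable; the category list itself is the standard one.

## Differential testing

The test is the two-sided Wilcoxon rank-sum with mid-ranks; the default
p-value uses the normal approximation with tie and continuity correction, and
sample sizes up to 12 switch to exact enumeration over all rank assignments
(the exact mode is also the test oracle). A hurdle-model test (MAST-style)
is a common alternative for single-cell comparisons; the nonparametric
rank-sum test is what is implemented here, and hurdle regression is out of
scope.
A caveat worth stating: no continuous approximation can track the exact null
distribution of tiny samples to 0.01 everywhere (the sup error is ~0.09 at
n = 2 + 2 and ~0.015 at n = 6 + 6), which is exactly why the exact mode is
the default at those sizes.

Fold changes are `log2((mean_a + 0.01) / (mean_b + 0.01))` on de-logged
normalized means; "|fold change| > 1.25" is read as a linear-scale bound,
i.e. `|log2FC| > log2(1.25)`, because threshold presets in this field mix
linear and log scales and the linear reading is the conservative one.
BH-FDR is the step-up `q_(i) = min_(j>=i) m p_(j) / j`. Named presets
register the threshold sets the package supports (`threshold_presets()`),
all with a 50-cell minimum group size. Features detected in under 10% of
both groups are not tested — a standard single-cell pre-filter.

## The synthetic world

The generator's defaults are one stated world, not tuning knobs:

* genome: 4 chromosomes x 2.5 Mb (2,000 5-kb bins); 500 genes of 2 kb laid
  out so promoters never overlap;
* cells: 8 capture groups (2 marks x 2 sexes x 2 conditions) x 250 nuclei;
  four cell types at fractions 0.55/0.20/0.15/0.10 (cortical-like
  proportions) with 8 canonical markers each, up-weighted 8-fold in their own
  type; RNA counts are negative binomial (dispersion 0.3) around a seeded
  gamma abundance baseline with log-normal library sizes;
* promoter states: 60 bivalent, 60 K4-only, 60 K27-only and 100 explicitly
  unmarked genes planted globally; under exposure 20 bivalent genes lose
  H3K27me3 (become K4-only); genes whose current state carries H3K27me3 are
  expressed at half rate (the repressive coupling), and 40 evaluation genes
  carry a planted +/-1 log2 fold change chosen among the more abundant half —
  planting fold changes on never-expressed genes would not define a
  meaningful power condition;
* DNA fragments per nucleus (800 by default) mix 40% uniform background,
  type-specific promoter signal, and shared planted-state promoter signal.
  H3K27me3 type signal is dense and disjoint (25 genes per type, 30% of
  fragments); H3K4me1 type signal is sparse and largely shared (two 12-gene
  pools — excitatory vs all other types — at 10%), emulating the widespread
  shared-enhancer distribution of H3K4me1. This is what makes
  H3K27me3-only clustering separate the types better than H3K4me1-only,
  as a planted property rather than a tuned outcome;
* noise: 1% per-round barcode substitution, 30% PCR duplication (geometric
  extra copies, so expected reads are exactly (1 + rate) x molecules), 10%
  adapter read-through, 50% RNA poly-dT tails, jitter uniform on 0-3.
  `sim_config_zero_noise()` switches these off (and shrinks dispersion) for
  exact-recovery tests.

What the generator does **not** emulate: realistic sequence composition,
splicing and intronic reads, ambient RNA, empty droplets, doublet nuclei
(mixtures are constructed explicitly in tests instead), chromatin fragment
length distributions, and batch effects. A green recovery test therefore
establishes that the computation inverts the generator's model exactly — not
that it would behave identically on real tissue.

Determinism: every stochastic step draws from a seed derived deterministically
from `sim_config(seed = ...)`, so two runs of any generator or pipeline
function with the same configuration are byte-identical, independent of call
order.

## Numerical and degenerate-input choices

* Rank-sum with all values identical returns p = 1 by convention; zero-length
  groups are errors.
* BH-FDR propagates NA p-values and rejects values outside [0, 1].
* TF-IDF errors on empty rows or columns, naming the offending identifier;
  normalization errors on zero-total cells (they should have been removed by
  the coverage filter).
* `reduce_dims()` lowers the component count with a warning when it exceeds
  the matrix rank; constant features get unit scale instead of dividing by
  zero.
* Tie-breaks are always by coordinate or identifier order (top-bin removal,
  variable-gene ranking, nearest-gene assignment), making every ranking
  deterministic.
* Promoter windows are clipped at chromosome bounds; fragments are never
  placed past a chromosome end by the simulator, and the bin matrix rejects
  such fragments as input errors.

## Known limitations

* Per-cell WNN modality weights are replaced by one global weight; the limit
  cases (weights 0, 0.5, 1) are tested, but cell-specific modality quality is
  not modelled.
* The exact-match locator requires error-free reads and a collision-free toy
  genome; it is a test harness, not an aligner.
* Bivalency calls pool cells per condition; per-cell-type calls work the same
  way but are only exercised at pooled scale in the tests.
* Headline numbers from any particular real dataset (nucleus counts,
  cluster counts, DEG counts, distal-intergenic fractions, correlation
  coefficients) depend on that dataset and are intentionally not reproduced
  here; the tests check the properties of the computation, and the
  qualitative contrasts (K27 clusters better than K4; promoter H3K27me3
  anticorrelates with expression while H3K4me1 does not) on planted data.
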