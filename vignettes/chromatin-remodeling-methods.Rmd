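---
title: "Methods: nucleosome dynamics and chromatin-state calling between two cell states"
author: "remodelscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome dynamics and chromatin-state calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`remodelscan` compares the chromatin landscape of two cell states — the
motivating system is a neural stem cell (NSC) differentiating into a neuron
— from aligned single-end sequencing tags: MNase-seq for nucleosome
positions, ChIP-seq for five histone modifications (H3K4me1, H3K4me3,
H3K9ac, H3K27ac, H3K27me3), a TSS annotation, and an FPKM expression table.
Read alignment and differential-expression calling are upstream of the
package; its inputs are plain-text BED6 tag files and TSV tables. All
internal coordinates are 0-based, half-open, BED-native; conversion happens
only at file boundaries, and chromosome names are matched by exact string
equality.

This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data generator
does and does not emulate. It states no empirical result beyond what the
package's test suite and `scripts/acceptance.R` themselves compute.

# Nucleosome calling from MNase tags

Each tag is extended 147 bp toward its 3' end (one nucleosomal DNA length);
the midpoint of the extension is the inferred **dyad**: `pos5 + 73` on the
`+` strand, `pos5 - 73` on the `-` strand (the floor of the half-integer
midpoint). The per-bp dyad histogram is smoothed with a Gaussian kernel and
local maxima are accepted greedily in descending smoothed height, rejecting
candidates within an exclusion zone of an accepted call — the scheme
popularised by GeneTrack, re-implemented here with every parameter exposed:

* `sigma = 20` bp — smoothing bandwidth. The kernel is evaluated on a 1-bp
  grid and truncated at ±4σ (exactness against cost; beyond 4σ the kernel
  mass is below 1e-4 of the peak).
* `exclusion_bp = 147` — one nucleosome footprint; two calls can be no
  closer than this, center to center.
* `min_reads = 3` — calls supported by fewer member reads are dropped.

These defaults reproduce canonical phasing on the synthetic genomes (the
acceptance suite measures ≥95% dyad recovery within ±20 bp at a 180-bp
repeat, 20-bp fuzziness and 20-fold coverage); the tool the original
analysis used does not publish its parameters, so ours are package
defaults, not a reproduction claim.

Each dyad is assigned to the nearest accepted call within ±73 bp (ties to
the leftmost call), so no read supports two nucleosomes. Per call the
package reports the member read count, **occupancy** = reads per million
mapped (if the library held exactly one million mapped reads, occupancy
equals the read count), and **fuzziness** = the *population* standard
deviation of the member dyad coordinates (a single-read call has fuzziness
0). Because membership is truncated at ±73 bp, fuzziness is biased low for
very delocalized nucleosomes: at a true dispersion of 30 bp the truncated
standard deviation is ≈0.95 of the true value, which stays within the ±10%
band the acceptance suite checks.

Genome-scan occupancy uses non-overlapping windows tiled from position 0
(default 500 bp; 150 and 300 bp behave consistently), counting tag dyads
per window and normalizing per million mapped. No significance test is
attached to per-window differences: the statistical test the original
analysis applied to 500-bp window changes is not described in its main
text, so the package deliberately emits the per-window difference track
only.

# Dynamics classification: fixed / shift / loss / gain

Two 147-bp footprints overlap by ≥20 bp exactly when their dyads are ≤127
bp apart; such cross-state pairs are candidates for being the same
nucleosome. The package computes the **exact optimum one-to-one matching**:
maximum number of matched pairs first, minimum total |Δdyad| among those.
Because both call sets are position-sorted and the cost |Δ| is convex, an
optimal matching can be chosen non-crossing (uncrossing two matched pairs
never raises the total L1 cost and preserves the ≤127-bp feasibility), so
the optimum is found by a sequence-alignment dynamic program. For
tractability the calls are first split into connected components wherever
consecutive pooled sorted positions gap by more than 127 bp — a split that
can only merge too much, never separate a pairable pair. The gap penalty is
scaled with component size so that cardinality strictly dominates cost.

A simple greedy nearest-pair scheme was evaluated first and rejected: with
coherent shift runs larger than half the repeat length (u > 90 bp at a
180-bp repeat), each state-B dyad is *closer to the next state-A dyad* than
to its own (180 − u < u), and greedy chains these mis-pairings, converting
a clean run of shifts into spurious losses and gains. On noiseless planted
maps this distorted the recovered fractions by several percentage points;
the exact matching recovers them to rounding. The test suite verifies the
matching against an exhaustive brute-force oracle (maximum cardinality,
then minimum total distance) on hundreds of random instances with up to 8
calls per side.

Matched pairs with Δ = 0 are **fixed** — exact at 1-bp resolution, which is
deliberately strict: with any positional noise in the dyad estimates the
probability of exact agreement is small, so end-to-end (reads → calls →
matching) the planted fixed class leaks into 1–10-bp shifts. At 20-fold
coverage the dyad estimate of each state has a standard error of several
bp, making P(Δ̂ = 0) ≈ 0.05; classification-level validation therefore runs
on the planted maps themselves, while the read-level path is validated on
the loss/gain fractions and on fixed+shift jointly. Matched pairs with
Δ ≠ 0 are **shift** (signed, reported both chromosome-absolute and
strand-aware); unmatched state-A calls are **loss**, unmatched state-B
calls **gain**. Fractions are reported under three denominators — the
union (pairs count once), state A, and state B — because a percentage of
"all nucleosomes" is ambiguous between them.

Feature enrichment assigns each call to promoter (TSS ±1 kb), genic
(TSS-to-TES) or intergenic by its dyad, promoter taking precedence, and
divides by the merged class length in kb.

# TSS-centered profiles and difference clustering

Gene-by-position matrices span ±1 kb of the TSS, strand-aware (downstream
= direction of transcription). Three metrics are supported: extended-read
coverage converted to RPKM (default 5-bp bins, 5-bin centered moving
average), call-dyad density per bin per million mapped (the convention for
call-level profiles: 10-bp bins, 3-bin moving average), and mean call
fuzziness per bin. Moving averages shrink to partial windows at the
boundary rather than dropping bins.

The per-gene difference matrix (state B − state A) is partitioned by
K-means with `k = 5` — the number of patterns the motivating analysis
reports; no model-selection criterion is applied because none is described
— with a fixed seed and 50 restarts (restarts are cheap and the archetype
recovery is otherwise vulnerable to local optima). An all-zero difference
returns a degenerate flag instead of clustering. Rows of the returned
matrix are ordered by cluster, then by distance to the centroid, for
heatmap export.

# Promoter NDRs and expression

The promoter nucleosome-depleted region is the strand-aware window
[−200, +50] around the TSS, mapped to `[tss − 200, tss + 51)` on `+`
genes and `[tss − 50, tss + 201)` on `-` genes. Both endpoints are
included (251 positions); the 250/251 ambiguity is a config constant
(`window_us`, `window_ds`). Occupancy is the extended-read coverage summed
over the window, divided by 147 (fractional read equivalents) and
RPKM-normalized. Windows running off a chromosome end are clipped and
flagged. Association with expression uses Spearman correlation (FPKM per
state) and, for gene-group contrasts, the two-sided Wilcoxon rank-sum
test.

# Promoter histone-modification states

Mark levels are RPKM over the ±1-kb promoter: `count × 1e9 / (2000 ×
total mapped)`. Thresholds are derived per mark from the pooled two-state
level distribution by a cascade:

1. **Valley threshold** — Gaussian KDE (Silverman's bandwidth, 512-point
   grid from 0 to the 99th percentile); the two highest local maxima are
   the modes; the threshold is the density minimum strictly between them.
   A bimodality guard requires the second mode to reach ≥10% of the first
   mode's height; if it fails, no threshold is returned.
2. **K-means fallback** — for unimodal marks (H3K27me3 in the motivating
   system): 1-D K-means with k = 2 (seeded, 10 restarts); the threshold is
   the midpoint of the two centers.

A promoter is *marked* iff its level is strictly greater than the
threshold — ties fall to unmarked. The combinatorial state string joins the
marked mark names in a fixed mark order; H3K4me3⁺ ∧ H3K27me3⁺ sets a
bivalent flag. Transition counting between states is a square matrix over
observed state strings whose grand total equals the gene universe exactly.

Fold-change clustering uses `log2((b + c)/(a + c))` with pseudocount
`c = 1` RPKM (zero-level promoters otherwise give infinite fold changes),
keeps genes whose largest per-mark |log2 FC| reaches log2(2), and runs
K-means with `k = 4` — inferred from the four patterns the motivating
analysis reports; both are config-exposed. Gain-mode classification for
H3K4me3/H3K9ac is a four-way partition — `de_novo` (unmarked→marked),
`increase_existing` (marked in both, FC ≥ 2), `lost` (marked→unmarked),
`unchanged` — that is mutually exclusive and exhaustive by construction.

# Enhancer identification and states

H3K4me1-enriched regions are found by a sliding-window Poisson scan: 1000-
bp windows advancing 100 bp, each window's tag count tested against
Poisson(genome-wide rate × window width), Benjamini–Hochberg control at
FDR 0.1%, significant windows merged, and merged peaks closer than 1000 bp
merged again. The published description fixes the window and FDR; the
internals here are a transparent re-implementation with the step exposed.
Each merged peak also carries its **summit window** — the highest-count
significant window inside it, the fixed-width peak a HOMER-style caller
reports. Element-level signal (the H3K4me3 filter and the state
classification) is quantified over the summit window: the merged extent
includes up to one window of sub-threshold overhang on each side, which
would otherwise dilute a 1-kb element's RPKM by more than half.

Peak sets from the two states merge by keeping the single highest-scoring
member of each overlap group (ties to the earlier start). Promoter-like
peaks are removed by fitting a **two-component Gaussian mixture** to the
per-peak H3K4me3 RPKM (maximum over states) with a hand-rolled 1-D EM:
components initialised at the lower/upper quartiles with a seeded jitter,
log-likelihood tolerance 1e-6, at most 500 iterations. The threshold is
the point between the fitted means where the weighted component densities
are equal — the Bayes boundary of the fitted model, a model-based cut
rather than an empirical-KDE valley. Fits are declared degenerate when the
means come closer than half the pooled standard deviation *or* when the
fitted mixture density has no interior minimum between the means: EM on a
unimodal sample usually splits it into two overlapping components with
separated means, and the second check is what actually catches that case.
Degenerate fits yield no threshold; the caller may supply a manual one.

State thresholds come from random background: as many non-overlapping
1000-bp regions as there are enhancers, sampled uniformly without
replacement (seeded, recorded), RPKM per region, threshold = the smallest
value among the top 10% under the nearest-rank-ceiling convention (the
⌈n/10⌉ largest values; levels 1…100 give exactly 91). Per state an
enhancer is `off` if H3K4me1 ≤ t_K4me1, otherwise `active` if H3K27ac >
t_K27ac, else `poised`. The pipeline derives one threshold per mark from
the post-differentiation state's tags; the 3×3 transition matrix conserves
the enhancer count exactly. Each enhancer is assigned its nearest gene by
|midpoint − TSS| (ties to the lexicographically smaller gene id), with a
strand-aware signed distance.

The per-enhancer level unit is RPKM (the published description does not
fix it; RPKM keeps promoters and enhancers on one scale).

# Enhancer NDRs and formation modes

Within each enhancer the maximal sub-intervals not intersecting any call
footprint `[dyad − 73, dyad + 74)` are collected; those ≥150 bp are NDRs.
Footprints extending beyond the enhancer still block positions inside it,
and NDR boundaries are clipped to the enhancer. Call footprints (rather
than raw coverage gaps) are used because "contains no nucleosome" is a
statement about called nucleosomes; the scan is validated exactly against
a brute-force position-scan oracle.

Formation modes are labeled from the paired-state differential: state-A
and state-B footprint coverage around the NDR midpoint are smoothed
(Gaussian, σ = 30 bp) and subtracted. The most negative excursion near the
NDR is where occupancy was lost; the most positive excursion within ±400
bp is where it reappeared. Lost occupancy with gain below 0.4 of the loss
is **eviction** (the nucleosome went away, not sideways); otherwise the
sign of (gain peak − loss peak) separates **shift5** from **shift3**; a
loss depth below 0.25 of the window's maximum state-A coverage means the
region was already open in state A and the label is **ambiguous** — this
is what identical A and B inputs produce. NDRs are then K-means-partitioned
(k = 3) by the central ±350 bp of their state-B profiles — the heatmap
view of the three patterns; the outer flanks carry position-specific array
noise uninformative about the NDR — and each NDR reports the **majority
label of its cluster**. Pooling a cluster's members averages out the
per-element Poisson noise that limits single-NDR labels at moderate
coverage; on planted modes at 20-fold coverage, cluster-consensus labels
recover ≥90% (the acceptance suite measures this), while single-NDR labels
plateau around 80–90%. How the three clusters map onto
eviction/5'-shift/3'-shift is not specified by the motivating analysis;
the differential rule above is this package's stated convention.

# The promoter–enhancer synergy table

Genes are joined to enhancers via the nearest-TSS assignment; the synergy
set keeps genes whose expression log2 fold change has the same sign as
their enhancer's H3K27ac log2 fold change with both magnitudes ≥ log2(1.5)
(the expression cutoff is not published; 1.5 is the config default), sorts
rows descending by enhancer H3K27ac log2 FC, attaches promoter-mark fold
changes, and partitions into up/down gene sets.

# The synthetic-data generator

The generator emits aligned tag coordinates directly — no sequences, no
alignment — because the analysed pipeline starts at uniquely mapped reads.
Reads are 147 bp (MNase geometry) or a notional 50 bp (ChIP; quantification
counts tags, so length is inert beyond boundary clipping). Reads whose
extension would leave the chromosome are dropped, keeping the dyad model
exact. Every draw comes from a named RNG stream hashed from the master
seed, so adding a mark or state never perturbs other outputs.

**Nucleosome arrays.** Chromosomes are tiled with blocks of 10 nucleosomes
at the configured repeat (default 180 bp) separated by 350-bp boundary
linkers. Dynamics labels are planted per block with exact quotas over the
configured fractions, and a shift block moves coherently by a single
signed magnitude drawn uniformly from the shift range (default [1, 120]).
Two modelling facts force this structure: per-nucleosome independent
shifts at a 180-bp repeat would park ~a third of adjacent state-B dyads
closer than 147 bp — sterically impossible for real nucleosomes — and
remodeling in the motivating system acts on runs of nucleosomes (whole
clusters shift toward 5'). The boundary linkers leave a residual ~0.1% of
junction pairs colliding. MNase reads per nucleosome are
Poisson(coverage × weight) with dyads Normal(planted dyad, fuzziness) and
uniform strand.

**Promoters.** Each gene gets the canonical architecture: phased arrays
at −270, −450, … and +75, +255, … (strand-aware), an NDR over [−200, +50],
and — for a configurable subset (default one half) — an NDR-positioned
nucleosome at −75 present in state A with a per-gene weight drawn
U(1, 2) and evicted in state B. Expression is
log2(FPKM + 1) = baseline − coupling × (planted NDR occupancy) + Gaussian
noise (defaults: baseline 5, coupling 1, noise sd 0.3), so promoter-NDR
occupancy and expression are negatively coupled by construction;
enhancer-synergy genes additionally get a state-B offset whose sign
matches their enhancer's planted H3K27ac change.

**Promoter marks.** Marked status is Bernoulli per mark (weights 0.35–0.5)
with a 15% flip between states; levels draw from two-mode Gaussians. Four
marks are well-separated (low mode ~1–2, high mode 10–24 RPKM-units);
H3K27me3's modes are close enough that its level density is effectively
unimodal, exercising the K-means threshold fallback. ChIP read counts are
Poisson(level × width × 2 reads/kb per unit), placed uniformly in the
element, over a uniform 1 read/kb genomic background.

**Enhancers.** Elements are 1 kb, placed with genes into evenly spaced
slots (shuffled, jittered) so promoters never overlap and every enhancer
is ≥2 kb from every TSS. Enhancer H3K4me1/H3K27ac levels follow the
planted active/poised/off states ("on" mean 28 against a 0.2 background
mode — the deliberate ≥3-fold separation from the background top-decile
threshold that the element-dense synthetic genome requires, since ~20% of
random background regions overlap some element). A configurable subset
(default one half) hosts a planted NDR in a local array at 280-bp spacing:
eviction removes the central nucleosome in state B (413-bp gap); shift
modes move it coherently by 120 bp (253-bp gap), landing it 160 bp from
its neighbour — physical, and resolvable by the caller.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: sequence-dependent MNase bias, mappability,
PCR duplicates, paired-end fragments, irregular gene density, overlapping
transcription units, replication-timing or copy-number effects, and
chromatin heterogeneity within a cell population. The planted NDR lengths
(253/413 bp) are also wider than the mono-nucleosome 150–250-bp range that
dominates real enhancer NDRs, a consequence of the sterically safe array
geometry.

# Problem sizes and determinism

The validation suite runs on 2 × 500-kb genomes (~5,000 nucleosomes,
~100,000 MNase tags per state, 150 genes, 60 enhancers), with 1,000-gene
genomes for the expression-coupling checks and 2,500 × 400 matrices for
the archetype-clustering check — sizes chosen so planted-truth recovery is
measured with useful precision while the whole suite stays interactive.
The full pipeline writes every stage product plus a versioned JSON report
(thresholds, fractions, seeds); log lines go to the console only, so two
runs under one config and seed produce byte-identical output trees, which
the acceptance suite verifies with file hashes. Stages cache on a content
hash of their parameters and input files and are skipped on unchanged
reruns.
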