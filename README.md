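# remodelscan

Chromatin-remodeling analysis between two cell states from aligned
sequencing tags. The package implements, as tested reusable R functions,
the pipeline used to compare the nucleosome and histone-modification
landscape of neural stem cells (NSCs) and neurons: MNase-seq nucleosome
calling and dynamics classification, promoter and enhancer
nucleosome-depleted region (NDR) detection, histone-modification state
calling in promoters and enhancers, and a promoter–enhancer synergy
analysis — together with a synthetic-data generator that plants ground
truth for end-to-end validation.

It is written for computational biologists who have aligned single-end
tags (BED6), a TSS annotation and an FPKM table, and want the analysis
from that point on to be reproducible and testable.

## The methods in brief

* **Nucleosome calling.** Each MNase tag is extended 147 bp toward its 3'
  end; the extension midpoint is the dyad (`pos5 ± 73`). The per-bp dyad
  histogram is Gaussian-smoothed (σ = 20 bp) and local maxima are accepted
  greedily under a 147-bp exclusion zone. Calls carry read count,
  occupancy (reads per million mapped) and fuzziness (population SD of
  member dyad coordinates).
* **Dynamics.** Calls from the two states pair when their footprints
  overlap ≥ 20 bp (|Δdyad| ≤ 127). The one-to-one matching is the exact
  optimum (maximum pairs, then minimum total |Δ|, via a non-crossing
  dynamic program). Δ = 0 → *fixed*, else *shift* (1–127 bp, signed);
  unmatched calls are *loss* (state A) or *gain* (state B).
* **Promoter NDR.** Occupancy of the strand-aware [−200, +50] window
  around each TSS, correlated with expression (Spearman; Wilcoxon for
  group contrasts).
* **Promoter HM states.** Per-mark promoter RPKM over TSS ± 1 kb;
  thresholds from the valley of the bimodal level density (K-means k = 2
  fallback for unimodal marks); combinatorial states, transition matrices,
  twofold-change K-means clustering (k = 4), and H3K4me3/H3K9ac gain-mode
  calls (*de novo* vs increase from existing levels).
* **Enhancers.** H3K4me1 peaks from a sliding-window Poisson scan (1-kb
  windows, BH FDR 0.1%), merged across states by best score; promoter-like
  peaks removed by a two-Gaussian EM threshold on H3K4me3; active /
  poised / off states against thresholds taken from random background
  regions (smallest value of the top 10%); nearest-gene assignment, NDR
  scanning (nucleosome-free stretches ≥ 150 bp) with
  eviction / 5'-shift / 3'-shift mode labeling, and the synergy table of
  genes whose expression change tracks their enhancer's H3K27ac change.

## Worked example

```r
library(remodelscan)

# a synthetic two-state genome with planted ground truth
cfg <- synthetic_config(seed = 7)
sim <- simulate_chromatin(cfg)
print(sim)
#> Synthetic chromatin data set
#>   genome: 2 x 5e+05 bp; 150 genes, 60 enhancers
#>   planted nucleosomes: 4909
#>   MNase tags: NSC=95515, neuron=93727

# nucleosome maps for both states
cs <- sim$annotation$chrom_sizes
dyads <- lapply(sim$mnase, reads_to_dyads, chrom_sizes = cs)
calls <- lapply(dyads, call_nucleosomes, chrom_sizes = cs)
print(calls$NSC)
#> Nucleosome calls: 4691 calls on 2 chromosome(s)
#>   sigma=20 bp, exclusion=147 bp, min_reads=3, total mapped=95515
#>   median fuzziness 19.2 bp, median read count 20

# fixed / shift / loss / gain between the states
m <- match_nucleosomes(calls$NSC, calls$neuron)
print(m)
#> Nucleosome dynamics: 4898 nucleosomes (union denominator)
#>   fixed 1.9%  shift 88.1%  loss 5.8%  gain 4.2%
```

The dynamics line reads: of all nucleosomes (matched pairs counted once),
~88% moved between states, ~6% were lost in neurons, ~4% newly formed.
With calling noise an exactly-unmoved nucleosome is rarely estimated at
the identical bp in both states, so most of the planted 10% fixed class
is recovered as 1–10-bp shifts — see the methods vignette for the
analysis.

The whole pipeline, from a config to a directory of tables plus a JSON
report of thresholds and fractions:

```r
run <- run_pipeline(list(synthetic = list(seed = 7),
                         params = list(seed = 7)), "out")
print(run)
#> remodelscan run -> out
#>   nucleosome calls: NSC=4691, neuron=4613
#>   dynamics: fixed 1.9% shift 88.1% loss 5.8% gain 4.2%
#>   enhancers: 78
```

A thin command-line wrapper is installed at
`inst/scripts/remodelscan.R`
(`Rscript remodelscan.R all --config run.yaml --out outdir`).

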