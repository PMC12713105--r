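# dsbloop

Quantitative analysis linking DNA double-strand breaks (DSBs) induced by
folate deficiency to reorganization of the 3D genome.

Folate deficiency — modelled in cells by methotrexate (MTX), a
dihydrofolate-reductase inhibitor — loads the genome with DSBs. When DSBs
accumulate at active promoters and enhancers, chromatin loops anchored
there can be gained or lost, and the genes sitting in those anchors become
mis-expressed. `dsbloop` implements the statistical pipeline for studying
this chain of events from mapped breakpoint sites, probability-scored
chromatin-loop lists, chromatin-state segmentations, Hi-C contact
matrices, and per-gene expression tables. It is aimed at epigenomics
analysts who have run the upstream callers (breakpoint mapping, a loop
caller emitting per-loop probabilities, ChromHMM, a TAD caller, a
compartment eigenvector tool) and need the downstream quantification,
tests and integration.

## What it computes

**Per-bin DSB ratio.** Breakpoint sites are counted into fixed bins
(default 5 kb). With library sizes $T$ and $C$, the per-bin ratio is

$$r_i = \frac{t_i/T \cdot 10^6 + c_0}{c_i/C \cdot 10^6 + c_0}$$

with pseudocount $c_0 = 0.5$. Per-bin enrichment is tested with an
upper-tail hypergeometric test, $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$ (population = pooled reads, marked =
treated reads, draws = reads in the bin); Benjamini–Hochberg-significant
bins with ratio $\ge 2$ merge into DSB enrichment regions.

**Differential chromatin loops.** A loop is *gained* when its calling
probability exceeds 0.95 in the treated condition and falls below 0.8 in
the control, *lost* in the mirrored case. Anchors recurring in $\ge 2$
loops are *busy anchors* (interaction hubs); a Yates-corrected chi-square
on the anchor-by-differential-membership 2×2 table tests whether busy
anchors are preferentially displaced, and a bin-level 2×2 table tests
DSB-region/differential-anchor colocalization. Aggregate peak analysis
(APA) scores loop strength as the center of the aggregate
observed/expected submatrix over its 3×3 lower-left corner.

**Stratified correlations and integration.** DSB ratio versus distance
from the nearest TSS (500 descending-ratio bins), promoter/enhancer
content across ten ratio classes, proximal (TssA within 20 kb) versus
distal enhancers, repeat-subtype coverage, TSS meta-profiles (±5 kb, 100
bins), expression–DSB coupling (100 gene bins, Pearson), compartment
(stable A / A-to-B / B-to-A / stable B) DEG enrichment, hierarchical-TAD
level trends, and an upset-style multi-evidence gene intersection.

**Synthetic data with planted truth.** A deterministic generator emulates
the study's data structure — Poisson DSB counts whose treatment effect
decays with TSS distance and concentrates at active promoters and
enhancers, two-condition loop lists with busy hubs and planted
differential loops co-located with DSB hotspots, contact matrices with
power-law distance decay and planted peaks, lognormal expression coupled
to gained/lost anchors — so every pipeline stage can be validated against
known ground truth.

## Worked example

```r
library(dsbloop)

params <- sim_params(seed = 7)
ds <- simulate_dataset(params, contacts = "treated")

ratio <- bin_enrichment_test(dsb_ratio(ds$dsb$treated, ds$dsb$control))
glance(ratio)
#> # A tibble: 1 × 7
#>   n_bins lib_treated lib_control pseudocount mean_bin_ratio median_bin_ratio
#>    <int>       <int>       <int>       <dbl>          <dbl>            <dbl>
#> 1   4000      232237       59033         0.5           1.02            0.908

diff <- call_differential_loops(ds$loops$treated, ds$loops$control)
glance(diff)
#> # A tibble: 1 × 6
#>   n_loops n_gained n_lost n_stable p_high p_low
#>     <int>    <int>  <int>    <int>  <dbl> <dbl>
#> 1     400       35     37      328   0.95   0.8

anchors <- build_anchor_table(diff, diff = diff)
busy_anchor_association(anchors)
#> busy-anchor vs differential-loop association
#>        differential not
#> busy             24  10
#> normal           95 589
#> chi-square (Yates) = 71.2633, df = 1, p = 3.126e-17
#> chi-square (uncorrected) = 75.3081, p = 4.027e-18

glance(tss_distance_profile(ratio, ds$annotation$genes, 500))
#> # A tibble: 1 × 6
#>   spearman_rho spearman_p pearson_r pearson_p n_groups n_regions
#>          <dbl>      <dbl>     <dbl>     <dbl>    <int>     <int>
#> 1       -0.665   3.21e-65    -0.177 0.0000712      500      4000

glance(apa(ds$contacts$treated,
           ds$loops$treated[ds$loops$treated$probability > 0.95, ]))
#> # A tibble: 1 × 4
#>   apa_score n_loops_used n_loops_dropped window
#>       <dbl>        <int>           <int>  <int>
#> 1      2.95          349              14     10
```

Reading the output: 35 of the 400 simulated loops are called gained and
37 lost (the planted differential loops, recovered exactly by the
0.95/0.8 rule); busy anchors overlap differential loops far more often
than normal anchors (24/34 versus 95/684, chi-square p ≈ 3×10⁻¹⁷); the
DSB ratio falls with distance from the nearest TSS (Spearman ρ = −0.665
across 500 ratio-ordered bins); and the planted loop pixels aggregate to
an APA score of ≈ 3, matching the generator's peak factor.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(distance profile, APA matrix, class fractions, TSS meta-profile).
`run_pipeline(pipeline_config(seed = 7), "outdir")` runs every stage end
to end, writes all intermediates in standard text formats (bedGraph,
BED, BEDPE, TSV, triplet contact text) and a JSON report;
`inst/scripts/run-pipeline.R` wraps it for shell use.

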