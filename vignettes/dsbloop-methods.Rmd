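---
title: "Methods: DSB quantification, differential loops, and the synthetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSB quantification, differential loops, and the synthetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dsbloop` quantifies how DNA double-strand breaks (DSBs) induced by folate
deficiency relate to 3D-genome reorganization: where breaks accumulate,
which chromatin loops are gained or lost, whether interaction hubs are
preferentially displaced, and which genes carry converging evidence of
DSB, loop and expression change. This vignette documents the models and
procedures, the parameters that matter, the synthetic generator that the
test suite validates the pipeline against, and the numerical choices made
where the underlying conventions were genuinely open.

## The DSB ratio model

Breakpoint sites are counted into fixed bins by their 5' coordinate; the
analysis resolution is 5 kb. For bin $i$ with treated count $t_i$,
control count $c_i$ and library sizes $T$, $C$, the DSB ratio is

$$ r_i = \frac{10^6\, t_i / T + c_0}{10^6\, c_i / C + c_0}, \qquad c_0 = 0.5 .$$

CPM normalization makes $r_i$ exactly invariant to global library
scaling; the pseudocount keeps it finite at empty bins. Three genome-wide
summaries are emitted because "average fold change" is ambiguous for a
ratio track: the mean of per-bin ratios, the median of per-bin ratios,
and the ratio of raw library totals. The mean of per-bin ratios is biased
upward at low counts (Jensen's inequality: $E[1/(X+c_0)] > 1/E[X+c_0]$),
so under a true null it sits above 1 by an amount that grows as
background coverage falls; the median and the totals ratio are the
null-centered summaries, and the tests use those.

Per-bin enrichment is an upper-tail hypergeometric test
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$ with population $N$ =
pooled reads of both samples, marked $K$ = treated reads, draws $n$ =
reads in the bin, successes $k$ = treated reads in the bin. Several
parameterizations are consistent with a spreadsheet-style hypergeometric
call; this one is isolated behind `hypergeom_bin_test()` so it can be
swapped wholesale. Enrichment regions are maximal runs of adjacent bins
that pass Benjamini–Hochberg FDR $q < 0.05$ *and* fold $\ge 2$ — both
thresholds are conventional defaults, exposed in `pipeline_config()`,
because no canonical values exist for this assay.

Multi-scale context uses non-overlapping-window median smoothing from
5 kb to 1000 kb in 5 kb steps; the median of an even-sized window is the
mean of its two central values, and trailing partial windows use the
values they have.

## Stratified correlation analyses

*TSS distance.* Each bin's representative point is its **median
nucleotide**, `start + floor((end - start - 1)/2)` (lower median on even
lengths — a deterministic tie rule). Distance is measured to the nearest
TSS on the same chromosome; whether "distance from TSS" should use the
nearest or an assigned gene is not a settled convention, and
nearest-TSS is this package's documented choice. Bins on gene-free
chromosomes are excluded. Bins are sorted by descending ratio, cut into
500 equal-count groups (sizes differ by at most one, larger groups
first, ties broken by genomic order), and Spearman/Pearson correlations
are computed on the 500 group means.

*Ratio classes.* The same sorting cut into ten classes gives the
promoter/enhancer content analysis: a bin "contains" an element if they
share at least 1 bp (not midpoint containment). *Enhancer proximity*
follows a 20 kb edge-to-edge rule: an active enhancer is proximal if a
TssA segment lies within 20 kb (an overlap is distance 0; exactly 20 kb
is proximal). Group comparisons use Wilcoxon rank-sum tests
(`stats::wilcox.test`: exact for small untied samples, otherwise the
normal approximation with continuity and tie correction).

*TSS meta-profile.* ±5 kb around each TSS in 100 bins of 100 bp,
RPKM-like units (reads per kb per million mapped sites), minus-strand
genes flipped so profiles read 5'→3', averaged over genes; genes whose
window leaves the chromosome are dropped.

## Differential loops, busy anchors, APA

Loops arrive as BEDPE with a calling probability; anchors are snapped
down to the 10 kb grid and matching across conditions requires exact
snapped-bin identity (a `slack` option exists but defaults to 0, since no
matching tolerance is standard). A loop absent from one condition carries
probability 0 there — an uncalled loop is an uncalled loop. The
differential rule is strict: gained means $p_\text{treated} > 0.95$ and
$p_\text{control} < 0.8$; lost is the mirror image. Swapping condition
labels swaps gained and lost exactly.

Anchors recurring in $\ge 2$ loops are busy. The busy-anchor association
is a 2×2 chi-square (anchor status × differential-loop membership) with
Yates continuity correction, mirroring the default of the standard
contingency-table implementations; the uncorrected statistic is also
reported. One interpretive caveat documented here deliberately: because a
busy anchor touches more loops, its probability of overlapping *some*
differential loop exceeds a normal anchor's even when each loop's
differential status is independent of anchor status — the anchor-level
test measures association including this exposure effect, which is part
of the question as posed (are hubs preferentially displaced?), not a bug
of the statistic. The chi-square itself is verified to be calibrated on
independently sampled tables.

DSB–anchor colocalization counts 5 kb bins (the unit could equally be
regions or reads; bins were chosen and are stated): the 2×2 table over
all bins of membership in a differential anchor versus a DSB enrichment
region, with the same corrected chi-square.

APA extracts the $(2w+1)^2$ observed submatrix around each loop pixel
($w = 10$ bins), divides pixel-wise by the distance-expected contact (the
mean count at each diagonal offset over the whole matrix), averages
across loops, and scores center over the mean of the 3×3 lower-left
corner — the standard convention when the upstream tool draws the plot
but prints no score. Loops closer than $3w$ bins or with windows leaving
the matrix are dropped and counted.

## Integration

Gene-to-anchor and gene-to-compartment assignment uses the TSS, not the
gene body (consistent with the DSB-region gene rule "TSS inside a
region"). Expression–DSB coupling filters to genes with FPKM > 1 in the
correlated condition (treated by default), ranks by the ratio at the
TSS-containing bin, cuts into 100 equal-count groups and reports the
Pearson correlation of the group means. Compartment bins classify by PC1
sign pairs — (+,+) stable A, (+,−) A-to-B, (−,+) B-to-A, (−,−) stable B —
with zero or missing PC1 mapped to *undefined* rather than forced to a
sign. DEG enrichment per class is the same upper-tail hypergeometric.
Under nested hierarchical TADs a bin or gene takes the *deepest* covering
level. The multi-evidence intersection uses exclusive (upset) semantics,
so combination counts sum to the union size; the candidate list is the
genes present in every designated set (DSB change ∧ loop change ∧
expression change by default). The precise gene-level definitions behind
such multi-way diagrams vary between studies, so the collection is
generic and the defaults are presets.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated, with planted ground truth for
every stage. One master seed is split into named substreams (genome,
DSB, loops, contacts, expression), so outputs are byte-identical across
runs and each stage is reproducible in isolation.

**Genome and annotation.** Two 10 Mb chromosomes; 300 genes placed
uniformly with distinct TSSs and bodies inside the chromosome; each TSS
gets a 1 kb TssA segment; 200 1 kb EnhA1/EnhA2 segments fall uniformly in
non-promoter space; the remainder is Quies/low, so states partition each
chromosome. Repeats are drawn for four subtypes. Baseline expression is
lognormal (meanlog 1, sdlog 1) and is drawn at the genome stage so DSB
rates can couple to it.

**DSB counts.** Control rate per 5 kb bin:
$\lambda_c = \lambda_0 (1 + \beta\,\text{enh})\, e^{-d/\tau} + \lambda_f$
with $\lambda_0 = 20$ reads/bin, enhancer boost $\beta = 1$, decay length
$\tau = 50$ kb against the nearest-TSS distance $d$, and floor
$\lambda_f = 2$. The treated rate multiplies this by

$$ m = 1 + (f - 1)\,\max\!\big(e^{-d/\tau} \cdot a,\ \text{enh}\big), $$

with treatment fold $f = 5$. The activity factor $a$ equals the nearest
gene's expression level relative to the gene mean (clamped at 10×,
renormalized to mean 1) **at promoter bins**, and 1 elsewhere. This is
the transcription-coupled-damage picture — Pol II stalling concentrates
the break excess at the promoters of highly expressed genes — and it is
what lets three observed structures coexist exactly as they do in real
data: a continuous negative ratio-versus-TSS-distance relation, elevated
ratios at both proximal and distal enhancers, and a strong binned
correlation between expression and DSB enrichment. (An earlier
rank-based coupling was rejected at design time: with lognormal
expression, group-mean FPKM is exponential in the rank while enrichment
is linear, capping the binned Pearson correlation near 0.78 regardless
of noise.) The mean of $a$ is 1, so the average promoter fold stays $f$.
Counts are Poisson by default; a negative-binomial size parameter is
available for overdispersion robustness checks. Setting $f = 1$,
$\tau = \infty$, or the coupling weight to 0 produces the corresponding
null regimes.

**Loops.** 400 loops per condition at 10 kb; 30% attach to hub anchors
(each hub serving ~3 loops, hence busy); every non-hub endpoint is a
globally fresh bin, so busy status equals the planted hub structure
exactly. A loop is planted differential with probability 0.4
(hub-anchored) or 0.1 (normal); differential loops get probabilities
drawn uniformly inside the rule's decision regions — $U(0.95, 1)$ on the
high side, $U(0, 0.8)$ on the low side — so threshold behavior is
unambiguous and the caller recovers the planted truth exactly; all other
loops sit in $U(0.95, 1)$ in both conditions. With probability 0.8 a
differential loop's free anchor is relocated into a top-decile
DSB-multiplier bin, planting the DSB–anchor colocalization. Anchor
separations are 350 kb–2.5 Mb so APA windows fit.

**Contacts.** Expected count $c/(d^\alpha + 1)$ at bin separation $d$
with $\alpha = 1$, scaled so a matrix totals 2×10⁶ expected reads,
multiplied by peak factor $\kappa = 3$ at the pixels of the condition's
high-probability loops, Poisson sampled, stored upper-triangular.

**Expression.** Genes whose TSS falls in a gained anchor get +1 log2 fold
in the treated condition, lost anchors −1 (opposing anchors cancel), with
lognormal noise (sd 0.25 log2) on both conditions; the DEG flag marks
exactly the planted effects.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: read-level artifacts (mappability, GC,
duplicates), biological replicates and their dispersion, inter-chromosomal
loops, compartment-scale PC1 structure (compartment classification is
tested on constructed tracks instead), TAD nesting (likewise), copy-number
and structural variation, and any coupling between repeats and breaks
(repeat placement is uniform, a deliberate null).

## Problem sizes and numerical choices in the test suite

The suite validates recovery at the generator's study conditions (two
10 Mb chromosomes, 4000 bins, 400 loops, seed 7) and calibration at the
null configurations: 400-replicate null panels run on a reduced
single-chromosome genome (10 Mb, 100 genes) to keep the full suite fast;
statistical thresholds are unchanged by the reduction. Exact oracles
cover the hypergeometric tail (full grid of margins ≤ 60 against direct
binomial-coefficient summation) and the 2×2 chi-square (all tables with
margins ≤ 50 against the expected-counts formulation, plus spot checks
against `stats::chisq.test`). Determinism is asserted byte-for-byte on
the full pipeline's outputs; no timestamps enter any output file.

Remaining numerical conventions, stated once: 0-based half-open
coordinates everywhere internally (BED-native, converted at readers);
trailing partial genome bins are kept so binning is a partition;
descending sorts break ties by genomic order (stable, reproducible);
equal-count groupings put the larger groups first; compartment PC1 of
exactly 0 is undefined; degenerate contingency margins return `NA`
p-values rather than errors, with the table still reported.

## Limitations

Single-replicate design: the ratio and its tests treat one treated and
one control library, as the assay produces; no dispersion estimation is
attempted. The hypergeometric per-bin test inherits the read-sampling
assumptions of that family (independent draws, fixed margins) and is
anti-conservative under overdispersion — the enrichment-region thresholds
are therefore conjunctive (FDR *and* fold). APA scores depend on the
expected model; the distance-mean expected used here is standard but
sensitive to sparse far-diagonal coverage, which the minimum-separation
filter mitigates. The multi-evidence candidate list is only as sharp as
the gene-level definitions fed into it.
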