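---
title: "Models and methods behind phasekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`phasekin` turns DNA methyltransferase induction time courses into
quantitative descriptions of nucleosome phasing and transcription-factor
dynamics. This vignette documents the models, the numerical choices, and
what the synthetic-data generator does and does not emulate — the
information a user needs to judge what a passing test suite implies about
real data.

## Kinetic model

Every methylation target site (GATC for Dam, CG for M.SssI) is assumed to
be methylated as a pseudo-first-order process once the enzyme is induced:
the methylated fraction follows `f(t) = 1 − (1 − f0)·e^(−kt)`, so
`ln(1 − f)` is linear in time with slope `−k`. The per-site apparent rate
constant `k` (units: per minute) is the accessibility observable; it
conflates intrinsic accessibility with enzyme concentration, which is why
normalization (below) matters.

Estimation is ordinary least squares of `ln(1 − f)` on time, with two
guards against saturation:

* fractions above a cap (default 0.99) are set to the cap, and
* of consecutive points exceeding the cap only the first is retained —
  later points carry no kinetic information and would otherwise drag the
  slope toward zero.

Sites with fewer than `min_points = 3` usable observations are flagged
unestimable and excluded downstream: two points determine a line exactly,
so a third is the minimum for the fit (and its R²) to mean anything.
`t = 0` observations participate when present; the intercept absorbs any
pre-induction background. Natural logarithms throughout; `log1p(−f)` is
used for numerical accuracy near `f = 0`.

## Normalization

The methylation rate is proportional to enzyme concentration, which
differs between strains and constructs. Two references are implemented:

* **mtDNA median** (Dam mode, default): mitochondrial DNA is not
  assembled into nucleosomes, so its methylation rate tracks enzyme
  exposure rather than chromatin. The reference is the median of per-site
  `k` over mtDNA sites. An alternative `median_trajectory` mode fits the
  kinetic model to the per-timepoint *median* mtDNA fraction; both modes
  agree on homogeneous data, and the per-site median is the default
  because it is robust to sparse or missing timepoints at individual
  sites.
* **Genome median** (CG mode): the median fraction over *all* sites
  (nuclear, mitochondrial, plasmid) is taken at each timepoint and the
  kinetic model is fitted to that median trajectory.

Normalized rates are dimensionless ratios; by construction the mtDNA
median ratio is 1 in mtDNA mode. All downstream quantities are invariant
under a global rescaling of rates.

## Decaying sine wave phasing model

Normalized rates are aligned on the +1 nucleosome dyad of each gene
(strand-aware: positive offsets run into the gene body), averaged per
integer offset, and the raw per-offset means over `x ∈ [−50, 1000]`
(1051 points) are fitted with

```
y(x) = A·e^(−λx)·sin(ωx + θ) + kx + b
```

Interpretation of the six parameters: `2π/ω` is the average nucleosome
spacing (bp); `A` the phasing amplitude at the +1 dyad (rate-ratio
units); `e^(−λ·2π/ω)` the proportional amplitude decay per nucleosome
repeat (how quickly phasing fades down the gene); `1000·k` the change in
mean rate per kb; `b` the baseline at the dyad. Derived reporting adds the
adjusted mean rate — the mean of the fitted curve over the window — and
the adjusted R², `1 − (SSR/SST)(N−1)/(N−7)` for the 6-parameter model, so
a perfect fit scores exactly 1 and overparameterization is penalized.

Numerical choices:

* **Optimizer**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  analytic residuals and Jacobian, `ftol = ptol = 1e−14`.
* **Multi-start**: the objective is multimodal in the period, so the fit
  restarts from a fixed grid — periods 140–200 bp in 5-bp steps crossed
  with phases `{−π/2, 0, π/2, π}` — and keeps the lowest SSR. The grid is
  deterministic, so refits are bit-reproducible. Starts stop early once a
  fit reaches SSR below `1e−14·SST` (numerically perfect).
* **Bounds**: the period is constrained to `[120, 220]` bp, bracketing
  every plausible yeast nucleosome spacing with margin; `A ≥ 0` and
  `λ ≥ 0` resolve the sign/phase degeneracy; `θ` is free in `(−π, π]`
  with no penalty forcing a trough at `x = 0`.
* **Degenerate inputs**: an essentially flat profile returns `A ≈ 0` with
  a warning, and the per-period decay — undefined without an oscillation —
  is reported as 1.
* **Fits use the raw per-offset means.** The 21-bp box smoothing applied
  to exported profiles is display-only: smoothing before fitting would
  bias the amplitude downward. The smoother runs on the complete integer
  offset grid, shrinks its window symmetrically at the edges, and ignores
  offsets with no sites.

## Per-gene rates and quintiles

The simple mean of a gene's site rates is biased by where its sites
happen to sit on the phasing curve. The bias is estimated from the
population fit: `bias = mean(curve at the gene's offsets) − population
curve mean`, and the reported unbiased rate is `raw mean − bias`,
anchored at the population mean so per-quintile values are directly
comparable with the population's adjusted mean rate. The deviation mean
is site-weighted (each site counts once; no per-offset binning within a
gene). Genes need at least `n_min = 5` sites in the window to be ranked —
below that the mean deviation is noise-dominated; the threshold is a
flag, and unranked genes are still reported.

Quintiles: ascending sort by unbiased rate, ties broken by gene id
(deterministic), five groups with sizes differing by at most one (the
earlier groups take the remainder). Q1 is slowest. The sine model is then
refit to the combined per-offset means of each quintile's genes.

## tRNA transcription-factor regions

TFIIIB occupies `−56..−13` relative to the TSS and TFIIIC `−2..end+10`,
excluding the intron where present. These published coordinates are read
as 1-based positions with the TSS as `+1` (there is no position 0) and
converted internally to 0-based half-open genomic intervals — e.g. a
plus-strand gene with TSS at 0-based 500 gets TFIIIB `[444, 488)`. The
Pol III terminator's protection is subsumed in the `+10` extension; no
separate terminator class is defined. TFIIIB spans are always 44 bp;
TFIIIC spans sum to gene length + 12 − intron length.

The TSS-aligned rate map uses 0-based offsets (TSS = 0). A gene of length
L contributes offsets `0..L−1`, so with most tRNA genes 72 bp long the
`+72..+99` band is covered only by longer genes; it is masked wherever
fewer than `min_genes_per_offset = 10` genes contribute (an SD over fewer
genes is not meaningful). From `+100` on, the map switches to a
downstream frame anchored at each gene's end (`position = end + offset −
72`), so downstream flanks line up across gene lengths.

## The synthetic-data generator

The generator is the package's ground-truth oracle. It emulates:

* coding genes on both strands (balanced), one per 2700-bp slot, +1 dyads
  jittered ±20 bp, arranged so each site maps to at most one gene;
* a gene-body rate landscape given by the sine model above, evaluated at
  the site's dyad-relative offset and multiplied by the mtDNA rate;
  offsets outside `[−50, 1000]` take the nearest window-edge value
  (the fitted landscape is not extrapolated);
* a promoter NDR at `−180..−80` from the dyad (typical yeast NDR span;
  the window is a config knob) methylated `ndr_rate_factor = 1.3×` the
  mtDNA rate, emulating fast NDR methylation;
* a circular 85.8-kb mtDNA at exactly the control rate `mt_rate`
  (default 0.005/min, which keeps all fractions below the 0.99 cap over
  a 240-min time course), plus optional plasmid;
* tRNA genes with TFIIIB/TFIIIC/intron subregions at 0.9×, 1.35× and
  1.8× the control rate (so TFIIIC/TFIIIB = 1.5 and intron/TFIIIB = 2);
* sites at jittered intervals (~256 bp emulates GATC density, ~16 bp CG
  density);
* first-order time courses at `t = 30, 60, 120, 240` min, noise-free or
  binomially sampled at a configurable coverage;
* DpnI-style fragments: cuts between the A and T of methylated GATCs,
  cut ends losing their terminal base with probability 0.1, fragments
  under 200 bp lost with probability 0.8.

Intergenic background sites sit at exactly the control rate. This keeps
more than half of all sites in a flat compartment, so the genome-median
reference equals `mt_rate` exactly and generating landscapes can be
expressed directly in normalized units — mirroring the convention that
the genome median defines 1 on real data.

Two-population genomes (`alt_truth_params`, `alt_gene_frac`) assign a
second landscape to a random subset of genes, which is how quintile
recovery is validated end to end.

What the generator does **not** emulate: real sequence composition
(sites are placed, not matched), replication and cell-cycle effects,
mappability artifacts, variable per-site coverage, sonication
breakpoints (the counting rule never uses them), or correlated
nucleosome positions along single molecules. Passing round trips
therefore demonstrate that the *estimators* are correct and unbiased
under the stated kinetic model — not that the model captures every
property of real chromatin. Fragment simulation linearizes circular
chromosomes at coordinate 0, so a handful of sites adjacent to the
linearization point see depressed counts; analyses of real circular
genomes should treat the junction with the same caution as a chromosome
end.

## Design decisions that were genuinely open

* **Half-site combination**: the two strand ratios are pooled (summed
  numerators over summed denominators) rather than averaged, weighting
  each strand's evidence by its coverage.
* **Coverage semantics**: coverage of a base is standard half-open
  interval coverage (`start ≤ base < end`); a fragment cut at a site
  still covers the base it ends on, which makes the count ratio an
  unbiased estimate of the methylated fraction (cut molecules appear in
  both numerator and denominator).
* **The <200 bp filter** is applied per half-site, using the distance to
  the adjacent site on the side the diagnostic fragment comes from; a
  site with one valid half-site keeps that measurement rather than being
  dropped whole. Neighbor distances are modular on circular chromosomes.
* **Capped points beyond the first are removed**, not set to the cap.
* **Sites shared by overlapping gene windows** contribute once per gene —
  each gene's alignment is independent.
* **Adjusted R²** uses the standard form with `N − 7` in the denominator,
  matching the 6-parameter model.

## Problem sizes and runtime

The test suite validates the estimators on genomes of 2000 genes
(~21,500 GATC sites or ~343,000 CG sites, chosen to give every integer
offset in the fitting window multi-site support), with smaller genomes
for fragment-level round trips and property checks; the whole suite runs
in under a minute on one core. Parameter-recovery properties use 100
random landscape draws, noise-free (every parameter recovered to 1e−4
relative) and with Gaussian noise of SD 0.05 on the profile (spacing
recovered within ±1 bp in at least 95 of 100 draws).

## Known limitations

* Rate uncertainty is not propagated into the sine fit, and no bootstrap
  intervals are provided for the fitted parameters.
* Kinetics are single-exponential; mixtures (e.g. two cell
  subpopulations) are not modeled.
* The fit weights every offset equally regardless of how many sites
  contribute to it; an option to fit raw per-site points instead of
  per-offset means is available through `fit_sine()` directly.
* BAM ingestion is out of scope: fragments enter as BED intervals.
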