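# phasekin

Methylation-kinetics analysis of nucleosome phasing and chromatin dynamics
in living cells.

## The problem

Inducibly expressed DNA methyltransferases (E. coli Dam, which methylates
GATC; M.SssI, which methylates CG) probe chromatin accessibility in vivo:
sites in linker DNA and nucleosome-depleted regions are methylated quickly,
sites buried in nucleosomes more slowly. Because the methylation rate is
proportional to enzyme concentration — which differs between strains — raw
rates are not comparable across mutants. `phasekin` implements the full
analysis chain for such induction time courses:

1. **qDA-seq quantification** — per-GATC methylated fractions from
   DpnI-generated fragment ends: molecules ending on the G or A of a GATC,
   divided by the fragment coverage of the G (and the mirror rule for
   T/C starts), with half-sites closer than 200 bp to their neighbor
   filtered out because short fragments are lost in library preparation.
2. **First-order kinetics** — per-site apparent rate constants from
   `ln(1 − fraction) = −k·t + b`, with fractions capped at 0.99 and
   saturated duplicates dropped.
3. **Internal-control normalization** — nuclear rates divided by the
   median rate of the non-nucleosomal mitochondrial DNA (Dam mode) or by
   the genome-median-trajectory rate (CG mode), cancelling enzyme-level
   differences between strains.
4. **Decaying sine wave phasing model** — normalized rates aligned on the
   +1 nucleosome dyad of each gene and fitted over offsets −50..+1000 bp
   with

   *y(x) = A·e^(−λx)·sin(ωx + θ) + kx + b*

   The period 2π/ω is the average nucleosome spacing; A the phasing
   amplitude at the +1 dyad; e^(−λ·period) the amplitude decay per
   nucleosome repeat; 1000·k the change in mean rate per kb; and the mean
   of the fitted curve over the window (1051 integer offsets) the adjusted
   mean rate. Fit quality is the adjusted R² `1 − (SSR/SST)(N−1)/(N−7)`.
5. **Per-gene rates and quintiles** — gene means corrected for how each
   gene's sites sample the population phasing curve (mean deviation from
   the fitted curve, anchored at the population mean), ranked into
   quintiles, with the sine model refit per quintile.
6. **tRNA transcription-factor dynamics** — TFIIIB (−56..−13 from the TSS)
   and TFIIIC (−2..end+10, introns excluded) footprints, per-class
   kinetics and ratios, and a TSS-aligned rate map with the +72..+99
   alignment discontinuity handled explicitly.

A first-class synthetic-data generator (`sim_config()`, `make_genome()`)
builds toy genomes with a *known* phased rate landscape — genes on both
strands, promoter NDRs, tRNA footprints, circular mtDNA, DpnI-style
fragment simulation with end trimming and short-fragment loss — so every
stage can be validated against ground truth.

## Worked example

```r
library(phasekin)

# a genome whose gene bodies follow a known phasing landscape
wt <- params_from_descriptors(spacing_bp = 166.3, amplitude = 0.39,
                              decay_per_period = 0.86, slope_per_kb = -0.12,
                              adj_mean = 0.80)
genome <- make_genome(sim_config(n_genes = 2000, seed = 1, truth_params = wt))
tc     <- genome_timecourse(genome, noise = "none")

rates  <- fit_first_order(tc)                       # per-site k from ln(1-f)
rates  <- normalize_rates(rates, mtdna_reference(rates))
phase_fit(rates, genome$genes[klass == "coding"])
```

```
phasing fit over 2000 genes
spacing 166.3 bp | amplitude 0.39 | slope/kb -0.12 | decay/period 0.86 | adj mean 0.80 | adj R2 1.00 (n=1051)
```

The refitted descriptors match the landscape the genome was generated
from: nucleosome spacing 166.3 bp, phasing amplitude 0.39 that decays to
0.86 of itself per repeat, a mean rate 0.80× the mtDNA control that falls
by 0.12 per kb along genes.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_genome.R` … `05_trna_dynamics.R`), each a thin driver over
the package functions that narrates what it finds and writes its tables
under `results/`.

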