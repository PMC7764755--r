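---
title: "Methods: isotopologue correction, label-propagation simulation, and pathway statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopologue correction, label-propagation simulation, and pathway statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirmtrace)
```

This vignette is the package's account of its models and the choices
behind them: what is computed, under which assumptions, and what the
synthetic data do and do not establish about real experiments.

## 1. Mass isotopologue distributions and natural-abundance correction

The atomic data structure is the mass isotopologue distribution (MID): the
abundances of mass shifts m+0 … m+n for a metabolite whose backbone carries
n tracer carbons. GC-MS measures the MID of a derivatized fragment, so the
measured pattern confounds tracer ¹³C with natural heavy isotopes of every
atom in the fragment — notably ²⁹Si/³⁰Si from trimethylsilyl groups, which
is why silicon appears in the packaged fragment formulas.

`build_correction_matrix()` constructs, for a fragment formula and its n
tracer carbons, the matrix whose column *j* is the convolution of the
natural mass-shift distributions of all atoms except the *j* labeled
tracer carbons (which contribute a fixed shift of +j). Two points of
definition:

* An *unlabeled* tracer carbon still carries natural ¹³C. This is the
  chemically correct convention (the unlabeled molecule's backbone carbons
  smear its pattern like any other carbon) and makes the matrix columns
  agree exactly with brute-force enumeration over all isotope assignments,
  which the test suite checks for small fragments.
* Columns are truncated at m+(n+headroom). The default headroom of 4 mass
  units accommodates the natural-isotope tail of Si-rich fragments; all
  packaged fragments lose at most 10⁻³ of column mass at this setting, and
  the packaged fragment ions of large molecules (sugar dimers, fatty
  acids, sterols) are capped at six backbone carbons and two TMS groups
  partly for this reason — quantified fragment ions of such molecules
  rarely span the full skeleton anyway.

Correction solves min‖Mx − raw‖₂ subject to x ≥ 0 (Lawson–Hanson NNLS via
`pracma::lsqnonneg`, with the measurement rescaled to unit sum first for
solver stability). NNLS is used instead of matrix inversion because
inversion can return negative isotopologues on noisy data; non-negativity
makes clipping unnecessary. The isotope abundances themselves
(`inst/extdata/isotopes.csv`) are physical constants, editable by the
user; ²H is included for completeness although its contribution is
numerically negligible. Phosphorus is carried as monoisotopic ³¹P so
phosphate-containing fragments are representable.

The enrichment conventions follow:
`fractional_enrichment()` divides each isotopologue by the metabolite's
total, and `labeled_fraction()` is 1 − f₀.

**Known limitation.** Tracer purity is treated as 100% ¹³C₆ in the
correction; no purity figure is modeled, and no correction for
ultra-high-resolution isotopomer fine structure is attempted. The
reference table's fragment formulas are documented assumptions — the
quantified ion per metabolite is not standardized — and can be replaced
wholesale via a user CSV.

## 2. The bolus and label-propagation simulator

The simulator emulates the experimental design: fasted mice, 2 g/kg
[U-¹³C]glucose by oral gavage (40 mg for a 20 g mouse in 250 µL), harvest
at 15 min, 30 min, 2 h, 4 h, n of 3–7 per group.

**Plasma glucose.** One-compartment first-order absorption/elimination
(Bateman): the bolus contributes B(t) = A(e^(−k_e t) − e^(−k_a t)) on top
of a constant unlabeled endogenous baseline, with
A = dose · Vd_scale · k_a/(k_a − k_e). All bolus glucose is fully labeled,
so m+6 = B/(baseline + B). Endogenous production is a constant unlabeled
baseline — no gluconeogenic relabeling is modeled, consistent with the
early post-prandial window the design samples. No absolute concentration
scale is asserted; concentrations are in units of
the fasting baseline, and only fractional quantities are treated as
meaningful.

**Tissue pools.** Each tissue (plasma, liver, brain) carries thirteen
metabolite pools as fractional MIDs that relax toward their influx MID
with first-order turnover, f ← (1 − λΔt)f + λΔt·f_in, using an explicit
Euler step of Δt = 0.5 min (stable for all packaged rates, trivially
reproducible; the step refuses λΔt > 1). The influx wiring follows the
central-carbon atom map:

* glycolysis halves glucose into a 3-carbon unit (m+6 → m+3), diluted by a
  per-tissue fraction γ of unlabeled carbon sources;
* pyruvate exchanges into lactate and alanine; the triose pool (GAP/3PG)
  sees the glucose-derived unit directly;
* PDH decarboxylates pyruvate to 2-carbon acetyl-CoA; citrate is the
  convolution of oxaloacetate and acetyl-CoA MIDs; α-ketoglutarate (in
  equilibrium with glutamate) is decarboxylated citrate;
* the 4-carbon pools (fumarate/malate) mix three routes with flux
  fractions φ: the PDH route (decarboxylated α-ketoglutarate, which keeps
  cycling label around the TCA loop), pyruvate carboxylase (all three
  pyruvate carbons plus an unlabeled CO₂-derived carbon), and malic
  enzyme, which attaches a carbon that is labeled with the current
  labeled-CO₂ probability and is therefore the model's source of m+1
  species;
* oxaloacetate is taken equal to malate (equilibrium), aspartate reflects
  oxaloacetate, GABA is decarboxylated glutamate, pyroglutamate tracks
  glutamate; serine is produced with one decarboxylate/re-add cycle from
  the triose unit (a modeling convenience standing in for the
  glycine/one-carbon route to m+2 serine) and glycine is decarboxylated
  serine.

A scalar labeled-CO₂ fraction relaxes toward the mean lost-label
probability of the decarboxylation steps at rate `co2_rate`.

**Mass isotopologues, not positional isotopomers.** Decarboxylation uses a
random-carbon-loss approximation, out_k = f_k(n−k)/n + f_{k+1}(k+1)/n,
with the probability that the lost carbon was labeled (Σf_k·k/n) credited
to the CO₂ pool. Real decarboxylases remove a specific carbon; the
positional information needed to do better is not recoverable from mass
isotopologue read-outs, and the approximation can distort multi-turn
m+1/m+2 ratios. This is the model's main structural simplification.

**Calibration.** The defaults returned by `calibrate_defaults()` were
fitted once, offline, by bounded coordinate search against the package's
anchor set — plasma glucose m+6 above 50% at 15 and 30 min, below
10% at 2 h and 5% at 4 h with the total-glucose peak at 15 min on the
sampling grid; plasma pyruvate and lactate m+3 near 20% at 15–30 min; a
brain neurotransmitter pathway share of 23.7% at 15 min rising to 40.4%
at 4 h — and then frozen as constants. Glycolytic turnover was pinned at
fast, physiologically sensible values (0.08–0.2 min⁻¹) and the TCA,
amino-acid and neurotransmitter rates fitted within 0.003–0.4 min⁻¹, so
that label retention at 4 h emerges from TCA-cycle recycling through the
PDH route rather than from implausibly frozen pools. The brain
neurotransmitter anchors are met to within 0.1 percentage points; the
calibration is not revisited. Tissue differences are realized solely
through γ and the λ vectors (liver fastest glycolytic pools; brain slower
serine turnover and fast glutamate exchange).

**Noise model.** `generate_sample_table()` forward-convolves pool MIDs
with each metabolite's correction matrix (natural abundance ON), scales by
a per-metabolite base abundance, a per-sample recovery factor shared with
the norvaline internal standard, and a protein mass, then applies
mean-one multiplicative log-normal noise with CV 0.15 (default) to every
ion count and to the internal standard itself. Everything is deterministic
given the seed, which is a required parameter field.

**What the synthetic data do not show.** The generator produces clean
first-order kinetics with known pathway wiring and independent log-normal
noise. It does not emulate drift, batch structure, co-elution,
deconvolution errors, missing peaks, inter-animal biological variance
beyond the noise CV, or any disease-model biology (group contrasts are
injected as explicit fold changes on pool sizes). A green suite therefore
establishes correctness of the operators and pipeline plumbing — not that
the kinetic model would fit any particular animal's data.

One behavior of real relevance does reproduce: at late time points, when
true enrichment of fast pools is near zero, non-negative correction of
noisy patterns can only inflate the labeled fraction, which biases
pathway shares computed from small labeled fractions (visible in the
`analysis/03` driver as the gap between noisy and noise-free donuts at
4 h). Interpret late-time shares of weakly enriched pathways with care.

## 3. Pathway distribution and surrogate activities

`pathway_distribution()` reads "average enrichment per pathway" as the
unweighted arithmetic mean of the labeled fractions of a pathway's
metabolites — not abundance-weighted — expressed as a percent of the sum
across pathways. Shares always total 100%, and adding an unlabeled
metabolite to a pathway dilutes that pathway's share (both are tested).
The packaged representative panel is: glycolysis — GAP/3PG, pyruvate,
lactate, alanine; TCA — citrate, fumarate, malate; amino acids — serine,
glycine; neurotransmitters — glutamate, aspartate, GABA, pyroglutamate.
Glutamate and aspartate are deliberately assigned to the neurotransmitter
pathway (single-assignment map, user-overridable). Because the per-animal
versus pooled question is genuinely open, the pipeline
computes per-animal shares and then averages them.

`enzyme_surrogates()` returns the ratios citrate m+2 / pyruvate m+3 (PDH)
and citrate m+3 / pyruvate m+3 (PC). Both MIDs are normalized internally,
so raw counts and fractions give identical answers. A zero pyruvate m+3
is an error ("undefined surrogate") rather than a silent 0 or infinity;
the pipeline driver drops such samples from group means with a note.
These are activity surrogates, not fluxes — no metabolic flux analysis is
attempted.

## 4. Pool-size statistics

Total pools (sums of corrected isotopologue counts) are divided by the
L-norvaline internal-standard abundance and the protein input.
`iqr_filter()` drops the lowest-IQR fraction of metabolites (default 0.1;
the threshold itself is a package choice), with ties
broken lexicographically for reproducibility. `autoscale()` mean-centers
and unit-variance-scales each metabolite; a log transform is available
but off by default.

Group comparisons are unpaired, two-tailed t-tests in the Welch
(unequal-variance) form — the safer default where group variances are not
known to match, with a pooled-variance flag — corrected by the two-stage
linear step-up procedure of Benjamini, Krieger and Yekutieli at Q = 1%:
BH at q′ = Q/(1+Q) gives r₁ rejections; if 0 < r₁ < m, BH is rerun at
q′·m/(m−r₁). The procedure never rejects fewer hypotheses than plain BH
at Q, and simulation tests confirm realized FDR ≤ Q on null and mixture
panels. Both raw p-values and BKY decisions are reported, so either
threshold convention can be applied downstream. Volcano inputs (log2 fold change, −log10 p) come from the same
table — a single code path. PCA is the singular value decomposition of
the auto-scaled matrix with a fixed sign convention (largest-magnitude
loading positive per component).

## 5. Problem sizes

The packaged study design is 3 tissues × 4 time points × n = 4–7, 80
metabolites (15 with simulated enrichment), headroom 4 — about 40,000
table rows and a few thousand NNLS solves per full pipeline run, well
under a minute. The deterministic simulations behind the calibration
anchors integrate 480 Euler steps per tissue. The FDR simulations in the
test suite use 80-row panels over 500 replicates. These sizes were chosen
as comfortable desk-scale defaults that still exercise every code path.
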