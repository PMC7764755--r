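# sirmtrace

Stable isotope-resolved metabolomics (SIRM) analysis of an oral
[U-¹³C]glucose bolus in mice, with a calibrated synthetic-data generator so
the entire workflow runs at desk scale with no external data.

## The problem

In vivo SIRM delivers a ¹³C-labeled substrate — here a 2 g/kg oral glucose
gavage, the standard glucose-tolerance-test dose (40 mg for a 20 g mouse) —
and reads out, by GC-MS, how the label distributes across central-carbon
metabolites in plasma, liver and brain at 15 min, 30 min, 2 h and 4 h
post-gavage. Turning raw ion counts into biology requires a chain of
computations that this package implements end to end:

* **Natural-abundance correction.** A measured mass-shift pattern of a
  derivatized fragment confounds tracer ¹³C with natural heavy isotopes
  (¹³C, ²⁹/³⁰Si from TMS groups, ¹⁸O, ...). For a fragment with *n* tracer
  carbons the package builds the correction matrix **M** whose column *j*
  is the predicted measured pattern of a molecule carrying exactly *j*
  tracer atoms, and recovers the tracer-only mass isotopologue distribution
  (MID) *x* by non-negative least squares,
  min‖**M**x − raw‖₂ s.t. x ≥ 0, so noise can never produce negative
  isotopologues.
* **Fractional enrichment and labeled fraction.** fᵢ = aᵢ/Σⱼaⱼ and
  1 − f₀ = Σ_{i≥1} fᵢ.
* **Pathway-distribution analysis** ("donuts"): per pathway, the unweighted
  mean labeled fraction of its representative metabolites, as a percent of
  the sum across pathways (glycolysis, TCA, amino acids,
  neurotransmitters).
* **Enzyme-activity surrogates**: PDH = citrate m+2 / pyruvate m+3,
  PC = citrate m+3 / pyruvate m+3 — ratios, not fluxes.
* **Pool-size statistics**: totals normalized to the L-norvaline internal
  standard and protein input, IQR filtering, auto-scaling, Welch t-tests
  with the two-stage Benjamini–Krieger–Yekutieli FDR procedure (Q = 1%),
  volcano inputs and PCA.
* **A kinetic simulator**: Bateman absorption/elimination of the bolus,
  atom-mapped label propagation (glycolysis halves glucose into m+3
  triose; PDH decarboxylates pyruvate; citrate is the convolution of
  oxaloacetate and acetyl-CoA MIDs; pyruvate carboxylase keeps all three
  carbons; malic enzyme plus labeled CO₂ generates m+1 species), with
  per-tissue turnover rates calibrated once against a fixed set of
  time-course anchors and then frozen.

## Worked example

```r
library(sirmtrace)

params <- calibrate_defaults()
dose_for_bodyweight(20, 2)
#> [1] 40                                  # mg tracer per 20 g mouse

plasma_glucose_timecourse(params, c(0, 15, 30, 120, 240))
#> # A tibble: 5 x 3
#>   time_min total_glucose m6_fraction
#>      <dbl>         <dbl>       <dbl>
#> 1        0          1            0
#> 2       15          2.58         0.613
#> 3       30          2.08         0.519
#> 4      120          1.09         0.0799
#> 5      240          1.00         0.00301
```

Total plasma glucose peaks at 15 min at ~2.6× the fasting baseline; 61% of
plasma glucose is fully labeled (m+6) at 15 min, falling below 10% by 2 h
and below 1% by 4 h. Downstream, the deterministic pool model gives the
brain pathway distribution:

```r
sim <- simulate_pools(params, "brain", c(15, 240))
panel <- representative_panel()
lf <- pool_labeled_fractions(sim, panel$metabolite_id, 15)
pathway_distribution(setNames(lf$labeled_fraction, lf$metabolite_id),
                     load_pathway_map())
#> # A tibble: 4 x 3
#>   pathway           mean_labeled_fraction share_pct
#>   <chr>                             <dbl>     <dbl>
#> 1 amino_acids                      0.0714      16.1
#> 2 glycolysis                       0.136       30.7
#> 3 neurotransmitters                0.106       23.8
#> 4 TCA                              0.131       29.4
```

At 15 min the label is spread across all four pathways
(neurotransmitters 23.8%); by 4 h the neurotransmitter share rises to
40.5% while glycolysis collapses with the cleared bolus. The same
operators applied to noisy simulated GC-MS tables, and the pool-size
statistics, are demonstrated in the numbered drivers under `analysis/`
(run them in order; summary tables land in `results/`).

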