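# hetg — reciprocity under hidden endowments

`hetg` is an analysis pipeline for a hidden-endowment variant of the
Trust Game. In the standard game an Investor with endowment *E* transfers
an investment *I*, which is multiplied by *M* = 4; the Trustee then
returns some share of the pot *I·M*. In the hidden-endowment variant the
Trustee never sees *E* — only *I* and three candidate endowments — so
before deciding how much to reciprocate they must first *impute* how much
trust (*I/E*) was bestowed. The package quantifies how that ambiguity is
resolved, for researchers in social decision-making and computational
cognitive modelling.

The analysis chain:

1. **Reciprocity model.** Returns follow an inequity-aversion rule,
   `R2 = max(0, (E − I + I·M)·Δ − (E − I))`, with fairness norm
   Δ ∈ [0, 1] fitted per participant by 101-point grid search on the 40
   unambiguous trials (`fit_delta_cohort()`).
2. **Reverse inference.** On the 80 ambiguous trials the fitted rule is
   inverted exactly, `E = (R2 − I − 3·I·Δ)/(Δ − 1)`, clamped to the
   displayed candidates, with zero returns flagged as censored
   (`infer_endowments()`).
3. **Strategy model.** Candidate endowments are scored by
   `p2(E) = (1 − |I/E − τ|)(1 − ψ) + (1 − |I/E − I/10|)·ψ`; the free
   parameters (τ, ψ) are fitted on a 101 × 101 grid and compared against
   four fixed archetypes — Highest/Lowest Assumed Trust (τ = 1 / τ = 0),
   Modal Trust (τ = 0.5) and a magnitude Heuristic (ψ = 1)
   (`fit_ars_cohort()`).
4. **Model selection.** Models are scored with
   `AIC = n·ln(SSE/n) + 2k`, compared with one-tailed paired t-tests and
   paired Cohen's *d*, and each participant is classified into a strategy
   (`score_models()`, `compare_paired()`, `classify_strategy()`,
   `cohort_report()`).

A synthetic-data module (`simulate_cohort()`) generates trustees with
known (Δ, τ, ψ) and pot-scaled response noise, so the whole chain is
validated by parameter recovery. See the methods vignette
(`vignettes/hetg-methods.Rmd`) for the model assumptions, the estimator
construction and every numerical design choice.

## Worked example

Run the full pipeline on the default synthetic cohort — 34 agents in a
24/8/2 Modal-Trust/Lowest-Assumed-Trust/Highest-Assumed-Trust mixture,
fairness norms drawn from [0.3, 0.7], response noise 0.05 of the pot:

```r
library(hetg)
cfg <- run_config(seed = 1, outdir = "hetg-run")
res <- run_pipeline(cfg)
print(res$report)
```

which prints (abridged):

```
Mean AIC by model (lower is better):
 model   mean_aic    sd_aic  n
   ARS -169.98388 68.827092 30
    MT -129.55173 85.987831 30
   LAT  -37.50666 77.911010 30
    HR  -27.97825  8.413071 30
   HAT  -21.38496 60.592690 30

ARS vs single-strategy models (one-tailed paired t):
 model_a model_b t_statistic df      p_value cohens_d n_pairs
     ARS     HAT  -10.311763 29 1.636939e-11 1.882662      30
     ARS     LAT   -7.904332 29 5.106452e-09 1.443127      30
     ARS      MT   -2.361807 29 1.255749e-02 0.431205      30
     ARS      HR  -11.247019 29 2.150285e-12 2.053415      30

Strategy prevalence (classified ARS fits):
 strategy count percent
      LAT     8    23.5
       MT    24    70.6
      HAT     2     5.9
       HR     0     0.0

Recovery vs ground truth:
  n strategy_accuracy median_abs_delta_error
 34                 1                   0.01
```

Reading the output: the two-parameter ambiguity-resolution (ARS) model
attains the lowest mean AIC, the Modal Trust archetype is the best of
the four single-strategy models, every synthetic agent is classified
back to its generating strategy (`strategy_accuracy` 1), fairness norms
are recovered to the grid step (median |Δ̂ − Δ| = 0.01), and the
prevalence table reproduces the generating 71%/23%/6% mixture. Four
participants whose behaviour some model predicts perfectly (SSE = 0, AIC
= −∞) are excluded from the AIC summary and the paired tests, which is
why n = 30. All stage artifacts (design, choices, fits, inferences,
scores, comparisons, report) are written to `hetg-run/` as CSV.

The same pipeline is available from the shell:

```sh
./exec/hetg run-all --seed 1 --outdir hetg-run
./exec/hetg design --seed 1 --outdir run2   # or stage by stage
```

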