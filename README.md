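# ddxbayes

Probabilistic differential diagnosis over a curated symptom–disease
knowledge base, with the complete evaluation protocol used to validate
such engines against gold-standard clinical vignettes.

The package is aimed at clinical-decision-support researchers who want a
transparent, fully reproducible baseline: a Bayesian ranker whose only
parameters are expert-curated association weights (no training data), and
an evaluation battery — top-3 accuracy, per-disease and
frequency-weighted precision/recall, Jaccard and cosine similarity of
ranked differentials, upper-tailed Welch *t* tests — stratified by how
specific each case's presentation is. Because real curated knowledge
bases and expert-written vignettes are rarely publishable, the package
also ships a synthetic study generator with planted ground truth and
simulated noisy raters, so the entire protocol can be exercised end to
end.

## The model

The engine treats diagnosis as multiclass classification over a closed,
exhaustive disease set *D*. A knowledge base supplies disease priors
π<sub>d</sub> (prevalence weights) and association weights
*w*(*s*, *d*) ∈ [0, 1], read as *P*(symptom *s* present | disease *d*).
Given coded findings *f*₁…*f*ₙ (symptom + present/absent polarity),
assumed conditionally independent given the disease (naive Bayes), the
posterior is

> *P*(*d* | *f*₁…*f*ₙ) ∝ π<sub>d</sub> ∏ᵢ *P*(*f*ᵢ | *d*)

with *P*(present | *d*) = clamp(*w*(*s*, *d*), ε, 1−ε), ε = 10⁻⁶, and
*P*(absent | *d*) its complement; the clamp guarantees no single finding
can zero out a disease. Accumulation is in log space. The posterior's
top *k* (default 3: one primary + two differential diagnoses) is
renormalized and converted to integer percentage sureties by
largest-remainder rounding, so every emitted differential sums to
exactly 100.

Symptoms a case never mentions are treated as unobserved, not absent.
Unknown symptom codes are skipped and counted in the posterior's
provenance.

## Worked example

```r
library(ddxbayes)

kb <- load_knowledge_base(system.file("extdata", "fever15_synthetic_kb.json",
                                      package = "ddxbayes"))
kb
#> <ddx_kb> 15 diseases x 60 symptoms
#> diseases: d01, d02, d03, d04, d05, d06, d07, d08 ...
#> symptoms: s01, s02, s03, s04, s05, s06, s07, s08 ...

# a 90-vignette study (15 diseases x 3 specificity strata x 2 per cell)
vs <- generate_study(kb, generator_config(seed = 7))
v <- vs$vignettes[[1]]
v
#> <ddx_vignette> v-d01-high-01 [high] 3 finding(s); gold primary: d01

diagnose(kb, v, k = 3)
#> <ddx_differential> k = 3
#>  disease_id rank surety
#>         d01    1    100
#>         d07    2      0
#>         d12    3      0

ev <- evaluate_study(vs, list(
  model     = diagnose_set(kb, vs),
  `rater-1` = simulate_rater(kb, vs, rater_config("rater-1", 0.3, 0.3, seed = 11))))
ev
#> <ddx_eval> 2 source(s), k = 3
#>   source  stratum  n top3_accuracy precision_aggregate recall_aggregate jaccard_mean cosine_mean
#>    model     high 30         1.000               1.000            1.000        1.000       1.000
#>    model moderate 30         0.700               0.410            0.467        0.850       0.951
#>    model      low 30         0.400               0.041            0.100        0.700       0.941
#>    model  overall 90         0.700               0.752            0.522        0.850       0.964
#>  rater-1     high 30         0.767               0.844            0.767        0.610       0.767
#>  rater-1 moderate 30         0.600               0.375            0.433        0.617       0.761
#>  rater-1      low 30         0.333               0.011            0.067        0.470       0.660
#>  rater-1  overall 90         0.567               0.483            0.422        0.566       0.729
#>
#> Model vs pooled raters (upper-tailed Welch t):
#>         metric source_a source_b statistic    df  p_value n_a n_b
#>  top3_accuracy    model  rater-1     1.864 176.9 3.20e-02  90  90
#>   jaccard_mean    model  rater-1     7.097 166.3 1.76e-11  90  90
#>    cosine_mean    model  rater-1     6.215  95.1 6.77e-09  90  90
```

Reading the output: on a vignette with a highly specific (near
pathognomonic) presentation the engine puts essentially all surety on
the planted disease. Over the whole study, accuracy falls monotonically
from highly specific to nonspecific presentations — the engine's top-3
accuracy here drops from 1.00 through 0.70 to 0.40 — and the engine
beats the simulated 30%-error rater on every similarity metric, with the
upper-tailed Welch *t* test quantifying the gap on per-vignette scores.

The packaged `fever15_synthetic_kb.json` is a *synthetic* illustrative
15-disease febrile-illness knowledge base (invented weights, placeholder
names); it demonstrates formats and behavior, not medical content.

## Command line

A thin wrapper over the same functions, for shell pipelines:

```sh
ddx=$(Rscript -e 'cat(system.file("cli", "ddx.R", package = "ddxbayes"))')
Rscript "$ddx" simulate --config config.yaml --out-dir runs/sim1
Rscript "$ddx" diagnose --kb runs/sim1/kb.json --vignettes runs/sim1/vignettes.jsonl --out preds.jsonl
Rscript "$ddx" evaluate --gold runs/sim1/vignettes.jsonl --predictions preds.jsonl --out report.json
Rscript "$ddx" validate --kb runs/sim1/kb.json
```

Exit codes: 0 ok, 2 validation failure, 1 unexpected error. Every
writing run leaves a JSON manifest beside its outputs.

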