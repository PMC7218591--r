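---
title: "The diagnostic model and its evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diagnostic model and its evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddxbayes)
```

## The model

`ddxbayes` ranks a closed set of candidate diseases given a coded
patient history. Three assumptions define the model:

1. **Findings are objectifiable.** A history can be coded as findings —
   symptom identifiers with a present/absent polarity — with stable
   meaning across cases.
2. **The disease set is closed and exhaustive.** Every case is caused by
   some disease in the knowledge base, so posteriors normalize over it.
3. **Single cause.** Exactly one disease explains the findings; there is
   no comorbidity inference.

Under these assumptions diagnosis is multiclass classification. The
knowledge base carries disease priors $\pi_d$ (prevalence weights) and
association weights $w(s,d) \in [0,1]$, interpreted as
$P(\text{symptom } s \text{ present} \mid d)$. With conditional
independence of findings given the disease (naive Bayes), the posterior
after findings $f_1,\dots,f_n$ is

$$P(d \mid f_{1:n}) \;\propto\; \pi_d \prod_{i=1}^{n} P(f_i \mid d),
\qquad
P(f \mid d) = \begin{cases}
\tilde w(s,d) & f \text{ present}\\
1 - \tilde w(s,d) & f \text{ absent}
\end{cases}$$

where $\tilde w = \min(\max(w, \varepsilon), 1-\varepsilon)$ with
$\varepsilon = 10^{-6}$.

Why these readings, where the design was genuinely open:

* **Weight semantics.** Curated association strengths have no canonical
  scale; treating them directly as conditional symptom probabilities is
  the minimal interpretation under which sequential Bayesian updating
  ("priors updated with each new piece of evidence") is exactly the
  product above, independent of finding order.
* **Smoothing by clamping** rather than pseudo-counts: the weights are
  expert-curated, not count-derived, so there is no sample size to add
  pseudo-observations to. The clamp's only job is to keep every
  likelihood strictly inside $(0,1)$ so that no single finding can
  eliminate a disease ($\varepsilon = 10^{-6}$ is far below any curated
  granularity and far above double-precision noise).
* **Unmentioned symptoms are unobserved, not absent.** Vignettes record
  elicited findings, not an exhaustive review of systems; silence about
  a symptom carries no evidence either way.
* **Unknown symptom codes are skipped**, warned about, and counted in
  the posterior's provenance, so a knowledge base covering a limited
  domain can still consume vignettes that mention out-of-scope findings.
* **Duplicate findings.** An exact duplicate (same symptom, same
  polarity) counts once — the evidence is a set, and double-counting
  would square its likelihood contribution. The same symptom reported
  both present and absent is contradictory and raises an error.
* **Demographics** (age, sex, presentation date) are vignette metadata.
  If a study wants them to carry evidence, age bands or sex can be
  declared as symptoms of category `demographic` and given weights; the
  engine itself does not special-case them.

## From posterior to differential

The reporting convention is a ranked differential of $k$ diagnoses
(default $k = 3$: one primary plus two differentials) with integer
percentage sureties summing to exactly 100. The top-$k$ posterior mass
is renormalized and apportioned by **largest-remainder (Hamilton)
rounding**: floors first, then the remaining points to the largest
fractional remainders, the higher-ranked entry winning ties. This is the
one standard rounding scheme that guarantees the printed sum-to-100
convention. Rank ties in the posterior are broken by disease id
(C-locale ascending) so results are byte-reproducible across sessions
and locales.

## Numerical choices and degenerate inputs

* Log-space accumulation with max-subtraction before exponentiation:
  hundreds of findings cannot underflow. The test suite checks the
  log-space path against a direct product-of-probabilities
  implementation to $10^{-9}$ on randomized small problems.
* Priors are normalized on load when all are non-negative with positive
  sum; a knowledge base that omits priors gets uniform ones. Validation
  (never exceptions) reports each broken invariant with a
  JSON-pointer-style location, deterministically ordered.
* Empty finding lists are legal and return the prior distribution; a
  differential of an empty posterior, `k` outside $[1, |D|]$, or a gold
  surety sum other than 100 are validation errors.
* The Welch upper-tailed $t$ test delegates to `stats::t.test`
  (`alternative = "greater"`, unequal variances). Two constant samples
  make the statistic degenerate: equal constants give $p = 0.5$ by
  convention, separated constants give $p \in \{0, 1\}$; both are
  flagged in the result.

## The evaluation battery

All primary-diagnosis metrics use only the top item of each
differential; the similarity metrics use the full 3-item lists.

* **Top-3 accuracy**: fraction of vignettes whose gold primary appears
  anywhere in the predicted 3-list.
* **Per-disease precision and recall** on primaries
  ($TP/(TP+FP)$, $TP/(TP+FN)$), aggregated by weighting each disease by
  its gold-primary frequency. A disease never predicted as primary has
  0/0 precision; the default policy counts it as 0 with its full gold
  weight (penalizing never-predicting), switchable to
  exclude-and-renormalize via `undefined = "exclude"` since the
  alternative is equally defensible.
* **Jaccard similarity** on the unordered disease sets of the two
  differentials, and **cosine similarity** on their surety-weighted
  vectors over the disease universe. The two are deliberately
  non-redundant: Jaccard ignores confidence, cosine is driven by it.
* **Significance**: upper-tailed Welch $t$ on per-vignette scores
  (binary top-3 hit indicators, per-vignette Jaccard and cosine), the
  model's score vector against the pooled non-model sources'. The
  sampling unit is the vignette and the test is two-sample; a paired or
  per-rater analysis would be equally defensible, so the choice is
  isolated in one function (`upper_tailed_t_test`) and stated here.
* Per-stratum statistics use only that stratum's vignettes; *overall*
  is computed on the full set, not by averaging strata.

## The synthetic study generator

Real curated knowledge bases and expert-written vignettes are rarely
publishable, so the generator manufactures a study with known ground
truth, emulating a 15-disease febrile-illness domain evaluated over a
$15 \times 3 \times 2$ design (90 vignettes, 30 per specificity
stratum) by default.

The generated knowledge base plants, per disease, two **pathognomonic**
symptoms (weight drawn in $(0.85, 0.99]$ for the owner, near zero
elsewhere) and at least one **disease-leaning** symptom (weight in
$[0.5, 0.8]$), on top of a **shared pool** of nonspecific complaints
(fever-like symptoms, weight in $[0.15, 0.45]$ for every disease; a
quarter of the symptom budget). Priors come from a symmetric Dirichlet
(Gamma(2) draws, normalized). The three strata then have threshold-based
policies, configurable but fixed here at the planting thresholds:

* **high**: at least one pathognomonic symptom of the generating
  disease, plus shared complaints;
* **moderate**: no pathognomonic symptom of any disease; at least one
  disease-leaning symptom, plus shared complaints;
* **low**: shared-pool symptoms only, drawn with probability
  proportional to their weight for the generating disease.

The gold primary is the generating disease; the two gold secondaries
are the next-best diseases under a direct-product posterior on the
sampled findings, with sureties from the same largest-remainder rule as
the engine — so the gold is internally consistent with the planted
model rather than invented. Simulated raters start from the engine's
own differential and corrupt it: the primary is swapped for a random
other disease with probability `primary_error_rate`, each secondary
slot perturbed with probability `differential_error_rate`; slot
sureties are retained so sums stay at 100.

Determinism: every generator draws from a sub-stream keyed by the
config seed and the vignette's cell index, so studies are reproducible
bit for bit and a single vignette can be regenerated without replaying
the whole study.

**What the synthetic study does and does not show.** Passing tests on
generated studies demonstrate that the inference, ranking, metric, and
comparison machinery are correct and that the engine recovers planted
structure, including the qualitative accuracy gradient from highly
specific to nonspecific presentations. They say nothing about clinical
performance on real fever cases: the generator's conditional
independence matches the engine's assumption (no model mismatch is
planted), its vignettes have 2–6 findings with no comorbidity, no
free-text ambiguity, no coder disagreement, and its raters err
uniformly at random rather than with human error structure.

## Scales used by the automated checks

The shipped checks run the protocol at sizes chosen to make the
planted-truth properties sharp while staying quick on one CPU: the
gradient check uses 20 vignettes per cell (900 vignettes, 300 per
stratum); the model-vs-rater comparison uses 7 per cell (315 vignettes,
the smallest balanced design above 300) with a planted 30% primary
error rate; oracle-equivalence sweeps use 200 random knowledge bases of
up to 5 diseases and 8 symptoms.

## Known limitations

* No learning of weights from data; the knowledge base is an input.
* No comorbidity, no physical-exam or laboratory evidence, no
  NLP — vignettes must arrive pre-coded.
* The association-weight interpretation and the Jaccard/cosine
  constructions are the package's own explicit choices among defensible
  alternatives; both are isolated behind single functions so other
  readings can be swapped in.
* The packaged 15-disease knowledge base is synthetic and illustrative;
  its disease labels are placeholders, not medical content.
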