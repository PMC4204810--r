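---
title: "Models and methods behind symptomLCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind symptomLCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`symptomLCA` fits competing latent-class models to longitudinal panels of
binary allergic-symptom indicators in birth cohorts. This vignette records
the modelling assumptions, the numerical choices, and the places where the
design was genuinely open — and what the synthetic-data tests do and do not
establish.

## Data model

A child is a panel `y[s, t]` over symptoms s ∈ {eczema, wheeze, rhinitis}
and a nominal age grid {1, 3, 5, 8, 11} years, each entry 0, 1 or missing.
Real review clinics happen near, not at, the nominal ages; the grid stores
nominal labels only and "previous time step" always means the adjacent grid
position. Missingness is explicit (`NA`), never a sentinel value, and comes
in two kinds: *structural* (a symptom never collected in a cohort at an age,
recorded per (cohort, symptom, age) cell) and random item missingness.

Two inclusion filters mirror common cohort practice. The minimum-timepoints
filter keeps children with at least k (default 2) observed ages per symptom;
structurally unobserved cells are exempt by default, because a symptom
collected at fewer than k ages in a cohort would otherwise disqualify that
entire cohort (a flag disables the exemption). The mild-eczema filter drops
children with reported early eczema but no confirming steroid prescription
(or a missing prescription flag), and children missing eczema at both early
ages.

Derived variables: current asthma is "any two of three" of current wheeze,
asthma-medication use, and physician diagnosis; the implementation resolves
the rule under partial missingness whenever the observed components already
decide it (e.g. two observed zeros give 0 even if the third is missing).
Sensitisation is a wheal at least 3 mm over the negative control on any
allergen.

## The three families

Each child belongs to one of *n* classes with weights π. Given the class:

* **independent Markov** — each symptom is a first-order chain with
  per-class initial probabilities and transition tables;
* **atopic-march Markov** — the same, plus cross-symptom lagged parents:
  wheeze at *t* conditioned additionally on eczema at *t−1*, rhinitis at *t*
  on wheeze at *t−1*. Rhinitis keeps its self-lag (the original description
  leaves this point open; a joint class with self-lags retained keeps the
  families nested, which the evidence comparison exploits);
* **latent profile** — given the class, all S×T indicators are independent
  Bernoulli draws.

All three tie the symptoms together through a single joint class index. The
alternative reading of the first family — three separate symptom-specific
class variables per child — is *not* implemented; the joint index keeps the
families directly comparable and matches the "one disease profile per child"
reading.

Transition tables are time-homogeneous (one table per symptom and class,
shared across steps). This is the conventional Markov-chain reading of
"transition probability", and it keeps the Markov families' parameter
counts comparable to the profile family's.

Emission, initial-state and transition probabilities are parameterised on
the probit scale, p = Φ(θ), with a standard Gaussian prior θ ~ N(0, 1);
class weights get a symmetric Dirichlet prior with pseudocount α (default
1; the sensitivity sweep uses 1/n, 2/n, 1, 2).

## Inference

The reference engine is MAP expectation–maximisation. The original analysis
used expectation propagation; every quantity this package consumes
downstream — posterior memberships, argmax assignments, evidence *ranking* —
is engine-agnostic, and the tests target those outputs, never engine
internals. The optional mean-field variational mode was dropped as
redundant with the same contract.

Missing data are never imputed. In the profile family a missing cell simply
contributes no Bernoulli factor. In the Markov families the per-child
likelihood is computed by a forward recursion over the 2³ = 8 joint symptom
configurations per time step, with observed cells constraining the state and
missing cells (including missing *parents*) left free — exact
marginalisation. The M-step uses the corresponding forward–backward pairwise
marginals, pooled over time steps, and each probability is re-estimated by a
damped Newton solve of its strictly concave weighted-Bernoulli-plus-prior
objective on the probit scale.

Numerical choices:

* log-probability floor −1e12 replaces −Inf (impossible panels under
  deterministic transitions stay finite for optimisation);
* probabilities are clamped to [1e−4, 1 − 1e−4];
* empty classes keep their slot: weights are floored at 1e−6 and
  renormalised, so a class-number sweep never silently changes n;
* restarts (default 10) alternate seeded k-means-style initialisations of
  the observed panels (missing cells mean-imputed *for clustering only*)
  with random responsibilities; the best penalised objective wins, ties
  break toward the lowest restart index;
* every source of randomness derives a 32-bit sub-seed from the master seed
  and a stage tag, so runs are bit-reproducible and order-independent.

Convergence follows a stability rule rather than a simple step criterion:
a run converges when the penalised objective stays within a relative
tolerance (default 1e−6, configurable — the original stability tolerance is
unstated) over a window of 100 consecutive iterations. Oscillating or
drifting runs are honestly reported as non-converged, and the sweep excludes
them from selection instead of hiding them.

## Evidence

Two approximations of model evidence are provided, both "higher is better":

* **hold-out** (default): mean per-child predictive log-likelihood over
  repeated random train/hold-out splits — 100 splits by default, 10% held
  out per split (the original split fraction is unstated; 10% is the
  package default and configurable). Split membership is derived from child
  identifiers, not row positions, so evidence is invariant to reordering.
  Per-split refits can warm-start from the full-data fit; time-constrained
  callers may reduce the number of splits (the acceptance tests use 6 and
  say so).
* **BIC**: maximised data log-likelihood minus (p/2)·log N with the exact
  free-parameter count per family. Deterministic and much cheaper; used
  where the selection question, not the evidence definition, is under test.

## The synthetic world

The generator draws children i.i.d.: class from the weights, panel from the
family's emission law, then missingness (structural cells, optional
per-visit attrition, then independent item missingness), then auxiliary
variables. True class labels travel in a side channel (an attribute and a
separate CSV), never as a cohort column, so recovery tests cannot leak them.

The default truth has eight classes with the published joint-cohort shares
(51.3%, 3.1%, 2.7%, 4.7%, 5.7%, 7.7%, 15.3%, 9.6%), two cohorts of 1,136
and 8,665 children, structural rhinitis missingness at ages 1 and 3 in the
larger cohort, and 5% item missingness. The per-cell emission curves are an
implementer choice: the source reports them only graphically, so the curves
were written to match each class's textual description (e.g. atopic march:
persistent eczema, wheeze rising with age, rhinitis near zero at age 1 and
near certainty by age 8) and then calibrated *once* so that posterior class
certainty under the truth is high (mean maximum posterior ≈ 0.92, oracle
adjusted Rand index ≈ 0.83), matching the reported "generally high"
assignment certainty. A first, more overlapping draft put even the
Bayes-optimal classifier below the recovery property the package is tested
against, which contradicted that reported certainty; the separation was
increased before any expected value was frozen and has not been revisited.
These curves are emphatically *not* ground truth for the original cohorts,
and no test claims numerical agreement with the original fitted profiles.

What a green synthetic test establishes: that the estimator recovers the
truth of its own generative family at realistic size, missingness and class
imbalance, and that the selection machinery finds the right class count and
family ordering there. What it cannot establish: anything about
questionnaire wording effects, informative (non-random) dropout, cohort
heterogeneity beyond structural missingness, or the actual shapes of the
original profiles.

Auxiliary variables are plumbing with plausible strengths (steroid
prescriptions at 65% given early eczema vs 3% otherwise; medication/
diagnosis flags correlated with wheeze; per-class sensitisation echoing the
published ordering, atopic march highest). They exist so the derived
-variable rules and association statistics run end to end, and carry no
epidemiological claims.

## Association statistics

Odds ratios against a baseline class use the Woolf (Wald log-OR)
construction — OR = ad/bc with CI exp(ln OR ± z·√(1/a+1/b+1/c+1/d)) — which
reproduces every printed confidence interval of the source's sensitisation
table to one decimal; any zero cell triggers the Haldane–Anscombe +0.5
correction and a flag. Categorical traits are compared per class against the
baseline with an uncorrected Pearson chi-square (which reproduces the
printed p = 0.001 gender comparison; the original test statistic is
unstated). Display rounding is half-up to one decimal, matching the printed
tables. No multiple-testing adjustment is applied, matching the source.

## Known limitations

* The EM surface is multimodal; restarts mitigate but cannot guarantee the
  global optimum, which is why sweeps and recovery tests fix seeds.
* Hold-out evidence with few splits is noisy; the 100-split default is the
  stable configuration, and the scaled-down test settings trade variance
  for run time.
* The atopic-march family is a superset of the independent family here
  (self-lags retained), so their evidence comparison is a penalised nested
  comparison, not a test of disjoint hypotheses.
* Attrition in the generator is independent per visit; real cohort dropout
  is monotone and possibly informative.
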