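# symptomLCA

Longitudinal latent class analysis of childhood allergic symptom
trajectories.

## The problem

Eczema, wheeze and allergic rhinitis are common in childhood, and their
population prevalences shift with age in a way that suggests a within-child
progression — eczema first, then asthma/wheeze, then rhinitis (the "atopic
march"). Whether individual children actually follow that sequence is a
different question, and answering it needs models of each child's joint
symptom *trajectory*, not cross-sectional prevalence curves.

`symptomLCA` implements that analysis for birth-cohort panels: per-child
binary indicators y[s, t] for s ∈ {eczema, wheeze, rhinitis} at discrete
review ages t ∈ {1, 3, 5, 8, 11} years, with missing entries, drawn from one
or two cohorts (including *structural* missingness — e.g. rhinitis never
collected at ages 1 and 3 in one cohort).

## The models

Each child belongs to one of *n* latent classes with weights π (symmetric
Dirichlet prior with pseudocount α). Given the class *c*, three competing
emission laws are available:

- **independent Markov** — each symptom follows its own first-order chain:
  P(y[s,t] = 1 | y[s,t−1], c), with per-class initial-state probabilities;
- **atopic-march Markov** — adds the hypothesised cross-symptom lags:
  wheeze at *t* is additionally conditioned on eczema at *t−1*, rhinitis at
  *t* on wheeze at *t−1*;
- **latent disease profile** — unconstrained mixture: given *c*, every
  indicator is an independent Bernoulli with its own probability
  p[c, s, t] = Φ(θ[c, s, t]) (probit link, standard Gaussian prior on θ).

Fitting is MAP expectation–maximisation with exact marginalisation of
missing cells (forward–backward over the 2³ joint symptom states for the
Markov families). Model evidence is the mean per-child hold-out predictive
log-likelihood over repeated random splits (default 100), or a BIC
approximation; class-number sweeps select the evidence-maximising model
*among runs that pass the stability convergence rule* (objective stable for
100 consecutive iterations). Downstream: posterior memberships and argmax
assignments, per-class trajectory tables, cross-sectional prevalence
summaries, confusion matrices, and 2×2 odds ratios with Woolf confidence
intervals (OR = ad/bc, CI = exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))) against a
baseline class.

Because the original cohort data are not redistributable, the package ships
a synthetic-cohort generator (`default_truth()`) that emulates the
two-cohort structure: eight trajectory classes with the published class
shares, structural rhinitis missingness, random item missingness, and
auxiliary variables (skin-prick wheals, steroid prescriptions, asthma
medication/diagnosis) feeding the derived-variable rules.

## Worked example

```r
library(symptomLCA)

# a scaled-down synthetic two-cohort world (class shares and missingness
# structure preserved), with true class labels kept out of band
truth  <- default_truth(seed = 1, cohort_sizes = c(A = 232, B = 1768))
cohort <- generate_cohort(truth)
cohort <- filter_min_timepoints(cohort, k = 2)

fit8 <- fit(cohort, model_spec("latent_profile", 8), seed = 1,
            control = em_control(restarts = 6, max_iter = 400))
print(fit8)
#> fit: latent_profile, n = 8 classes, 1988 children
#>   objective -9000.911, converged: TRUE, restarts: 6
#>   class sizes: 73, 89, 143, 49, 1092, 258, 174, 110

head(profile_table(fit8, cohort), 3)
#>   class size      share symptom age observed_prop model_prob
#> 1     1   73 0.03672032  eczema   1     0.7826087  0.7761995
#> 2     1   73 0.03672032  eczema   3     0.8857143  0.8749921
#> 3     1   73 0.03672032  eczema   5     0.9859155  0.9674460

# association of a binary trait (here: derived sensitisation) with class,
# odds ratios vs the largest fitted class (the "no disease" analogue)
sens <- with(as.data.frame(cohort), mapply(
  function(w1, w2, nc) derive_sensitised(c(w1, w2), nc),
  wheal_m1_8, wheal_m2_8, negctl_8))
tt <- class_trait_table(fit8$assignment, sens, baseline_class = 5)
print(tt$table[1, c("class", "trait_pos", "trait_neg", "or", "ci_low", "ci_high")])
#>   class trait_pos trait_neg       or  ci_low  ci_high
#> 1     1        54        19 38.53895 21.7297 68.35118
```

The `observed_prop` column is the raw per-class symptom proportion among
assigned children (non-missing cells); `model_prob` is the fitted emission
probability — agreement between the two is a fit diagnostic. Class 1 here is
the fitted atopic-march analogue (persistent early eczema, 3.7% of the
cohort); the odds-ratio row reads: its children have ~39 times the odds of
skin-prick sensitisation of the "no disease" baseline class, with Woolf 95%
CI (21.7, 68.4) — the synthetic generator plants exactly this kind of
class–sensitisation gradient.

A full pipeline (simulate → filter → sweep → profiles → associations, with a
reproducibility manifest) is available as `run_pipeline(run_config(...))` or
from the shell via `inst/cli/symptomlca`.

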