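---
title: "Bayesian models for medical test accuracy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian models for medical test accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtabayes)
```

This vignette is the package's account of the statistical models it
implements, the assumptions they rest on, the tunable settings that
matter, and the design decisions taken where more than one defensible
choice existed.  Everything quantitative shown here is computed by the
code at build/test time; the test suite asserts the same properties at
tighter settings.

## 1. Basic measures for a binary test

A binary test cross-classified against a gold standard gives a 2x2 table
of counts \(n_{ij}\) (test score \(i\), disease status \(j\)) with cell
probabilities \(\theta_{ij}\).  Under multinomial sampling and a uniform
Dirichlet prior, the posterior is
\(\theta \mid \mathrm{data} \sim
\mathrm{Dir}(n_{00}+1, n_{01}+1, n_{10}+1, n_{11}+1)\).
All the standard measures are functions of \(\theta\):

* sensitivity \(\mathrm{TPF} = \theta_{11}/(\theta_{11}+\theta_{01})\),
  false positive fraction \(\mathrm{FPF} = \theta_{10}/(\theta_{00}+\theta_{10})\);
* predictive values \(\mathrm{PPV} = \theta_{11}/(\theta_{10}+\theta_{11})\),
  \(\mathrm{NPV} = \theta_{00}/(\theta_{00}+\theta_{01})\);
* diagnostic likelihood ratios
  \(\mathrm{PDLR} = \mathrm{TPF}/\mathrm{FPF}\),
  \(\mathrm{NDLR} = \mathrm{FNF}/\mathrm{TNF}\).

`basic_measures()` transforms i.i.d. Dirichlet draws through these maps
and summarises them.  Because sampling is conjugate and i.i.d., no
burn-in or convergence diagnostics are needed; the default 55,000 draws
makes the Monte Carlo error of a posterior mean on the order of
\(10^{-4}\).

Note that the predictive values condition on the *test* margin.  One
sometimes sees PPV written with the disease-margin denominator
\(\theta_{01}+\theta_{11}\); that is the sensitivity denominator, and
using it contradicts both the verbal definition of PPV and the numbers
any worked 2x2 example produces.  We use
\(\theta_{10}+\theta_{11}\).

**Exact oracle.** Every measure above except the likelihood ratios is a
ratio of a Dirichlet sub-sum to a containing sub-sum, and such a ratio
is exactly Beta-distributed (`beta_margin()`).  The test suite checks
every Monte Carlo mean against this closed form to within four Monte
Carlo standard errors; this catches both indexing and sampling errors.

## 2. Ordinal scores: empirical ROC and posterior AUC

For a k-category ordinal score the test is called positive when the
score is at or above a threshold; sweeping the threshold traces the
empirical ROC (`empirical_roc_points()`, endpoints (0,0) and (1,1)
appended).  With \(P(Y=i)=\theta_i\) for diseased and
\(P(X=j)=\phi_j\) for non-diseased scores, the area under the linearly
interpolated curve is

\[
\mathrm{AUC} = P(Y>X) + \tfrac12 P(Y=X)
 = \sum_{i>j}\theta_i\phi_j + \tfrac12\sum_i \theta_i\phi_i .
\]

`auc_ordinal_posterior()` puts independent uniform-prior Dirichlet
posteriors on \(\theta\) and \(\phi\).  Because the AUC is *bilinear* in
\((\theta,\phi)\) and the posteriors are independent, its posterior mean
equals the bilinear form evaluated at the posterior means —
`auc_ordinal_expectation()` — which the tests use as an exact oracle.

## 3. Continuous scores: the binormal model

When both classes' scores are (approximately) normal, the ROC area is
\(\Phi\!\left(a/\sqrt{1+b^2}\right)\) with \(a\) the standardised mean
separation and \(b\) the SD ratio.  `fit_binormal()` estimates this by
Gibbs sampling the heteroscedastic regression
\(y_i = \beta_1 + \beta_2 d_i + e_i\),
\(e_i \sim N(0, 1/\mathrm{prec}_{d_i})\), with vague priors
(coefficients \(N(0, 10^{6})\) variance, precisions
\(\Gamma(0.001, 0.001)\)).  Both full conditionals are conjugate —
bivariate normal for \((\beta_1,\beta_2)\), gamma for each precision —
so mixing is essentially immediate; the default 75,000 iterations with
5,000 burn-in is deliberately generous because the sampler costs
microseconds per sweep.

**Scaling convention.** Two conventions exist for \(a\): standardise the
mean difference by the diseased SD, or by the non-diseased SD (with the
variance ratio flipped accordingly).  The regression formulation tracks
`la1 = beta2 * sqrt(prec0)` and `la2 = prec0/prec1` with group 0 the
non-diseased baseline, i.e. the *non-diseased* convention; that is what
reproduces the reference analysis of the bundled glucose data, so it is
the default, with `scale_group = "diseased"` available.  When the two
variances are equal the conventions coincide (tested).

The bundled glucose data carry one documented ambiguity: the published
listing prints 78 score values but its label vector and prose disagree
about the diseased count (59 in the data layout, 49 in one prose
sentence).  The package adopts the 59/19 split because it alone
reproduces the published baseline mean (107.5 mg/dl) and group effect
(16.1 mg/dl).

## 4. Verification bias under MAR

When only some subjects are verified by the gold standard and the
decision to verify depends on the test result alone
(\(P(V=1\mid D,Y)=P(V=1\mid Y)\), missing at random), accuracy computed
from the verified subset is biased — when positives are verified
preferentially, both the naive TPF and the naive FPF are too large.
Parameterising by \(\phi_i = P(D=1\mid Y=i)\) and
\(\theta_i = P(Y=i)\), the likelihood factorises and with uniform
priors \(\phi_i \sim \mathrm{Beta}(s_i+1, r_i+1)\) independently and
\(\theta \sim \mathrm{Dir}(m_1+1,\dots,m_k+1)\), where \(s_i, r_i\) are
verified diseased/non-diseased counts and \(m_i\) the column totals.
Bayes' theorem then gives the corrected result-given-disease fractions
\(\alpha_i \propto \phi_i\theta_i\) and
\(\beta_i \propto (1-\phi_i)\theta_i\) per draw, and for ordinal tests
the corrected ROC area by the same bilinear formula as Section 2.

Two reporting conventions are worth noting:

* For the ordinal area the package reports `A2` as the *halved* tie term
  so that `A = A1 + A2` holds row-wise in the output table (matching
  how the bundled mammography verification analysis is conventionally
  tabulated); the raw tie probability is kept as `tie_prob`.
* For the binary scintigraphy study the posterior mean of the corrected
  sensitivity implied by its own Beta/Dirichlet posterior is 0.849
  (the plug-in closed form gives 0.848); the historically reported
  value 0.839 differs by about 0.01.  The package computes the
  functional exactly as defined and reports what the posterior gives.

The recovery tests generate data with known (TPF, FPF, prevalence) and
a verification rule depending only on Y (rates 0.35 for negatives, 0.85
for positives, n = 1000 — a realistic screening-referral pattern), and
check 95% interval coverage of the truth over 50 replicates together
with the documented upward bias of the naive estimates.

## 5. Two tests without a gold standard

For two conditionally independent binary tests (new test T, imperfect
reference R) with no gold standard, the disease status is latent.  The
data-augmented Gibbs sampler alternates between (i) drawing each cell's
latent diseased count \(y_{RT} \sim \mathrm{Binomial}(n_{RT}, m_{RT})\),
where \(m_{RT}\) is the cell's posterior probability of disease given
the current parameters, and (ii) drawing prevalence, sensitivities and
specificities from conjugate Beta conditionals built from the latent
counts; informative priors simply replace the uniform "+1"s with their
hyperparameters.  Indexing note: the first index is R throughout,
forced by the pairing of the new test's sensitivity with the T = 1
column of the cross-tab.

With uniform priors the model is only weakly identified: the likelihood
is invariant under \((p, s, c) \to (1-p, 1-c, 1-s)\), so the posterior
is bimodal and summaries sit near the symmetry point.  The package does
not hide this — a long-run test asserts the sampler visits both modes —
and uniform-prior output should be read qualitatively.  Informative
accuracy priors (such as the expert-elicited Beta priors bundled for
the stool/serology example) remove the ambiguity; a 125,000-iteration
default run reproduces that published analysis to well under 0.02.

Two printed-source corrections are built in: the conditional for the
(R=0, T=1) latent count uses
\(m_{01} = p s_1 (1-s_2) / [p s_1 (1-s_2) + (1-p)(1-c_1) c_2]\)
(one source prints a stray extra \(s_2\) factor in the numerator, which
would not be a probability), and the (R=0, T=1) cell label in the
augmented-data layout is taken as \(y_{01}\) (the printed layout
repeats \(y_{10}\), which the likelihood's exponent pairing rules out).

**Exact small-instance oracle.** With the accuracies pinned at known
values (near-point-mass priors), the prevalence posterior is an
explicit finite mixture of Beta laws over all latent configurations; on
a table with six subjects the test suite enumerates this mixture and
checks the Gibbs mean against it.

## 6. Combined tests

For two binary tests on the same subjects, the believe-the-positive
rule (positive if either is positive) and believe-the-negative rule
(positive only if both are) have TPF/FPF that are plain sums of joint
cell probabilities, so their posteriors come from the same independent
Dirichlet construction as Section 1.  The truncated (conditional) cell
probabilities are exposed for completeness but deliberately not used in
the rule fractions — only the plain cell sums reproduce the worked
stenosis example.  Frechet-type inequalities (BP can only gain
sensitivity; BN can only shed false positives) hold per draw by
construction and are asserted per draw in the tests.

For ordinal or continuous tests the optimal combination is through the
likelihood ratio \(LR(Y) = P(Y\mid D=1)/P(Y\mid D=0)\): by the
Neyman-Pearson lemma, thresholding LR maximises TPF at every FPF
(`lr_roc()`, with ties grouped and zero-denominator cells ranked first
at \(LR=\infty\)).  The risk score \(RS(Y) = P(D=1\mid Y)\) is a
monotone increasing function of LR, hence shares its ROC curve; it is
estimated by Bayesian logistic regression
(`fit_risk_score()`, vague normal priors with precision \(10^{-4}\)).
The sampler is a random-walk Metropolis-within-Gibbs with
per-coefficient step sizes adapted during burn-in towards an acceptance
rate of 0.3–0.45; identical covariate rows are aggregated into binomial
observations so grouped ordinal designs cost almost nothing per sweep.
Complete separation is detected via a quiet ML fit and reported as a
warning (the posterior stays proper under the normal prior).

`risk_score_auc()` offers two routes from fitted risk scores to an ROC
area: the default feeds the posterior-mean risk scores into the
binormal sampler by disease label, mirroring the two-stage pipeline of
the reference analyses; the alternative computes the empirical
Mann–Whitney area directly, which is preferable in principle because
risk scores are generally not normal.  A property-based test asserts
that risk scores computed from *true* cell probabilities attain the
likelihood-ratio ROC area exactly on randomly generated small grids.

The bundled paired-ordinal pipeline is exercised on synthetic joints
only: the real five-category lung study and the pancreatic biomarker
study behind the published versions of these analyses do not print
complete subject-level or non-diseased joint data, so no fixture can
reproduce them faithfully.

## 7. Synthetic-data generators

Each estimator has a matching generator (`gen_binary()`,
`gen_verified()`, `gen_no_gold()`, `gen_paired_binary()`,
`gen_ordinal()`, `gen_ordinal_joint()`, `gen_scores()`,
`gen_logistic_subjects()`) that produces data with exactly the
dependence structure the model assumes — e.g. `gen_verified()` draws
the verification indicator from the observed result only (MAR holds by
construction), and `gen_no_gold()` draws the two tests independently
given the latent status.  What the generators deliberately do *not*
emulate: conditional dependence between tests given disease status,
covariate effects, non-MAR verification, reader variability.  Passing
recovery tests therefore demonstrates correctness of the estimators
under their stated assumptions, not robustness to their violation.

All generators are deterministic given a seed and emit the same file
formats the readers consume; a goodness-of-fit test at \(n=10^5\)
checks the generated frequencies against the specified probabilities.

## 8. Numerical choices and degenerate inputs

* **Monte Carlo error** is estimated by batch means with 50 batches
  (the estimator behind the "MC error" column of standard Bayesian
  output tables; the batch count is a common default and for i.i.d.
  draws agrees with \(sd/\sqrt{n}\)).
* **Quantiles** are empirical order statistics with linear
  interpolation (R's type-7 default).
* **Zero denominators** in measure ratios have probability zero under
  Dirichlet draws; they are nevertheless floored at the smallest
  positive double and reported if ever triggered.
* **Counts must be integers**; the conjugate updates assume multinomial
  data, so fractional "counts" are rejected rather than silently used.
* **Dirichlet sampling** uses the gamma-ratio construction; each row is
  normalised and tested to sum to 1 within \(10^{-12}\).
* **Run lengths.** Defaults mirror the reference analyses (55,000
  conjugate draws; 75,000/5,000 binormal; 125,000/10,000 latent class;
  45,000/5,000 logistic; 25,000 for the combination rules).  Unit tests
  use a few thousand draws, which keeps the whole suite under half a
  minute while the closed-form oracles keep the comparisons sharp; the
  end-to-end tests rerun the bundled studies at the full defaults.

## 9. Known limitations

* Two tests at most in the latent-class model, and conditional
  independence is assumed, not testable from a single 2x2 cross-tab.
* Extreme verification bias (no negatives verified at all) is out of
  scope; the MAR correction needs verified subjects in every result
  category to say anything about \(\phi_i\).
* No covariate adjustment anywhere; no reader-agreement modelling; no
  smooth ROC for ordinal data; no partial AUC.
* The uniform-prior latent-class posterior is reported as-is, bimodality
  included; users wanting a unimodal answer must supply informative
  priors.
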