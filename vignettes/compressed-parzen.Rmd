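---
title: "Compressed Parzen Window classification of binary fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed Parzen Window classification of binary fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parzenfp)
```

## The model

A pattern is a binary vector $x \in \{0,1\}^L$ — in cheminformatics,
typically a molecular fingerprint whose bits flag presence or absence of
structural features. Given a training set $D = \{(x_i, y_i)\}_{i=1}^N$
with labels $y_i \in \{\omega_1, \dots, \omega_J\}$, classification goes
through Bayes' rule,
$$ p(\omega_j \mid x) = \frac{p(x \mid \omega_j)\, p(\omega_j)}{p(x)},
   \qquad p(x) = \sum_j p(x \mid \omega_j)\, p(\omega_j), $$
assigning $x$ to the class with maximal posterior (equal
misclassification costs are assumed; exact posterior ties go to the
lexicographically smallest label). Priors are either the class
frequencies $N_{\omega_j}/N$ or uniform $1/J$.

The class-conditional density is the Parzen Window estimate: the mean of
a kernel placed on each prototype of the class,
$$ \hat p(x \mid \omega_j) = \frac{1}{N_{\omega_j}}
   \sum_{i : y_i = \omega_j} K(x, x_i; \lambda). $$
The kernel is the Aitchison–Aitken kernel on $\{0,1\}^L$,
$$ K(x, x_i; \lambda) = \lambda^L
   \left(\tfrac{1-\lambda}{\lambda}\right)^{d(x, x_i)},
   \qquad 0.5 < \lambda < 1, $$
with $d$ the Hamming distance — a discrete analogue of an isotropic
Gaussian. It is a probability mass function in $x$ for every reference
$x_i$, so the Parzen average is automatically normalized.

## The compressed estimator

The brute-force estimate must keep every prototype in memory and touch
all of them per query. Writing $d$ through inner products,
$d = x^\top x - 2 x^\top x_i + x_i^\top x_i$, and setting
$\alpha = \ln\!\big(\lambda/(1-\lambda)\big) > 0$, the kernel factorizes
as
$$ K(x, x_i; \lambda) = \lambda^L e^{-\alpha x^\top x}\,
   e^{2\alpha x^\top x_i}\, e^{-\alpha x_i^\top x_i}, $$
and the middle factor expands as
$e^{2\alpha t} = \sum_{r \ge 0} \gamma_r t^r$ with
$\gamma_r = (2\alpha)^r / r!$. With the per-prototype weights
$\beta_i = e^{-\alpha\, x_i^\top x_i}$ and the class accumulators
$$ a = \sum_i \beta_i, \quad z = \sum_i x_i, \quad
   z' = \sum_i \beta_i x_i, \quad Q = \sum_i \beta_i\, x_i x_i^\top, $$
the estimator becomes
$$ \hat p(x \mid \omega_j) = B\Big[\, a + 2\alpha\,(x^\top z')
   + g(\mu)\,(x^\top Q x) \Big], \qquad
   B = \frac{\lambda^L e^{-\alpha x^\top x}}{N_{\omega_j}}, $$
where $\mu = 2\alpha\,(x^\top z)$ and the order-$\ge 2$ series terms are
summed in closed form by the tail factor
$$ g(\mu) = \frac{4\alpha^2 \left(e^\mu - \mu - 1\right)}{\mu^2},
   \qquad g(0) = 2\alpha^2 . $$
After the single fitting pass the prototypes are discarded: each class
is represented by one scalar, two $L$-vectors and one symmetric
$L \times L$ matrix, whatever $N_{\omega_j}$ is. For sparse fingerprints
$z$, $z'$ and $Q$ are themselves sparse — $Q$'s support is the set of
co-occurring bit pairs — so storage scales with the squared number of
active bits, not with $L^2$.

### Exactness and approximation

The terms of order 0 and 1 ($a$ and $x^\top z'$) are exact for any class.
The tail replaces $\sum_i \beta_i (x^\top x_i)^r$ for $r \ge 2$ by
$(x^\top Q x)(x^\top z)^{r-2}$. With the adopted construction
$Q = \sum_i \beta_i x_i x_i^\top$:

* the $r = 2$ term $x^\top Q x = \sum_i \beta_i (x^\top x_i)^2$ is exact;
* for a class holding a single (possibly repeated) prototype the whole
  series is exact, because $(x^\top Q x)(x^\top z)^{r-2} =
  \beta (x^\top x_1)^r$ identically;
* for multi-prototype classes and $r > 2$ the factorization is an
  approximation: it couples the class through the aggregate overlap
  $x^\top z$ instead of the per-prototype overlaps.

This construction was a genuinely open design point: it is the unique
symmetric single-pass accumulator that matches the dimensional
description of the compressed model, reproduces the quadratic term
exactly, and makes the single-prototype regime an identity. Because the
quality of the higher-order approximation cannot be settled on paper,
the package ships `compression_error_report()`, which tabulates exact
vs. compressed densities and decision agreement on any dataset, rather
than asserting a fidelity it cannot guarantee. No renormalization is
applied to the compressed density; the posterior normalizes over classes
anyway, and a per-class rescaling would have to be estimated, reblurring
exactly what the report is meant to measure.

## Tunable parameters

* `lambda` (dimensionless, open interval (0.5, 1), default 0.75): the
  kernel bandwidth analogue. Near 1 the density concentrates on the
  prototypes (small-sample variance); near 0.5 it flattens (bias). The
  default sits midway on the log-odds scale; there is no universally
  correct value and users should treat it as a model-selection knob.
  Both endpoints are rejected rather than clamped.
* `prior` (`"empirical"` or `"uniform"`): class frequencies when the
  training class balance is informative, uniform otherwise.
* `backend` (`"compressed"`, `"exact"`, `"truncated"`): interchangeable
  density engines behind the same posterior machinery. `"truncated"`
  (with `r_max`, default 60) exists mainly as the verification bridge:
  it converges monotonically to the exact estimator as `r_max` grows.

## Numerical policy

* `lambda^L` underflows for `L` in the hundreds, so every density has a
  log-scale variant and posteriors are always formed in the log domain
  with max-subtraction; scaling all class-conditionals by a common
  constant provably leaves posteriors unchanged.
* The tail factor is evaluated in three regimes: a Taylor expansion
  $2\alpha^2(1 + \mu/3 + \mu^2/12)$ below $\mu = 10^{-4}$ (the naive
  form loses all significant digits there), `expm1`-based arithmetic up
  to $\mu = 700$, and a log-scale form
  $\log g = \log(4\alpha^2) + \mu + \log(1 - (\mu+1)e^{-\mu}) - 2\log\mu$
  beyond, since $e^\mu$ overflows past $\mu \approx 709$ and
  $\mu = 2\alpha\, x^\top z$ grows with class size.
* The truncated backend evaluates its partial sums with log-sum-exp for
  the same reason. Order 60 reproduces the exact estimator to better
  than $10^{-10}$ while the series argument $2\alpha\, x^\top x_i$ stays
  below roughly 24; beyond that the order-60 Taylor remainder of $e^w$
  is no longer negligible, which is a property of truncation itself, not
  of the implementation.
* Prototypes are summed in stored order; density estimates are invariant
  under prototype permutation to within $10^{-12}$ summation tolerance.
* Degenerate inputs: empty classes are rejected at fit time, a query of
  all zeros keeps only the zeroth-order term ($B\,a$), an all-zero
  prototype set yields $\beta_i = 1$ and an empty $Q$, and a summary is
  only usable with the `lambda` it was built with (the `beta_i` depend
  on `alpha`), enforced with an explicit error.

## The synthetic generator

`fp_sim_config()` draws each class's patterns with independent Bernoulli
bits from a per-class probability profile; `disjoint_block_preset()`
builds the standard separable benchmark (each class owns a contiguous
block of high-probability bits over a low background, 0.9 and 0.01 by
default, 100 patterns per class) on which any correct classifier must
score near-perfectly. The generator is deterministic under its seed.

What it emulates: per-class bit-occurrence profiles, controllable
dimension, class sizes, density and separation. What it does not: real
fingerprints have strongly correlated bits (substructures imply one
another) and scaffold-induced multimodality within a class. Passing
tests on this generator therefore validate estimator mechanics —
normalization, identities, compression fidelity, decision rules — not
real-world classification accuracy.

## Problem sizes used in the checks

The shipped verification suite enumerates pattern spaces up to
$L = 12$ for kernel normalization ($2^{12}$ terms) and $L \le 10$ for
density normalization; runs the series-vs-exact bridge at $L = 16$,
$N_\omega = 20$ over 100 instances; checks single-prototype exactness
over 1000 draws across $\lambda \in \{0.55, 0.75, 0.95\}$ and
$L \in \{4, 16, 64\}$; and trains/tests the end-to-end benchmark at
$J = 2$, $L = 64$, 100 + 100 patterns per class. These sizes exercise
every code path (including the log-scale tail regime) while keeping the
whole suite in the tens of seconds.

## Known limitations

* The compressed tail is an uncontrolled approximation for
  heterogeneous multi-prototype classes: since $\mu = 2\alpha\, x^\top z$
  grows with class size, the tail term can overestimate the true series
  by many orders of magnitude for large classes. The fidelity report
  therefore measures density disagreement with the bounded symmetric
  relative difference $|c - e|/\max(c, e)$ computed on the log scale,
  and carries the signed log-ratio alongside. Measure before trusting
  compressed densities; decision agreement is typically far better than
  density agreement, since the posterior argmax is invariant to density
  error that is shared across classes.
* Only the Aitchison–Aitken instance of the factorizable kernel family
  is implemented; the continuous (Gaussian) analogue is out of scope.
* There is no cost-sensitive decision rule and no online deletion of
  prototypes from a summary (addition is supported — summaries are
  additive).
* Bit-correlation structure in the generator is a documented extension
  point, not implemented.

## A worked example

```{r example}
train <- simulate_fingerprints(
  disjoint_block_preset(J = 2, L = 64, n_per_class = 100, seed = 2025))
test <- simulate_fingerprints(
  disjoint_block_preset(J = 2, L = 64, n_per_class = 100, seed = 2026))

model <- parzen_fit(train, lambda = 0.75, backend = "compressed")
model

mean(predict(model, test$patterns, type = "class") == test$labels)

rep <- compression_error_report(train, kernel_params(0.75, 64),
                                test$patterns)
rep
```
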