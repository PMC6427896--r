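---
title: "Methods: negative binomial likelihood ratio tests for homeolog expression bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative binomial likelihood ratio tests for homeolog expression bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heblrt)
```

## The statistical problem

In an allopolyploid, most genes exist as a homeologous pair, one copy per
subgenome. When reads can be assigned to each copy, two questions arise:

1. **HEB** — within one condition, are the two copies expressed at
   different levels (expression ratio $\omega = \lambda_b/\lambda_a \ne 1$)?
2. **$\Delta$HEB** — does the expression ratio differ between two
   conditions ($\omega_1 \ne \omega_2$)?

The second question is not reducible to running the first test in each
condition: whether a change in bias is detectable depends jointly on
sequencing depths, expression levels and gene-length ratios, which a single
joint likelihood handles coherently.

## Count model

Counts for homeologs A and B in replicate $i$ are modelled as negative
binomial,

$$a_i \sim \mathrm{NB}(\mu = \lambda\,\ell_a d_i,\; r_i), \qquad
  b_i \sim \mathrm{NB}(\mu = \omega\lambda\,\ell_b d_i,\; r_i),$$

with $\lambda$ the expression level of the reference homeolog (units
kb$^{-1}$ per million mapped reads, i.e. the RPKM scale), $\ell$ gene
lengths in kilobases, $d_i$ sequencing depth in millions of mapped reads,
and $r_i$ the aggregation parameter ($\mathrm{var} = \mu + \mu^2/r$; the
Poisson limit is $r \to \infty$). Replicates are independent; both
homeologs of one replicate share one $r_i$. In the two-condition model each
condition carries its own depth vector and its own aggregation parameters,
which reduces to a single shared depth vector when the designs coincide.

The log-likelihood is the sum over replicates (and, for $\Delta$HEB,
conditions) of the NB log pmf, computed throughout with `lgamma` so large
counts cannot overflow. The combinatorial terms are parameter-free and
cancel in the likelihood ratio.

## Hypotheses and test statistic

Both tests compare nested hypotheses differing by one free parameter:

* HEB: $H_0: \omega = 1$ (2 vs 1 free parameters),
* $\Delta$HEB: $H_0: \omega_1 = \omega_2$ (4 vs 3 free parameters),

via $W = 2(\ln\hat L_1 - \ln\hat L_0)$ referenced to $\chi^2_1$. A pair is
*testable* when each homeolog has at least one read in total (per condition
for $\Delta$HEB); otherwise the ratio MLE sits on the parameter boundary
and the fit functions refuse to run. "Measurable expression" is not
quantified further; one read per homeolog is the weakest reading and
mirrors the explicit two-condition rule. Screens over many pairs apply
Benjamini–Hochberg FDR control across all testable pairs (not within
direction classes — the standard reading of correcting a genome-wide
screen), at $\alpha = 0.05$ by default.

Two point estimates of bias are reported and deliberately kept distinct:
the descriptive $\mathrm{HEB} = \log_2(\bar b/\bar a)$ from
length/depth-normalized mean counts, and the model MLE $\hat\omega$. They
coincide asymptotically under equal per-replicate depths but differ in
finite samples; downstream plots conventionally use HEB, so the screens
emit both. Logs are base 2 in all reported statistics (natural logs
internally).

## Dispersion estimation

With typical replicate numbers, per-gene dispersion estimation is not
realistic, so a single $r_k$ is fitted per replicate: all replicates are
rescaled to replicate $k$'s depth, $y^i_{k,j} = (d_k/d_i)\,x^i_j$; per-gene
means $\mu_j$ and sample variances $\sigma^2_j$ (divisor $n-1$, the
standard unbiased choice — the convention is otherwise unspecified) are
taken across replicates; and $r_k$ minimizes
$\sum_j (\sigma^2_j - \mu_j - \mu_j^2/r_k)^2$. The objective is linear in
$\phi = 1/r$, giving the closed form
$\phi = \sum_j \mu_j^2(\sigma^2_j - \mu_j) \big/ \sum_j \mu_j^4$, which the
tests verify against a numeric minimizer over $r$. Every individual
homeolog contributes one row; rows with zero mean are excluded (they carry
no information and destabilize nothing by their absence). $\phi$ is clamped
to $[10^{-8}, 10^3]$ ($r \in [10^{-3}, 10^8]$) so underdispersed tables
yield an effectively-Poisson $r$ instead of a negative one; clamping is
messaged. Conditions are always processed separately.

Depth units cancel inside the rescaling (only ratios $d_k/d_i$ enter), but
must be consistent with the likelihood's depths; the readers default to
column totals / $10^6$ and accept explicit overrides for tables
pre-filtered to homeologs, where column totals underestimate library depth.

## Maximum likelihood: numerics

Likelihoods are maximized by solving the score equations in the
transformed variables $v = \ln\sqrt{\lambda_a\lambda_b}$,
$y = \tfrac12\ln\omega$, which enforce positivity and make the system
symmetric under relabeling A $\leftrightarrow$ B (the relabeling maps
$\hat\omega \to 1/\hat\omega$ and leaves $W$ unchanged, a property the test
suite asserts to $10^{-8}$). The per-replicate score terms have closed
forms, as do all Jacobian entries, so each fit is a damped Newton iteration
on a 1-D (HEB null), 2-D (HEB alternative) or 3-D ($\Delta$HEB null,
coupled through the shared $y$) system:

* convergence: residual max-norm $\le 10^{-10}$, at most 200 iterations,
  step halving when a step fails to reduce the residual;
* initialization: moment estimates
  $\tilde\lambda_g = (\sum_i c_{g,i} + 0.5)/(\ell_g \sum_i d_i)$, the 0.5
  guarding $\log 0$ and used only to start;
* fallback: if Newton stalls, Nelder–Mead maximization of the
  log-likelihood in $(v, y)$ from the same start (and, for the HEB null,
  monotone bracketing — the $v$-score is strictly decreasing); fallback use
  is flagged in the result and surfaced in screen output, never silent;
* a fit reports `converged` only when the score residual is
  $\le 10^{-8}$, and screens record per-pair failures in a `note` column
  rather than aborting.

With a single replicate and unit offsets the equations collapse to closed
forms ($\hat\lambda = a$, $\hat\omega = b/a$; null
$\hat\lambda = (a+b)/2$), which the tests check exactly; on general
fixtures the solver is validated against independent grid and simplex
maximization of the log-likelihood to $10^{-6}$.

$W$ is clamped to 0 when numerical slack leaves $\ln\hat L_1$ below
$\ln\hat L_0$ by at most $10^{-8}$; a larger violation raises an error
(it indicates an optimizer failure, not noise).

## What the simulator emulates

`simulate_pair()` draws i.i.d. NB counts at unit lengths and depths, so the
expression level equals the mean — matching the validation protocol
($\mu_a = 100$, $\mu_b = 2^x\mu_a$ with $x \in [0,2]$ in steps of 0.1,
$r = 10$, $N \in \{3, 6, 12, 24\}$, $\alpha = 0.05$, 10,000 trials per
cell, one test per trial so no multiplicity correction). The true $r$ is
passed to the test by default (re-estimation is available as a sensitivity
option). Power cells are seeded independently of grid order, so any
sub-grid reproduces the full run bitwise.

The ROC benchmark simulates data sets of gene pairs, half null
($\omega_1 = \omega_2 = 1$) and half with the condition-2 bias ratio
multiplied by a fold level. The levels $\{2, 8, 16\}$ are interpreted as
fold changes of the bias ratio, not log-scale values — a log$_2$ level of
16 would mean a 65,536-fold shift, irreconcilable with near-chance
detection at level 2. Baseline parameters ($\mu = 100$, $r = 10$, 3
replicates) mirror the power study. Comparator methods score each pair by
a Welch t-test and a pooled-SE z-test on per-replicate
$\log_2((b+0.5)/(a+0.5))$ ratios; the +0.5 pseudo-count defines the ratio
at zero counts. ROC curves sweep the p-value threshold with ties grouped;
the partial area integrates FPR $\in [0, 0.1]$ with linear interpolation
at the cut.

What the generator does **not** emulate: library-composition artifacts,
mapping bias between subgenomes (misassigned reads shrink apparent bias),
correlated replicates, per-gene dispersion heterogeneity, and zero
inflation. Passing simulations therefore validate the statistical
machinery under the stated model, not robustness to those violations.

## Problem sizes in the shipped checks

The package's own validation runs at sizes chosen to give tight Monte
Carlo error while staying desk-scale: 2,000 trials per power cell (binomial
SE $\approx 0.005$), except the $\Delta$HEB cell at $x = 1$, $N = 12$,
which sits essentially at the 95% detection threshold (measured 0.952
$\pm$ 0.002 at 20,000 trials) and therefore runs at the full 10,000-trial
protocol so the comparison against 0.95 is resolved rather than a coin
flip. Dispersion recovery uses 20 matrices of 1,000 genes at $n = 5$; the
ROC ordering check uses 10 data sets of 2,000 pairs at fold level 16.

## Known limitations

* One aggregation parameter per replicate: genes far from the fitted
  mean–variance trend are mis-weighted; no empirical-Bayes shrinkage or
  trended dispersion is attempted.
* The $\chi^2_1$ reference is asymptotic; at $N = 3$ the realized size is
  close to, but not exactly, $\alpha$ (the size-calibration tests bound it
  within 3 MC standard errors of 0.05).
* Boundary pairs (a silent homeolog) are filtered, not tested; a test for
  presence/absence switching is a different problem.
* Gene lengths and the pair map are user-supplied; no annotation parsing.
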