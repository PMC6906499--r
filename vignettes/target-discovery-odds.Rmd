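---
title: "Modelling the odds of drug target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the odds of drug target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetodds)
```

## The model

`targetodds` treats drug development as a statistical discovery problem.
The universe of hypotheses is the matrix of all gene–disease pairings: the
protein-coding genome (rows) crossed with the "disease-ome" of common
complex diseases (columns). Three labels structure this space:

* **causal** — the gene's protein influences the disease's pathogenesis;
* **druggable** — the protein can be targeted by a small molecule, peptide
  or antibody;
* **declared positive** — an experiment (a preclinical study, or a GWAS
  locus test) claims the pairing is real.

The base-case parameterisation, held in `sample_space()`, is 20,000
protein-coding genes, 10,000 diseases, 4,000 druggable genes and an average
of 100 causal genes per disease. From these, the prior probability that a
random pairing is causal is $\gamma_C = \bar{C}/N_G = 0.005$, druggable
$P_T = N_T/N_G = 0.2$, and both $\gamma_{CT} = 0.001$ (causality and
druggability are assumed independent). Restricting the sampling frame to
the druggable genome removes the druggability factor and lifts the prior
back to $\bar{C}/N_G$.

### Modelling assumptions

The closed forms inherit strong simplifications: each gene encodes one
protein with one function; a protein may influence several diseases, with
independent causal assignment across diseases and independent of
druggability; mis-specified targets are the *only* cause of clinical
failure; and discovery experiments behave as independent Bernoulli tests
with homogeneous error rates $\alpha$ and $\beta$ across hypotheses. None
of these is literally true of real biology — pleiotropy is correlated,
druggability and causality are probably not independent, and clinical
programmes fail for pharmacokinetics and safety too — so the numbers are
base-case anchors, not forecasts.

### Discovery rates

`confusion()` applies Bayes' rule to a test with prior truth fraction
$\gamma$:

$$FDR = \frac{\alpha(1-\gamma)}{(1-\beta)\gamma + \alpha(1-\gamma)},$$

with the four cell rates (population fractions summing to one) returned
alongside. At $\gamma = 0.005$, $\alpha = 0.05$, $1-\beta = 0.8$ the FDR is
92.6%; at the causal-and-druggable prior $\gamma = 0.001$ it is 98.4%.

### The two-stage pipeline

`two_stage()` composes two confusion tables. All preclinical declared
successes advance, so the clinical prior is the preclinical true discovery
rate, $\gamma_c = TDR_{pc}$, and the overall declared success rate is
$S_o = S_{pc} S_c$. `tdr_clinical()` is the equivalent closed form

$$TDR_c = \left[1 + \frac{\alpha_c}{1-\beta_c}\cdot
\frac{\alpha_{pc}}{1-\beta_{pc}}\cdot
\frac{1-\gamma_{pc}}{\gamma_{pc}}\right]^{-1},$$

the posterior odds of an advanced drug being effective written as prior
odds times two Bayes factors; the tests verify the two routes agree to
1e-12 everywhere. `development_sweep()` tabulates the twelve canonical
scenarios ($\bar C \in \{10, 100, 1000\}$, whole-genome vs
druggable-genome frame, orthodox $\alpha_{pc}=0.05$ vs genomic
$\alpha_{pc}=5\times10^{-8}$).

`back_calculate()` inverts the pipeline from observed success rates. The
system is linear in the priors, so the solution is exact:
$\gamma_c = (S_c - \alpha_c)/((1-\beta_c) - \alpha_c)$, then
$\gamma_{pc} = \gamma_c S_{pc}/(1-\beta_{pc})$ and
$\alpha_{pc} = (S_{pc} - \gamma_{pc}(1-\beta_{pc}))/(1-\gamma_{pc})$.
Solving in closed form rather than numerically makes the feasibility
region explicit: $S_c < \alpha_c$ or $1-\beta_c \le \alpha_c$ raise typed
`targetodds_infeasible` errors instead of silently clipping — a clipped
value would fabricate model output. `back_calculate_sweep()` traces the
inferred $\gamma_{pc}$ and $\alpha_{pc}$ over a grid of assumed
preclinical powers (default 0.2–0.8 in steps of 0.05, configurable).

```{r}
glance(back_calculate(s_pc = 0.4, s_c = 0.1))
```

### Portfolios of parallel programmes

`n_programmes_needed()` solves $1-(1-P_s)^N \ge$ confidence. The default
returns the smallest integer attaining the confidence (114 programmes at
$P_s = 0.02$ for 90%). A `rounding = "nearest"` option instead rounds the
real-valued solution; this reproduces quoted counts that attain the stated
confidence only approximately (34 programmes for an "evens" chance — 34
gives 49.7%). The two conventions are both exposed because neither alone
reproduces every quoted count; the ceiling is the default because it is
the semantically correct "number needed".

`causal_in_sample_pmf()` and `expected_causal_in_sample()` describe the
hypergeometric capture of causal targets when a portfolio of programmes is
drawn without replacement from a candidate frame (computed through
`stats::dhyper`, which works in log space, so a 4,000-gene frame is
numerically safe). `development_success_prob()` models the full selection
step — **draw** a portfolio, **test** every target (power $1-\beta$ on
causal targets, rate $\alpha$ on the rest), **advance** one nominal
positive chosen uniformly — and returns the probability the advanced
target is truly causal, by exact summation over the joint distribution of
causal draws, true positives and false positives. The uniform choice among
positives is a modelling decision (no analytic reference exists for this
step); it is validated against exhaustive enumeration on tiny frames and
an independent Monte-Carlo oracle at the working scale, and the simulator
(`simulate_portfolio()`) replays the identical process stochastically.

### Repurposing

`diseases_per_target()` treats the diseases affected by one gene as
binomial: mean 50, SD 7 under the defaults. The 95% interval is reported
with the normal approximation ($\pm 1.96$ SD, rounded to whole diseases:
36–64); the exact binomial quantile interval (37–64) is reported alongside
for transparency. The lower tail at 28 diseases is likewise reported both
ways (exact 0.0005, normal 0.0009), since at one significant figure either
could be read as "1 in 1000".

`prob_no_shared_gene_chain()` gives the probability that $k$ diseases
share no causal gene as the chained product
$\prod_{j=1}^{k-1}\binom{N_G - j\bar C}{\bar C}/\binom{N_G}{\bar C}$,
evaluated with log binomial coefficients. The chain conditions disease
$j+1$ on the $j\bar C$ genes accumulated so far being distinct; this is
exact on the no-overlap event being computed (the 200-gene numerator for
the third disease), and the simulator's direct frequency estimate
(`simulate_shared_targets()`) confirms it within Monte-Carlo error.

### GWAS rediscovery and yield

Rediscovery of licensed targets is binomial with per-locus power
$1-\beta$: `rediscovery_pmf()`, `expected_rediscoveries()` (which also
accepts a vector of per-locus $\beta$ and then uses Poisson-binomial
moments, since power is introduced per locus before being assumed
homogeneous), `multi_disease_rediscoveries()` for totals across $K$
disease GWAS, and `backcalc_power()` for the inverse problem (74
rediscoveries over 315 GWAS'd diseases imply average power 0.23 per
available target). `druggable_yield()` applies the same machinery
prospectively to the $C \cdot N_T / N_G$ causal, druggable targets of one
disease.

## The synthetic-data simulator

`generate_world()` draws one realisation of the assumed causal structure.
The model does not fix a distribution for the per-disease causal count, so
two modes are provided:

* `"fixed"` (default): exactly $C$ causal genes per disease, drawn
  uniformly without replacement — matching the exact-count worked examples;
* `"bernoulli"`: each cell causal independently at rate $\bar C / N_G$ —
  matching the independence language of the assumptions.

Both give the same analytic targets in expectation. Druggable genes are a
uniform subset, independent of causality. Every simulation function takes
a `seed`; seeded calls are bit-reproducible and restore the caller's RNG
stream, so replicate counts can change without reshuffling earlier draws.

`simulate_discovery()` and `simulate_two_stage()` replay the confusion
machinery over every pair of a world; `simulate_shared_targets()` and
`simulate_portfolio()` replay the repurposing chain and the
draw-test-advance portfolio. Each returns its estimate with a binomial
standard error, and the test suite asserts $|$empirical $-$ analytic$|
< 3\,$SE throughout. Empirical rates are compared with the closed forms
evaluated at the world's *realised* truth fraction (for fixed-count worlds
the realised causal fraction is exactly $\bar C/N_G$; the realised
causal-and-druggable fraction varies hypergeometrically around 0.001),
which is the right conditioning for validating the formulas themselves.

### What the simulator does and does not emulate

The worlds reproduce the statistical skeleton the closed forms assume —
independent causal assignment, independent druggability, Bernoulli
detection. They do not emulate linkage disequilibrium, genotyping-array
coverage, correlated pleiotropy, effect-size distributions, or any real
association-testing machinery. Passing simulation checks therefore
demonstrates internal consistency of the closed forms, not external
validity for real genomes or diseases.

### Problem sizes

Desk-scale runs use a disease count of 100 (2 million pairs) for the
discovery and two-stage replays — the analytic quantities are invariant to
the disease count, and that invariance is itself asserted — with
$10^5$-replicate Monte-Carlo runs for the shared-gene and portfolio
checks; module-level tests use a further scaled world (2,000 genes, 50
diseases) with proportionally scaled labels.

## Numerical and design choices

* All computation is done at full double precision; presentation rounding
  (92.6%, 0.016, …) happens only in reporting (`write_report()`'s CSV
  formatting, printed summaries). JSON reports always carry full precision.
* $\bar C$ may be non-integer in the analytic formulas (it is an average);
  the fixed-count simulator and the combinatorial chain require integer
  counts and say so in their errors.
* Degenerate inputs return well-defined limits where the algebra permits
  (e.g. $\alpha = 0 \Rightarrow FDR = 0$); genuine 0/0 cases (declared
  success rate of zero, zero prior odds) raise typed errors
  (`targetodds_undefined_rate`) rather than sentinels.
* Scenario sweeps collect per-row errors into an `error` column instead of
  failing the whole table.
* Configuration files (YAML or JSON, `load_scenario()`) are validated
  against the base-case schema with path-qualified messages; unknown keys
  are rejected rather than ignored.

## Known limitations

The package implements the base-case probability model faithfully, and
only that. It does not estimate $\bar C$, $N_T$ or $N_D$ from annotation
resources; does not model programme costs, correlated programmes, or
failure modes other than target mis-specification; and the repurposing
chain is a conditioning approximation, not an exact exchangeable-model
probability. Where headline counts admit more than one rounding convention
("number needed" versus the rounded real-valued solution), both are
exposed and the default is the semantically correct one.
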