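# targetodds

Probabilistic models of drug target identification and development success.

## The problem

Most clinical-phase drug development failures are failures of efficacy: the
chosen protein target turns out not to play a causal role in the disease.
`targetodds` models drug development as a discovery problem over the sample
space of all gene–disease pairings — every protein-coding gene (≈20,000)
crossed with every common human disease (≈10,000) — of which only a small
fraction are causal (≈100 causal genes per disease) and only some genes
(≈4,000) encode druggable proteins. On this space the package computes, in
closed form:

- the false discovery rate of a preclinical experiment by Bayes' rule,

  FDR = α(1 − γ) / [(1 − β)γ + α(1 − γ)],

  where γ is the prior fraction of true target–disease relationships, α the
  false-positive rate and 1 − β the power;
- a linked two-stage (preclinical → clinical) success model in which the
  clinical prior equals the preclinical true discovery rate (γc = TDRpc),
  with forward prediction of success rates and exact back-calculation of
  γpc and αpc from observed success rates;
- portfolio arithmetic: how many parallel programmes are needed for one
  success, and the hypergeometric distribution of truly causal targets in a
  programme portfolio drawn from a candidate frame;
- repurposing probabilities: diseases affected per target, the chance that
  several diseases share no causal gene, and the number of diseases to
  screen to find one affected by a given target;
- GWAS rediscovery and yield: binomial counts of licensed targets
  rediscovered and of causal, druggable targets discovered prospectively,
  plus back-calculation of average GWAS power from observed rediscoveries.

Every closed form is paired with a seeded Monte-Carlo simulator
(`generate_world()` and the `simulate_*()` functions) that replays the same
process stochastically on a synthetic gene-by-disease causal world, so the
analytic results can be checked against simulation within Monte-Carlo error.

The audience is anyone doing quantitative triage of drug-development
strategy: translational scientists, genetic epidemiologists and
portfolio-level decision makers.

## Worked example

```r
library(targetodds)

space <- sample_space()   # 20,000 genes x 10,000 diseases, 4,000 druggable, 100 causal/disease
p_causal(space)
#> [1] 0.005
fdr_rate(gamma = p_causal(space), alpha = 0.05, beta = 0.2)
#> [1] 0.9255814
```

A random preclinical pick is causal for the disease of interest once in 200
(γ = 0.005), so at conventional error rates 92.6% of declared preclinical
successes are false — close to the observed ~96% overall failure rate.
Chaining the two stages for causal-and-druggable targets (γ = 0.001):

```r
glance(two_stage(gamma_pc = 0.001, alpha_pc = 0.05, beta_pc = 0.2))
#> # A tibble: 1 × 8
#>   gamma_pc gamma_c fdr_pc fdr_c tdr_c   s_pc    s_c     s_o
#>      <dbl>   <dbl>  <dbl> <dbl> <dbl>  <dbl>  <dbl>   <dbl>
#> 1    0.001  0.0158  0.984 0.796 0.204 0.0508 0.0618 0.00314
```

Only 0.3% of programmes succeed end to end, and 80% of declared clinical
successes are themselves false discoveries. Swapping the preclinical stage
for a genome-wide association study (α = 5 × 10⁻⁸, same power) reverses the
discovery odds — `fdr_pc` drops from 0.984 to 6 × 10⁻⁵ and `tdr_c` rises to
0.9999996 — at the price of a much lower declared stage-1 success rate
(`development_sweep()` tabulates all twelve orthodox/genomic scenarios).
Inverting the model from the reported success rates instead:

```r
glance(back_calculate(s_pc = 0.4, s_c = 0.1))
#> # A tibble: 1 × 9
#>    s_pc   s_c alpha_c beta_c beta_pc gamma_c gamma_pc alpha_pc fdr_pc
#>   <dbl> <dbl>   <dbl>  <dbl>   <dbl>   <dbl>    <dbl>    <dbl>  <dbl>
#> 1   0.4   0.1    0.05    0.2     0.2  0.0667   0.0333    0.386  0.933
```

so the targets actually studied preclinically are enriched only ~7-fold
over a random pick, and 93% of declared preclinical successes are still
false. Other headline quantities:

```r
n_programmes_needed(p_s = 0.02, confidence = 0.9)
#> [1] 114
prob_no_shared_gene_chain(space, k = 3)   # three diseases, no shared causal gene
#> [1] 0.2209003
glance(druggable_yield(space, beta = 0.2))
#> # A tibble: 1 × 4
#>    n_ct  e_ct sd_ct power
#>   <int> <dbl> <dbl> <dbl>
#> 1    20    16  1.79   0.8
```

A well-powered GWAS of one disease is expected to deliver 16 of its 20
causal, druggable targets in a single experiment.

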