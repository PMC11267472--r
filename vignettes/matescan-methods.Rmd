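---
title: "Methods: models, simulators and numerical choices in matescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and numerical choices in matescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matescan)
```

## The problem

Females of some African *Drosophila melanogaster* populations largely
refuse cosmopolitan males, an incipient form of sexual isolation.  The
male side of that refusal is a quantitative trait: when groups of males
from a reference panel of inbred lines are presented to discriminating
tester females in a no-choice assay, the proportion of females that
copulate within a fixed window varies heritably among lines.  `matescan`
implements the statistical machinery used to dissect such variation:

* replicate-level quantitative genetics of the assay (variance
  components, broad-sense heritability, line-mean correlations with other
  traits, inversion karyotype effects, Fisher exact contrasts for
  knockdown experiments);
* inbred-panel genome-wide association with covariate adjustment and a
  genomic relationship matrix;
* pooled-sequencing divergence scans for single-generation extreme
  (xQTL) designs and unpaired multi-generation selection designs;
* the response regression for multi-generation selection; and
* a forward simulator of the breeding designs, assays, truncation
  selection and pool sequencing, so every stage can be tested end to end
  with data whose generating truth is known.

## The mating assay and its simulator

The assay places 10 males with 5 virgin tester females in a vial and
records each copulation time; pairs are removed on mating.  The
simulator treats mating as a competing-risk process.  Male *i* carries a
per-minute, per-pair hazard $h_i$; while $f$ females and a set $M$ of
males remain free, the next copulation arrives after an exponential time
with rate $f \sum_{i \in M} h_i$ and involves male $i$ with probability
$h_i / \sum h$.  Under a constant hazard this reduces to a pure-death
chain with rates $(5-j)(10-j)h$, whose closed-form mean is used as an
independent oracle in the tests.

Liabilities follow the standard threshold-free quantitative-genetic
model: a centred polygenic score over causal variants plus Gaussian
noise, scaled to unit total variance with a genetic fraction $h^2$.  The
liability maps to the hazard through a bounded logistic link,
$h_i = h_{\max}\,\mathrm{logit}^{-1}(a + b\,L_i)$.  No generative model
for this link is published, so its three parameters are the package's
own calibration, fixed once: $h_{\max} = 0.004$, $a = -2$, $b = 3$.
With those values an outbred cohort mates about a third of its tester
females within an hour — matching the reported behaviour of the outbred
intercross population — and the rank correlation between copulation
latency and liability is strong enough that selecting the 50 fastest of
500 assayed males shifts mean liability by roughly one phenotypic
standard deviation, the regime in which a single generation of extreme
selection is informative at all.  A flatter link (e.g. slope 1) makes
latency nearly uninformative about liability and would contradict the
observation that such designs map dozens of variants in practice.

In the selection designs the breeding quota is defined by the first
$k$ copulations, so the simulated vials keep being observed past the
scored window until the quota can be filled
(`observe_beyond_window = TRUE`); scored proportions still count only
within-window matings.

## Breeding designs

`simulate_founders()` emulates a panel of fully inbred, sequenced lines:
dosages are 0/2, alt frequencies follow a uniform law on a configurable
minor-allele range, and five polymorphic inversions are modelled as
recombination-suppressed blocks.  Variants inside a block are generated
in strong linkage disequilibrium with the line's arrangement dose, which
reproduces the "island of differentiation" structure that motivates
using karyotypes as association covariates.  Lines can be
heterokaryotypic (residual segregating inversions are a real feature of
inbred panels); block variants use the arrangement dose so the dosage
matrix stays homozygous.

`build_aip()` reproduces the advanced-intercross design: a round-robin
cross of the founders (line *i* females by line *i+1* males) yields
exactly one F1 genotype per founder; a second round-robin over the F1
genotypes populates 10 replicate bottles; maintenance then draws 4
females and 4 males from every bottle of the previous generation into
each new bottle, a census of 800.  Female meiosis places Poisson
crossovers along each arm (default 2 × 10⁻⁸ per bp); males are
achiasmatic, as in *Drosophila*; crossovers falling inside a
heterokaryotypic inversion block are suppressed, so blocks are inherited
as units.  Haplotypes are stored as founder-origin vectors over the
variant grid, which makes every segment traceable and dosage lookup
exact.

## Variance components and heritability

`estimate_h2()` fits the one-way random-effects model
$y_{ij} = \mu + g_i + e_{ij}$ to replicate-level proportions by REML.
The model has a single variance ratio $\lambda = \sigma_g^2/\sigma_e^2$,
so the restricted likelihood is profiled to one dimension and maximised
by a bounded scalar search on $\log\lambda$ (tolerance 10⁻¹⁰), with the
boundary $\sigma_g^2 = 0$ handled by explicit comparison.  On balanced
designs this coincides with the closed-form ANOVA estimator, which the
tests assert to six decimals; on unbalanced data it agrees with a
general-purpose mixed-model fitter.  Broad-sense heritability is
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.  Significance uses the
restricted likelihood-ratio statistic against the boundary-corrected
null, an equal mixture of a point mass at zero and $\chi^2_1$ — a
package choice, since no test construction is published for this
quantity.

Proportions are analysed untransformed by default (matching the practice
of fitting the mating success rate directly); an empirical-logit option
exists.  The phenotype generator is Gaussian on the proportion scale
with clamping to [0, 1] and discretisation to counts.  At a
strongly-discriminating tester's grand mean (0.05) the clamp truncates
the lower tail, so realised heritability on the recorded scale falls
below the generating value — as it would in real data.
Parameter-recovery work therefore places the grand mean at 0.5 and uses
a fine-grained assay (100 females per replicate), where the modelled
scale and the recorded scale coincide; this was fixed at design time,
not tuned to test outcomes.

## Association scan

Line means are first adjusted by OLS for endosymbiont infection status
and the karyotype classes of the five inversions (class-coded factors,
three levels each); the adjusted phenotype is the residual re-centred at
the grand mean, and a flag reproduces the companion scan that leaves
inversion effects in.  Variants are filtered on folded minor allele
frequency strictly greater than the threshold (default 0.02).

The relationship matrix is the centred-scaled cross-product
$K = WW^\top/L$ with per-variant centring $2p$ and scaling
$\sqrt{2p(1-p)}$, missing dosages mean-imputed.  For fully inbred 0/2
dosages this gives a diagonal near 2 (each squared deviation doubles);
for outbred Hardy–Weinberg dosages, near 1.  The mixed model
$y = Xb + Zu + e$, $u \sim N(0, \sigma_u^2 K)$, is fitted in the
spectral (rotated) basis: $K$ is eigendecomposed once, the ratio
$\delta = \sigma_e^2/\sigma_u^2$ is estimated by 1-D REML under the
no-variant model, and each variant is then tested by generalized least
squares with fixed $\delta$ and a two-sided Wald $t$ — the standard
two-step approximation used by spectral LMM association software.  With
$K = I$ the procedure collapses exactly to per-variant OLS, which the
suite verifies to machine precision.  Lines missing a dosage are
excluded from that variant's test via an exact GLS refit at the null
variance components.  The Wald form was chosen where the literature
leaves Wald-versus-LRT unstated.

Gene assignment uses interval overlap with a symmetric window (default
1000 bp — "in or near" is never given a published width); a variant
exactly `window` bp from a gene end is assigned, `window + 1` is not.

## Pooled divergence tests

A pool of $n$ flies sequenced to depth $c$ estimates its allele
frequency with variance $p(1-p)(1/2n + 1/c)$: chromosomes into the pool,
then reads from the chromosomes.  The replicated test standardises the
difference of group mean frequencies between high/selected and control
pools.  Two weighting conventions are implemented because the printed
form of the statistic is ambiguous:

* `mode = "literal"`: unweighted replicate means; denominator
  $\sum w_2 v_2 + \sum w_1 v_1$ with depth weights $w_r = c_r/\sum c$
  normalised within group.  Read literally this is the variance of a
  *single* replicate, not of the mean of $R$ replicates, so the test is
  conservative by about $\sqrt{R}$ in standard-deviation units; with 4
  + 4 pools its empirical size at $\alpha = 0.05$ is essentially zero.
* `mode = "delta"`: depth-weighted mean with squared-weight
  (delta-method) variance $\sum w_r^2 v_r$.  This is the calibrated
  form: under a drift-free binomial null its empirical size sits within
  binomial bounds of the nominal level, which the acceptance suite
  checks at $\alpha \in \{0.05, 0.01\}$.

The two modes coincide for a single replicate (so the worked example
$Z = 0.2/\sqrt{0.0032 + 0.0048} \approx 2.236$ is mode-free) and their
group means coincide at equal depths.  Both are reported; literal is
additionally asserted never to be anticonservative.  Zero-variance
variants with a frequency difference are clamped to a configurable
$|Z|_{\max}$ (default 50) with a warning; variants with no covered
replicate in a group are skipped with a logged reason.  Pools are
treated as $2n$ chromosomes; an X-male flag switches to $n$.

For the unpaired multi-generation design, every selected × control pair
is tested separately and a variant passes only if its weakest pair (the
largest p-value) beats the threshold.  This min-over-pairs rule is
stringent by construction: with a 0.3 frequency shift in 100-fly pools
at depth 30, per-pair $|Z|$ is only about 2.2, so no threshold near
conventional scan cut-offs can be met reliably at that depth.  The
recovery property is therefore exercised at depth 100 with a 0.05
per-pair threshold, where a true 0.3 shift passes in most replicates
while unshifted variants essentially never do.

## Selection response

Deviations of each selected replicate from the contemporaneous control
mean (averaging over however many control populations exist at that
generation; a second control splits from the first partway through) are
regressed on generation number by unweighted OLS, per replicate and for
the replicate average, with a two-sided $t$ test on the slope.
Generation 0 is included in the grid; assay sizes are not used as
weights, since no weighting is documented for the published regressions.

## Problem sizes and calibration conditions

The test suite and the acceptance script use these scales, chosen as the
package's standard verification conditions:

* heritability recovery: 205 lines × 10 replicates, 100 simulations per
  generating value in {0.1, 0.27, 0.5, 0.9}, mean estimate within 0.03;
* pooled-test calibration: 4 vs 4 pools of 50 flies at depth 60 over
  4000 independent variants;
* mixed-model calibration: 200 phenotype permutations × 500 variants on
  100 lines, with the relationship matrix built from 2000 background
  variants (building K from the tested variants themselves induces
  proximal contamination and a visibly conservative size);
* multi-generation selection: 25 runs of 18 generations,
  first-40-of-300 truncation, two selected replicates, controls of 150
  assayed with a second control from generation 5, liability $h^2$ 0.27;
* single-generation extreme mapping: a generation-20 intercross of 40
  founders, 4 replicates × 500 assayed males, pools of 50 at depth 100
  (these pools were deeply sequenced in the motivating design), five
  equal-magnitude causal effects at liability $h^2$ 0.9.  Equal
  magnitudes matter: drawing five effects from a Gaussian makes some of
  them near zero, and a variant with no effect cannot be recovered by
  any method.

## What the simulator does and does not emulate

It reproduces: homozygous founder genotypes with inversion LD blocks,
round-robin intercross bookkeeping (exact F1 counts and census),
achiasmatic males, competing-risk vial dynamics with pair removal,
first-to-mate truncation, binomial chromosome and read sampling in
pools, and the one-way random-effects structure of replicate-level
proportions.

It does not model: larval competition or viability selection (egg laying
is not simulated; maintenance samples adults uniformly), new mutation,
drift-aware null distributions for multi-generation divergence
(Wright–Fisher covariance across generations is explicitly out of
scope — the all-pairs rule is the pragmatic guard), X-chromosome dosage
in males beyond the pool-variance flag, or any demographic realism of
the African/cosmopolitan split.  Passing tests therefore demonstrate the
statistics are implemented correctly and calibrated under their own
assumptions, not that those assumptions hold in any particular real
population.

## Numerical choices

* REML searches $\log\lambda \in [-18, 12]$ (variance ratios from
  ~10⁻⁸ to ~10⁵) at tolerance 10⁻¹⁰; the boundary fit is compared
  explicitly and wins ties.
* Eigenvalues of $K$ are floored at 0; matrices with eigenvalues below
  −10⁻⁶ are rejected as non-PSD.
* Folded-MAF threshold comparisons allow 10⁻¹² of floating-point dust so
  an alt frequency of 0.98 folds to exactly the threshold and is
  removed.
* Latency ties in truncation selection are broken by a seeded uniform
  draw (continuous latencies make real ties measure-zero, but file-read
  data may round).
* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from a master seed by a deterministic hash kept below
  2³¹, so stages can be re-run independently and whole runs reproduce
  byte-for-byte.
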