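---
title: "Methods: fitness scoring, resistance classification and prediction for inhibitor DMS screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness scoring, resistance classification and prediction for inhibitor DMS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdms)
```

# The experiment being modelled

A deep mutational scanning (DMS) screen expresses a saturation-mutagenesis
library of a kinase domain in a kinase-dependent cell population and grows
the pool under a panel of ATP-competitive inhibitors, each dosed at its
IC50, plus a DMSO control. Samples are sequenced at four time points
(T0-T3) in three replicates; each variant's frequency trajectory encodes
its growth rate. The dosing is controlled so that wild-type cells double
exactly twice between contiguous time points in every condition, which is
what makes fitness scores directly comparable across inhibitors.

`metdms` implements the downstream computation, starting from variant
count tables: count filtering, fitness scoring on the doubling-rate scale,
resistance classification, hotspot aggregation by inhibitor type,
differential-sensitivity comparison of inhibitor pairs, and a
feature-augmented machine-learning fitness predictor. A synthetic-data
module generates count and feature tables with the statistical structure
the analysis assumes, so the whole pipeline is testable without any
sequencing data. The repository is organised as an analysis workflow —
numbered drivers under `analysis/` run the full study over the package's
functions — because the product here is a sequence of analyses rather than
a standalone tool; every computational step nevertheless lives in the
package, where it is unit-tested.

# Fitness scores on the doubling-rate scale

For variant $v$, replicate $r$ and time index $t = 0, \dots, T-1$, counts
are log2-transformed with a pseudocount and centred on the mean of the
synonymous (wild-type-equivalent) variants in the same sample:

$$ m_{vrt} = \log_2(c_{vrt} + p) - \frac{1}{|S|}\sum_{w \in S} \log_2(c_{wrt} + p). $$

This wild-type normalisation anchors wild type at 0, and because wild type
doubles twice per interval, the per-replicate ordinary-least-squares slope
of $m_{vrt}$ against $t$ is the variant's growth-rate offset from wild
type in doublings per interval. The score $\beta_v$ is the mean of the
replicate slopes: $\beta = 0$ is wild-type-like growth, $\beta = -2$ means
the cells do not grow at all ($2^{2-2} = 1$), and $\beta = 1$ means they
double three times per interval ($2^{2+1}$). Slopes are invariant to the
time labelling (only the spacing matters) and to any per-sample rescaling
of counts, i.e. to sequencing depth.

The default pseudocount is 0.5, a standard zero-count guard. For
noise-free simulated counts, which are strictly positive reals, a
pseudocount of 0 makes score recovery exact to machine precision; the
acceptance checks use this.

## Uncertainty: the counting-variance random-effects estimator

A Bayesian hierarchical scorer would pool information across variants and
replicates; this package substitutes a deterministic estimator that keeps
the same decision semantics. Each normalised value carries a delta-method
counting variance $\mathrm{Var}(m_{vrt}) \approx 1/(\ln^2 2 \,(c_{vrt}+p))$
plus the variance of the synonymous reference mean, which propagates to a
known per-replicate slope variance $v_r$. The reported squared standard
error combines this counting floor with the total observed
between-replicate dispersion:

$$ \mathrm{se}^2(\beta) = \frac{\overline{v_r} + s^2_{\text{slopes}}}{R}, $$

with normal tails. Two points deserve emphasis:

* With $R = 3$ replicates, the naive between-replicate estimator
  ($\mathrm{se} = s/\sqrt{R}$, $t_2$ tails) is exact but its 2-df pivot
  makes 1.96-sigma intervals cover only ~81% — too few replicates to
  estimate a variance reliably. It remains available as
  `method = "replicate"`.
* Subtracting the counting floor from the observed dispersion
  (the positive-part moment estimator familiar from random-effects
  meta-analysis) is too noisy at $R = 3$ and under-covers. Keeping the
  *total* dispersion is deliberately conservative, in the spirit of the
  conservative initial estimate in Sidik-Jonkman variance estimation. In
  simulation at depth $10^6$ this yields ~98% empirical coverage of true
  scores by $\beta \pm 1.96\,\mathrm{se}$, never below 95% across seeds,
  at a cost in power that the downstream resistance test absorbs easily
  (planted effects sit many standard errors above the threshold).

One-sided tail probabilities are reported against two anchors: 0 (wild
type) and the resistance effect threshold 0.5.

# Resistance classification

All classification rules operate on two scored conditions:

* **Resistance mutation** (per inhibitor): the one-sided test of
  $\beta_{\text{inh}} < 0.5$ must have tail probability $\le 0.1$
  (the variant credibly out-grows wild type by more than half a doubling
  per interval under drug), *and* $\beta_{\text{DMSO}} \le 0$ (it enjoys
  no advantage without drug — the behaviour is inhibitor-specific).
  Synonymous variants are never called.
* **Resistance position**: any position carrying at least one resistance
  mutation for that inhibitor.
* **Recentered score** $\gamma = \beta_{\text{inh}} - \beta_{\text{DMSO}}$
  isolates drug response from expression/stability effects.
  **Gain-of-function** is $\gamma > 0.75$, **loss-of-function**
  $\gamma < 0$; the 0.75 threshold is exposed as a parameter.
* **Hotspots**: resistance (mutation, inhibitor) pairs are summed per
  position over all inhibitors of a type; variants are also partitioned by
  the combination of types they resist (a Venn partition), and
  type-exclusive sets collect variants resistant to one type only.
* **Divergent pairs**: for two inhibitors, mutations gain-of-function
  under one (and, by default, passing the statistical resistance filter
  there) while loss-of-function under the other. A laxer
  $\gamma$-only mode is available by flag.

Boundary conventions follow the printed thresholds inclusively for the
count filter (mean $\ge 4$, zero fraction $\le 10/12$, T0 zero fraction
$\le 2/3$; a variant with mean exactly 4 is kept) and exclusively for the
GOF/LOF gamma thresholds ($\gamma = 0.75$ is neutral). Filtering is per
condition; downstream cross-condition operations intersect variant sets
and propagate NA.

# The synthetic-data generator

The generator defines the study conditions the tests probe, not a tuning
surface:

* **Library**: 19 missense + 1 synonymous variant per position over a
  contiguous region, plus an early-stop nonsense control every 11th
  position starting at the region start (the spacing's phase is not
  constrained by the design, so the first position anchors it).
* **DMSO truth**: a bimodal mixture — neutral $N(0, 0.15^2)$ with weight
  0.6 and deleterious $N(-2, 0.4^2)$ with weight 0.4 — reflecting the
  qualitative shape of a kinase-domain mutational landscape under
  selection; nonsense variants sit below the deleterious mean. Synonymous
  variants are exactly 0 in every condition.
* **Inhibitor truth**: neutral-component variants receive a sensitivity
  shift of $-1.5$ doublings per interval (they grow, but slower than
  dosed wild type); planted resistance (position, mutation) pairs receive
  $+0.75$ to $+1.5$ under inhibitors of the matching type and a strictly
  negative DMSO score, so their resistance is inhibitor-specific by
  construction. The strictly negative DMSO truth (rather than exactly 0)
  keeps the classifier's DMSO cutoff testable: a true value on the
  decision boundary would be misclassified half the time by the noise of
  the estimate alone.
* **Counts**: variant $v$'s expected abundance at time $t$ is
  $\propto f_0(v)\, 2^{(g_{wt} + s_v)t}$ with $g_{wt} = 2$; sequencing is
  one multinomial draw of `depth` reads per (replicate, timepoint), or the
  exact expectations in noise-free mode. No overdispersion is added: the
  scorer's variance model is meant to be a floor, and the conservative
  total-dispersion term absorbs modest extra noise in real data.
* **Features**: all 14 catalogue features with the relationships the
  predictor exploits — the language-model log-likelihood ratio (`llr`)
  tracks DMSO fitness positively, the stability change `ddG` negatively;
  `residue_atp_distance` and `crystal_rmsf` depend only on position,
  `inhibitor_mw` only on the inhibitor, `delta_volume` only on the
  residue pair. Features stand in for structure-based pipelines
  (language-model inference, stability prediction, docking, pocket
  analysis), which are out of scope.

What passing tests on this generator do **not** show: robustness to PCR
jackpots and other overdispersed sequencing artifacts, codon-level
effects, variant dropout during library cloning, or the real covariance
structure of structural features. Conclusions about real screens need the
real feature pipelines.

# The fitness predictor

A gradient-boosted tree regressor (XGBoost) predicts per-(variant,
inhibitor) fitness from `llr` plus up to 13 optional features.
Protections against overfitting mirror the screen's structure:

* **Monotone constraints**: predictions are non-decreasing in `llr` and
  non-increasing in `ddG`.
* **Binning**: the 12 non-monotone optional features are coarsened to 4-5
  bins (training-quantile breakpoints by default, manual breakpoints
  supported), each value replaced by the median of its training bin;
  near-discrete features get one bin per observed level.
* **Split design**: the test set unions (a) every row of one held-out
  type I and one held-out type II inhibitor, (b) all rows at a random 20%
  of positions, (c) all rows of two held-out mutant residues. Of the
  rest, 20% tunes hyperparameters. DMSO and the lone type I 1/2 condition
  are excluded — a single condition of a type would be learned by
  memorising the condition label.
* **Cross-validation**: 10 folds partition training positions into equal
  groups (padding by re-sampling when not divisible) and residues into
  pairs (re-sampling when fewer than 20), so every fold's validation rows
  are at unseen positions or unseen substitutions.
* **Search**: all $2^{13} = 8192$ subsets of the optional features
  (`llr` always included) can be enumerated; the deterministic
  binary-counter order makes a cap of $2^j$ an exhaustive search over the
  first $j$ optional features, which is the desk-scale default (cap 64).
  Hyperparameters (booster, depth, trees, learning rate, minimum split
  loss, column subsample, L1/L2, growth policy) are chosen per subset by
  seeded random search minimising tuning MSE — a deliberate, declared
  substitute for Bayesian optimisation at these budgets (default 30
  trials; the analysis scripts use 10). Subsets are ranked by mean
  cross-validation Pearson r; the winner is refit on the full training
  set and reported per held-out inhibitor.

The analysis scripts regress the raw inhibitor-condition score
$\beta_{\text{inh}}$ rather than $\gamma$: the language model's signal is
mutational tolerance, which carries over to inhibitor conditions, whereas
subtracting DMSO removes exactly that shared structure and (under this
generator) leaves a target anti-correlated with `llr`, contradicting its
monotone constraint. Any target column can be supplied.

# Numerical and design choices

* Time index $t = 0, \dots, T-1$; slopes are shift-invariant so the
  labelling is a convention.
* Wild-type reference is the *mean* over synonymous variants
  (median configurable upstream by filtering); the synonymous mean of
  normalised values is exactly 0 by construction.
* `se = 0` (degenerate noise-free input) short-circuits tail
  probabilities to exact 0/1/0.5 steps.
* Pearson correlations between conditions use pairwise-complete variants,
  with a minimum of 3 shared variants per pair (NA with a warning below
  that).
* Ties in the model-search ranking break by enumeration order
  (first-come); empty training bins merge into their nearest non-empty
  neighbour with a warning.
* Per-stage seeds derive from one global seed by hashing the stage name,
  so any stage can be re-run in isolation; all outputs are byte-identical
  under a fixed config.
* Problem sizes in the shipped analysis: a 60-position library (1206
  variants), 7 conditions at depth $3\times10^5$, and a 64-subset search
  with 10 hyperparameter trials — small enough to re-run interactively
  while preserving every structural property of the full design.

# Known limitations

* The scorer is a deterministic surrogate; it does not produce posterior
  quantities (e.g. local false sign rates), and its conservative variance
  trades power for calibration.
* The resistance test's "tail probability" is a frequentist analogue of a
  posterior tail; with real, overdispersed data the 0.1 cutoff's operating
  characteristics will differ from the simulation's.
* Synthetic features have simple, independent structure; real structural
  features are collinear, and feature-subset selection on real data will
  be less decisive.
* The predictor family is fixed to monotone-constrained gradient-boosted
  trees; no neural alternatives are provided.
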