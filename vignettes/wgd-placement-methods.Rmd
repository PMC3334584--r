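---
title: "Placing and dating ancient whole-genome duplications: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing and dating ancient whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `wgdphylo`, the
assumptions behind them, the defaults and why they were chosen, and the
places where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The species scaffold and the placement hypotheses

The scaffold is fixed a priori:
`(basal_angiosperm,(magnoliid,(monocot,(basal_eudicot,(caryophyllid,asterid,rosid)))))`,
with the three core-eudicot lineages left as an unresolved trichotomy. The
four candidate duplication branches are nested: BR1 subtends monocots +
eudicots, BR2 all eudicots, BR3 core eudicots, BR4 rosids only. The
classification rule never needs the core-eudicot trichotomy resolved — it
only asks "inside core eudicots vs outside" — which is why the scaffold can
leave it open while the dated chronogram used for simulation resolves it
(caryophyllids first, then asterids + rosids).

Design choices made here:

* **Caryophyllids count as core-eudicot evidence equivalent to asterids.**
  Caryophyllids are core eudicots, so a caryophyllid inside a duplicate
  clade brackets the duplication exactly as an asterid does. Treating them
  as evidence uses the full species panel; a scorer that ignored them would
  only lose resolution.
* **Grass monocots (rice, sorghum) are admitted as monocot evidence by
  default.** Their elevated substitution rates are a hazard for *tree
  estimation*, which is upstream of this package; once a tree is given,
  a grass leaf is ordinary evidence. `use_grasses = FALSE` excludes them
  for sensitivity analyses.

## 2. The support-based placement rule

For a pair (a, b) on a rooted gene tree, the duplication node is the MRCA;
its two child clades (clade2 ∋ a, clade3 ∋ b) and the joining node carry
the support triplet (bootstrap1, bootstrap2, bootstrap3). A duplication is
scored at threshold *T* only when bootstrap1 ≥ *T* and at least one of
bootstrap2/bootstrap3 ≥ *T*; single-leaf clades count as trivially
supported (100), missing supports fail every threshold (conservative), and
a multifurcating MRCA is treated as a zero-support resolution.

The textual rule "a lineage contained in clade2 or clade3 with support ≥
*T*" leaves open *which* node's support certifies containment. The
implemented rule: a lineage L is certified inside a duplicate clade iff
some node of that clade (including its root) with support ≥ *T* subtends at
least one L leaf together with at least one focal-lineage (rosid) leaf.
This has two consequences we consider the right reading:

* a single L unigene inside a well-supported duplicate clade certifies L
  (the clade root is the certifying node — the situation where one asterid
  EST suffices);
* a single contaminant leaf none of whose rosid-containing ancestors within
  the clade is supported is ignored rather than escalating the call.

Sister evidence walks the ancestors of the duplication node; an ancestor
certifies the lineages appearing in its subtree outside the duplicate
clades when its bipartition support is ≥ *T*. At the root — which carries
no bipartition of its own in a rooted tree — the support of the root's
child on the path is used (the same bipartition).

The decision table then brackets the duplication: deepest certified inside
lineage monocot-or-deeper → BR1 (requires basal angiosperm sister), basal
eudicot → BR2 (requires monocot sister), asterid/caryophyllid → BR3
(requires basal eudicot sister), only rosids inside → BR4 (requires an
asterid/caryophyllid sister). We require the sister witness at the same
threshold as the inside witness — the stricter of the two possible
readings — because without a supported upper bracket the branch assignment
would be a guess.

A *tiered* call classifies at 50% first; the tier is `ge80` only when the
80% evaluation yields the same branch. This makes "every ≥80 call is also a
≥50 call" true by construction, matching how the two tiers are tabulated.
In principle the raw rule evaluated at 80% alone could name a different
branch than at 50% (extra evidence can be certified at the lower
threshold); the tiered call resolves that by always reporting the
50%-threshold branch.

Percentage rows are computed per tier over the BR1–BR4 total and printed at
one decimal with deterministic half-up rounding; the headline share is the
integer-rounded (BR2+BR3)/total. The published table these summaries mirror
rounds inconsistently (67% alongside 27.9%, 18.3% where the counts give
18.4%); we keep uniform rounding and check only the entries the arithmetic
actually reproduces.

**Rooting.** Orthogroup trees arrive unrooted (or arbitrarily rooted); the
package roots on the phylogenetically deepest lineage present (basal
angiosperm > magnoliid > monocot > basal eudicot), using the largest subset
of that lineage's leaves that forms a clade of the unrooted tree when they
are not monophyletic. This is a reconstruction of standard practice —
display trees rooted on basal angiosperms — not a published procedure.
Supports stay attached to the bipartitions they annotate. Trees containing
only core eudicots cannot be rooted and are logged as failures.

## 3. Penalized-likelihood dating

Branch substitution counts `x_k = branch length × nsites` are modeled as
Poisson with mean `r_k t_k`; the objective is the Poisson log-likelihood
minus `λ` times a smoothness penalty (squared rate differences across
adjacent branches, plus the variance of the root's child rates). Choices
that matter:

* **nsites defaults to 1000.** Branch lengths are per-site; the Poisson
  needs counts. When the alignment behind a tree is known its length should
  be passed instead; the default is a typical trimmed-alignment length and
  only scales the information content, not the age point estimates on
  clock-like data.
* **Age parameterization.** Each free internal node's age is a bounded
  fraction of its parent's age (logistic transform with a 1e-4 guard away
  from the boundaries), computed root-down. Ordering, fixed calibrations,
  and min/max constraints therefore hold *by construction*: fixed nodes are
  pinned exactly, and floors are propagated up from descendant constraints
  before fitting. Durations are floored at 1e-6 my; zero-length branches
  use the convention 0·log 0 = 0.
* **Optimization.** BFGS on (age parameters, log rates) with an analytic
  gradient (validated against finite differences in the tests); 5 restarts
  by default from a clock initialization (node ages proportional to mean
  subtending depth, scaled through the fixed calibrations) with jitter.
  The objective is multimodal in principle; restarts plus the clock start
  have been sufficient on every simulated tree (the tests include a
  beats-random-feasible-points check and a grid-search oracle on a 5-leaf
  tree).
* **Calibration transfer.** Calibrations are defined on the scaffold but
  applied to gene trees: the root (crown of the sampled angiosperms) gets
  min 131 / max 309 mya; every *minimal* node whose subtree contains only
  eudicot leaves, among them at least one basal eudicot and at least one
  core eudicot, is fixed at 125 mya. Minimality matters in duplicated
  trees: after a eudicot-wide duplication each surviving copy contains its
  own copy of the eudicot crown speciation, and each is fixed at 125, while
  the duplication node above them (which also subtends only eudicots) is
  left free.
* **Cross-validation.** For each candidate λ, each terminal branch is
  pruned, the tree refitted (one start, initialized from the clock
  solution, to keep the procedure affordable), and the pruned branch's
  count predicted as fitted-attachment-rate × attachment age, with the
  attachment age interpolated along the merged edge in proportion to the
  original branch lengths (midpoint fallback at multifurcations). The
  chi-squared prediction error is summed; ties go to the smaller λ. Tips
  hanging directly off a two-child root are skipped (their attachment
  vanishes when pruned). On clock-like or iid-rate data the curve is flat
  or favors large λ; a lineage-wide rate shift pushes the optimum back
  down — both behaviors are exercised in the tests. For large cohorts of
  exchangeable trees, `run_dating_pipeline(cv_pilot = m)` cross-validates
  only the first m trees and applies the modal winning λ cohort-wide;
  per-tree selection remains the default.
* **Root-edge caveat.** Re-rooting places one root child on a (near)
  zero-length edge, so the *root* age itself is weakly identified (the
  classic root-edge ambiguity); duplication-node ages below are unaffected,
  and the strict-clock recovery test dates the simulator's original rooted
  tree where the root age is identified.

## 4. Mixture models of ages and Ks

Univariate normal mixtures with per-component variances, fitted by EM: 100
random starts (means uniform on the data range, pooled variance, equal
proportions) plus 10 k-means starts with k-means++ seeding. Each start is
run for up to 30 iterations and the three best basins are then iterated to
convergence (relative log-likelihood change < 1e-8, cap 1000 iterations) —
the standard short-EM economy; the returned fit is the best converged
log-likelihood. A start whose component variance collapses below
1e-8 × var(data) is discarded; if every start collapses the fit errors.
BIC uses p = 3k − 1 free parameters (k means, k variances, k − 1
proportions); ties go to the smaller k. Component-mean CIs use the
effective component size n_j = Σ responsibilities: mean ± 1.96·sqrt(var/n_j).
An optional `split_at` adds one deterministic two-component start split at
a given value (e.g. 125 mya) to probe for bimodality around a constraint;
it is an initialization, not a hard constraint.

The EM log-likelihood trace is retained on every fit and asserted
non-decreasing in the tests; agreement with an independent implementation
(`mclust`, equal-loglik optima) is checked on fixtures.

## 5. Ks estimation

The primary estimator is the Goldman–Yang (1994) codon model with F3×4
frequencies: 61 sense codons (universal code only), single-nucleotide
exchanges at rate π_target × κ^[transition] × ω^[nonsynonymous], matrix
scaled to one expected nucleotide substitution per codon per unit t, and
the pairwise likelihood maximized over (t, κ, ω) with bounds t ∈ [1e-6,
50], κ ∈ [0.1, 20], ω ∈ [1e-4, 10], three outer starts, and t profiled by
one-dimensional optimization reusing the eigendecomposition per (κ, ω)
(the model is reversible, so the decomposition is symmetric and cheap).
Ks and Ka use the mutational-opportunity site definition: ks = t·ρS/(3·ρS¹)
with ρS the synonymous flux proportion at the MLE and ρS¹ the same at
ω = 1. F3×4 positions with a zero base frequency get a 1e-6
pseudo-frequency before renormalization; codons with gaps or ambiguity in
either sequence are masked pairwise; in-frame stops are an error.

The Nei–Gojobori (1986) counting method serves as the independent
cross-check: per-position synonymous site fractions with stop-codon
targets excluded from the alternatives (each codon carries exactly 3
sites), differences averaged uniformly over all shortest substitution
paths avoiding stop codons (if every path is blocked, steps count as
nonsynonymous), and the Jukes–Cantor correction −3/4·log(1 − 4p/3) with a
saturation error at p ≥ 3/4. Path averaging means a small nonsynonymous
fraction can be assigned even between codons reachable by purely
synonymous steps (e.g. arginine pairs whose alternative path crosses
serine) — this is inherent to the method, not a defect.

The codon-pair simulator inverts the same model: given a target Ks it
evolves a pair at t = 3·ρS¹·Ks/ρS, so the model-defined synonymous
divergence equals the target exactly and simulate-and-refit tests are
circularity-free with respect to the *estimator* (optimizer, site
decomposition, F3×4 estimation) while sharing the generator matrix.

## 6. The synthetic-orthogroup generator

`simulate_orthogroup()` clones the chronogram clade below a chosen scaffold
branch into 2 (or 3) copies at the duplication age, then applies:

* **Loss:** one copy per species is protected; each extra copy survives
  with probability exp(−loss_rate × age). The pre-duplication backbone
  never loses its single copy, so orthogroups stay single-copy outside the
  event. Expected copies per duplicated species are therefore
  1 + (m−1)·exp(−loss_rate·τ), which the tests verify by Monte Carlo.
  Default loss_rate 0.008 /my puts extra-copy survival at roughly 40% after
  ~120 my — heavy post-polyploidy fractionation, which is the realistic
  regime — while conditioning (resampling until the focal species keeps ≥ 2
  copies) mirrors conditioning on syntenic focal pairs.
* **Sampling:** each non-focal species is present with probability
  `sampling_prob` (default 0.8, emulating incomplete transcriptome
  coverage); the focal genome is always sampled.
* **Rates:** each branch duration is multiplied by rate_base (default
  0.002 substitutions/site/my, a typical angiosperm nuclear rate) and a
  mean-one lognormal multiplier with sigma `rate_sigma` (default 0.2,
  moderate among-branch heterogeneity). Multipliers are iid across
  branches — there is no autocorrelated or lineage-specific rate process,
  which is precisely why cross-validation tends to select strong smoothing
  on these cohorts.
* **Supports:** `support_clean()` (all 100) or `support_noisy()`
  (logistic in branch duration plus bounded noise, so radiations get low
  support, reproducing the resolution loss near the duplication).

Default duplication: branch BR3 at 122 mya, roughly centered on the default
chronogram's BR3 span (120–125). The feasibility invariant (the age must
lie on the branch) is enforced at configuration time. Cohorts seeded at
117 mya — the dated peak the recovery runs target — keep the same
mid-branch convention and use a chronogram variant with the core-eudicot
crown at 112 and the rosid–asterid split at 109 mya (anchors are
constructor arguments); the eudicot-crown calibration stays at 125, so the
dating problem is unchanged. The dating cohorts use one exemplar species
per lineage (10-tip trees), 161 orthogroups, clean supports, no loss, full
sampling, rate_sigma 0.2 and per-tree cross-validated smoothing; these
problem sizes keep a full cohort simulate–classify–cross-validate–date–mix
run in the minutes range on one core.

On such cohorts the dated ages recover the seeded peak without detectable
bias in the mean, and the BIC-selected mixture's dominant component covers
the seeded age. Whether BIC additionally spends a small (~5%) component on
the left tail of the estimation-error distribution is *not* numerically
stable — the 1-vs-2 choice has been observed to flip between
floating-point-equivalent runs of the same seeded cohort — so recovery
statements in the tests are made about the dominant component, not about
the selected k (see also the limitations below).

What passing on synthetic cohorts does **not** show about real data: the
generator has no gene-tree estimation error beyond the support model (no
long-branch attraction, no alignment error, no chimeric transcripts), no
incomplete lineage sorting, no lineage-specific rates, and no paralog
misassignment from collapsed tandem arrays. Recovery rates on clean
cohorts are upper bounds.

## 7. Degenerate inputs and tie-breaks, collected

* Missing bootstrap labels → fail all thresholds; non-numeric or
  out-of-range labels → parse error.
* Coverage filter boundary is inclusive (a sequence at exactly 70% is
  kept): the removal rule is "less than 70%".
* Duplicate (unordered) pairs collapse with a warning count; a pair whose
  genes coincide is an error.
* Mixture BIC ties → smaller k; CV ties → smaller λ; EM degenerate starts
  discarded, all-degenerate → error.
* Strata with fewer than 5 values skip the mixture with a warning.
* Unresolved calls cannot be dated; trees whose every λ fails
  cross-validation are excluded with a reason, and every input pair
  appears exactly once across the classified/failed/skipped logs.

## 8. Known limitations

* The placement rule is support-based, not reconciliation-based: it never
  optimizes duplication–loss costs, and it cannot place duplications for
  non-focal species pairs.
* Only the universal genetic code is supported; no site-heterogeneous
  codon models.
* Penalized-likelihood dating assumes the given topology and treats
  branch lengths as exact sufficient statistics scaled by `nsites`;
  gene-tree error propagates directly into ages.
* The root age of re-rooted trees is weakly identified (root-edge
  ambiguity); calibrations below the root are unaffected.
* BIC component counts on small cohorts (n in the low hundreds) are
  sensitive to skew in the age-error distribution; the peak location is
  much more stable than k itself.
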