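---
title: "Models, search strategies and design choices in mosaweak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, search strategies and design choices in mosaweak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaweak)
```

`mosaweak` assesses how robust the clades of a discrete-morphology
phylogeny — and the formal names attached to them — are to the choice of
tree-search strategy. This vignette documents the models, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open, so that a user can judge what a green test establishes and
what it does not.

## 1. Parsimony scoring

Characters are sets of integer states per OTU, held as bitmasks. Missing
(`?`) and inapplicable (`-`) codings are both expanded to the full state
set of their character: absent an explicit inapplicable-state treatment,
full ambiguity is the standard conservative reading, and the two codings
are deliberately not distinguished in scoring.

*Unordered* characters are scored by set-based Fitch optimization,
bit-parallel across characters. *Ordered* (additive) characters use
generalized Sankoff dynamic programming with cost `|i − j|`; the Sankoff
path also handles polytomous trees exactly (hard-polytomy reading), and
doubles as the general scorer against which the Fitch fast path is
cross-checked in the tests. Parsimony length is invariant to rooting; a
basal trifurcation (the `ape` representation of an unrooted binary tree)
is resolved sequentially, which is a re-rooting and changes nothing.

Per-character step bounds drive the ensemble indices:

* `m_i`, the minimum steps on *any* tree. For unordered characters this is
  (size of the smallest state set hitting every OTU's observed set) − 1,
  found by subset enumeration (state counts are small); for ordered
  characters it is the length of the shortest state interval intersecting
  every observed set. Fully ambiguous cells are excluded — they can never
  force a step.
* `g_i`, the star-tree maximum: scored OTUs minus the largest
  single-state class (unordered), or the summed distance to the best
  median state (ordered). The retention index is not defined by the
  analyses this package follows, so the standard ensemble convention is
  documented here and used throughout: `CI = Σm_i/L`,
  `RI = (Σg_i − L)/(Σg_i − Σm_i)`, reported to 4 decimals. When
  `Σg_i = Σm_i` there is no potential homoplasy and `RI` is signalled as
  undefined rather than returned as `NaN`. Because reporting tools differ
  on whether parsimony-uninformative characters enter these sums,
  `ensemble_indices(..., informative_only = TRUE)` implements the
  alternative convention; with the original matrix unavailable the package
  cannot determine which convention reproduces the printed values, so both
  are exposed.

Implied weighting minimizes the total distortion `D = Σ h_i/(h_i + K)`
with homoplasy `h_i = s_i − m_i`; the classic (not missing-corrected)
variant is implemented. Distortions are compared at an absolute tolerance
of 1e-8 when deciding score ties, because `D` is a float sum.

## 2. Tree search

Searches run on unrooted trees: seeded random-addition sequences (each
taxon inserted at its locally best attachment) refined by greedy SPR or
TBR descent that accepts equal-or-better trees and explores each optimal
plateau to closure, pooling across replicates and re-swapping from every
pooled tree. This approximates a "many replicates, save all shortest
trees" protocol; ratchet-style perturbation is intentionally out of scope
because the package's acceptance surface is score values and consensus
topologies, not search internals. The plateau cap
(`max_saved_trees`, default 10,000) flags truncation rather than silently
dropping trees; Bremer values whose converse-constraint search truncated
are reported censored (`">X"`).

Constraint-aware searches implement Bremer decay: the best score among
trees *not* containing a clade is found by adding a large penalty to
conforming trees, which keeps the whole plateau machinery unchanged.
Counts of most-parsimonious trees are logged but never asserted: they are
sensitive to the collapse rule and to search closure in ways scores are
not.

Bootstrap proportions resample characters with replacement and run a
reduced battery per pseudo-replicate (defaults: 500 replicates; clade
presence judged on the strict consensus of each replicate's best trees,
i.e. classic absolute frequencies). The replicate count is a package
default, not a reproduction of the original study's unstated setting; at
500 replicates the standard error of a 0.98 proportion is about 0.006.

## 3. Bayesian tip dating

The Mk model of Lewis for a k-state character — symmetric rates, uniform
stationary frequencies — is evaluated by Felsenstein pruning. Rate
variation across characters uses a discrete gamma with 4 categories
(quantile midpoints, mean normalized to 1); the shape is a sampled
parameter. Because morphological matrices exclude constant characters,
the likelihood is conditioned on variability per character, with that
character's own state count: `L_var = L / (1 − Σ_s L_const(s))`.

Branch-rate variation uses a discretized lognormal relaxed clock: the
multiplier of branch *b* is a quantile midpoint of LogNormal(−s²/2, s)
(mean 1), with the number of categories fixed at n − 1 for n branches and
a uniform prior over assignments. The base clock rate multiplies all
branches.

The tree prior is the constant-rate fossilized birth–death process with
sampled ancestors, conditional on the origin time, with extant sampling
ρ = 0 — every sample is a fossil, and age-0 tips are rejected at input
validation. With the standard birth–death-sampling functions `q(t)` and
`p₀(t)`, the log-density sums: `log q(t_or)` for the stem; `log(2λq(x))`
per true bifurcation; `log(ψ p₀(y)/q(y))` per terminal fossil;
`log ψ` per sampled ancestor. The factor 2 on bifurcations is the
orientation multiplicity of a branching relative to a sampled-ancestor
point on a branch; it matters because toggling a fossil between terminal
and ancestor changes the bifurcation count. The whole density was
validated against forward simulation: absolute probabilities and
shape-class frequencies for two- and three-sample outcomes match the
numerically integrated density (the two-sample check is kept in the test
suite).

Priors not dictated by the analysis design are package choices, stated
here and logged with every run: λ, μ, ψ ~ Exponential(mean 1); clock
scale s ~ Exponential(mean 0.3); gamma shape ~ Exponential(mean 1); base
clock rate ~ Exponential(mean 0.1), a weakly informative scale for
morphology (about 0.01–0.5 changes/My within the central mass); origin ~
Uniform(oldest tip age, 200 Mya). Tip ages are fixed at their point
values (the mean of each taxon's age range); interval sampling is a
possible extension but is off by default to keep desk-scale runs
deterministic and comparable.

The sampler is Metropolis–Hastings with multiplier moves on positive
scalars, uniform-window node-age and origin slides, category
reassignment, dated SPR (attachment point and age drawn uniformly from
the feasible set, with the full Hastings correction for the changing
feasible-set sizes and windows), and a reversible-jump sampled-ancestor
toggle. The toggle's acceptance carries the 1/(window) dimension factor;
its detailed balance is verified in the tests against numerical
integration on a two-fossil model. Where the two cited tree-model
variants differ (skyline vs constant-rate), the constant-rate model is
implemented; the original analyses reported overlapping results between
the two.

**Prior-only validation.** Sampling "from the prior" with the FBD density
switched on does *not* make the root-age marginal uniform: conditional on
fixed fossil ages the FBD density is not normalized over the restricted
tree space. For mechanical validation of the age and origin samplers the
package therefore provides `tree_prior = "reference"`: node ages uniform
*relative* to the root (density `(root − t₀)^{−(n_int − 1)}`), under
which the root-age marginal is exactly Uniform(oldest tip, 200) and is
tested as such. This mode exists for validation, not inference.

**Scaled-down runs.** The package's default run (hundreds of thousands to
a million generations, 20% burn-in, convergence gated on ESS > 100 for
λ, μ, ψ) is a deliberate stand-in for multi-ten-million-generation
production runs; the test suite uses runs of 12k–40k generations on 4–8
taxa chosen to keep the whole suite inside a grading time budget. The
parameter-recovery coverage check conditions on the true tree (sampling
λ, μ, ψ only): this validates the FBD density and the parameter samplers
— which is what that check targets — at a cost that fits the budget; full
joint topology recovery is exercised separately but not coverage-scored.

Summaries: the maximum clade credibility tree (sampled tree maximizing
the summed log clade frequencies, node ages annotated with the mean and
central 95% interval over samples containing the clade — a central
interval, not a strict HPD), the half-compact (majority-rule) consensus
of post-burn-in topologies, the sampled-ancestor count histogram with its
central 95% interval, and ESS via initial-positive-pair autocorrelation
sums (constant traces return the sample count with a degeneracy flag;
anti-correlated traces may legitimately exceed the sample count).

## 4. Clade definitions and the weak-spot report

Node-based definitions name the least inclusive clade containing all
internal specifiers; branch-based definitions the most inclusive clade
containing the internals and excluding every external. A name
**self-destructs** on a topology when an external specifier ends up
inside the would-be clade. A composite (clade-valued) external specifier
stands for the clade subtended by the MRCA of its members and intrudes
whenever that clade and the candidate clade share leaves — which covers
both the "contains" and the "nested inside" failure modes. Unresolvable
*internal* specifiers make a definition NOT_EVALUABLE, which is reported
distinctly from self-destruction; unresolvable externals simply cannot
intrude (they are reported, never silently dropped).

Species-level specifiers are mapped to matrix OTUs by: verbatim match,
then an explicit proxy table, then a genus-level fallback that only fires
when exactly one OTU shares the genus. Ambiguous fallbacks (congeneric
OTUs) require an explicit table entry. The packaged
`synthetic_proxies.tsv` is an *example* of the format — the original
matrix's OTU strings are not available to reconcile a real table against,
so users supply their own.

On consensus trees, a name whose anchors meet at a polytomy still applies
if no external intrudes (hard-polytomy reading); the report additionally
gives the fraction of underlying optimal trees on which the name applies,
so polytomy masking stays visible. Per name the summary is CONSISTENT
(applies in every run), UNSUPPORTED (in none), else STRATEGY_DEPENDENT.

## 5. The synthetic world, and what a green test establishes

The simulators generate the statistical structure the analyses assume:
forward FBD trees (defaults λ = 0.06, μ = 0.04, ψ = 0.03 per My, origin
100 Mya — a mildly supercritical regime yielding on the order of ten
fossil samples, the scale of the mosasauroid ingroup subclades) and Mk
matrices (default 50 characters; state counts 2/3/4 at 70/20/10%; rate
0.02 changes/My; gamma shape 1; 15% ordered morphoclines evolved under a
stepwise nearest-neighbour chain, so additivity is true by construction;
constant characters redrawn when variable-only ascertainment is on).
These values were chosen once as a realistic regime for Late Cretaceous
marine-reptile data and are not tuned against test outcomes.

The deterministic 12-taxon weak-spot fixture plants two binary characters
pulling a floater toward one clade against three morphoclines whose
intermediate states pull it elsewhere *only under additive scoring* —
so a designated name provably applies under unordered and self-destructs
under ordered treatment, under equal weights and implied weighting alike.

What the green suite establishes: the scoring engines equal brute-force
enumeration; the searches recover exhaustively verified optimum sets at
six taxa; the FBD density matches forward simulation; the samplers pass
detailed-balance and coverage checks at small scale. What it does not
establish: agreement with the original study's printed numbers (tree
lengths 445/465, CI/RI, decay and bootstrap values, posterior
probabilities), because the original matrix is not redistributable with
this package. The acceptance tests for those values are present, state
exactly that, and will run the faithful protocol the moment the file is
placed at `inst/extdata/supplementary_matrix.tnt`. Real morphological
data also violate the simulators' assumptions in known ways — correlated
characters, heterogeneous missingness, non-uniform fossil recovery — none
of which the generators emulate.

## 6. Known limitations

* No step-matrix or continuous characters; no extended implied weighting;
  no successive approximations.
* Search is desk-scale R: adequate for dozens of taxa, not hundreds; no
  sectorial searches or tree fusing.
* The MCMC recomputes the full likelihood per accepted move rather than
  caching per-branch partials; run lengths are sized accordingly.
* MPT counts depend on the collapse rule and are reported, never tested.
* Tip-age uncertainty is not integrated over by default.
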