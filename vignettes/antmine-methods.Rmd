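---
title: "Mining binary traits from literature and testing their effect on diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining binary traits from literature and testing their effect on diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antmine)
```

## The problem

Comparative questions of the form "does trait X change how fast lineages
diversify?" need two ingredients that are both expensive to assemble: a
binary trait scored for many species, and a dated phylogeny covering
them. `antmine` implements a workflow for the ant–plant mutualism case:
binary traits (nesting in domatia, visiting extrafloral nectaries,
consuming plant food bodies, dispersing seeds) are mined from the titles
and abstracts of the myrmecological literature by dictionary matching,
audited, and then analyzed on a phylogeny with state-dependent
speciation–extinction (SSE) models — BiSSE and the HiSSE family with
hidden rate classes and their character-independent (CID) null models.

Because the corpora such studies mine are not redistributable, the
package carries a first-class synthetic-corpus generator with known
ground truth and a state-dependent birth–death tree simulator; every
stage of the pipeline is tested against those known answers.

## Text mining

Documents are normalized (lower case, punctuation to spaces, whitespace
collapsed; the map is idempotent) and deduplicated on normalized text.
Matching is **exact whole-token phrase matching**: a species binomial or
a (possibly multi-word) trait term scores a document only if it appears
as a contiguous token sequence. There is no stemming and no abbreviation
expansion; plural/singular variants are explicit entries in the lexicon.
This is deliberately strict: it makes matcher behavior provable against
a brute-force token-window scan, and abbreviated genus names ("A.
cephalotes") are simply out of scope.

Scoring follows a presence/absence rule with an explicit evidence
threshold: a species scores 1 for a category if its name co-occurs with
a term of that category in at least `min_docs` documents (default 1)
that survive the correction overlay; it scores 0 if it appears in at
least one document but never with a surviving trait term; species
appearing in no document carry no information and are excluded. The
`min_docs` threshold is exposed because a stricter co-occurrence rule is
the natural dial against false positives, at the cost of recall.
`mutualist` is the OR of the four categories and `defense` the OR of the
three bodyguard categories; both are recomputed whenever a table
changes.

## Validation

Three instruments quantify mining quality:

* **Species accumulation curves**: at each sub-corpus size x the curve
  reports the mean and population standard deviation of the number of
  unique species detected, over `n_resamples` without-replacement
  samples. The implementation uses a nested design — each resample is
  one random permutation of the corpus read as prefixes — so every
  resample's counts, and hence the means, are monotone in x by
  construction, while each prefix is still a uniform
  without-replacement sample. At x = corpus size the curve equals the
  total observed count exactly with zero standard deviation.
* **False-positive audit**: (species, category) pairs with k = 1..5
  co-occurring documents are judged against labels (a manual overlay,
  or generator ground truth in synthetic studies) and the audit reports
  the false fraction per k, plus whether it declines with k.
* **Dataset comparison**: species- and genus-level overlap and
  differences between the mined list and an independently hand-compiled
  list, satisfying inclusion–exclusion exactly.

## The synthetic corpus generator

The generator is the testbed's definition of truth, so its structure is
chosen to make correctness provable rather than to imitate prose.
Documents are sentences of filler tokens disjoint from both the
dictionary and the lexicon. Each document is either a *co-occurrence
document* — exactly one species name plus one term of one category,
planted either as a true association or a deliberate false positive —
or a *plain document* with species mentions and no trait terms. True
(species, category) pairs receive 1 + Poisson(`trait_doc_rate`)
co-occurrence documents (default rate 1.5, giving audits a spread of
evidence counts); false pairs receive exactly one, which pins planted
noise to the k = 1 audit bin. Duplicates alter only case, punctuation,
and whitespace, so normalization must catch 100% of them. Species
mentions arrive at Poisson(`mention_rate`) plain documents (default 3).
Default per-category prevalences (6%, 8%, 4%, 12%) are of the order
seen in mined ant data, but they are chosen for test power — every
category populated in modest corpora — not as estimates of the real
literature. What the generator does **not** emulate: real abstracts'
phrasing, abbreviated or misspelled names, synonymy, and
cross-contaminated documents mentioning several species alongside
terms. Passing the end-to-end identity tests therefore certifies the
machinery, not the error rate to expect on a real corpus.

## Phylogeny preparation and sampling fractions

The tree is pruned to the species with trait data (`ape::keep.tip`;
degree-2 nodes are collapsed, so patristic distances among survivors
are unchanged). State totals are estimated by scaling the trait
dataset's state-1 proportion to the described-species total, rounding
to the nearest integer and obtaining the state-0 total by subtraction
so the described total is conserved (432/3341 of 14,416 gives 1,864
and 12,552). State-specific sampling fractions divide tip counts per
state by those totals; a global mode divides total tips by the
described total. Per-genus fractions (tips in tree over described per
genus) support clade-wise missing-data accounting.

## The SSE engine

The likelihood is the standard pruning computation for state-dependent
birth–death models. Along every branch the per-state extinction
probability E and likelihood density D satisfy

$$\frac{dE_i}{dt} = \mu_i - (\lambda_i + \mu_i + \textstyle\sum_j q_{ij})E_i + \sum_j q_{ij}E_j + \lambda_i E_i^2,$$
$$\frac{dD_i}{dt} = -(\lambda_i + \mu_i + \textstyle\sum_j q_{ij})D_i + \sum_j q_{ij}D_j + 2\lambda_i E_i D_i,$$

with tips initialized at \(D_i = f_i\,[\text{state compatible}]\) and
\(E_i = 1 - f_i\) (f the state's sampling fraction), daughters combined
at nodes with a factor \(\lambda_i\), and the root applying the root
policy. The default policy places all mass on observed state 0 (spread
equally over its hidden classes); alternatives are uniform weights or
user-supplied weights. No survival conditioning is applied by default;
a flag enables it.

Numerics: branches are integrated independently with an adaptive
Cash–Karp Runge–Kutta 4(5) scheme (relative tolerance 1e-8, absolute
1e-10), D is renormalized after every branch with the log of the factor
accumulated, and E is required to stay in [0, 1] up to roundoff.
Integration failures or vanishing likelihoods return `-Inf` rather than
an error during optimization. Under incomplete sampling E starts at
1 − f and converges monotonically to its equilibrium, so it need not be
non-decreasing along a branch; with complete sampling it is. The
integrator is verified against `deSolve::lsoda` at 1e-12 tolerance, a
closed-form constant-rate birth–death likelihood, an exact two-tip
analytic case, and independent full-tree recomputation on small trees.

### Model family

`make_model()` encodes the shared-parameter classes of each family:
BiSSE (k = 6) and its null (λ and μ shared, k = 4); CID-2 (four states
0A–1B, diversification tied across observed states within a hidden
class, one shared transition rate, k = 5); CID-4 (eight states, four
class-wise diversification pairs, all 32 allowed transitions equal,
k = 9); a one-hidden-class model in which class B attaches to observed
state 1 only (k = 10); and the full model (four λ, four μ, eight free
transitions, k = 16). Dual transitions — simultaneous change of
observed state and hidden class — are structurally zero in all
hidden-class models. Where the one-hidden-class model's transition
structure is genuinely ambiguous in published summaries, this package
fixes it as the four rates among 0A, 1A, 1B; and the CID-2 default
collapses all transitions to one class since that is how its rates are
reported. Free parameters are counted as one per class; fixed-zero
rates are not counted; AIC = 2k − 2 lnL.

### Fitting, MCMC, and derived quantities

`fit_mle()` optimizes the free parameters on the log scale from
multiple starts (a character-independent pure-birth guess plus
log-normal jitters), Nelder–Mead exploration polished by L-BFGS-B, with
an early rejection of rate vectors implying more than ~1e4 events over
the tree depth (such regions are numerically stiff and statistically
irrelevant). Ties across starts go to the first best. `mcmc_bisse()` is
a univariate slice sampler (stepping-out with a randomly split step
budget, then shrinkage) with independent exponential priors of rate
1/(2r), where r is the net diversification of a constant-rate
birth–death fit to the tree computed by the same engine with one state.
The two-phase scheme runs 1,000 tuning generations at width 0.1, resets
each width to the 5–95 percentile spread of the tuning samples, and
runs 10,000 main generations (defaults; experiments in the package use
shorter chains sized in their scripts). Sampling is on the natural
scale. Summaries report posterior means, standard deviations, and
2.5/97.5 percentile credible intervals, plus per-state net
diversification (λ − μ).

Marginal ancestral states are computed by constraining each node to
each observed state (hidden classes summed out) and renormalizing the
resulting likelihoods; tip-averaged rates weight each tip's class rates
by its hidden-class marginals computed the same way. Both reduce to
exact answers in degenerate cases (no transitions; identical classes)
and match independent recomputation on small trees.

## Tree simulation

`simulate_tree()` is an event-driven (Gillespie) simulation: waiting
times are exponential in the summed rate over extant lineages; events
are speciation (both daughters inherit the state), extinction, or an
anagenetic state change. The stop rule is simple stop-at-n on the
extant lineage count (or a time cap). This estimator of the stopping
time has the known mild bias relative to sampling-conditioned
approaches; for parameter-recovery and coverage experiments it is
adequate and far simpler. Incomplete sampling is applied post hoc by
independent per-tip retention with the state's f. Attempts that leave
fewer than two sampled tips are retried with a capped count.

## Experiment sizes and what the tests show

The packaged experiments use sizes chosen to make the statistical
checks decisive at desk scale: sign recovery of the speciation
difference uses 20 replicates of 300-tip trees (λ0 = 0.1, λ1 = 0.3,
μ = 0.03, q = 0.01); credible-interval coverage uses 10 replicates of
150-tip trees with 150 tuning and 500 main generations; the
prior-recovery check samples the prior alone for 4,000 generations. On
these sizes the sign of λ1 − λ0 is recovered in ≥ 90% of replicates and
CI coverage exceeds 80%. These are properties of the estimator on data
generated by the model; they do not certify behavior under model
misspecification, phylogenetic error, or trait misclassification, which
the real-data setting would add.

## Known limitations

* Matching cannot resolve abbreviated genus names or synonyms; the
  dictionary is taken as canonical.
* Non-ultrametric trees are accepted by the likelihood, but E-values
  from sister subtrees are then inconsistent at nodes (the model
  assumes contemporaneous tips); the engine uses the last-processed
  child's E, as is conventional.
* The one-hidden-class model's transition structure is a design choice
  (see above), not an established convention.
* Polytomies are rejected for fitting; resolve them upstream.
* The accumulation "non-mutualist" curve is not guaranteed monotone:
  a species can leave the set when a later document links it to a
  trait term.
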