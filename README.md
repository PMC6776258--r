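# antmine

Text-mined binary traits and state-dependent diversification on ant
phylogenies.

`antmine` is for evolutionary biologists who want to (1) assemble a
binary species-trait table from the titles and abstracts of a large
literature corpus by dictionary matching, (2) quantify how trustworthy
that table is, and (3) ask whether the trait changed speciation and
extinction rates on a phylogeny. The motivating system is ant–plant
mutualism: ants that nest in domatia, visit extrafloral nectaries
(EFNs), consume plant food bodies, or disperse elaiosome-bearing seeds,
versus ants never reported doing any of these.

## What it computes

**Mining.** Documents are normalized and deduplicated; a binary
term-document matrix records which n-grams — species binomials from a
dictionary and (possibly multi-word) trait terms from a lexicon — occur
as whole-token phrases in each document. A species scores 1 for a
category iff its name co-occurs with a category term in at least
`min_docs` documents surviving a manual-correction overlay, 0 if it
appears only without trait terms, and is excluded if it never appears.
A combined `mutualist` column is the OR of the four categories;
`defense` the OR of the three bodyguard categories. Validation tools
compute species accumulation curves (mean ± SD over sub-corpus
resamples), a false-positive audit by co-occurrence count k, and
species/genus-level comparison against a hand-compiled list.

**Diversification.** The package implements the BiSSE/HiSSE model
family from scratch: per-state speciation (λ), extinction (μ), and
transition (q) rates, with hidden rate classes A/B (and C/D for the
CID-4 null) and dual transitions fixed to zero. The pruning likelihood
integrates, along every branch,

    dE_i/dt = μ_i − (λ_i + μ_i + Σ_j q_ij) E_i + Σ_j q_ij E_j + λ_i E_i²
    dD_i/dt = −(λ_i + μ_i + Σ_j q_ij) D_i + Σ_j q_ij D_j + 2 λ_i E_i D_i

with tip initialization D = f·1[state], E = 1 − f for state-specific
sampling fractions f, node combination D_i = λ_i·D_left,i·D_right,i,
and a root policy that by default fixes the observed root state to 0.
On top of the likelihood: multi-start maximum likelihood with
AIC = 2k − 2 lnL model ranking across six families (BiSSE null, BiSSE,
CID-2, CID-4, one-hidden-class, full HiSSE), slice-sampling MCMC with
exponential priors of rate 1/(2r), marginal ancestral state
reconstruction, and tip-averaged rates under hidden-class models. A
Gillespie simulator of state-dependent birth–death trees and a
ground-truthed synthetic-corpus generator make every stage testable.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study:
`01` simulates a 200-tip phylogeny under mutualism-dependent rates
(λ0 = 0.10, λ1 = 0.25, μ = 0.03, q01 = 0.01, q10 = 0.12) plus a
2,875-document corpus (2,500 unique) whose planted species–trait
associations match the tip states; `02` mines it; `03` validates;
`04` fits the model battery; `05` runs the MCMC; `06` calibrates the
estimators. From `02`–`04`:

```
corrected: domatia=20 efn=34 food_bodies=8 seed_dispersal=75
           defense=53 mutualist=98 of 469 species
false-positive rate by co-occurrence count:
 k n_pairs n_false   fp_rate
 1     112      87 0.7767857
 2      52       0 0.0000000
 ...
Tips after pruning: 191 (state 1: 56, state 0: 135)
Model comparison (AIC ascending):
  model                 lnL    k          AIC     dAIC
  bisse            -676.283    6     1364.566     0.00
  hisse_1hidden    -675.229   10     1370.459     5.89
  hisse_full       -672.247   16     1376.495    11.93
  bisse_null       -692.478    4     1392.957    28.39
  ...
tip-averaged rates by observed state (best hidden model):
 state n_tips    lambda          mu       div
     0    135 0.1735721 0.071066132 0.1025060
     1     56 0.3695782 0.000816767 0.3687614
```

Reading this: the overlay removed all 87 planted false associations
(which all sit in the k = 1 bin, so the corrected table equals ground
truth); after pruning the tree to trait-scored species the
trait-dependent two-state model wins the AIC comparison — correctly,
since the data were simulated under it — and the tip-averaged rates
recover the planted pattern of faster net diversification in
mutualists (0.37 vs 0.10, truth 0.22 vs 0.07).

Equivalent single calls: `mine_corpus()`, `accumulation_curve()`,
`false_positive_audit()`, `compare_datasets()`, `prune_to_traits()`,
`estimate_state_totals()`, `state_sampling_fractions()`,
`make_model()` + `fit_mle()` + `compare_models()`, `mcmc_bisse()`,
`asr_marginal()`, `tip_rate_average()`, `simulate_tree()`,
`recovery_experiment()`, or `run_pipeline()` for the whole chain.

## Layout

```
R/                 package code (mining, validation, phylogeny prep,
                   SSE models, simulation, pipeline)
src/               Rcpp ODE integration + pruning core
analysis/          numbered study scripts writing under results/
vignettes/         methods vignette (model, assumptions, design choices)
tests/testthat/    unit, property, and acceptance suites
scripts/           acceptance.R
```
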