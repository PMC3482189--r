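---
title: "Phylogenetics on secondary-structure recoded rRNA: models and methods"
author: "strucphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetics on secondary-structure recoded rRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucphylo)
```

## The problem and the model

Ribosomal RNA folds into a conserved secondary structure of base-paired
*stems* and unpaired *loops*.  Standard nucleotide phylogenetics treats
every alignment column as an independent 4-state character, which is
wrong for stems twice over: the two partners of a pair are strongly
correlated (a substitution on one side selects for a compensatory
substitution on the other), and the substitution dynamics of paired
bases differ from unpaired ones.  Treating the two columns of a pair as
independent both miscounts evidence (each compensated change is counted
twice) and mismodels it.

`strucphylo` implements the recoding approach to this problem.  Given a
secondary-structure model for one *reference taxon* (for the real data
that is a curated comparative model of *Saccharomyces cerevisiae*
rRNA), each sequence is rewritten over a **20-symbol structure
alphabet**:

* 4 symbols for unpaired bases: A, C, G, U;
* 16 symbols for ordered base-pair doublets: AA, AC, ..., UU
  (5' partner first, bases ordered A < C < G < U).

One base pair becomes **one** 20-state character, so a compensated
change is one event, and non-Watson–Crick doublets (A·G and the rest)
are ordinary states rather than errors.  Because the alphabet has
exactly 20 symbols, each symbol carries a fixed one-letter amino-acid
alias (`structure_alphabet()` prints the bijection), which lets the
recoded matrix flow through any 20-state protein phylogenetics stack.

### Projection and missing data

The structure is known for the ungapped reference sequence; it is
projected through the reference's gapped alignment row
(`project_to_alignment()`).  Columns where the reference has a residue
become `loop` or `stem5`/`stem3` columns; columns where the reference
has a gap are `uncovered`.  Uncovered columns are retained and coded as
unpaired single bases by default (`drop_uncovered = TRUE` removes
them): the structure model is silent about them, but their nucleotides
still carry signal.

Gaps and IUPAC ambiguity codes map to a single missing symbol `?`; at a
stem site a gap or ambiguity in *either* partner makes the whole
doublet missing.  Ambiguities are not expanded into partial state sets
because every downstream 20-state model here shares one missing-data
convention (a partial-likelihood vector of ones); no columns are ever
deleted.

## The likelihood engine

`log_likelihood()` is a Felsenstein-pruning implementation over generic
reversible k-state models, used for both the 20-state structure arm and
the 4-state nucleotide comparison arm.  `build_model()` constructs

* `poisson` — all exchangeabilities equal (the Jukes–Cantor/Mk family),
* `gtr` — free symmetric exchangeabilities,
* `fixed_exchangeability` — any published table in PAML lower-triangle
  format, e.g. LG;

each with equal, empirical (pooled over the whole matrix, missing cells
excluded) or user-supplied frequencies, and normalised so one unit of
branch length is one expected substitution per site at equilibrium.
Rate variation is the usual discrete gamma (equal-probability
categories, category rate = mean of its quantile slice, renormalised to
mean one; 4 categories by default, the field standard) plus an optional
invariant-site class.

The default model for recoded data is **Poisson(20) + empirical
frequencies**.  The historical analyses of such data used the LG
protein matrix, but LG's exchangeabilities encode amino-acid
biochemistry that has no meaning for doublet symbols; the engine
accepts LG (or any fixed table) for fidelity runs, while the package
default is the assumption-free symmetric model.

Branch lengths are optimized coordinate-wise against cached "up/down"
edge partials, so one branch evaluation costs a single k×patterns
product; each univariate problem is solved on [1e-8, 20] and cycles
repeat until the log-likelihood improves by less than 1e-6 (at most 100
cycles).  The trace is non-decreasing by construction.  Gamma shape,
invariant fraction and (softmax-parameterised) frequencies can be freed
alongside.

## Tree search, bootstrap, consensus

Both criteria use seeded random-addition starting trees (10 by default)
followed by NNI hill-climbing: parsimony uses bitmask Fitch scoring
(polytomies by sequential pairwise set combination), likelihood scores
each NNI neighbour with a short branch-length pass and fully
re-optimizes accepted moves.  NNI rather than TBR is a deliberate
trade: at the tens-of-taxa scale of this analysis, NNI from multiple
random-addition starts recovers the same optima at a fraction of the
cost, and the multi-start design preserves the spirit of classic
"10 random addition sequences per replicate" parsimony practice.
Equally optimal trees are all retained.

The nonparametric bootstrap resamples **structure sites** — a stem pair
is one resampling unit, which is precisely the point of the recoding —
with replacement, reruns a (shallower, 2-start) search per replicate,
and summarises support either as a ≥50% majority-rule consensus or by
mapping split frequencies onto a target tree (`majority_consensus()`).
Full-fidelity replicate counts are 100 (ML) and 1000 (MP); tests and
the bundled analysis scripts use reduced counts, which changes only the
Monte-Carlo resolution of the support values.

## Ancestral-state reconstruction

Before reconstruction, internal edges with support strictly below 50%
are contracted into soft polytomies (`collapse_weak_nodes()`; support
exactly 50 is retained, and the contracted edge's length is discarded
rather than redistributed — collapsing is a topological statement).

Two reconstructions are reported per character on the collapsed tree:

* **Mk ML** (`mk_asr_ml()`): the one-parameter symmetric Markov model;
  the single rate is fitted per character (characters evolve at very
  different tempos, so sharing a rate would bias both), then marginal
  posterior state probabilities are computed at every internal node by
  an up/down pass that handles polytomies natively.  Missing tips (the
  outgroups' ascus state, for instance) contribute uniform partials.
* **MP** (`fitch_asr_mp()`): the set of states attained at each node in
  at least one most-parsimonious reconstruction, computed exactly by
  Sankoff dynamic programming (down and up passes) rather than the
  approximate Fitch up-pass, so polytomies and missing data cost no
  accuracy.  Equivocal nodes are displayed as equal pie fractions
  1/|set|.

The two built-in characters replicate the study's morphology at class
level: ascus dehiscence mechanism (six states: wall-deliquescent
*Schizosaccharomyces*–*Saccharomyces* type, *Taphrina*–*Neolecta*
apical slit, *Orbilia* apex-tearing, operculate lid, bitunicate
two-walled, inoperculate pore) and ascoma shape (absent / exposed
hymenium / ostiolar-or-sealed).  Where the source descriptions are
class-level with named exceptions, the fixture follows them
(*Caespitotheca*, *Erysiphe* ostiolar within otherwise-apothecial
Leotiomycetes); the one genuinely ambiguous case — which sampled
Dothideomycetes are apothecial — is coded at class level and flagged in
the fixture's comments rather than silently guessed.

## The synthetic-data generator

Real rRNA data cannot ship with the package, and the study's headline
support values depend on 66 GenBank sequences and hours of bootstrap.
Testing therefore rests on a generator whose statistical structure is
exactly what the recoder assumes:

* a seeded Yule tree (`simulate_tree()`), birth rate 5 by default so an
  8-tip tree has mean root-to-tip depth ≈ 0.35 expected
  substitutions/site — the divergence scale of phylum-level SSU+LSU
  data (at depths much beyond this, 4-state loop sites saturate toward
  ~25% identity, which real rRNA alignments never show);
* loop columns evolving independently under a 4-state model, and each
  stem pair evolving as a **single 16-state doublet** that is then
  written out as its two nucleotide columns — compensatory change is
  built in by construction, so recoding the emitted alignment recovers
  the simulated doublet states exactly (a tested round-trip);
* Mk-evolved tip characters for the reconstruction machinery.

All randomness flows from one explicit seed through a scoped generator
(`withr::with_seed`), so nothing perturbs or depends on the session RNG.

What the generator does *not* emulate: indels and alignment error
(sequences are simulated ungapped; the real pipeline consumes a curated
alignment), pseudoknots, SSU/LSU partition differences (a single
concatenated partition, as in the emulated analysis), base-composition
heterogeneity across lineages, and any difference between the true and
assumed structure model.  Passing tests on simulated data therefore
demonstrate the correctness and calibration of the machinery, not the
fidelity of any particular biological reconstruction.

## Numerical choices and problem sizes

* Likelihood: site patterns compressed; partial-likelihood underflow
  handled by per-node rescaling only when detected (cheap common case,
  exact rare case).  Transition matrices come from a symmetrised eigen
  decomposition computed once per model.
* Optimization: branch bounds [1e-8, 20]; lnL tolerance 1e-6; gamma
  shape searched on a log scale in [0.02, 100]; Mk rate in [1e-6, 1e3].
* Ties: equally-good start trees deduplicated by Robinson–Foulds
  distance; MP ties within 0.5 changes, ML ties within 1e-4 lnL.
* Test problem sizes: oracle equivalence is proven exhaustively on all
  unrooted 4- and 5-tip topologies (k ∈ {2, 4, 20} for likelihood,
  k ≤ 3 for parsimony); recovery experiments use 8 tips × 300 structure
  sites × 20 seeds and 16 tips × 200 characters — sizes chosen so the
  full suite runs in minutes on one core while keeping every estimate's
  Monte-Carlo error far below its acceptance margin.

## Known limitations

* With 300 structure sites, an internal edge much below ~0.01
  substitutions/site carries on the order of one un-overwritten change,
  so maximum likelihood can genuinely tie between the true resolution
  and a neighbouring one.  Raw Yule trees produce such an edge in
  roughly a fifth of 8-tip draws at any realistic depth, which bounds
  achievable topology-recovery rates below 100% regardless of
  implementation; the bootstrap correctly reports those edges as
  unsupported.
* NNI search can in principle be trapped by local optima that TBR would
  escape; multiple random-addition starts mitigate but do not eliminate
  this.
* The Mk reconstruction assumes a single symmetric rate per character;
  directional (asymmetric) evolution of, say, fruitbody closure would
  require a richer model that the data here cannot identify.
* The 20-state model treats loop and stem sites as draws from one
  stationary distribution; empirical frequencies absorb the marginal
  mixture but not the class difference in dynamics.  A partitioned
  analysis would be more faithful; the single-matrix analysis is kept
  because it is the method under study.
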