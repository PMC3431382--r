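---
title: "EDGE prioritization: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EDGE prioritization: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical and design
choices made where more than one defensible option existed.

## The pipeline

The package turns two inputs — a rooted, dated higher-taxon tree and a table
assigning species to those higher taxa (with optional subgeneric species
groups and an IUCN Red List category per species) — into ranked conservation
priority lists, in five stages:

1. **Grafting** (`graft_species`). Each backbone tip with *k* ≥ 2 assigned
   species becomes an internal node carrying a star polytomy of its species,
   or nested stars when species-group labels are present (groups are treated
   as monophyletic; `"genus/group"` paths nest stars within stars, which is
   also how suprageneric backbone tips are handled). A tip with exactly one
   species is renamed. Species whose higher taxon is unknown are dropped with
   a warning and counted — a judgment call that favours assembling the bulk
   of a class over failing on stragglers.
2. **Dating** (`date_pure_birth`). New nodes get ages from the pure-birth
   interpolation *t* = *T*·ln(*a*)/ln(*b*), processed root-to-tip so every
   node's *T* is its immediate (possibly just-dated) parent's age. The
   assumption is a constant-rate branching process within unresolved clades —
   a null model, not an inference.
3. **ED** (`ed_fair_proportion`, `ed_polytomy_corrected`). Fair-proportion
   ED divides each branch equally among descendant tips. The polytomy
   correction replaces each polytomy child's literal star share with its
   expected share over random dated resolutions of that polytomy.
4. **Scoring** (`edge_scores`, `candidate_list`, `running_mean_ed`). Five
   weighting schemes (EDGE log-2/log-1.25/log-5, expected loss, IUCN500);
   DD/EX species excluded from ranking; a DD candidate list from the top 5%
   of the all-species ED distribution; scheme-comparison curves with the
   pure-ED upper and threat-first lower envelopes.
5. **Robustness** (`perturb_ed`, `perturb_ge`, `impute_dd`,
   `run_experiment`). Monte-Carlo perturbation of placement, threat status
   and DD fate, summarised as the proportion of the reference top-100
   retained.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| EDGE fold-increase *f* | 2 (variants 1.25, 5) | — | one Red List step doubles quasi-extinction-risk; the variants bracket threat-light and threat-heavy listing |
| expected-loss probabilities | 0.001/0.01/0.1/0.67/0.999 | 100-y extinction prob. per LC..CR | the standard 100-year expected-loss weights |
| IUCN500 probabilities | 0.005/0.05/0.39/0.996/1 | 500-y extinction prob. | longer-horizon variant; the most even-handed scheme in the curve comparison |
| candidate threshold | top 5% of all-species ED | — | "high ED" for unassessable species |
| enumeration cutoff `max_exact` | 7 children | — | 10,395 labeled topologies is the largest exhaustive set that stays sub-second |
| Monte-Carlo draws `n_samples` | 1000 per polytomy | — | standard error of a star share at k = 20 is well under 1% of the share |
| top-list size `top_n` | 100 | species | the conventional actionable list size |
| experiment `replicates` | 1000 | — | similarity SE ≈ 0.002 at 500 species |

## The polytomy correction, precisely

A polytomy node of age *T* with children *c₁..c_k* (each child a tip or an
already-resolved clade with *m_j* tips and age *a_j*) is treated as *k*
exchangeable units. A *resolution* is a labeled rooted binary topology on
the units; its internal nodes are dated top-down by the same pure-birth
interpolation, floored at the oldest unit below (so a pre-dated child clade
never hangs from a younger node) and capped at the parent's age. Each tip
below unit *j* receives the sum over the root-to-unit path of
(edge length)/(tips below the edge); the correction is the mean of this over
resolutions. Only shares *inside* the polytomy change: the branches above it
see the same total tip count, so the correction is strictly local, and
nested polytomies can be corrected independently in any order.

Design choices here, and why:

* **Uniform vs Yule weighting of resolutions.** The expectation "over all
  possible resolutions" can weight every labeled topology equally (default)
  or by its probability under a pure-birth branching process on the units
  (`weights = "yule"`, using the Steel–McKenzie form
  ∏ 1/(*n_v* − 1) over internal nodes). The two coincide at *k* = 3 and
  differ little beyond; both are provided because neither reading is
  uniquely forced by the method's description, and the choice is the single
  most consequential ambiguity in the correction.
* **No renormalization by default.** Corrected scores sum to the *expected
  resolved* PD, which is below the star tree's PD; rescaling to the literal
  PD is available (`renormalize = TRUE`) but off, because the expectation is
  the quantity the correction defines.
* **Determinism.** Pure-star expected shares depend only on the star size
  *k*, so they are cached; above the enumeration cutoff they are estimated
  once per *k* with an internal RNG seed derived from *k* (isolated from the
  caller's RNG via `withr::with_seed`), making corrected ED bit-reproducible
  regardless of call order. Mixed polytomies (units with *m_j* > 1) use the
  caller's seed.

## Numerical choices and degenerate inputs

* Ages are the primary quantity; branch lengths are derived
  (length = parent age − child age). Ultrametry is asserted to 1e−8·depth.
* Dating's degenerate case *a* = *b* (a chain node that adds no branching)
  gets age 0.99·*T*, keeping strict parent-over-child order; occurrences are
  reported. *a* = 1 internal nodes cannot arise from grafting (stars have
  ≥ 2 children) and are an error.
* Ranking ties break by higher ED, then species name — priority lists are
  deterministic, which the similarity statistic requires.
* "Clades away" is formalized as edge-count distance between nodes
  (`clade_distance`); an intermediate-node count would differ by one. Moves
  target internal nodes at exactly that distance on the *reference* tree;
  when none is available the maximum available distance is used (and when
  earlier moves within a replicate have spliced away every node at exactly
  the requested distance, the nearest available one), with fallbacks
  counted.
* A moved species joins the target clade's root polytomy with a pendant
  branch equal to the target's age — the minimal re-dating consistent with
  ultrametry.
* Replicate seeds are drawn once from the master seed, so any replicate is
  reproducible in isolation from its recorded seed.

## The combined experiment

For the combined scenario the package draws one subset of species (the
`fraction`); each drawn species independently receives an ED move with
probability 1/2 (severity uniform on 1–2 clades) and a GE shift with
probability 1/2 (severity uniform on 1–2 categories, clamped at LC/CR), and
all DD species are imputed from the assessed category mixture (`dd_shift`
= 0 by default). The equal mixing weights are a package choice — the
scenario is described qualitatively ("one or two categories, one to two
clades") without exact weights — and are configurable in code.

Inside replicate loops ED is recomputed as fair proportion
(`correction = "none"`) by default: within a pure star the correction moves
all member tips identically, so it barely reorders lists, while costing a
full resolution-sampling pass per perturbed polytomy per replicate.
`correction = "polytomy"` is available when fidelity matters more than time.

## What the synthetic generator does and does not emulate

`simulate_study` produces a Yule backbone (default 380 tips, root 300 My),
log-series genus sizes (many monotypic genera, a few huge ones), a
`star_fraction` (default 0.7) of polytypic genera left fully unresolved with
the rest split into 2–6 random species groups, and categories drawn i.i.d.
from a mixture approximating a class-wide amphibian assessment
(LC .34, NT .07, VU .13, EN .13, CR .08, DD .24, EX .01). These defaults
were fixed once, from the qualitative description of the study system, and
produce the right gross structure: at the default scale the corrected-ED
distribution is strongly right-skewed, with a maximum near 190 My, ~10% of
species above 25 My and roughly 70% below 12.5 My.

What it does *not* emulate: phylogenetic signal in threat status (categories
are independent of the tree, whereas real extinction risk clusters),
taxonomic error structure, biogeography, and the literature-derived
placements a real backbone embodies. Passing tests on synthetic data
therefore demonstrate the *machinery* — conservation of PD, correction
oracles, monotone degradation under perturbation — not amphibian-specific
numbers; reproducing a published list requires supplying the corresponding
published tree and category table to the same functions.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run at 150–1500 species; the robustness property
checks use a 500-species, 40-genus study with 200 replicates per
experiment — enough for similarity standard errors near 0.002. One caveat
found there: a 500-species tree's internal diameter is about 18 edges, so
the extreme 16-clades-away severity saturates (most moves fall back to the
farthest available clade) and the similarity ladder is only monotone up to
8; the saturated point is checked as a bounded drop instead. The acceptance
script runs the full default scale (5700 species, 380 genera) with 250
replicates for tree-perturbing experiments and 1000 for category-only ones.

## Known limitations

* The pure-birth interpolation dates nodes from richness alone; it cannot
  recover rate variation, and grafted clades inherit their depth entirely
  from the backbone calibration.
* The correction treats nested polytomies independently; joint resolutions
  of parent and child polytomies are not sampled (no joint procedure is
  defined for the expectation, and the local corrections interact only
  through fixed tip counts).
* Perturbation experiments assume errors strike species uniformly at
  random; real misassessment and misplacement are biased toward poorly
  known, often high-DD clades.
* Newick is the only tree format (no NEXUS/phyloXML), and reticulation is
  out of scope.
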