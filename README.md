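# edgeprior

Phylogenetically informed conservation prioritization in R: build a dated
species-level phylogeny from a higher-taxon backbone plus a taxonomy, score
every species' Evolutionary Distinctiveness (ED), combine ED with IUCN Red
List categories into ranked EDGE-style priority lists, and measure how robust
the resulting top-100 list is to errors in the tree, the threat assessments,
and the fate of Data Deficient species.

It is aimed at conservation scientists assembling class-wide priority lists
(the motivating case is a near-complete amphibian phylogeny of thousands of
species, most of them hanging off unresolved genus-level star clades) and at
methods people who want the polytomy-corrected ED computation and the
rank-list sensitivity machinery as reusable, tested components.

## The method in brief

**ED (fair proportion).** For tip $i$,
$ED_i = \sum_{e \in \mathrm{anc}(i)} \ell_e / n_e$, where $\ell_e$ is the
branch length (My) and $n_e$ the number of tips descending from branch $e$.
Summed over tips, ED equals the tree's phylogenetic diversity (PD).

**Pure-birth node dating.** Species grafted under a calibrated backbone get
node ages by the Yule interpolation $t = T \cdot \ln(a)/\ln(b)$, with $T$ the
parent's age and $a, b$ the tip counts below the node and its parent,
applied root-to-tip so each new node's $T$ is its (possibly just-dated)
parent's age.

**Polytomy correction.** A star clade understates expected branch sharing.
For every polytomy, each child's share of the polytomy's branching is
replaced by its *expected* share over random dated resolutions: all labeled
binary topologies on the children (exhaustive up to 7 children; seeded
Monte-Carlo with ≥1000 draws above that), each dated by the same pure-birth
interpolation. Uniform weighting over labeled topologies is the default;
pure-birth (Yule) weighting is available.

**Scoring.** Five weighting schemes: the EDGE family
$\ln(1+ED) + GE\cdot\ln f$ with $f \in \{2, 1.25, 5\}$ and $GE = 0..4$ for
LC..CR; expected loss $ED \times p_{100}$
($p_{100}$ = 0.001/0.01/0.1/0.67/0.999); and IUCN500 $ED \times p_{500}$
($p_{500}$ = 0.005/0.05/0.39/0.996/1). Data Deficient and Extinct species are
excluded from ranking; DD species in the top 5% of the all-species ED
distribution form a *candidate list* for urgent assessment.

**Robustness.** Monte-Carlo experiments perturb (a) phylogenetic placement —
moving a fraction of species 1–16 clades away, (b) Red List categories —
shifting up/down 1–4 steps with clamping at LC/CR, (c) Data Deficient species
— imputing categories from the assessed mixture, optionally biased ±2 levels,
and (d) all of the above combined; the effect size is the proportion of the
reference top-100 list retained.

## Worked example

Everything below is synthetic — the generator emulates the statistical
structure of a class-wide assessment (Yule backbone, log-series genus sizes,
star-dominated resolution, ~¼ DD species):

```r
library(edgeprior)
library(dplyr)

study <- simulate_study(synthetic_config(n_species = 800, backbone_tips = 60,
                                         root_age = 300, seed = 42))
asm  <- graft_species(study$backbone, study$species, seed = 42)
tree <- date_pure_birth(asm$tree)
asm$report
#> # A tibble: 1 × 4
#>   n_assigned n_orphans_randomized n_unplaced  seed
#>        <int>                <int>      <int> <int>
#> 1        800                    0          0    42

ed  <- ed_polytomy_corrected(tree, seed = 42)
tab <- left_join(ed, study$species[, c("species", "category")], by = "species")
edge_scores(tab, quiet = TRUE) |>
  arrange(rank_edge_log2) |>
  select(species, ed, category, score_edge_log2, rank_edge_log2) |>
  head(5)
#> # A tibble: 5 × 5
#>   species    ed category score_edge_log2 rank_edge_log2
#>   <chr>   <dbl> <chr>              <dbl>          <int>
#> 1 g26_sp1 127.  CR                  7.62              1
#> 2 g41_sp1  68.1 CR                  7.01              2
#> 3 g14_sp1  59.3 CR                  6.87              3
#> 4 g29_sp8  49.9 CR                  6.70              4
#> 5 g59_sp2  46.5 CR                  6.63              5
```

The top of the list is what the method is built to find: species that are
both highly evolutionarily distinct (`ed`, in My of unique evolutionary
history) and highly threatened. The candidate list surfaces Data Deficient
species whose ED alone would place them near the top if they turn out to be
threatened:

```r
candidate_list(tab) |> head(3)
#> # A tibble: 3 × 3
#>   species     ed  rank
#>   <chr>    <dbl> <int>
#> 1 g52_sp1  152.      1
#> 2 g47_sp1   86.0     2
#> 3 g34_sp10  64.2     3
```

How stable is the top-100 under plausible assessment error? Shift 10% of
species' Red List categories by two steps, 200 times:

```r
run_experiment(tree, study$species[, c("species", "category")],
               kind = "ge", fraction = 0.1, n_categories = 2,
               replicates = 200, seed = 1)
#> <edge_experiment> kind = ge  fraction = 0.1  replicates = 200
#>   top-100 similarity: mean 0.943 [0.910, 0.970]
```

On average ~94% of the list survives. `tidy()` returns per-replicate rows,
`glance()` a one-row summary, and `autoplot()` plots the similarity
distribution; `running_mean_ed()` + `autoplot()` draw the scheme-comparison
curves with their pure-ED upper and threat-first lower envelopes.
`run_pipeline()` runs the whole chain from a YAML config and writes CSVs plus
a checksummed manifest.

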