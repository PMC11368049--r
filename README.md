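# adlearn — exploitative active learning on molecular pairs

`adlearn` is an R package for model-guided compound selection when potency
data is scarce: the early phase of a hit-finding or lead-optimization
campaign, where only a handful of measured molecules exist and each new
assay result is expensive. It implements the **ActiveDelta** acquisition
strategy alongside the standard single-molecule and random baselines, plus
the evaluation suite used to compare them (top-decile hit retrieval,
Bemis–Murcko scaffold diversity, nearest-neighbor similarity trajectories,
chemical-space embeddings, Wilcoxon signed-rank comparisons).

## The method

Classic exploitative active learning trains a regressor
$\hat{f}(x) \approx y$ on the labeled training set (molecule fingerprint
$x$, potency $y$) and acquires the pool candidate with the highest predicted
potency. With two starting molecules, such models have almost nothing to
learn from and tend to chase analogs of the best compound seen so far.

ActiveDelta instead trains on *molecular pairs*. The $n$ training molecules
are cross-merged into all $n^2$ ordered pairs $(i, j)$, each labeled with
the potency difference

$$\Delta y_{ij} = y_j - y_i,$$

and a regressor $\hat{g}(x_i \oplus x_j) \approx \Delta y_{ij}$ is fit on
the concatenated fingerprints. At acquisition time the current best training
compound (the *anchor* $a$) is paired with every pool candidate $c$, and the
candidate maximizing the predicted improvement $\hat{g}(x_a \oplus x_c)$ is
acquired. Two properties make this attractive in low-data regimes:

- **combinatorial expansion** — $n$ labels become $n^2$ training examples;
- **offset cancellation** — any constant assay shift cancels exactly in the
  difference labels.

Everything runs on Morgan fingerprints (radius 2, 2048 bits); potencies are
oriented so larger = more potent (the loader maps raw $K_i$ to
$\mathrm{p}K_i = -\log_{10} K_i$). Regressors: gradient-boosted trees
(xgboost) and random forest with library-default settings, perfect/noisy
oracles for protocol testing, and an adapter slot for an external
two-molecule message-passing network.

## Worked example

A synthetic benchmark — valid SMILES from a fragment grammar with potency a
linear function of fingerprint bits plus assay noise — so the full loop runs
without any external data:

```r
library(adlearn)

spec <- landscape_spec(library_size = 120, noise_sd = 0.3, seed = 42)
ds   <- generate_library(spec)
ds
#> <compound_dataset 'synthetic_seed42' (learning): 120 molecules>
#>      id                 smiles  potency
#> 1 syn_1  NC1CCC(CN1)OCc1ccncc1 6.414954
#> 2 syn_2   Fc1occ(c1)C=Cc1cccs1 5.941923
#> ...

hits <- top_decile(ds)           # the 12 most potent molecules = "hits"
hits
#> <hit_set: 12 hits, potency >= 9.870>

pol  <- policy_config("activedelta", iterations = 30, seeds = 7)
traj <- run_active_learning(pol, ds)
summary(traj)
#> Active learning (activedelta): 30 acquisitions
#>   best potency: 7.773 at cold start -> 12.383 after run

round(retrieval_curve(traj, hits)[c("0", "10", "20", "30")], 3)
#>     0    10    20    30
#> 0.000 0.000 0.167 0.417
```

Starting from two random compounds (neither a hit, best potency 7.77), the
paired gradient-boosted model finds 42% of the top-decile hits within 30
acquisitions — including the single most potent molecule in the library
(potency 12.38) — and those hits span 5 distinct Murcko scaffolds (42% of
all scaffolds present among the hits):

```r
sel <- rbind(attr(traj, "cold_start"),
             as.data.frame(traj)[, c("id", "smiles", "potency")])
scaffold_diversity(sel, hits)
#> $count
#> [1] 5
#> $fraction
#> [1] 0.4166667
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/adlearn-cli.R simulate --size 300 --noise 0.3 --seed 7 --out fixture.csv
Rscript inst/scripts/adlearn-cli.R run --dataset fixture.csv --policy activedelta \
        --family gbt --iterations 50 --repeats 3 --seed 7 --out runs/ad
Rscript inst/scripts/adlearn-cli.R evaluate --runs runs/ad --dataset fixture.csv
```

Each run directory receives one trajectory CSV per repeat and a JSON
manifest (resolved config, seeds, versions, dataset checksum) sufficient to
re-execute the run bit-compatibly for the deterministic model families.

`inst/scripts/benchmark-harness.R` documents how to rerun the full
external-benchmark comparison given a downloaded collection of per-target
K_i CSVs; it is not part of the test suite.

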