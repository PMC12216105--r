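# demSBI — simulation-based machine learning for two-population demographic inference

`demSBI` estimates the demographic parameters of two connected populations
from genomic polymorphism data.  An ancestral population of diploid size
*N<sub>anc</sub>* splits *T* generations ago into two populations of sizes
*N₁*, *N₂* exchanging migrants at a symmetric per-generation rate *m*
(isolation-with-migration, IM); a secondary-contact variant (SC) adds
exponential size change at per-generation rates *g₁*, *g₂* and restricts
gene flow to the most recent fraction *d* of the post-split period.  The
likelihood of sequence data under these models is intractable, so the
package works the simulation-based way:

1. draw parameters from uniform priors and simulate multi-locus phased
   haplotype data with a coalescent backend (msprime, bridged from R);
2. reduce every simulated data set to a large, fixed vector of summary
   statistics — site-frequency spectra, linkage disequilibrium (*r²* by
   distance), identity-by-state and allele-frequency-conditioned IBS
   segment lengths, windowed haplotypic heterozygosity, Tajima's D,
   Hudson's *F*<sub>ST</sub>, *D*<sub>xy</sub> and the joint SFS — 3024
   features for the default design (10 diploids per population, 20 × 2 Mb
   loci), aggregated across loci by mean, median and variance;
3. train one regressor per parameter (random forest, gradient-boosted
   trees, and a multilayer perceptron with six ReLU hidden layers trained
   on MSE with prior-bound clipping), with accuracy reported as RMSE, MAE
   (± se) and NMAE = MAE / prior range;
4. compare against three ABC baselines (rejection, local-linear and
   neural-network regression adjustment over MAD-scaled Euclidean
   distances);
5. explain predictions with permutation feature importance (per feature
   and per statistic class) and Shapley values (exact tree-path algorithm
   for boosted trees, a sampling estimator otherwise).

It is aimed at population geneticists who want to benchmark or deploy
supervised, summary-statistic-based inference for two-population models,
with every stage reproducible from one master seed.

## A worked example

A miniature end-to-end run (the built-in fixture: 4 diploids per
population, 2 loci of 100 kb, 12 simulations), from priors to an accuracy
table:

```r
library(demSBI)

fx <- fixtureConfig()
cfg <- runConfig(model = fx$model, priors = fx$priors, design = fx$design,
                 nSims = 12L, splitSizes = c(8L, 2L, 2L),
                 methods = c("rf", "xgb"), targets = c("split_time"),
                 outDir = tempfile("demo_"), seed = 7L)
man <- runPipeline(cfg)
read.csv(man$files$evalTab)
#>    parameter method      RMSE       MAE    seMAE      NMAE
#> 1 split_time     rf  749.1673  693.1548 284.2325 0.2390189
#> 2 split_time    xgb 1490.9511 1336.8020 660.2240 0.4609662
```

(two test simulations and eight training draws; the numbers are what this
README's code printed — at fixture scale they hover around the
midpoint-baseline NMAE of 0.25, which is the point of the fixture: it
exercises the machinery in seconds, not the accuracy.)

At benchmark scale (`benchmarkConfig()`: the standard IM priors,
1500 simulations of 5 × 500 kb loci, 1000/250/250 split) the package's
accuracy picture emerges within ~15 minutes on one CPU; from a run of
`scripts/acceptance.R`:

```
rf   split_time      NMAE 0.1718      mlp  split_time      NMAE 0.1857
rf   n_ancestral     NMAE 0.0318      mlp  n_ancestral     NMAE 0.0711
xgb  n_current_1     NMAE 0.1382      mlp  n_current_1     NMAE 0.1442
abc rejection n_current_1  NMAE 0.2053
```

Every trained method beats the analytic midpoint baseline (NMAE 0.25) on
every parameter, and the learned regressors beat rejection ABC for the
current population size — the scaled-down analogue of the full-design
result.  `n_ancestral` is by far the easiest parameter, split time and
migration rate the hardest, matching the full-scale ordering.

Interpretation tools work on any trained model:

```r
imp <- permutationImportance(model, Xtest, ytest)   # R2 degradation
classImportance(imp, schema)                        # 11-class fractions
sh  <- shapleyValues(model, Xbackground, Xexplain)  # phi, base, ranking
plotShapBeeswarm(sh)
```

A thin command-line interface wraps the same functions
(`inst/cli/demsbi run-all --config run.yaml`); the methods vignette
(`vignettes/demographic-inference.Rmd`) documents the models, the
statistic layout, every tunable default and the package's numerical
choices.

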