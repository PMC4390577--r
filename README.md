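# blupga

Whole-genome prediction of breeding values for populations genotyped
with dense SNP panels, aimed at animal and plant breeders and
quantitative geneticists who want GBLUP's robustness *and* the extra
accuracy that knowledge of a trait's genetic architecture can buy —
without external GWAS priors.

## The model

Standard GBLUP fits the animal model

```
y = Xμ + Zu + e,   u ~ N(0, σu² G),   G = MM' / 2Σ p(1−p)
```

with `M` the centered dosage matrix (0/1/2 coding, p fixed at 0.5).
BLUP|GA ("BLUP given genetic architecture") replaces `G` with a
trait-specific covariance

```
T = ω S + (1−ω) G,   S = M₁ D M₁' / 2Σ p(1−p)
```

where `M₁` holds the *top%* fraction of SNPs with the largest RRBLUP
effects estimated in the training data (plus `nflank` map-adjacent SNPs
per side for linkage disequilibrium), and `D` carries their absolute
effects rescaled to mean 1. The three hyperparameters `(top%, nflank,
ω)` are chosen by cross-validated grid search inside the reference
population (training stage), then applied once to predict never-seen
candidates (application stage). With `ω = 0` the model *is* GBLUP, so a
calibrated BLUP|GA can never be talked into a worse model family.

The package implements the full pipeline: delimited-text/PLINK-style
I/O, G/S/T construction, eigendecomposition REML, the one-pass
equivalent solver (GBLUP GEBVs + RRBLUP marker effects from a single
factorization), the two-stage validation workflow, model-choice
diagnostics (cumulative variance curves, the T–G distance σ and its
zero-intercept regression on the accuracy gain Δ), and a
quantitative-trait simulator with normal or gamma QTL effects used by
the test suite.

## Worked example

A major-gene trait (one QTL carrying 30% of the genetic variance over a
polygenic background of 2,999 small QTL; 600 phenotyped reference
individuals, 300 unphenotyped candidates, 3,000 markers, h² = 0.5):

```r
library(blupga)

cfg  <- preset("major_gene", seed = 42)
sim  <- simulate_dataset(cfg)
data <- as_wgp_data(sim)             # scores predictions against true BVs
print(sim)
#> sim_dataset: 600 ref + 300 cand, 3000 markers, 3000 QTL, realized h2 0.476

plan <- make_folds(sim$reference_ids, n_folds = 5, n_replicates = 1, seed = 42)
grid <- default_grid(omega = c(0, 0.1, 0.3), top_pct = c(0.001, 0.01),
                     nflank = c(0, 3))
res  <- grid_search(plan, data, grid)
print(res)
#> grid search: 9 cells; best omega=0.1 top_pct=0.001 nflank=0 (mean acc 0.5532)

rep <- apply_stage(data, sim$reference_ids, sim$candidate_ids, res$best_params)
print(rep)
#> application stage: GBLUP acc 0.2333 | BLUP|GA acc 0.4881 (omega=0.1, top=0.001, nflank=0)
```

Reading the output: five-fold cross-validation inside the reference
population picks a 0.1% top-SNP fraction (3 SNPs — the grid cell that
captures the major gene) blended at ω = 0.1; applying those parameters
to the candidates roughly doubles the correlation between predicted and
true breeding values relative to plain GBLUP (0.49 vs 0.23). On a
purely polygenic trait the same search selects ω ≈ 0 and reduces to
GBLUP — run `preset("polygenic")` through the same code to see it.

## Command line

```sh
Rscript inst/cli/blupga.R simulate --preset major_gene --seed 1 --out sim/
Rscript inst/cli/blupga.R train    --geno sim/genotypes.tsv --map sim/markers.map \
    --pheno sim/phenotypes.tsv --out train/ --n-folds 5 --n-replicates 5 --seed 1
Rscript inst/cli/blupga.R predict  --geno sim/genotypes.tsv --map sim/markers.map \
    --pheno sim/phenotypes.tsv --params train/best_params.txt \
    --candidates cand.txt --out pred/
Rscript inst/cli/blupga.R diagnose --geno sim/genotypes.tsv --map sim/markers.map \
    --pheno sim/phenotypes.tsv --out diag/
```

Every run writes a `manifest.txt` with the resolved configuration;
identical flags and seed give byte-identical outputs.

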