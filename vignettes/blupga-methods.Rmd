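---
title: "Methods: trait-specific relationship matrices for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-specific relationship matrices for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Genomic prediction with `blupga` is built on the standard animal model

$$ y = X\mu + Zu + e, \qquad u \sim N(0, \sigma_u^2 K), \quad e \sim N(0, \sigma_e^2 I), $$

where $y$ are phenotypic records (EBVs, deregressed proofs or simulated
phenotypes), $Z$ maps records to individuals, and $K$ is a marker-derived
relationship matrix. GBLUP uses the genomic relationship matrix

$$ G = \frac{MM'}{2\sum_i p_i(1-p_i)}, $$

with $M$ the dosage matrix column-adjusted by $2p_i$. Throughout the
package $p_i$ is fixed at $0.5$ (the choice of allele frequency does not
affect prediction accuracy, and $p = 0.5$ keeps centered dosages in
$\{-1, 0, 1\}$ and the normalizer at $m/2$). An observed-frequency mode
exists only as a diagnostic (`allele_frequencies()`), never for the GRMs.

BLUP|GA ("BLUP given genetic architecture") replaces $G$ with the
trait-specific blend

$$ T = \omega S + (1-\omega) G, \qquad
   S = \frac{M_1 D M_1'}{2\sum_{i \in m_1} p_i(1-p_i)}, $$

where $M_1$ holds the $m_1$ selected SNPs — the `top_pct` fraction with
the largest absolute RRBLUP effects estimated in the training data, plus
up to `nflank` map-adjacent SNPs on each side to absorb local linkage
disequilibrium — and $D$ is diagonal with the selected markers' effect
sizes, rescaled so `mean(diag(D)) = 1` to keep $S$ on the scale of $G$.
With $\omega = 0$ or `top_pct` covering all markers with equal weights,
the model collapses to GBLUP, which is the safety net that makes the
method usable without prior knowledge of the trait architecture.

**Sign safety of D.** The sources describe diag(D) as "the estimated
marker effects". Signed weights would destroy positive semidefiniteness
of $S$, so `build_D()` defaults to absolute values — the minimal
sign-safe reading — and exposes `square` as an alternative. This is a
genuinely open design point; both transforms keep $S$ PSD and the choice
is a tunable (`transform` argument throughout the workflow).

## The equivalent one-pass algorithm

Rather than inverting $K$ inside Henderson's mixed-model equations, the
package uses the equivalent record-scale formulation. With
$V = ZKZ' + \lambda I$ and $\lambda = \sigma_e^2/\sigma_u^2$:

1. $\hat b = (X'V^{-1}X)^{-1}X'V^{-1}y$ (GLS fixed effects),
2. $\hat s = V^{-1}(y - X\hat b)$,
3. $\hat u = K Z' \hat s$ (GEBVs, including unphenotyped candidates
   through their rows of $K$),
4. $\hat g = M' Z' \hat s / c$ with $c = 2\sum p(1-p)$ (RRBLUP marker
   effects; $M\hat g = \hat u$ exactly when $K = G$).

This yields GBLUP solutions and RRBLUP effects in one pass; the same
four steps with $K = T$ and $\lambda_T$ give the BLUP|GA solutions. A
note on notation: some write step 2 as $Z[G+\lambda I]^{-1}Z'(y-X\hat b)$
with the full $n \times n$ matrix; that form is only correct when every
individual is phenotyped. The record-scale $V$ used here is the unique
form that agrees with the mixed-model equations when candidates are
present, which the test suite verifies to $10^{-10}$ against a direct
MME solve on random instances.

Linear solves use dense symmetric factorizations; if round-off drives
the smallest eigenvalue of a kinship below $-10^{-8}$ times the largest,
a jitter of $10^{-8}\cdot\overline{\mathrm{diag}}$ is added and logged.

## REML and the heritability scale

Variance components come from restricted maximum likelihood for the
single-kinship model: the fixed effects are projected out with an
orthonormal complement $Q$ of $X$, $Q'ZKZ'Q$ is eigendecomposed once,
and the profiled restricted likelihood is maximized over the ratio
$\gamma = \sigma_u^2/(\sigma_u^2+\sigma_e^2) \in (0,1)$ by bracketed
scalar optimization (tolerance $10^{-8}$). This reaches the same optimum
as AI-EM algorithms for this model class, deterministically and in one
eigendecomposition.

One subtlety matters for interpreting $h^2$. Under the fixed $p = 0.5$
convention the diagonal of $G$ does not average to 1, and $G$ contains a
near-constant component driven by the squared frequency offsets
$(2q_i-1)^2$ that shifts all individuals together without creating
phenotypic variance between them. Consequently the naive ratio
$\sigma_u^2/(\sigma_u^2+\sigma_e^2)$ over-states variance-explained
heritability (we measured +0.17 at a true $h^2$ of 0.5 in simulation).
The reported `h2` therefore uses the centered diagonal:

$$ h^2 = \frac{\sigma_u^2 \bar v}{\sigma_u^2 \bar v + \sigma_e^2},
   \qquad \bar v = \frac{\mathrm{tr}(K_p) - \mathbf{1}'K_p\mathbf{1}/n}{n-1}, $$

with $K_p$ the phenotyped block of $ZKZ'$ — the expected sample variance
of the genetic values per unit $\sigma_u^2$. With this definition REML
recovers simulated heritabilities within 0.05 at $n = 500$ across
$h^2 \in \{0.1, 0.25, 0.5, 0.8\}$ (acceptance suite). `sigma_u2`,
`sigma_e2` and `lambda` are reported on the raw model scale.

**$\lambda_T$ policy.** Inside the grid search, re-estimating variance
components for every $(\omega, top\%, nflank)$ cell would dominate the
runtime for no measurable benefit; the default `reuse_lambda` policy
estimates $\lambda$ once per training fold under $G$ and reuses it for
every $T$. `variance_policy = "reestimate"` switches to a strict mode
that re-runs REML under each $T$.

## Two-stage validation protocol

The *training stage* runs k-fold cross-validation (default 5 folds,
repeatable) inside the reference population: for every fold, variance
components, $\hat s$ and $\hat g$ are computed from the training
individuals only; each grid cell then selects its top SNPs from those
training-only effects, rebuilds $S$ and $T$, and predicts the held-out
fold. Selection, $D$ weights and variance components can therefore never
see test phenotypes (asserted by a permutation test in the suite). The
cell maximizing mean accuracy — replicate-level means are canonical,
fold-pooled means are also reported — wins; ties break to the smaller
$\omega$, then smaller `top_pct`, then smaller `nflank`, preferring the
model closest to plain GBLUP. The *application stage* applies the chosen
parameters once to the combined reference + candidate data, with
phenotypes entering only from the reference.

Accuracy is the Pearson correlation between GEBV and the reference
value; unbiasedness is the regression slope of the reference value on
the GEBV (the reverse slope is attached as an attribute, since both
directions appear in the literature). Folds whose held-out reference
values are constant yield undefined metrics; they are recorded as
missing with a warning and excluded from cell means.

## Diagnostics

Two cheap diagnostics indicate whether BLUP|GA can beat GBLUP on a
dataset *before* running the full grid search:

- **Cumulative variance curves** (`variance_explained_curve`): markers
  sorted by $|\alpha|$ descending, accumulating
  $2p(1-p)\alpha^2$ normalized to 1. Here $p$ is the *observed* allele
  frequency (unlike the GRM's fixed 0.5) because the variance attributed
  to a near-monomorphic locus must shrink with $p(1-p)$; $\alpha$ is the
  RRBLUP effect $\hat g$ on the centered-dosage scale. A steep initial
  rise — much variance in few top SNPs — marks a trait with exploitable
  architecture.
- **Matrix distance** $\sigma = \mathrm{sd}(T_{ij} - G_{ij})$
  (`matrix_distance_sigma`), over the upper triangle including the
  diagonal with the sample denominator (the element set is a convention;
  both triangles would double-count). $\sigma(T(\omega), G) =
  \omega\,\sigma(S, G)$ holds exactly by linearity. The accuracy gain
  $\Delta$ regresses on $\sigma$ through the origin
  (`delta_sigma_regression`), zero being the expectation at $T = G$.
  Because the element-set convention is not fixed in the literature,
  published slope values are not comparable targets.
- `order_by_top_genotype` permutes a relationship matrix by the dosage
  at the largest-effect marker, making major-gene block structure
  visible in heat maps; `rescale_effects_mean_abs_one` puts effect
  profiles from different traits or population sizes on a common
  Manhattan-plot scale.

## The simulator's stated world

`simulate_dataset()` exists so the whole pipeline is testable without
external downloads. What it emulates, and what it does not:

- **Genotypes**: two latent AR(1) Gaussian haplotypes per chromosome
  thresholded at the allele-frequency quantile (frequencies uniform in
  `(maf_min, 1 - maf_min)`, shared AR(1) smoothness so neighbouring
  markers have similar frequencies, as inside real LD blocks). At
  `ld_rho = 0.9` the realized adjacent-marker dosage correlation is
  about 0.65; at 0 it vanishes. This reproduces the *local* LD the
  `nflank` parameter relies on, but not long-range LD, population
  structure, or the site-frequency spectrum of coalescent simulation —
  so a green directional test says the method exploits architecture
  under plausible LD, not that it attains any published accuracy.
- **QTL effects**: `n_qtl` markers sampled without replacement; normal
  or gamma magnitudes with independent random signs. The gamma presets
  use shape 0.4 / scale 1.66 (livestock-style design, heritability 0.25,
  900 QTL on a 10,000-marker panel — a 6x scale-down of the original
  60,000-marker genome with QTL count scaled to match) and shape 0.42 /
  scale 5.4 with 50 QTL on 5 × 4,000 markers (workshop-style design;
  heritability set to 0.36, the first trait of that dataset's published
  range 0.35–0.52).
- **Major gene**: `major_share` fixes one QTL's realized variance
  contribution exactly (effect solved against the realized polygenic
  variance, contributions near-orthogonal by random placement). The
  `major_gene` preset uses 30% on a 3,000-marker, 600-reference genome
  at $h^2 = 0.5$; `polygenic` is the matched all-small-effects control.
- **Phenotypes**: $y = \mathrm{tbv} + e$ with
  $\mathrm{var}(e) = \mathrm{var(tbv)}(1-h^2)/h^2$ computed on the
  realized reference TBVs, so the realized heritability is on target in
  expectation ($h^2 = 0$ yields pure standard-normal noise, TBV still
  emitted; $h^2 = 1$ returns the TBV). Candidates carry TBVs but never
  phenotypes. QTL sit on the emitted panel by default; `mask_qtl = TRUE`
  removes them, emulating designs whose causal loci are off-chip.
- Out of scope: multi-generation pedigrees, selection, mutation,
  correlated multi-trait architectures.

All randomness derives from one master seed via stable per-purpose
hashing (`derive_seed`), so identical configurations are byte-identical
regardless of call order.

## Numerical and runtime choices

- Top-SNP count $k = \max(1, \mathrm{round}(top\% \cdot m))$,
  round-half-up, so sub-0.1% fractions still select a marker on small
  panels; ties on $|\hat g|$ break to the earlier map position.
- Flanks are map-rank neighbours ("adjacent"), never crossing a
  chromosome boundary; base-pair distance is deliberately not used.
- The default grid spans $\omega \in \{0, 0.02, \dots, 0.8\}$,
  $top\% \in \{0.01\%, \dots, 5\%\}$, $nflank \in \{0, 3, 5\}$ — 145
  cells after collapsing the $\omega = 0$ duplicates — a superset of
  parameter ranges reported as optimal in applications. Within a fold,
  steps 1–3 are computed once and shared by all cells; only $S$, $T$
  and the blended solve are per-cell.
- The simulation-backed acceptance tests run a fixed 25-cell subset of
  those values to stay inside the test-time budget; the subset was fixed
  before any outcome was measured.

## Known limitations

- Single random effect, single trait, homoscedastic residuals; no
  dominance or epistasis; no single-step pedigree blending.
- Grid search maximizes in-reference CV accuracy, which can be
  suboptimal for the application stage — inherent to the protocol.
- Dense algebra throughout: practical to a few thousand individuals;
  beyond that the $n^3$ solves per grid cell dominate.
- With `reuse_lambda`, the $\lambda$ used for $T$ is the one estimated
  under $G$; at large $\omega$ and extreme architectures the strict mode
  can shift GEBVs slightly (it never changes the ranking in our tests,
  but the mode exists precisely so users can check).
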