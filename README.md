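# bmfa — Bayesian mixtures of factor analyzers for bifurcating single-cell trajectories

`bmfa` infers **pseudotimes**, **bifurcation branch assignments** and the
**genes driving a bifurcation** from a single-cell expression matrix — all
jointly, inside one generative probabilistic model fitted by Gibbs
sampling. It is aimed at people analyzing differentiation or fate-decision
processes in scRNA-seq (or other single-cell) data who want posterior
uncertainty and a principled gene ranking instead of post-hoc heuristics.

## The model

For an N × G matrix *y* of normalized log-expression, each cell *i* has a
latent pseudotime *tᵢ* ~ N(0, 1) and branch label *γᵢ* ∈ {1, …, B}
(γᵢ ~ Categorical(ω), ω ~ Dirichlet(1/B, …, 1/B)). Each branch *b* carries
a factor loading matrix Λ_b = [c_b k_b] and

  yᵢ | γᵢ, tᵢ ~ Normal(c_{γᵢ} + k_{γᵢ} tᵢ, diag(τ)⁻¹).

Branch gradients share an ARD-style hierarchical shrinkage prior,
k_{bg} ~ N(θ_g, χ_g⁻¹) with χ_g ~ Gamma(α_χ, β_χ) (default
α_χ = β_χ = 10⁻²): genes whose behavior is common to both branches get a
large shrinkage precision χ_g, genes that the data force apart get a small
one, so **1 / E[χ_g | y] ranks genes by their involvement in the
bifurcation**. The model is fully conjugate, so inference is exact
block-wise Gibbs sampling; a zero-inflated variant treats observed zeros
as droppable measurements with per-gene dropout probability
exp(−(λ/N) Σᵢ x_{ig}) and a global rate λ estimated Empirical-Bayes style.

## Worked example

```r
library(bmfa)

# 300 cells x 60 genes; sigmoidal kinetics; 30 genes differ across branches
truth <- generate_sigmoidal_toy(n_cells = 300, n_genes = 60, seed = 1)

fit <- gibbs_sample(truth$Y,
                    settings = gibbs_settings(20000, 10000, 10, seed = 1))

cells <- map_pseudotime(fit)              # posterior-mean t + 95% intervals
abs(cor(cells$t_map, truth$t_true))
#> [1] 0.9840858

branch <- map_branch(fit)                 # modal branch label per cell
match_branch_labels(truth$gamma_true, branch, B = 2)$accuracy
#> [1] 0.7566667

genes <- chi_relevance(fit)               # 1 / posterior-mean chi, ranked
auroc(genes$chi_inverse, truth$bifurcating)
#> [1] 0.6811111
```

What the numbers mean: the posterior-mean pseudotime correlates with the
(unobserved) true progression at |ρ| ≈ 0.98 — the same accuracy as the
first principal component on this easy, high-signal benchmark, but with
credible intervals and a joint branch assignment. Branch agreement of
~0.76 is close to the ceiling for this simulation: branch labels of cells
*before* the bifurcation are arbitrary by construction (≈ half the cells),
so only post-bifurcation cells are informative. The inverse-χ scores rank
the 30 truly branch-different genes above the common ones with AUROC ≈
0.68 on this mis-specified toy; on data generated from the model itself
the same score attains AUROC ≈ 0.9 (see `tests/testthat/test-acceptance.R`).

## Command-line interface

```sh
MFA=$(Rscript -e 'cat(system.file("cli/mfa.R", package="bmfa"))')
Rscript $MFA simulate --output-dir sim --cells 300 --genes 60 --seed 1
Rscript $MFA fit --input sim/expression.csv --iterations 20000 \
                 --seed 1 --output-dir out        # add --zero-inflation for ZI
Rscript $MFA summarize --trace out/trace --output-dir out
```

`fit` accepts CSV/TSV (cells × genes; `--orientation genes_by_cells` for
the transposed dialect) or MatrixMarket `.mtx` with `.rownames`/`.colnames`
sidecars, writes a plain-text trace archive (one CSV per parameter block
plus `meta.json`), `cells.csv` (cell_id, t_map, t_lower, t_upper,
gamma_map), `genes.csv` (gene_id, chi_inverse, rank) and a resolved
`config.json` for provenance. A JSON config file (`--config`) can supply
any option; explicit flags win.

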