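# mirbeam

`mirbeam` discovers miRNA–mRNA pairs whose **joint** expression state
carries probabilistic dependency with a categorical clinical feature —
tumor vs. normal tissue, a metastasis indicator, or a molecular subtype —
even when each member alone shows weak or no marginal association. That
regime (statistical epistasis between a regulator and its target) is
invisible to per-feature tests, which is exactly why it needs a model-based
search. The package is aimed at computational biologists with paired
miRNA/mRNA expression profiles and per-patient clinical annotation.

## Method

The clinical feature is the target node `T` of a discrete Bayesian
network; candidate parents are discretized expression levels. A parent set
`Pa(T)` is scored by the Bayesian Dirichlet equivalent uniform (BDeu)
marginal likelihood

```
score_α(G : Data) = ∏_i ∏_j  Γ(α/q_i) / Γ(α/q_i + Σ_k s_ijk)
                            ∏_k Γ(α/(r_i q_i) + s_ijk) / Γ(α/(r_i q_i))
```

with `r_i` the arity of node `X_i`, `q_i` the number of joint parent
instantiations and `s_ijk` the usual sufficient statistics (all
computation is in natural logs via `lgamma`; default `α = 54`).

A **Multiple Beam Search** launches one greedy beam from every predictor:
forward additions while the score strictly improves, then backward
deletions under the same rule; surviving models are pooled, deduplicated
and ranked. Models containing a miRNA and an mRNA yield candidate pairs,
and each pair is validated by its **Bayesian network posterior
probability (BNPP)**: the posterior of the joint model `M_ij` against
`M_0` (neither predictor associated), `M_i` and `M_j` (one each), under a
non-informative prior of 0.25 per model; pairs with BNPP > 0.95 are
reported as validated.

A synthetic-data generator plants XOR-style interactions — marginally
null by construction, jointly informative — so the entire pipeline is
testable without any external download. Preprocessing (patient merge,
all-zero filtering, `log2(x + 1)`, per-feature equal-width binning,
curated-candidate extraction with mature-arm `*`/`-5p`/`-3p` name
matching) is part of the package.

## Worked example

```r
library(mirbeam)

cfg <- synth_config(n_samples = 500, n_mirna = 15, n_mrna = 15,
                    n_interacting_pairs = 1, interaction_effect = 0.35,
                    seed = 1)
d   <- generate_dataset(cfg)
run <- run_pipeline(d$mirna, d$mrna, d$clinical, verbose = TRUE)
#> preprocess: 500 samples, 30 predictors, target arity 2
#> search: checked 1615 DAG models, 6 model(s) after dedup
#> bnpp: 2 interaction pair(s), 1 validated at threshold 0.95

run
#> mirbeam_run: checked 1615 DAG models, discovered 6, 2 interaction pair(s), 1 with BNPP > 0.95
#>   rank           mirna    mrna  log_bdeu      bnpp validated
#> 1    1 hsa-miR-sim-001 GENE001 -15571.51 1.0000000      TRUE
#> 2    2 hsa-miR-sim-011 GENE004 -15652.67 0.4735414     FALSE

evaluate_against_truth(run, d$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

The search checked 1,615 DAG models and the one planted pair —
`hsa-miR-sim-001` with `GENE001` — comes out rank 1 with BNPP ≈ 1 and is
the only validated pair; the runner-up decoy pair sits well below the 0.95
cutoff. `log_bdeu` is the natural-log BDeu score of the full star network,
used for the Table-style ordering of the report. The per-pair posterior
breakdown is available directly:

```r
bnpp(run$dataset, "hsa-miR-sim-001", "GENE001")
#> BNPP(hsa-miR-sim-001, GENE001) = 1.0000  [alpha = 54]
#>   model    loglik prior    posterior
#> 1  M_ij -264.1777  0.25 1.000000e+00
#> 2   M_0 -347.7274  0.25 5.185875e-37
#> 3   M_i -349.0346  0.25 1.403096e-37
#> 4   M_j -349.0207  0.25 1.422817e-37
```

Real data enter the same way: `run_pipeline()` accepts file paths to
expression TSVs (`feature_id` column plus one column per sample), a
clinical TSV (`sample_id`, `target`) and optionally a curated candidate
CSV (`mirna,mrna,...`), and writes `interactions.tsv` when `out_dir` is
given. See the methods vignette (`vignettes/mirbeam-methods.Rmd`) for the
model, parameter meanings and design choices.

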