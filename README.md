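# coopbalance

Compositional association analysis between a microbiome and clinical
phenotypes, built around two ideas: the **nearest balance** of a clinical
factor, and **co-abundance cooperatives** ("coops") of genera tested as
balances. The package is aimed at microbiome statisticians analysing
16S/shotgun taxon count tables against panels of clinical parameters
(immune, cardiovascular, endothelial, metabolite markers and the like),
and at method developers who want a fully synthetic, ground-truthed
benchmark of the whole workflow.

## The statistics

All analysis happens in Aitchison geometry. A sample's counts
`x = (x_1, ..., x_D)` are mapped by the centred log-ratio transform
(zeros replaced by a pseudocount of 0.5):

    clr(x)_j = log x_j - (1/D) * sum_k log x_k

A **balance** between disjoint taxon sets P (|P| = p, numerator) and Q
(|Q| = q, denominator) is the normalised log-contrast

    b(P,Q) = sqrt(pq/(p+q)) * ( mean_{j in P} log x_j - mean_{j in Q} log x_j )

whose coefficient vector has unit norm and zero sum, so the balance value
is a dot product with the clr row. Given a factor `y`, the per-taxon
association direction `v_j = cov(clr_j, y/sd(y))` points along the
compositional gradient of the factor; the **nearest balance** is the
balance whose coefficient vector maximises cosine similarity with `v`.
Because balance coefficients are constant within each side, the optimum
for fixed (p, q) takes the p largest and q smallest components of `v`,
so an O(D^2) scan over (p, q) on the sorted direction is provably
exhaustive (the package ships a 3^D brute-force oracle and tests the
equivalence). Reproducibility is assessed by re-identifying the nearest
balance on 100 random half-sample subsets; only taxa landing on one side
in more than 90 of 100 iterations enter the final reported balance.

Cooperatives are communities of a sparse co-abundance graph: per-genus
L1-penalised neighbourhood regressions on clr data (Meinshausen–Bühlmann
style, 10 random 80% subsamples, a 10-value lambda path down to
0.2·λ_max, stability-selected penalty), symmetrised by the OR rule and
clustered with Louvain modularity. Each coop is tested as the balance of
its genera against all other filtered genera; standardised slopes,
p-values and Benjamini–Hochberg q-values (per parameter group and
feature family) are reported. Beta diversity uses a single permutation
engine (pseudo-F on the Gower-centred Aitchison distance matrix) that
reproduces PERMANOVA for categorical factors and dbRDA for continuous
ones; alpha diversity (Shannon, Chao1) is screened with linear models.

A synthetic-cohort generator emulates the target study design — three
groups (48/46/86 samples), 120 genera with log-normal latent structure,
four correlated genus blocks (ρ = 0.7), multinomial depths on
[10459, 40000], a planted 7+7-genus balance effect, and clinical
parameter clusters with pairwise Spearman ρ > 0.8 plus pure-noise
parameters — and exports the full ground truth for recovery testing.

## Worked example

```r
library(coopbalance)

coh <- simulate_cohort(synthetic_scenario(seed = 7))
write_cohort(coh, "demo/in")
res <- run_pipeline(analysis_config(seed = 7),
                    "demo/in/counts.tsv", "demo/in/metadata.tsv",
                    "demo/out", group_spec = coh$metadata$parameter_groups)

head(res$beta[order(res$beta$p), ], 4)
#>     feature               factor statistic       r2     p      q   n
#>  beta:dbRDA       factor_planted     6.876 0.037194 0.001 0.0060 180
#>  beta:dbRDA         immune_null1     1.319 0.007356 0.064 0.1920 180
#>  beta:dbRDA cardiovascular_null4     1.120 0.006251 0.242 0.6945 180
#>  beta:dbRDA cardiovascular_null2     1.053 0.005882 0.323 0.6945 180
```

Only the planted factor is significantly associated with overall
composition (dbRDA pseudo-F = 6.9, R² = 0.037, q = 0.006); the null
clinical parameters stay flat. The coop stage recovers the four planted
co-abundance blocks (plus the planted balance genera, which co-vary
through the shared factor):

```r
res$partition
#> coop_partition: 9 coops (Genus_001-coop n=13; Genus_013-coop n=10;
#>   Genus_023-coop n=8; Genus_034-coop n=7; ...), 19 singleton genera,
#>   modularity 0.751

res$nearest_balances[["factor_planted"]]
#> reproducible_balance (factor_planted): 7 + 7 taxa, n=180
head(balance_membership_table(res$nearest_balances[[1]]), 5)
#>      taxon      side reproducibility coefficient
#>  Genus_043 numerator               1       0.600
#>  Genus_044 numerator               1       0.556
#>  Genus_042 numerator               1       0.522
#>  Genus_046 numerator               1       0.520
#>  Genus_047 numerator               1       0.481
```

The cross-validated nearest balance recovers exactly the planted
7-versus-7 genus structure (ground truth: `coh$truth$balances`), each
member reproducible in 93–100 of the 100 half-sample iterations.

Result tables (`alpha_associations.tsv`, `beta_associations.tsv`,
`coop_associations.tsv` with coefficient/p/FDR/n columns,
`nearest_balance.tsv` with taxon/side/reproducibility/coefficient,
network edge lists, coop memberships, parameter de-duplication map and a
`run_log.json` echoing the configuration) are written to the output
directory. A thin CLI wraps the same functions:
`Rscript inst/cli/coopbalance.R {run|simulate|nb} ...`.

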