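---
title: "Methods: nearest balances, cooperatives, and their validation"
author: "coopbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nearest balances, cooperatives, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic cohorts do and do not emulate, and the numerical
and design choices a maintainer should know about.

## Compositional geometry

Sequencing counts carry only relative information, so every statistic in
the package operates on centred log-ratio (clr) transformed data. Zero
counts are replaced by a pseudocount of 0.5 **before** closure to
proportions — the replacement is phrased on counts, not proportions, so
a zero in a deep sample is (correctly) treated as stronger evidence of
rarity than a zero in a shallow one. Each clr row sums to zero by
construction; the Euclidean distance between clr rows is the Aitchison
distance, which is perturbation-invariant and scale-invariant (both are
property-tested). Principal-coordinate analysis of the Aitchison
distance matrix is therefore an exact Euclidean embedding, identical to
a clr PCA up to sign; taxon arrows on the biplot are the covariances of
each clr column with the retained axes.

Rarefaction is applied **only** where read depth itself changes the
statistic, i.e. for Shannon/Chao1 and for the distance matrix entering
the beta-diversity tests (each sample is drawn down without replacement
to the minimum depth, deterministically per seed). The network,
cooperative, nearest-balance and per-rank clr screens run on the
unrarefied filtered table: the clr transform is already scale-invariant,
so subsampling reads before it would only discard information. This
split is a deliberate design decision, consistent with the
recommendations of the sparse co-occurrence inference literature.

## The nearest balance

A balance between numerator set P (size p) and denominator set Q (size
q) is the normalised log-contrast with coefficients `+sqrt(q/(p(p+q)))`
on P and `-sqrt(p/(q(p+q)))` on Q: a unit-norm, sum-zero vector, so the
per-sample balance value is both a mean-log difference and a dot product
with the clr row (the two code paths are required to agree to 1e-9).

The association direction of a factor is the vector of sample
covariances between each clr column and the standardised factor; for a
two-level categorical factor it is the difference of group mean clr
vectors. The search for the balance with maximal cosine similarity to
the direction sorts components once and scans all (p, q) prefixes and
suffixes. This restriction is exhaustive: for fixed side sizes the
objective is linear in the memberships with a constant coefficient per
side, so the optimum must take the largest p and smallest q components.
An explicit 3^n brute-force enumerator ships as a test oracle, and the
scan is required to match it exactly on random directions up to n = 8.
Ties in the direction (exactly equal components) are broken by taxon
identifier; among equal-cosine (p, q) candidates the smaller balance
wins, then the smaller numerator — applied identically in the scan and
the oracle.

### Cross-validated reproducibility

The reported balance is not the single full-data optimum but the
consensus of 100 half-sample re-analyses: in each iteration floor(n/2)
complete cases are drawn without replacement, the nearest balance is
recomputed, and each taxon's side is tallied. Taxa landing on the
numerator (or denominator) in **more than 90** of 100 iterations form
the final balance; displayed coefficients are the full-data direction
restricted to those taxa. When one side has no such taxon, the result is
flagged "no reproducible balance" rather than treated as an error.

A property worth understanding before interpreting this screen: the 100
half-samples are subsets of one fixed data set, so their association
directions are strongly coupled to the full-data direction (the
conditional standard deviation of a half-sample correlation given the
full sample is about `sqrt(2/n - 1/n)`, ~0.075 at n = 180). A spurious
but extreme full-data association — the expected maximum |r| over ~70
genera under the null is ~0.18 — therefore keeps its side in well over
90/100 iterations with appreciable probability. In simulations under
fully null factors, about a third to a half of cohorts still certify one
or two taxa per side. Half-sample reproducibility measures *estimation
stability, not statistical significance*; that is why the pipeline only
runs the nearest-balance stage on factors that already pass the
FDR-controlled beta-diversity screen (with a single flagged
"exploratory" analysis of the best-p factor when nothing is
significant). Recovery of planted structure, by contrast, is excellent:
at a planted effect of 2 clr units per factor SD, the screen recovers on
average 13.9 of 14 planted taxa over ten simulated cohorts with zero
spurious and zero side-misassigned taxa, and recovery is monotone in the
effect size (0 at beta = 0 through complete at beta = 2). The
occasional miss is a planted taxon stopping at 84–88/100 repetitions —
the conservatism of the strict >90 bar, not a search failure.

## Co-abundance cooperatives

The genus universe is first filtered to genera with more than 20 reads
in more than 10 samples (strict inequalities). For each genus, an
L1-penalised regression of its clr column on all other genera is fitted
over a geometric path of 10 lambda values from λ_max (the largest
absolute off-diagonal covariance) down to 0.2·λ_max; an edge exists when
either of the two regressions selects the other genus (OR rule). Fits
are repeated on 10 random subsamples of 80% of the samples, keyed to
sorted sample identifiers so the graph is invariant to input row order.

The penalty is chosen by a stability criterion: per lambda, the average
edge instability `mean(2 f (1 - f))` over selection frequencies f is
monotonised from the sparse end of the path, and the **densest** lambda
whose monotonised instability stays at or below 0.05 is selected. (The
densest-acceptable rule is the standard stability-selection convention;
selecting the sparsest acceptable lambda would always return the empty
graph.) Edges with selection frequency ≥ 0.8 at the chosen lambda are
kept, weighted by that frequency.

Louvain modularity optimisation on the stability-weighted graph is
restarted 10 times with derived seeds and the best-modularity partition
kept, which in practice removes the optimiser's run-to-run variation.
Communities of a single genus are reported as singletons, not
cooperatives; coops are named after their most abundant member
(`Genus_X-coop`). Each coop is represented as the balance of its genera
against all other filtered genera, and screened against factors by the
slope between the standardised balance values and the standardised
factor — i.e. a correlation-scale coefficient comparable across factors
— or a one-way F for categorical factors. On cohorts with four planted
covariance blocks (within-block latent correlation 0.7, blocks of 6–12
genera), the network-plus-Louvain stage recovers the planted partition
with a mean adjusted Rand index of 1.0 over ten seeds.

## Beta diversity and multiplicity

One permutation engine serves both factor types: the factor is coded
into a centred model matrix X, the distance matrix is Gower-centred
(G = −CD²C/2), the model sum of squares is tr(HGH) for the hat matrix of
X, and p-values use label permutation with the +1 correction (a reported
p can never be exactly zero; 999 permutations give a resolution of
0.001). For categorical factors this is PERMANOVA; for continuous ones,
distance-based redundancy analysis. The engine agrees with
`vegan::adonis2` to numerical precision on F and R², and the categorical
engine on a two-level factor is identical to the continuous engine on
its 0/1 coding.

Clinical parameters are de-duplicated before testing: parameters of one
group form a graph with edges at |Spearman ρ| > 0.8 (pairwise complete
observations), connected components are clusters, and the member with
the fewest missing values (ties alphabetical) represents each cluster.
Benjamini–Hochberg control is applied within parameter group and feature
family (alpha metrics, beta tests, coop balances, per-rank taxon
screens). Note a pipeline-level consequence: with four or more
independent BH families each controlled at 0.05, the chance that *some*
family reports a discovery on a fully null cohort is ≈ 1 − 0.95⁴ ≈ 0.19.
The per-family any-discovery rate is the quantity BH actually controls,
and that is what the test suite bounds (measured ≈ 0.05 over 80
cohort-by-group families). Per-test complete cases are used throughout
(missing values are never imputed) and every result row reports its n.

## The synthetic cohorts

The generator emulates the study design the analysis is built for: three
groups of 48/46/86 samples (the group labels are pure labels by default
— no group effect is planted, matching the emulated study's null finding
at follow-up), 120 genera whose baseline mean log-abundances are normal
with SD 2 (giving a stool-like rank-abundance curve: one dominant genus
around 20–25%, a long tail of rare genera), unit-variance latent
log-normal noise with four planted correlation blocks at ρ = 0.7,
multinomial counts at per-sample depths uniform on [10459, 40000], and
one planted balance effect: 2 clr units per SD of a standard-normal
factor along the unit coefficient vector of a 7-versus-7 genus balance
placed in the mid-abundance range, disjoint from the coop blocks.
Clinical parameters come as clusters (monotone transforms — identity,
exponential, cubic — of one latent normal plus noise with SD 0.3, which
keeps empirical pairwise Spearman ρ above 0.8 at n = 180) plus
independent standard-normal nulls in each of four parameter groups.

What the generator does **not** emulate: Dirichlet-multinomial
overdispersion beyond the log-normal latent layer, taxonomic
misclassification, structural zeros, batch effects, missing clinical
values, or any fit to a real cohort's abundance profiles. Passing
recovery tests on these cohorts therefore demonstrates correctness of
the machinery under its own model assumptions, not performance on real
data with heavier tails and sparser signals.

A note on the cohort size: the emulated study's per-group sizes (48, 46,
86) sum to 180, and the generator follows the group sizes; per-analysis
n can be smaller than the cohort when parameters have missing values.

## Numerical choices and degenerate inputs

* Shannon defaults to base 2 (bits), configurable; Chao1 uses
  `S_obs + F1(F1−1)/(2(F2+1))` exactly (no small-sample factor).
* All-zero samples are an error for the clr transform; constant factors
  are errors for every association; an all-equal direction is an error
  for the balance search.
* Negative PCoA eigenvalues are clipped at zero for variance
  proportions; a distance matrix whose dominant negative eigenvalue
  exceeds the retained positive ones is rejected (cannot happen for
  Aitchison distances, which is itself asserted in the tests).
* Floats in output tables are printed with 6 significant digits; TSV is
  the canonical output dialect, with BIOM-JSON supported for count
  input/output.
* One master seed drives everything; each stochastic stage (rarefaction
  per sample, each CV iteration, each network subsample, each Louvain
  restart, each permutation stream per factor) derives its own seed from
  the master seed and a stage label via a small deterministic string
  hash. Two runs with the same configuration produce byte-identical
  output files.

## Problem sizes used in validation

The validation suite simulates cohorts of 180 samples and 120 genera
(about 70 after filtering): 200 random directions of up to 8 taxa for
the exhaustive-search comparison, 10 cohorts for balance recovery and
for coop recovery, 20 null cohorts for the reproducibility screen's
null behaviour, 200 null factors (999 permutations each) for p-value
uniformity, and two full pipeline runs for determinism. These sizes give
stable estimates of each rate while keeping a full validation run in the
minutes range on a single core.

## Known limitations

* The nearest-balance direction is univariate (no covariate
  adjustment); confounded factors will share balances.
* Half-sample reproducibility does not control type-I error (see above);
  treat a reproducible balance for a factor that failed the
  beta-diversity screen as exploratory.
* The co-abundance graph is a conditional-dependence estimate under a
  linear (partial-correlation-like) model on clr data; strong
  compositional closure effects at very low genus counts can induce
  edges, which the prevalence filter mitigates but does not remove.
* Louvain is a heuristic; the 10-restart best-modularity rule
  stabilises, but does not globally optimise, the partition.
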