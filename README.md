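# pathactivity

Pathway-level activity scoring for metabolism and mitochondria gene-set
catalogues in bulk and single-cell transcriptomes, with the downstream
statistics needed to turn those activities into clinically interpretable
strata.

Colorectal tumors broadly repress metabolic and mitochondrial programs, and
the extent of that repression tracks molecular subtype, mutation status
(notably BRAF-V600E) and prognosis. Studying this requires: (i) a
per-sample, rank-based summary of each pathway's coordinated expression;
(ii) a differential test across sample groups that is stable for small
cohorts and a few dozen gene sets; (iii) a way to compress dozens of
pathway activities into one predictive score with a decision threshold; and
(iv) the standard cohort statistics used in clinical tables. `pathactivity`
implements all four stages, plus single-cell count input with QC filtering
and a synthetic-data generator so every stage is testable offline.

## The methods in brief

**Single-sample enrichment (kcdf-walk).** For gene *i* with expression
x\_i1…x\_in, a kernel CDF statistic
z\_ij = (1/n) Σ\_k K((x\_ij − x\_ik)/h\_i) (Gaussian with h\_i = s\_i/4 for
continuous data, Poisson with rate x\_ik + 0.5 for counts, or the plain
ECDF) makes genes comparable across rows. Within each sample genes are
ranked by decreasing z, the symmetric rank statistic r\_ij = |p/2 − rank|
up-weights both tails, and the enrichment score of a set S is a weighted
Kolmogorov–Smirnov-like random walk

ν(ℓ) = Σ\_{i≤ℓ, i∈S} r\_i^τ / Σ\_{i∈S} r\_i^τ − #{i≤ℓ, i∉S}/(p − |S|),

summarized as max(ν,0) + min(ν,0) (`maxdiff`, bounded in [−1, 1]) or the
largest-magnitude deviation (`absmax`). A pure rank-walk variant
(weight rank^α, α = 0.25) is provided for sparse single-cell data.

**Differential enrichment.** Per-set two-group contrasts with pooled
variance are moderated by empirical Bayes: a scaled inverse-chi-square
prior (d0, s0²) is moment-matched on log-variances, posterior variances
s̃² = (d0·s0² + d·s²)/(d0 + d) give moderated t-statistics on d0 + d
degrees of freedom, with Benjamini–Hochberg control.

**Composite MM score.** An elastic-net penalized logistic model
(glmnet-style objective, α/λ tuned by stratified cross-validation inside a
0.7/0.3 split with a one-standard-error parsimony rule) yields
coefficients β; the composite score of a sample is MM = Σ β\_f ×
activity\_f over all, only-negative, or only-positive coefficients. The
optimal cutpoint maximizes Youden's J over observed scores; AUC uses the
tie-corrected rank-sum formula.

**Cohort statistics.** Pearson chi-square (Yates-corrected exactly for
2×2), Student/Welch t (raw values or printed mean/sd/n summaries), one-way
ANOVA, Kaplan–Meier with the log-rank test, and multivariable
binomial-logit regression with Wald CIs and separation flagging.

## Worked example

```r
library(pathactivity)

# two-condition expression cohort with three planted pathway shifts
sim <- simulate_expression(sim_expr_config(n_genes = 500, n_per_group = 8,
                                           n_sets = 12, seed = 1))
act <- score_activity(sim$expr, sim$collection)   # kcdf-walk, auto kernel
de  <- differential_enrichment(act, sim$groups)
head(de[order(de$p), c("set", "delta", "t_mod", "p", "q")], 5)
#>       set delta t_mod        p        q
#> 1  SET001 0.965 32.15 2.35e-16 2.82e-15
#> 2  SET002 0.905 26.27 6.28e-15 3.77e-14
#> 3  SET003 0.965 25.29 1.17e-14 4.66e-14
#> 11 SET011 0.226  2.66 1.67e-02 4.08e-02
#> 5  SET005 0.319  2.65 1.70e-02 4.08e-02
```

The three planted sets (SET001–SET003) dominate the ranking with activity
differences near one (scores live in [−1, 1]) and q-values twelve orders of
magnitude below the rest.

```r
# published cohort table: metastasis stage vs. composite-score stratum
tabs <- cohort_contingency_tables()
chi_square_test(tabs$metastasis)
#> chi-square (Yates): statistic 7.6031, df 1, p = 0.005826744

# composite score on a simulated activity cohort
co    <- simulate_cohort(sim_cohort_config(seed = 1))
model <- tune_penalized_logistic(co$activity, co$outcome, seed = 1)
model
#> composite_model: 60 features (5 nonzero), alpha=0.1, lambda=3.472
#>   intercept -0.1188; negative coefficients: 2
cp <- roc_cutpoint(mm_score(t(co$activity), model), co$outcome)
cp
#> cutpoint_result: AUC 0.954, threshold -0.007833 (>=), sens 0.936,
#>                  spec 0.937, J 0.873
```

The tuner recovers a sparse model containing exactly the informative
features, and the composite score separates outcome classes with AUC ≈
0.95 at the Youden-optimal threshold.

## Methods documentation

`vignettes/pathway-activity.Rmd` describes the models, the tunable
parameters and their defaults, what the synthetic generators emulate (and
do not), numerical conventions, and known limitations.
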