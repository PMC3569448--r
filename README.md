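# pplsda

Two-group classification of high-dimensional expression matrices by powered
partial least squares discriminant analysis (PPLS-DA), with the power
parameter chosen for *prediction* rather than correlation.

## The problem and the method

Gene-expression classification problems routinely have thousands of features
and a few dozen samples, so classifiers are built on a handful of supervised
latent components. PLS-DA extracts those components as dominant eigenvectors
of the between-group matrix B = Σ_g π_g m_g m_gᵀ (computed through the
g × g reduced eigenproblem, never the p × p one). PPLS-DA generalises the
loading weights with a power parameter γ ∈ [0, 1],

    w_k(γ) ∝ sign(ρ_k) |ρ_k|^(γ/(1−γ)) · s_k^((1−γ)/γ),

which interpolates between variance-driven (γ → 0), classical covariance
(γ = 0.5, identical to PLS-DA) and correlation-driven (γ → 1) weights. The
classical rule picks γ per component by maximising the canonical correlation
between the candidate projection and the group response (γ_cc). This package
additionally implements the prediction-optimised rule γ_PE: γ (one value for
all components) and the number of components (1–5) are selected **jointly**
by nested Monte-Carlo cross-validation — q stratified 0.7/0.3 inner resamples
of the outer training set, an LDA on the component scores, and the pair
minimising mean inner prediction error wins. An outer evaluation harness
(balanced down-sampled splits, mean PE with Student-t 95% confidence
intervals, CI-overlap significance calls), t-test-filtered LDA and linear SVM
baselines, the five benchmark simulation designs (60 + 60 samples, 1000
genes, 10 differentially expressed at δ, σ_b² = 0.04) and covariance
diagnostics (condition indexes, PC/class covariances) round out the toolkit.

The compute-heavy inner CV runs in C++ (RcppArmadillo); a pure-R reference
engine produces bit-identical results and backs the test suite.

## Worked example

```r
library(pplsda)
set.seed(1)

design <- simulation_design(case = 3)     # high technical noise, delta ~ U[0.1, 0.5]
data <- simulate_case(design)
condition_indexes(data)                   # weak collinearity by construction
#> [1] 1.000000 1.017913 1.035672 1.040688 1.046058

split <- outer_split(data)                # 42 + 42 train, 18 + 18 test
train <- subset_samples(data, split$train)
test  <- subset_samples(data, split$test)

sel <- select_gamma_pe(train, grid = gamma_grid(0.1), q = 50)
sel
#> inner_cv_result: gamma* = 0.8, 1 component(s), mean inner PE 0.1354 (q = 50)

model <- fit_pplsda(train, n_components = sel$ncomp_star, gamma = sel$gamma_star)
lda <- fit_lda(model$training_scores, train$labels)
prediction_error(predict_lda(lda, project(model, test$x)), test$labels)
#> [1] 0.08333333
```

The selection picked γ = 0.8 — correlation-weighted loading weights that
concentrate on the 10 informative genes — and a single component, and the
refitted pipeline misclassifies 8.3% of the held-out samples. A full
multi-method comparison with shared outer splits:

```r
ev <- run_experiment(simulation_design(case = 3),
                     methods = c("pplsda_pe", "pplsda_cc", "plsda"),
                     repeats = 20, q = 50, base_seed = 7)
summary(ev)
#>      method    mean_pe      ci_lo      ci_hi mean_gamma mean_ncomp n_ok
#> 1 pplsda_pe 0.05694444 0.03443697 0.07945192  0.8450000       1.50   20
#> 2 pplsda_cc 0.19027778 0.14421293 0.23634262  0.5014137       1.90   20
#> 3     plsda 0.20555556 0.16123763 0.24987348  0.5000000       3.15   20
compare_methods(ev)    # TRUE where the 95% CIs are disjoint
#>           pplsda_pe pplsda_cc plsda
#> pplsda_pe     FALSE      TRUE  TRUE
#> pplsda_cc      TRUE     FALSE FALSE
#> plsda          TRUE     FALSE FALSE
```

The prediction-optimised rule (mean PE 5.7%) separates significantly from the
canonical-correlation rule (19.0%) — disjoint confidence intervals — while
PLS-DA tracks the γ = 0.5 fit; this is the package's headline behaviour.

A thin command-line front end ships in `inst/cli/pplsda`
(`pplsda simulate 3 1 case3.tsv`, `pplsda run config.yml`,
`pplsda diagnose data.tsv class diag.tsv`).

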