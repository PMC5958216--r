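# dinadif

Monte-Carlo machinery for studying **differential item functioning (DIF)
detection in cognitive diagnostic models when the Q-matrix is
misspecified**. The package is aimed at psychometricians and measurement
researchers who want to reproduce, extend, or stress-test the operating
characteristics (Type I error, power) of standard DIF detectors under the
DINA model.

## The model and the question

The DINA ("deterministic inputs, noisy and-gate") model scores examinee
*i* on item *j* through the ideal response

    eta_ij = prod_k alpha_ik ^ q_jk,

where the binary Q-matrix entry `q_jk` says whether item *j* requires
attribute *k* and `alpha_ik` is examinee *i*'s mastery of attribute *k*.
Responses are noisy observations of eta:

    P(X_ij = 1 | alpha_i) = (1 - s_j)^eta_ij * g_j^(1 - eta_ij),

with slipping `s_j` and guessing `g_j`. DIF means a reference and a focal
group differ in `s_j` or `g_j` for the same mastery profile. The package
crosses controlled DIF (shifts of ±0.075 / ±0.10 in the focal group's
parameters on six fixed items) with controlled Q-matrix misspecification
(10% of entries flipped — at random, only among low-complexity items, or
only among high-complexity items; in both groups or in the focal group
only) and three attribute correlations (0.3, 0.5, 0.8): a 357-condition
factorial design.

Three detectors are implemented and applied per item:

* **Mantel–Haenszel** — continuity-corrected common-odds-ratio chi-square
  over total-score strata (1 df);
* **logistic regression** — 2-df likelihood-ratio test of group +
  group×score;
* **Wald** — two-group marginal-ML EM fit of the DINA model with one
  studied item freed per group, 2-df Wald statistic on the parameter
  differences with an outer-product-of-gradients covariance.

## A worked example

```r
library(dinadif)
grid <- build_condition_grid()
nrow(grid)
#> [1] 357

# large uniform DIF (+0.10 on guessing and slipping), 10% random Q flips
# in both groups, attribute correlation 0.5
cond <- grid[grid$condition_id == "dif09_Rb_rho50", ]
tb <- run_condition(cond, n_reps = 30, methods = c("MH", "logistic"))
aggregate_overall(tb)
#>     condition_id   method type1_error     power
#> 1 dif09_Rb_rho50 logistic  0.08266667 0.8777778
#> 2 dif09_Rb_rho50       MH  0.07066667 0.4333333
```

The `type1_error` column is the mean flag rate over the 25 DIF-free items
(nominal level 0.05), `power` the mean flag rate over the six DIF items.
Here the logistic test retains high power (0.88) with mild Type I
inflation, while Mantel–Haenszel stays closer to the nominal level but
pays for it with much lower power — the uniform same-sign shifts on
slipping and guessing partially cancel in the marginal item difficulty
that MH sees.

`aggregate_by_complexity()` breaks the same rates down by item-complexity
stratum (items measuring ≤2 vs ≥3 attributes), and `cli_run()` drives a
configured multi-condition study from a YAML file, writing tidy,
resumable CSV summaries.

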