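# kerndr

Kernel-based drug repositioning: predict unknown drug–disease associations
from a binary association matrix plus chemical-structure and
disease-semantic similarities.

`kerndr` is aimed at computational biologists evaluating link-prediction
pipelines for drug repurposing. It implements the full chain:

1. **Sigmoid interaction-profile kernels** for drugs and diseases:
   `K(u, v) = tanh(a⟨u, v⟩ + r)` with `a = 1/N`, `r = 0`, where `u`, `v`
   are binary interaction profiles (columns/rows of the association
   matrix `A`).
2. **Logistic rescaling** `L(x) = 1/(1 + exp(cx + f))` (defaults
   `c = −15`, `f = ln 9999`) of the raw structure/semantic similarities,
   silencing weak values and amplifying strong ones.
3. **Cohesive-module enhancement**: deterministic greedy module detection
   on the weighted co-association graph maximising the cohesiveness
   `f(C) = W_in / (W_in + W_bound + 2|C|)`; similarities of co-clustered
   pairs are multiplied by `1 + f(C)` and capped at 0.99.
4. **Fusion**: per pair, the kernel value when both entities have known
   associations, the enhanced side similarity otherwise.
5. **Convolutional feature learning**: each pair's fused similarity rows
   are reshaped into a square grid and encoded by a small CNN
   (conv → 2×2 max-pool → dense, sigmoid activations, binary cross-entropy
   with L2 penalty, Adam); the dense-layer activations are the features.
6. **Random-forest scoring** (SVM comparator included), stratified
   ten-fold cross-validation with strict per-fold recomputation of every
   similarity from the training view, and leave-one-disease-out candidate
   ranking.

A synthetic benchmark generator with planted block structure makes every
stage testable offline.

## Worked example

```r
library(kerndr)

syn <- generate_synthetic(seed = 0)     # 60 drugs x 40 diseases, 4 planted blocks
cv  <- run_cross_validation(syn$association,
                            syn$drug_similarity, syn$disease_similarity,
                            k = 10, seed = 1, paper_mode = TRUE)
cv
#> <cv_result> 10-fold cross-validation (seed 1, paper mode)
#>   accuracy   80.18% +/- 6.10
#>   precision  80.63% +/- 7.38
#>   recall     80.00% +/- 8.78
#>   f1         80.06% +/- 6.36
#>   auc         0.85 +/- 0.06
```

Accuracy, precision, recall and F1 are percentages (mean ± SD over the ten
folds, hard predictions at probability 0.5); AUC is the midrank
Mann–Whitney estimate per fold. `tidy(cv)` returns the per-fold table,
`glance(cv)` the one-row summary, `autoplot(cv)` the ROC curves.
`paper_mode = TRUE` computes similarities once from the full matrix (the
optimistic protocol of the benchmark literature); the default instead
recomputes them per fold from the training view only, which is slower and
scores lower but leaks nothing — the methods vignette discusses the
difference and the benchmark's information ceiling.

Ranking candidates for one disease with all of its associations withheld
(the case-study protocol):

```r
rank <- rank_candidates_for_disease(syn$association, syn$drug_similarity,
                                    syn$disease_similarity, "disease_021",
                                    seed = 0, paper_mode = TRUE)
head(rank, 3)
#> # A tibble: 3 × 4
#>    rank drug_id  score known
#>   <int> <chr>    <dbl> <dbl>
#> 1     1 drug_033 0.998     0
#> 2     2 drug_059 0.998     0
#> 3     3 drug_021 0.996     0
sum(head(rank$known, 14))
#> [1] 7
```

`known` is the withheld truth: rows with `known = 0` near the top are the
model's new repositioning candidates, and `sum(head(rank$known, n))`
measures top-n recovery of the withheld positives — here 7 of the
disease's 14 known drugs land in its top 14 (chance would place about 3).
A thin command line sits in `inst/cli/kerndr` (subcommands `synth`,
`similarity`, `cv`, `rank`).

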