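# ambumetric

Personalized metric learning for estimating daily well-being constructs
(anxiety, stress, positive affect, negative affect) from multimodal
ambulatory data.

## The problem

Wearable and smartphone sensing can track the well-being of people in
high-stakes jobs (the motivating population is hospital workers) without
burdensome daily self-reports. The obstacle is inter-individual variability:
the same physiological or acoustic feature has a different location, scale
and shape for every participant, so models trained across people largely
learn *who* a sample came from rather than *how that person felt that day*.

`ambumetric` implements a Siamese-network metric-learning approach to this
problem. A shared embedding `f_W` maps a day's 69 ambulatory features
(25 activity/sleep, 29 vocal acoustic, 15 physiological) into a space where
the distance between two same-participant days matches the distance between
their (l2-normalized) self-reported labels, via the pairwise feature loss

    l_F = sum over participants n, sample pairs (m, m') of
          | ||f_W(x_nm) - f_W(x_nm')||_2  -  | y^_nm - y^_nm' | |

while a single-node head `g_V` regresses the raw label with a squared-error
loss `l_R = sum (g_V(f_W(x_nm)) - y_nm)^2`; both are minimized jointly by
mini-batch SGD (total loss `l_F + lambda * l_R`). Pairs are formed strictly
within participant, flagged similar when the raw labels differ by at most 1,
and class-imbalance weighted. Personalization is layered on top:

- **ML-A** — the Siamese regressor on ambulatory features alone;
- **ML-AT** — ambulatory features plus the participant's 14 one-time trait
  scores (12 for the affect constructs: the trait version of the target
  construct is dropped to avoid leakage);
- **ML-C** — trait-cluster-specific ML-AT models: traits are min-max
  scaled, projected onto 3 principal components, K-means clustered (K = 4 by
  default, elbow diagnostics provided), and one model is trained per
  cluster;
- **fine-tuning** — 0–90% of each test participant's days can be moved into
  the training pool before evaluation;
- baselines: a parameter-matched feed-forward regressor (**FNN**) and
  semi-supervised maximum-independence domain adaptation (**SMIDA**,
  participant-as-domain, linear kernel, HSIC objective, linear-regression
  head).

Evaluation follows a participant-independent 10-fold stratified
cross-validation (one fold validation, one test, the rest training, no
participant overlap), Pearson correlation scoring over random restarts,
one-tailed paired t-tests between variants, and a person-identification
probe (multinomial logistic regression) that measures how much identity
information a representation retains.

The original study's cohort is external and access-restricted, so the
package ships a first-class synthetic cohort generator that reproduces the
structure the method assumes: per-participant feature location/scale shifts,
4-cluster trait structure, skewed label marginals (>50% of anxiety labels at
1, ~80% of negative-affect labels at the minimum), ~10% missing feature
cells, and a configurable trait effect on the labels.

## Worked example

```r
library(ambumetric)

cfg <- generator_config(n_participants = 20, n_days = 15,
                        construct = "stress", signal_strength = 1.5,
                        seed = 7)
cohort <- generate_cohort(cfg)
d <- filter_participants(cohort$dataset, "stress", min_labeled_days = 13)
print(d)
#> <wb_dataset> 300 participant-days, 20 participants, 69 features, 14 traits

pairs <- compute_pair_weights(form_pairs(d, "stress"))
print(pairs)
#> <pair_set> 2100 pairs (1629 similar, 471 dissimilar), threshold 1

plan <- make_folds(d, "stress", n_folds = 4, seed = 1)
mc <- model_config(dropout = 0.1, patience = 3, max_epochs = 20)
report <- run_experiment("ml-a", d, plan, "stress",
                         fractions = c(0, 0.4), restarts = 3,
                         cfg = mc, folds = 1, seed = 5)
aggregate_report(report)
#>   variant construct fraction    mean_r      sd_r n_scores n_missing
#> 1    ml-a    stress      0.0 0.8614787 0.0291829        3         0
#> 2    ml-a    stress      0.4 0.7929878 0.0215761        3         0
```

The report rows are the mean and SD over restarts of the Pearson correlation
between predicted and self-reported stress on the held-out test fold, at two
fine-tuning fractions. (At this toy scale the two fractions are evaluated on
different reduced test sets — at 0.4, each test participant keeps only 9 of
15 days — so their scores are not directly comparable; the full protocol's
fine-tuning trend is exercised in `tests/testthat/test-acceptance.R`.)

A command-line wrapper covers the common steps:

```sh
ambumetric simulate --out cohort.csv --participants 30 --days 21 --seed 1
ambumetric validate --data cohort.csv --construct stress
ambumetric pairs    --data cohort.csv --construct stress --out pairs.csv
ambumetric evaluate --data cohort.csv --construct stress \
                    --variants ml-a,ml-at --fractions 0,0.4 \
                    --restarts 5 --folds 1,2 --out report
```

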