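# persense

Passive smartphone and wearable sensing for perioperative symptom
monitoring: an R pipeline that turns raw sensor streams (accelerometer,
activity recognition, GPS, screen, call/SMS, battery, ambient light,
conversation, per-minute heart rate and steps, sleep episodes) plus a
daily ten-symptom diary into a prediction of whether **tomorrow** will
be a high symptom-burden day for that patient.

It is written for methodologists working on digital biomarkers in
oncology and perioperative care: people who need a complete, tested,
leakage-disciplined reference implementation of this kind of pipeline —
feature engineering, person-mean-centered labeling, order-faithful
cleaning, split-aware imputation, SVM-SMOTE class rebalancing, temporal
leave-one-day-out nested cross-validation, gradient-boosted
classification, and SHAP attribution — together with a synthetic cohort
generator, because the patient cohorts this method targets are small
and not publicly shareable.

## The method in brief

Ten symptoms are each rated 0–10 every morning; their sum is the daily
composite burden *s<sub>it</sub>* ∈ [0, 100]. Days are labeled relative
to each person's own typical level:

&nbsp;&nbsp;&nbsp;&nbsp;*y<sub>it</sub>* = **1**{ *s<sub>it</sub>* − *s̄<sub>i</sub>* > 0 }

(ties are class 0). Day-level behavioral features from phone and
wearable — activity bouts, exertional episodes, heart-rate zone minutes
(HRmax = 220 − age), sleep attributed to the day an episode ends,
location-cluster dwell and entropy, screen sessions, communication,
light, battery — plus three non-sensor covariates (days since surgery,
most recent score, running mean score) predict the **next day's** label.
Surgery and hospital days are excluded; cleaning drops days with < 20 h
of sensor coverage, participants with < 5 days, features > 30% missing
or constant, days > 30% missing, and participants with < 5 labeled
days, in exactly that order.

Evaluation is leave-one-day-out with a temporal rule — the fold testing
participant *p*'s day *d* trains on other participants' rows plus *p*'s
rows strictly before *d* — with 3-fold stratified inner tuning of a
leaf-wise gradient-boosted model (seed 0, 200 trees, 128 max leaves,
learning rate ∈ {0.008, 0.01, 0.012}, column subsample ∈ {0.68, 0.70,
0.72}). Imputation, encoding, scaling, mutual-information feature
selection (top 75), and SVM-SMOTE all fit on training rows only, inside
each fold. Predictions are pooled across folds into accuracy, per-class
precision/recall/F1, macro F1, and rank AUC, and compared against three
baselines: majority class, prevalence-weighted random, and a decision
tree on the three non-sensor features alone.

## Worked example

Simulate a 20-participant perioperative cohort whose behavior couples
to symptom state (effect size 0.8 on high-burden days), inject 7%
sensor-day missingness, and run the full pipeline:

```r
library(persense)

coh <- inject_missingness(
  simulate_cohort(sim_config(n_participants = 20, postdischarge_days = 40,
                             beta = 0.8, seed = 1)),
  fraction = 0.07, seed = 1)
prep <- prepare_experiment(coh, target = "burden")
res  <- run_experiment(prep$data, seed = 1)

str(res$metrics)
#> List of 9
#>  $ accuracy   : num 70.9
#>  $ precision_0: num 73.8
#>  $ recall_0   : num 78.5
#>  $ f1_0       : num 76.1
#>  $ precision_1: num 66.1
#>  $ recall_1   : num 60
#>  $ f1_1       : num 62.9
#>  $ macro_f1   : num 69.5
#>  $ auc        : num 75

res$baseline_metrics$majority$auc        #> 50
res$baseline_metrics$tree_nonsensor$auc  #> 66.7

res$shap_ranking[1:3]
#>               feature mean_abs_shap
#> 1: days_since_surgery    0.69174018
#> 2:  most_recent_score    0.11401794
#> 3:           n_sms_in    0.08143880
```

Reading: on 973 labeled synthetic days the boosted model classifies
next-day burden with 70.9% pooled accuracy and 75.0% AUC, beating the
majority baseline (AUC 50) and the non-sensor decision tree (AUC 66.7)
— i.e. the pipeline recovers the behavior–symptom coupling the
generator planted beyond what symptom history alone explains. The
attribution ranking puts days-since-surgery and recent symptom history
first, with behavioral channels (heart rate, light, location movement)
following.

`prepare_experiment(coh, target = "pain")` (or `"fatigue"`, `"bowel"`)
runs the same pipeline against a single symptom's centered rating.

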