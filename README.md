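# nextdayrec

Next-day medical-activity recommendation from inpatient records.

## The problem

During a hospital stay, each day of care is a *set* of medical activities —
drug administrations, lab tests, nursing orders. Given the ordered sequence
of daily activity sets since admission and the patient's free-text medical
history (past history, current history, allergies), the task is to predict
the set of activities that will be ordered on the *next* day. This is a
temporal-set-prediction / next-basket problem with two clinically important
twists: many activities are **long-term orders** issued every day regardless
of condition changes (a diabetic diet, blood-pressure measurement), and the
free text carries patient-specific context that pure order sequences lack.
The package is aimed at clinical-informatics researchers who want a tested,
self-contained implementation of this model class plus the baselines and
metrics used to evaluate it — with a synthetic EMR generator in place of
protected hospital data.

## The model

For a day with activities \(v_1,\dots,v_{n_k}\) and embeddings
\(e_i = W_e v_i\), the day embedding is a soft-attention pooled sum

    d_k = Σ_i α_i e_i,   α_i = qᵀ σ(W e_i + b)

(the weights are left unnormalised, so the vector scales with basket size;
mean and max pooling are available as ablations). Day embeddings and history
word embeddings receive sinusoidal positional encodings
(`sin(pos/100^{2i/d_e})`, `cos(pos/100^{2i/d_e})`) and pass through
multi-head self-attention encoder blocks
(`LayerNorm(A + FFN(A))`, one layer over days, two over the history).
Per-day hidden states are aggregated by attention against the current day
(an MLP scores `concat(h_i, h_K)`; scores are softmax-normalised), and
history states by average pooling. A generator head maps the aggregated day
state to a probability vector over all M activities and is trained both with
a mean binary cross-entropy `L_g` and adversarially against a discriminator
that separates generated vectors from true next-day multi-hot vectors
(losses `L_D = −mean[log D(real) + log(1−D(fake))]` and
`L_G = mean log(1−D(fake))`). Final scores come from a frequency-gated
additive fusion over the day state `z_d`, history state `z_w`, and the
per-activity observed-frequency vector `l^p`:

    ŷ = σ( (1−α) ⊙ β ⊙ (W_d z_d + b_d) + α ⊙ l̃^p + λ (W_txt z_w + b_txt) ),
    α  = σ(W_p l̃^p + b_p)

so that frequently repeated orders can bypass the learned branch entirely.
Training minimises `L = mean ‖y − ŷ‖² + γ L_g` (plus the adversarial term)
with Adam, on a small reverse-mode autodiff engine implemented in the
package. Recommendation lists are top-K by score and evaluated with
Recall@K and NDCG@K averaged over patients; `PersonalTOP` (frequency
ranking) and `ItemTransfer` (last-day transition counts) are included as
baselines.

## Worked example

```r
library(nextdayrec)

# simulate an EMR-like cohort with planted structure
cfg <- synthetic_config(n_patients = 100, n_activities = 50, seed = 42)
cohort <- generate_cohort(cfg)
empirical_summary(cohort$records)[c("mean_days", "mean_activities_per_day")]
#> $mean_days                 [1] 8.61
#> $mean_activities_per_day   [1] 7.915215

# truncate each admission to ~70-80% of its days; the next day is the target
instances <- make_instances(cohort$records, cfg$n_activities, seed = 43)
split <- split_cohort(length(instances), seed = 44)

mcfg <- model_config(cfg$n_activities, cfg$n_words, d_e = 16, heads = 2)
model <- ndm_model(mcfg, seed = 45)
model <- train_model(model, instances[split$train], epochs = 10,
                     batch_size = 32, seed = 46)
tail(model$history[, 1:3], 3)
#>    epoch     loss        ce
#> 8      8 5.245332 0.3020961
#> 9      9 4.850025 0.3891970
#> 10    10 4.251678 0.4742253

evaluate_cohort(model, instances[split$test], cfg$n_activities)
#>  method  k recall   ndcg
#>   model 10 0.9342 0.9192
#>   model 15 0.9532 0.9299
#>   model 20 0.9594 0.9329
#>   model 25 0.9719 0.9385

predict(model, instances[split$test][[1]], k = 10)$top_k
#> [1]  4  5  3  2  1 18 19 21 25 40
```

After ten epochs the model recovers 93% of the true next-day activities in
its top 10 (random ranking would give 10/50 = 20%): the five long-term
orders (ids 1–5), the patient's condition cluster (here 18, 19, 21), and a
transfer-rule consequent. The per-epoch `loss` column is the total training
loss (squared error plus `γ·L_g`); on this cohort ten epochs is early —
frequency baselines remain competitive until the learned branches converge
(compare `evaluate_cohort("personal_top", ...)`), mirroring the situation
on real wards where long-term orders dominate. Attention weights for
inspection are available via `predict(...)$day_weights` (which day drove
the recommendation) and `attention_weight_table()` (which activities drove
each day embedding).

The command-line front end exposes the same pipeline:

```sh
exec/nextdayrec simulate   --out records.jsonl --n-patients 200 --seed 1
exec/nextdayrec preprocess --in records.jsonl --out inst.jsonl --n-activities 50
exec/nextdayrec train      --in inst.jsonl --out model.rds \
                           --n-activities 50 --n-words 120 --epochs 50
exec/nextdayrec evaluate   --model model.rds --in inst.jsonl --k 10,15,20,25
exec/nextdayrec baseline   --method item_transfer --in inst.jsonl \
                           --n-activities 50 --k 10
```

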