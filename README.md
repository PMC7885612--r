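# mortnet

Multimodal ICU mortality prediction from the first 48 hours of an intensive
care stay, fusing irregular physiological time series with sectioned
clinical notes — including the pre-admission history notes of
chronic-disease patients — and explaining its predictions through
label-aware attention.

## Who this is for

Clinical-informatics researchers working on in-hospital mortality
prediction from MIMIC-style electronic records (timestamped CHARTEVENTS/
LABEVENTS measurements, NOTEEVENTS free text, ICD-9 diagnosis codes), and
anyone who needs a fully testable reference implementation of a
label-aware-attention multimodal network without access to restricted
clinical data: the package ships a synthetic-EMR generator that reproduces
the statistical structure the model assumes, so every pathway is
exercisable end to end.

## The model

For a stay *P*, the temporal record is an hourly grid
*S_P* ∈ ℝ^(48×17) over the 17 acute-physiology features of APACHE II
(hourly means of raw measurements; forward-fill + clinical-normal
imputation; train-split z-scoring), encoded by an LSTM whose last hidden
state *h* is the temporal embedding:

    h_t = LSTM(S_t, h_{t-1}),   h = h_48.

The notes *N_P* (for chronic patients: history notes charted before the
observation window, then in-window notes) are segmented at section headers,
tokenized and embedded. Words and the two mortality labels are projected
into a joint space where compatibility is cosine similarity
*G[i,k] = cos(v_i, l_k)*; a windowed map gives non-negative word–label
scores *u_i = ReLU(G_win(i) W + b)*; attention is the content-only softmax
of *m_i = max_k u[i,k]*; and a 1-D convolution with global max-pooling over
the attended sequence *q_i = α_i v_i* yields the text feature *c*. The
fused vector *z = h ⊕ c* feeds a sigmoid head, trained with

    loss = BCE(y, ŷ) + (1/2) Σ_k BCE(y_k, σ(m_k)),

where *m_k = max_i u[i,k]* are label-wise pooled attention scores — the
joint-embedding regularizer that ties attention to the labels. Section
importance is the attention mass of a section's non-stop-words divided by
the total non-stop-word attention. Ablation variants (`lstm_only`,
`cn_only`, `multi_cn`, `multi_atten`, `multi_atten_chronic`) isolate each
architectural contribution. The entire network, including
backpropagation and Adam, is implemented in base R matrix algebra.

## Worked example

```r
library(mortnet)

spec <- cohort_spec(n_patients = 300, prevalence = 0.3,
                    signal_strength = 0.9, effect_size = 1.5, seed = 11)
episodes <- as_episodes(generate_cohort(spec))

cfg <- model_config(variant = "multi_atten_chronic", H = 24, embed_dim = 16,
                    P_joint = 12, n_filters = 12, L_max = 160,
                    dropout_rate = 0.5, learning_rate = 5e-3,
                    batch_size = 16, max_epochs = 30,
                    early_stop_rounds = 30, seed = 1)
model <- mortnet(episodes, cfg)
model
#> Multimodal ICU mortality network
#>   variant:      multi_atten_chronic
#>   episodes:    300 (99 positive)
#>   best epoch:  28 (val AUCPR 1.000)
#>   test:         AUCPR 1.000 | AUCROC 1.000
```

The synthetic cohort plants the tokens `sepsis`, `hypotension`, `anuric`,
`pressors` in positive-label notes and shifts heart rate, respiratory rate
and systolic pressure; held-out AUCPR/AUCROC of 1.000 show both channels
were recovered. Explanations come from the attention weights:

```r
ex <- explain(model, episodes[[15]])
ex
#> <mortnet_explanation> S00015  y_hat = 0.997
#> top sections: HISTORY_OF_PRESENT_ILLNESS (0.33),
#>   MAJOR_SURGICAL_OR_INVASIVE_PROCEDURE (0.18), SOCIAL_HISTORY (0.15)
explanation_heatmap(ex, "heatmap.html")   # token-level attention rendering

predict(model, episodes[1:3])
#>       S00001       S00002       S00003
#> 0.0002732817 0.0001960003 0.0001392060
```

`y_hat = 0.997` is the predicted death probability for a positive-label
patient; the top section is the one the generator plants signal into, and
the three survivors above get probabilities near zero. A shell pipeline
wraps the same functions:

```sh
inst/cli/mortnet simulate --n 50 --seed 1 --out data/
inst/cli/mortnet train    --data data/ --out ckpt/ --config cfg.json
inst/cli/mortnet evaluate --ckpt ckpt/ --data data/ --out metrics.csv
inst/cli/mortnet explain  --ckpt ckpt/ --data data/ --out report/
```

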