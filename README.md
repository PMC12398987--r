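# dentplan

Can a small neural network learn standard-care dental prosthesis
planning? `dentplan` is an R package for studying that question *in
silico* on a single 16-tooth jaw. It is aimed at dental-informatics and
clinical-decision-support researchers who want a fully controlled test
bed: a deterministic rule engine supplies perfect labels, a constrained
generator supplies unlimited valid cases, and a compact sequence-labelling
network is trained and scored against the rules it is supposed to
internalize.

## The problem and the model

A findings chart assigns each of 16 tooth positions one of ten codes
(`f` missing, `.` sufficient, `x` condemned, `k`/`b` sufficient
crown/bridge unit, `e` sufficient denture tooth, `ww` preservation-worthy
insufficient tooth, `kw`/`bw`/`ew` insufficient restorations). The
standard-care rules map this chart deterministically to a plan chart over
`-` (nothing), `K` (crown), `B` (bridge unit), `E` (removable-denture
replacement): bridges require crownable abutments on both sides (no
cantilevers), four or more missing teeth — or any unbounded gap, or an
insufficient existing denture — force the removable-denture pathway, and
missing wisdom teeth are never replaced.

The learning task is multi-output multi-class classification,
`x ∈ {0,…,9}^16 → ŷ ∈ Δ^4×16`: an embedding maps each finding token to a
dense vector, a bidirectional LSTM (128 units per direction in the
baseline M0) propagates context across positions, and position-wise dense
layers emit a softmax over the four plan codes per tooth. Training
minimizes categorical cross-entropy with Adam (initial learning rate
10⁻³, halved after 5 plateau epochs down to 10⁻⁷), batch size 32, an
80/20 train/validation split of the N_cal available cases, early stopping
with patience 10 and best-weight restore, at most 200 epochs. The
headline metric is **exact-set accuracy**: the percentage of test cases
whose predicted plan is correct at *all 16* positions. Six architecture
presets (M0–M5: LSTM replaced by a dense layer, extra dense layer, dense
layer removed, all widths doubled, all widths halved) support an
architecture ablation; the neural engine is implemented in
RcppArmadillo with a finite-difference-verified backward pass.

## A worked example

```r
library(dentplan)

# the rule engine: one missing tooth in an intact arch gets a bridge
plan_case(". . . . . . . f . . . . . . . .")
#> <plan chart>
#>  FDI:  18 17 16 15 14 13 12 11 21 22 23 24 25 26 27 28
#>         -  -  -  -  -  -  K  B  K  -  -  -  -  -  -  -

# four missing teeth force a removable denture
plan_case(". . . . f f f f . . . . . . . .")
#>         -  -  -  -  E  E  E  E  -  -  -  -  -  -  -  -

# a labelled synthetic collection: unique, valid, half reserved for testing
col <- generate_collection(generator_config(n_total = 20000, n_test = 10000,
                                            seed = 1))
col
#> <case_collection> 20000 cases (10000 trainpool / 10000 test), seed 1
#>   plans containing a bridge: 71.0%

# train the baseline on 7000 cases and score it on the untouched test pool
fit <- plan_net(draw_ncal(col, 7000, seed = 11), arch = "M0",
                config = training_config(seed = 11))
evaluate_model(fit, collection_split(col, "test"))
#> <plan_eval> 10000 cases: exact-set 99.64%, per-tooth 99.94%

predict_plan(fit, ". . . . . . . f . . . . . . . .")
#>         -  -  -  -  -  -  K  B  K  -  -  -  -  -  -  -
```

So a trained M0 reproduces the rule engine's decision on an unseen chart,
and gets the *entire* 16-position plan right on 99.6% of 10,000 held-out
cases. At smaller training sizes accuracy drops steeply and depends on
the architecture; `run_size_sweep()` and `run_architecture_comparison()`
drive those experiments, and `compare_groups()` applies Kruskal–Wallis
with Dunn–Bonferroni post-hoc tests and z-based effect sizes to the
per-architecture accuracy samples. Note that absolute accuracies at small
N_cal depend on the generator's sampling distribution (a declared
stand-in; see the methods vignette), while the large-N_cal end does not.

A command-line front end is installed with the package
(`system.file("scripts", "dentplan", package = "dentplan")`) with
subcommands `generate`, `plan`, `train`, `evaluate`, `predict`, `sweep`,
`compare`, `stats`; every output directory receives a `manifest.json`
with seeds and input digests, and `evaluate` warns when the offered cases
overlap a run's recorded training draw.

## Package layout

* `R/vocab.R`, `R/rules.R` — chart vocabularies, parsing/encoding, the
  standard-care rule engine (`plan_case()`, `validate_findings()`).
* `R/generator.R`, `R/io.R` — constrained synthetic generator and the
  CSV + JSON-sidecar dataset format.
* `R/architectures.R`, `R/network.R`, `src/nn.cpp` — the six presets,
  the `plan_net` model object and the compiled training engine.
* `R/experiments.R`, `R/stats.R` — experiment drivers, summaries,
  Kruskal–Wallis/Dunn–Bonferroni.
* `vignettes/dental-prosthesis-planning.Rmd` — the methods vignette:
  model, assumptions, parameter choices, limitations.
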