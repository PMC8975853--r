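# screenrhythms

Daily and weekly rhythms of smartphone use, decomposed into interpretable
diurnal components, with sleep inferred from inactivity gaps.

People differ in when they are active and when they sleep — their
*chronotype*. Instead of questionnaires, `screenrhythms` measures these
rhythms from a passive signal: timestamped phone screen-on/off events. For
every participant it builds a normalized 168-bin hour-of-week activity
profile, stacks the cohort into a matrix `X` (N people × 168 hours), and
factorizes

```
X ≈ W Hᵀ,   minimizing  E = ½ ‖X − W Hᵀ‖²_F  subject to  W, H ≥ 0,
```

with a from-scratch hierarchical alternating least squares (HALS)
non-negative matrix factorization under a 1000-restart protocol. The K
columns of `H` are basis rhythms (in practice: morning, noon, evening and
night activity); each person is reduced to K non-negative weights,
normalized to sum to one. The number of components is chosen by consensus
clustering over repeated randomly initialized runs, scored by the
cophenetic correlation coefficient. Independently, nightly sleep, wake and
mid-sleep times are estimated per day by the longest-inactivity rule in
noon-anchored 24-hour windows, summarized per person by modes, and
correlated (Pearson r with two-sided p) with the component weights.

The package is intended for researchers in digital phenotyping and
chronobiology who have event-level phone logs (or any comparable
timestamped activity stream) and want population rhythm components,
per-person chronotype-like weights, and sleep-timing estimates from one
reproducible pipeline. A synthetic cohort generator with planted ground
truth (archetypes, weights, sleep windows, filter violators) makes every
stage testable without access to any private dataset.

## Worked example

```r
library(screenrhythms)

# a synthetic cohort: 200 compliant participants, 50 weeks, plus 10 planted
# filter violators; fully reproducible from the seed
cfg <- generator_config(n_low_activity = 5, n_sparse_days = 5, seed = 1)
pop <- generate_population(cfg)

log      <- filter_participants(pop$log)          # inclusion filters
X        <- assemble_matrix(weekly_profiles(log)) # 200 x 168 profile matrix
sel      <- select_k(X, 2, 7, n_runs = 30, seed = 1001)
fit      <- nmf_multistart(X, K = 4, n_seeds = 1000, seed = 2001)
weights  <- normalize_weights(fit, ids = rownames(X))
sleep    <- summarize_sleep_all(infer_sleep(log))
assoc    <- sleep_weight_associations(weights, sleep)

sel$best_k                      # 4
round(fit$error, 4)             # 0.0163
weights$labels                  # "morning" "night" "evening" "noon" (order varies)
round(assoc$r["night", "sleep_time"], 2)    #  0.95
round(assoc$r["evening", "sleep_time"], 2)  # -0.44
round(assoc$r["morning", "wake_time"], 2)   # -0.90
```

Reading the numbers: the cophenetic sweep is maximized at four components;
the multi-restart HALS fit reconstructs the 200 weekly profiles with a
squared-Frobenius error of 0.016; and the recovered weights carry the
planted association structure — people with more night-component weight go
to sleep later (r = 0.95), people with more evening weight go to sleep
earlier (r = −0.44), and people with more morning weight wake earlier
(r = −0.90). On the same run, the recovered components match the planted
archetypes with a mean cosine similarity of 0.994 and the normalized
weights recover the planted weights to a mean absolute error of 0.028.

A command-line interface wrapping the same functions is installed at
`inst/cli/screenrhythms` with subcommands `simulate`, `filter`, `profiles`,
`select-k`, `decompose`, `sleep`, `associate` and `run-all`, e.g.

```sh
Rscript inst/cli/screenrhythms simulate --n-participants 50 --seed 7 --out sim
Rscript inst/cli/screenrhythms run-all --events sim/events.csv --K 4 --out run
```

`run-all` writes every stage artifact (filtered events, profile matrix,
`W.csv`/`H.csv`, normalized weights, per-day sleep records and summaries,
association tables) plus a JSON manifest of seeds and counts.

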