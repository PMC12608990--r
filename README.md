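# menusim

Population-level simulation benchmark for menu recommender systems.

Food services would like to recommend, per diner and day, the dishes each
diner is most likely to pick — but public interaction datasets carry no
demographics, so algorithms cannot be compared *across populations*.
`menusim` closes that gap by simulation: a Mamdani fuzzy-logic engine turns
demographic attributes (age, gender, coastal/inland region, locality size)
into ground-truth diner profiles, a menu environment simulates daily
choices, and five recommendation policies compete on the resulting
populations.

## The model in brief

**Profiles.** Each attribute record is fuzzified through overlapping
membership sets (five age classes, crisp categoricals) and pushed through
three rule blocks — 17 rules for diet, 30 for per-tag tastes, 15 for
innovation appetite — with Mamdani min–max inference and centroid
defuzzification. The output profile holds a diet class *d* ∈ {omnivore,
flexitarian, vegetarian, vegan} (vegan zeroes all animal-derived tags,
vegetarian zeroes meat and fish), taste probabilities *p_t* ∈ [0, 1] over
the 12 dish tags (rice, pasta, potato, legume, vegetables, white meat, red
meat, fish, fried, egg, dairy, fruit), and an innovation score ι ∈ [0, 1].
Calibrated against national reference statistics: 1300 emergent users hit
87% omnivores (±3 pp) and 6% vegetarian+vegan above age 15 (±2 pp).

**Environment.** A catalog of 60/60/25 dishes (10/23/4 innovative) feeds
daily menus of 3/3/2 distinct plate types; users select each course with
probability ∝ *p_t* · (0.5 + ι for innovative dishes). A recommendation
(course, tag) that matches the selection scores reward 1; the action space
has 5 + 8 + 2 = 15 course–tag pairs. A uniform-random recommender earns
exactly 1/3 + 1/3 + 1/2 = 7/6 per day.

**Policies.** random baseline; the *Optimum* oracle (argmax of true
weights, an upper bound); an ε-greedy multi-armed bandit (ε = 0.15,
per-user match-rate estimates); tabular SARSA (α = 0.1, γ = 0.9); and a
DQN — 3-day selection history → 32-unit LSTM → concat with one-hot action
→ 16-unit ReLU → Q, trained from replay memory with a target network,
ε decaying 0.15 → 0.01.

**Evaluation.** Accumulated reward (mean ± SD of per-user totals),
improvement over random, efficiency (matches/day out of 3), macro
precision/recall/F1, and pairwise population comparisons with two-sided
Mann–Whitney tests and Cliff's delta.

## Worked example

Benchmark four policies on two contrasting 10-user groups — urban
"Foodies" with sharp preferences and flat-preference "Seniors" — over 120
simulated days:

```r
library(menusim)
groups <- lapply(default_groups()[c("Foodies", "Senior")],
                 function(g) { g$n_users <- 10L; g })
ec  <- experiment_config(seed = 10, n_days = 120, groups = groups,
                         policies = c("random", "optimum", "mab", "dqn"))
res <- run_benchmark(ec)
res$metrics
```

```
 algorithm   group accumulated_reward improvement_pct efficiency    f1
   optimum Foodies                194           35.95       1.62 0.456
       dqn Foodies                159           11.70       1.33 0.348
       mab Foodies                157           10.30       1.31 0.403
    random Foodies                143            0.00       1.19 0.390
   optimum  Senior                157            5.88       1.30 0.423
    random  Senior                148            0.00       1.23 0.410
       mab  Senior                146           -1.22       1.22 0.386
       dqn  Senior                137           -7.37       1.14 0.314
```

Reading the numbers: on Foodies the oracle matches 1.62 of 3 courses per
day (+36% over random) and both learners recover roughly a third of that
headroom in four months; on Seniors, whose tastes sit at the flat midpoint,
no policy can beat random by more than a few percent — recommendation has
little value when preferences are undifferentiated. The pairwise module
quantifies the population difference for the DQN: Cliff's δ = 0.78 with
p = 0.0036 (per-user accumulated rewards, Foodies vs Senior).

`report(res, "out/")` writes the metrics CSV, pairwise p/δ matrices,
accumulated-reward and rolling-accuracy plots per group, a ranked summary,
and a manifest with a content hash; identical seeds reproduce runs
bit-for-bit. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/menusim.R run-benchmark --seed 10 --days 120 --users 10 --out out/
Rscript inst/cli/menusim.R simulate-population --n 1300 --seed 10 --out pop.csv
```

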