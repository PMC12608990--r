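---
title: "Simulating populations of diners and benchmarking menu recommenders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating populations of diners and benchmarking menu recommenders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menusim)
```

## The problem

Food services — canteens, delivery platforms, care-home kitchens — would
like to recommend, for every diner and every day, the dishes the diner is
most likely to choose. Evaluating recommendation algorithms for this task
on real data is hard: public interaction datasets carry no demographics, so
nothing can be said about how an algorithm behaves on *different
populations*. `menusim` takes the simulation route: it synthesizes
populations of diners whose preferences are driven by demographic
attributes through an interpretable fuzzy-logic model, and uses them as a
ground-truth test bed for reinforcement-learning recommenders.

The package has three layers:

1. a **Mamdani fuzzy inference engine** that turns demographic attributes
   (age, gender, coastal/inland region, locality size) into a user profile:
   a diet class, a probability of choosing each of 12 dish-category tags,
   and an innovation score;
2. a **menu environment**: a dish catalog (60 first courses, 60 second
   courses, 25 desserts, tagged and partly flagged innovative), daily menus
   of 3/3/2 options, simulated selections, and match rewards;
3. five **recommendation policies** behind one contract — uniform random, a
   preference oracle ("Optimum"), an epsilon-greedy multi-armed bandit,
   tabular SARSA, and a deep Q-network with an LSTM history encoder — plus
   an evaluation suite (accumulated reward, improvement over random,
   efficiency, classification metrics, rank-sum tests and Cliff's delta).

## The fuzzy preference model

Crisp attributes are fuzzified through overlapping membership sets. Age has
five sets (children, teenagers, youths, adults, seniors) with trapezoidal
memberships whose plateaus follow the conventional ranges 0–16, 14–25,
22–32, 42–70 and 68+; the published ranges leave the band between 32 and 42
uncovered, so the youth and adult shoulders are extended to meet near 37
with a slight overlap, keeping every age assignable. Gender, region and
locality size enter the same rule machinery as crisp categorical variables.

Inference is Mamdani min–max: a rule's firing degree is the minimum (AND)
or maximum (OR) of its antecedent memberships times an optional weight; the
consequent set is clipped at that degree; all clipped areas for one output
variable are aggregated pointwise by maximum; and the aggregated area is
collapsed to its centroid by trapezoidal quadrature. If no rule fires for
an output, the universe midpoint (0.5) is used.

Three rule blocks are shipped as editable YAML
(`system.file("extdata", "rulebase.yaml", package = "menusim")`):

* **diet** (17 rules) places each profile on a `[0, 1]` axis that is
  partitioned at 0.25 / 0.5 / 0.75 into vegan, vegetarian, flexitarian and
  omnivore. A zero-mean Gaussian perturbation (`sigma_diet`, default 0.06)
  is added before thresholding, so the same demographic cell can produce
  different diet classes. Vegetarian and vegan outcomes concentrate among
  young women in medium and large localities — the only demographic pattern
  strong enough in the reference statistics to carry the national shares.
* **tastes** (30 rules) sets one probability per tag. The encoded
  tendencies are deliberately conventional: children and teenagers favour
  pasta, fried food and dairy and dislike vegetables and legumes; adults
  favour vegetables, legumes and fruit; coastal residents of working age
  favour fish while inland adults favour red meat; seniors get no taste
  rules at all, so their profile sits at the flat midpoint — a population
  with no clear preferences. Symmetric truncated-Gaussian noise
  (`sigma_taste`, default 0.05) individualizes profiles without moving the
  cell means; diet constraints are applied afterwards (vegan zeroes all
  animal-derived tags, vegetarian zeroes meat and fish, flexitarian halves
  the meat tastes) and are never undone downstream.
* **innovation** (15 rules) grows with locality size and falls with age; a
  profile counts as innovative at a score of at least 0.5. During
  selection, innovative dishes have their weight multiplied by
  `0.5 + innovation`, so innovation-averse users actively avoid them.

The diet thresholds, noise scales, damping factor and multiplier base are
all held in `fuzzy_config()`.

### Calibration

The generator is calibrated against published reference statistics, not
fitted to data: with the shipped rule base and demographic reference
(Spanish-like age pyramid in 5-year bins sampled through a piecewise-linear
density, 51% women, 45% coastal, locality mix 28/37/35), a 1300-user
emergent population lands within 3 percentage points of 87% omnivores and
within 2 points of 6% vegetarians-plus-vegans among users older than 15.
`calibration_curve()` exposes the running shares as the population grows,
which is the intended way to validate a modified rule base. Subgroup
generation is different: the four shipped group specifications (Spanish,
Foodies, Veggies, Senior — 50 users each) state diet shares as quotas, and
`generate_population()` enforces them exactly by stratified assignment,
because those rows read as specifications rather than emergent statistics.
The innovative-user percentages, by contrast, are *not* enforced: each
group's attribute recipe (Foodies and Veggies are urban any-age adults,
Seniors live in small and medium localities) reproduces them through the
innovation block, within a few points.

## The menu environment

Daily menus offer distinct plate types: 3 of the 5 first-course tags, 3 of
the 8 second-course tags, and both dessert tags, each tag realized by one
uniformly drawn dish. Distinct tags per course make the uniform-random
recommender's expected daily reward exactly 1/3 + 1/3 + 1/2 = 7/6, which
serves as an analytic anchor for the whole pipeline. A course is resampled
until it contains at least one plant-tag vegetarian option, so every diet
class always has a positive-probability choice. By default each user
receives their own menu draw per day (a delivery-service framing); a single
shared menu per group-day (canteen framing) is a configuration switch.

Users select one option per course with probability proportional to
taste times the innovation multiplier. The recommendation never influences
the selection, so one selection stream per user-day can score every policy
(the default; independent draws per policy are available). A course-level
match earns evaluation reward 1.

## The recommenders

All policies see only the menu and (for learning policies) the user's
observed selections; only the oracle sees the true profile.

* **random** — uniform over the day's options; the baseline for the
  improvement metric.
* **optimum** — recommends the offered tag with the maximal true selection
  weight. Because selections are stochastic, even the oracle cannot match
  every choice; it upper-bounds every learner.
* **MAB** — per user and course, epsilon-greedy (epsilon 0.15) over learned
  propensities. The default update is bandit feedback: p_i is the match
  rate of the bandit's own recommendations of tag i, so the bandit learns
  only about arms it plays. A full-information variant (p_i = the user's
  selection frequency of tag i) is config-exposed; it is considerably
  stronger because it turns every selection into feedback about all arms.
* **SARSA** — per user and course, a Q table over (last selected tag,
  candidate tag) updated on-policy once per day with learning rate 0.1 and
  discount 0.9. Its state carries little signal early on, which is why it
  tracks the random baseline over a one-year horizon.
* **DQN** — one shared network per group. The last 3 days of selections
  (one-hot per course slot, 36 inputs per day, zero-padded before day 3)
  pass through a 32-unit LSTM; the final hidden state is concatenated with
  the one-hot action (course + tag) and scored by a 16-unit ReLU layer and
  a linear output. Adam with learning rate 0.0005; training every 20
  recommendations after a 20-day burn-in, on a replay sample of 30
  transitions with 30 gradient passes per training event; bootstrap targets
  `r + 0.9 * max Q_target(s', a')` with the target network synced every 3
  trainings; epsilon starts at 0.15 and decays 0.01 per training to a floor
  of 0.01; total gradient steps are capped at 15000.

Two DQN choices deserve explanation. First, training rewards default to +3
for a match and −2 for a miss (both inside the tuning ranges 1–10 and −5–0
considered for these parameters): at typical match rates around 40% this
centres the expected reward near zero, which keeps the bootstrap value
offset `gamma / (1 - gamma) * mean(r)` small — with a fixed learning rate
of 0.0005, an uncentred offset dominates the regression for thousands of
steps before any action discrimination emerges. Second, the number of
gradient passes per training event is not a published quantity; 30 was
chosen as the smallest value at which the network reliably converges on a
degenerate single-preference user within 200 days under the fixed learning
rate and schedule.

The discount factor (never stated for the network) defaults to 0.9, and
the bootstrap maximum is taken over all 15 actions by default, with a
per-course restriction available (`bootstrap_scope = "course"`); at the
scales we examined the two are indistinguishable.

## Evaluation

`metrics_table()` reports, per algorithm and group: accumulated reward
(mean and SD over users of total matches), improvement over the same run's
random policy, efficiency (mean matches per day, out of 3), and macro
precision/recall/F1 with the recommended tag as the prediction and the
selected tag as the truth (macro over tags within course, then averaged
over courses; a micro variant is config-exposed). `pairwise_comparison()`
compares groups on per-user totals and on per-user oracle gaps with
two-sided Mann–Whitney tests (the effect-size companion Cliff's delta is
computed by its all-pairs definition). The significance test is not named
in the source material; Mann–Whitney is the natural partner of Cliff's
delta, and Welch's t is available as an alternative.

## Problem sizes and what the tests show

The shipped test-suite benchmark uses 4 groups x 10 users x 120 days — a
size at which the full five-policy comparison, including network training,
completes in about a minute — with 10 x 1000 user-days for the analytic
baseline check and 1300 users for calibration. At this reduced scale the
qualitative structure of the full-size benchmark emerges: the oracle
dominates everywhere; the bandit clearly beats SARSA, which tracks random;
all policies cluster within 15% of random on the flat-preference Senior
group; and the network overtakes the bandit on the urban groups (Foodies,
Veggies) whose members are demographically similar.

One finding does not transfer to desk scale: on the demographically mixed
Spanish group the shared network stays near the random baseline while the
per-user bandit gains 10–20%. With ten users and 120 days the network sees
too few interactions to condition its recommendations on the selection
history (its only route to personalization), whereas the bandit's per-user
match-rate estimator is exactly the sufficient statistic and converges
within weeks. Offline experiments with idealized, fully exploratory
training data confirm the ceiling: at this data volume the network cannot
exceed the bandit on that group. The network's advantage over the bandit
on mixed populations should therefore be expected to emerge only at larger
scales — the default configuration of 50 users over a full year supplies
roughly fifteen times the interaction data of the reduced setting.

## Known limitations

* Preferences are static: no seasonality, fatigue, or novelty dynamics.
* The dish catalog is synthetic (names are templated from tags) and has no
  nutritional, cost or logistic attributes.
* The rule base encodes conventional, literature-level tendencies; only
  the national diet shares and the innovative-user percentages are
  calibrated against published statistics. Per-tag taste levels for
  specific demographics are modelling choices, not measurements.
* Selections depend only on the profile and the menu; real diners react to
  presentation, price and the recommendation itself.

## Reproducibility

Every stochastic component draws from R's RNG, so a single `set.seed()`
(or the `seed` field of `experiment_config()`) makes population
generation, menu streams, selections and network initialization
bit-reproducible; `run_benchmark()` stamps its output with a content hash
recorded in the manifest, and re-running `report()` on the same result
reproduces byte-identical tables.
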