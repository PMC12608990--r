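Package: menusim
Title: Population-Level Simulation Benchmark for Menu Recommender Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates demographically distinct populations of diners with a
    Mamdani fuzzy inference engine (diet class, per-tag taste probabilities,
    and an innovation score derived from age, gender, region, and locality
    size), builds a tagged dish catalog with daily 3/3/2 menus, and benchmarks
    menu recommendation policies on the resulting Markov decision process:
    a uniform-random baseline, a preference oracle, an epsilon-greedy
    multi-armed bandit, tabular SARSA, and a deep Q-network with an LSTM
    state encoder, replay memory, and a target network. Includes an
    evaluation suite with accumulated reward, improvement over random,
    efficiency, classification metrics, and pairwise population comparisons
    via rank-sum tests and Cliff's delta.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
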