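# Random, oracle, bandit and SARSA policies.

test_that("random recommendations are uniform over a course's options", {
  menu <- fixture_menu(c("rice", "pasta", "potato"),
                       c("legume", "vegetables", "potato"),
                       c("fruit", "dairy"))
  set.seed(1)
  recs <- replicate(9000, random_recommend(menu)[1])
  tab <- table(factor(recs, levels = c("rice", "pasta", "potato")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  single <- fixture_menu("rice", "fish", "fruit")
  expect_equal(unname(random_recommend(single)),
               c("rice", "fish", "fruit"))
})

test_that("the oracle recommends the argmax effective weight", {
  prof <- fixture_profile(c(pasta = 0.9, rice = 0.05, vegetables = 0.05,
                            fish = 0.6, egg = 0.2, legume = 0.3,
                            fruit = 0.5, dairy = 0.5))
  menu <- fixture_menu(c("pasta", "rice", "vegetables"),
                       c("fish", "egg", "legume"), c("fruit", "dairy"))
  rec <- optimum_recommend(prof, menu)
  expect_equal(unname(rec[1:2]), c("pasta", "fish"))
  # dessert tie at 0.5/0.5 -> alphabetical tag order
  expect_equal(unname(rec[3]), "dairy")
  # favourite absent -> best offered tag
  menu2 <- fixture_menu(c("rice", "vegetables", "legume"),
                        c("fish", "egg", "legume"), c("fruit", "dairy"))
  expect_equal(unname(optimum_recommend(prof, menu2)[1]), "legume")
  # deterministic
  expect_identical(optimum_recommend(prof, menu),
                   optimum_recommend(prof, menu))
})

run_policy_days <- function(policy, prof, days, seed = 2, ctl = NULL) {
  if (is.null(ctl)) ctl <- fixture_catalog()
  set.seed(seed)
  st <- history_state(prof$user_id)
  recs <- vector("list", days)
  for (m in seq_len(days)) {
    menu <- sample_daily_menu(ctl, m)
    r <- policy_recommend(policy, st, menu)
    policy <- r$policy
    sel <- simulate_selection(prof, menu)
    policy <- policy_observe(policy, st, menu, r$tags, sel)
    st <- advance_state(st, sel)
    recs[[m]] <- list(tags = r$tags, menu = menu, sel = sel)
  }
  list(policy = policy, recs = recs)
}

test_that("selection-frequency propensities equal k / n over observed days", {
  prof <- fixture_profile(c(rice = 0.7, pasta = 0.3, potato = 0.4,
                            legume = 0.3, vegetables = 0.4, fish = 0.6,
                            egg = 0.4, fried = 0.3, fruit = 0.6,
                            dairy = 0.4, white_meat = 0.5, red_meat = 0.4))
  out <- run_policy_days(mab_policy(update = "selection_frequency"),
                         prof, 40)
  pol <- out$policy
  expect_equal(pol$n_days, 40L)
  p <- menusim:::mab_propensities(pol)
  sel_first <- vapply(out$recs, function(r) r$sel$tag[1], character(1))
  for (tg in names(p$first))
    expect_equal(p$first[[tg]], mean(sel_first == tg))
  expect_equal(sum(p$first), 1)
})

test_that("match-feedback propensities are own-recommendation match rates", {
  prof <- fixture_profile(c(rice = 0.9, pasta = 0.2, potato = 0.2,
                            legume = 0.2, vegetables = 0.2, fish = 0.5,
                            egg = 0.4, fried = 0.3, fruit = 0.6,
                            dairy = 0.4, white_meat = 0.5, red_meat = 0.4))
  out <- run_policy_days(mab_policy(), prof, 60)
  pol <- out$policy
  p <- menusim:::mab_propensities(pol)
  rec_first <- vapply(out$recs, function(r) r$tags[1], character(1))
  hit_first <- vapply(out$recs, function(r)
    r$tags[1] == r$sel$tag[1], logical(1))
  for (tg in names(p$first)) {
    n <- sum(rec_first == tg)
    expect_equal(p$first[[tg]],
                 if (n > 0) sum(hit_first[rec_first == tg]) / n else 0)
  }
})

test_that("a greedy selection-frequency bandit converges on a degenerate user", {
  prof <- fixture_profile(c(pasta = 1))
  prof$tastes[prof$tastes == 0] <- 1e-6
  out <- run_policy_days(mab_policy(epsilon = 0,
                                    update = "selection_frequency"),
                         prof, 30)
  # after the first selections, pasta is recommended whenever offered
  late <- out$recs[11:30]
  for (r in late)
    if ("pasta" %in% r$menu$first$tag)
      expect_equal(r$tags[1], "pasta")
})

test_that("a fully exploring bandit is indistinguishable from random", {
  prof <- fixture_profile(c(rice = 0.9, pasta = 0.1, potato = 0.1,
                            legume = 0.1, vegetables = 0.1))
  menu <- fixture_menu(c("rice", "pasta", "potato"),
                       c("legume", "vegetables", "potato"),
                       c("fruit", "dairy"))
  pol <- mab_policy(epsilon = 1)
  st <- history_state("fx1")
  set.seed(3)
  recs <- replicate(9000, policy_recommend(pol, st, menu)$tags[1])
  tab <- table(factor(recs, levels = c("rice", "pasta", "potato")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("epsilon-greedy explores at the configured rate", {
  # with propensities locked on rice, non-rice recommendations can only
  # come from the exploration branch (2 of 3 explored options differ)
  pol <- mab_policy(epsilon = 0.3)
  pol$counts$first["rice"] <- 100; pol$trials$first["rice"] <- 100
  menu <- fixture_menu(c("rice", "pasta", "potato"),
                       c("legume", "vegetables", "potato"),
                       c("fruit", "dairy"))
  st <- history_state("fx1")
  set.seed(4)
  n <- 5000
  recs <- replicate(n, policy_recommend(pol, st, menu)$tags[1])
  p_expl <- 0.3 * 2 / 3
  se <- sqrt(p_expl * (1 - p_expl) / n)
  expect_lt(abs(mean(recs != "rice") - p_expl), 3 * se)
})

test_that("the SARSA update follows the temporal-difference rule", {
  tb <- matrix(0, 2, 2, dimnames = list(c("none", "pasta"),
                                        c("pasta", "rice")))
  tb1 <- sarsa_step(tb, c("none", "pasta"), 1, c("pasta", "rice"),
                    alpha = 0.5, gamma = 0)
  expect_equal(tb1["none", "pasta"], 0.5)
  tb2 <- sarsa_step(tb1, c("none", "pasta"), 1, c("pasta", "rice"),
                    alpha = 0.5, gamma = 0)
  expect_equal(tb2["none", "pasta"], 0.75)

  # zero rewards keep the table at the zero fixed point
  tb0 <- tb
  for (i in 1:20)
    tb0 <- sarsa_step(tb0, c("pasta", "rice"), 0, c("none", "pasta"),
                      alpha = 0.3, gamma = 0.9)
  expect_true(all(tb0 == 0))

  # constant reward on a single (s, a) loop converges to 1 / (1 - gamma)
  q <- matrix(0, 1, 1, dimnames = list("s", "a"))
  for (i in 1:200)
    q <- sarsa_step(q, c("s", "a"), 1, c("s", "a"), alpha = 0.5,
                    gamma = 0.9)
  expect_equal(q["s", "a"], 10, tolerance = 1e-3)
})

test_that("all policies only recommend offered tags", {
  prof <- fixture_profile(c(rice = 0.5, pasta = 0.4, potato = 0.3,
                            legume = 0.2, vegetables = 0.6, fish = 0.5,
                            egg = 0.3, fried = 0.2, fruit = 0.6,
                            dairy = 0.5, white_meat = 0.4, red_meat = 0.3))
  ctl <- fixture_catalog()
  for (mk in list(random_policy(), optimum_policy(prof), mab_policy(),
                  sarsa_policy(),
                  dqn_policy(config = policy_config(epochs = 1L)))) {
    set.seed(5)
    st <- history_state("fx1")
    pol <- mk
    for (m in 1:8) {
      menu <- sample_daily_menu(ctl, m)
      r <- policy_recommend(pol, st, menu)
      pol <- r$policy
      for (ci in 1:3)
        expect_true(r$tags[ci] %in%
                      menu[[c("first", "second", "dessert")[ci]]]$tag)
      sel <- simulate_selection(prof, menu)
      pol <- policy_observe(pol, st, menu, r$tags, sel)
      st <- advance_state(st, sel)
    }
  }
})
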