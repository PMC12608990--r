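# DQN internals: network gradients, replay training, schedules.

test_that("analytic gradients match numerical differentiation", {
  set.seed(1)
  par <- menusim:::qnet_init(6L, 4L, H = 5L, D = 4L)
  X <- lapply(1:3, function(t) matrix(stats::rnorm(2 * 6), 2, 6))
  A <- matrix(stats::rnorm(2 * 4), 2, 4)
  target <- c(0.7, -0.2)
  fw <- menusim:::qnet_forward(par, X, A, cache = TRUE)
  gr <- menusim:::qnet_backward(par, fw, target)
  loss <- function(p) {
    q <- menusim:::qnet_forward(p, X, A)
    mean((q - target)^2) / 2
  }
  eps <- 1e-6
  for (nm in c("W_lstm", "b_lstm", "W1", "b1", "W2", "b2")) {
    idx <- sample(length(par[[nm]]), min(8, length(par[[nm]])))
    for (i in idx) {
      p2 <- par
      p2[[nm]][i] <- p2[[nm]][i] + eps
      expect_equal(gr[[nm]][i], (loss(p2) - loss(par)) / eps,
                   tolerance = 1e-3)
    }
  }
})

test_that("batched Q evaluation equals one-at-a-time forwards", {
  set.seed(2)
  par <- menusim:::qnet_init(36L, 15L, H = 8L, D = 6L)
  states <- replicate(5, matrix(stats::rbinom(3 * 36, 1, 0.1), 3, 36),
                      simplify = FALSE)
  acts <- lapply(1:5, function(i)
    menusim:::encode_action(sample(1:3, 1), sample(menu_tags(), 1)))
  q_batch <- menusim:::qnet_batch_q(par, states, acts, 3L)
  q_single <- vapply(1:5, function(i)
    menusim:::qnet_batch_q(par, states[i], acts[i], 3L), numeric(1))
  expect_equal(q_batch, q_single, tolerance = 1e-12)
})

test_that("a freshly synced target network gives identical Q values", {
  set.seed(3)
  cfg <- policy_config(epochs = 2L, replay_sample_size = 4L,
                       target_update_every = 1L, start_day = 0L,
                       train_every = 3L)
  pol <- dqn_policy(config = cfg)
  ctl <- fixture_catalog()
  prof <- fixture_profile(c(rice = 0.8, pasta = 0.3, fruit = 0.6,
                            dairy = 0.4, fish = 0.5, legume = 0.4,
                            vegetables = 0.4, potato = 0.4, egg = 0.4,
                            fried = 0.3))
  st <- history_state("fx1")
  for (m in 1:5) {
    menu <- sample_daily_menu(ctl, m)
    r <- policy_recommend(pol, st, menu)
    sel <- simulate_selection(prof, menu)
    pol <- policy_observe(r$policy, st, menu, r$tags, sel)
    st <- advance_state(st, sel)
  }
  expect_gt(pol$trainings, 0L)
  # target was just synced (update interval 1): identical outputs
  expect_equal(pol$target_par[c("W_lstm", "W1", "W2")],
               pol$par[c("W_lstm", "W1", "W2")])
  s_enc <- menusim:::encode_state(st, 3L)
  a <- menusim:::encode_action(1L, "rice")
  expect_equal(menusim:::qnet_batch_q(pol$par, list(s_enc), list(a), 3L),
               menusim:::qnet_batch_q(pol$target_par, list(s_enc), list(a),
                                      3L))
})

test_that("discount zero reduces training targets to the stored rewards", {
  set.seed(4)
  par <- menusim:::qnet_init(36L, 15L, H = 6L, D = 4L)
  trans <- lapply(1:3, function(i) {
    list(s = matrix(0, 3, 36),
         a = menusim:::encode_action(i, c("rice", "fish", "fruit")[i]),
         r = c(1, -2, 3)[i],
         s2 = matrix(stats::rbinom(3 * 36, 1, 0.1), 3, 36),
         course = i)
  })
  cfg <- policy_config(gamma = 0, epochs = 1L)
  out <- dqn_train_step(par, par, trans, enumerate_actions(),
                        config = cfg)
  expect_equal(out$targets, c(1, -2, 3))
})

test_that("epsilon decays by 0.01 per training down to its floor", {
  set.seed(5)
  cfg <- policy_config(epochs = 1L, replay_sample_size = 2L,
                       train_every = 3L, start_day = 0L)
  pol <- dqn_policy(config = cfg)
  ctl <- fixture_catalog()
  prof <- fixture_profile(c(rice = 0.8, fruit = 0.6, dairy = 0.4,
                            fish = 0.5, pasta = 0.4, legume = 0.3,
                            vegetables = 0.5, potato = 0.4, egg = 0.4,
                            fried = 0.3))
  st <- history_state("fx1")
  m <- 0
  while (pol$trainings < 5L) {
    m <- m + 1
    menu <- sample_daily_menu(ctl, m)
    r <- policy_recommend(pol, st, menu)
    sel <- simulate_selection(prof, menu)
    pol <- policy_observe(r$policy, st, menu, r$tags, sel)
    st <- advance_state(st, sel)
  }
  expect_equal(pol$epsilon, 0.15 - 5 * 0.01)
  pol$epsilon <- 0.015
  pol <- menusim:::dqn_train(pol)
  expect_equal(pol$epsilon, 0.01) # floor
})

test_that("training is skipped while the replay memory is too small", {
  set.seed(6)
  cfg <- policy_config(replay_sample_size = 1000L, train_every = 1L,
                       start_day = 0L)
  pol <- dqn_policy(config = cfg)
  ctl <- fixture_catalog()
  prof <- fixture_profile(c(rice = 0.8, fruit = 0.6, dairy = 0.4,
                            fish = 0.5, pasta = 0.4, legume = 0.3,
                            vegetables = 0.5, potato = 0.4, egg = 0.4,
                            fried = 0.3))
  st <- history_state("fx1")
  for (m in 1:4) {
    menu <- sample_daily_menu(ctl, m)
    r <- policy_recommend(pol, st, menu)
    sel <- simulate_selection(prof, menu)
    pol <- policy_observe(r$policy, st, menu, r$tags, sel)
    st <- advance_state(st, sel)
  }
  expect_equal(pol$trainings, 0L)
  expect_equal(pol$grad_steps, 0L)
})

test_that("a fully exploring DQN recommends uniformly over options", {
  set.seed(7)
  pol <- dqn_policy(config = policy_config(epsilon = 1))
  menu <- fixture_menu(c("rice", "pasta", "potato"),
                       c("legume", "vegetables", "potato"),
                       c("fruit", "dairy"))
  st <- history_state("fx1")
  recs <- replicate(9000, policy_recommend(pol, st, menu)$tags[1])
  tab <- table(factor(recs, levels = c("rice", "pasta", "potato")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("network weights round-trip through the JSON checkpoint", {
  set.seed(8)
  par <- menusim:::qnet_init(36L, 15L, H = 4L, D = 3L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "qnet.json")
  write_qnet(par, path)
  back <- read_qnet(path)
  for (nm in c("W_lstm", "b_lstm", "W1", "b1", "W2", "b2"))
    expect_equal(back[[nm]], par[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  s <- matrix(stats::rbinom(3 * 36, 1, 0.2), 3, 36)
  a <- menusim:::encode_action(2L, "fish")
  expect_equal(menusim:::qnet_batch_q(back, list(s), list(a), 3L),
               menusim:::qnet_batch_q(par, list(s), list(a), 3L),
               tolerance = 1e-9)
})
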