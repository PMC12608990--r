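# Metric suite and pairwise statistics.

test_that("accumulated reward aggregates per-user totals", {
  log2 <- rbind(
    fixture_log(rep("rice", 6), c("rice", "rice", rep("x", 4)),
                user_id = "u1"),
    fixture_log(rep("rice", 6), c(rep("rice", 4), "x", "x"),
                user_id = "u2"))
  st <- accumulated_reward_stats(log2, "alg", "G")
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2))

  # single user: mean defined, sd flagged undefined
  l1 <- fixture_log(rep("rice", 9), rep("rice", 9))
  s1 <- accumulated_reward_stats(l1, "alg", "G")
  expect_equal(s1$mean, 9)
  expect_true(is.na(s1$sd))

  # no matches anywhere
  l0 <- fixture_log(rep("rice", 6), rep("fish", 6))
  expect_equal(accumulated_reward_stats(l0, "alg", "G")$mean, 0)
  expect_error(accumulated_reward_stats(l0, "other", "G"), "empty")
})

test_that("improvement is the relative gain over the random baseline", {
  expect_equal(improvement(150, 100), 50)
  expect_equal(improvement(100, 100), 0)
  expect_error(improvement(1, 0), "positive")
  # cross-row inversion of the published summary table: a baseline of
  # 401.16 reproduces both printed improvements on the same population
  base <- 617.44 / (1 + 53.91 / 100)
  expect_equal(base, 401.16, tolerance = 1e-4)
  expect_equal(improvement(655.74, base), 63.46, tolerance = 1e-3)
})

test_that("efficiency counts mean correct courses per day", {
  l <- fixture_log(rep("rice", 12), rep("rice", 12))
  expect_equal(efficiency(l, "alg", "G"), 3)
  l2 <- fixture_log(rep(c("rice", "a", "b"), 4),
                    rep(c("rice", "x", "y"), 4))
  expect_equal(efficiency(l2, "alg", "G"), 1)
  # warm-up exclusion drops early days
  l3 <- l2; l3$match[l3$day == 1] <- 1
  expect_equal(efficiency(l3, "alg", "G", warmup_days = 1),
               1)
})

test_that("classification metrics match a hand-computed confusion matrix", {
  perfect <- fixture_log(rep(c("rice", "fish", "fruit"), 4),
                         rep(c("rice", "fish", "fruit"), 4))
  cm <- classification_metrics(perfect, "alg", "G")
  expect_equal(unlist(cm), c(precision = 1, recall = 1, f1 = 1))

  never <- fixture_log(rep("rice", 6), rep("pasta", 6))
  cm0 <- classification_metrics(never, "alg", "G")
  expect_equal(unlist(cm0), c(precision = 0, recall = 0, f1 = 0))

  # 6 instances in one course with known counts:
  # pred a,a,a,b,b,b vs true a,a,b,b,b,a
  l <- fixture_log(c("a", "a", "a", "b", "b", "b"),
                   c("a", "a", "b", "b", "b", "a"),
                   course = rep(1, 6), day = 1:6)
  cm6 <- classification_metrics(l, "alg", "G")
  # per tag: a: P=2/3 R=2/3 F=2/3; b: P=2/3 R=2/3 F=2/3
  expect_equal(cm6$precision, 2 / 3)
  expect_equal(cm6$recall, 2 / 3)
  expect_equal(cm6$f1, 2 / 3)

  micro <- classification_metrics(l, "alg", "G", average = "micro")
  expect_equal(micro$f1, 4 / 6)
})

test_that("Cliff's delta agrees with an explicit double-loop oracle", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(2, 2), c(1, 1)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 2)), 0)
  expect_error(cliffs_delta(numeric(0), 1), "nonempty")

  oracle <- function(x, y) {
    gt <- 0; lt <- 0
    for (xi in x) for (yj in y) {
      if (xi > yj) gt <- gt + 1
      if (xi < yj) lt <- lt + 1
    }
    (gt - lt) / (length(x) * length(y))
  }
  set.seed(8)
  for (i in 1:20) {
    x <- sample(0:10, sample(2:30, 1), replace = TRUE)
    y <- sample(0:10, sample(2:30, 1), replace = TRUE)
    expect_equal(cliffs_delta(x, y), oracle(x, y))
  }
})

test_that("rank-sum p-values agree with exact enumeration for small n", {
  # enumeration oracle: distribution of the rank-sum statistic over all
  # C(n1 + n2, n1) assignments of the pooled sample (no ties)
  exact_p <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    combos <- utils::combn(length(pooled), length(x))
    ws <- apply(combos, 2, function(idx)
      sum(r[idx]) - length(x) * (length(x) + 1) / 2)
    mu <- length(x) * length(y) / 2
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  }
  set.seed(9)
  for (i in 1:10) {
    x <- stats::runif(sample(3:8, 1))
    y <- stats::runif(sample(3:8, 1))
    expect_equal(suppressWarnings(stats::wilcox.test(x, y)$p.value),
                 exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("pairwise matrices have the required structure", {
  set.seed(10)
  totals <- list(A = stats::rnorm(50, 10), B = stats::rnorm(50, 12),
                 C = stats::rnorm(50, 10.5))
  opt <- list(A = totals$A + stats::rlnorm(50), B = totals$B + 1,
              C = totals$C + stats::rlnorm(50, 1))
  pw <- pairwise_comparison(totals, opt)
  for (mode in c("absolute", "gap")) {
    p <- pw[[mode]]$p; d <- pw[[mode]]$delta
    expect_equal(diag(p), rep(1, 3), ignore_attr = TRUE)
    expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
    expect_equal(p, t(p))
    expect_equal(d, -t(d))
    expect_true(all(d >= -1 & d <= 1))
  }
  # swapping groups flips delta, keeps p
  pw2 <- pairwise_comparison(totals[c("B", "A", "C")])
  expect_equal(pw2$absolute$delta["A", "B"], -pw$absolute$delta["B", "A"])
  expect_equal(pw2$absolute$p["A", "B"], pw$absolute$p["A", "B"])

  # complete separation at n = 50: delta 1 and p far below 0.005
  sep <- list(hi = 101:150, lo = 1:50)
  ps <- pairwise_comparison(sep)
  expect_equal(ps$absolute$delta["hi", "lo"], 1)
  expect_lt(ps$absolute$p["hi", "lo"], 0.005)

  expect_error(pairwise_comparison(list(A = 1:5)), "two groups")
  expect_error(pairwise_comparison(list(A = 1:5, B = 2)), "fewer than 2")
})

test_that("the metrics table mirrors the summary-table structure", {
  log <- rbind(
    fixture_log(rep("rice", 6), rep(c("rice", "x", "rice"), 2),
                algorithm = "random"),
    fixture_log(rep(c("rice", "x", "y"), 2), rep(c("rice", "x", "rice"), 2),
                algorithm = "mab"))
  m <- metrics_table(log)
  expect_equal(nrow(m), 2L)
  expect_named(m, c("algorithm", "group", "accumulated_reward", "std_dev",
                    "improvement_pct", "efficiency", "f1", "recall",
                    "precision"))
  expect_equal(m$improvement_pct[m$algorithm == "random"], 0)
  expect_error(metrics_table(log[log$algorithm != "random", ]), "random")
})
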