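#' Accumulated-reward statistics
#'
#' Per-user totals of course-level matches summed over the horizon; returns
#' their mean and sample standard deviation (divisor n - 1; `NA` for a
#' single user) across the users of one algorithm-group cell.
#'
#' @param log Run log data frame with columns `algorithm`, `group`,
#'   `user_id`, `day`, `course`, `recommended_tag`, `selected_tag`, `match`.
#' @param algorithm,group Cell selectors.
#' @return `list(mean =, sd =, totals =)`.
#' @export
accumulated_reward_stats <- function(log, algorithm, group) {
  sub <- log[log$algorithm == algorithm & log$group == group, ]
  if (nrow(sub) == 0L) stop("empty run log for ", algorithm, "/", group)
  totals <- tapply(sub$match, sub$user_id, sum)
  list(mean = mean(totals),
       sd = if (length(totals) > 1L) stats::sd(totals) else NA_real_,
       totals = totals)
}

#' Improvement over the random baseline
#'
#' `100 * (reward_alg - reward_random) / reward_random`.
#'
#' @param reward_alg,reward_random Accumulated rewards (baseline must be
#'   positive).
#' @return Percent improvement.
#' @export
improvement <- function(reward_alg, reward_random) {
  if (!is.numeric(reward_random) || reward_random <= 0)
    stop("the random baseline reward must be positive")
  100 * (reward_alg - reward_random) / reward_random
}

#' Efficiency: mean correct recommendations per day
#'
#' Total matches divided by users x days, i.e. how many of the three daily
#' courses the recommender guessed right on average; bounded by `[0, 3]`.
#'
#' @inheritParams accumulated_reward_stats
#' @param warmup_days Days excluded from the start of the horizon (default
#'   0: the full horizon).
#' @return Scalar efficiency.
#' @export
efficiency <- function(log, algorithm, group, warmup_days = 0L) {
  sub <- log[log$algorithm == algorithm & log$group == group &
               log$day > warmup_days, ]
  if (nrow(sub) == 0L) stop("empty run log for ", algorithm, "/", group)
  n_users <- length(unique(sub$user_id))
  n_days <- length(unique(sub$day))
  sum(sub$match) / (n_users * n_days)
}

# Per-tag precision/recall/F1 within one course, macro-averaged.
macro_prf <- function(pred, true) {
  tags <- union(unique(pred), unique(true))
  per <- vapply(tags, function(tg) {
    tp <- sum(pred == tg & true == tg)
    np <- sum(pred == tg); nt <- sum(true == tg)
    p <- if (np > 0) tp / np else 0
    r <- if (nt > 0) tp / nt else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3))
  rowMeans(per)
}

#' Classification metrics of a recommendation log
#'
#' Treats the recommended tag as the predicted label and the selected tag as
#' the true label, one instance per user-day-course. Scores are
#' macro-averaged over tags within each course and then averaged over the
#' three courses (`average = "micro"` pools all instances and returns
#' overall accuracy-style scores instead).
#'
#' @inheritParams accumulated_reward_stats
#' @param average `"macro"` (default) or `"micro"`.
#' @return `list(precision =, recall =, f1 =)`, each in `[0, 1]`.
#' @export
classification_metrics <- function(log, algorithm, group,
                                   average = c("macro", "micro")) {
  average <- match.arg(average)
  sub <- log[log$algorithm == algorithm & log$group == group, ]
  if (nrow(sub) == 0L) stop("empty run log for ", algorithm, "/", group)
  if (average == "micro") {
    acc <- mean(sub$recommended_tag == sub$selected_tag)
    return(list(precision = acc, recall = acc, f1 = acc))
  }
  per_course <- vapply(sort(unique(sub$course)), function(ci) {
    s <- sub[sub$course == ci, ]
    macro_prf(s$recommended_tag, s$selected_tag)
  }, numeric(3))
  m <- rowMeans(per_course)
  list(precision = m[1], recall = m[2], f1 = m[3])
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`; positive when
#' `x` tends to exceed `y`.
#'
#' @param x,y Numeric samples (nonempty).
#' @return Scalar in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  d <- outer(x, y, `-`)
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Pairwise population comparison
#'
#' For every unordered pair of groups, a two-sided rank-sum (Mann-Whitney)
#' test and Cliff's delta on (a) per-user accumulated rewards and, when
#' oracle totals are supplied, (b) per-user gaps (oracle minus algorithm).
#' Deltas are antisymmetric, p values symmetric, diagonals (p = 1,
#' delta = 0).
#'
#' @param totals_by_group Named list of per-user accumulated-reward vectors
#'   (>= 2 groups, each >= 2 users).
#' @param optimum_by_group Optional named list of oracle totals aligned with
#'   `totals_by_group` (same users, same order).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return A list of class `pairwise_stats`: `absolute` (and `gap`) each
#'   holding matrices `p` and `delta`.
#' @export
pairwise_comparison <- function(totals_by_group, optimum_by_group = NULL,
                                test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  gs <- names(totals_by_group)
  if (length(gs) < 2L) stop("need at least two groups")
  for (g in gs) if (length(totals_by_group[[g]]) < 2L)
    stop("group '", g, "' has fewer than 2 users")
  one <- function(vals) {
    p <- matrix(1, length(gs), length(gs), dimnames = list(gs, gs))
    d <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i >= j) next
      x <- vals[[gs[i]]]; y <- vals[[gs[j]]]
      pv <- if (test == "wilcoxon") {
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
      } else {
        stats::t.test(x, y)$p.value
      }
      dl <- cliffs_delta(x, y)
      p[i, j] <- p[j, i] <- pv
      d[i, j] <- dl; d[j, i] <- -dl
    }
    list(p = p, delta = d)
  }
  out <- list(absolute = one(totals_by_group))
  if (!is.null(optimum_by_group)) {
    gaps <- lapply(gs, function(g)
      optimum_by_group[[g]] - totals_by_group[[g]])
    names(gaps) <- gs
    out$gap <- one(gaps)
  }
  structure(out, class = "pairwise_stats")
}

#' Metrics table for a benchmark run
#'
#' One row per (algorithm, group): accumulated-reward mean and standard
#' deviation over users, improvement over the same run's random policy,
#' efficiency, and macro F1/recall/precision.
#'
#' @param log Run log data frame (must include a `"random"` algorithm).
#' @param average Passed to [classification_metrics()].
#' @return Data frame shaped like the benchmark's summary table.
#' @export
metrics_table <- function(log, average = "macro") {
  algs <- unique(log$algorithm)
  groups <- unique(log$group)
  if (!"random" %in% algs)
    stop("the run log must contain the random baseline")
  rows <- list()
  for (g in groups) {
    base <- accumulated_reward_stats(log, "random", g)$mean
    for (a in algs) {
      st <- accumulated_reward_stats(log, a, g)
      cm <- classification_metrics(log, a, g, average)
      rows[[paste(a, g)]] <- data.frame(
        algorithm = a, group = g,
        accumulated_reward = st$mean, std_dev = st$sd,
        improvement_pct = improvement(st$mean, base),
        efficiency = efficiency(log, a, g),
        f1 = cm$f1, recall = cm$recall, precision = cm$precision,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(match(out$algorithm, algs), match(out$group, groups)), ]
}
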