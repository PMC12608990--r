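#' Benchmark configuration
#'
#' Bundles everything one benchmark run needs: the seed, the horizon, the
#' target groups, which policies compete, and the component configurations.
#' The random baseline is always required (improvement is measured against
#' it).
#'
#' @param seed Master seed (default 10).
#' @param n_days Simulated days (default 365).
#' @param groups Named list of [group_spec()]s (default the four shipped
#'   groups).
#' @param policies Character subset of
#'   `c("random", "optimum", "mab", "sarsa", "dqn")`.
#' @param policy_cfg A [policy_config()].
#' @param fuzzy_cfg A [fuzzy_config()].
#' @param catalog A [catalog_spec()].
#' @param shared_selections When `TRUE` (default) every policy is scored
#'   against the same selection stream per user-day; when `FALSE` each
#'   policy gets an independent selection draw.
#' @param menu_per_user When `TRUE` (default) each user receives their own
#'   daily menu draw (delivery-service framing); when `FALSE` all users of
#'   a group face the same daily menu (canteen framing).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 10L, n_days = 365L,
                              groups = default_groups(),
                              policies = c("random", "optimum", "mab",
                                           "sarsa", "dqn"),
                              policy_cfg = policy_config(),
                              fuzzy_cfg = fuzzy_config(),
                              catalog = catalog_spec(),
                              shared_selections = TRUE,
                              menu_per_user = TRUE) {
  policies <- match.arg(policies, c("random", "optimum", "mab", "sarsa",
                                    "dqn"), several.ok = TRUE)
  stopifnot(n_days >= 1L, length(groups) >= 1L)
  if (!"random" %in% policies)
    stop("the random baseline policy is always required")
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 groups = groups, policies = policies,
                 policy_cfg = policy_cfg, fuzzy_cfg = fuzzy_cfg,
                 catalog = catalog, shared_selections = shared_selections,
                 menu_per_user = menu_per_user),
            class = "experiment_config")
}

new_policy_instance <- function(name, profile, availability, cfg, fz) {
  switch(name,
         random = random_policy(),
         optimum = optimum_policy(profile, fz),
         mab = mab_policy(availability, epsilon = cfg$epsilon),
         sarsa = sarsa_policy(availability, alpha = cfg$sarsa_alpha,
                              gamma = cfg$gamma, epsilon = cfg$epsilon),
         dqn = dqn_policy(availability, cfg),
         stop("unknown policy '", name, "'"))
}

# Policies with learnable state kept per user; the DQN is shared per group.
per_user_policies <- function() c("random", "optimum", "mab", "sarsa")

#' Run the full benchmark
#'
#' For every group: generate the population, then for every day sample one
#' daily menu (all users of a group face the same canteen menu), let every
#' policy recommend one tag per course for every user, draw the user's
#' selection once (shared across policies by default), score matches, and
#' update every policy on its own schedule (MAB/SARSA daily and per user;
#' the shared DQN every `train_every` recommendations pooled over the
#' group's users).
#'
#' @param config An [experiment_config()].
#' @param progress Print per-group progress lines.
#' @return A list of class `benchmark_result`: `log` (one row per
#'   algorithm-user-day-course), `metrics` ([metrics_table()]), `pairwise`
#'   (per learned algorithm, [pairwise_comparison()] against the oracle
#'   gap when the oracle ran), `populations`, and a `manifest` recording
#'   seed, configuration and a content hash of the log.
#' @export
run_benchmark <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  catalog <- generate_catalog(config$catalog)
  av <- catalog$availability
  pols <- config$policies
  n_days <- config$n_days

  logs <- list()
  populations <- list()
  for (gname in names(config$groups)) {
    gspec <- config$groups[[gname]]
    pop <- generate_population(gspec, rule_base = default_rule_base(),
                               config = config$fuzzy_cfg,
                               id_prefix = paste0(substr(gname, 1, 2), "_"))
    populations[[gname]] <- pop
    n_users <- length(pop)

    user_pol <- lapply(pop, function(p) {
      ps <- lapply(intersect(pols, per_user_policies()), function(nm)
        new_policy_instance(nm, p, av, config$policy_cfg, config$fuzzy_cfg))
      names(ps) <- intersect(pols, per_user_policies())
      ps
    })
    shared_dqn <- if ("dqn" %in% pols)
      new_policy_instance("dqn", NULL, av, config$policy_cfg,
                          config$fuzzy_cfg)
    states <- lapply(pop, function(p)
      history_state(p$user_id, w = config$policy_cfg$window_days))

    n_rows <- length(pols) * n_users * n_days * 3L
    col_alg <- character(n_rows); col_user <- character(n_rows)
    col_day <- integer(n_rows); col_course <- integer(n_rows)
    col_rec <- character(n_rows); col_sel <- character(n_rows)
    k <- 0L

    for (m in seq_len(n_days)) {
      menu <- sample_daily_menu(catalog, m)
      for (ui in seq_len(n_users)) {
        if (config$menu_per_user && ui > 1L)
          menu <- sample_daily_menu(catalog, m)
        prof <- pop[[ui]]
        st <- states[[ui]]
        recs <- list()
        for (nm in pols) {
          if (nm == "dqn") {
            r <- policy_recommend(shared_dqn, st, menu)
            shared_dqn <- r$policy
          } else {
            r <- policy_recommend(user_pol[[ui]][[nm]], st, menu)
            user_pol[[ui]][[nm]] <- r$policy
          }
          recs[[nm]] <- r$tags
        }
        sel <- simulate_selection(prof, menu, config$fuzzy_cfg)
        for (nm in pols) {
          sel_nm <- if (config$shared_selections) sel else
            simulate_selection(prof, menu, config$fuzzy_cfg)
          if (nm == "dqn") {
            shared_dqn <- policy_observe(shared_dqn, st, menu, recs[[nm]],
                                         sel_nm)
          } else {
            user_pol[[ui]][[nm]] <- policy_observe(user_pol[[ui]][[nm]], st,
                                                   menu, recs[[nm]], sel_nm)
          }
          idx <- k + 1:3
          col_alg[idx] <- nm; col_user[idx] <- prof$user_id
          col_day[idx] <- m; col_course[idx] <- 1:3
          col_rec[idx] <- recs[[nm]]; col_sel[idx] <- sel_nm$tag
          k <- k + 3L
        }
        states[[ui]] <- advance_state(st, sel)
      }
    }
    logs[[gname]] <- data.frame(
      algorithm = col_alg, group = gname, user_id = col_user, day = col_day,
      course = col_course, recommended_tag = col_rec, selected_tag = col_sel,
      match = as.numeric(col_rec == col_sel), stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("group %s done (%d users x %d days)", gname, n_users,
                      n_days))
  }
  log <- do.call(rbind, c(logs, make.row.names = FALSE))

  metrics <- metrics_table(log)
  pairwise <- list()
  learned <- intersect(pols, c("mab", "sarsa", "dqn"))
  if (length(names(config$groups)) >= 2L) {
    for (nm in learned) {
      totals <- lapply(names(config$groups), function(g)
        as.numeric(accumulated_reward_stats(log, nm, g)$totals))
      names(totals) <- names(config$groups)
      opt <- if ("optimum" %in% pols) {
        o <- lapply(names(config$groups), function(g)
          as.numeric(accumulated_reward_stats(log, "optimum", g)$totals))
        names(o) <- names(config$groups)
        o
      }
      pairwise[[nm]] <- pairwise_comparison(totals, opt)
    }
  }
  manifest <- list(seed = config$seed, n_days = config$n_days,
                   groups = names(config$groups), policies = pols,
                   package_version =
                     as.character(utils::packageVersion("menusim")),
                   log_hash = content_hash(log))
  structure(list(log = log, metrics = metrics, pairwise = pairwise,
                 populations = populations, manifest = manifest),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", length(unique(x$log$group)), "groups,",
      length(unique(x$log$algorithm)), "policies,",
      max(x$log$day), "days (log hash", x$manifest$log_hash, ")\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

# Cumulative mean accumulated reward per day for trajectory plots.
reward_trajectories <- function(log, group) {
  sub <- log[log$group == group, ]
  daily <- stats::aggregate(match ~ algorithm + day + user_id, sub, sum)
  per_day <- stats::aggregate(match ~ algorithm + day, daily, mean)
  per_day <- per_day[order(per_day$algorithm, per_day$day), ]
  per_day$cumulative <- stats::ave(per_day$match, per_day$algorithm,
                                   FUN = cumsum)
  per_day
}

#' Write the report artifacts of a benchmark run
#'
#' Emits the metrics CSV, two pairwise matrices (p and delta) per
#' comparison mode and learned algorithm, per-group accumulated-reward and
#' rolling-accuracy plots, a ranked plain-text summary, and the JSON
#' manifest.
#'
#' @param result A `benchmark_result`.
#' @param out_dir Output directory (created if missing).
#' @param plot_device `"png"` or `"pdf"` (PNG falls back to PDF when no PNG
#'   device is available).
#' @return Invisibly, the paths written.
#' @export
report <- function(result, out_dir, plot_device = c("png", "pdf")) {
  stopifnot(inherits(result, "benchmark_result"))
  plot_device <- match.arg(plot_device)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }

  utils::write.csv(result$metrics, w(file.path(out_dir, "metrics.csv")),
                   row.names = FALSE)
  for (nm in names(result$pairwise)) {
    pw <- result$pairwise[[nm]]
    for (mode in names(pw)) {
      utils::write.csv(pw[[mode]]$p,
                       w(file.path(out_dir, sprintf("pairwise_%s_%s_p.csv",
                                                    nm, mode))))
      utils::write.csv(pw[[mode]]$delta,
                       w(file.path(out_dir,
                                   sprintf("pairwise_%s_%s_delta.csv",
                                           nm, mode))))
    }
  }

  dev_ok <- plot_device == "pdf" || capabilities("png")
  ext <- if (dev_ok && plot_device == "png") "png" else "pdf"
  for (g in unique(result$log$group)) {
    traj <- reward_trajectories(result$log, g)
    p1 <- ggplot2::ggplot(traj, ggplot2::aes(x = day,
                                             y = cumulative,
                                             colour = algorithm)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = paste("Accumulated reward -", g),
                    x = "day", y = "mean accumulated reward") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(w(file.path(out_dir, sprintf("reward_%s.%s", g, ext))),
                    p1, width = 7, height = 4.5, device = ext)
    traj$accuracy <- 100 * traj$cumulative / (3 * traj$day)
    p2 <- ggplot2::ggplot(traj, ggplot2::aes(x = day,
                                             y = accuracy,
                                             colour = algorithm)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = paste("Recommendation accuracy -", g),
                    x = "day", y = "% accurate recommendations") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(w(file.path(out_dir, sprintf("accuracy_%s.%s", g, ext))),
                    p2, width = 7, height = 4.5, device = ext)
  }

  summ <- character(0)
  for (g in unique(result$metrics$group)) {
    mg <- result$metrics[result$metrics$group == g, ]
    mg <- mg[order(-mg$accumulated_reward), ]
    summ <- c(summ, sprintf("Group %s - policies ranked by accumulated reward:",
                            g),
              sprintf("  %d. %-8s %8.2f (improvement %6.2f%%, efficiency %.2f)",
                      seq_len(nrow(mg)), mg$algorithm, mg$accumulated_reward,
                      mg$improvement_pct, mg$efficiency), "")
  }
  summ <- c(summ,
            "Selection notes: the oracle bound is not a deployable policy;",
            "among learners, the bandit is the most interpretable and",
            "cheapest to run, while the DQN handles richer state at a",
            "higher computational cost. Choose by balancing performance,",
            "interpretability and compute for the target population.")
  writeLines(summ, w(file.path(out_dir, "summary.txt")))
  jsonlite::write_json(result$manifest,
                       w(file.path(out_dir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Grid search over policy hyperparameters
#'
#' Exhaustively evaluates every configuration in the grid by running a
#' reduced benchmark `repetitions` times and averaging the target policy's
#' accumulated reward; returns the best configuration and the full results
#' table.
#'
#' @param grid Data frame whose columns are [policy_config()] argument names
#'   and whose rows are the configurations to try.
#' @param group A [group_spec()] for the evaluation population.
#' @param policy Which policy the grid tunes (default `"dqn"`).
#' @param n_days,repetitions Evaluation horizon and repeats per
#'   configuration.
#' @param seed Base seed; repetition r of configuration i runs with
#'   `seed + i * repetitions + r`.
#' @param base_config Baseline [policy_config()] the grid rows override.
#' @return `list(best =, results =)`: the winning `policy_config` and a data
#'   frame of mean rewards per configuration.
#' @export
grid_search <- function(grid, group, policy = "dqn", n_days = 120L,
                        repetitions = 3L, seed = 10L,
                        base_config = policy_config()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  unknown <- setdiff(names(grid), names(formals(policy_config)))
  if (length(unknown))
    stop("unknown policy_config fields: ", paste(unknown, collapse = ", "))
  means <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- utils::modifyList(unclass(base_config),
                              as.list(grid[i, , drop = FALSE]))
    cfg_i <- do.call(policy_config, args[names(formals(policy_config))])
    rewards <- vapply(seq_len(repetitions), function(r) {
      ec <- experiment_config(seed = seed + i * repetitions + r,
                              n_days = n_days,
                              groups = stats::setNames(list(group),
                                                       group$name),
                              policies = unique(c("random", policy)),
                              policy_cfg = cfg_i)
      res <- run_benchmark(ec)
      accumulated_reward_stats(res$log, policy, group$name)$mean
    }, numeric(1))
    means[i] <- mean(rewards)
  }
  results <- cbind(grid, mean_accumulated_reward = means)
  best_args <- utils::modifyList(unclass(base_config),
                                 as.list(grid[which.max(means), ,
                                              drop = FALSE]))
  list(best = do.call(policy_config,
                      best_args[names(formals(policy_config))]),
       results = results)
}
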