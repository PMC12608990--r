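#' Policy hyperparameters
#'
#' Defaults follow the benchmark configuration: epsilon 0.15 for all
#' learners, with the DQN's epsilon decaying by 0.01 after each training
#' down to a floor of 0.01; a 3-day history window; 32 LSTM units and a
#' 16-unit ReLU layer before the scalar Q output; Adam with learning rate
#' 0.0005; training every 20 recommendations on a replay sample of 20
#' transitions, starting after a 20-day burn-in; target-network sync every 3
#' trainings; and a cap of 15000 gradient steps.
#'
#' @param epsilon Initial exploration probability.
#' @param epsilon_decay,epsilon_min Per-training decay and floor of the
#'   DQN's epsilon.
#' @param sarsa_alpha SARSA learning rate.
#' @param gamma Discount factor (shared by SARSA and the DQN).
#' @param window_days DQN history window d.
#' @param lstm_neurons,hidden_neurons LSTM and dense-layer widths.
#' @param learning_rate Adam learning rate.
#' @param lr_decay Multiplicative learning-rate decay applied after each
#'   training (1 = constant).
#' @param train_every Recommendations between DQN trainings.
#' @param start_day First day on which the DQN may train.
#' @param replay_sample_size Transitions sampled per training.
#' @param epochs Gradient steps per training on the sampled batch.
#' @param target_update_every Trainings between target-network syncs.
#' @param positive_reward,negative_reward Training reward for a match /
#'   mismatch (evaluation always scores 1/0).
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param dropout_rate Inverted-dropout rate on the dense hidden layer
#'   during training.
#' @param max_train_steps Cap on total gradient steps.
#' @return A list of class `policy_config`.
#' @export
policy_config <- function(epsilon = 0.15, epsilon_decay = 0.01,
                          epsilon_min = 0.01, sarsa_alpha = 0.1,
                          gamma = 0.9, window_days = 3L,
                          lstm_neurons = 32L, hidden_neurons = 16L,
                          learning_rate = 5e-4, lr_decay = 1,
                          train_every = 20L, start_day = 20L,
                          replay_sample_size = 30L, epochs = 30L,
                          target_update_every = 3L,
                          positive_reward = 3, negative_reward = -2,
                          adam_beta1 = 0.9, adam_beta2 = 0.999,
                          dropout_rate = 0, max_train_steps = 15000L,
                          bootstrap_scope = c("course", "all")) {
  bootstrap_scope <- match.arg(bootstrap_scope)
  stopifnot(epsilon >= 0, epsilon <= 1, gamma >= 0, gamma <= 1,
            sarsa_alpha > 0, sarsa_alpha <= 1, window_days >= 1,
            train_every >= 1, replay_sample_size >= 1, epochs >= 1,
            target_update_every >= 1, dropout_rate >= 0, dropout_rate < 1,
            positive_reward > negative_reward)
  structure(as.list(environment()), class = "policy_config")
}

# One-hot encoding of a day of selections: 3 course slots x 12 tags.
encode_day <- function(tags = NULL) {
  v <- numeric(3L * 12L)
  if (!is.null(tags)) {
    all_tags <- menu_tags()
    for (ci in 1:3) {
      j <- match(tags[ci], all_tags)
      if (!is.na(j)) v[(ci - 1L) * 12L + j] <- 1
    }
  }
  v
}

# Window of the last d days as a d x 36 matrix, zero-padded on the left
# (days before the first observation encode as the reserved all-zero "none"
# day).
encode_state <- function(state, d) {
  win <- state$window
  n <- length(win)
  keep <- if (n >= d) win[(n - d + 1L):n] else win
  rows <- c(replicate(d - length(keep), encode_day(), simplify = FALSE),
            lapply(keep, encode_day))
  do.call(rbind, rows)
}

# One-hot course (3) (+) one-hot tag (12).
encode_action <- function(course, tag) {
  v <- numeric(3L + 12L)
  v[course] <- 1
  v[3L + match(tag, menu_tags())] <- 1
  v
}

# Q values of the online (or target) network for a batch of
# (state matrix, action vector) pairs. states: list of d x 36 matrices.
qnet_batch_q <- function(par, states, actions, d) {
  n <- length(states)
  X <- lapply(seq_len(d), function(t)
    do.call(rbind, lapply(states, function(s) s[t, ])))
  A <- do.call(rbind, actions)
  qnet_forward(par, X, A)
}

#' Deep Q-network recommender
#'
#' Encodes the user's last `window_days` selected-tag triples with an LSTM,
#' concatenates the encoding with a candidate (course, tag) action, and
#' scores it with a dense head; per course the offered tag with the highest
#' Q value is recommended (or a random option with probability epsilon).
#' Observed transitions go to a replay memory; every `train_every`
#' recommendations (after the burn-in day) the online network is regressed
#' towards `r + gamma * max Q_target(s', a')` on a random replay sample,
#' epsilon decays, and the target network is synced every
#' `target_update_every` trainings.
#'
#' @param availability Course-tag availability map.
#' @param config A [policy_config()].
#' @return A policy object.
#' @export
dqn_policy <- function(availability = course_tag_map(),
                       config = policy_config()) {
  par <- qnet_init(36L, 15L, H = config$lstm_neurons,
                   D = config$hidden_neurons)
  actions <- enumerate_actions(list(availability = availability))
  structure(list(par = par, target_par = par, opt = adam_init(par),
                 config = config, epsilon = config$epsilon,
                 lr = config$learning_rate,
                 actions = actions,
                 mem = vector("list", 1024L), mem_n = 0L,
                 recs_since_train = 0L, trainings = 0L, grad_steps = 0L),
            class = c("dqn_policy", "policy"))
}

#' @export
policy_recommend.dqn_policy <- function(policy, state, menu) {
  d <- policy$config$window_days
  s_enc <- encode_state(state, d)
  tags <- character(3L)
  for (ci in seq_along(course_names())) {
    opts <- menu[[course_names()[ci]]]
    if (stats::runif(1L) < policy$epsilon) {
      tags[ci] <- opts$tag[sample.int(nrow(opts), 1L)]
      next
    }
    offered <- sort(unique(opts$tag))
    acts <- lapply(offered, function(tg) encode_action(ci, tg))
    q <- qnet_batch_q(policy$par, rep(list(s_enc), length(offered)), acts, d)
    tags[ci] <- offered[order(-q, offered)][1L]
  }
  list(tags = tags, policy = policy)
}

#' @export
policy_observe.dqn_policy <- function(policy, state, menu, recommended,
                                      selected) {
  cfg <- policy$config
  d <- cfg$window_days
  s_enc <- encode_state(state, d)
  next_state <- advance_state(state, selected)
  s2_enc <- encode_state(next_state, d)
  reward <- compute_reward(recommended, selected)
  for (ci in seq_along(course_names())) {
    r_train <- if (reward[[ci]] == 1) cfg$positive_reward else
      cfg$negative_reward
    tr <- list(s = s_enc, a = encode_action(ci, recommended[ci]),
               r = r_train, s2 = s2_enc, course = ci)
    if (policy$mem_n == length(policy$mem))
      policy$mem <- c(policy$mem, vector("list", length(policy$mem)))
    policy$mem_n <- policy$mem_n + 1L
    policy$mem[[policy$mem_n]] <- tr
  }
  policy$recs_since_train <- policy$recs_since_train + 3L
  if (next_state$day > cfg$start_day &&
      policy$recs_since_train >= cfg$train_every &&
      policy$mem_n >= cfg$replay_sample_size &&
      policy$grad_steps < cfg$max_train_steps) {
    policy <- dqn_train(policy)
    policy$recs_since_train <- 0L
  }
  policy
}

# One training event: `epochs` Adam steps on one replay sample, then
# epsilon decay, learning-rate decay and periodic target sync.
dqn_train <- function(policy) {
  cfg <- policy$config
  d <- cfg$window_days
  idx <- sample.int(policy$mem_n, cfg$replay_sample_size)
  batch <- policy$mem[idx]
  n <- length(batch)
  # bootstrap targets from the target network over the full action space
  all_acts <- lapply(seq_len(nrow(policy$actions)), function(i)
    encode_action(policy$actions$course[i], policy$actions$tag[i]))
  k <- length(all_acts)
  s2_rep <- rep(lapply(batch, `[[`, "s2"), each = k)
  a_rep <- rep(all_acts, times = n)
  q2 <- matrix(qnet_batch_q(policy$target_par, s2_rep, a_rep, d), nrow = k)
  # the successor decision for a course-c transition chooses among course-c
  # actions, so the bootstrap max is taken within that course
  vmax <- vapply(seq_len(n), function(i) {
    ci <- batch[[i]]$course
    rows <- if (is.null(ci) || cfg$bootstrap_scope == "all") seq_len(k) else
      which(policy$actions$course == ci)
    max(q2[rows, i])
  }, numeric(1))
  target <- vapply(batch, `[[`, numeric(1), "r") + cfg$gamma * vmax
  X <- lapply(seq_len(d), function(t)
    do.call(rbind, lapply(batch, function(b) b$s[t, ])))
  A <- do.call(rbind, lapply(batch, `[[`, "a"))
  for (e in seq_len(cfg$epochs)) {
    mask <- if (cfg$dropout_rate > 0) {
      matrix(stats::rbinom(n * policy$par$dims$D, 1L,
                           1 - cfg$dropout_rate) / (1 - cfg$dropout_rate),
             n, policy$par$dims$D)
    } else NULL
    fw <- qnet_forward(policy$par, X, A, cache = TRUE, drop_mask = mask)
    gr <- qnet_backward(policy$par, fw, target, drop_mask = mask)
    st <- adam_step(policy$par, gr, policy$opt, policy$lr,
                    cfg$adam_beta1, cfg$adam_beta2)
    policy$par <- utils::modifyList(policy$par, st$par[names(policy$opt$m)])
    policy$opt <- st$opt
    policy$grad_steps <- policy$grad_steps + 1L
    if (policy$grad_steps >= cfg$max_train_steps) break
  }
  policy$trainings <- policy$trainings + 1L
  policy$epsilon <- max(policy$epsilon - cfg$epsilon_decay, cfg$epsilon_min)
  policy$lr <- policy$lr * cfg$lr_decay
  if (policy$trainings %% cfg$target_update_every == 0L)
    policy$target_par <- policy$par
  policy
}

#' One DQN training pass on an explicit replay sample
#'
#' Exposed for testing and inspection: regresses the online network towards
#' `r + gamma * max Q_target(s', a')` over the given transitions.
#'
#' @param par,target_par Online and target network parameter lists.
#' @param transitions List of transitions `list(s, a, r, s2)` with encoded
#'   states/actions.
#' @param actions Action data frame from [enumerate_actions()].
#' @param config A [policy_config()].
#' @param opt Adam state (default fresh).
#' @return `list(par =, opt =, targets =)` after `config$epochs` steps.
#' @export
dqn_train_step <- function(par, target_par, transitions, actions,
                           config = policy_config(),
                           opt = adam_init(par)) {
  d <- config$window_days
  n <- length(transitions)
  if (n < 1L) stop("empty transition sample")
  all_acts <- lapply(seq_len(nrow(actions)), function(i)
    encode_action(actions$course[i], actions$tag[i]))
  k <- length(all_acts)
  q2 <- qnet_batch_q(target_par, rep(lapply(transitions, `[[`, "s2"),
                                     each = k),
                     rep(all_acts, times = n), d)
  vmax <- apply(matrix(q2, nrow = k), 2L, max)
  target <- vapply(transitions, `[[`, numeric(1), "r") + config$gamma * vmax
  X <- lapply(seq_len(d), function(t)
    do.call(rbind, lapply(transitions, function(b) b$s[t, ])))
  A <- do.call(rbind, lapply(transitions, `[[`, "a"))
  for (e in seq_len(config$epochs)) {
    fw <- qnet_forward(par, X, A, cache = TRUE)
    gr <- qnet_backward(par, fw, target)
    st <- adam_step(par, gr, opt, config$learning_rate,
                    config$adam_beta1, config$adam_beta2)
    par <- utils::modifyList(par, st$par[names(opt$m)])
    opt <- st$opt
  }
  list(par = par, opt = opt, targets = target)
}

#' Serialize / restore DQN network weights
#'
#' Weights are written as plain JSON (portable, text-only) together with the
#' layer dimensions.
#'
#' @param par Network parameter list.
#' @param path Output JSON path.
#' @return `path` (write) or a parameter list (read).
#' @export
write_qnet <- function(par, path) {
  flat <- lapply(par[c("W_lstm", "b_lstm", "W1", "b1", "W2", "b2")],
                 function(p) list(dim = dim(p), data = as.numeric(p)))
  jsonlite::write_json(list(weights = flat, dims = par$dims), path,
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_qnet
#' @export
read_qnet <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(doc$weights, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) == 2L) dim(v) <- p$dim
    v
  })
  par$dims <- as.list(doc$dims)
  par
}
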