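#' Recommendation policy contract
#'
#' Every recommender implements two generics. [policy_recommend()] produces
#' one tag per course for the day's menu given the user's history state and
#' may update internal bookkeeping (exploration draws, pending on-policy
#' updates), so it returns both the tags and the policy.
#' [policy_observe()] feeds the observed user selection back to the policy
#' after the day is over and returns the updated policy.
#'
#' @param policy A policy object.
#' @param state The user's [history_state()] *before* the day's selections.
#' @param menu The day's `menu_day`.
#' @param recommended Character vector of the 3 tags the policy recommended.
#' @param selected Selection data frame from [simulate_selection()].
#' @return `policy_recommend()`: `list(tags =, policy =)`;
#'   `policy_observe()`: the updated policy.
#' @name policy-contract
NULL

#' @rdname policy-contract
#' @export
policy_recommend <- function(policy, state, menu) {
  UseMethod("policy_recommend")
}

#' @rdname policy-contract
#' @export
policy_observe <- function(policy, state, menu, recommended, selected) {
  UseMethod("policy_observe")
}

#' @export
policy_observe.default <- function(policy, state, menu, recommended,
                                   selected) {
  policy
}

course_names <- function() c("first", "second", "dessert")

# ---- random baseline --------------------------------------------------------

#' Uniform-random recommender
#'
#' Recommends, per course, the tag of one option drawn uniformly from the
#' day's options, ignoring all history. Its expected daily reward against
#' any user under 3/3/2 menus is 1/3 + 1/3 + 1/2 = 7/6.
#'
#' @return A policy object.
#' @export
random_policy <- function() structure(list(), class = c("random_policy",
                                                        "policy"))

#' @rdname random_policy
#' @param menu A `menu_day`.
#' @export
random_recommend <- function(menu) {
  vapply(course_names(), function(crs) {
    opts <- menu[[crs]]
    opts$tag[sample.int(nrow(opts), 1L)]
  }, character(1))
}

#' @export
policy_recommend.random_policy <- function(policy, state, menu) {
  list(tags = random_recommend(menu), policy = policy)
}

# ---- optimum oracle ---------------------------------------------------------

#' Preference-oracle recommender
#'
#' Recommends, per course, the offered option with the maximal effective
#' selection weight (true taste times the innovation multiplier). This is
#' the upper bound on achievable accumulated reward; since selections are
#' sampled from the same weights, even the oracle does not match every
#' choice. Deterministic; weight ties are broken by alphabetical tag order.
#'
#' @param profile The `user_profile` whose true preferences the oracle sees.
#' @param config A [fuzzy_config()].
#' @return A policy object.
#' @export
optimum_policy <- function(profile, config = fuzzy_config()) {
  structure(list(profile = profile, config = config),
            class = c("optimum_policy", "policy"))
}

#' @rdname optimum_policy
#' @param menu A `menu_day`.
#' @export
optimum_recommend <- function(profile, menu, config = fuzzy_config()) {
  vapply(course_names(), function(crs) {
    opts <- menu[[crs]]
    w <- selection_weights(profile, opts, config)
    ord <- order(-w, opts$tag)
    opts$tag[ord[1L]]
  }, character(1))
}

#' @export
policy_recommend.optimum_policy <- function(policy, state, menu) {
  list(tags = optimum_recommend(policy$profile, menu, policy$config),
       policy = policy)
}

# ---- epsilon-greedy multi-armed bandit --------------------------------------

#' Epsilon-greedy multi-armed bandit recommender
#'
#' Each day the bandit recommends, per course, the offered tag with the
#' highest learned propensity p_i, or a uniformly random option with
#' probability `epsilon`; it is updated daily. Two update rules are
#' available:
#'
#' * `"match_feedback"` (default): p_i is the match rate of the bandit's
#'   own recommendations of tag i — a match increases p_i, a miss decreases
#'   it. The bandit only learns about arms it has played.
#' * `"selection_frequency"`: p_i is the empirical frequency with which the
#'   user selected tag i over observed days (k selections in n days give
#'   p_i = k/n), regardless of what was recommended.
#'
#' @param availability Course-tag availability map ([course_tag_map()]).
#' @param epsilon Exploration probability (default 0.15).
#' @param update Update rule, see above.
#' @return A policy object.
#' @export
mab_policy <- function(availability = course_tag_map(), epsilon = 0.15,
                       update = c("match_feedback", "selection_frequency")) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  update <- match.arg(update)
  zero <- lapply(availability, function(tags)
    stats::setNames(numeric(length(tags)), sort(tags)))
  names(zero) <- course_names()
  structure(list(counts = zero, trials = zero, n_days = 0L,
                 epsilon = epsilon, update = update),
            class = c("mab_policy", "policy"))
}

#' @export
policy_recommend.mab_policy <- function(policy, state, menu) {
  p_all <- mab_propensities(policy)
  tags <- vapply(seq_along(course_names()), function(ci) {
    opts <- menu[[course_names()[ci]]]
    if (stats::runif(1L) < policy$epsilon)
      return(opts$tag[sample.int(nrow(opts), 1L)])
    offered <- sort(unique(opts$tag))
    offered[order(-p_all[[ci]][offered], offered)][1L]
  }, character(1))
  list(tags = tags, policy = policy)
}

#' @export
policy_observe.mab_policy <- function(policy, state, menu, recommended,
                                      selected) {
  for (ci in seq_along(course_names())) {
    tg_sel <- selected$tag[selected$course == ci]
    if (policy$update == "match_feedback") {
      tg_rec <- recommended[ci]
      policy$trials[[ci]][tg_rec] <- policy$trials[[ci]][tg_rec] + 1
      if (identical(tg_rec, tg_sel))
        policy$counts[[ci]][tg_rec] <- policy$counts[[ci]][tg_rec] + 1
    } else {
      policy$counts[[ci]][tg_sel] <- policy$counts[[ci]][tg_sel] + 1
    }
  }
  policy$n_days <- policy$n_days + 1L
  policy
}

# Learned propensities: own-recommendation match rates (match_feedback;
# untried arms score 0) or selection frequencies k / n days.
mab_propensities <- function(policy) {
  if (policy$update == "match_feedback") {
    mapply(function(k, n) ifelse(n > 0, k / n, 0), policy$counts,
           policy$trials, SIMPLIFY = FALSE)
  } else if (policy$n_days == 0L) {
    policy$counts
  } else {
    lapply(policy$counts, function(k) k / policy$n_days)
  }
}

# ---- tabular SARSA ----------------------------------------------------------

#' One SARSA temporal-difference update
#'
#' `Q(s, a) <- Q(s, a) + alpha * (r + gamma * Q(s', a') - Q(s, a))`.
#'
#' @param table Numeric Q matrix (states x actions, dimnames required).
#' @param prev `c(state, action)` labels of the updated entry.
#' @param reward Observed reward.
#' @param nxt `c(state, action)` labels of the successor pair.
#' @param alpha Learning rate in (0, 1].
#' @param gamma Discount factor in \[0, 1\].
#' @return The updated table.
#' @export
sarsa_step <- function(table, prev, reward, nxt, alpha, gamma) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma <= 1)
  td <- reward + gamma * table[nxt[1L], nxt[2L]] - table[prev[1L], prev[2L]]
  table[prev[1L], prev[2L]] <- table[prev[1L], prev[2L]] + alpha * td
  table
}

#' Tabular SARSA recommender
#'
#' Per course, the state is the tag the user last selected for that course
#' and the action is the recommended tag; the Q table (last-selected tag by
#' candidate tag) is updated on-policy once per day with the standard SARSA
#' rule, using the epsilon-greedy action chosen for the following day.
#'
#' @param availability Course-tag availability map.
#' @param alpha Learning rate (default 0.1).
#' @param gamma Discount factor (default 0.9).
#' @param epsilon Exploration probability (default 0.15).
#' @return A policy object.
#' @export
sarsa_policy <- function(availability = course_tag_map(), alpha = 0.1,
                         gamma = 0.9, epsilon = 0.15) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma <= 1,
            epsilon >= 0, epsilon <= 1)
  tables <- lapply(availability, function(tags) {
    tags <- sort(tags)
    matrix(0, length(tags) + 1L, length(tags),
           dimnames = list(c("none", tags), tags))
  })
  names(tables) <- course_names()
  structure(list(tables = tables,
                 last_sel = stats::setNames(rep("none", 3L), course_names()),
                 pending = vector("list", 3L),
                 alpha = alpha, gamma = gamma, epsilon = epsilon),
            class = c("sarsa_policy", "policy"))
}

#' @export
policy_recommend.sarsa_policy <- function(policy, state, menu) {
  tags <- character(3L)
  for (ci in seq_along(course_names())) {
    opts <- menu[[course_names()[ci]]]
    s_now <- policy$last_sel[[ci]]
    offered <- sort(unique(opts$tag))
    a_now <- if (stats::runif(1L) < policy$epsilon) {
      opts$tag[sample.int(nrow(opts), 1L)]
    } else {
      qrow <- policy$tables[[ci]][s_now, offered]
      offered[order(-qrow, offered)][1L]
    }
    pend <- policy$pending[[ci]]
    if (!is.null(pend))
      policy$tables[[ci]] <- sarsa_step(policy$tables[[ci]],
                                        c(pend$s, pend$a), pend$r,
                                        c(s_now, a_now),
                                        policy$alpha, policy$gamma)
    policy$pending[[ci]] <- list(s = s_now, a = a_now, r = NA_real_)
    tags[ci] <- a_now
  }
  list(tags = tags, policy = policy)
}

#' @export
policy_observe.sarsa_policy <- function(policy, state, menu, recommended,
                                        selected, ...) {
  reward <- compute_reward(recommended, selected)
  for (ci in seq_along(course_names())) {
    if (!is.null(policy$pending[[ci]]))
      policy$pending[[ci]]$r <- reward[[ci]]
    policy$last_sel[[ci]] <- selected$tag[selected$course == ci]
  }
  policy
}
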