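#' Effective selection weights of a profile over menu options
#'
#' The weight of an option is the user's taste for its tag, multiplied by
#' `(innovation_multiplier_base + innovation)` when the dish is flagged
#' innovative. Weights are renormalized per course at selection time.
#'
#' @param profile A `user_profile`.
#' @param options Data frame of dish options (one course of a `menu_day`).
#' @param config A [fuzzy_config()] (supplies the multiplier base).
#' @return Numeric weights, one per option row.
#' @export
selection_weights <- function(profile, options, config = fuzzy_config()) {
  w <- unname(profile$tastes[options$tag])
  mult <- ifelse(options$innovative,
                 config$innovation_multiplier_base + profile$innovation, 1)
  w * mult
}

#' Simulate one day of user selections
#'
#' For each course the user picks one option with probability proportional
#' to the effective selection weights. If every weight is zero the choice is
#' uniform among diet-permitted options (options whose tag the diet does not
#' forbid); a course without any diet-permitted option raises an
#' infeasibility error (impossible under the menu's vegetarian guarantee).
#'
#' @param profile A `user_profile`.
#' @param menu A `menu_day`.
#' @param config A [fuzzy_config()].
#' @return Data frame with one row per course: `course` (1, 2, 3),
#'   `course_name`, `dish_id`, `tag`.
#' @export
simulate_selection <- function(profile, menu, config = fuzzy_config()) {
  courses <- c("first", "second", "dessert")
  rows <- lapply(seq_along(courses), function(ci) {
    opts <- menu[[courses[ci]]]
    w <- selection_weights(profile, opts, config)
    if (sum(w) <= 0) {
      ok <- !(opts$tag %in% diet_forbidden_tags(profile$diet))
      if (!any(ok))
        stop("no diet-permitted ", courses[ci], " option for user ",
             profile$user_id, " (diet ", profile$diet, ")")
      w <- as.numeric(ok)
    }
    pick <- sample.int(nrow(opts), 1L, prob = w)
    data.frame(course = ci, course_name = courses[ci],
               dish_id = opts$dish_id[pick], tag = opts$tag[pick],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-course match rewards
#'
#' Reward 1 when the recommended tag equals the tag of the dish the user
#' selected for that course, else 0 (the evaluation scale; policy training
#' may rescale internally).
#'
#' @param recommended Character vector of 3 recommended tags (first, second,
#'   dessert).
#' @param selected Selection data frame from [simulate_selection()], or a
#'   character vector of 3 selected tags.
#' @return Named numeric vector `c(first =, second =, dessert =)` of 0/1;
#'   the daily sum lies in 0..3.
#' @export
compute_reward <- function(recommended, selected) {
  sel_tags <- if (is.data.frame(selected)) selected$tag else selected
  stopifnot(length(recommended) == 3L, length(sel_tags) == 3L)
  stats::setNames(as.numeric(recommended == sel_tags),
                  c("first", "second", "dessert"))
}

#' History state of a user
#'
#' The MDP state: the user's selected tags (one triple per day) over a
#' sliding window of the last `w` days.
#'
#' @param user_id User identifier.
#' @param w Window length in days.
#' @return A list of class `history_state` with an empty window at day 0.
#' @export
history_state <- function(user_id, w = 3L) {
  structure(list(user_id = user_id, w = as.integer(w), window = list(),
                 day = 0L), class = "history_state")
}

#' Append a day of selections to a history state
#'
#' Appends the day's selected-tag triple, drops entries older than the
#' window, and increments the day counter.
#'
#' @param state A [history_state()].
#' @param selections Selection data frame or character vector of 3 tags.
#' @return The advanced `history_state`.
#' @export
advance_state <- function(state, selections) {
  tags <- if (is.data.frame(selections)) selections$tag else selections
  stopifnot(inherits(state, "history_state"), length(tags) == 3L)
  state$window <- c(state$window, list(as.character(tags)))
  if (length(state$window) > state$w)
    state$window <- state$window[(length(state$window) - state$w + 1L):
                                   length(state$window)]
  state$day <- state$day + 1L
  state
}
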