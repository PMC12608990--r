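# Shared fixtures built in code. The rule base parse is memoised by the
# package; catalogs and small profiles are cheap to rebuild per file.

fixture_catalog <- function(seed = 1) {
  withr::with_seed(seed, generate_catalog())
}

# A profile with hand-set tastes, bypassing inference (for environment and
# policy tests where the ground truth must be exact).
fixture_profile <- function(tastes, diet = "omnivore", innovation = 0.5,
                            id = "fx1") {
  full <- stats::setNames(rep(0, 12), menu_tags())
  full[names(tastes)] <- tastes
  structure(list(user_id = id, diet = diet, tastes = full,
                 innovation = innovation,
                 attributes = user_attributes(40, "female", "coastal",
                                              "medium")),
            class = "user_profile")
}

# Deterministic menu from explicit dish rows.
fixture_menu <- function(first_tags, second_tags, dessert_tags,
                         innovative = FALSE) {
  mk <- function(tags, course) {
    data.frame(dish_id = paste0(substr(course, 1, 1), seq_along(tags)),
               name = tags, course = course, tag = tags,
               innovative = rep_len(innovative, length(tags)),
               vegetarian = TRUE,
               vegan = tags %in% menusim:::plant_tags(),
               stringsAsFactors = FALSE)
  }
  structure(list(day = 1L, first = mk(first_tags, "first"),
                 second = mk(second_tags, "second"),
                 dessert = mk(dessert_tags, "dessert")),
            class = "menu_day")
}

# Minimal run-log builder for evaluation tests.
fixture_log <- function(rec, sel, algorithm = "alg", group = "G",
                        user_id = "u1", day = NULL, course = NULL) {
  n <- length(rec)
  if (is.null(day)) day <- rep(seq_len(ceiling(n / 3)), each = 3)[1:n]
  if (is.null(course)) course <- rep_len(1:3, n)
  data.frame(algorithm = algorithm, group = group, user_id = user_id,
             day = day, course = course, recommended_tag = rec,
             selected_tag = sel, match = as.numeric(rec == sel),
             stringsAsFactors = FALSE)
}
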