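#' The 12 dish category tags
#'
#' Tags serve both as preference coordinates of a user profile and as
#' recommendation targets.
#'
#' @return Character vector of the 12 tags.
#' @export
menu_tags <- function() {
  c("rice", "pasta", "potato", "legume", "vegetables",
    "white_meat", "red_meat", "fish", "fried", "egg", "dairy", "fruit")
}

# Tags forbidden (zeroed) per diet class; flexitarian meat tags are damped,
# not zeroed.
diet_forbidden_tags <- function(diet) {
  switch(diet,
         vegan      = c("white_meat", "red_meat", "fish", "egg", "dairy"),
         vegetarian = c("white_meat", "red_meat", "fish"),
         character(0))
}

#' Tunable parameters of the fuzzy profile generator
#'
#' @param sigma_taste Standard deviation of the symmetric truncated-Gaussian
#'   perturbation applied to taste probabilities (default 0.05).
#' @param sigma_diet Standard deviation of the Gaussian perturbation added to
#'   the defuzzified diet score before thresholding (default 0.06).
#' @param sigma_innovation Standard deviation of the truncated-Gaussian
#'   perturbation of the innovation score (default 0.08).
#' @param diet_thresholds Increasing named cut points partitioning the diet
#'   axis: below `vegan` is vegan, then vegetarian, then flexitarian, and
#'   `>= flexitarian` is omnivore.
#' @param innovation_cutoff Score at or above which a user counts as
#'   innovative (default 0.5).
#' @param flexitarian_damping Multiplier applied to flexitarians' white- and
#'   red-meat tastes (default 0.5).
#' @param innovation_multiplier_base Offset b in the selection-weight
#'   multiplier `b + innovation` applied to innovative dishes (default 0.5).
#' @return A list of class `fuzzy_config`.
#' @export
fuzzy_config <- function(sigma_taste = 0.05,
                         sigma_diet = 0.06,
                         sigma_innovation = 0.08,
                         diet_thresholds = c(vegan = 0.25, vegetarian = 0.5,
                                             flexitarian = 0.75),
                         innovation_cutoff = 0.5,
                         flexitarian_damping = 0.5,
                         innovation_multiplier_base = 0.5) {
  stopifnot(sigma_taste >= 0, sigma_diet >= 0, sigma_innovation >= 0,
            length(diet_thresholds) == 3L, !is.unsorted(diet_thresholds),
            all(diet_thresholds > 0), all(diet_thresholds < 1),
            flexitarian_damping >= 0, flexitarian_damping <= 1)
  structure(list(sigma_taste = sigma_taste, sigma_diet = sigma_diet,
                 sigma_innovation = sigma_innovation,
                 diet_thresholds = diet_thresholds,
                 innovation_cutoff = innovation_cutoff,
                 flexitarian_damping = flexitarian_damping,
                 innovation_multiplier_base = innovation_multiplier_base),
            class = "fuzzy_config")
}

#' Demographic attributes of a simulated user
#'
#' @param age Age in years, in `[0, 100]`.
#' @param gender `"female"` or `"male"`.
#' @param region `"coastal"` or `"inland"`.
#' @param locality Locality size: `"small"`, `"medium"` or `"large"`.
#' @return A list of class `user_attributes`.
#' @export
user_attributes <- function(age, gender, region, locality) {
  stopifnot(is.numeric(age), length(age) == 1L, age >= 0, age <= 100)
  gender <- match.arg(gender, c("female", "male"))
  region <- match.arg(region, c("coastal", "inland"))
  locality <- match.arg(locality, c("small", "medium", "large"))
  structure(list(age = age, gender = gender, region = region,
                 locality = locality), class = "user_attributes")
}

#' Fuzzify a full attribute record
#'
#' @param attributes A [user_attributes()] object.
#' @param inputs Named list of input [fuzzy_variable()]s (as held by any
#'   shipped rule block).
#' @return Named list of degree vectors, one per input variable.
#' @export
fuzzify_attributes <- function(attributes, inputs) {
  stopifnot(inherits(attributes, "user_attributes"))
  list(age = fuzzify(attributes$age, inputs$age),
       gender = fuzzify(attributes$gender, inputs$gender),
       region = fuzzify(attributes$region, inputs$region),
       locality = fuzzify(attributes$locality, inputs$locality))
}

# Draw from N(0, sigma) truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm1 <- function(n, sigma, lo, hi) {
  if (sigma == 0) return(rep(0, n))
  p <- stats::runif(n, stats::pnorm(lo, 0, sigma), stats::pnorm(hi, 0, sigma))
  stats::qnorm(p, 0, sigma)
}

#' Defuzzified diet score of an attribute record
#'
#' Runs the diet rule block and returns the crisp position on the diet axis
#' before stochastic perturbation and thresholding.
#'
#' @inheritParams fuzzify_attributes
#' @param rule_base Named list of rule blocks (default the shipped base).
#' @return Scalar in `[0, 1]`.
#' @export
infer_diet_score <- function(attributes, rule_base = default_rule_base()) {
  m <- fuzzify_attributes(attributes, rule_base$diet$inputs)
  defuzzify_or_midpoint(infer(rule_base$diet, m))
}

#' Infer the diet class of a user
#'
#' Defuzzifies the diet rule block onto the `[0, 1]` diet axis, adds a
#' zero-mean Gaussian perturbation (`sigma_diet`), and partitions the axis
#' into the four diet classes at the configured thresholds. With
#' `sigma_diet = 0` the mapping is deterministic in the attributes.
#'
#' @inheritParams infer_diet_score
#' @param config A [fuzzy_config()].
#' @return One of `"vegan"`, `"vegetarian"`, `"flexitarian"`, `"omnivore"`.
#' @export
infer_diet <- function(attributes, rule_base = default_rule_base(),
                       config = fuzzy_config()) {
  score <- infer_diet_score(attributes, rule_base)
  score <- score + stats::rnorm(1L, 0, config$sigma_diet)
  th <- config$diet_thresholds
  if (score < th[["vegan"]]) "vegan"
  else if (score < th[["vegetarian"]]) "vegetarian"
  else if (score < th[["flexitarian"]]) "flexitarian"
  else "omnivore"
}

#' Perturb taste probabilities with symmetric truncated noise
#'
#' Adds zero-mean Gaussian noise to every nonzero taste, truncated
#' symmetrically to `[-b, b]` with `b = min(x, 1 - x)` so the perturbed value
#' stays in `[0, 1]` and its expectation equals the unperturbed value.
#' Tastes that are exactly 0 (diet-forbidden tags) are never moved.
#'
#' @param tastes Named numeric vector of tag probabilities in `[0, 1]`.
#' @param sigma Noise standard deviation, `>= 0`.
#' @return Perturbed tastes, same names, values in `[0, 1]`.
#' @export
perturb_tastes <- function(tastes, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a nonnegative scalar")
  if (sigma == 0) return(tastes)
  b <- pmin(tastes, 1 - tastes)
  out <- tastes
  idx <- which(tastes > 0 & b > 0)
  for (i in idx)
    out[i] <- tastes[i] + rtruncnorm1(1L, sigma, -b[i], b[i])
  pmin(pmax(out, 0), 1)
}

#' Infer the taste probabilities of a user
#'
#' Runs the taste rule block once per tag, defuzzifies each aggregated area
#' (falling back to the universe midpoint 0.5 when no rule fires for a tag),
#' perturbs the values with [perturb_tastes()], then applies the diet
#' constraints: vegan zeroes all animal-derived tags, vegetarian zeroes the
#' meat and fish tags, and flexitarian damps white/red meat by
#' `flexitarian_damping`.
#'
#' @inheritParams infer_diet
#' @param diet Diet class of the user.
#' @return Named numeric vector over [menu_tags()], values in `[0, 1]`.
#' @export
infer_tastes <- function(attributes, diet, rule_base = default_rule_base(),
                         config = fuzzy_config()) {
  block <- rule_base$tastes
  m <- fuzzify_attributes(attributes, block$inputs)
  tags <- menu_tags()
  vals <- vapply(tags, function(tg) {
    defuzzify_or_midpoint(infer(block, m, output = paste0("taste_", tg)))
  }, numeric(1))
  names(vals) <- tags
  vals <- perturb_tastes(vals, config$sigma_taste)
  vals[diet_forbidden_tags(diet)] <- 0
  if (diet == "flexitarian")
    vals[c("white_meat", "red_meat")] <-
      vals[c("white_meat", "red_meat")] * config$flexitarian_damping
  vals
}

#' Infer the innovation score of a user
#'
#' Runs the innovation rule block, defuzzifies onto `[0, 1]`, and adds a
#' zero-mean Gaussian perturbation truncated so the score stays in `[0, 1]`.
#' A user counts as innovative when the score reaches
#' `config$innovation_cutoff`.
#'
#' @inheritParams infer_diet
#' @return Scalar in `[0, 1]`.
#' @export
infer_innovation <- function(attributes, rule_base = default_rule_base(),
                             config = fuzzy_config()) {
  block <- rule_base$innovation
  m <- fuzzify_attributes(attributes, block$inputs)
  score <- defuzzify_or_midpoint(infer(block, m))
  score + rtruncnorm1(1L, config$sigma_innovation, -score, 1 - score)
}

#' Assemble a full user profile
#'
#' Runs all three rule blocks for one attribute record. When `diet` is given
#' (quota-based subgroup generation) the diet class is imposed instead of
#' inferred; tastes and innovation are always inferred.
#'
#' @inheritParams infer_diet
#' @param user_id Identifier for the profile.
#' @param diet Optional fixed diet class overriding inference.
#' @return A list of class `user_profile` with fields `user_id`, `diet`,
#'   `tastes`, `innovation`, `attributes`.
#' @export
make_profile <- function(user_id, attributes,
                         rule_base = default_rule_base(),
                         config = fuzzy_config(), diet = NULL) {
  if (is.null(diet)) {
    diet <- infer_diet(attributes, rule_base, config)
  } else {
    diet <- match.arg(diet, c("omnivore", "flexitarian", "vegetarian", "vegan"))
  }
  profile <- structure(
    list(user_id = user_id, diet = diet,
         tastes = infer_tastes(attributes, diet, rule_base, config),
         innovation = infer_innovation(attributes, rule_base, config),
         attributes = attributes),
    class = "user_profile")
  validate_profile(profile)
  profile
}

#' Validate the invariants of a user profile
#'
#' Checks that all tastes and the innovation score lie in `[0, 1]`, that the
#' taste vector covers exactly the 12 tags, and that diet-forbidden tags are
#' exactly zero.
#'
#' @param profile A `user_profile`.
#' @return The profile, invisibly; errors if an invariant is violated.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "user_profile"))
  t <- profile$tastes
  if (!identical(sort(names(t)), sort(menu_tags())))
    stop("profile tastes must cover exactly the 12 tags")
  if (any(t < 0 | t > 1)) stop("taste probabilities must lie in [0, 1]")
  if (profile$innovation < 0 || profile$innovation > 1)
    stop("innovation score must lie in [0, 1]")
  bad <- diet_forbidden_tags(profile$diet)
  if (length(bad) && any(t[bad] != 0))
    stop("diet '", profile$diet, "' requires zero taste on: ",
         paste(bad, collapse = ", "))
  invisible(profile)
}

#' @export
print.user_profile <- function(x, ...) {
  cat("<user_profile>", x$user_id, "-", x$diet,
      sprintf("(age %g %s, %s/%s), innovation %.2f\n", x$attributes$age,
              x$attributes$gender, x$attributes$region, x$attributes$locality,
              x$innovation))
  top <- sort(x$tastes, decreasing = TRUE)[1:3]
  cat("  top tastes:", paste(sprintf("%s %.2f", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}
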