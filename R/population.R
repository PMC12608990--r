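#' Demographic reference specification
#'
#' Reads the national demographic reference: an age pyramid in 5-year bins
#' (sampled through a piecewise-linear density), the share of women, of
#' coastal residents, and the locality-size mix.
#'
#' @param path YAML file; defaults to the spec shipped with the package.
#' @return A list of class `demographic_spec`.
#' @export
demographic_spec <- function(path = system.file("extdata", "demographics.yaml",
                                                package = "menusim")) {
  doc <- yaml::read_yaml(path)
  bins <- do.call(rbind, lapply(doc$age_bins, as.data.frame))
  stopifnot(all(bins$weight >= 0), sum(bins$weight) > 0)
  structure(list(age_bins = bins,
                 pct_female = doc$pct_female,
                 pct_coastal = doc$pct_coastal,
                 locality_shares = unlist(doc$locality_shares)),
            class = "demographic_spec")
}

# Inverse-CDF sampler for the piecewise-linear age density through the bin
# midpoints (grid step 0.25 years).
sample_ages_demographic <- function(n, spec, min_age = 0, max_age = 100) {
  bins <- spec$age_bins
  mid <- (bins$lo + bins$hi) / 2
  dens <- bins$weight / (bins$hi - bins$lo)
  grid <- seq(0, 100, by = 0.25)
  d <- stats::approx(c(0, mid, 100), c(dens[1], dens, dens[length(dens)]),
                     xout = grid, rule = 2)$y
  d[grid < min_age | grid > max_age] <- 0
  cdf <- cumsum(d); cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  vapply(u, function(p) grid[which.max(cdf >= p)], numeric(1)) +
    stats::runif(n, 0, 0.25)
}

sample_categorical <- function(n, shares) {
  stopifnot(sum(shares) > 0)
  sample(names(shares), n, replace = TRUE, prob = shares / sum(shares))
}

#' Sample demographic attribute records
#'
#' @param n Number of records.
#' @param spec A [demographic_spec()] (national sampling) or a
#'   [group_spec()] (recipe-based sampling).
#' @param demo Demographic reference used for "national"/"demographic"
#'   entries inside a group recipe.
#' @return List of [user_attributes()].
#' @export
sample_attributes <- function(n, spec, demo = demographic_spec()) {
  if (inherits(spec, "demographic_spec")) {
    ages <- sample_ages_demographic(n, spec)
    genders <- ifelse(stats::runif(n) < spec$pct_female / 100,
                      "female", "male")
    regions <- ifelse(stats::runif(n) < spec$pct_coastal / 100,
                      "coastal", "inland")
    locs <- sample_categorical(n, spec$locality_shares)
  } else if (inherits(spec, "group_spec")) {
    ages <- if (identical(spec$age$kind, "demographic")) {
      sample_ages_demographic(n, demo)
    } else {
      stats::runif(n, spec$age$min, spec$age$max)
    }
    genders <- ifelse(stats::runif(n) < spec$pct_female / 100,
                      "female", "male")
    regions <- if (identical(spec$region, "national")) {
      ifelse(stats::runif(n) < demo$pct_coastal / 100, "coastal", "inland")
    } else {
      sample_categorical(n, unlist(spec$region))
    }
    locs <- if (identical(spec$locality, "national")) {
      sample_categorical(n, demo$locality_shares)
    } else {
      sample_categorical(n, unlist(spec$locality))
    }
  } else {
    stop("spec must be a demographic_spec or a group_spec")
  }
  lapply(seq_len(n), function(i)
    user_attributes(pmin(ages[i], 100), genders[i], regions[i], locs[i]))
}

#' Target-group specification
#'
#' Mirrors one row of the benchmark's group table: sample size, share of
#' women, an age rule, exact diet-share quotas, and the reference share of
#' innovative users the attribute recipe is calibrated to.
#'
#' @param name Group name.
#' @param n_users Number of users (default 50).
#' @param pct_female Percentage of women.
#' @param age Either `list(kind = "demographic")` or
#'   `list(kind = "range", min =, max =)`.
#' @param diet_shares Named percentages (omnivore, flexitarian, vegetarian,
#'   vegan) summing to 100; enforced exactly during generation.
#' @param pct_innovative Reference percentage of innovative users.
#' @param locality,region `"national"` or a named percentage map.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(name, n_users = 50L, pct_female, age, diet_shares,
                       pct_innovative, locality = "national",
                       region = "national") {
  stopifnot(n_users > 0, pct_female >= 0, pct_female <= 100)
  diet_shares <- unlist(diet_shares)
  need <- c("omnivore", "flexitarian", "vegetarian", "vegan")
  if (!all(need %in% names(diet_shares)))
    stop("diet_shares must name omnivore, flexitarian, vegetarian, vegan")
  if (abs(sum(diet_shares) - 100) > 0.5)
    stop("diet_shares must sum to 100 (got ", sum(diet_shares), ")")
  structure(list(name = name, n_users = as.integer(n_users),
                 pct_female = pct_female, age = age,
                 diet_shares = diet_shares[need],
                 pct_innovative = pct_innovative,
                 locality = locality, region = region),
            class = "group_spec")
}

#' Default target groups
#'
#' Parses the four shipped group specifications (Spanish, Foodies, Veggies,
#' Senior; 50 users each).
#'
#' @param path YAML file of group definitions.
#' @return Named list of [group_spec()]s.
#' @export
default_groups <- function(path = system.file("extdata", "groups.yaml",
                                              package = "menusim")) {
  doc <- yaml::read_yaml(path)
  gs <- lapply(doc$groups, function(g)
    group_spec(g$name, g$n_users, g$pct_female, g$age, g$diet_shares,
               g$pct_innovative, locality = g$locality, region = g$region))
  names(gs) <- vapply(gs, `[[`, character(1), "name")
  gs
}

# Largest-remainder apportionment of n among shares (percent).
quota_counts <- function(shares, n) {
  raw <- shares / 100 * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    frac_order <- order(raw - k, decreasing = TRUE)
    k[frac_order[seq_len(rem)]] <- k[frac_order[seq_len(rem)]] + 1
  }
  k
}

#' Generate a population of user profiles
#'
#' For a [demographic_spec()] the diet class of every user emerges from the
#' fuzzy diet block. For a [group_spec()] the diet quotas are enforced
#' exactly: the diet labels implied by `diet_shares` are assigned to users in
#' a random order (stratified assignment); tastes and innovation are always
#' inferred from the sampled attributes.
#'
#' @param spec A [demographic_spec()] or [group_spec()].
#' @param n Number of users; defaults to `spec$n_users` for group specs.
#' @param rule_base,config,demo See [make_profile()] and
#'   [sample_attributes()].
#' @param id_prefix Prefix for user ids.
#' @return List of `user_profile` objects (class `population`).
#' @examples
#' \dontrun{
#' set.seed(1)
#' pop <- generate_population(default_groups()$Veggies)
#' table(vapply(pop, `[[`, character(1), "diet"))
#' }
#' @export
generate_population <- function(spec, n = NULL,
                                rule_base = default_rule_base(),
                                config = fuzzy_config(),
                                demo = demographic_spec(),
                                id_prefix = "u") {
  if (is.null(n))
    n <- if (inherits(spec, "group_spec")) spec$n_users else
      stop("n is required for demographic-spec generation")
  stopifnot(n > 0)
  attrs <- sample_attributes(n, spec, demo)
  diets <- if (inherits(spec, "group_spec")) {
    k <- quota_counts(spec$diet_shares, n)
    sample(rep(names(spec$diet_shares), k))
  } else {
    rep(list(NULL), n)
  }
  pop <- lapply(seq_len(n), function(i)
    make_profile(sprintf("%s%04d", id_prefix, i), attrs[[i]],
                 rule_base, config,
                 diet = if (is.character(diets)) diets[i] else NULL))
  class(pop) <- c("population", "list")
  pop
}

population_diets <- function(pop) vapply(pop, `[[`, character(1), "diet")

#' Running calibration statistics of an emergent population
#'
#' Generates users one batch at a time from a demographic specification and
#' tracks the running value of calibration statistics against their
#' reference values, reproducing the convergence view used to validate the
#' generator (reference statistics are validation targets, not enforced
#' quotas).
#'
#' @param spec A [demographic_spec()].
#' @param n_max Total users to generate (at least 100).
#' @param reference Named reference values (percent). Supported statistics:
#'   `omnivore_share`, `veg_share_over15` (vegetarian + vegan among users
#'   older than 15), `female_share`, `innovative_share`.
#' @param step Evaluation stride along n.
#' @param rule_base,config,demo Passed to [generate_population()].
#' @return Data frame with columns `n`, `statistic`, `value`, `reference`.
#' @export
calibration_curve <- function(spec, n_max = 1300L,
                              reference = c(omnivore_share = 87,
                                            veg_share_over15 = 6),
                              step = 25L,
                              rule_base = default_rule_base(),
                              config = fuzzy_config(),
                              demo = demographic_spec()) {
  stopifnot(inherits(spec, "demographic_spec"), n_max >= 100)
  known <- c("omnivore_share", "veg_share_over15", "female_share",
             "innovative_share")
  if (!all(names(reference) %in% known))
    stop("unknown statistic(s): ",
         paste(setdiff(names(reference), known), collapse = ", "))
  pop <- generate_population(spec, n_max, rule_base, config, demo)
  diets <- population_diets(pop)
  ages <- vapply(pop, function(p) p$attributes$age, numeric(1))
  female <- vapply(pop, function(p) p$attributes$gender, character(1)) ==
    "female"
  innov <- vapply(pop, `[[`, numeric(1), "innovation") >=
    config$innovation_cutoff
  ns <- unique(c(seq(step, n_max, by = step), n_max))
  stat_at <- function(stat, n) {
    i <- seq_len(n)
    switch(stat,
      omnivore_share = 100 * mean(diets[i] == "omnivore"),
      veg_share_over15 = {
        j <- i[ages[i] > 15]
        100 * mean(diets[j] %in% c("vegetarian", "vegan"))
      },
      female_share = 100 * mean(female[i]),
      innovative_share = 100 * mean(innov[i]))
  }
  out <- expand.grid(n = ns, statistic = names(reference),
                     stringsAsFactors = FALSE)
  out$value <- mapply(function(s, n) stat_at(s, n), out$statistic, out$n)
  out$reference <- reference[out$statistic]
  out[order(out$statistic, out$n), c("n", "statistic", "value", "reference")]
}

#' Convert a population to a data frame
#'
#' @param pop A `population` (list of `user_profile`s).
#' @return Data frame with one row per user: id, attributes, diet,
#'   innovation, and one column per taste tag.
#' @export
population_to_df <- function(pop) {
  rows <- lapply(pop, function(p) {
    d <- data.frame(user_id = p$user_id, age = p$attributes$age,
                    gender = p$attributes$gender,
                    region = p$attributes$region,
                    locality_size = p$attributes$locality,
                    diet = p$diet, innovation = p$innovation,
                    stringsAsFactors = FALSE)
    cbind(d, as.data.frame(as.list(p$tastes)))
  })
  do.call(rbind, rows)
}

#' Write a population to disk
#'
#' Writes a CSV (one row per user) plus a JSON sidecar recording the spec
#' and the seed used for generation.
#'
#' @param pop A `population`.
#' @param path Output CSV path; the sidecar gets extension `.json`.
#' @param spec The spec the population was generated from.
#' @param seed The seed used (recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path, spec = NULL, seed = NULL) {
  utils::write.csv(population_to_df(pop), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- list(n = length(pop), seed = seed,
               spec = if (is.null(spec)) NULL else unclass(spec),
               generated = "menusim population export")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
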