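#' Course-tag availability map
#'
#' Which of the 12 tags can appear in each course. First courses carry the 5
#' starch/vegetable tags, second courses the 8 protein-or-side tags (three
#' tags — legume, vegetables, potato — can appear in either savoury course),
#' and desserts only fruit and dairy. The map defines the 5 + 8 + 2 = 15
#' course-tag pairs that make up the recommendation action space.
#'
#' @return Named list `first`, `second`, `dessert` of tag vectors.
#' @export
course_tag_map <- function() {
  list(first = c("rice", "pasta", "potato", "legume", "vegetables"),
       second = c("white_meat", "red_meat", "fish", "fried", "egg",
                  "legume", "vegetables", "potato"),
       dessert = c("fruit", "dairy"))
}

plant_tags <- function() {
  c("rice", "pasta", "potato", "legume", "vegetables", "fruit")
}

#' Catalog specification
#'
#' @param n_first,n_second,n_dessert Dish counts per course (default
#'   60/60/25).
#' @param n_innovative Named counts of innovative dishes per course (default
#'   10/23/4).
#' @param availability Course-tag availability map (default
#'   [course_tag_map()]).
#' @param fried_vegetarian_share Share of fried dishes flagged vegetarian
#'   (the only ambiguous tag; meat/fish tags force non-vegetarian, all other
#'   tags force vegetarian).
#' @return A list of class `catalog_spec`.
#' @export
catalog_spec <- function(n_first = 60L, n_second = 60L, n_dessert = 25L,
                         n_innovative = c(first = 10L, second = 23L,
                                          dessert = 4L),
                         availability = course_tag_map(),
                         fried_vegetarian_share = 0.5) {
  counts <- c(first = as.integer(n_first), second = as.integer(n_second),
              dessert = as.integer(n_dessert))
  stopifnot(all(counts > 0), all(n_innovative >= 0),
            all(n_innovative <= counts[names(n_innovative)]),
            all(names(availability) == c("first", "second", "dessert")),
            fried_vegetarian_share >= 0, fried_vegetarian_share <= 1)
  for (crs in names(availability)) {
    if (!all(availability[[crs]] %in% menu_tags()))
      stop("availability map for ", crs, " contains unknown tags")
    if (counts[[crs]] < length(availability[[crs]]))
      stop("course ", crs, " has fewer dishes than tags")
  }
  structure(list(counts = counts, n_innovative = n_innovative,
                 availability = availability,
                 fried_vegetarian_share = fried_vegetarian_share),
            class = "catalog_spec")
}

#' Generate the dish catalog
#'
#' Builds a synthetic dish database: per course, dishes are spread as evenly
#' as possible over the course's available tags, the configured number of
#' dishes is flagged innovative (at random), and dietary flags are derived
#' from the tag — meat and fish tags are never vegetarian, fried dishes are
#' vegetarian with `fried_vegetarian_share`, everything else is vegetarian;
#' a dish is vegan when it is vegetarian and its tag is plant-based. Dish
#' names are synthesized from tag templates.
#'
#' @param spec A [catalog_spec()].
#' @return A list of class `catalog`: data frame `dishes` (dish_id, name,
#'   course, tag, innovative, vegetarian, vegan) plus the availability map.
#' @examples
#' set.seed(1)
#' cat60 <- generate_catalog()
#' table(cat60$dishes$course)
#' @export
generate_catalog <- function(spec = catalog_spec()) {
  rows <- list()
  for (crs in c("first", "second", "dessert")) {
    tags <- spec$availability[[crs]]
    n <- spec$counts[[crs]]
    tag_vec <- sort(rep_len(sort(tags), n))
    innovative <- rep(FALSE, n)
    innovative[sample.int(n, spec$n_innovative[[crs]])] <- TRUE
    vegetarian <- !(tag_vec %in% c("white_meat", "red_meat", "fish"))
    fried <- which(tag_vec == "fried")
    if (length(fried))
      vegetarian[fried] <- stats::runif(length(fried)) <
        spec$fried_vegetarian_share
    vegan <- vegetarian & tag_vec %in% plant_tags()
    rows[[crs]] <- data.frame(
      dish_id = sprintf("%s_%03d", substr(crs, 1, 1), seq_len(n)),
      name = sprintf("%s%s plate %02d",
                     ifelse(innovative, "innovative ", ""),
                     gsub("_", " ", tag_vec), seq_len(n)),
      course = crs, tag = tag_vec, innovative = innovative,
      vegetarian = vegetarian, vegan = vegan, stringsAsFactors = FALSE)
  }
  structure(list(dishes = do.call(rbind, c(rows, make.row.names = FALSE)),
                 availability = spec$availability),
            class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  tb <- table(x$dishes$course)[c("first", "second", "dessert")]
  cat("<catalog>", paste(tb, collapse = "/"), "dishes,",
      sum(x$dishes$innovative), "innovative\n")
  invisible(x)
}

#' Enumerate the action space
#'
#' All (course, tag) pairs present in the availability map, in deterministic
#' order: course-major (first, second, dessert), tags alphabetical within a
#' course. With the default map this yields 15 actions.
#'
#' @param catalog A `catalog` (or anything with an `availability` field).
#' @return Data frame with columns `course` (1, 2, 3) and `tag`.
#' @export
enumerate_actions <- function(catalog = generate_catalog()) {
  av <- catalog$availability
  do.call(rbind, lapply(seq_along(av), function(ci)
    data.frame(course = ci, tag = sort(av[[ci]]), stringsAsFactors = FALSE)))
}

#' Sample a daily menu
#'
#' Offers distinct plate types per course, as a canteen would: 3 (first and
#' second courses) or 2 (dessert) tags are drawn uniformly without
#' replacement from the course's available tags, then one dish is drawn
#' uniformly within each tag. A course is resampled until it offers at
#' least one vegan-permitted vegetarian option (plant-tag dish), which
#' guarantees a positive-weight choice for every diet class. Distinct tags
#' make a uniform-random recommender's per-course match probability exactly
#' 1/#options.
#'
#' @param catalog A `catalog`.
#' @param day Day index stored on the menu.
#' @param max_tries Resampling cap per course before an infeasibility error.
#' @return A list of class `menu_day` with data-frame elements `first`
#'   (3 rows), `second` (3 rows), `dessert` (2 rows) and the `day` index.
#' @export
sample_daily_menu <- function(catalog, day = 1L, max_tries = 1000L) {
  n_opts <- c(first = 3L, second = 3L, dessert = 2L)
  menu <- list(day = as.integer(day))
  for (crs in names(n_opts)) {
    pool <- catalog$dishes[catalog$dishes$course == crs, ]
    tags <- unique(pool$tag)
    if (length(tags) < n_opts[[crs]])
      stop("catalog offers fewer than ", n_opts[[crs]], " ", crs, " tags")
    if (!any(pool$vegan))
      stop("catalog cannot satisfy the vegetarian guarantee for ", crs)
    for (k in seq_len(max_tries)) {
      day_tags <- sample(tags, n_opts[[crs]])
      rows <- vapply(day_tags, function(tg) {
        cand <- which(pool$tag == tg)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      opts <- pool[rows, ]
      if (any(opts$vegan)) break
      if (k == max_tries)
        stop("could not satisfy the vegetarian guarantee for ", crs)
    }
    rownames(opts) <- NULL
    menu[[crs]] <- opts
  }
  structure(menu, class = "menu_day")
}

#' Write / read a catalog
#'
#' The dish table is stored as CSV and the availability map as a JSON
#' sidecar.
#'
#' @param catalog A `catalog`.
#' @param path CSV path; the availability sidecar uses extension `.json`.
#' @return `path` (write) or a `catalog` (read).
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog$dishes, path, row.names = FALSE)
  jsonlite::write_json(catalog$availability,
                       sub("\\.csv$", ".json", path), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  dishes <- utils::read.csv(path, stringsAsFactors = FALSE)
  av <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                            simplifyVector = TRUE)
  structure(list(dishes = dishes, availability = av), class = "catalog")
}
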