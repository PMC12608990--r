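#' Fuzzy variables and fuzzification
#'
#' A fuzzy variable is either continuous (a universe of discourse plus a set
#' of overlapping trapezoidal/triangular membership functions) or categorical
#' (a plain vocabulary; membership is crisp 0/1). Categorical variables let
#' demographic attributes such as gender enter the same rule machinery as
#' continuous ones such as age.
#'
#' @param name Variable name (character scalar).
#' @param universe Numeric `c(min, max)` for continuous variables.
#' @param sets Named list. For continuous variables each element is a numeric
#'   vector of length 3 (triangle `a,b,c`) or 4 (trapezoid `a,b,c,d`) with
#'   non-decreasing vertices inside the universe. For categorical variables,
#'   use `levels` instead.
#' @param levels Character vector of categories (categorical variables only).
#' @param resolution Number of grid points used when the variable serves as a
#'   rule-block output (default 201).
#' @return An object of class `fuzzy_variable`.
#' @examples
#' age <- fuzzy_variable("age", c(0, 100),
#'   sets = list(children = c(0, 0, 14, 16), seniors = c(68, 70, 100, 100)))
#' fuzzify(5, age)
#' @export
fuzzy_variable <- function(name, universe = NULL, sets = NULL, levels = NULL,
                           resolution = 201L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(levels)) {
    v <- list(name = name, kind = "categorical", levels = levels)
  } else {
    stopifnot(is.numeric(universe), length(universe) == 2L,
              universe[1] < universe[2], is.list(sets), length(sets) >= 1L)
    for (lab in names(sets)) {
      p <- sets[[lab]]
      if (!length(p) %in% c(3L, 4L) || is.unsorted(p))
        stop("set '", lab, "' of variable '", name,
             "' must be a sorted length-3 or length-4 vertex vector")
      if (p[1] < universe[1] || p[length(p)] > universe[2])
        stop("set '", lab, "' of variable '", name, "' exceeds the universe")
    }
    v <- list(name = name, kind = "continuous", universe = universe,
              sets = sets, resolution = as.integer(resolution))
  }
  structure(v, class = "fuzzy_variable")
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  if (x$kind == "categorical") {
    cat("<fuzzy_variable>", x$name, "(categorical):",
        paste(x$levels, collapse = ", "), "\n")
  } else {
    cat("<fuzzy_variable>", x$name, sprintf("on [%g, %g], sets: %s\n",
        x$universe[1], x$universe[2], paste(names(x$sets), collapse = ", ")))
  }
  invisible(x)
}

# Trapezoidal membership with vertical-edge handling (a == b or c == d).
# p is length 3 (triangle) or 4 (trapezoid); vectorised over x.
trapezoid_membership <- function(x, p) {
  if (length(p) == 3L) p <- p[c(1L, 2L, 2L, 3L)]
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= cc)
  pmax(0, pmin(up, 1, dn))
}

#' Fuzzify a crisp value
#'
#' Maps a crisp input to a named vector of membership degrees, one per
#' linguistic set of the variable. For categorical variables the degree is 1
#' for the matching level and 0 elsewhere.
#'
#' @param value A numeric scalar (continuous variable) or a character scalar
#'   (categorical variable).
#' @param variable A [fuzzy_variable()].
#' @return Named numeric vector of degrees in `[0, 1]`.
#' @export
fuzzify <- function(value, variable) {
  stopifnot(inherits(variable, "fuzzy_variable"))
  if (variable$kind == "categorical") {
    if (!value %in% variable$levels)
      stop("value '", value, "' is not a level of variable '",
           variable$name, "'")
    return(stats::setNames(as.numeric(variable$levels == value),
                           variable$levels))
  }
  if (!is.numeric(value) || length(value) != 1L || is.na(value))
    stop("value for '", variable$name, "' must be a numeric scalar")
  if (value < variable$universe[1] || value > variable$universe[2])
    stop("value ", value, " outside the universe of '", variable$name, "'")
  vapply(variable$sets, function(p) trapezoid_membership(value, p),
         numeric(1))
}

# Discretised membership matrix of an output variable: grid x sets.
output_grid <- function(variable, resolution = NULL) {
  stopifnot(variable$kind == "continuous")
  n <- if (is.null(resolution)) variable$resolution else as.integer(resolution)
  x <- seq(variable$universe[1], variable$universe[2], length.out = n)
  mu <- vapply(variable$sets, function(p) trapezoid_membership(x, p),
               numeric(n))
  list(x = x, mu = mu)
}

#' Centroid defuzzification
#'
#' Collapses an aggregated fuzzy output area to its centre of mass,
#' integral x mu(x) dx / integral mu(x) dx, by trapezoidal quadrature on the
#' area's grid.
#'
#' @param area A `fuzzy_area` as returned by [infer()]: a list with numeric
#'   `x` (uniform grid over the output universe) and `mu` (degrees in
#'   `[0, 1]`).
#' @return The crisp output, a scalar inside the support of the area.
#' @seealso [infer()]
#' @export
defuzzify_centroid <- function(area) {
  x <- area$x; mu <- area$mu
  stopifnot(is.numeric(x), is.numeric(mu), length(x) == length(mu),
            length(x) >= 2L)
  w <- rep(1, length(x)); w[c(1L, length(x))] <- 0.5
  mass <- sum(w * mu)
  if (mass <= 0)
    stop(structure(class = c("menusim_zero_mass", "error", "condition"),
                   list(message = "aggregated area has zero mass",
                        call = sys.call(-1))))
  sum(w * x * mu) / mass
}

# Midpoint fallback used by profile inference when no rule fires.
defuzzify_or_midpoint <- function(area) {
  tryCatch(defuzzify_centroid(area),
           menusim_zero_mass = function(e) mean(range(area$x)))
}
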