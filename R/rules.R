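#' Fuzzy rules and Mamdani inference
#'
#' Rules are IF-THEN statements whose antecedent combines membership degrees
#' of input variables (AND = minimum, OR = maximum) and whose consequent
#' names a linguistic set of an output variable. Inference is Mamdani
#' min-implication: each consequent set is clipped at the rule's firing
#' degree (scaled by the optional rule weight) and the clipped areas are
#' aggregated pointwise by maximum.
#'
#' @name fuzzy-rules
NULL

#' Construct a fuzzy rule
#'
#' @param if_terms List of `list(var =, is =)` antecedent terms (1 to 8).
#' @param then_var,then_is Output variable name and linguistic set label.
#' @param connective `"and"` (minimum, default) or `"or"` (maximum).
#' @param weight Firing-degree multiplier in `(0, 1]`.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(if_terms, then_var, then_is,
                       connective = c("and", "or"), weight = 1) {
  connective <- match.arg(connective)
  stopifnot(is.list(if_terms), length(if_terms) >= 1L, length(if_terms) <= 8L,
            is.numeric(weight), weight > 0, weight <= 1)
  for (tm in if_terms)
    if (is.null(tm$var) || is.null(tm$is))
      stop("each antecedent term needs fields 'var' and 'is'")
  structure(list(if_terms = if_terms, connective = connective,
                 then_var = then_var, then_is = then_is, weight = weight),
            class = "fuzzy_rule")
}

#' Construct a rule block
#'
#' A rule block groups the rules that produce one family of outputs (diet
#' classification, per-tag tastes, or innovation) together with the input
#' and output variable definitions they reference.
#'
#' @param block_id One of `"diet"`, `"tastes"`, `"innovation"` (free-form ids
#'   are allowed for custom blocks).
#' @param rules List of [fuzzy_rule()] objects.
#' @param inputs Named list of input [fuzzy_variable()]s.
#' @param outputs Named list of output [fuzzy_variable()]s (continuous).
#' @return An object of class `rule_block`.
#' @export
rule_block <- function(block_id, rules, inputs, outputs) {
  stopifnot(is.list(rules), length(rules) >= 1L)
  for (r in rules) {
    stopifnot(inherits(r, "fuzzy_rule"))
    for (tm in r$if_terms) {
      v <- inputs[[tm$var]]
      if (is.null(v))
        stop("rule references unknown input variable '", tm$var, "'")
      labs <- if (v$kind == "categorical") v$levels else names(v$sets)
      if (!tm$is %in% labs)
        stop("rule references unknown label '", tm$is, "' of variable '",
             tm$var, "'")
    }
    ov <- outputs[[r$then_var]]
    if (is.null(ov))
      stop("rule references unknown output variable '", r$then_var, "'")
    if (!r$then_is %in% names(ov$sets))
      stop("rule references unknown label '", r$then_is,
           "' of output variable '", r$then_var, "'")
  }
  structure(list(block_id = block_id, rules = rules, inputs = inputs,
                 outputs = outputs), class = "rule_block")
}

#' @export
print.rule_block <- function(x, ...) {
  cat("<rule_block>", x$block_id, "-", length(x$rules), "rules,",
      length(x$inputs), "inputs,", length(x$outputs), "outputs\n")
  invisible(x)
}

# Firing degree of one rule given fuzzified inputs
# (memberships: named list of named degree vectors).
rule_firing_degree <- function(rule, memberships) {
  degs <- vapply(rule$if_terms, function(tm) {
    m <- memberships[[tm$var]]
    if (is.null(m))
      stop("memberships are missing variable '", tm$var, "'")
    d <- m[[tm$is]]
    if (is.null(d) || is.na(d))
      stop("memberships for '", tm$var, "' lack label '", tm$is, "'")
    d
  }, numeric(1))
  deg <- if (rule$connective == "and") min(degs) else max(degs)
  deg * rule$weight
}

#' Mamdani inference over a rule block
#'
#' Computes the aggregated fuzzy output area for one output variable: the
#' pointwise maximum, over all rules targeting that variable, of the
#' consequent set clipped at the rule's firing degree.
#'
#' @param block A [rule_block()].
#' @param memberships Named list: for every input variable referenced by the
#'   block, the named degree vector returned by [fuzzify()].
#' @param output Name of the output variable to aggregate. May be omitted
#'   when the block has a single output.
#' @param resolution Optional grid-resolution override.
#' @return A `fuzzy_area`: list with `x` (grid), `mu` (aggregated degrees)
#'   and `variable` (output name).
#' @examples
#' \dontrun{
#' rb <- default_rule_base()
#' m <- fuzzify_attributes(user_attributes(30, "female", "coastal", "large"),
#'                         rb$diet$inputs)
#' area <- infer(rb$diet, m)
#' defuzzify_centroid(area)
#' }
#' @export
infer <- function(block, memberships, output = NULL, resolution = NULL) {
  stopifnot(inherits(block, "rule_block"))
  if (is.null(output)) {
    if (length(block$outputs) != 1L)
      stop("block '", block$block_id,
           "' has several outputs; name one via `output`")
    output <- names(block$outputs)[1L]
  }
  ovar <- block$outputs[[output]]
  if (is.null(ovar)) stop("unknown output variable '", output, "'")
  grid <- output_grid(ovar, resolution)
  mu <- numeric(length(grid$x))
  for (r in block$rules) {
    if (r$then_var != output) next
    deg <- rule_firing_degree(r, memberships)
    if (deg <= 0) next
    clipped <- pmin(deg, grid$mu[, r$then_is])
    mu <- pmax(mu, clipped)
  }
  structure(list(x = grid$x, mu = mu, variable = output),
            class = "fuzzy_area")
}

#' Read a rule base from a YAML file
#'
#' The file holds the three shipped rule blocks (`diet`, `tastes`,
#' `innovation`) as data: variable definitions plus one rule list per block,
#' each rule as `{if: [{var, is}, ...], connective, then: {var, is}, weight}`.
#' Rule bases are configuration, not code; edit the file to change the
#' encoded domain knowledge.
#'
#' @param path Path to the YAML rule-base file; defaults to the rule base
#'   shipped with the package.
#' @return Named list of [rule_block()]s (`diet`, `tastes`, `innovation`).
#' @export
read_rule_base <- function(path = system.file("extdata", "rulebase.yaml",
                                              package = "menusim")) {
  doc <- yaml::read_yaml(path)
  inputs <- lapply(doc$input_variables, parse_variable)
  names(inputs) <- vapply(inputs, `[[`, character(1), "name")
  blocks <- lapply(doc$blocks, function(b) {
    outputs <- lapply(b$output_variables, parse_variable)
    names(outputs) <- vapply(outputs, `[[`, character(1), "name")
    rules <- lapply(b$rules, function(r) {
      fuzzy_rule(if_terms = r$`if`,
                 then_var = r$then$var, then_is = r$then$is,
                 connective = if (is.null(r$connective)) "and" else r$connective,
                 weight = if (is.null(r$weight)) 1 else r$weight)
    })
    rule_block(b$block_id, rules, inputs, outputs)
  })
  names(blocks) <- vapply(blocks, `[[`, character(1), "block_id")
  blocks
}

parse_variable <- function(v) {
  if (!is.null(v$levels)) {
    fuzzy_variable(v$name, levels = unlist(v$levels))
  } else {
    sets <- lapply(v$sets, unlist)
    fuzzy_variable(v$name, universe = unlist(v$universe), sets = sets,
                   resolution = if (is.null(v$resolution)) 201L else v$resolution)
  }
}

rule_base_cache <- new.env(parent = emptyenv())

#' Default shipped rule base
#'
#' Parses (and memoises) the rule base shipped under `inst/extdata/`.
#' The three blocks carry 17 (diet), 30 (tastes) and 15 (innovation) rules.
#'
#' @return Named list of [rule_block()]s.
#' @export
default_rule_base <- function() {
  if (is.null(rule_base_cache$default))
    rule_base_cache$default <- read_rule_base()
  rule_base_cache$default
}
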