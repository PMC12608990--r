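# Fuzzification, Mamdani inference and centroid defuzzification.

age_var <- function() default_rule_base()$diet$inputs$age

test_that("age fuzzification matches the membership-set geometry", {
  age <- age_var()
  m5 <- fuzzify(5, age)
  expect_equal(m5[["children"]], 1)
  expect_equal(sum(m5[setdiff(names(m5), "children")]), 0)

  m70 <- fuzzify(70, age)
  expect_gt(m70[["adults"]], 0)
  expect_gt(m70[["seniors"]], 0)

  # any value on a set's plateau has membership 1 there
  expect_equal(fuzzify(50, age)[["adults"]], 1)
  expect_equal(fuzzify(90, age)[["seniors"]], 1)

  expect_error(fuzzify(120, age), "universe")
  expect_error(fuzzify(-1, age), "universe")
})

test_that("every age in the universe has positive membership somewhere", {
  age <- age_var()
  for (a in seq(0, 100, by = 0.5)) {
    m <- fuzzify(a, age)
    expect_true(all(m >= 0 & m <= 1))
    expect_gt(max(m), 0)
  }
})

test_that("categorical fuzzification is crisp", {
  gender <- default_rule_base()$diet$inputs$gender
  expect_equal(fuzzify("female", gender),
               c(female = 1, male = 0))
  expect_error(fuzzify("other", gender), "not a level")
})

simple_block <- function() {
  x <- fuzzy_variable("x", c(0, 1),
                      sets = list(lo = c(0, 0, 0.4), hi = c(0.6, 1, 1)))
  out <- fuzzy_variable("y", c(0, 1),
                        sets = list(a = c(0, 0.2, 0.4, 0.6),
                                    b = c(0.4, 0.6, 0.8, 1)),
                        resolution = 1001L)
  rule_block("toy",
             list(fuzzy_rule(list(list(var = "x", is = "lo")), "y", "a"),
                  fuzzy_rule(list(list(var = "x", is = "hi")), "y", "b")),
             inputs = list(x = x), outputs = list(y = out))
}

test_that("Mamdani aggregation is the pointwise max of clipped consequents", {
  blk <- simple_block()
  # no rule fires -> identically zero area
  a0 <- infer(blk, list(x = c(lo = 0, hi = 0)))
  expect_true(all(a0$mu == 0))

  # single rule at degree 1 -> area equals the consequent set
  a1 <- infer(blk, list(x = c(lo = 1, hi = 0)))
  grid <- menusim:::output_grid(blk$outputs$y)
  expect_equal(a1$mu, unname(grid$mu[, "a"]))

  # two rules at 0.4 / 0.7 -> pointwise max of clipped sets, checked
  # against a brute-force evaluation on the same 1001-point grid
  a2 <- infer(blk, list(x = c(lo = 0.4, hi = 0.7)))
  brute <- pmax(pmin(0.4, grid$mu[, "a"]), pmin(0.7, grid$mu[, "b"]))
  expect_equal(a2$mu, unname(brute))

  expect_error(infer(blk, list()), "missing variable")
})

test_that("aggregation is monotone in the firing degrees", {
  blk <- simple_block()
  degs <- seq(0, 1, by = 0.1)
  prev <- rep(0, 1001L)
  for (d in degs) {
    a <- infer(blk, list(x = c(lo = d, hi = 0.3)))
    expect_true(all(a$mu >= prev - 1e-12))
    prev <- a$mu
  }
})

test_that("centroid defuzzification matches geometry and a fine-grid oracle", {
  # symmetric triangle centred at 0.5
  tri <- fuzzy_variable("y", c(0, 1), sets = list(s = c(0.3, 0.5, 0.7)),
                        resolution = 2001L)
  blk <- rule_block("t", list(fuzzy_rule(list(list(var = "x", is = "on")),
                                         "y", "s")),
                    inputs = list(x = fuzzy_variable("x", levels = "on")),
                    outputs = list(y = tri))
  a <- infer(blk, list(x = c(on = 1)))
  expect_equal(defuzzify_centroid(a), 0.5, tolerance = 1e-6)

  # rectangle on [0.2, 0.6] -> 0.4
  rect <- list(x = seq(0, 1, length.out = 2001L))
  rect$mu <- as.numeric(rect$x >= 0.2 & rect$x <= 0.6)
  expect_equal(defuzzify_centroid(rect), 0.4, tolerance = 1e-3)

  # asymmetric composite area vs 10x-resolution trapezoidal oracle
  blk2 <- simple_block()
  a_lo <- infer(blk2, list(x = c(lo = 0.8, hi = 0.35)))
  a_hi <- infer(blk2, list(x = c(lo = 0.8, hi = 0.35)), resolution = 10010L)
  expect_equal(defuzzify_centroid(a_lo), defuzzify_centroid(a_hi),
               tolerance = 1e-3)

  # centroid lies inside the support of the area
  sup <- range(a_lo$x[a_lo$mu > 0])
  v <- defuzzify_centroid(a_lo)
  expect_gte(v, sup[1]); expect_lte(v, sup[2])

  # zero mass errors
  zero <- list(x = seq(0, 1, length.out = 11L), mu = rep(0, 11L))
  expect_error(defuzzify_centroid(zero), class = "menusim_zero_mass")
  expect_equal(menusim:::defuzzify_or_midpoint(zero), 0.5)
})

test_that("shipped rule blocks have the documented sizes", {
  rb <- default_rule_base()
  expect_named(rb, c("diet", "tastes", "innovation"))
  expect_length(rb$diet$rules, 17L)
  expect_length(rb$tastes$rules, 30L)
  expect_length(rb$innovation$rules, 15L)
  # every rule references declared variables and labels (validated on parse)
  for (b in rb) expect_s3_class(b, "rule_block")
})
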