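make_or_table <- function(entries) {
  effect_table(entries, outcome = "gali", effect_kind = "OR",
               apply_from_age = 50L)
}

test_that("effect_at resolves the three specification kinds", {
  # no entries: everything is a reference category
  empty <- make_or_table(data.frame(sex = character(), factor = character(),
                                    category = character(),
                                    spec_kind = character(),
                                    stratum = character(), value = numeric(),
                                    slope = numeric()))
  expect_equal(effect_at(empty, "smoking", "current", "male", c(0, 55, 100)),
               c(1, 1, 1))

  ll <- make_or_table(data.frame(sex = "male", factor = "smoking",
                                 category = "current",
                                 spec_kind = "loglinear",
                                 stratum = NA_character_,
                                 value = log(2), slope = 0.01))
  expect_equal(effect_at(ll, "smoking", "current", "male", 60),
               2 * exp(0.6), tolerance = 1e-12)
  # below apply_from_age the effect is switched off
  expect_equal(effect_at(ll, "smoking", "current", "male", 40), 1)
  # other sex / category / factor resolve to reference
  expect_equal(effect_at(ll, "smoking", "current", "female", 60), 1)
  expect_equal(effect_at(ll, "bmi", "bmi_gt30", "male", 60), 1)
  expect_error(effect_at(ll, "smoking", "current", "male", 140), "model span")

  st <- make_or_table(data.frame(sex = "male", factor = "bmi",
                                 category = rep("bmi_gt30", 2),
                                 spec_kind = "stratified",
                                 stratum = c("50-65", "65+"),
                                 value = c(1.9, 1.7), slope = NA_real_))
  ages <- 50:100
  v <- effect_at(st, "bmi", "bmi_gt30", "male", ages)
  expect_true(all(v[ages < 65] == 1.9))
  # the boundary age 65 belongs to the upper stratum
  expect_true(all(v[ages >= 65] == 1.7))
})

test_that("loglinear effects are continuous in age, stratified are steps", {
  ll <- make_or_table(data.frame(sex = "male", factor = "alcohol",
                                 category = "none", spec_kind = "loglinear",
                                 stratum = NA_character_, value = 0,
                                 slope = 0.01))
  v <- effect_at(ll, "alcohol", "none", "male", 50:100)
  expect_lt(max(abs(diff(log(v)))), 0.0100001)
  st <- make_or_table(data.frame(sex = "male", factor = "smoking",
                                 category = rep("ex", 2),
                                 spec_kind = "stratified",
                                 stratum = c("50-65", "65+"),
                                 value = c(1.4, 1.25), slope = NA_real_))
  v <- effect_at(st, "smoking", "ex", "male", 50:100)
  expect_equal(sort(unique(v)), c(1.25, 1.4))
})

test_that("odds-ratio estimation reproduces the estimation design", {
  p <- default_params()
  rec <- generate_survey(p, 15000, seed = 91)
  est <- estimate_odds_ratios(rec, "gali", p$defs)
  e <- est$entries
  expect_s3_class(est, "effect_table")
  expect_identical(est$outcome, "gali")
  # smoking and bmi stratified in both strata, both sexes, with SEs
  sb <- e[e$factor %in% c("smoking", "bmi"), ]
  expect_true(all(sb$spec_kind == "stratified"))
  expect_setequal(unique(sb$stratum), c("50-65", "65+"))
  expect_setequal(unique(sb$sex), c("female", "male"))
  expect_true(all(is.finite(sb$se) & sb$se > 0))
  # alcohol log-linear with an age slope per category
  al <- e[e$factor == "alcohol", ]
  expect_true(all(al$spec_kind == "loglinear"))
  expect_setequal(unique(al$category), c("none", "high", "very_high"))
  expect_true(all(is.finite(al$se_slope)))
  # strong true effect (current-smoker OR 1.9/1.6) estimated above 1
  cur <- e[e$factor == "smoking" & e$category == "current", ]
  expect_true(all(cur$value > 1))
})

test_that("odds-ratio recovery error shrinks with sample size", {
  p <- default_params()
  err <- sapply(c(5000, 50000), function(n) {
    rec <- generate_survey(p, n, seed = 101)
    est <- estimate_odds_ratios(rec, "gali", p$defs)
    e <- est$entries
    e <- e[e$spec_kind == "stratified", ]
    tr <- p$effects$gali$entries
    d <- merge(e, tr, by = c("sex", "factor", "category", "stratum"))
    mean(abs(log(d$value.x) - log(d$value.y)))
  })
  expect_lt(err[2], err[1])
})

test_that("odds-ratio estimation validates its inputs", {
  p <- default_params()
  rec <- generate_survey(p, 1500, seed = 111)
  expect_error(estimate_odds_ratios(rec[1:500, ], "gali", p$defs),
               "at least 1000")
  rec2 <- rec
  rec2$gali_limited <- 0L
  expect_error(estimate_odds_ratios(rec2, "gali", p$defs), "outcome levels")
})

test_that("effect tables round-trip through CSV", {
  p <- default_params()
  path <- withr::local_tempfile(fileext = ".csv")
  write_effect_table(p$effects$gali, path)
  back <- read_effect_table(path)
  expect_equal(back$outcome, "gali")
  expect_equal(back$apply_from_age, 50L)
  for (sx in c("female", "male")) {
    expect_equal(
      effect_at(back, "alcohol", "none", sx, 50:100),
      effect_at(p$effects$gali, "alcohol", "none", sx, 50:100))
    expect_equal(
      effect_at(back, "smoking", "current", sx, 50:100),
      effect_at(p$effects$gali, "smoking", "current", sx, 50:100))
  }
})
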