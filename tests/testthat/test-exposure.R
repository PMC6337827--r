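test_that("joint exposure multiplies marginals cell by cell", {
  defs <- lifestyle_factors()
  comp <- composite_categories(defs)

  # degenerate bmi/alcohol marginals: the smoking marginal is carried
  # onto the single active slice
  p <- joint_exposure(c(.5, .3, .2), c(1, 0, 0), c(1, 0, 0, 0), defs)
  active <- comp$i_bmi == 1 & comp$i_alcohol == 1
  expect_equal(unname(p[active]), c(.5, .3, .2))
  expect_true(all(p[!active] == 0))

  # hand product and brute-force triple loop over all 36 cells
  ps <- c(.5, .3, .2); pb <- c(.4, .4, .2); pa <- rep(.25, 4)
  p <- joint_exposure(ps, pb, pa, defs)
  expect_equal(unname(p[comp$smoking == "current" & comp$bmi == "bmi_gt30" &
                          comp$alcohol == "high"]), 0.2 * 0.2 * 0.25)
  brute <- numeric(36)
  for (i in 1:36) {
    brute[i] <- ps[comp$i_smoking[i]] * pb[comp$i_bmi[i]] * pa[comp$i_alcohol[i]]
  }
  expect_equal(unname(p), brute)

  # uniform marginals: all cells 1/36
  p <- joint_exposure(rep(1/3, 3), rep(1/3, 3), rep(1/4, 4), defs)
  expect_equal(unname(p), rep(1/36, 36))

  expect_error(joint_exposure(c(.7, .2, .2), pb, pa, defs), "simplex")
  expect_error(joint_exposure(c(.5, .5), pb, pa, defs), "length")
})

test_that("marginalizing the joint recovers the inputs exactly", {
  defs <- lifestyle_factors()
  set.seed(61)
  for (i in 1:25) {
    ps <- rsimplex(3); pb <- rsimplex(3); pa <- rsimplex(4)
    p <- joint_exposure(ps, pb, pa, defs)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_lt(max(abs(marginalize_joint(p, "smoking", defs) - ps)), 1e-12)
    expect_lt(max(abs(marginalize_joint(p, "bmi", defs) - pb)), 1e-12)
    expect_lt(max(abs(marginalize_joint(p, "alcohol", defs) - pa)), 1e-12)
  }
})

test_that("degenerate single-category survey yields an indicator", {
  rec <- data.frame(country = rep(c("A", "B"), each = 50),
                    sex = "female", age = rep(50:74, 4),
                    smoking = "ex", stringsAsFactors = FALSE)
  expect_warning(
    est <- estimate_marginal_prevalence(rec, "smoking", ages = 50:74),
    "never observed")
  ex <- est$prevalence[est$category == "ex"]
  expect_true(all(abs(ex - 1) < 1e-6))
  expect_true(all(est$prevalence[est$category != "ex"] < 1e-6))
})

test_that("country-specific age slopes are recovered in direction", {
  # country A: flat current-smoking logit; country B: strongly increasing
  set.seed(71)
  n <- 20000
  cty <- sample(c("A", "B"), n, replace = TRUE)
  age <- sample(50:100, n, replace = TRUE)
  eta <- ifelse(cty == "A", -1, -3 + 0.04 * age)
  pr <- exp(eta) / (1 + exp(eta))
  smoking <- ifelse(runif(n) < pr, "current", "never")
  rec <- data.frame(country = cty, sex = "female", age = age,
                    smoking = smoking, stringsAsFactors = FALSE)
  expect_warning(est <- estimate_marginal_prevalence(rec, "smoking",
                                                     ages = 50:100),
                 "never observed")  # nobody is an ex-smoker here
  cur <- est[est$category == "current", ]
  slope <- function(ct) {
    d <- cur[cur$country == ct, ]
    d$prevalence[d$age == 95] - d$prevalence[d$age == 55]
  }
  expect_gt(slope("B"), slope("A") + 0.1)
  # every predicted age is a simplex
  sums <- tapply(est$prevalence, paste(est$country, est$age), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("prevalence estimates are invariant to record order", {
  p <- default_generator_params()
  rec <- generate_survey(p, 4000, seed = 81, countries = c("East-A", "West-A"),
                         age_dist = "uniform")
  est1 <- estimate_marginal_prevalence(rec, "bmi", ages = 50:100)
  set.seed(82)
  est2 <- estimate_marginal_prevalence(rec[sample(nrow(rec)), ], "bmi",
                                       ages = 50:100)
  expect_equal(est1$prevalence, est2$prevalence, tolerance = 1e-6)
})

test_that("band smoothing reproduces constants and lines", {
  cats <- c("a", "b", "c")
  mids <- c(52, 57, 62, 67, 72, 77)

  # constant bands -> constant single ages
  g <- data.frame(age = rep(mids, 3), category = rep(cats, each = 6),
                  prevalence = rep(c(0.6, 0.3, 0.1), each = 6))
  s <- smooth_to_single_ages(g, ages = 52:77)
  for (i in seq_along(cats)) {
    expect_equal(s$prevalence[s$category == cats[i]],
                 rep(c(0.6, 0.3, 0.1)[i], 26), tolerance = 1e-8)
  }

  # linear bands -> the line at interior ages
  p_a <- 0.2 + 0.004 * (mids - 52)
  g <- data.frame(age = rep(mids, 2), category = rep(c("a", "b"), each = 6),
                  prevalence = c(p_a, 1 - p_a))
  s <- smooth_to_single_ages(g, ages = 55:75)
  truth <- 0.2 + 0.004 * (55:75 - 52)
  expect_lt(max(abs(s$prevalence[s$category == "a"] - truth)), 1e-6)

  # simplex at every output age
  sums <- tapply(s$prevalence, s$age, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("band smoothing ignores duplicated bands and needs >= 3", {
  mids <- c(52, 62, 72, 82)
  g <- data.frame(age = rep(mids, 2), category = rep(c("a", "b"), each = 4),
                  prevalence = c(.3, .35, .32, .4, .7, .65, .68, .6))
  s1 <- smooth_to_single_ages(g, ages = 52:82)
  s2 <- smooth_to_single_ages(rbind(g, g[g$age == 62, ]), ages = 52:82)
  expect_equal(s1, s2)
  expect_error(smooth_to_single_ages(g[g$age < 60, ], ages = 52:82),
               "at least 3")
})
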