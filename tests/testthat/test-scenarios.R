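ages5 <- 50:54

# A constant-in-age marginal matrix for smoking
const_marg <- function(p, ages = ages5) {
  matrix(rep(p, each = length(ages)), length(ages), length(p))
}

rr_increasing <- effect_table(
  data.frame(sex = "female", factor = "smoking",
             category = c("ex", "current"), spec_kind = "constant",
             stratum = NA_character_, value = c(1.3, 2.0),
             slope = NA_real_),
  outcome = "mortality", effect_kind = "RR", apply_from_age = 0L)

test_that("best-observed selection picks the dominant country", {
  mA <- marginal_df(const_marg(c(0.8, 0.1, 0.1)), "smoking", "female", ages5, "A")
  mB <- marginal_df(const_marg(c(0.6, 0.2, 0.2)), "smoking", "female", ages5, "B")
  best <- best_observed_marginal(rbind(mA, mB), "smoking", rr_increasing)
  expect_true(all(best$donor == "A"))
  expect_equal(best$prevalence[best$category == "never"], rep(0.8, 5))
  # tie: alphabetically first country wins
  mB2 <- marginal_df(const_marg(c(0.8, 0.1, 0.1)), "smoking", "female", ages5, "B")
  best <- best_observed_marginal(rbind(mA, mB2), "smoking", rr_increasing)
  expect_true(all(best$donor == "A"))
  expect_error(best_observed_marginal(mA[0, ], "smoking", rr_increasing),
               "no marginal|empty")
})

test_that("best-observed switches donor where prevalences cross age", {
  ages <- 50:70
  # healthy share rises with age in A, falls in B; they cross at age 60
  pA <- 0.5 + 0.01 * (ages - 60)
  pB <- 0.5 - 0.01 * (ages - 60)
  mk <- function(p, cty) {
    M <- cbind(p, (1 - p) * 0.6, (1 - p) * 0.4)
    marginal_df(M, "smoking", "female", ages, cty)
  }
  marg <- rbind(mk(pA, "A"), mk(pB, "B"))
  best <- best_observed_marginal(marg, "smoking", rr_increasing)
  # brute force: enumerate both countries at each age
  rr_vec <- c(1, 1.3, 2.0)
  for (i in seq_along(ages)) {
    wA <- sum(c(pA[i], (1 - pA[i]) * 0.6, (1 - pA[i]) * 0.4) * rr_vec)
    wB <- sum(c(pB[i], (1 - pB[i]) * 0.6, (1 - pB[i]) * 0.4) * rr_vec)
    want <- if (wA < wB || (wA == wB)) "A" else "B"
    expect_equal(best$donor[best$age == ages[i]][1], want)
  }
  expect_setequal(unique(best$donor), c("A", "B"))
})

test_that("max-healthy-share criterion is available", {
  # A has more never-smokers but also far more current (vs ex) smokers,
  # so the two criteria can disagree
  mA <- marginal_df(const_marg(c(0.55, 0.05, 0.40)), "smoking", "female",
                    ages5, "A")
  mB <- marginal_df(const_marg(c(0.50, 0.40, 0.10)), "smoking", "female",
                    ages5, "B")
  best_rr <- best_observed_marginal(rbind(mA, mB), "smoking", rr_increasing,
                                    criterion = "min_weighted_rr")
  best_h <- best_observed_marginal(rbind(mA, mB), "smoking", rr_increasing,
                                   criterion = "max_healthy_share")
  expect_true(all(best_rr$donor == "B"))
  expect_true(all(best_h$donor == "A"))
})

test_that("scenario exposure realises the per-factor modes", {
  st <- default_study()
  defs <- st$defs
  ages <- st$ages
  marg <- st$marginals[st$marginals$country == "East-A", ]
  comp <- composite_categories(defs)

  ref <- build_scenario_exposure(scenario_spec("reference"), marg,
                                 defs = defs, sex = "female", ages = ages)
  # reference equals the country's baseline joint, cell by cell
  base <- joint_matrix(
    healthgains:::marginal_matrix(marg, "smoking", "female", ages, defs),
    healthgains:::marginal_matrix(marg, "bmi", "female", ages, defs),
    healthgains:::marginal_matrix(marg, "alcohol", "female", ages, defs),
    comp)
  expect_equal(unname(ref), unname(base))

  # positive-all: point mass on the all-healthy composite cell
  pos <- build_scenario_exposure(standard_scenarios()$positive_all, marg,
                                 defs = defs, sex = "female", ages = ages)
  healthy_cell <- which(comp$i_smoking == defs$smoking$healthy_index &
                          comp$i_bmi == defs$bmi$healthy_index &
                          comp$i_alcohol == defs$alcohol$healthy_index)
  expect_true(all(pos[, healthy_cell] == 1))
  expect_true(all(pos[, -healthy_cell] == 0))

  # positive-smoking: smoking collapsed to never, bmi/alcohol untouched
  ps <- build_scenario_exposure(standard_scenarios()$positive_smoking, marg,
                                defs = defs, sex = "female", ages = ages)
  for (a in c(1, 51, 101)) {
    sm <- marginalize_joint(ps[a, ], "smoking", defs)
    expect_equal(unname(sm), c(1, 0, 0))
    expect_equal(marginalize_joint(ps[a, ], "bmi", defs),
                 marginalize_joint(base[a, ], "bmi", defs), tolerance = 1e-12)
    expect_equal(marginalize_joint(ps[a, ], "alcohol", defs),
                 marginalize_joint(base[a, ], "alcohol", defs),
                 tolerance = 1e-12)
  }

  # best_observed without best marginals is an error
  expect_error(build_scenario_exposure(standard_scenarios()$best_of_all, marg,
                                       defs = defs, sex = "female",
                                       ages = ages),
               "best-observed")
})

test_that("reference scenario yields exactly zero gains", {
  out <- default_outcomes()
  ref <- out[out$scenario == "reference", ]
  expect_true(all(ref$gain_le == 0))
  expect_true(all(ref$gain_hly == 0))
  expect_true(all(ref$gain_legph == 0))
  expect_true(all(is.finite(out$gain_hly)))
  expect_true(all(out$hly <= out$le + 1e-12))
  expect_true(all(out$legph <= out$le + 1e-12))
})

test_that("null effects make every scenario reproduce the baseline", {
  st <- default_study()
  cty <- "West-A"
  out <- run_scenario(
    demography = st$demography[st$demography$country == cty, ],
    health_prev = st$health_prev[st$health_prev$country == cty, ],
    marginals = st$marginals[st$marginals$country == cty, ],
    specs = standard_scenarios()[c("positive_all", "positive_smoking")],
    effects = null_effects(),
    best_marginals = NULL, ages = st$ages, country = cty)
  expect_lt(max(abs(out$gain_le)), 1e-12)
  expect_lt(max(abs(out$gain_hly)), 1e-12)
  expect_lt(max(abs(out$gain_legph)), 1e-12)
})

test_that("regional pooling is a population-weighted mean", {
  base <- data.frame(sex = "female", scenario = "reference", at_age = 0,
                     le = 0, legph = 0, gain_le = 0, gain_hly = 0,
                     gain_legph = 0)
  outcomes <- rbind(cbind(country = "A", base, hly = 10),
                    cbind(country = "B", base, hly = 20),
                    cbind(country = "C", base, hly = 33))
  pops <- data.frame(country = c("A", "B", "C"), population = c(1, 3, 9))
  rm <- list(ab = c("A", "B"), c = "C")
  pooled <- pool_regions(outcomes, pops, rm)
  expect_equal(pooled$hly[pooled$region == "ab"], 17.5)
  # single-country region: identity
  expect_equal(pooled$hly[pooled$region == "c"], 33)
  # equal weights reduce to the simple mean
  pops2 <- data.frame(country = c("A", "B", "C"), population = c(2, 2, 2))
  pooled2 <- pool_regions(outcomes, pops2, rm)
  expect_equal(pooled2$hly[pooled2$region == "ab"], mean(c(10, 20)))
  expect_error(pool_regions(outcomes[outcomes$country != "B", ], pops, rm),
               "missing.*B")
  expect_error(pool_regions(outcomes, pops, list(x = c("A", "B"), y = "A")),
               "duplicated")
})
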