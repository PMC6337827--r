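#' Counterfactual lifestyle scenario
#'
#' A scenario assigns each factor one of three modes:
#' \describe{
#'   \item{`as_observed`}{the country's own marginal prevalences;}
#'   \item{`best_observed`}{the most favourable marginal observed among all
#'     modelled countries at each sex and age (see
#'     [best_observed_marginal()]);}
#'   \item{`all_healthy`}{everyone in the designated healthy category.}
#' }
#' The reference scenario is all factors `as_observed`.
#'
#' @param name Scenario name.
#' @param smoking,bmi,alcohol Mode per factor.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, smoking = "as_observed", bmi = "as_observed",
                          alcohol = "as_observed") {
  modes <- c("as_observed", "best_observed", "all_healthy")
  spec <- list(name = name,
               smoking = match.arg(smoking, modes),
               bmi = match.arg(bmi, modes),
               alcohol = match.arg(alcohol, modes))
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario '%s': smoking=%s, bmi=%s, alcohol=%s>\n",
              x$name, x$smoking, x$bmi, x$alcohol))
  invisible(x)
}

#' The standard scenario set
#'
#' Reference; best-of-all (healthy example country, per factor/sex/age);
#' positive-all (ideal world, 100% healthy in all three factors); and the
#' three single-factor positive scenarios.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
standard_scenarios <- function() {
  list(
    reference = scenario_spec("reference"),
    best_of_all = scenario_spec("best_of_all", "best_observed",
                                "best_observed", "best_observed"),
    positive_all = scenario_spec("positive_all", "all_healthy",
                                 "all_healthy", "all_healthy"),
    positive_smoking = scenario_spec("positive_smoking", smoking = "all_healthy"),
    positive_bmi = scenario_spec("positive_bmi", bmi = "all_healthy"),
    positive_alcohol = scenario_spec("positive_alcohol", alcohol = "all_healthy")
  )
}

#' Paper-style European region map
#'
#' The 26-country grouping into four regions used for pooling:
#' Central-East and Eastern Europe (10), Nordic countries (3), Central-West
#' and Western Europe (7), Southern Europe (6).
#'
#' @return Named list of country-name character vectors.
#' @export
eu_region_map <- function() {
  list(
    east = c("Bulgaria", "Czech Republic", "Estonia", "Hungary", "Latvia",
             "Lithuania", "Poland", "Romania", "Slovakia", "Slovenia"),
    north = c("Denmark", "Finland", "Sweden"),
    west = c("Austria", "Belgium", "France", "Germany", "Ireland",
             "Netherlands", "UK"),
    south = c("Cyprus", "Greece", "Italy", "Malta", "Spain", "Portugal")
  )
}

#' Most favourable observed marginal, per sex and age
#'
#' For each (sex, age), selects among the modelled countries the marginal
#' distribution of the factor that is most favourable, and returns that
#' country's full category vector. "Most favourable" defaults to the
#' minimal exposure-weighted mortality relative risk
#' `sum(p_c * rr_c)` (criterion `"min_weighted_rr"`); the alternative
#' `"max_healthy_share"` picks the largest healthy-category share. Ties go
#' to the alphabetically first country. Donor countries may differ by age.
#'
#' @param marginals Long data frame `country`, `sex`, `age`, `factor`,
#'   `category`, `prevalence` covering >= 2 countries.
#' @param factor Factor name.
#' @param rr Mortality [effect_table()] (used by `"min_weighted_rr"`).
#' @param defs Factor definitions.
#' @param criterion Selection criterion.
#' @param ages,sexes Cells to cover (defaults: all present in `marginals`).
#' @return Long data frame `sex`, `age`, `category`, `prevalence`, `donor`.
#' @export
best_observed_marginal <- function(marginals, factor, rr,
                                   defs = lifestyle_factors(),
                                   criterion = c("min_weighted_rr",
                                                 "max_healthy_share"),
                                   ages = NULL, sexes = NULL) {
  criterion <- match.arg(criterion)
  countries <- sort(unique(as.character(marginals$country)))
  if (length(countries) < 1L) stop("empty country set", call. = FALSE)
  if (is.null(ages)) ages <- sort(unique(marginals$age))
  if (is.null(sexes)) sexes <- sort(unique(as.character(marginals$sex)))
  cats <- defs[[factor]]$categories
  out <- list()
  for (sx in sexes) {
    mats <- lapply(countries, function(cty) {
      marginal_matrix(marginals, factor, sx, ages, defs, country = cty)
    })
    if (criterion == "min_weighted_rr") {
      rrM <- vapply(cats, function(ct) effect_at(rr, factor, ct, sx, ages,
                                                 max_age = max(ages)),
                    numeric(length(ages)))
      scores <- vapply(mats, function(M) rowSums(M * rrM),
                       numeric(length(ages)))
      pick <- apply(scores, 1L, which.min)  # ties: first = alphabetical
    } else {
      h <- defs[[factor]]$healthy_index
      shares <- vapply(mats, function(M) M[, h], numeric(length(ages)))
      pick <- apply(-shares, 1L, which.min)
    }
    sel <- t(vapply(seq_along(ages), function(i) mats[[pick[i]]][i, ],
                    numeric(length(cats))))
    out[[sx]] <- data.frame(
      sex = sx, age = rep(ages, length(cats)),
      factor = factor, category = rep(cats, each = length(ages)),
      prevalence = as.vector(sel),
      donor = rep(countries[pick], length(cats)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint exposure under a scenario, for one sex
#'
#' Realises a scenario's per-factor modes — the country's own marginal,
#' the best observed marginal, or a point mass on the healthy category —
#' and combines them multiplicatively into the 36-category joint exposure.
#'
#' @param spec A [scenario_spec()].
#' @param country_marginals Long marginal data frame for one country
#'   (columns `sex`, `age`, `factor`, `category`, `prevalence`).
#' @param best_marginals Named list (by factor) of
#'   [best_observed_marginal()] outputs; required iff the spec uses
#'   `best_observed`.
#' @param defs Factor definitions.
#' @param sex,ages Cell coverage.
#' @return Matrix `length(ages) x 36` of joint probabilities (rows sum to
#'   1), columns ordered as [composite_categories()].
#' @export
build_scenario_exposure <- function(spec, country_marginals,
                                    best_marginals = NULL,
                                    defs = lifestyle_factors(),
                                    sex, ages) {
  stopifnot(inherits(spec, "scenario_spec"))
  comp <- composite_categories(defs)
  one_factor <- function(f) {
    mode <- spec[[f]]
    cats <- defs[[f]]$categories
    if (mode == "as_observed") {
      marginal_matrix(country_marginals, f, sex, ages, defs)
    } else if (mode == "all_healthy") {
      M <- matrix(0, length(ages), length(cats),
                  dimnames = list(ages, cats))
      M[, defs[[f]]$healthy_index] <- 1
      M
    } else {
      if (is.null(best_marginals[[f]])) {
        stop(sprintf("scenario '%s' needs best-observed marginals for '%s'",
                     spec$name, f), call. = FALSE)
      }
      marginal_matrix(best_marginals[[f]], f, sex, ages, defs)
    }
  }
  P <- joint_matrix(one_factor("smoking"), one_factor("bmi"),
                    one_factor("alcohol"), comp)
  dimnames(P) <- list(ages, comp$label)
  P
}

# ---- scenario engine --------------------------------------------------------

# Decompose one country-sex cell into category rates and prevalences.
# Returns ages x 36 matrices (rates, pi_gali, pi_sph) plus baseline schedules.
baseline_decomposition <- function(demography, health_prev, marginals,
                                   effects, sex, ages,
                                   defs = lifestyle_factors()) {
  comp <- composite_categories(defs)
  dem <- demography[demography$sex == sex, , drop = FALSE]
  dem <- dem[match(ages, dem$age), , drop = FALSE]
  if (anyNA(dem$deaths) || anyNA(dem$population)) {
    stop(sprintf("demography does not cover ages %d-%d for sex %s",
                 min(ages), max(ages), sex), call. = FALSE)
  }
  hp <- health_prev[health_prev$sex == sex, , drop = FALSE]
  hp <- hp[match(ages, hp$age), , drop = FALSE]
  if (anyNA(hp$gali) || anyNA(hp$sph)) {
    stop(sprintf("health-state prevalences do not cover ages for sex %s", sex),
         call. = FALSE)
  }
  P <- build_scenario_exposure(scenario_spec("reference"), marginals,
                               defs = defs, sex = sex, ages = ages)
  RR <- resolve_composite_effects(effects$mortality, sex, ages, defs, comp)
  ORg <- resolve_composite_effects(effects$gali, sex, ages, defs, comp)
  ORs <- resolve_composite_effects(effects$sph, sex, ages, defs, comp)
  m_agg <- dem$deaths / dem$population
  n36 <- nrow(comp)
  rates <- matrix(NA_real_, length(ages), n36)
  pg <- matrix(NA_real_, length(ages), n36)
  ps <- matrix(NA_real_, length(ages), n36)
  for (i in seq_along(ages)) {
    rates[i, ] <- decompose_mortality(m_agg[i], P[i, ], RR[i, ])$rates
    pg[i, ] <- invert_prevalence(hp$gali[i], P[i, ], ORg[i, ])$prev
    ps[i, ] <- invert_prevalence(hp$sph[i], P[i, ], ORs[i, ])$prev
  }
  list(exposure = P, rates = rates, pi_gali = pg, pi_sph = ps,
       m_agg = m_agg, or_gali = ORg, or_sph = ORs)
}

# Outcomes at reporting ages from category schedules + a scenario exposure.
outcomes_from_categories <- function(base, P_new, ages, at_ages,
                                     ax = 0.5, radix = 1e5) {
  n <- length(ages)
  m_new <- numeric(n)
  pg_new <- numeric(n)
  ps_new <- numeric(n)
  for (i in seq_len(n)) {
    m_new[i] <- counterfactual_mortality(base$rates[i, ], P_new[i, ])
    pg_new[i] <- sum(P_new[i, ] * base$pi_gali[i, ])
    ps_new[i] <- sum(P_new[i, ] * base$pi_sph[i, ])
  }
  lt <- life_table_from_rates(m_new, ages = ages, ax = ax, radix = radix)
  do.call(rbind, lapply(at_ages, function(a) {
    health_expectancy(lt, pg_new, ps_new, at_age = a)
  }))
}

#' Run scenarios for one country
#'
#' Full chain for one country: baseline joint exposure, attributable
#' mortality decomposition and odds-ratio prevalence inversion per age and
#' sex, scenario exposure, counterfactual aggregate rates and prevalences,
#' a fresh life table (so competing risks are handled consistently), and
#' Sullivan health expectancies. Gains are computed against the reference
#' scenario, which is always run.
#'
#' @param demography Data frame `sex`, `age`, `deaths`, `population` for
#'   the country.
#' @param health_prev Data frame `sex`, `age`, `gali`, `sph` (aggregate
#'   unhealthy-state prevalences).
#' @param marginals Long marginal data frame for the country (`sex`,
#'   `age`, `factor`, `category`, `prevalence`).
#' @param specs A [scenario_spec()] or list of them.
#' @param effects Named list of [effect_table()]s: `mortality`, `gali`,
#'   `sph`.
#' @param best_marginals Named list (by factor) from
#'   [best_observed_marginal()], required for `best_observed` modes.
#' @param defs Factor definitions.
#' @param ages Model span (last age open).
#' @param at_ages Reporting ages for LE/HLY/LEGPH.
#' @param country Country label carried into the result.
#' @param ax,radix Life-table conventions; see [build_life_table()].
#' @return Data frame `country`, `sex`, `scenario`, `at_age`, `le`, `hly`,
#'   `legph`, `gain_le`, `gain_hly`, `gain_legph` (gains in years vs the
#'   reference scenario).
#' @export
run_scenario <- function(demography, health_prev, marginals, specs, effects,
                         best_marginals = NULL, defs = lifestyle_factors(),
                         ages = 0:100, at_ages = c(0, 50, 65),
                         country = "country", ax = 0.5, radix = 1e5) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (!any(vapply(specs, function(s) s$name == "reference", logical(1)))) {
    specs <- c(list(reference = scenario_spec("reference")), specs)
  }
  sexes <- sort(unique(as.character(demography$sex)))
  out <- list()
  for (sx in sexes) {
    base <- tryCatch(
      baseline_decomposition(demography, health_prev, marginals, effects,
                             sx, ages, defs),
      error = function(e) {
        stop(sprintf("country %s, sex %s: %s", country, sx, conditionMessage(e)),
             call. = FALSE)
      })
    ref <- NULL
    for (spec in specs) {
      P_new <- build_scenario_exposure(spec, marginals, best_marginals,
                                       defs, sx, ages)
      he <- outcomes_from_categories(base, P_new, ages, at_ages, ax, radix)
      he$country <- country
      he$sex <- sx
      he$scenario <- spec$name
      if (spec$name == "reference") ref <- he
      out[[paste(sx, spec$name)]] <- he
    }
    for (nm in names(out)) {
      if (!startsWith(nm, paste0(sx, " "))) next
      he <- out[[nm]]
      he$gain_le <- he$le - ref$le
      he$gain_hly <- he$hly - ref$hly
      he$gain_legph <- he$legph - ref$legph
      out[[nm]] <- he
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("country", "sex", "scenario", "at_age", "le", "hly", "legph",
          "gain_le", "gain_hly", "gain_legph")]
}

#' Run scenarios for every country in a study
#'
#' Computes the best-observed marginals once across all countries (when
#' any scenario needs them), then runs [run_scenario()] per country.
#'
#' @param study A study list as produced by [synthetic_study()] or
#'   [read_study()]: elements `demography`, `health_prev`, `marginals`
#'   (all with a `country` column), `effects`, `defs`, `ages`.
#' @param specs List of [scenario_spec()]s (default
#'   [standard_scenarios()]).
#' @param at_ages Reporting ages.
#' @param criterion Best-observed selection criterion; see
#'   [best_observed_marginal()].
#' @param verbose Log per-country progress to stderr.
#' @return Row-bound [run_scenario()] results for all countries.
#' @export
run_study <- function(study, specs = standard_scenarios(),
                      at_ages = c(0, 50, 65),
                      criterion = c("min_weighted_rr", "max_healthy_share"),
                      verbose = FALSE) {
  criterion <- match.arg(criterion)
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  defs <- study$defs
  ages <- study$ages
  needs_best <- any(vapply(specs, function(s) {
    any(unlist(s[c("smoking", "bmi", "alcohol")]) == "best_observed")
  }, logical(1)))
  best <- NULL
  if (needs_best) {
    best <- lapply(stats::setNames(nm = c("smoking", "bmi", "alcohol")),
                   function(f) {
                     best_observed_marginal(study$marginals, f,
                                            study$effects$mortality, defs,
                                            criterion = criterion,
                                            ages = ages)
                   })
  }
  countries <- sort(unique(as.character(study$demography$country)))
  out <- lapply(countries, function(cty) {
    if (verbose) message("running scenarios for ", cty)
    run_scenario(
      demography = study$demography[study$demography$country == cty, ],
      health_prev = study$health_prev[study$health_prev$country == cty, ],
      marginals = study$marginals[study$marginals$country == cty, ],
      specs = specs, effects = study$effects, best_marginals = best,
      defs = defs, ages = ages, at_ages = at_ages, country = cty)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pool country outcomes into regions by population weight
#'
#' @param outcomes Output of [run_study()] / [run_scenario()].
#' @param populations Country weights: a data frame with columns `country`
#'   and `population`, or a named numeric vector. Typically the total
#'   mid-year population.
#' @param region_map Named list mapping region name to country vector
#'   (default [eu_region_map()]). Every mapped country must appear in
#'   `outcomes`.
#' @return Data frame `region`, `sex`, `scenario`, `at_age` with
#'   population-weighted means of the outcome and gain columns.
#' @export
pool_regions <- function(outcomes, populations, region_map = eu_region_map()) {
  if (is.data.frame(populations)) {
    w <- stats::setNames(populations$population, populations$country)
  } else {
    w <- populations
  }
  all_countries <- unlist(region_map)
  if (anyDuplicated(all_countries)) {
    stop("countries duplicated across regions", call. = FALSE)
  }
  missing <- setdiff(all_countries, unique(outcomes$country))
  if (length(missing)) {
    stop(sprintf("countries missing from outcomes: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(w[all_countries])) || any(w[all_countries] <= 0)) {
    stop("every mapped country needs a positive population weight",
         call. = FALSE)
  }
  value_cols <- c("le", "hly", "legph", "gain_le", "gain_hly", "gain_legph")
  value_cols <- intersect(value_cols, names(outcomes))
  out <- list()
  for (rg in names(region_map)) {
    d <- outcomes[outcomes$country %in% region_map[[rg]], , drop = FALSE]
    ww <- w[as.character(d$country)]
    keys <- interaction(d$sex, d$scenario, d$at_age, drop = TRUE)
    for (ky in levels(keys)) {
      sel <- keys == ky
      row <- data.frame(region = rg,
                        sex = d$sex[sel][1],
                        scenario = d$scenario[sel][1],
                        at_age = d$at_age[sel][1],
                        stringsAsFactors = FALSE)
      for (vc in value_cols) {
        row[[vc]] <- sum(d[[vc]][sel] * ww[sel]) / sum(ww[sel])
      }
      out[[paste(rg, ky)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$region, res$sex, res$scenario, res$at_age), ]
}
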