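# Shared fixtures, built once per test run (everything is generated in
# code; no stored data). Heavy objects are cached lazily.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

default_params <- function() fixture("params", default_generator_params())

default_study <- function() fixture("study", synthetic_study(default_params()))

default_outcomes <- function() {
  fixture("outcomes", run_study(default_study()))
}

# Effect tables in which every category is a reference category (all
# effects resolve to 1 at every age).
null_effects <- function() {
  e0 <- data.frame(sex = character(), factor = character(),
                   category = character(), spec_kind = character(),
                   stratum = character(), value = numeric(),
                   slope = numeric(), stringsAsFactors = FALSE)
  list(mortality = effect_table(e0, "mortality", "RR"),
       gali = effect_table(e0, "gali", "OR"),
       sph = effect_table(e0, "sph", "OR"))
}

# Random probability simplex
rsimplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Long marginal data frame for one factor from a per-age matrix
marginal_df <- function(M, factor, sex, ages, country = NULL,
                        defs = lifestyle_factors()) {
  cats <- defs[[factor]]$categories
  d <- data.frame(sex = sex, age = rep(ages, length(cats)), factor = factor,
                  category = rep(cats, each = length(ages)),
                  prevalence = as.vector(M), stringsAsFactors = FALSE)
  if (!is.null(country)) d <- cbind(country = country, d)
  d
}
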