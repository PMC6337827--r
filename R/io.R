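#' Write / read a study directory
#'
#' A study directory holds plain CSV tables: `demography.csv` (country,
#' sex, age, deaths, population), `health_prev.csv` (country, sex, age,
#' gali, sph), `marginals.csv` (country, sex, age, factor, category,
#' prevalence), one effect CSV per outcome
#' (`effects_mortality.csv`, `effects_gali.csv`, `effects_sph.csv`), and
#' `regions.yaml` (region map). For synthetic studies a `truth.yaml`
#' provenance record of the generator settings is written alongside.
#'
#' @param study A study list (see [synthetic_study()]).
#' @param dir Directory path (created if missing).
#' @return `write_study` returns `dir` invisibly; `read_study` returns a
#'   study list usable by [run_study()].
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$demography, file.path(dir, "demography.csv"),
                   row.names = FALSE)
  utils::write.csv(study$health_prev, file.path(dir, "health_prev.csv"),
                   row.names = FALSE)
  utils::write.csv(study$marginals, file.path(dir, "marginals.csv"),
                   row.names = FALSE)
  for (oc in names(study$effects)) {
    write_effect_table(study$effects[[oc]],
                       file.path(dir, sprintf("effects_%s.csv", oc)))
  }
  yaml::write_yaml(study$region_map, file.path(dir, "regions.yaml"))
  if (!is.null(study$params)) {
    pr <- study$params
    yaml::write_yaml(list(
      ages = range(pr$ages),
      countries = pr$countries,
      country_effects = pr$country_effects,
      m0 = pr$m0,
      o0 = lapply(pr$o0, as.list)
    ), file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  dem <- utils::read.csv(file.path(dir, "demography.csv"),
                         stringsAsFactors = FALSE)
  hp <- utils::read.csv(file.path(dir, "health_prev.csv"),
                        stringsAsFactors = FALSE)
  marg <- utils::read.csv(file.path(dir, "marginals.csv"),
                          stringsAsFactors = FALSE)
  effects <- lapply(stats::setNames(nm = c("mortality", "gali", "sph")),
                    function(oc) {
                      read_effect_table(file.path(dir,
                                                  sprintf("effects_%s.csv", oc)))
                    })
  region_map <- NULL
  rp <- file.path(dir, "regions.yaml")
  if (file.exists(rp)) region_map <- yaml::read_yaml(rp)
  pops <- stats::aggregate(population ~ country, data = dem, FUN = sum)
  list(demography = dem, health_prev = hp, marginals = marg,
       effects = effects, defs = lifestyle_factors(),
       ages = sort(unique(dem$age)), region_map = region_map,
       populations = pops)
}

#' Write a life table as CSV
#'
#' Seven standard columns (`mx`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`) plus
#' `age`.
#'
#' @param lt A `life_table`.
#' @param path Output file.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' Read country demography from a long CSV
#'
#' Expects columns `country`, `sex`, `age`, `deaths`, `population`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_demography <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "sex", "age", "deaths", "population")
  if (!all(need %in% names(d))) {
    stop(sprintf("demography CSV needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Run the full study pipeline and write tidy result tables
#'
#' End-to-end convenience used by the command-line wrapper: generates (or
#' reads) a study, runs the standard scenarios, pools regions by
#' population weight, and writes `outcomes.csv` (per country) and
#' `regional.csv` (pooled) plus `gains.csv` (long, one row per region /
#' sex / scenario / outcome measure) into `out_dir`. Fully deterministic
#' given the study and seed.
#'
#' @param study A study list, or `NULL` to generate the default synthetic
#'   study.
#' @param out_dir Output directory.
#' @param specs Scenarios (default [standard_scenarios()]).
#' @param at_ages Reporting ages.
#' @param seed Seed used when `study` is `NULL` and `noise != "none"`.
#' @param noise Noise mode for a generated study.
#' @param criterion Best-observed criterion.
#' @return Invisibly, a list with `outcomes` and `regional` data frames.
#' @export
write_study_outputs <- function(study = NULL, out_dir,
                                specs = standard_scenarios(),
                                at_ages = c(0, 50, 65), seed = 1L,
                                noise = "none",
                                criterion = "min_weighted_rr") {
  if (is.null(study)) {
    study <- synthetic_study(noise = noise, seed = seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outcomes <- run_study(study, specs = specs, at_ages = at_ages,
                        criterion = criterion)
  regional <- pool_regions(outcomes, study$populations, study$region_map)
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(regional, file.path(out_dir, "regional.csv"),
                   row.names = FALSE)
  long <- stats::reshape(
    regional[, c("region", "sex", "scenario", "at_age",
                 "gain_le", "gain_legph", "gain_hly")],
    direction = "long",
    varying = c("gain_le", "gain_legph", "gain_hly"),
    v.names = "gain_years",
    times = c("le", "legph", "hly"), timevar = "measure",
    idvar = c("region", "sex", "scenario", "at_age"))
  rownames(long) <- NULL
  utils::write.csv(long, file.path(out_dir, "gains.csv"), row.names = FALSE)
  invisible(list(outcomes = outcomes, regional = regional))
}
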