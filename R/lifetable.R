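#' Build a period life table from death and population counts
#'
#' Standard single-year period life table. Death rates are
#' `m_x = D_x / N_x`; death probabilities use the usual separation-factor
#' conversion `q_x = m_x / (1 + (1 - a_x) m_x)`; the last age is an open
#' interval closed with `L_omega = l_omega / m_omega` (i.e. the remaining
#' person-years of survivors to the open age under their current death
#' rate).
#'
#' @param deaths,population Death and mid-year population counts: either
#'   [age_schedule()] objects (role `"count"`) on the same span, or bare
#'   numeric vectors aligned with `ages`.
#' @param ages Integer ages of the model span (used when counts are bare
#'   vectors; default `0:100`, with the last age open).
#' @param sex Optional sex label carried through to the result.
#' @param ax Separation factor: average fraction of the year lived by those
#'   dying in the interval. A scalar (recycled) or one value per age.
#'   Default 0.5 at all ages, including age 0.
#' @param radix Number of survivors at the youngest age (`l_0`); all
#'   expectancies are invariant to it.
#' @return A `life_table`: a data frame with columns `age`, `mx`, `qx`,
#'   `lx`, `dx`, `Lx`, `Tx`, `ex` and attributes `sex`, `radix`, `ax`,
#'   `open_age`.
#' @examples
#' lt <- build_life_table(rep(20, 101), rep(1000, 101))
#' lt$ex[1]  # 50 years: constant hazard 0.02
#' @seealso [life_table_from_rates()], [sullivan()]
#' @export
build_life_table <- function(deaths, population, ages = 0:100, sex = NA,
                             ax = 0.5, radix = 1e5) {
  if (inherits(deaths, "age_schedule")) ages <- deaths$ages
  D <- as_schedule_values(deaths, ages, "count", "deaths")
  N <- as_schedule_values(population, ages, "count", "population")
  if (inherits(deaths, "age_schedule") && inherits(population, "age_schedule") &&
      !identical(deaths$ages, population$ages)) {
    stop("deaths and population cover different age spans", call. = FALSE)
  }
  if (any(N <= 0)) {
    stop(sprintf("population must be positive at every age (zero at age %d)",
                 ages[which(N <= 0)[1]]), call. = FALSE)
  }
  if (any(D < 0)) stop("death counts must be non-negative", call. = FALSE)
  life_table_from_rates(D / N, ages = ages, sex = sex, ax = ax, radix = radix)
}

#' Build a period life table from age-specific death rates
#'
#' @param mx Death rates (deaths per person-year): an [age_schedule()] or a
#'   numeric vector aligned with `ages`. The rate at the open last age must
#'   be positive (it closes the table).
#' @inheritParams build_life_table
#' @return A `life_table` data frame; see [build_life_table()].
#' @examples
#' life_table_from_rates(rep(0.01, 101))$ex[1]  # 100 years
#' @export
life_table_from_rates <- function(mx, ages = 0:100, sex = NA,
                                  ax = 0.5, radix = 1e5) {
  if (inherits(mx, "age_schedule")) {
    ages <- mx$ages
    if (is.na(sex)) sex <- mx$sex
  }
  m <- as_schedule_values(mx, ages, "rate", "mx")
  ages <- as.integer(ages)
  n <- length(ages)
  if (n < 2L || any(diff(ages) != 1L)) {
    stop("ages must be contiguous single years", call. = FALSE)
  }
  if (any(m < 0)) stop("death rates must be non-negative", call. = FALSE)
  if (m[n] <= 0) {
    stop(sprintf(
      "death rate at the open age %d must be positive to close the table",
      ages[n]), call. = FALSE)
  }
  a <- rep_len(ax, n)
  if (any(a < 0) || any(a > 1)) stop("ax must lie in [0, 1]", call. = FALSE)

  qx <- m / (1 + (1 - a) * m)
  qx[n] <- 1  # open interval: everyone reaching it dies within it
  lx <- radix * cumprod(c(1, 1 - qx[-n]))
  dx <- lx * qx
  Lx <- lx - (1 - a) * dx
  Lx[n] <- lx[n] / m[n]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx

  out <- data.frame(age = ages, mx = m, qx = qx, lx = lx, dx = dx,
                    Lx = Lx, Tx = Tx, ex = ex)
  structure(out, class = c("life_table", "data.frame"),
            sex = sex, radix = radix, ax = a, open_age = ages[n])
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Period life table, ages %d-%d (open), e_%d = %.2f years\n",
              x$age[1], attr(x, "open_age"), x$age[1], x$ex[1]))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE, ...)
  cat(sprintf("... %d more ages\n", nrow(x) - 5L))
  invisible(x)
}

#' Sullivan health expectancy
#'
#' Weights the life table's person-years by the age-specific proportion in
#' the healthy state: health expectancy at age `a` is
#' `(1 / l_a) * sum_{x >= a} L_x (1 - pi_x)` where `pi_x` is the prevalence
#' of the unhealthy state (activity limitation for HLY, less-than-good
#' self-perceived health for LEGPH).
#'
#' @param lt A `life_table` from [build_life_table()] or
#'   [life_table_from_rates()].
#' @param unhealthy_prev Prevalence of the unhealthy state: an
#'   [age_schedule()] (role `"prevalence"`) covering the life-table ages,
#'   or a numeric vector aligned with them.
#' @param at_age Age at which the expectancy is evaluated (default: the
#'   youngest table age).
#' @return Years expected in the healthy state (a scalar). Equals
#'   `lt$ex` at `at_age` when the prevalence is identically zero.
#' @examples
#' lt <- life_table_from_rates(rep(0.02, 101))
#' sullivan(lt, rep(0.25, 101))  # 37.5 years
#' @export
sullivan <- function(lt, unhealthy_prev, at_age = NULL) {
  stopifnot(inherits(lt, "life_table"))
  ages <- lt$age
  if (is.null(at_age)) at_age <- ages[1]
  if (!at_age %in% ages) {
    stop(sprintf("`at_age` %d is outside the life-table span %d-%d",
                 at_age, ages[1], ages[length(ages)]), call. = FALSE)
  }
  if (inherits(unhealthy_prev, "age_schedule")) {
    if (!all(ages %in% unhealthy_prev$ages)) {
      stop("prevalence schedule does not cover the life-table ages",
           call. = FALSE)
    }
    prev <- unhealthy_prev$values[match(ages, unhealthy_prev$ages)]
  } else {
    prev <- as_schedule_values(unhealthy_prev, ages, "prevalence",
                               "unhealthy_prev")
  }
  if (any(prev < 0) || any(prev > 1)) {
    stop("unhealthy-state prevalence must lie in [0, 1]", call. = FALSE)
  }
  # Summed tail-first so that pi = 0 reproduces Tx (hence ex) bit-for-bit.
  healthy_T <- rev(cumsum(rev(lt$Lx * (1 - prev))))
  i <- match(at_age, ages)
  healthy_T[i] / lt$lx[i]
}

#' Life expectancy and both health expectancies at one age
#'
#' Convenience wrapper returning LE together with the two Sullivan health
#' expectancies used throughout the pipeline: HLY (free of activity
#' limitation, GALI) and LEGPH (in good self-perceived health).
#'
#' @inheritParams sullivan
#' @param prev_gali Prevalence of activity limitation by age.
#' @param prev_sph Prevalence of less-than-good self-perceived health by age.
#' @return One-row data frame with columns `at_age`, `le`, `hly`, `legph`.
#' @export
health_expectancy <- function(lt, prev_gali, prev_sph, at_age = NULL) {
  if (is.null(at_age)) at_age <- lt$age[1]
  data.frame(
    at_age = at_age,
    le = lt$ex[match(at_age, lt$age)],
    hly = sullivan(lt, prev_gali, at_age),
    legph = sullivan(lt, prev_sph, at_age)
  )
}

#' Cohort microsimulation of mean lifespan
#'
#' Independent validation oracle for the deterministic life table: draws
#' individual deaths age by age from the table's `q_x`, assigns those dying
#' in `[x, x + 1)` a lifespan of `x + a_x`, and gives survivors reaching the
#' open age an exponentially distributed residual life with rate `m_omega`.
#' The mean lifespan estimates `e_0` with Monte Carlo error `se`.
#'
#' @param lt A `life_table`.
#' @param n Cohort size.
#' @return List with `mean`, `se` (standard error of the mean) and `n`.
#' @examples
#' lt <- life_table_from_rates(rep(0.02, 101))
#' set.seed(1)
#' microsim_life_expectancy(lt, n = 20000)
#' @export
microsim_life_expectancy <- function(lt, n = 200000) {
  stopifnot(inherits(lt, "life_table"), n >= 1)
  ages <- lt$age
  k <- length(ages)
  a <- attr(lt, "ax")
  alive <- as.integer(n)
  deaths_by_age <- integer(k - 1L)
  for (i in seq_len(k - 1L)) {
    d <- stats::rbinom(1L, alive, lt$qx[i])
    deaths_by_age[i] <- d
    alive <- alive - d
  }
  lifespans <- c(rep(ages[-k] + a[-k], deaths_by_age),
                 if (alive > 0) ages[k] + stats::rexp(alive, rate = lt$mx[k]))
  list(mean = mean(lifespans),
       se = stats::sd(lifespans) / sqrt(n),
       n = as.integer(n))
}
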