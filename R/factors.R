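#' Define a lifestyle risk factor
#'
#' @param name Factor name: `"smoking"`, `"bmi"` or `"alcohol"`.
#' @param categories Ordered category labels (3 for smoking and BMI, 4 for
#'   alcohol).
#' @param healthy_index Index of the designated healthy category — the one
#'   a "100% healthy" scenario assigns everyone to, and the reference
#'   category of the effect tables.
#' @param cutoffs Optional named list of numeric category boundaries (grams
#'   of alcohol per day, sex-specific for alcohol). Informational only:
#'   categorisation of raw quantities is done upstream of this package.
#' @return A `factor_def` object.
#' @export
factor_def <- function(name = c("smoking", "bmi", "alcohol"), categories,
                       healthy_index, cutoffs = NULL) {
  name <- match.arg(name)
  expected <- c(smoking = 3L, bmi = 3L, alcohol = 4L)[[name]]
  if (length(categories) != expected) {
    stop(sprintf("`%s` must have %d categories", name, expected),
         call. = FALSE)
  }
  healthy_index <- as.integer(healthy_index)
  if (healthy_index < 1L || healthy_index > length(categories)) {
    stop("`healthy_index` out of range", call. = FALSE)
  }
  structure(list(name = name, categories = as.character(categories),
                 healthy_index = healthy_index, cutoffs = cutoffs),
            class = "factor_def")
}

#' Default lifestyle factor definitions
#'
#' Smoking: never / ex / current (healthy: never). BMI: below 25 (includes
#' underweight) / 25 to 30 / above 30 (healthy: below 25). Alcohol: four
#' consumption levels by grams of alcohol per day with sex-specific
#' boundaries (defaults: female 0 / <=20 / <=40 / >40; male
#' 0 / <=40 / <=60 / >60). The designated healthy alcohol category defaults
#' to `"moderate"`: with U-shaped health odds ratios, abstainers carry
#' higher odds of the unhealthy state than moderate drinkers, and the
#' healthy category must coincide with the effect reference for the ideal
#' scenario to be the all-reference population.
#'
#' @param alcohol_healthy_index Override for the alcohol healthy category
#'   (1 = none, 2 = moderate).
#' @param alcohol_cutoffs Named list with numeric upper bounds (g/day) for
#'   the first three categories, per sex.
#' @return Named list of three [factor_def()] objects.
#' @export
lifestyle_factors <- function(alcohol_healthy_index = 2L,
                              alcohol_cutoffs = list(female = c(0, 20, 40),
                                                     male = c(0, 40, 60))) {
  list(
    smoking = factor_def("smoking", c("never", "ex", "current"), 1L),
    bmi = factor_def("bmi", c("bmi_lt25", "bmi_25_30", "bmi_gt30"), 1L),
    alcohol = factor_def("alcohol", c("none", "moderate", "high", "very_high"),
                         alcohol_healthy_index, cutoffs = alcohol_cutoffs)
  )
}

#' Composite 36-category index
#'
#' The joint risk factor combines smoking x BMI x alcohol into 36 composite
#' categories. Cells are ordered with smoking varying slowest and alcohol
#' fastest; the same ordering is used everywhere a length-36 vector appears.
#'
#' @param defs Factor definitions from [lifestyle_factors()].
#' @return Data frame with 36 rows: integer indices `i_smoking`, `i_bmi`,
#'   `i_alcohol`, labels `smoking`, `bmi`, `alcohol`, and `label`
#'   (dot-separated).
#' @export
composite_categories <- function(defs = lifestyle_factors()) {
  ks <- length(defs$smoking$categories)
  kb <- length(defs$bmi$categories)
  ka <- length(defs$alcohol$categories)
  g <- expand.grid(i_alcohol = seq_len(ka), i_bmi = seq_len(kb),
                   i_smoking = seq_len(ks))[, c("i_smoking", "i_bmi", "i_alcohol")]
  g$smoking <- defs$smoking$categories[g$i_smoking]
  g$bmi <- defs$bmi$categories[g$i_bmi]
  g$alcohol <- defs$alcohol$categories[g$i_alcohol]
  g$label <- paste(g$smoking, g$bmi, g$alcohol, sep = ".")
  rownames(g) <- NULL
  g
}
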