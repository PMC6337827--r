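#' Single-year age schedule
#'
#' A vector of values indexed by single year of age over a contiguous,
#' closed model span, for one sex. The same container carries mortality
#' rates (deaths per person-year), prevalences (proportions in \[0, 1\]),
#' population or death counts, or weights, depending on `role`.
#'
#' @param values Numeric vector, one value per age.
#' @param ages Integer vector of ages, contiguous and strictly increasing.
#'   Each age `x` labels the half-open interval `[x, x + 1)`; the last age
#'   is an open interval.
#' @param sex `"female"` or `"male"`, or `NA` when the schedule is sex-free.
#' @param role What the values are: `"rate"`, `"prevalence"`, `"count"` or
#'   `"weight"`. Prevalences must lie in \[0, 1\]; rates and counts must be
#'   non-negative.
#' @return An object of class `age_schedule`: a list with elements `ages`,
#'   `values`, `sex`, `role`.
#' @examples
#' age_schedule(rep(0.01, 101), 0:100, sex = "female", role = "rate")
#' @export
age_schedule <- function(values, ages, sex = NA_character_,
                         role = c("rate", "prevalence", "count", "weight")) {
  role <- match.arg(role)
  ages <- as.integer(ages)
  values <- as.numeric(values)
  if (length(values) != length(ages)) {
    stop("`values` and `ages` must have the same length", call. = FALSE)
  }
  if (length(ages) < 2L || any(diff(ages) != 1L)) {
    stop("`ages` must be contiguous single years, strictly increasing",
         call. = FALSE)
  }
  if (anyNA(values)) stop("age schedule contains missing values", call. = FALSE)
  if (role == "prevalence" && (any(values < 0) || any(values > 1))) {
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  }
  if (role %in% c("rate", "count", "weight") && any(values < 0)) {
    stop(sprintf("%s values must be non-negative", role), call. = FALSE)
  }
  if (!is.na(sex)) sex <- match.arg(sex, c("female", "male"))
  structure(list(ages = ages, values = values, sex = sex, role = role),
            class = "age_schedule")
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("<age_schedule: %s, sex %s, ages %d-%d>\n",
              x$role, x$sex, min(x$ages), max(x$ages)))
  invisible(x)
}

# Accept an age_schedule or a bare numeric vector (ages supplied separately).
as_schedule_values <- function(x, ages, role, what) {
  if (inherits(x, "age_schedule")) {
    if (!identical(x$ages, as.integer(ages))) {
      stop(sprintf("`%s` ages do not match the expected span %d-%d",
                   what, min(ages), max(ages)), call. = FALSE)
    }
    return(x$values)
  }
  x <- as.numeric(x)
  if (length(x) != length(ages)) {
    stop(sprintf("`%s` must have one value per age (%d expected, got %d)",
                 what, length(ages), length(x)), call. = FALSE)
  }
  x
}

# Simplex validation shared by the exposure and linkage modules.
check_simplex <- function(p, what = "exposure", tol = 1e-6) {
  if (anyNA(p) || any(!is.finite(p))) {
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  }
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` is not a probability simplex (sum = %.8g)",
                 what, sum(p)), call. = FALSE)
  }
  invisible(TRUE)
}
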