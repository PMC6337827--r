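#' Joint exposure over the 36 composite categories
#'
#' Combines the three marginal category distributions of one (sex, age)
#' cell under multiplicative independence:
#' `P(s, b, a) = P(s) P(b) P(a)`. Clustering of lifestyle behaviours is
#' thereby ignored by assumption; the effect tables are defined to match
#' (composite effects multiply the marginal effects).
#'
#' @param smoking,bmi,alcohol Probability vectors over the categories of
#'   each factor (lengths 3, 3, 4), each summing to 1.
#' @param defs Factor definitions ([lifestyle_factors()]); supplies labels
#'   and the cell ordering of [composite_categories()].
#' @return Named numeric vector of length 36 summing to 1, ordered as
#'   [composite_categories()].
#' @examples
#' defs <- lifestyle_factors()
#' p <- joint_exposure(c(.5, .3, .2), c(.4, .4, .2), c(.25, .25, .25, .25))
#' sum(p)  # 1
#' @export
joint_exposure <- function(smoking, bmi, alcohol, defs = lifestyle_factors()) {
  check_simplex(smoking, "smoking marginal")
  check_simplex(bmi, "bmi marginal")
  check_simplex(alcohol, "alcohol marginal")
  if (length(smoking) != length(defs$smoking$categories) ||
      length(bmi) != length(defs$bmi$categories) ||
      length(alcohol) != length(defs$alcohol$categories)) {
    stop("marginal lengths do not match the factor definitions", call. = FALSE)
  }
  comp <- composite_categories(defs)
  p <- smoking[comp$i_smoking] * bmi[comp$i_bmi] * alcohol[comp$i_alcohol]
  names(p) <- comp$label
  p
}

#' Marginalize a joint exposure back to one factor
#'
#' @param p Length-36 joint probability vector (ordering of
#'   [composite_categories()]).
#' @param factor Factor to keep: `"smoking"`, `"bmi"` or `"alcohol"`.
#' @param defs Factor definitions.
#' @return Named probability vector over that factor's categories.
#' @export
marginalize_joint <- function(p, factor = c("smoking", "bmi", "alcohol"),
                              defs = lifestyle_factors()) {
  factor <- match.arg(factor)
  comp <- composite_categories(defs)
  idx <- comp[[paste0("i_", factor)]]
  out <- vapply(seq_along(defs[[factor]]$categories),
                function(k) sum(p[idx == k]), numeric(1))
  names(out) <- defs[[factor]]$categories
  out
}

# ---- long marginal tables ---------------------------------------------------
#
# Marginal prevalences travel through the pipeline as long data frames with
# columns (country,) sex, age, factor, category, prevalence. These helpers
# extract dense ages x categories matrices for one cell.

marginal_matrix <- function(marginals, factor_name, sex, ages,
                            defs = lifestyle_factors(), country = NULL) {
  cats <- defs[[factor_name]]$categories
  d <- marginals[marginals$factor == factor_name & marginals$sex == sex, ,
                 drop = FALSE]
  if (!is.null(country)) d <- d[d$country == country, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("no marginal prevalences for factor '%s', sex '%s'%s",
                 factor_name, sex,
                 if (is.null(country)) "" else paste0(", country '", country, "'")),
         call. = FALSE)
  }
  M <- matrix(NA_real_, length(ages), length(cats),
              dimnames = list(ages, cats))
  M[cbind(match(d$age, ages), match(d$category, cats))] <- d$prevalence
  if (anyNA(M)) {
    stop(sprintf("marginal prevalences for '%s' (%s) do not cover ages %d-%d",
                 factor_name, sex, min(ages), max(ages)), call. = FALSE)
  }
  bad <- which(abs(rowSums(M) - 1) > 1e-6)
  if (length(bad)) {
    stop(sprintf("marginal prevalences for '%s' (%s) do not sum to 1 at age %s",
                 factor_name, sex, rownames(M)[bad[1]]), call. = FALSE)
  }
  M
}

# ages x 36 joint exposure matrix from three ages x K marginal matrices
joint_matrix <- function(Ms, Mb, Ma, comp) {
  Ms[, comp$i_smoking, drop = FALSE] *
    Mb[, comp$i_bmi, drop = FALSE] *
    Ma[, comp$i_alcohol, drop = FALSE]
}

#' Estimate marginal category prevalences from survey records
#'
#' Fits, separately per sex, a multinomial logit of the factor's category
#' on a country dummy and its interaction with age (continuous), then
#' predicts category probabilities for every country at the requested
#' single ages. A multinomial model (rather than per-category binary
#' logits) guarantees that predictions form a probability simplex at every
#' age without post-hoc renormalisation.
#'
#' @param records Data frame of survey respondents with columns `country`,
#'   `sex`, `age` and one column per factor holding category labels
#'   (e.g. from [generate_survey()]).
#' @param factor Which factor to model: `"smoking"`, `"bmi"` or `"alcohol"`.
#' @param defs Factor definitions; category labels must match `records`.
#' @param ages Ages at which prevalences are predicted.
#' @return Long data frame `country`, `sex`, `age`, `factor`, `category`,
#'   `prevalence`. Categories absent from the data get probability 0 (with
#'   a warning).
#' @export
estimate_marginal_prevalence <- function(records,
                                         factor = c("smoking", "bmi", "alcohol"),
                                         defs = lifestyle_factors(),
                                         ages = 50:100) {
  factor <- match.arg(factor)
  cats <- defs[[factor]]$categories
  needed <- c("country", "sex", "age", factor)
  if (!all(needed %in% names(records))) {
    stop(sprintf("records must have columns %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  if (length(unique(records$country)) < 2L) {
    stop("at least 2 countries are required", call. = FALSE)
  }
  bad <- setdiff(unique(records[[factor]]), cats)
  if (length(bad)) {
    stop(sprintf("unknown %s categories in records: %s", factor,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  countries <- sort(unique(as.character(records$country)))
  out <- list()
  for (sx in sort(unique(as.character(records$sex)))) {
    d <- records[records$sex == sx, , drop = FALSE]
    if (nrow(d) < 30L) {
      stop(sprintf("fewer than 30 records for sex '%s'", sx), call. = FALSE)
    }
    present <- cats[cats %in% unique(d[[factor]])]
    if (length(present) < length(cats)) {
      warning(sprintf(
        "sex '%s': categories never observed get prevalence 0: %s",
        sx, paste(setdiff(cats, present), collapse = ", ")), call. = FALSE)
    }
    grid <- expand.grid(country = countries, age = ages,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (length(present) == 1L) {
      P <- matrix(1, nrow(grid), 1L)
    } else {
      d$.y <- base::factor(d[[factor]], levels = present)
      d$country <- base::factor(d$country, levels = countries)
      fit <- nnet::multinom(.y ~ country * age, data = d,
                            trace = FALSE, maxit = 500L)
      if (fit$convergence != 0) {
        stop(sprintf("multinomial fit did not converge for %s (%s)",
                     factor, sx), call. = FALSE)
      }
      grid$country <- base::factor(grid$country, levels = countries)
      P <- stats::predict(fit, newdata = grid, type = "probs")
      if (is.null(dim(P))) P <- cbind(1 - P, P)  # two-category case
    }
    full <- matrix(0, nrow(grid), length(cats), dimnames = list(NULL, cats))
    full[, present] <- P
    for (k in seq_along(cats)) {
      out[[length(out) + 1L]] <- data.frame(
        country = as.character(grid$country), sex = sx, age = grid$age,
        factor = factor, category = cats[k], prevalence = full[, k],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$country, out$sex, out$age, match(out$category, cats)), ]
}

#' Interpolate grouped prevalences to single years of age
#'
#' Reproduces the preprocessing applied to age-banded survey prevalences:
#' per category, a linear regression on the band midpoints captures the
#' trend and a generalized-cross-validated smoothing spline captures the
#' residual age pattern; the fit is evaluated at single ages, clipped to
#' \[0, 1\] and each age's category vector renormalised to sum to 1. With
#' fewer than four distinct bands (the minimum for a smoothing spline) a
#' natural interpolating spline is used instead. Constant or linear band
#' patterns are reproduced exactly at interior ages.
#'
#' @param grouped Data frame with columns `age` (band midpoint), `category`,
#'   `prevalence`, and optionally `sex` (processed separately). Duplicate
#'   rows are collapsed.
#' @param ages Output single ages.
#' @param factor Optional factor name stamped on the output.
#' @return Long data frame `sex` (if present), `age`, `category`,
#'   `prevalence` with a valid simplex at every age.
#' @export
smooth_to_single_ages <- function(grouped, ages = 50:100, factor = NULL) {
  stopifnot(all(c("age", "category", "prevalence") %in% names(grouped)))
  has_sex <- "sex" %in% names(grouped)
  split_by <- if (has_sex) unique(as.character(grouped$sex)) else NA_character_
  out <- list()
  for (sx in split_by) {
    d <- if (has_sex) grouped[grouped$sex == sx, , drop = FALSE] else grouped
    d <- unique(d[, c("age", "category", "prevalence")])
    cats <- unique(as.character(d$category))
    fitted <- sapply(cats, function(ct) {
      dd <- d[d$category == ct, , drop = FALSE]
      dd <- dd[order(dd$age), ]
      if (length(unique(dd$age)) < 3L) {
        stop("at least 3 age bands are required for interpolation",
             call. = FALSE)
      }
      if (anyDuplicated(dd$age)) {
        stop(sprintf("conflicting prevalences for category '%s' at one band",
                     ct), call. = FALSE)
      }
      if (nrow(dd) < 4L) {
        stats::spline(dd$age, dd$prevalence, xout = ages,
                      method = "natural")$y
      } else {
        trend <- stats::lm(prevalence ~ age, data = dd)
        res <- stats::residuals(trend)
        ss <- stats::smooth.spline(dd$age, res, cv = FALSE)
        stats::predict(trend, data.frame(age = ages)) +
          stats::predict(ss, ages)$y
      }
    })
    fitted <- pmin(pmax(fitted, 0), 1)
    sums <- rowSums(fitted)
    if (any(sums <= 0)) {
      stop("all-category prevalence collapsed to zero at some age",
           call. = FALSE)
    }
    fitted <- fitted / sums
    res <- data.frame(age = rep(ages, length(cats)),
                      category = rep(cats, each = length(ages)),
                      prevalence = as.vector(fitted),
                      stringsAsFactors = FALSE)
    if (has_sex) res <- cbind(sex = sx, res, stringsAsFactors = FALSE)
    if (!is.null(factor)) res$factor <- factor
    out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
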