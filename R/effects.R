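#' Effect table: relative risks or odds ratios per lifestyle category
#'
#' Holds multiplicative effects on one outcome — mortality (relative
#' risks) or an unhealthy health state (odds ratios) — per sex, factor and
#' category, resolvable at any age. Three specifications are supported per
#' entry:
#' \describe{
#'   \item{`constant`}{one effect at all (applicable) ages; `value` is the
#'     effect itself.}
#'   \item{`stratified`}{one effect per age stratum (default strata
#'     50-65 and 65+, the boundary age belonging to the upper stratum);
#'     `value` is the effect, `stratum` names the stratum.}
#'   \item{`loglinear`}{effect `exp(value + slope * age)` — a continuous
#'     age interaction on the log scale.}
#' }
#' Below `apply_from_age` every effect resolves to 1 (no differential
#' risk). Categories without entries are reference categories and resolve
#' to 1 at every age.
#'
#' @param entries Data frame with columns `sex`, `factor`, `category`,
#'   `spec_kind`, `stratum` (`NA` unless stratified), `value`, `slope`
#'   (`NA` unless loglinear), and optionally `se`, `se_slope`.
#' @param outcome `"mortality"`, `"gali"` (activity limitation) or `"sph"`
#'   (less-than-good self-perceived health).
#' @param effect_kind `"RR"` or `"OR"`.
#' @param apply_from_age Age from which effects apply (defaults: 20 for
#'   mortality RRs, 50 for health-state ORs, matching the coverage of the
#'   underlying evidence).
#' @param strata_breaks Stratum boundaries for stratified entries; default
#'   `c(50, 65)` defines strata `[50, 65)` and `[65, Inf)`.
#' @return An `effect_table` object.
#' @export
effect_table <- function(entries, outcome = c("mortality", "gali", "sph"),
                         effect_kind = c("RR", "OR"),
                         apply_from_age = NULL,
                         strata_breaks = c(50, 65)) {
  outcome <- match.arg(outcome)
  effect_kind <- match.arg(effect_kind)
  if (is.null(apply_from_age)) {
    apply_from_age <- if (outcome == "mortality") 20L else 50L
  }
  need <- c("sex", "factor", "category", "spec_kind", "value")
  if (!all(need %in% names(entries))) {
    stop(sprintf("effect entries need columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"stratum" %in% names(entries)) entries$stratum <- NA_character_
  if (!"slope" %in% names(entries)) entries$slope <- NA_real_
  if (!all(entries$spec_kind %in% c("constant", "stratified", "loglinear"))) {
    stop("spec_kind must be constant, stratified or loglinear", call. = FALSE)
  }
  cv <- entries$spec_kind %in% c("constant", "stratified")
  if (any(entries$value[cv] <= 0)) {
    stop("constant/stratified effects must be positive", call. = FALSE)
  }
  structure(list(entries = entries, outcome = outcome,
                 effect_kind = effect_kind,
                 apply_from_age = as.integer(apply_from_age),
                 strata_breaks = as.numeric(strata_breaks)),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("<effect_table: %s (%s), %d entries, applies from age %d>\n",
              x$outcome, x$effect_kind, nrow(x$entries), x$apply_from_age))
  invisible(x)
}

stratum_label <- function(breaks) {
  c(sprintf("%d-%d", breaks[1], breaks[2]), sprintf("%d+", breaks[2]))
}

#' Resolve a marginal effect at given ages
#'
#' @param table An [effect_table()].
#' @param factor,category Marginal category to resolve.
#' @param sex `"female"` or `"male"`.
#' @param age Numeric vector of ages (vectorised).
#' @param max_age Upper bound of the model span; ages outside
#'   `[0, max_age]` are an error.
#' @return Positive effect value(s), 1 below `apply_from_age` and for
#'   reference (absent) categories.
#' @examples
#' et <- effect_table(data.frame(sex = "male", factor = "smoking",
#'   category = "current", spec_kind = "loglinear", value = log(2),
#'   slope = 0.01), outcome = "gali", effect_kind = "OR")
#' effect_at(et, "smoking", "current", "male", 60)  # 2 * exp(0.6)
#' @export
effect_at <- function(table, factor, category, sex, age, max_age = 100) {
  stopifnot(inherits(table, "effect_table"))
  if (any(age < 0) || any(age > max_age)) {
    stop(sprintf("age outside the model span [0, %d]", as.integer(max_age)),
         call. = FALSE)
  }
  e <- table$entries
  rows <- e[e$sex == sex & e$factor == factor & e$category == category, ,
            drop = FALSE]
  out <- rep(1, length(age))
  if (nrow(rows) > 0L) {
    kind <- rows$spec_kind[1]
    if (kind == "constant") {
      out[] <- rows$value[1]
    } else if (kind == "loglinear") {
      out <- exp(rows$value[1] + rows$slope[1] * age)
    } else {
      labs <- stratum_label(table$strata_breaks)
      upper <- age >= table$strata_breaks[2]  # boundary age -> upper stratum
      for (i in seq_along(age)) {
        lab <- labs[if (upper[i]) 2L else 1L]
        v <- rows$value[rows$stratum == lab]
        out[i] <- if (length(v)) v[1] else 1
      }
    }
  }
  out[age < table$apply_from_age] <- 1
  out
}

# ages x 36 matrix of composite effects: product of the three marginal
# effects, consistent with mutually adjusted regressions and multiplicative
# clustering of the joint risk factor.
resolve_composite_effects <- function(table, sex, ages,
                                      defs = lifestyle_factors(),
                                      comp = composite_categories(defs)) {
  mats <- lapply(c("smoking", "bmi", "alcohol"), function(f) {
    cats <- defs[[f]]$categories
    vapply(cats, function(ct) effect_at(table, f, ct, sex, ages,
                                        max_age = max(ages)),
           numeric(length(ages)))
  })
  names(mats) <- c("smoking", "bmi", "alcohol")
  M <- mats$smoking[, comp$i_smoking, drop = FALSE] *
    mats$bmi[, comp$i_bmi, drop = FALSE] *
    mats$alcohol[, comp$i_alcohol, drop = FALSE]
  dimnames(M) <- list(ages, comp$label)
  M
}

#' Estimate health-state odds ratios from individual survey records
#'
#' Emulates the study's estimation design: logistic regressions of the
#' unhealthy outcome on all three lifestyle factors (mutually adjusted),
#' age and country intercepts, run separately per sex. Smoking and BMI
#' odds ratios are estimated within two age strata (50-65 and 65+, the
#' boundary in the upper stratum); alcohol odds ratios come from a single
#' model over all ages with a continuous category-by-age interaction, so
#' the alcohol effect is log-linear in age. Reference categories are the
#' designated healthy categories.
#'
#' @param records Data frame with columns `country`, `sex`, `age`,
#'   `smoking`, `bmi`, `alcohol` (category labels) and the binary outcome
#'   columns `gali_limited` and/or `sph_poor`.
#' @param outcome `"gali"` or `"sph"`.
#' @param defs Factor definitions.
#' @param apply_from_age,strata_breaks See [effect_table()].
#' @return An [effect_table()] (`effect_kind = "OR"`) with standard errors
#'   in columns `se` (and `se_slope` for alcohol entries).
#' @export
estimate_odds_ratios <- function(records, outcome = c("gali", "sph"),
                                 defs = lifestyle_factors(),
                                 apply_from_age = 50L,
                                 strata_breaks = c(50, 65)) {
  outcome <- match.arg(outcome)
  ycol <- c(gali = "gali_limited", sph = "sph_poor")[[outcome]]
  need <- c("country", "sex", "age", "smoking", "bmi", "alcohol", ycol)
  if (!all(need %in% names(records))) {
    stop(sprintf("records must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(records) < 1000L) {
    stop("at least 1000 records are required", call. = FALSE)
  }
  if (length(unique(records[[ycol]])) < 2L) {
    stop("both outcome levels must be present", call. = FALSE)
  }
  d <- records[records$age >= apply_from_age, , drop = FALSE]
  for (f in c("smoking", "bmi", "alcohol")) {
    cats <- defs[[f]]$categories
    ref <- cats[defs[[f]]$healthy_index]
    d[[f]] <- stats::relevel(base::factor(d[[f]], levels = cats), ref = ref)
  }
  d$country <- base::factor(d$country)
  d$.y <- d[[ycol]]
  labs <- stratum_label(strata_breaks)

  pull_terms <- function(fit, f, kind, stratum = NA_character_, sex) {
    sm <- summary(fit)$coefficients
    cats <- setdiff(defs[[f]]$categories,
                    defs[[f]]$categories[defs[[f]]$healthy_index])
    rows <- list()
    for (ct in cats) {
      nm <- paste0(f, ct)
      if (!nm %in% rownames(sm)) next
      if (abs(sm[nm, "Estimate"]) > 15) {
        stop(sprintf("complete separation suspected for covariate '%s'", nm),
             call. = FALSE)
      }
      if (kind == "stratified") {
        rows[[ct]] <- data.frame(
          sex = sex, factor = f, category = ct, spec_kind = "stratified",
          stratum = stratum, value = exp(sm[nm, "Estimate"]), slope = NA_real_,
          se = sm[nm, "Std. Error"], se_slope = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        nm2 <- paste0(nm, ":age")
        rows[[ct]] <- data.frame(
          sex = sex, factor = f, category = ct, spec_kind = "loglinear",
          stratum = NA_character_, value = sm[nm, "Estimate"],
          slope = sm[nm2, "Estimate"], se = sm[nm, "Std. Error"],
          se_slope = sm[nm2, "Std. Error"], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  entries <- list()
  for (sx in sort(unique(as.character(d$sex)))) {
    ds <- d[d$sex == sx, , drop = FALSE]
    # smoking & BMI: separate fits within the two age strata
    strata <- list(ds[ds$age < strata_breaks[2], , drop = FALSE],
                   ds[ds$age >= strata_breaks[2], , drop = FALSE])
    for (i in 1:2) {
      dd <- strata[[i]]
      if (nrow(dd) < 100L || length(unique(dd$.y)) < 2L) {
        warning(sprintf("stratum %s (%s) too sparse; dropped", labs[i], sx),
                call. = FALSE)
        next
      }
      fit <- stats::glm(.y ~ smoking + bmi + alcohol + age + country,
                        family = stats::binomial(), data = dd)
      entries[[length(entries) + 1L]] <-
        pull_terms(fit, "smoking", "stratified", labs[i], sx)
      entries[[length(entries) + 1L]] <-
        pull_terms(fit, "bmi", "stratified", labs[i], sx)
    }
    # alcohol: single fit with continuous age interaction
    fit_a <- stats::glm(.y ~ smoking + bmi + alcohol * age + country,
                        family = stats::binomial(), data = ds)
    entries[[length(entries) + 1L]] <- pull_terms(fit_a, "alcohol", "loglinear",
                                                  sex = sx)
  }
  effect_table(do.call(rbind, entries), outcome = outcome, effect_kind = "OR",
               apply_from_age = apply_from_age, strata_breaks = strata_breaks)
}

#' Read / write effect tables as CSV
#'
#' Long CSV with columns `outcome`, `effect_kind`, `sex`, `factor`,
#' `category`, `spec_kind`, `stratum`, `value`, `slope`, `apply_from_age`
#' (standard-error columns are preserved when present).
#'
#' @param table An [effect_table()].
#' @param path File path.
#' @return `read_effect_table` returns an [effect_table()];
#'   `write_effect_table` returns `path` invisibly.
#' @export
write_effect_table <- function(table, path) {
  stopifnot(inherits(table, "effect_table"))
  e <- table$entries
  e$outcome <- table$outcome
  e$effect_kind <- table$effect_kind
  e$apply_from_age <- table$apply_from_age
  front <- c("outcome", "effect_kind", "sex", "factor", "category",
             "spec_kind", "stratum", "value", "slope", "apply_from_age")
  e <- e[, c(front, setdiff(names(e), front)), drop = FALSE]
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  effect_table(e, outcome = e$outcome[1], effect_kind = e$effect_kind[1],
               apply_from_age = e$apply_from_age[1])
}
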