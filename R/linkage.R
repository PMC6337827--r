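#' Decompose an aggregate mortality rate into category-specific rates
#'
#' Attributable-risk decomposition for one (sex, age) cell: given the
#' observed aggregate rate `m`, the exposure distribution `p` over the
#' composite categories and their relative risks `rr`, the rate in the
#' all-reference category is `m0 = m / sum(p * rr)` and each category's
#' rate is `m0 * rr`. The exposure-weighted mean of the category rates
#' reproduces the aggregate exactly, by construction.
#'
#' @param m_total Observed aggregate death rate (>= 0).
#' @param exposure Probability vector over the categories.
#' @param rr Positive relative risks, same length, reference = 1.
#' @return List with `m0` (baseline rate) and `rates` (category rates).
#' @examples
#' decompose_mortality(0.02, c(0.5, 0.5), c(1, 3))  # m0 = 0.01
#' @export
decompose_mortality <- function(m_total, exposure, rr) {
  check_simplex(exposure)
  if (any(rr <= 0) || length(rr) != length(exposure)) {
    stop("`rr` must be positive and match the exposure length", call. = FALSE)
  }
  if (m_total < 0) stop("`m_total` must be non-negative", call. = FALSE)
  s <- sum(exposure * rr)
  if (s <= 0) stop("degenerate input: sum(p * rr) is zero", call. = FALSE)
  m0 <- m_total / s
  list(m0 = m0, rates = m0 * rr)
}

#' Aggregate category rates under a counterfactual exposure
#'
#' Category rates are held fixed (the counterfactual changes who is in
#' which category, not the risk each category carries); the new aggregate
#' is the exposure-weighted mean `sum(p_new * rates)`.
#'
#' @param rates Category rates (e.g. from [decompose_mortality()]`$rates`).
#' @param new_exposure Counterfactual probability vector over the same
#'   categories.
#' @return Counterfactual aggregate rate.
#' @export
counterfactual_mortality <- function(rates, new_exposure) {
  check_simplex(new_exposure, "new_exposure")
  if (length(rates) != length(new_exposure)) {
    stop("`rates` and `new_exposure` lengths differ", call. = FALSE)
  }
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  sum(new_exposure * rates)
}

#' Invert an aggregate prevalence into category prevalences via odds ratios
#'
#' Solves, for one (sex, age, outcome) cell, for the unhealthy-state odds
#' `o0` in the all-reference category such that the exposure-weighted mean
#' of the category prevalences `pi_c = o0 OR_c / (1 + o0 OR_c)` reproduces
#' the observed aggregate prevalence. The aggregation
#' `g(o) = sum(p * o OR / (1 + o OR))` is strictly increasing with
#' `g(0) = 0` and `g(Inf) = 1`, so the root is unique; it is found by
#' bisection on `log(o)` over an expanding bracket (guaranteed convergence,
#' unlike Newton steps), to residual `|g(o) - pi| <= tol`.
#'
#' Aggregate prevalences of exactly 0 or 1 are clamped to
#' `[1e-9, 1 - 1e-9]` with a warning: the odds transform is undefined at
#' the boundary, which occurs only at extreme ages where the state is
#' (near-)universal.
#'
#' @param pi_total Observed aggregate prevalence.
#' @param exposure Probability vector over categories.
#' @param or_ Positive odds ratios, reference = 1.
#' @param tol Residual tolerance on the aggregate prevalence.
#' @param max_iter Maximum bisection iterations.
#' @return List with `o0` (baseline odds) and `prev` (category
#'   prevalences).
#' @examples
#' invert_prevalence(0.5, c(0.5, 0.5), c(1, 3))$o0  # 1/sqrt(3)
#' @export
invert_prevalence <- function(pi_total, exposure, or_, tol = 1e-12,
                              max_iter = 200L) {
  check_simplex(exposure)
  if (any(or_ <= 0) || length(or_) != length(exposure)) {
    stop("`or_` must be positive and match the exposure length", call. = FALSE)
  }
  lo_clamp <- 1e-9
  if (pi_total < lo_clamp || pi_total > 1 - lo_clamp) {
    warning(sprintf("aggregate prevalence %.3g clamped into [%g, %g]",
                    pi_total, lo_clamp, 1 - lo_clamp), call. = FALSE)
    pi_total <- min(max(pi_total, lo_clamp), 1 - lo_clamp)
  }
  g <- function(o) sum(exposure * (o * or_) / (1 + o * or_))
  lo <- 1e-12
  hi <- 1e6
  while (g(hi) < pi_total && hi < 1e30) hi <- hi * 100
  while (g(lo) > pi_total && lo > 1e-30) lo <- lo / 100
  llo <- log(lo)
  lhi <- log(hi)
  o <- NA_real_
  converged <- FALSE
  resid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- exp((llo + lhi) / 2)
    resid <- g(mid) - pi_total
    if (abs(resid) <= tol) {
      o <- mid
      converged <- TRUE
      break
    }
    if (resid > 0) lhi <- log(mid) else llo <- log(mid)
  }
  if (!converged) {
    stop(sprintf(
      "prevalence inversion did not converge in %d iterations (residual %.3e)",
      max_iter, resid), call. = FALSE)
  }
  list(o0 = o, prev = (o * or_) / (1 + o * or_))
}

#' Aggregate category prevalences under a counterfactual exposure
#'
#' Baseline odds and odds ratios are held fixed; the counterfactual
#' aggregate prevalence is `sum(p_new * o0 OR / (1 + o0 OR))`.
#'
#' @param o0 Baseline (all-reference) odds from [invert_prevalence()].
#' @param or_ Positive odds ratios per category.
#' @param new_exposure Counterfactual probability vector.
#' @return Counterfactual aggregate prevalence, in `[0, 1]`.
#' @export
counterfactual_prevalence <- function(o0, or_, new_exposure) {
  check_simplex(new_exposure, "new_exposure")
  if (any(or_ <= 0) || length(or_) != length(new_exposure)) {
    stop("`or_` must be positive and match the exposure length", call. = FALSE)
  }
  if (o0 <= 0) stop("`o0` must be positive", call. = FALSE)
  sum(new_exposure * (o0 * or_) / (1 + o0 * or_))
}
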