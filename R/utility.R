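check_amount <- function(A, what = "A") {
  if (!is.numeric(A) || length(A) < 1L || anyNA(A) || any(A < 0)) {
    stop(sprintf("`%s` must be non-negative", what), call. = FALSE)
  }
  invisible(A)
}

#' Single-period utility components
#'
#' The psychological and monetary components of the utility of gambling an
#' amount `A` in one session are quadratics in `A`:
#' `U_P(A) = alpha_P * A + (alpha_PP / 2) * A^2` and
#' `U_M(A) = alpha_M * A + (alpha_MM / 2) * A^2`.
#' Their sum, the baseline gamble utility, governs a non-gambler (no stock,
#' hence no cravings). With an objective frame the monetary component is
#' strictly negative and strictly decreasing for all `A > 0`.
#'
#' @param A amount gambled in the session; non-negative (vectorised).
#' @param coeffs a [coefficient_set()].
#' @return Utility value(s), same length as `A`.
#' @examples
#' cs <- coefficient_set(1, -1, 0, -1e-9)
#' psych_utility(1, cs)
#' @export
psych_utility <- function(A, coeffs) {
  check_amount(A)
  stopifnot(inherits(coeffs, "coefficient_set"))
  coeffs$alpha_P * A + (coeffs$alpha_PP / 2) * A^2
}

#' @rdname psych_utility
#' @export
monetary_utility <- function(A, coeffs) {
  check_amount(A)
  stopifnot(inherits(coeffs, "coefficient_set"))
  coeffs$alpha_M * A + (coeffs$alpha_MM / 2) * A^2
}

#' @rdname psych_utility
#' @export
baseline_gamble_utility <- function(A, coeffs) {
  check_amount(A)
  stopifnot(inherits(coeffs, "coefficient_set"))
  net_slope(coeffs) * A + (net_curvature(coeffs) / 2) * A^2
}

#' Disutility of unsatisfied gambling cravings
#'
#' Cravings are generated by the stock of past gambling `S` at level
#' `alpha_C * S` and are exactly satisfied when the agent gambles the
#' myopic optimum. Gambling less leaves unsatisfied cravings with loss
#' `alpha_C * S * (A_sat(S) - A)`, where
#' `A_sat(S) = -(b + alpha_C * S) / c` with `b` and `c` the subjective net
#' slope and curvature; the loss is clipped at zero so satisfied cravings
#' never add positive utility. Craving coefficients are always the
#' subjective ones: cravings are internal and felt as believed.
#'
#' @param A amount gambled (non-negative, vectorised).
#' @param S stock of past gambling (non-negative scalar).
#' @param params an [agent_parameters()] object.
#' @return Non-negative craving loss; its contribution to total utility is
#'   the negation of this value.
#' @export
craving_disutility <- function(A, S, params) {
  check_amount(A)
  check_amount(S, "S")
  stopifnot(inherits(params, "agent_parameters"))
  if (length(S) != 1L) stop("`S` must be a single stock value", call. = FALSE)
  if (S == 0) return(rep(0, length(A)))
  b <- net_slope(params$subjective)
  c_ <- net_curvature(params$subjective)
  sat <- -(b + params$alpha_C * S) / c_
  pmax(params$alpha_C * S * (sat - A), 0)
}

#' Decision and experienced utility of gambling
#'
#' Decision utility is what the agent maximises: baseline gamble utility
#' under subjective beliefs minus the craving loss. Experienced utility is
#' what the agent actually gets: the baseline term uses the objective
#' coefficients while the craving term is unchanged (cravings are inherently
#' subjective). When beliefs are unbiased the two coincide; when every
#' subjective coefficient weakly exceeds its objective counterpart, decision
#' utility weakly exceeds experienced utility for every amount.
#'
#' @inheritParams craving_disutility
#' @return Utility value(s), same length as `A`.
#' @examples
#' ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5)
#' decision_utility(1, 0, ag)
#' @export
decision_utility <- function(A, S, params) {
  stopifnot(inherits(params, "agent_parameters"))
  baseline_gamble_utility(A, params$subjective) -
    craving_disutility(A, S, params)
}

#' @rdname decision_utility
#' @export
experienced_utility <- function(A, S, params) {
  stopifnot(inherits(params, "agent_parameters"))
  baseline_gamble_utility(A, params$objective) -
    craving_disutility(A, S, params)
}

#' Indirect experienced utility at a given stock
#'
#' Experienced utility as a function of stock when the agent gambles the
#' myopic decision-utility optimum at that stock: the objective baseline
#' quadratic evaluated at `A*(S)`. Its value at `S = 0` is positive exactly
#' when `alpha_P^O > -alpha_M^O`; as the stock grows the curve falls and
#' crosses zero at the harm threshold stock. On the non-participation
#' region, where the myopic optimum is zero, the function returns the
#' experienced utility of not gambling at that stock (the negated craving
#' loss at `A = 0`); the closed-form curve only applies where gambling is
#' interior.
#'
#' @param S stock of past gambling (non-negative scalar).
#' @param params an [agent_parameters()] object.
#' @return A single utility value.
#' @export
indirect_experienced_utility <- function(S, params) {
  check_amount(S, "S")
  stopifnot(inherits(params, "agent_parameters"))
  A_star <- myopic_optimal_amount(S, params)
  if (A_star <= 0) return(-craving_disutility(0, S, params))
  baseline_gamble_utility(A_star, params$objective)
}

#' Discounted lifetime utility
#'
#' Aggregates a sequence of per-period utilities `u_t`, `t = 0, ..., n`,
#' into `sum((1 - delta)^t * u_t)`. With `delta = 1` only the current
#' period counts; with `delta = 0` nothing is discounted.
#'
#' @param per_period_utilities numeric vector of utilities, first element
#'   the current period.
#' @param delta discount rate in \[0, 1\].
#' @return A single discounted total.
#' @export
lifetime_utility <- function(per_period_utilities, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1) {
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  }
  u <- per_period_utilities
  if (length(u) == 0L) return(0)
  sum((1 - delta)^(seq_along(u) - 1L) * u)
}
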