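#' Intervention transforms on agents and cohorts
#'
#' Interventions act on the levers the two-stage structure exposes:
#' reducing cravings (scaling `alpha_C` down leaves participation untouched
#' while weakly lowering equilibrium gambling and harm), making large
#' amounts less attractive (shifting the quadratic psychological
#' coefficients downward, e.g. minimum time between bets), capping the
#' amount per period (maximum bet sizes), and limiting the budget (deposit
#' limits, ATM removal).
#'
#' * `intervention_scale_alpha_C(factor)` — multiply craving propensity by
#'   `factor` in (0, 1].
#' * `intervention_shift_alpha_PP(shift)` — subtract `shift >= 0` from both
#'   the subjective and objective quadratic psychological coefficients.
#' * `intervention_amount_cap(cap)` — cap the amount gambled each period.
#' * `intervention_income_limit(limit)` — replace income by
#'   `min(income, limit)` each period.
#'
#' @param factor scaling factor in (0, 1].
#' @param shift non-negative downward shift.
#' @param cap,limit non-negative per-period bounds (scalar or schedule).
#' @return An object of class `gambling_intervention`.
#' @examples
#' ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.6, d = 0.5)
#' ag2 <- apply_intervention(ag, intervention_scale_alpha_C(0.5))
#' ag2$alpha_C
#' @export
intervention_scale_alpha_C <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
      factor > 1) {
    stop("`factor` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(type = "scale_alpha_C", factor = factor),
            class = "gambling_intervention")
}

#' @rdname intervention_scale_alpha_C
#' @export
intervention_shift_alpha_PP <- function(shift) {
  if (!is.numeric(shift) || length(shift) != 1L || shift < 0) {
    stop("`shift` must be non-negative", call. = FALSE)
  }
  structure(list(type = "shift_alpha_PP", shift = shift),
            class = "gambling_intervention")
}

#' @rdname intervention_scale_alpha_C
#' @export
intervention_amount_cap <- function(cap) {
  if (!is.numeric(cap) || length(cap) < 1L || anyNA(cap) || any(cap < 0)) {
    stop("`cap` must be non-negative", call. = FALSE)
  }
  structure(list(type = "amount_cap", cap = cap),
            class = "gambling_intervention")
}

#' @rdname intervention_scale_alpha_C
#' @export
intervention_income_limit <- function(limit) {
  if (!is.numeric(limit) || length(limit) < 1L || anyNA(limit) ||
      any(limit < 0)) {
    stop("`limit` must be non-negative", call. = FALSE)
  }
  structure(list(type = "income_limit", limit = limit),
            class = "gambling_intervention")
}

#' Apply an intervention
#'
#' Applies a [gambling intervention][intervention_scale_alpha_C] to a
#' single agent or to a whole cohort. Parameter transforms return modified,
#' re-validated [agent_parameters()]; an amount cap attaches a cap schedule
#' that [simulate_cohort()] and [simulate_trajectory()] honour.
#' Interventions compose: applying several in sequence is supported.
#'
#' @param x an [agent_parameters()] object or an `agent_cohort` / list of
#'   agents.
#' @param intervention a `gambling_intervention`.
#' @return The modified agent or cohort.
#' @export
apply_intervention <- function(x, intervention) {
  stopifnot(inherits(intervention, "gambling_intervention"))
  UseMethod("apply_intervention")
}

#' @export
apply_intervention.agent_parameters <- function(x, intervention) {
  switch(intervention$type,
    scale_alpha_C = agent_parameters(
      subjective = x$subjective, objective = x$objective,
      alpha_C = x$alpha_C * intervention$factor,
      d = x$d, delta = x$delta, income = x$income),
    shift_alpha_PP = agent_parameters(
      subjective = coefficient_set(
        x$subjective$alpha_P, x$subjective$alpha_PP - intervention$shift,
        x$subjective$alpha_M, x$subjective$alpha_MM, frame = "subjective"),
      objective = coefficient_set(
        x$objective$alpha_P, x$objective$alpha_PP - intervention$shift,
        x$objective$alpha_M, x$objective$alpha_MM, frame = "objective"),
      alpha_C = x$alpha_C, d = x$d, delta = x$delta, income = x$income),
    income_limit = agent_parameters(
      subjective = x$subjective, objective = x$objective,
      alpha_C = x$alpha_C, d = x$d, delta = x$delta,
      income = pmin(x$income, intervention$limit)),
    amount_cap = stop(
      "an amount cap applies to a cohort or a simulation, not to agent parameters; pass `cap` to simulate_trajectory() or apply to a cohort",
      call. = FALSE),
    stop(sprintf("unknown intervention `%s`", intervention$type),
         call. = FALSE)
  )
}

#' @export
apply_intervention.list <- function(x, intervention) {
  spec <- attr(x, "spec")
  existing_cap <- attr(x, "amount_cap")
  if (intervention$type == "amount_cap") {
    new_cap <- if (is.null(existing_cap)) intervention$cap
               else pmin(existing_cap, intervention$cap)
    out <- x
  } else {
    out <- lapply(unclass(x), apply_intervention, intervention = intervention)
    new_cap <- existing_cap
  }
  structure(out, class = "agent_cohort", spec = spec, amount_cap = new_cap)
}

#' @export
apply_intervention.agent_cohort <- apply_intervention.list
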