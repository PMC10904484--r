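#' Full parameter set for one agent
#'
#' An agent is described by two coefficient sets (subjective beliefs used to
#' decide, objective coefficients that determine experience), a craving
#' propensity, a stock depreciation rate, a time discount rate, and a
#' per-period income available for gambling. Craving propensity and
#' depreciation carry no belief frame: cravings are internal and not subject
#' to bias.
#'
#' @param subjective a [coefficient_set()] with `frame = "subjective"`.
#' @param objective a [coefficient_set()] with `frame = "objective"`.
#' @param alpha_C craving propensity; strictly positive. The craving level
#'   at stock `S` is `alpha_C * S`.
#' @param d per-period depreciation fraction of the stock of past gambling,
#'   strictly inside (0, 1). Low `d` means persistent cravings.
#' @param delta per-period time discount rate in \[0, 1\] used only when
#'   aggregating per-period utilities into a lifetime total.
#' @param income non-negative budget available for gambling each period;
#'   a scalar or a per-period schedule (recycled by its last value when a
#'   simulation runs longer than the schedule).
#'
#' @return An object of class `agent_parameters`.
#' @examples
#' ag <- unbiased_agent(alpha_P = 1.5, alpha_PP = -1, alpha_M = -0.5,
#'                      alpha_MM = -1, alpha_C = 0.5, d = 0.5)
#' ag$alpha_C
#' @export
agent_parameters <- function(subjective, objective, alpha_C, d,
                             delta = 0, income = Inf) {
  if (!inherits(subjective, "coefficient_set") ||
      subjective$frame != "subjective") {
    stop("`subjective` must be a coefficient_set with frame = \"subjective\"",
         call. = FALSE)
  }
  if (!inherits(objective, "coefficient_set") ||
      objective$frame != "objective") {
    stop("`objective` must be a coefficient_set with frame = \"objective\"",
         call. = FALSE)
  }
  if (!is.numeric(alpha_C) || length(alpha_C) != 1L || !is.finite(alpha_C) ||
      alpha_C <= 0) {
    stop("`alpha_C` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) ||
      d <= 0 || d >= 1) {
    stop("`d` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1) {
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(income) || length(income) < 1L || anyNA(income) ||
      any(income < 0)) {
    stop("`income` must be non-negative in every period", call. = FALSE)
  }
  structure(
    list(subjective = subjective, objective = objective,
         alpha_C = alpha_C, d = d, delta = delta, income = income),
    class = "agent_parameters"
  )
}

#' @rdname agent_parameters
#' @param alpha_P,alpha_PP,alpha_M,alpha_MM shared coefficients used for
#'   both frames by `unbiased_agent()` (requires `alpha_M < 0` so the
#'   objective restriction holds).
#' @details `unbiased_agent()` builds an agent whose subjective beliefs
#'   coincide with the objective coefficients, so decision and experienced
#'   utility are identical.
#' @export
unbiased_agent <- function(alpha_P, alpha_PP, alpha_M, alpha_MM,
                           alpha_C, d, delta = 0, income = Inf) {
  agent_parameters(
    subjective = coefficient_set(alpha_P, alpha_PP, alpha_M, alpha_MM,
                                 frame = "subjective"),
    objective  = coefficient_set(alpha_P, alpha_PP, alpha_M, alpha_MM,
                                 frame = "objective"),
    alpha_C = alpha_C, d = d, delta = delta, income = income
  )
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat("<agent_parameters>\n")
  cat(sprintf("  subjective: alpha_P=%g alpha_PP=%g alpha_M=%g alpha_MM=%g\n",
              x$subjective$alpha_P, x$subjective$alpha_PP,
              x$subjective$alpha_M, x$subjective$alpha_MM))
  cat(sprintf("  objective : alpha_P=%g alpha_PP=%g alpha_M=%g alpha_MM=%g\n",
              x$objective$alpha_P, x$objective$alpha_PP,
              x$objective$alpha_M, x$objective$alpha_MM))
  cat(sprintf("  alpha_C=%g d=%g delta=%g income=%s\n",
              x$alpha_C, x$d, x$delta,
              if (length(x$income) == 1L) format(x$income)
              else sprintf("schedule[%d]", length(x$income))))
  invisible(x)
}

# income available in period t (0-based); schedules extend by last value
income_at <- function(params, t) {
  inc <- params$income
  if (length(inc) == 1L) return(inc)
  inc[min(t + 1L, length(inc))]
}
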