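#' Does the agent's gambling reach an equilibrium?
#'
#' Under unconstrained myopic optimisation the stock follows an affine
#' recurrence with slope `1 - d + alpha_C / |c^S|`. The amount gambled
#' converges to a fixed point exactly when `|c^S| > alpha_C / d` strictly
#' (the slope is then below one); otherwise the amount grows without bound.
#' The knife-edge case `|c^S| = alpha_C / d` has slope exactly one and
#' drifts upward whenever the agent participates, so it is classified as
#' not reaching equilibrium.
#'
#' @param params an [agent_parameters()] object.
#' @return `TRUE` if the convergence condition holds strictly.
#' @export
reaches_equilibrium <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  abs(net_curvature(params$subjective)) > params$alpha_C / params$d
}

#' Equilibrium amount and stock
#'
#' For a participating agent satisfying the convergence condition, the
#' amount gambled converges to `A_bar = -b^S / (c^S + alpha_C / d)` and the
#' stock to its fixed point `S_bar = A_bar / d`.
#'
#' @param params an [agent_parameters()] object.
#' @return A positive amount (`equilibrium_amount`) or stock
#'   (`equilibrium_stock`).
#' @examples
#' ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5)
#' equilibrium_amount(ag)  # 1
#' equilibrium_stock(ag)   # 2
#' @export
equilibrium_amount <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  if (!reaches_equilibrium(params)) {
    stop("agent does not reach an equilibrium (amount grows indefinitely)",
         call. = FALSE)
  }
  b <- net_slope(params$subjective)
  if (b <= 0) {
    stop("agent does not participate (subjective net slope <= 0)",
         call. = FALSE)
  }
  -b / (net_curvature(params$subjective) + params$alpha_C / params$d)
}

#' @rdname equilibrium_amount
#' @export
equilibrium_stock <- function(params) {
  equilibrium_amount(params) / params$d
}

#' Does the agent develop gambling with negative experienced utility?
#'
#' For a convergent participating agent the verdict is the sign of the
#' objective baseline utility at the equilibrium amount:
#' `(alpha_P^O + alpha_M^O) A_bar + (alpha_PP^O + alpha_MM^O)/2 A_bar^2 < 0`.
#' An agent whose amount grows indefinitely always develops negative
#' experienced utility. The direct sign evaluation is authoritative; the
#' equivalent printed threshold inequality on `2 alpha_C / d` is exposed via
#' [harm_condition_inequality()] as a cross-check and a warning is raised if
#' the two ever disagree for a positive objective net slope.
#'
#' @param params an [agent_parameters()] object.
#' @param cross_check also evaluate the threshold-form inequality and warn
#'   on disagreement (only meaningful when `b^O > 0`).
#' @return `TRUE` if long-run experienced utility from gambling is negative.
#' @export
develops_negative_utility <- function(params, cross_check = FALSE) {
  stopifnot(inherits(params, "agent_parameters"))
  if (net_slope(params$subjective) <= 0) {
    stop("agent does not participate; harm flag is undefined", call. = FALSE)
  }
  if (!reaches_equilibrium(params)) return(TRUE)
  A_bar <- equilibrium_amount(params)
  direct <- baseline_gamble_utility(A_bar, params$objective) < 0
  if (cross_check && net_slope(params$objective) > 0) {
    printed <- harm_condition_inequality(params)
    if (!identical(direct, printed)) {
      warning(sprintf(
        paste0("harm verdict disagreement: direct sign at equilibrium = %s",
               " but threshold inequality = %s"), direct, printed),
        call. = FALSE)
    }
  }
  direct
}

#' @rdname develops_negative_utility
#' @details `harm_condition_inequality()` evaluates the closed-form harm
#'   condition in its threshold form,
#'   `2 alpha_C / d > |c^S| - ((b^S / b^O) |c^O| - |c^S|)`,
#'   which for `b^O > 0` is algebraically equivalent to the direct sign
#'   evaluation.
#' @export
harm_condition_inequality <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  bS <- net_slope(params$subjective)
  bO <- net_slope(params$objective)
  cS <- net_curvature(params$subjective)
  cO <- net_curvature(params$objective)
  2 * params$alpha_C / params$d >
    abs(cS) - ((bS / bO) * abs(cO) - abs(cS))
}

#' Harm thresholds on amount and stock
#'
#' `harm_threshold_amount()` is the positive root `2 b^O / |c^O|` of the
#' objective baseline quadratic: experienced baseline utility is positive
#' below it, zero at it, and negative above it. When `b^O <= 0` every
#' positive amount yields negative experienced utility; the threshold is
#' reported as 0 with the attribute `harmful_at_any_amount` set.
#'
#' `harm_threshold_stock()` inverts the myopic rule at that amount:
#' `S* = (|c^S| * A_harm - b^S) / alpha_C`, clipped at 0. The indirect
#' experienced-utility curve changes sign at this stock.
#'
#' @param params an [agent_parameters()] object.
#' @return A non-negative amount or stock; possibly with attribute
#'   `harmful_at_any_amount = TRUE`.
#' @export
harm_threshold_amount <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  bO <- net_slope(params$objective)
  if (bO <= 0) {
    return(structure(0, harmful_at_any_amount = TRUE))
  }
  2 * bO / abs(net_curvature(params$objective))
}

#' @rdname harm_threshold_amount
#' @export
harm_threshold_stock <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  bS <- net_slope(params$subjective)
  if (bS <= 0) {
    stop("agent does not participate; harm threshold stock is undefined",
         call. = FALSE)
  }
  A_h <- harm_threshold_amount(params)
  if (isTRUE(attr(A_h, "harmful_at_any_amount"))) {
    return(structure(0, harmful_at_any_amount = TRUE))
  }
  max(0, (abs(net_curvature(params$subjective)) * A_h - bS) / params$alpha_C)
}

#' Classify an agent's long-run gambling regime
#'
#' Composes the participation condition, the convergence condition, the
#' equilibrium values, and the harm verdict into one record. Regimes:
#' `non_participant` (subjective net slope not positive, or no income),
#' `divergent_harmful` (participates, amount grows indefinitely),
#' `harmful_equilibrium` (converges to negative long-run experienced
#' utility), `benign_equilibrium` (converges with non-negative long-run
#' utility; the exact-zero boundary counts as benign).
#'
#' @param params an [agent_parameters()] object.
#' @return An object of class `regime_classification` with fields
#'   `participates`, `converges`, `equilibrium_amount`, `equilibrium_stock`,
#'   `long_run_experienced_utility` (`-Inf` for divergent agents),
#'   `develops_negative_utility`, `harm_threshold_amount`,
#'   `harm_threshold_stock`, `harmful_at_any_amount` and `regime`.
#' @examples
#' ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.6, d = 0.5)
#' classify_agent(ag)
#' @export
classify_agent <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  participates <- net_slope(params$subjective) > 0 && any(params$income > 0)
  converges <- reaches_equilibrium(params)

  out <- list(
    participates = participates,
    converges = converges,
    equilibrium_amount = NA_real_,
    equilibrium_stock = NA_real_,
    long_run_experienced_utility = NA_real_,
    develops_negative_utility = FALSE,
    harm_threshold_amount = NA_real_,
    harm_threshold_stock = NA_real_,
    harmful_at_any_amount = FALSE,
    regime = "non_participant"
  )

  if (!participates) {
    return(structure(out, class = "regime_classification"))
  }

  A_h <- harm_threshold_amount(params)
  out$harmful_at_any_amount <- isTRUE(attr(A_h, "harmful_at_any_amount"))
  out$harm_threshold_amount <- as.numeric(A_h)
  S_h <- harm_threshold_stock(params)
  out$harm_threshold_stock <- as.numeric(S_h)

  if (!converges) {
    out$develops_negative_utility <- TRUE
    out$long_run_experienced_utility <- -Inf
    out$regime <- "divergent_harmful"
    return(structure(out, class = "regime_classification"))
  }

  out$equilibrium_amount <- equilibrium_amount(params)
  out$equilibrium_stock <- equilibrium_stock(params)
  out$long_run_experienced_utility <-
    baseline_gamble_utility(out$equilibrium_amount, params$objective)
  out$develops_negative_utility <- out$long_run_experienced_utility < 0
  out$regime <- if (out$develops_negative_utility) "harmful_equilibrium"
                else "benign_equilibrium"
  structure(out, class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("<regime_classification> %s\n", x$regime))
  cat(sprintf("  participates: %s  converges: %s  harmful: %s\n",
              x$participates, x$converges, x$develops_negative_utility))
  if (x$converges && x$participates) {
    cat(sprintf("  equilibrium amount %.6g, stock %.6g, long-run utility %.6g\n",
                x$equilibrium_amount, x$equilibrium_stock,
                x$long_run_experienced_utility))
  }
  if (x$participates) {
    cat(sprintf("  harm thresholds: amount %.6g, stock %.6g%s\n",
                x$harm_threshold_amount, x$harm_threshold_stock,
                if (x$harmful_at_any_amount) " (harmful at any amount)" else ""))
  }
  invisible(x)
}
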