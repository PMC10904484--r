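#' Evolution of the stock of past gambling
#'
#' One step of the stock recursion `S_t = (1 - d) * S_{t-1} + A_{t-1}`:
#' existing stock depreciates by the fraction `d` and the amount actually
#' gambled is added. Under abstinence the stock decays geometrically toward
#' zero but never becomes negative, so cravings persist while diminishing.
#'
#' @param S current stock (non-negative).
#' @param A amount gambled this period (non-negative).
#' @param d depreciation fraction, strictly inside (0, 1).
#' @return The next-period stock.
#' @examples
#' stock_update(10, 3, 0.2)  # 11
#' @export
stock_update <- function(S, A, d) {
  check_amount(S, "S")
  check_amount(A)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) ||
      d <= 0 || d >= 1) {
    stop("`d` must lie strictly inside (0, 1)", call. = FALSE)
  }
  (1 - d) * S + A
}

#' Myopic optimal amount gambled
#'
#' The amount maximising current-period decision utility at stock `S`:
#' `A*(S) = -(b + alpha_C * S) / c` with `b` and `c` the subjective net
#' slope and curvature, and a corner solution at 0 when the interior
#' optimum is negative. At `S = 0` this is positive precisely when
#' `alpha_P^S > -alpha_M^S`, which is the participation condition for a
#' non-gambler. Gambling `A*(S)` exactly satisfies cravings.
#'
#' @param S stock of past gambling (non-negative scalar).
#' @param params an [agent_parameters()] object.
#' @return The optimal non-negative amount.
#' @examples
#' ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 1, d = 0.5)
#' myopic_optimal_amount(0, ag)  # 0.5
#' myopic_optimal_amount(1, ag)  # 1
#' @export
myopic_optimal_amount <- function(S, params) {
  check_amount(S, "S")
  stopifnot(inherits(params, "agent_parameters"))
  b <- net_slope(params$subjective)
  c_ <- net_curvature(params$subjective)
  pmax(0, -(b + params$alpha_C * S) / c_)
}

#' Grid-search maximiser of decision utility
#'
#' Verification oracle for the closed-form myopic optimum: evaluates
#' decision utility on the grid `{0, step, 2*step, ...}` up to four times
#' the closed-form bound and returns the argmax. Agrees with
#' [myopic_optimal_amount()] to within one grid step, including corner
#' solutions at zero.
#'
#' @inheritParams myopic_optimal_amount
#' @param grid_step positive grid spacing.
#' @return The grid amount with the highest decision utility.
#' @export
brute_force_optimum <- function(S, params, grid_step = 1e-4) {
  check_amount(S, "S")
  stopifnot(inherits(params, "agent_parameters"))
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0) {
    stop("`grid_step` must be positive", call. = FALSE)
  }
  b <- net_slope(params$subjective)
  c_ <- net_curvature(params$subjective)
  bound <- max(0, -(b + params$alpha_C * S) / c_)
  A_max <- max(4 * bound, grid_step)
  grid <- seq(0, A_max, by = grid_step)
  u <- decision_utility(grid, S, params)
  grid[which.max(u)]
}

#' Simulate a gambling trajectory under myopic optimisation
#'
#' Each period the agent computes the unconstrained myopic optimum from the
#' start-of-period stock, then gambles the minimum of that optimum, the
#' period's income, and any external cap. Craving losses are positive
#' exactly when the realised amount falls short of the optimum while stock
#' is positive ("gamble their total available income" when constrained).
#' Gambler status moves from non-gambler to current gambler on the first
#' positive amount, and to ex-gambler in the first abstaining period after
#' having gambled (relapse moves it back). The stock then evolves by
#' `S' = (1 - d) S + A` using the realised amount.
#'
#' Convergence is declared when consecutive amounts change by less than
#' `tol` for five periods in a row; a trajectory whose amounts are still
#' growing at the horizon for a non-converging agent is flagged divergent.
#'
#' @param params an [agent_parameters()] object.
#' @param T_horizon number of periods to simulate (>= 1).
#' @param S0 initial stock of past gambling (default 0: a non-gambler; a
#'   current gambler entering mid-history can be given positive stock).
#' @param cap optional per-period maximum amount (scalar or schedule,
#'   recycled by its last value); `NULL` means no cap.
#' @param tol convergence tolerance on consecutive amounts.
#' @return An object of class `gambling_trajectory`: a list with `periods`
#'   (data frame with columns `t`, `S`, `A_star`, `A`, `U_decision`,
#'   `U_experienced`, `craving_loss`, `status`), discounted
#'   `lifetime_decision_utility` and `lifetime_experienced_utility`, and
#'   flags `converged` and `divergent`.
#' @examples
#' ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5)
#' tr <- simulate_trajectory(ag, T_horizon = 100)
#' tail(tr$periods$A, 1)  # ~ equilibrium_amount(ag)
#' @export
simulate_trajectory <- function(params, T_horizon, S0 = 0, cap = NULL,
                                tol = 1e-9) {
  stopifnot(inherits(params, "agent_parameters"))
  if (!is.numeric(T_horizon) || length(T_horizon) != 1L || T_horizon < 1) {
    stop("`T_horizon` must be at least 1", call. = FALSE)
  }
  T_horizon <- as.integer(T_horizon)
  check_amount(S0, "S0")
  if (!is.null(cap)) check_amount(cap, "cap")

  cap_at <- function(t) {
    if (is.null(cap)) return(Inf)
    if (length(cap) == 1L) cap else cap[min(t + 1L, length(cap))]
  }

  n <- T_horizon
  S <- A_star <- A <- Ud <- Ue <- cl <- numeric(n)
  status <- character(n)
  has_gambled <- FALSE
  s <- S0
  for (t in seq_len(n) - 1L) {
    i <- t + 1L
    S[i] <- s
    A_star[i] <- myopic_optimal_amount(s, params)
    A[i] <- min(A_star[i], income_at(params, t), cap_at(t))
    Ud[i] <- decision_utility(A[i], s, params)
    Ue[i] <- experienced_utility(A[i], s, params)
    cl[i] <- craving_disutility(A[i], s, params)
    if (A[i] > 0) {
      status[i] <- "current_gambler"
      has_gambled <- TRUE
    } else {
      status[i] <- if (has_gambled) "ex_gambler" else "non_gambler"
    }
    s <- stock_update(s, A[i], params$d)
  }

  dA <- abs(diff(A))
  converged <- FALSE
  if (n >= 6L) {
    small <- dA < tol
    run <- 0L
    for (k in seq_along(small)) {
      run <- if (small[k]) run + 1L else 0L
      if (run >= 5L) { converged <- TRUE; break }
    }
  }
  divergent <- !converged && !reaches_equilibrium(params) &&
    n >= 2L && A[n] > A[1L]

  structure(
    list(
      periods = data.frame(
        t = seq_len(n) - 1L, S = S, A_star = A_star, A = A,
        U_decision = Ud, U_experienced = Ue, craving_loss = cl,
        status = status, stringsAsFactors = FALSE),
      lifetime_decision_utility = lifetime_utility(Ud, params$delta),
      lifetime_experienced_utility = lifetime_utility(Ue, params$delta),
      converged = converged,
      divergent = divergent,
      params = params
    ),
    class = "gambling_trajectory"
  )
}

#' @export
print.gambling_trajectory <- function(x, ...) {
  n <- nrow(x$periods)
  cat(sprintf("<gambling_trajectory> %d periods; final A=%.6g, S=%.6g\n",
              n, x$periods$A[n], x$periods$S[n]))
  cat(sprintf("  lifetime decision utility   : %.6g\n",
              x$lifetime_decision_utility))
  cat(sprintf("  lifetime experienced utility: %.6g\n",
              x$lifetime_experienced_utility))
  cat(sprintf("  converged: %s  divergent: %s\n",
              x$converged, x$divergent))
  invisible(x)
}
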