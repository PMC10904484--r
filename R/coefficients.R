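#' Utility coefficients for one belief frame
#'
#' Bundles the four coefficients of the quadratic single-period utility of
#' gambling for one belief frame: the linear and quadratic psychological
#' coefficients and the linear and quadratic monetary coefficients. The
#' `subjective` frame holds the (possibly biased) beliefs the agent decides
#' on; the `objective` frame holds the coefficients that determine what the
#' agent actually experiences.
#'
#' Restrictions enforced at construction:
#' * `alpha_PP < 0` and `alpha_MM < 0` in both frames (concavity of the
#'   psychological component; risk aversion over wealth).
#' * `alpha_M < 0` in the objective frame (gambles carry an objective
#'   expected monetary loss). The subjective `alpha_M` is unrestricted, so a
#'   biased agent may believe in an expected monetary gain.
#'
#' @param alpha_P linear psychological coefficient (utility per unit amount
#'   gambled); positive when the agent has net positive psychological
#'   effects for some amounts.
#' @param alpha_PP quadratic psychological coefficient; must be negative.
#' @param alpha_M linear monetary coefficient.
#' @param alpha_MM quadratic monetary coefficient; must be negative.
#' @param frame `"subjective"` or `"objective"`.
#'
#' @return An object of class `coefficient_set`.
#' @examples
#' cs <- coefficient_set(1, -1, -0.25, -1, frame = "subjective")
#' net_slope(cs)      # alpha_P + alpha_M
#' net_curvature(cs)  # alpha_PP + alpha_MM (always negative)
#' @export
coefficient_set <- function(alpha_P, alpha_PP, alpha_M, alpha_MM,
                            frame = c("subjective", "objective")) {
  frame <- match.arg(frame)
  for (nm in c("alpha_P", "alpha_PP", "alpha_M", "alpha_MM")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (alpha_PP >= 0) {
    stop("`alpha_PP` must be negative (concave psychological utility)",
         call. = FALSE)
  }
  if (alpha_MM >= 0) {
    stop("`alpha_MM` must be negative (risk aversion over wealth)",
         call. = FALSE)
  }
  if (frame == "objective" && alpha_M >= 0) {
    stop("objective `alpha_M` must be negative (expected monetary loss)",
         call. = FALSE)
  }
  structure(
    list(alpha_P = alpha_P, alpha_PP = alpha_PP,
         alpha_M = alpha_M, alpha_MM = alpha_MM, frame = frame),
    class = "coefficient_set"
  )
}

#' @rdname coefficient_set
#' @param x a `coefficient_set`.
#' @details `net_slope()` returns `alpha_P + alpha_M`, the marginal utility
#'   of the first unit gambled; a non-gambler participates if and only if it
#'   is positive in the subjective frame. `net_curvature()` returns
#'   `alpha_PP + alpha_MM`, which is negative by construction.
#' @export
net_slope <- function(x) {
  stopifnot(inherits(x, "coefficient_set"))
  x$alpha_P + x$alpha_M
}

#' @rdname coefficient_set
#' @export
net_curvature <- function(x) {
  stopifnot(inherits(x, "coefficient_set"))
  x$alpha_PP + x$alpha_MM
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf(
    "<coefficient_set [%s]> alpha_P=%g alpha_PP=%g alpha_M=%g alpha_MM=%g\n",
    x$frame, x$alpha_P, x$alpha_PP, x$alpha_M, x$alpha_MM))
  invisible(x)
}
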