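# Random valid agents for property-style tests.
#
# Draws are constructed so that requested structural properties hold by
# construction:
#   * participating = TRUE forces a positive subjective net slope.
#   * convergent = TRUE draws alpha_C = u * |c^S| * d with u in
#     `u_range` below 1, so |c^S| > alpha_C / d holds and the amount
#     recursion contracts with ratio 1 - d(1 - u); convergent = FALSE uses
#     u above 1.
#   * biased = TRUE subtracts independent non-negative wedges from each
#     subjective coefficient to form the objective frame (so every
#     subjective coefficient weakly exceeds its objective counterpart).
rand_agent <- function(participating = TRUE, convergent = TRUE,
                       biased = FALSE, u_range = c(0.1, 0.8),
                       income = Inf) {
  alpha_M_S <- runif(1, -1, if (biased) 0.3 else -0.05)
  alpha_P_S <- if (participating) {
    -alpha_M_S + runif(1, 0.1, 1.5)
  } else {
    -alpha_M_S - runif(1, 0.1, 1.5)
  }
  alpha_PP_S <- runif(1, -2, -0.2)
  alpha_MM_S <- runif(1, -2, -0.2)
  if (biased) {
    wedge <- runif(4, 0, 0.3)
    alpha_P_O <- alpha_P_S - wedge[1]
    alpha_PP_O <- alpha_PP_S - wedge[2]
    alpha_M_O <- min(alpha_M_S, -0.01) - wedge[3]
    alpha_MM_O <- alpha_MM_S - wedge[4]
  } else {
    alpha_P_O <- alpha_P_S
    alpha_PP_O <- alpha_PP_S
    alpha_M_O <- alpha_M_S
    alpha_MM_O <- alpha_MM_S
  }
  d <- runif(1, 0.3, 0.9)
  cS_abs <- abs(alpha_PP_S + alpha_MM_S)
  # divergent draws keep the expansion ratio moderate so a 500-period
  # trajectory stays within double range while still growing unboundedly
  u <- if (convergent) runif(1, u_range[1], u_range[2])
       else runif(1, 1.05, 1.5)
  agent_parameters(
    subjective = coefficient_set(alpha_P_S, alpha_PP_S, alpha_M_S,
                                 alpha_MM_S, frame = "subjective"),
    objective  = coefficient_set(alpha_P_O, alpha_PP_O, alpha_M_O,
                                 alpha_MM_O, frame = "objective"),
    alpha_C = u * cS_abs * d, d = d, delta = runif(1, 0, 0.3),
    income = income
  )
}

# the worked reference agents used across tests: unbiased, b = 1, c = -2
boundary_agent <- function(alpha_C = 0.5) {
  unbiased_agent(alpha_P = 1.5, alpha_PP = -1, alpha_M = -0.5,
                 alpha_MM = -1, alpha_C = alpha_C, d = 0.5)
}
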