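# Independent literal transcription of the single-period utility formulas,
# written symbol-by-symbol from the model definition and kept separate from
# the package implementation. Used only as an oracle.
lit_UP <- function(A, aP, aPP) aP * A + aPP / 2 * A^2
lit_UM <- function(A, aM, aMM) aM * A + aMM / 2 * A^2

lit_UC <- function(A, S, aP, aPP, aM, aMM, aC) {
  max(aC * S * ((-(aP + aM + aC * S)) / (aPP + aMM) - A), 0)
}

lit_decision <- function(A, S, p) {
  s <- p$subjective
  lit_UP(A, s$alpha_P, s$alpha_PP) + lit_UM(A, s$alpha_M, s$alpha_MM) -
    lit_UC(A, S, s$alpha_P, s$alpha_PP, s$alpha_M, s$alpha_MM, p$alpha_C)
}

lit_experienced <- function(A, S, p) {
  s <- p$subjective; o <- p$objective
  lit_UP(A, o$alpha_P, o$alpha_PP) + lit_UM(A, o$alpha_M, o$alpha_MM) -
    lit_UC(A, S, s$alpha_P, s$alpha_PP, s$alpha_M, s$alpha_MM, p$alpha_C)
}

lit_lifetime <- function(u, delta) {
  total <- 0
  for (t in seq_along(u) - 1L) total <- total + (1 - delta)^t * u[t + 1L]
  total
}
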