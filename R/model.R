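#' Monod growth function
#'
#' Saturating growth-rate response to nutrient concentration,
#' `g_max * P / (k_P + P)`.  Equals half the maximum rate when the nutrient
#' concentration equals the half-saturation constant.
#'
#' @param g_max Maximum specific growth rate, 1/h.
#' @param k_P Half-saturation constant, uM (> 0).
#' @param P Nutrient concentration, uM.
#' @return Growth rate in 1/h, in `[0, g_max)`.
#' @export
#' @examples
#' monod_growth(0.1, 0.5, 0.5)  # half-saturation: 0.05
monod_growth <- function(g_max, k_P, P) {
  if (any(g_max < 0) || any(k_P <= 0) || any(P < 0))
    stop("monod_growth() requires g_max >= 0, k_P > 0, P >= 0",
         call. = FALSE)
  g_max * P / (k_P + P)
}

#' Haldane-type growth inhibition factor
#'
#' Growth multiplier `1 / (1 + X / H)`: equal to 1 in the absence of the
#' inhibitory substance and to 0.5 when the inhibitor concentration `X`
#' equals the half-inhibition constant `H`.
#'
#' @param H Half-inhibition constant, uM (> 0).
#' @param X Inhibitor concentration, uM.
#' @return Dimensionless factor in `(0, 1]`.
#' @export
#' @examples
#' haldane_inhibition(100, 100)  # 0.5 by definition
haldane_inhibition <- function(H, X) {
  if (any(H <= 0) || any(X < 0))
    stop("haldane_inhibition() requires H > 0 and X >= 0", call. = FALSE)
  1 / (1 + X / H)
}

#' Time derivatives of the ecosystem model
#'
#' The five coupled rates of change: both bacterial groups grow on
#' phosphorus (Monod), are inhibited by the substrate produced by the other
#' group (Haldane) and die at a constant rate; each substrate is produced in
#' proportion to the growth of its producer, lost by abiotic oxidation of
#' sulfide by oxygen (`c * O * S`, removing both), and exchanged with a fixed
#' background pool at its diffusivity; phosphorus is consumed in proportion
#' to growth over the yield, and diffuses likewise.
#'
#' This pure-R evaluation mirrors the compiled right-hand side used by the
#' integrator and is intended for diagnostics (steady-state residuals) and
#' testing.
#'
#' @param state Named state vector (see [system_state()]).
#' @param params A `symtip_params` object.
#' @param a_O Oxygen diffusivity, 1/h.
#' @param a_S Sulfide diffusivity, 1/h.
#' @return Named numeric vector of time derivatives, same layout as `state`.
#' @export
model_derivatives <- function(state, params, a_O, a_S) {
  stopifnot(inherits(params, "symtip_params"))
  if (!all(is.finite(state)))
    stop("non-finite state component", call. = FALSE)
  if (a_O < 0 || a_S < 0)
    stop("diffusivities must be nonnegative", call. = FALSE)
  N_CB <- unname(state["N_CB"]); N_SB <- unname(state["N_SB"])
  O <- unname(state["O"]); S <- unname(state["S"]); P <- unname(state["P"])
  g  <- monod_growth(params$g_max, params$k_P, P)
  hS <- haldane_inhibition(params$H_S, S)
  hO <- haldane_inhibition(params$H_O, O)
  ox <- params$c * O * S
  c(N_CB = g * hS * N_CB - params$m * N_CB,
    N_SB = g * hO * N_SB - params$m * N_SB,
    O = params$p_O * g * hS * N_CB - ox + a_O * (params$O_b - O),
    S = params$p_S * g * hO * N_SB - ox + a_S * (params$S_b - S),
    P = -(g * hS * N_CB + g * hO * N_SB) / params$y_P +
      params$alpha_P * (params$P_b - P))
}
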