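#' Create a homeostatic reward circuit at equilibrium
#'
#' Two rate neurons: R receives and amplifies reward input on top of a tonic
#' baseline; M's activity is the product of the plastic weight `W` and R's
#' activity. A setpoint rule on postsynaptic activity drives `W` toward
#' `M_set / x_R`. Reward experience is the linear readout
#' `RE = k_RE * (x_M - M_set)`: positive under fresh reward, negative in
#' withdrawal when a depressed weight acts on the tonic baseline alone.
#'
#' @param ap Affect parameter block (`config$affect`).
#' @return HRC state list: pulse `u`, rates `x_R`, `x_M`, weight `W`, readout
#'   `RE`.
#' @export
make_hrc <- function(ap) {
  x_R <- ap$r0
  x_M <- ap$W_init * x_R
  list(u = 0, x_R = x_R, x_M = x_M, W = ap$W_init,
       RE = ap$k_RE * (x_M - ap$M_set))
}

#' Inject a reward pulse into the circuit
#'
#' Adds `g_pulse * r` to the reward-input trace; one call per consumption
#' event. Negative rewards (noxious prey) pass through the same channel.
#'
#' @param hrc HRC state.
#' @param r Signed reward magnitude.
#' @param ap Affect parameter block.
#' @return The updated HRC state.
#' @export
inject_reward <- function(hrc, r, ap) {
  if (!is.finite(r)) stop("non-finite reward", call. = FALSE)
  hrc$u <- hrc$u + ap$g_pulse * r
  hrc
}

#' Advance the homeostatic reward circuit one tick
#'
#' Dynamics per tick: the input trace decays (`u <- u (1 - 1/tau_u) + input`);
#' `x_R = max(0, r0 + u)`; `x_M = W x_R`; the weight follows the homeostatic
#' setpoint rule `W <- clamp(W + eta_W (M_set - x_M), W_min, W_max)`; the
#' readout is `RE = k_RE (x_M - M_set)`. Sustained positive input drives `W`
#' down (desensitization); removing input afterwards leaves `x_M = W r0`
#' below the setpoint, i.e. negative `RE` (withdrawal), which decays back to
#' zero as `W` recovers (resensitization).
#'
#' @param hrc HRC state.
#' @param ap Affect parameter block.
#' @param input Optional sustained drive added to the input trace this tick
#'   (event pulses go through [inject_reward()] instead).
#' @return The updated HRC state (with its `RE` readout).
#' @export
hrc_step <- function(hrc, ap, input = 0) {
  if (!all(is.finite(c(hrc$u, hrc$W, input)))) {
    stop("non-finite reward-circuit state", call. = FALSE)
  }
  hrc$u <- hrc$u * (1 - 1 / ap$tau_u) + input
  hrc$x_R <- max(0, ap$r0 + hrc$u)
  hrc$x_M <- hrc$W * hrc$x_R
  hrc$W <- min(max(hrc$W + ap$eta_W * (ap$M_set - hrc$x_M), ap$W_min), ap$W_max)
  hrc$RE <- ap$k_RE * (hrc$x_M - ap$M_set)
  hrc
}

#' Create a pain-center state
#'
#' @return Pain state list: output `P` (non-negative) and `site`, the
#'   body-relative bearing (degrees) of the last applied stimulus.
#' @export
make_pain <- function() {
  list(P = 0, site = NA_real_)
}

#' Advance the pain center one tick
#'
#' `P <- P (1 - 1/tau_P) + applied_strength`; without input, pain decays
#' geometrically toward zero. The stimulus site is recorded for somatic-map
#' routing (pain contributes an aversive-side input at its bearing). A
#' sustained stimulus of strength `A` is maintained by applying `A / tau_P`
#' per tick, which holds `P` at `A` in steady state.
#'
#' @param pain Pain state.
#' @param applied_strength Non-negative strength applied this tick.
#' @param ap Affect parameter block.
#' @param site Bearing (degrees, body-relative) of the applied stimulus.
#' @return The updated pain state.
#' @export
pain_step <- function(pain, applied_strength = 0, ap, site = pain$site) {
  if (applied_strength < 0) config_error("pain strength must be >= 0")
  pain$P <- pain$P * (1 - 1 / ap$tau_P) + applied_strength
  if (applied_strength > 0) pain$site <- site
  pain
}

#' Reciprocal inhibition of reward experience and pain
#'
#' Positive reward experience and pain suppress each other; whichever
#' dominates becomes the major suppressor of appetitive state. Negative
#' reward experience (withdrawal) amplifies pain instead:
#' `P_eff = max(0, P (1 + c_p max(0, -RE)) - k_pr max(0, RE))`,
#' `RE_eff = max(0, max(0, RE) - k_rp P)`, and the net suppression fed to the
#' appetitive state is `Q = P_eff + RE_eff`. With large positive `RE` and
#' matching pain the two cancel, so a pain stimulus can disinhibit appetitive
#' state and evoke an approach turn.
#'
#' @param RE Signed reward experience.
#' @param P Non-negative pain output.
#' @param k_rp Pain suppression of positive reward experience.
#' @param k_pr Positive-RE suppression of pain.
#' @param c_p Amplification of pain by negative reward experience.
#' @return List with `Q` (net suppression), `P_eff`, and `RE_eff`.
#' @export
mutual_inhibition <- function(RE, P, k_rp, k_pr, c_p) {
  re_pos <- max(0, RE)
  re_neg <- max(0, -RE)
  P_eff <- max(0, P * (1 + c_p * re_neg) - k_pr * re_pos)
  RE_eff <- max(0, re_pos - k_rp * P)
  list(Q = P_eff + RE_eff, P_eff = P_eff, RE_eff = RE_eff)
}
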