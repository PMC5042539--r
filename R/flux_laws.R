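#' Elementary flux laws of the compartmental network
#'
#' Every mass transfer or reaction in the model is one of four rate laws.
#' All state variables are amounts (mmol) and all rates are mmol/h; the
#' Michaelis constant is the amount at which a carrier runs at half its
#' capacity, so compartment volumes never enter a flux law.
#'
#' * `first_order_rate()`: rate `k * A` for passive diffusion, transit and
#'   linear metabolic steps.
#' * `saturable_rate()`: carrier-mediated transport following
#'   `vmax * A / (km + A)`.
#' * `competitive_rate()`: saturable transport of one substrate with
#'   competitive inhibition by a second substrate sharing the carrier,
#'   `vmax * A / (km * (1 + A/km + A_comp/km_comp))`. At
#'   `amount_comp = 0` this reduces to `saturable_rate()` exactly (the
#'   implementation uses the algebraically identical form
#'   `vmax * A / (km + A + (km/km_comp) * A_comp)` so the reduction holds
#'   to floating point).
#' * `zero_order_with_feedback()`: constant production damped by a
#'   saturable negative-feedback multiplier (see [feedback_law()]).
#'
#' @param k first-order rate constant (1/h), `>= 0`.
#' @param amount amount (mmol) of the transported or reacting state, `>= 0`.
#' @param vmax maximum velocity of the carrier (mmol/h), `>= 0`.
#' @param km Michaelis constant (mmol), `> 0`.
#' @param km_comp Michaelis constant (mmol) of the competing substrate, `> 0`.
#' @param amount_comp amount (mmol) of the competing substrate, `>= 0`.
#' @param base_rate zero-order production rate (mmol/h), `>= 0`.
#' @param law a [feedback_law()], or `NULL` for no feedback.
#' @param inhibitor_amounts amounts (mmol) of the circulating inhibitor
#'   states, aligned with `law$inhibitor_states`.
#' @return Rate in mmol/h.
#' @examples
#' first_order_rate(0.5, 10)            # 5
#' saturable_rate(4, 2, 2)              # half saturation: 2
#' competitive_rate(4, 2, 2, km_comp = 5, amount_comp = 0)  # reduces to 2
#' zero_order_with_feedback(3, feedback_law(1, imax = 1, ic50 = 5), 5)
#' @name flux_laws
NULL

#' @rdname flux_laws
#' @export
first_order_rate <- function(k, amount) {
  check_nonneg(k, "k")
  check_nonneg(amount, "amount")
  k * amount
}

#' @rdname flux_laws
#' @export
saturable_rate <- function(vmax, km, amount) {
  check_nonneg(vmax, "vmax")
  check_pos(km, "km")
  check_nonneg(amount, "amount")
  vmax * amount / (km + amount)
}

#' @rdname flux_laws
#' @export
competitive_rate <- function(vmax, km, amount, km_comp, amount_comp) {
  check_nonneg(vmax, "vmax")
  check_pos(km, "km")
  check_pos(km_comp, "km_comp")
  check_nonneg(amount, "amount")
  check_nonneg(amount_comp, "amount_comp")
  vmax * amount / (km + amount + (km / km_comp) * amount_comp)
}

#' Saturable negative-feedback law on zero-order production
#'
#' Circulating factors (blood ketone bodies and a lumped "other" state
#' standing for compounds such as glucose and insulin) inhibit endogenous
#' ketogenesis. The inhibition is saturable: with
#' `S = sum(weights * inhibitor_amounts)` the production multiplier is
#' `1 - imax * S / (ic50 + S)`, which lies in `(1 - imax, 1]` and equals 1
#' when all inhibitor amounts are zero.
#'
#' @param inhibitor_states integer ids of the circulating inhibitor states.
#' @param imax maximal fractional inhibition, in `[0, 1]`.
#' @param ic50 weighted inhibitor amount (mmol) giving half-maximal
#'   inhibition, `> 0`.
#' @param weights non-negative weights applied to the inhibitor amounts;
#'   zero a weight to exclude a state from the feedback signal.
#' @return An object of class `keto_feedback`.
#' @export
feedback_law <- function(inhibitor_states, imax, ic50,
                         weights = rep(1, length(inhibitor_states))) {
  inhibitor_states <- as.integer(inhibitor_states)
  if (length(inhibitor_states) < 1L) stop("need at least one inhibitor state")
  check_fraction(imax, "imax")
  check_pos(ic50, "ic50")
  check_nonneg(weights, "weights")
  if (length(weights) != length(inhibitor_states))
    stop("`weights` must match `inhibitor_states` in length")
  structure(list(inhibitor_states = inhibitor_states, imax = imax,
                 ic50 = ic50, weights = weights),
            class = "keto_feedback")
}

feedback_multiplier <- function(law, inhibitor_amounts) {
  s <- sum(law$weights * pmax(inhibitor_amounts, 0))
  1 - law$imax * s / (law$ic50 + s)
}

#' @rdname flux_laws
#' @export
zero_order_with_feedback <- function(base_rate, law = NULL,
                                     inhibitor_amounts = NULL) {
  check_nonneg(base_rate, "base_rate")
  if (is.null(law)) return(base_rate)
  if (!inherits(law, "keto_feedback")) stop("`law` must be a feedback_law()")
  check_nonneg(inhibitor_amounts, "inhibitor_amounts")
  base_rate * feedback_multiplier(law, inhibitor_amounts)
}
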