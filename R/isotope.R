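# natural 15N atom fraction of atmospheric nitrogen
.NAT_15N <- 0.00366

#' 15N label state of the dissolved nitrogen pools
#'
#' Atom fractions of 15N in the nitrate and ammonium pools; the nitrite pool
#' inherits the nitrate label because it is generated from nitrate and the
#' formulas neglect isotopic fractionation and label recycling through
#' anammox-produced nitrate.
#'
#' @param f15_no3 15N atom fraction of the nitrate (and derived nitrite)
#'   pool, in `[0, 1]`.
#' @param f15_nh4 15N atom fraction of the ammonium pool; defaults to
#'   natural abundance (0.00366).
#' @return An object of class `"label_state"`.
#' @export
label_state <- function(f15_no3, f15_nh4 = .NAT_15N) {
  if (f15_no3 < 0 || f15_no3 > 1 || f15_nh4 < 0 || f15_nh4 > 1)
    stop("label fractions must lie in [0, 1]")
  structure(list(f15_no3 = f15_no3, f15_nh4 = f15_nh4), class = "label_state")
}

#' Predict 29N2 and 30N2 production by isotope pairing
#'
#' Forward model for the labelled dinitrogen isotopologues produced when
#' all nitrate is reduced to nitrite and the nitrite is removed by anammox
#' (pairing one nitrite-derived with one ammonium-derived nitrogen atom,
#' 2.04 N2-N per NH4-N) and by denitrification (pairing two nitrite-derived
#' atoms). In `"as_printed"` mode the denitrification 29N2 term uses the
#' single-ordering product `f (1 - f)`; `"binomial"` mode doubles it to the
#' full heterolabel probability `2 f (1 - f)` of random pairing.
#'
#' @param label A [label_state()].
#' @param r_nh4 Ammonium oxidation rate, mmol N/d (>= 0).
#' @param r_no3_denit Nitrate reduction routed to denitrification, mmol N/d
#'   (>= 0), e.g. from [nitrate_partition()].
#' @param pairing `"as_printed"` (default) or `"binomial"`.
#' @return A list of class `"isotopologue_rates"`: `r29`, `r30`
#'   (mmol N/d) and `pairing`.
#' @examples
#' predict_isotopologues(label_state(0.2), r_nh4 = 1, r_no3_denit = 0.05)
#' @export
predict_isotopologues <- function(label, r_nh4, r_no3_denit,
                                  pairing = c("as_printed", "binomial")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(label, "label_state"))
  if (r_nh4 < 0 || r_no3_denit < 0) stop("rates must be >= 0")
  k <- anammox_coefficients()$n2_n
  fn <- label$f15_no3; fa <- label$f15_nh4
  het_denit <- if (pairing == "binomial") 2 * fn * (1 - fn) else fn * (1 - fn)
  r29 <- (fn * (1 - fa) + (1 - fn) * fa) * r_nh4 * k + het_denit * r_no3_denit
  r30 <- fn * fa * r_nh4 * k + fn^2 * r_no3_denit
  structure(list(r29 = r29, r30 = r30, pairing = pairing),
            class = "isotopologue_rates")
}

#' Invert measured isotopologue rates for the denitrification rate
#'
#' Least-squares estimate of the denitrification-routed nitrate reduction
#' rate from measured 29N2/30N2 production rates, using both isotopologue
#' equations of the pairing model with equal weights. The anammox
#' contributions (known from the label state and the ammonium oxidation
#' rate) are subtracted and the remaining one-parameter linear system is
#' solved in closed form.
#'
#' @param r29,r30 Measured 29N2-N and 30N2-N production rates, mmol N/d;
#'   vectors of equal length (one entry per observation).
#' @param label A [label_state()] with `f15_no3 > f15_nh4` (identifiable).
#' @param r_nh4 Ammonium oxidation rate, mmol N/d.
#' @param r_no3 Total nitrate consumption rate, mmol N/d (> 0); sets the
#'   denominator of the recovered share.
#' @param pairing Pairing mode assumed for the forward model.
#' @return A list of class `"denit_share"`: `r_no3_denit` (estimate,
#'   mmol N/d), `share` (fraction of generated nitrite reduced by
#'   denitrification, clipped to `[0, 1]`), `clipped` (flag), and
#'   `residual_norm` of the stacked equations at the estimate.
#' @export
invert_denit_share <- function(r29, r30, label, r_nh4, r_no3,
                               pairing = c("as_printed", "binomial")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(label, "label_state"))
  if (label$f15_no3 == 0)
    stop("non-identifiable: nitrate pool carries no 15N label")
  if (r_no3 <= 0) stop("r_no3 must be > 0")
  if (length(r29) != length(r30) || length(r29) == 0L)
    stop("r29 and r30 must be non-empty vectors of equal length")
  base <- predict_isotopologues(label, r_nh4, 0, pairing)
  unit <- predict_isotopologues(label, 0, 1, pairing)
  y <- c(r29 - base$r29, r30 - base$r30)
  x <- c(rep(unit$r29, length(r29)), rep(unit$r30, length(r30)))
  est <- sum(x * y) / sum(x * x)
  share_raw <- est / r_no3
  clipped <- share_raw < 0 || share_raw > 1
  structure(list(r_no3_denit = est,
                 share = min(max(share_raw, 0), 1),
                 clipped = clipped,
                 residual_norm = sqrt(sum((y - x * est)^2)),
                 pairing = pairing),
            class = "denit_share")
}

#' Label fraction after adding a spike to a pool
#'
#' Amount-weighted mixing of the 15N atom fractions of a pre-existing pool
#' and an added spike.
#'
#' @param amount_before,amount_spike Amounts, mmol N (>= 0, not both 0).
#' @param f_before,f_spike 15N atom fractions in `[0, 1]`.
#' @return Mixed atom fraction.
#' @examples
#' label_after_spike(5, 0.00366, 5, 0.98)  # 0.4918
#' @export
label_after_spike <- function(amount_before, f_before, amount_spike, f_spike) {
  if (amount_before < 0 || amount_spike < 0) stop("amounts must be >= 0")
  total <- amount_before + amount_spike
  if (total == 0) stop("undefined mixture: both amounts are zero")
  (amount_before * f_before + amount_spike * f_spike) / total
}

#' Denitrification share from a labelled batch dataset
#'
#' Pipeline wrapper: fits OLS production rates to the cumulative 29N2/30N2
#' partial-pressure series (gas phase, atm), converts them to mmol N/d
#' through the headspace ideal-gas law (two N per molecule), and inverts the
#' pairing model with [invert_denit_share()].
#'
#' @param p29,p30 Gas-phase [concentration_series()] of 29N2 and 30N2
#'   partial pressures (atm).
#' @param label A [label_state()].
#' @param r_nh4,r_no3 Ammonium and nitrate consumption rates, mmol N/d
#'   (per reactor).
#' @param config A [reactor_config()].
#' @param pairing Pairing mode.
#' @return A `"denit_share"` list, see [invert_denit_share()].
#' @export
estimate_denit_share <- function(p29, p30, label, r_nh4, r_no3,
                                 config = reactor_config(),
                                 pairing = c("as_printed", "binomial")) {
  to_nrate <- function(s) {
    est <- fit_rate(s)
    # atm/d of N2 molecules -> mmol N2/d -> mmol N/d
    gas_to_moles(abs(est$slope), config) * 2 * sign(est$slope)
  }
  invert_denit_share(to_nrate(p29), to_nrate(p30), label, r_nh4, r_no3,
                     pairing = match.arg(pairing))
}
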