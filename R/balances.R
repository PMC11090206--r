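#' Guild rate vector on a common basis
#'
#' Collects the measured consumption/production rates of the consortium:
#' alkane and nitrate/ammonium consumption, net nitrite change and
#' dinitrogen-gas production. All rates are magnitudes (consumption and
#' production positive) except `r_no2`, which is a signed net rate with
#' accumulation positive. Ratios (electron ratio, closure) are
#' scale-invariant, so per-litre and per-reactor rate vectors are both
#' accepted, but the basis must be declared and consistent.
#'
#' @param alkane `"propane"` or `"butane"`.
#' @param r_alkane Alkane consumption, mmol/d (or mmol/L/d).
#' @param r_nh4,r_no3 Ammonium and nitrate consumption, mmol N/d.
#' @param r_no2 Signed net nitrite rate (accumulation positive), mmol N/d.
#' @param r_n2 Dinitrogen gas production, mmol N/d.
#' @param basis `"per_reactor"` or `"per_litre"`.
#' @return An object of class `"guild_rates"`.
#' @export
guild_rates <- function(alkane = c("propane", "butane"), r_alkane, r_nh4,
                        r_no3, r_n2 = 0, r_no2 = 0,
                        basis = c("per_reactor", "per_litre")) {
  alkane <- match.arg(alkane)
  basis <- match.arg(basis)
  vals <- c(r_alkane = r_alkane, r_nh4 = r_nh4, r_no3 = r_no3, r_n2 = r_n2,
            r_no2 = r_no2)
  if (any(!is.finite(vals))) stop("guild rates must be finite")
  if (any(vals[c("r_alkane", "r_nh4", "r_no3", "r_n2")] < 0))
    stop("r_alkane, r_nh4, r_no3 and r_n2 are magnitudes and must be >= 0")
  structure(c(as.list(vals), list(alkane = alkane, basis = basis)),
            class = "guild_rates")
}

#' Partition nitrate reduction between anammox coupling and denitrification
#'
#' All nitrate is reduced to nitrite; anammox consumes 1.32 mol nitrite and
#' regenerates 0.26 mol nitrate per mol ammonium oxidized, so the nitrate
#' reduction not accounted for by anammox coupling,
#' `r_no3 + 0.26 r_nh4 - 1.32 r_nh4`, is attributed to full denitrification.
#'
#' @param r_no3 Nitrate consumption rate (>= 0), mmol N/d (any consistent
#'   basis).
#' @param r_nh4 Ammonium consumption rate (>= 0), same basis.
#' @return A list of class `"nitrate_partition"`: `r_no3_denit`,
#'   `fraction_denit` (share of generated nitrite reduced by
#'   denitrification; `NA` when `r_no3` is 0), `r_no2_anammox`
#'   (`1.32 r_nh4`), `r_no3_recycled` (`0.26 r_nh4`), and `infeasible`
#'   (`TRUE` when the anammox nitrite demand exceeds the nitrite supply,
#'   i.e. `r_no3_denit < 0`).
#' @examples
#' nitrate_partition(2.34, 2.051)  # denitrification share about 7%
#' @export
nitrate_partition <- function(r_no3, r_nh4) {
  if (r_no3 < 0 || r_nh4 < 0) stop("rates must be >= 0")
  k <- anammox_coefficients()
  r_denit <- r_no3 + k$no3 * r_nh4 - k$no2 * r_nh4
  infeasible <- r_denit < 0 || (r_no3 == 0 && r_nh4 > 0)
  if (infeasible)
    warning("anammox nitrite demand exceeds nitrite supply; ",
            "partition is infeasible at these rates")
  structure(list(r_no3_denit = r_denit,
                 fraction_denit = if (r_no3 > 0) r_denit / r_no3 else NA_real_,
                 r_no2_anammox = k$no2 * r_nh4,
                 r_no3_recycled = k$no3 * r_nh4,
                 infeasible = infeasible),
            class = "nitrate_partition")
}

#' Electron balance of the guild rates
#'
#' Donor electrons come from alkane oxidation to CO2 (20 e-/mol propane,
#' 26 e-/mol butane) and ammonium oxidation to N2 (3 e-/mol N); acceptor
#' electrons from nitrate reduction to N2 (5 e-/mol N). A ratio of 1
#' indicates a closed balance with nitrate as the sole electron sink.
#'
#' @param rates A [guild_rates()].
#' @param registry Reaction registry supplying the redox conventions.
#' @return List with `e_donated`, `e_accepted` (mmol e-/d) and `e_ratio`.
#' @examples
#' r <- guild_rates("propane", 0.35, 2.051, 2.34, basis = "per_litre")
#' electron_ratio(r)$e_ratio  # about 1.12
#' @export
electron_ratio <- function(rates, registry = default_registry()) {
  stopifnot(inherits(rates, "guild_rates"))
  if (rates$r_no3 == 0) stop("electron ratio undefined: nitrate rate is 0")
  conv <- if (rates$alkane == "propane") "propane_to_co2" else "butane_to_co2"
  cp <- if (rates$alkane == "propane") "C3H8" else "C4H10"
  e_alk <- electrons_per_mole(cp, conv, registry)
  e_nh4 <- electrons_per_mole("NH4", "ammonium_to_n2", registry)
  e_no3 <- electrons_per_mole("NO3", "nitrate_to_n2", registry)
  donated <- e_alk * rates$r_alkane + e_nh4 * rates$r_nh4
  accepted <- e_no3 * rates$r_no3
  list(e_donated = donated, e_accepted = accepted,
       e_ratio = donated / accepted)
}

#' Nitrogen balance of the guild rates
#'
#' Compares nitrogen leaving the dissolved pools (nitrate + ammonium
#' consumption) with nitrogen appearing as dinitrogen gas plus any net
#' nitrite accumulation. A closure near 1 means the measured products
#' account for the consumed nitrogen.
#'
#' @param rates A [guild_rates()].
#' @return List with `n_consumed`, `n_produced` (mmol N/d) and `n_closure`.
#' @export
nitrogen_balance <- function(rates) {
  stopifnot(inherits(rates, "guild_rates"))
  consumed <- rates$r_no3 + rates$r_nh4
  if (consumed == 0) stop("nitrogen closure undefined: no nitrogen consumed")
  produced <- rates$r_n2 + max(rates$r_no2, 0)
  list(n_consumed = consumed, n_produced = produced,
       n_closure = produced / consumed)
}

#' Full balance report
#'
#' @param rates A [guild_rates()].
#' @param registry Reaction registry.
#' @return A list of class `"balance_report"` combining [nitrogen_balance()]
#'   and [electron_ratio()] fields.
#' @export
balance_report <- function(rates, registry = default_registry()) {
  structure(c(nitrogen_balance(rates), electron_ratio(rates, registry)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("N: consumed %.3g, produced %.3g mmol N/d (closure %.3f)\n",
              x$n_consumed, x$n_produced, x$n_closure))
  cat(sprintf("e-: donated %.3g, accepted %.3g mmol e-/d (ratio %.3f)\n",
              x$e_donated, x$e_accepted, x$e_ratio))
  invisible(x)
}

#' Check observed batch deltas against the anammox stoichiometry
#'
#' Compares the consumed-nitrite and produced-nitrate amounts per unit of
#' consumed ammonium with the theoretical ratios of 1.32 and 0.26.
#'
#' @param delta_no2 Nitrite consumed, mmol N (> 0 expected).
#' @param delta_nh4 Ammonium consumed, mmol N (must be > 0).
#' @param delta_no3 Nitrate produced, mmol N.
#' @return List with `ratio_no2_nh4`, `ratio_no3_nh4`, and the relative
#'   deviations `dev_no2` and `dev_no3` from the theoretical values.
#' @examples
#' anammox_ratio_check(1.42, 1, 0.27)  # deviations ~ +7.6% and +3.8%
#' @export
anammox_ratio_check <- function(delta_no2, delta_nh4, delta_no3) {
  if (delta_nh4 <= 0) stop("ratio undefined: ammonium consumption must be > 0")
  k <- anammox_coefficients()
  r1 <- delta_no2 / delta_nh4
  r2 <- delta_no3 / delta_nh4
  list(ratio_no2_nh4 = r1, ratio_no3_nh4 = r2,
       dev_no2 = r1 / k$no2 - 1, dev_no3 = r2 / k$no3 - 1)
}

#' Diagnose DNRA-trigger conditions from concentration profiles
#'
#' DNRA (dissimilatory nitrate reduction to ammonium) is triggered by the
#' combination of nitrate depletion and nitrite accumulation. Nitrate is
#' depleted when its final concentration falls below `depletion`; nitrite
#' has accumulated when its maximum exceeds `accumulation`; net ammonium
#' production holds when the OLS slope of ammonium over the evaluation
#' window (from the first nitrate-depleted timepoint onward when nitrate is
#' depleted, otherwise the full series) is positive with one-sided p < 0.05.
#'
#' @param no3,no2,nh4 [concentration_series()] objects (liquid phase,
#'   mmol N/L) over a comparable time range.
#' @param depletion Nitrate depletion threshold, mmol N/L.
#' @param accumulation Nitrite accumulation threshold, mmol N/L.
#' @param alpha One-sided significance level for the ammonium slope.
#' @return A list of class `"dnra_flags"`: `nitrate_depleted`,
#'   `nitrite_accumulated`, `net_ammonium_production`, `dnra_expected`
#'   (the conjunction of the first two).
#' @export
dnra_flags <- function(no3, no2, nh4, depletion = 0.1, accumulation = 0.5,
                       alpha = 0.05) {
  for (s in list(no3, no2, nh4))
    if (length(s$times) == 0L) stop("empty concentration series")
  nitrate_depleted <- no3$values[length(no3$values)] < depletion
  nitrite_accumulated <- max(no2$values) > accumulation
  idx <- seq_along(nh4$times)
  if (nitrate_depleted) {
    t_dep <- no3$times[which(no3$values < depletion)[1L]]
    cand <- which(nh4$times >= t_dep)
    if (length(cand) >= 3L) idx <- cand
  }
  net_amm <- FALSE
  if (length(idx) >= 3L && diff(range(nh4$times[idx])) > 0) {
    fit <- suppressWarnings(summary(stats::lm(nh4$values[idx] ~ nh4$times[idx])))
    b <- fit$coefficients[2L, 1L]; se <- fit$coefficients[2L, 2L]
    df <- fit$df[2L]
    if (is.finite(se) && se > 0) {
      p_one <- stats::pt(b / se, df = df, lower.tail = FALSE)
      net_amm <- b > 0 && p_one < alpha
    }
  }
  structure(list(nitrate_depleted = nitrate_depleted,
                 nitrite_accumulated = nitrite_accumulated,
                 net_ammonium_production = net_amm,
                 dnra_expected = nitrate_depleted && nitrite_accumulated),
            class = "dnra_flags")
}
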