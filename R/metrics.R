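#' Lactation dose-calculation constants
#'
#' Daily milk intake of a fully breastfed infant (0.150 L/kg/day) and the
#' reference maternal body weight (60.3 kg, the average three-months
#' postpartum individual of the simulated population).
#'
#' @param milk_intake Infant milk intake, L/kg/day (> 0).
#' @param maternal_weight Maternal body weight, kg (> 0).
#' @return Object of class `lactation_constants`.
#' @export
lactation_constants <- function(milk_intake = 0.150, maternal_weight = 60.3) {
  stopifnot(milk_intake > 0, maternal_weight > 0)
  structure(list(milk_intake = milk_intake, maternal_weight = maternal_weight),
            class = "lactation_constants")
}

#' Linear-trapezoid partial AUC
#'
#' AUC of a sampled concentration-time curve between `t0` and `t1`, with
#' linear interpolation of the concentration at the interval bounds when
#' they fall between samples.
#'
#' @param times Sampling times, h (strictly increasing).
#' @param conc Concentrations, mg/L.
#' @param t0,t1 Integration bounds, h; must lie within the sampled range.
#' @return Partial AUC, mg*h/L.
#' @export
trapezoid_auc <- function(times, conc, t0 = min(times), t1 = max(times)) {
  stopifnot(length(times) == length(conc), length(times) >= 2)
  stopifnot(t0 < t1)
  if (t0 < min(times) - 1e-9 || t1 > max(times) + 1e-9)
    stop("integration bounds outside the sampled time range")
  inner <- times > t0 & times < t1
  tt <- c(t0, times[inner], t1)
  cc <- c(stats::approx(times, conc, xout = t0)$y,
          conc[inner],
          stats::approx(times, conc, xout = t1)$y)
  .trapz(tt, cc)
}

#' Exposure metrics over a dosing interval
#'
#' @inheritParams trapezoid_auc
#' @return Object of class `exposure_metrics`: `auc` (mg*h/L), `cmax`
#'   (mg/L), `tmax` (h), and `cave = auc / (t1 - t0)` (mg/L).
#' @export
exposure_metrics <- function(times, conc, t0 = min(times), t1 = max(times)) {
  auc <- trapezoid_auc(times, conc, t0, t1)
  win <- times >= t0 - 1e-9 & times <= t1 + 1e-9
  cmax <- max(conc[win])
  tmax <- times[win][which.max(conc[win])]
  structure(list(auc = auc, cmax = cmax, tmax = tmax,
                 cave = auc / (t1 - t0)),
            class = "exposure_metrics")
}

#' AUC-based milk-to-plasma ratio
#'
#' @param auc_milk,auc_plasma Interval AUCs at steady state, mg*h/L
#'   (`auc_plasma` > 0).
#' @return Dimensionless milk-to-plasma ratio.
#' @export
mp_ratio <- function(auc_milk, auc_plasma) {
  stopifnot(auc_milk >= 0)
  if (auc_plasma <= 0) stop("plasma AUC must be positive")
  auc_milk / auc_plasma
}

#' Daily infant dosage via breastfeeding (DID)
#'
#' `DID = C_milk * milk_intake`. Pass the average milk concentration for
#' `DID_ave` and the maximal concentration for `DID_max`.
#'
#' @param c_milk Milk concentration, mg/L (>= 0).
#' @param constants [lactation_constants()].
#' @return DID in mg/kg/day.
#' @export
daily_infant_dose <- function(c_milk, constants = lactation_constants()) {
  stopifnot(c_milk >= 0, inherits(constants, "lactation_constants"))
  c_milk * constants$milk_intake
}

#' Relative infant dose (RID)
#'
#' Infant weight-normalized daily dose via milk as a percentage of the
#' maternal weight-normalized daily dose:
#' `RID = 100 * DID / (daily_maternal_dose / maternal_weight)`.
#'
#' @param did Daily infant dose, mg/kg/day.
#' @param daily_maternal_dose Total maternal dose per day, mg/day (> 0).
#' @param constants [lactation_constants()].
#' @return RID in percent.
#' @export
relative_infant_dose <- function(did, daily_maternal_dose,
                                 constants = lactation_constants()) {
  stopifnot(did >= 0)
  if (daily_maternal_dose <= 0) stop("daily maternal dose must be positive")
  100 * did / (daily_maternal_dose / constants$maternal_weight)
}

#' Relative therapeutic infant dose
#'
#' Daily infant dose via milk as a percentage of the pediatric therapeutic
#' dose for the same medicine, when one exists.
#'
#' @param did Daily infant dose, mg/kg/day.
#' @param therapeutic_dose Pediatric therapeutic dose, mg/kg/day (> 0).
#' @return Percentage of the therapeutic dose.
#' @export
relative_therapeutic_dose <- function(did, therapeutic_dose) {
  stopifnot(did >= 0)
  if (therapeutic_dose <= 0) stop("therapeutic dose must be positive")
  100 * did / therapeutic_dose
}

#' Fold error of a prediction
#'
#' `fold_error = 10^|log10(pred/obs)|`, always >= 1 and symmetric in its
#' arguments. The conventional acceptance bound for physiological PK
#' predictions is a two-fold error.
#'
#' @param predicted,observed Positive values (vectorized).
#' @return Fold errors (>= 1).
#' @seealso [gmfe()], [within_two_fold()]
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0))
    stop("fold error requires strictly positive values")
  10^abs(log10(predicted / observed))
}

#' Geometric mean fold error (GMFE)
#'
#' @inheritParams fold_error
#' @return Geometric mean of the pairwise fold errors.
#' @export
gmfe <- function(predicted, observed) {
  fe <- fold_error(predicted, observed)
  exp(mean(log(fe)))
}

#' Two-fold acceptance flag
#'
#' @inheritParams fold_error
#' @return Logical vector: `TRUE` where the fold error is at most 2.
#' @export
within_two_fold <- function(predicted, observed) {
  fold_error(predicted, observed) <= 2
}

#' Infant dose report from a steady-state simulation
#'
#' Computes the AUC-based milk-to-plasma ratio, the daily infant dosage
#' based on the average and maximal milk concentrations, the relative infant
#' dose, and (when a pediatric therapeutic dose is supplied) the relative
#' therapeutic dose, from one dosing interval at periodic steady state.
#'
#' @param ss A `sim_result` for one dosing interval at steady state, e.g.
#'   from [simulate_to_steady_state()].
#' @param dose Maternal dose per administration, mg.
#' @param tau Dosing interval, h.
#' @param therapeutic_dose Optional pediatric therapeutic dose, mg/kg/day.
#' @param constants [lactation_constants()].
#' @return Object of class `infant_dose_report`.
#' @export
infant_dose_report <- function(ss, dose, tau, therapeutic_dose = NULL,
                               constants = lactation_constants()) {
  stopifnot(inherits(ss, "sim_result"), dose > 0, tau > 0)
  t0 <- min(ss$times)
  t1 <- t0 + tau
  pl <- exposure_metrics(ss$times, ss$c_plasma, t0, t1)
  mk <- exposure_metrics(ss$times, ss$c_milk, t0, t1)
  did_ave <- daily_infant_dose(mk$cave, constants)
  did_max <- daily_infant_dose(mk$cmax, constants)
  daily_dose <- dose * 24 / tau
  out <- list(
    mp_ratio = mp_ratio(mk$auc, pl$auc),
    plasma = pl, milk = mk,
    did_ave = did_ave, did_max = did_max,
    rid_ave = relative_infant_dose(did_ave, daily_dose, constants),
    rid_max = relative_infant_dose(did_max, daily_dose, constants),
    rid_therapeutic_ave = if (is.null(therapeutic_dose)) NA_real_ else
      relative_therapeutic_dose(did_ave, therapeutic_dose),
    rid_therapeutic_max = if (is.null(therapeutic_dose)) NA_real_ else
      relative_therapeutic_dose(did_max, therapeutic_dose),
    dose = dose, tau = tau, daily_maternal_dose = daily_dose,
    therapeutic_dose = therapeutic_dose, constants = constants)
  structure(out, class = "infant_dose_report")
}

#' @export
print.infant_dose_report <- function(x, ...) {
  cat("<infant_dose_report>\n")
  cat(sprintf("  regimen: %g mg q%gh (%g mg/day); maternal weight %.1f kg\n",
              x$dose, x$tau, x$daily_maternal_dose, x$constants$maternal_weight))
  cat(sprintf("  AUC plasma %.4g, milk %.4g mg*h/L -> M/P %.2f\n",
              x$plasma$auc, x$milk$auc, x$mp_ratio))
  cat(sprintf("  milk Cave %.4g, Cmax %.4g mg/L\n", x$milk$cave, x$milk$cmax))
  cat(sprintf("  DID %.3g (ave) / %.3g (max) mg/kg/day\n", x$did_ave, x$did_max))
  cat(sprintf("  RID %.2f%% (ave) / %.2f%% (max)\n", x$rid_ave, x$rid_max))
  if (!is.na(x$rid_therapeutic_ave))
    cat(sprintf("  %% of therapeutic dose (%g mg/kg/day): %.2f (ave) / %.2f (max)\n",
                x$therapeutic_dose, x$rid_therapeutic_ave, x$rid_therapeutic_max))
  invisible(x)
}

#' @export
as.data.frame.infant_dose_report <- function(x, ...) {
  data.frame(mp_ratio = x$mp_ratio,
             auc_plasma = x$plasma$auc, auc_milk = x$milk$auc,
             cave_milk = x$milk$cave, cmax_milk = x$milk$cmax,
             did_ave = x$did_ave, did_max = x$did_max,
             rid_ave = x$rid_ave, rid_max = x$rid_max,
             rid_therapeutic_ave = x$rid_therapeutic_ave,
             rid_therapeutic_max = x$rid_therapeutic_max)
}
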