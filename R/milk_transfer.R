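#' Secretion clearance from plasma into milk
#'
#' Semi-mechanistic regression of the plasma-to-milk secretion clearance on
#' polar surface area, molecular weight and the pH 7.4 distribution
#' coefficient:
#' `log10(CLsec) = -3.912 - 0.015*PSA + 3.367*log10(MW) - 0.164*LogD7.4`.
#' The clearance acts on the unbound plasma concentration.
#'
#' @param psa Polar surface area, Angstrom^2 (>= 0).
#' @param mw Molecular weight, g/mol (> 0).
#' @param logd74 Log10 octanol:buffer distribution coefficient at pH 7.4.
#' @return Secretion clearance, mL/h.
#' @export
compute_clsec <- function(psa, mw, logd74) {
  stopifnot(psa >= 0, mw > 0, is.finite(logd74))
  10^(-3.912 - 0.015 * psa + 3.367 * log10(mw) - 0.164 * logd74)
}

#' Reuptake clearance from milk back into plasma
#'
#' Semi-mechanistic regression of the milk-to-plasma reuptake clearance on
#' lipophilicity and hydrogen-bond donor count:
#' `log10(CLre) = 2.793 + 0.179*LogP - 0.132*HBD`. The clearance acts on the
#' unbound (total) milk concentration.
#'
#' @param logp Log10 octanol/water partition coefficient.
#' @param hbd Hydrogen-bond donor count (>= 0).
#' @return Reuptake clearance, mL/h.
#' @export
compute_clre <- function(logp, hbd) {
  stopifnot(hbd >= 0, is.finite(logp))
  10^(2.793 + 0.179 * logp - 0.132 * hbd)
}

#' Milk lipid / ultrafiltrate partition coefficient
#'
#' `log10(Pmilk) = -0.88 + 1.29 * LogD7.2`; milk pH is about 7.2, hence the
#' pH 7.2 distribution coefficient drives partitioning into the milk fat
#' fraction.
#'
#' @param logd72 Log10 distribution coefficient at pH 7.2.
#' @return Dimensionless partition coefficient (> 0).
#' @export
compute_pmilk <- function(logd72) {
  stopifnot(is.finite(logd72))
  10^(-0.88 + 1.29 * logd72)
}

#' Unbound fraction in skimmed milk
#'
#' Empirical link between plasma protein binding and milk protein binding:
#' `fu_skim = fu_plasma^0.448 / ((6.94e-4)^0.448 + fu_plasma^0.448)`.
#' Monotone increasing in `fu_plasma`, approaching ~0.963 for a fully unbound
#' drug (milk contains less binding protein than plasma).
#'
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @return Unbound fraction in skimmed milk, in (0, 1).
#' @export
compute_fu_skim <- function(fu_plasma) {
  stopifnot(fu_plasma > 0, fu_plasma <= 1)
  a <- fu_plasma^0.448
  a / ((6.94e-4)^0.448 + a)
}

#' Unbound fraction in whole milk
#'
#' Combines protein binding (via skimmed milk) with partitioning into the
#' milk fat fraction: `fu_milk_total = 1 / (0.955/fu_skim + 0.045*Pmilk)`,
#' where 0.955 / 0.045 are the aqueous and lipid volume fractions of mature
#' milk. The value is deliberately not capped at 1: the milk aqueous phase is
#' slightly smaller than whole milk, so weakly bound drugs can exceed 1 by a
#' few percent and that excess is required to reproduce published
#' milk-to-plasma ratios.
#'
#' @param fu_skim Unbound fraction in skimmed milk (> 0).
#' @param pmilk Milk lipid partition coefficient (>= 0).
#' @return Unbound fraction in whole milk (> 0, may slightly exceed 1).
#' @export
compute_fu_milk_total <- function(fu_skim, pmilk) {
  if (!is.numeric(fu_skim) || fu_skim <= 0)
    stop("'fu_skim' must be > 0 (a drug fully bound in skimmed milk is not representable)")
  stopifnot(pmilk >= 0)
  1 / (0.955 / fu_skim + 0.045 * pmilk)
}

#' Closed-form steady-state milk-to-plasma ratio
#'
#' At periodic steady state the amount secreted into milk over one dosing
#' interval equals the amount reabsorbed, so integrating the bidirectional
#' transfer rates over the interval gives
#' `AUC_milk / AUC_plasma = (fu_plasma * CLsec) / (fu_milk_total * CLre)`.
#' This is exactly the AUC-based milk-to-plasma ratio of the coupled
#' plasma--milk system at periodic steady state, independent of the maternal
#' disposition model, dose, route or interval (linearity assumed).
#'
#' @param fu_plasma Unbound fraction in plasma (> 0).
#' @param clsec Secretion clearance, mL/h (> 0).
#' @param fu_milk_total Unbound fraction in whole milk (> 0).
#' @param clre Reuptake clearance, mL/h (> 0).
#' @return Dimensionless AUC-based milk-to-plasma ratio.
#' @export
mp_ratio_steady_state <- function(fu_plasma, clsec, fu_milk_total, clre) {
  stopifnot(fu_plasma > 0, clsec > 0, fu_milk_total > 0, clre > 0)
  (fu_plasma * clsec) / (fu_milk_total * clre)
}

#' Derive all milk-transfer parameters for a drug
#'
#' Chains the pH-dependent distribution coefficients (7.4 for secretion, 7.2
#' for milk partitioning), the secretion/reuptake clearance regressions, the
#' milk binding model and the closed-form steady-state milk-to-plasma ratio
#' into one record.
#'
#' @param drug A [drug_physchem()] record.
#' @return An object of class `milk_transfer_params` with fields `clsec`,
#'   `clre` (mL/h), `pmilk`, `fu_skim`, `fu_milk_total`, `mp_ss`, plus the
#'   `logd74`/`logd72` inputs used.
#' @examples
#' met <- drug_physchem("metformin", mw = 129.16, logp = -1.43,
#'   groups = list(ionization_group("base", 2.80), ionization_group("acid", 11.50)),
#'   hbd = 3, hba = 1, psa = 91.50, fu_plasma = 1.00)
#' derive_milk_transfer(met)
#' @export
derive_milk_transfer <- function(drug) {
  stopifnot(inherits(drug, "drug_physchem"))
  logd74 <- logd(drug, 7.4)
  logd72 <- logd(drug, 7.2)
  clsec <- compute_clsec(drug$psa, drug$mw, logd74)
  clre <- compute_clre(drug$logp, drug$hbd)
  pmilk <- compute_pmilk(logd72)
  fu_skim <- compute_fu_skim(drug$fu_plasma)
  fu_milk_total <- compute_fu_milk_total(fu_skim, pmilk)
  milk_transfer_params(clsec = clsec, clre = clre, pmilk = pmilk,
                       fu_skim = fu_skim, fu_milk_total = fu_milk_total,
                       fu_plasma = drug$fu_plasma,
                       logd74 = logd74, logd72 = logd72)
}

#' Milk-transfer parameter record
#'
#' Low-level constructor; most users should call [derive_milk_transfer()].
#' Use this directly to inject externally published clearances (e.g. values
#' from a reference table) while keeping the binding chain.
#'
#' @param clsec,clre Secretion / reuptake clearances, mL/h (> 0).
#' @param pmilk Milk lipid partition coefficient (> 0 unless explicitly 0).
#' @param fu_skim Unbound fraction in skimmed milk, (0, 1].
#' @param fu_milk_total Unbound fraction in whole milk (> 0; may exceed 1).
#' @param fu_plasma Unbound plasma fraction used for the steady-state ratio.
#' @param logd74,logd72 Distribution coefficients used (optional, recorded
#'   for provenance).
#' @return Object of class `milk_transfer_params`; `mp_ss` is filled in via
#'   [mp_ratio_steady_state()]. Regression-derived clearances are always
#'   strictly positive; zero clearances are tolerated here only to allow
#'   structurally decoupled test models, in which case `mp_ss` is `NA`.
#' @export
milk_transfer_params <- function(clsec, clre, pmilk, fu_skim, fu_milk_total,
                                 fu_plasma, logd74 = NA_real_, logd72 = NA_real_) {
  stopifnot(clsec >= 0, clre >= 0, pmilk >= 0, fu_skim > 0, fu_skim <= 1,
            fu_milk_total > 0, fu_plasma > 0, fu_plasma <= 1)
  mp_ss <- if (clsec > 0 && clre > 0)
    mp_ratio_steady_state(fu_plasma, clsec, fu_milk_total, clre)
  else NA_real_
  structure(list(clsec = clsec, clre = clre, pmilk = pmilk,
                 fu_skim = fu_skim, fu_milk_total = fu_milk_total,
                 fu_plasma = fu_plasma, mp_ss = mp_ss,
                 logd74 = logd74, logd72 = logd72),
            class = "milk_transfer_params")
}

#' @export
print.milk_transfer_params <- function(x, ...) {
  cat("<milk_transfer_params>\n")
  cat(sprintf("  CLsec %.2f mL/h   CLre %.2f mL/h\n", x$clsec, x$clre))
  cat(sprintf("  Pmilk %.4g   fu,skim %.4f   fu,milk,total %.4f\n",
              x$pmilk, x$fu_skim, x$fu_milk_total))
  cat(sprintf("  LogD7.4 %.3f   LogD7.2 %.3f\n", x$logd74, x$logd72))
  cat(sprintf("  steady-state M/P (closed form) %.4f\n", x$mp_ss))
  invisible(x)
}

#' Milk-transfer summary table for a batch of drugs
#'
#' @param drugs List of [drug_physchem()] records.
#' @return A data.frame with one row per drug: the LogD inputs, clearances
#'   (mL/h), milk binding quantities and the closed-form steady-state
#'   milk-to-plasma ratio.
#' @export
milk_transfer_table <- function(drugs) {
  stopifnot(is.list(drugs), length(drugs) > 0)
  rows <- lapply(drugs, function(d) {
    tr <- derive_milk_transfer(d)
    data.frame(name = d$name, logd74 = tr$logd74, logd72 = tr$logd72,
               clsec_ml_h = tr$clsec, clre_ml_h = tr$clre,
               pmilk = tr$pmilk, fu_skim = tr$fu_skim,
               fu_milk_total = tr$fu_milk_total, mp_ss = tr$mp_ss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
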