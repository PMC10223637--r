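#' Ionization group of a drug molecule
#'
#' A single ionizable group, described by its acid dissociation constant and
#' whether the group behaves as an acid (neutral when protonated) or a base
#' (charged when protonated). A drug may carry several groups; a drug with
#' none is treated as permanently neutral.
#'
#' @param kind `"acid"` or `"base"`.
#' @param pka Acid dissociation constant, in pH units. Values outside the
#'   0--14 aqueous range trigger a warning (never a silent rejection) because
#'   they usually indicate a data-entry problem but are still mathematically
#'   usable.
#' @return An object of class `ionization_group`.
#' @examples
#' ionization_group("acid", 4.80)
#' @export
ionization_group <- function(kind, pka) {
  kind <- match.arg(kind, c("acid", "base"))
  stopifnot(is.numeric(pka), length(pka) == 1L, is.finite(pka))
  if (pka <= 0 || pka >= 14) {
    warning(sprintf("pKa %.2f lies outside the aqueous range (0, 14); using it anyway", pka),
            call. = FALSE)
  }
  structure(list(kind = kind, pka = as.numeric(pka)), class = "ionization_group")
}

#' Physicochemical record of a medicine
#'
#' Container for the molecular descriptors that drive the milk-transfer
#' predictions: molecular weight, lipophilicity, ionization, hydrogen-bond
#' donors/acceptors, polar surface area and the unbound fraction in maternal
#' plasma. Optional measured LogD overrides (at pH 7.4 and 7.2) take
#' precedence over the Henderson--Hasselbalch calculation when present.
#'
#' @param name Identifier (character scalar).
#' @param mw Molecular weight, g/mol (> 0).
#' @param logp Log10 octanol/water partition coefficient of the neutral
#'   species.
#' @param groups List of [ionization_group()] objects; empty for a neutral
#'   drug. Bare lists of the form `list(kind =, pka =)` are coerced.
#' @param hbd,hba Hydrogen-bond donor / acceptor counts (non-negative
#'   integers).
#' @param psa Topological polar surface area, Angstrom^2 (>= 0).
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param logd74_override,logd72_override Optional measured log10
#'   distribution coefficients at pH 7.4 / 7.2; when supplied they are
#'   returned verbatim by [logd()] for the matching pH.
#' @return An object of class `drug_physchem`.
#' @examples
#' caffeine <- drug_physchem("caffeine", mw = 194.20, logp = -0.07,
#'   groups = list(ionization_group("base", 0.80)),
#'   hbd = 0, hba = 3, psa = 58.44, fu_plasma = 0.70)
#' logd(caffeine, 7.2)
#' @export
drug_physchem <- function(name, mw, logp, groups = list(), hbd = 0L, hba = 0L,
                          psa = 0, fu_plasma,
                          logd74_override = NULL, logd72_override = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(mw), length(mw) == 1L, mw > 0)
  stopifnot(is.numeric(logp), length(logp) == 1L, is.finite(logp))
  stopifnot(is.numeric(psa), length(psa) == 1L, psa >= 0)
  stopifnot(is.numeric(hbd), hbd >= 0, hbd == round(hbd))
  stopifnot(is.numeric(hba), hba >= 0, hba == round(hba))
  stopifnot(is.numeric(fu_plasma), length(fu_plasma) == 1L,
            fu_plasma > 0, fu_plasma <= 1)
  groups <- lapply(groups, function(g) {
    if (inherits(g, "ionization_group")) g else ionization_group(g$kind, g$pka)
  })
  for (ov in list(logd74_override, logd72_override)) {
    if (!is.null(ov)) stopifnot(is.numeric(ov), length(ov) == 1L, is.finite(ov))
  }
  structure(list(
    name = name, mw = as.numeric(mw), logp = as.numeric(logp),
    groups = groups, hbd = as.integer(hbd), hba = as.integer(hba),
    psa = as.numeric(psa), fu_plasma = as.numeric(fu_plasma),
    logd74_override = logd74_override, logd72_override = logd72_override
  ), class = "drug_physchem")
}

#' @export
print.drug_physchem <- function(x, ...) {
  grp <- if (length(x$groups) == 0L) "neutral" else
    paste(vapply(x$groups, function(g) sprintf("%.2f (%s)", g$pka, g$kind),
                 character(1)), collapse = ", ")
  cat(sprintf("<drug_physchem> %s\n", x$name))
  cat(sprintf("  MW %.2f g/mol  LogP %.2f  pKa: %s\n", x$mw, x$logp, grp))
  cat(sprintf("  HBD %d  HBA %d  PSA %.2f A^2  fu,plasma %.3g\n",
              x$hbd, x$hba, x$psa, x$fu_plasma))
  if (!is.null(x$logd74_override))
    cat(sprintf("  LogD7.4 override: %.3f\n", x$logd74_override))
  if (!is.null(x$logd72_override))
    cat(sprintf("  LogD7.2 override: %.3f\n", x$logd72_override))
  invisible(x)
}

#' Henderson--Hasselbalch neutral fraction
#'
#' Fraction of drug in the neutral (un-ionized) species at a given pH. For a
#' single acid this is `1 / (1 + 10^(pH - pKa))`, for a single base
#' `1 / (1 + 10^(pKa - pH))`; with several groups the per-group neutral
#' fractions multiply (the zwitterion convention), and a drug without
#' ionizable groups is fully neutral.
#'
#' @param drug A [drug_physchem()] record.
#' @param ph pH, in (0, 14).
#' @return Neutral fraction in (0, 1].
#' @export
fraction_neutral <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_physchem"))
  stopifnot(is.numeric(ph), length(ph) == 1L, ph > 0, ph < 14)
  f <- 1
  for (g in drug$groups) {
    f <- f * if (g$kind == "acid") 1 / (1 + 10^(ph - g$pka))
             else                  1 / (1 + 10^(g$pka - ph))
  }
  f
}

#' pH-dependent distribution coefficient (LogD)
#'
#' Log10 octanol:buffer distribution coefficient at the requested pH. A
#' measured override stored on the drug record (for pH 7.4 or 7.2) is
#' returned as-is; otherwise LogD is computed from LogP and the
#' Henderson--Hasselbalch neutral fraction as
#' `LogD = LogP + log10(fraction_neutral)`, i.e. only the neutral species is
#' assumed to partition into the octanol phase.
#'
#' @inheritParams fraction_neutral
#' @return Log10 distribution coefficient.
#' @seealso [fraction_neutral()]
#' @export
logd <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_physchem"))
  if (!is.null(drug$logd74_override) && isTRUE(all.equal(ph, 7.4)))
    return(drug$logd74_override)
  if (!is.null(drug$logd72_override) && isTRUE(all.equal(ph, 7.2)))
    return(drug$logd72_override)
  drug$logp + log10(fraction_neutral(drug, ph))
}
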