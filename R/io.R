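.config_keys <- c("name", "mw", "logp", "pka", "hbd", "hba", "psa",
                  "fu_plasma", "logd74_override", "logd72_override",
                  "pk", "regimen", "therapeutic_dose_mg_kg_day",
                  "published", "effective", "provenance", "notes")
.pk_keys <- c("cl", "vc", "peripherals", "ka", "f", "tlag")
.regimen_keys <- c("dose_mg", "interval_h", "n_doses", "route", "duration_h")

#' Validate a raw drug configuration
#'
#' Schema check for a drug configuration document before object
#' construction: unknown keys are rejected (with the offending field path),
#' required fields and type invariants are verified.
#'
#' @param raw A named list, e.g. from [jsonlite::read_json()].
#' @return A list with `ok` (logical) and `errors` (character vector of
#'   field-path-tagged messages).
#' @export
validate_config <- function(raw) {
  errors <- character(0)
  add <- function(...) errors <<- c(errors, sprintf(...))
  if (!is.list(raw)) return(list(ok = FALSE, errors = "config is not a mapping"))
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) add("unknown key(s): %s", paste(unknown, collapse = ", "))
  for (k in c("name", "mw", "logp", "fu_plasma"))
    if (is.null(raw[[k]])) add("missing required key '%s'", k)
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!is.null(raw$mw) && (!num_ok(raw$mw) || raw$mw <= 0))
    add("mw: must be a positive number")
  if (!is.null(raw$psa) && (!num_ok(raw$psa) || raw$psa < 0))
    add("psa: must be >= 0")
  if (!is.null(raw$fu_plasma) &&
      (!num_ok(raw$fu_plasma) || raw$fu_plasma <= 0 || raw$fu_plasma > 1))
    add("fu_plasma: must be in (0, 1]")
  for (k in c("hbd", "hba"))
    if (!is.null(raw[[k]]) && (!num_ok(raw[[k]]) || raw[[k]] < 0 ||
                               raw[[k]] != round(raw[[k]])))
      add("%s: must be a non-negative integer", k)
  if (!is.null(raw$pka)) {
    for (i in seq_along(raw$pka)) {
      g <- raw$pka[[i]]
      if (is.null(g$kind) || !g$kind %in% c("acid", "base"))
        add("pka[%d].kind: must be 'acid' or 'base'", i)
      if (is.null(g$pka) || !num_ok(g$pka))
        add("pka[%d].pka: must be a number", i)
    }
  }
  if (!is.null(raw$pk)) {
    unknown <- setdiff(names(raw$pk), .pk_keys)
    if (length(unknown)) add("pk: unknown key(s): %s", paste(unknown, collapse = ", "))
    for (k in c("cl", "vc"))
      if (is.null(raw$pk[[k]]) || !num_ok(raw$pk[[k]]) || raw$pk[[k]] <= 0)
        add("pk.%s: must be a positive number", k)
  }
  if (!is.null(raw$regimen)) {
    unknown <- setdiff(names(raw$regimen), .regimen_keys)
    if (length(unknown))
      add("regimen: unknown key(s): %s", paste(unknown, collapse = ", "))
    if (!is.null(raw$regimen$route) &&
        !raw$regimen$route %in% c("oral", "iv_bolus", "iv_infusion"))
      add("regimen.route: must be oral, iv_bolus or iv_infusion")
  }
  if (!is.null(raw$provenance)) {
    bad <- setdiff(unlist(raw$provenance),
                   c("published", "backcalculated", "user"))
    if (length(bad)) add("provenance: unknown tag(s): %s", paste(bad, collapse = ", "))
  }
  list(ok = length(errors) == 0L, errors = errors)
}

#' Load a drug configuration document
#'
#' Reads a structured (JSON) per-drug configuration mirroring the
#' [drug_physchem()] fields plus optional maternal PK parameters, a default
#' regimen, a pediatric therapeutic dose, published reference clearances and
#' back-calculated effective inputs with provenance tags. The document is
#' schema-validated first; unknown keys are rejected with their field path.
#'
#' @param path Path to the JSON document.
#' @return Object of class `drug_config` with elements `drug`
#'   ([drug_physchem()]), `pk` ([maternal_pk_params()] or `NULL`), `regimen`
#'   ([regimen()] or `NULL`), `therapeutic_dose`, `published`, `effective`,
#'   `provenance` and `notes`.
#' @export
load_drug_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  chk <- validate_config(raw)
  if (!chk$ok)
    stop("invalid drug config '", path, "':\n  ",
         paste(chk$errors, collapse = "\n  "))
  drug <- drug_physchem(
    name = raw$name, mw = raw$mw, logp = raw$logp,
    groups = lapply(raw$pka, function(g) ionization_group(g$kind, g$pka)),
    hbd = raw$hbd %||% 0L, hba = raw$hba %||% 0L, psa = raw$psa %||% 0,
    fu_plasma = raw$fu_plasma,
    logd74_override = raw$logd74_override,
    logd72_override = raw$logd72_override)
  pk <- NULL
  if (!is.null(raw$pk)) {
    pk <- maternal_pk_params(
      cl = raw$pk$cl, vc = raw$pk$vc,
      peripherals = lapply(raw$pk$peripherals, function(p) list(v = p$v, q = p$q)),
      ka = raw$pk$ka, f = raw$pk$f %||% 1, tlag = raw$pk$tlag %||% 0)
  }
  reg <- NULL
  if (!is.null(raw$regimen)) {
    reg <- regimen(dose = raw$regimen$dose_mg,
                   interval = raw$regimen$interval_h,
                   n_doses = raw$regimen$n_doses %||% 1L,
                   route = raw$regimen$route %||% "oral",
                   duration = raw$regimen$duration_h %||% 0)
  }
  structure(list(drug = drug, pk = pk, regimen = reg,
                 therapeutic_dose = raw$therapeutic_dose_mg_kg_day,
                 published = raw$published, effective = raw$effective,
                 provenance = raw$provenance, notes = raw$notes),
            class = "drug_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a drug configuration document
#'
#' Inverse of [load_drug_config()]; writing then reading a configuration is
#' an identity on all fields.
#'
#' @param config A `drug_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(config, path) {
  stopifnot(inherits(config, "drug_config"))
  d <- config$drug
  raw <- list(name = d$name, mw = d$mw, logp = d$logp,
              pka = lapply(d$groups, function(g) list(kind = g$kind, pka = g$pka)),
              hbd = d$hbd, hba = d$hba, psa = d$psa, fu_plasma = d$fu_plasma)
  if (!is.null(d$logd74_override)) raw$logd74_override <- d$logd74_override
  if (!is.null(d$logd72_override)) raw$logd72_override <- d$logd72_override
  if (!is.null(config$pk)) {
    pk <- config$pk
    raw$pk <- list(cl = pk$cl, vc = pk$vc,
                   peripherals = pk$peripherals, f = pk$f, tlag = pk$tlag)
    if (!is.null(pk$ka)) raw$pk$ka <- pk$ka
  }
  if (!is.null(config$regimen)) {
    r <- config$regimen
    raw$regimen <- list(dose_mg = r$dose, interval_h = r$interval,
                        n_doses = r$n_doses, route = r$route)
    if (r$duration > 0) raw$regimen$duration_h <- r$duration
  }
  if (!is.null(config$therapeutic_dose))
    raw$therapeutic_dose_mg_kg_day <- config$therapeutic_dose
  for (k in c("published", "effective", "provenance", "notes"))
    if (!is.null(config[[k]])) raw[[k]] <- config[[k]]
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' List the packaged model medicines
#'
#' @return Character vector of fixture drug names shipped with the package.
#' @export
list_fixture_drugs <- function() {
  dir <- system.file("extdata", "drugs", package = "milkPBPK")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Load a packaged model medicine
#'
#' Ten physicochemically diverse medicines ship as fixtures. Physicochemical
#' fields carry their published reference values; maternal PK parameters are
#' literature-plausible placeholders (provenance `"user"`), since the source
#' whole-body models are not redistributable. For three medicines
#' (cetirizine, sertraline, tenofovir) the published reuptake clearance is
#' not reproducible from the tabulated LogP; the configuration also stores
#' back-calculated effective inputs (provenance `"backcalculated"`) that
#' exactly reproduce the published clearances, selectable via
#' `effective = TRUE`.
#'
#' @param name Fixture name (see [list_fixture_drugs()]).
#' @param effective Use the back-calculated effective LogP / LogD7.4 inputs
#'   instead of the tabulated ones.
#' @return A `drug_config`.
#' @export
load_fixture_drug <- function(name, effective = FALSE) {
  path <- system.file("extdata", "drugs", paste0(name, ".json"),
                      package = "milkPBPK")
  if (!nzchar(path))
    stop("no packaged fixture named '", name, "'; see list_fixture_drugs()")
  cfg <- load_drug_config(path)
  if (effective) {
    eff <- cfg$effective
    if (is.null(eff)) stop("fixture '", name, "' has no effective-input block")
    d <- cfg$drug
    cfg$drug <- drug_physchem(
      name = d$name, mw = d$mw,
      logp = eff$logp %||% d$logp,
      groups = d$groups, hbd = d$hbd, hba = d$hba, psa = d$psa,
      fu_plasma = d$fu_plasma,
      logd74_override = eff$logd74 %||% d$logd74_override,
      logd72_override = d$logd72_override)
  }
  cfg
}

#' Synthetic drug generator specification
#'
#' Uniform sampling ranges spanning the physicochemical diversity of
#' small-molecule medicines, used for property-based testing (oracle
#' equivalence, monotonicity, mass balance).
#'
#' @param mw,logp,psa,fu_plasma,pka Numeric `c(lower, upper)` ranges.
#' @param hbd Integer range `c(lower, upper)`.
#' @param seed Optional integer seed.
#' @return Object of class `synthetic_drug_spec`.
#' @export
synthetic_drug_spec <- function(mw = c(100, 600), logp = c(-3, 6),
                                hbd = c(0L, 6L), psa = c(10, 200),
                                fu_plasma = c(0.01, 1), pka = c(2, 12),
                                seed = NULL) {
  for (r in list(mw, logp, hbd, psa, fu_plasma, pka))
    stopifnot(length(r) == 2L, r[1] < r[2])
  structure(list(mw = mw, logp = logp, hbd = hbd, psa = psa,
                 fu_plasma = fu_plasma, pka = pka, seed = seed),
            class = "synthetic_drug_spec")
}

#' Generate random synthetic drugs
#'
#' Draws `n` reproducible random [drug_physchem()] records spanning the
#' spec's ranges. Ionization is drawn uniformly over neutral / single acid /
#' single base / zwitterion (one acid plus one base).
#'
#' @param spec A [synthetic_drug_spec()].
#' @param n Number of drugs.
#' @return List of `drug_physchem` records named `synthetic_001`, ...
#' @export
generate_synthetic_drugs <- function(spec, n) {
  stopifnot(inherits(spec, "synthetic_drug_spec"), n >= 1)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  runif_r <- function(r) stats::runif(1, r[1], r[2])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- sample(c("neutral", "acid", "base", "zwitterion"), 1)
    groups <- switch(kind,
      neutral = list(),
      acid = list(ionization_group("acid", runif_r(spec$pka))),
      base = list(ionization_group("base", runif_r(spec$pka))),
      zwitterion = list(ionization_group("acid", runif_r(spec$pka)),
                        ionization_group("base", runif_r(spec$pka))))
    out[[i]] <- drug_physchem(
      name = sprintf("synthetic_%03d", i),
      mw = runif_r(spec$mw), logp = runif_r(spec$logp), groups = groups,
      hbd = sample(seq(spec$hbd[1], spec$hbd[2]), 1),
      hba = sample(0:10, 1),
      psa = runif_r(spec$psa), fu_plasma = runif_r(spec$fu_plasma))
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Parse a regimen string
#'
#' Grammar: `"<dose>mg q<tau>h x<n> <route>"`, e.g. `"1000mg q8h x15 po"`.
#' Routes: `po` (oral), `iv` (bolus), `ivinf:<hours>` (infusion).
#'
#' @param text Regimen string.
#' @return A [regimen()].
#' @examples
#' parse_regimen("1000mg q8h x15 po")
#' @export
parse_regimen <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*([0-9.]+)\\s*mg\\s+q([0-9.]+)h\\s+x([0-9]+)\\s+(po|iv|ivinf:[0-9.]+)\\s*$",
    text))[[1]]
  if (length(m) == 0)
    stop("cannot parse regimen '", text,
         "'; expected e.g. \"1000mg q8h x15 po\"")
  route <- m[5]
  duration <- 0
  if (startsWith(route, "ivinf:")) {
    duration <- as.numeric(sub("ivinf:", "", route))
    route <- "iv_infusion"
  } else route <- c(po = "oral", iv = "iv_bolus")[route]
  regimen(dose = as.numeric(m[2]), interval = as.numeric(m[3]),
          n_doses = as.integer(m[4]), route = unname(route),
          duration = duration)
}
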