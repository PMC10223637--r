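#' Maternal compartmental PK parameters
#'
#' Reduced disposition model for the mother: 1--3 distribution compartments
#' with linear clearance and optional first-order oral absorption. This
#' stands in for a whole-body physiological model; its parameters are user
#' inputs (typically from literature population PK analyses).
#'
#' @param cl Systemic clearance, L/h (> 0).
#' @param vc Central volume of distribution, L (> 0).
#' @param peripherals List of peripheral compartments, each
#'   `list(v = <L>, q = <L/h>)`.
#' @param ka First-order absorption rate constant, 1/h (required for oral
#'   dosing).
#' @param f Oral bioavailability fraction, (0, 1].
#' @param tlag Absorption lag time, h (>= 0).
#' @return Object of class `maternal_pk_params`.
#' @export
maternal_pk_params <- function(cl, vc, peripherals = list(), ka = NULL,
                               f = 1, tlag = 0) {
  stopifnot(cl > 0, vc > 0, f > 0, f <= 1, tlag >= 0)
  peripherals <- lapply(peripherals, function(p) {
    stopifnot(p$v > 0, p$q > 0)
    list(v = as.numeric(p$v), q = as.numeric(p$q))
  })
  if (!is.null(ka)) stopifnot(ka > 0)
  structure(list(cl = cl, vc = vc, peripherals = peripherals,
                 ka = ka, f = f, tlag = tlag),
            class = "maternal_pk_params")
}

#' Lactation physiology constants
#'
#' Physiological constants of the three-months-postpartum lactation model:
#' a fixed-volume milk compartment connected directly to plasma, plus breast
#' tissue metadata (volume, specific blood flow, sub-compartment fractions).
#' Breast tissue does not intercept the plasma--milk exchange; it can be
#' carried as an optional perfusion-limited distribution compartment.
#'
#' @param v_milk Milk compartment volume, L. Default 0.5 L, the volume used
#'   to calibrate the secretion/reuptake clearance regressions.
#' @param v_milk_gsd Geometric SD of milk volume across the population
#'   (default 1.16).
#' @param breast_volume Total breast volume, L (default 1.0).
#' @param breast_flow Specific breast blood flow, mL/min/100 g (default 27.0).
#' @param frac_vascular,frac_interstitial,frac_intracellular Breast
#'   sub-compartment volume fractions; must sum to 1 within 0.001.
#' @param hematocrit Blood cell fraction (default 0.47).
#' @return Object of class `lactation_physiology`.
#' @export
lactation_physiology <- function(v_milk = 0.5, v_milk_gsd = 1.16,
                                 breast_volume = 1.0, breast_flow = 27.0,
                                 frac_vascular = 0.14, frac_interstitial = 0.10,
                                 frac_intracellular = 0.76, hematocrit = 0.47) {
  stopifnot(v_milk > 0, v_milk_gsd >= 1, breast_volume > 0, breast_flow > 0,
            hematocrit > 0, hematocrit < 1)
  fr <- frac_vascular + frac_interstitial + frac_intracellular
  if (abs(fr - 1) > 0.001)
    stop(sprintf("breast sub-compartment fractions sum to %.4f, not 1", fr))
  structure(list(v_milk = v_milk, v_milk_gsd = v_milk_gsd,
                 breast_volume = breast_volume, breast_flow = breast_flow,
                 frac_vascular = frac_vascular,
                 frac_interstitial = frac_interstitial,
                 frac_intracellular = frac_intracellular,
                 hematocrit = hematocrit),
            class = "lactation_physiology")
}

#' A single dose event
#'
#' @param time Time of administration, h (>= 0).
#' @param amount Dose amount, mg (>= 0).
#' @param route `"iv_bolus"`, `"oral"` or `"iv_infusion"`.
#' @param duration Infusion duration, h (required > 0 for infusions).
#' @return Object of class `dose_event`.
#' @export
dose_event <- function(time, amount, route = c("iv_bolus", "oral", "iv_infusion"),
                       duration = 0) {
  route <- match.arg(route)
  stopifnot(time >= 0, amount >= 0)
  if (route == "iv_infusion") stopifnot(duration > 0)
  structure(list(time = time, amount = amount, route = route,
                 duration = duration), class = "dose_event")
}

#' Dosing regimen
#'
#' Either an explicit list of [dose_event()]s, or a repeating schedule
#' (`dose` mg every `interval` h for `n_doses` doses by `route`).
#'
#' @param dose Dose amount, mg.
#' @param interval Dosing interval tau, h (> 0).
#' @param n_doses Number of doses (>= 1).
#' @param route Administration route (see [dose_event()]).
#' @param duration Infusion duration per dose, h.
#' @param events Explicit list of [dose_event()]s; overrides the schedule
#'   fields when supplied.
#' @return Object of class `regimen`.
#' @export
regimen <- function(dose = NULL, interval = NULL, n_doses = NULL,
                    route = "oral", duration = 0, events = NULL) {
  if (is.null(events)) {
    stopifnot(!is.null(dose), !is.null(interval), !is.null(n_doses))
    stopifnot(interval > 0, n_doses >= 1, dose >= 0)
    events <- lapply(seq_len(n_doses) - 1L, function(i)
      dose_event(i * interval, dose, route, duration))
  } else {
    stopifnot(all(vapply(events, inherits, logical(1), "dose_event")))
  }
  structure(list(dose = dose, interval = interval, n_doses = n_doses,
                 route = route, duration = duration, events = events),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  if (!is.null(x$dose))
    cat(sprintf("<regimen> %g mg q%gh x%d %s\n", x$dose, x$interval,
                x$n_doses, x$route))
  else
    cat(sprintf("<regimen> %d explicit dose events\n", length(x$events)))
  invisible(x)
}

#' Assemble the coupled maternal plasma / milk model
#'
#' Builds the linear ODE system coupling the maternal disposition model to
#' the fixed-volume milk compartment. The milk compartment connects directly
#' to plasma: secretion inflow is `Cplasma * fu_plasma * CLsec` and reuptake
#' outflow `Cmilk * fu_milk_total * CLre`, with `Cmilk = Nmilk / v_milk` and
#' no other milk efflux (no nursing removal). Because the system is linear
#' with constant coefficients between dose events, trajectories are computed
#' by exact eigendecomposition propagation rather than numerical ODE
#' stepping (see the methods vignette), with a matrix-exponential fallback
#' for defective systems.
#'
#' @param drug A [drug_physchem()] record.
#' @param pk [maternal_pk_params()].
#' @param transfer [milk_transfer_params()], typically from
#'   [derive_milk_transfer()].
#' @param physio [lactation_physiology()].
#' @param include_breast Carry breast tissue as an explicit perfusion-limited
#'   compartment (default `FALSE`; it never intercepts the milk exchange).
#' @param breast_kp Breast tissue:plasma partition coefficient (default 1).
#' @return Object of class `lactation_model`.
#' @export
build_model <- function(drug, pk, transfer, physio = lactation_physiology(),
                        include_breast = FALSE, breast_kp = 1) {
  stopifnot(inherits(drug, "drug_physchem"),
            inherits(pk, "maternal_pk_params"),
            inherits(transfer, "milk_transfer_params"),
            inherits(physio, "lactation_physiology"))
  stopifnot(breast_kp > 0)

  # clearances are carried in L/h internally; mL/h at the API boundary
  clsec_l <- transfer$clsec / 1000
  clre_l <- transfer$clre / 1000

  states <- character(0)
  if (!is.null(pk$ka)) states <- c(states, "depot")
  states <- c(states, "central")
  np <- length(pk$peripherals)
  if (np > 0) states <- c(states, paste0("peripheral", seq_len(np)))
  if (include_breast) states <- c(states, "breast")
  states <- c(states, "milk")
  n <- length(states)
  i_dep <- match("depot", states)
  i_cen <- match("central", states)
  i_mlk <- match("milk", states)

  A <- matrix(0, n, n, dimnames = list(states, states))
  if (!is.na(i_dep)) {
    A[i_dep, i_dep] <- -pk$ka
    A[i_cen, i_dep] <- pk$ka
  }
  kel <- pk$cl / pk$vc
  A[i_cen, i_cen] <- A[i_cen, i_cen] - kel
  for (j in seq_len(np)) {
    ip <- match(paste0("peripheral", j), states)
    q <- pk$peripherals[[j]]$q
    v <- pk$peripherals[[j]]$v
    A[ip, i_cen] <- q / pk$vc
    A[i_cen, i_cen] <- A[i_cen, i_cen] - q / pk$vc
    A[ip, ip] <- -q / v
    A[i_cen, ip] <- q / v
  }
  if (include_breast) {
    ib <- match("breast", states)
    # perfusion-limited exchange; flow in mL/min/100 g converted to L/h
    # assuming tissue density 1 g/mL
    q_br <- physio$breast_flow * (physio$breast_volume * 1000 / 100) * 60 / 1000
    A[ib, i_cen] <- q_br / pk$vc
    A[i_cen, i_cen] <- A[i_cen, i_cen] - q_br / pk$vc
    A[ib, ib] <- -q_br / (physio$breast_volume * breast_kp)
    A[i_cen, ib] <- q_br / (physio$breast_volume * breast_kp)
  }
  # bidirectional plasma <-> milk transfer on unbound concentrations
  A[i_mlk, i_cen] <- drug$fu_plasma * clsec_l / pk$vc
  A[i_cen, i_cen] <- A[i_cen, i_cen] - drug$fu_plasma * clsec_l / pk$vc
  A[i_mlk, i_mlk] <- -transfer$fu_milk_total * clre_l / physio$v_milk
  A[i_cen, i_mlk] <- transfer$fu_milk_total * clre_l / physio$v_milk

  ode <- .ode_setup(A)
  structure(list(drug = drug, pk = pk, transfer = transfer, physio = physio,
                 include_breast = include_breast, breast_kp = breast_kp,
                 states = states, A = A, i_depot = i_dep, i_central = i_cen,
                 i_milk = i_mlk, kel = kel, ode = ode),
            class = "lactation_model")
}

#' @export
print.lactation_model <- function(x, ...) {
  cat(sprintf("<lactation_model> %s\n", x$drug$name))
  cat(sprintf("  states: %s\n", paste(x$states, collapse = ", ")))
  cat(sprintf("  CL %.3g L/h, Vc %.3g L, v_milk %.3g L\n",
              x$pk$cl, x$pk$vc, x$physio$v_milk))
  cat(sprintf("  CLsec %.4g mL/h (fu,p %.3g)  CLre %.4g mL/h (fu,milk %.4g)\n",
              x$transfer$clsec, x$drug$fu_plasma,
              x$transfer$clre, x$transfer$fu_milk_total))
  cat(sprintf("  propagation: %s\n",
              if (x$ode$diagonalizable) "eigendecomposition (exact)"
              else "matrix exponential (exact)"))
  invisible(x)
}

#' Number of model states
#' @param model A `lactation_model`.
#' @return Integer state count (depot, central, peripherals, optional breast,
#'   milk).
#' @export
n_states <- function(model) length(model$states)

# ---- exact linear propagation ------------------------------------------------

.ode_setup <- function(A) {
  eg <- eigen(A)
  V <- eg$vectors
  d <- eg$values
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  ok <- !is.null(Vinv)
  if (ok) {
    # reciprocal condition estimate; defective systems get the expm fallback
    kappa <- norm(abs(V), "1") * norm(abs(Vinv), "1")
    ok <- is.finite(kappa) && kappa < 1e10
  }
  list(V = V, d = d, Vinv = Vinv, diagonalizable = ok, A = A)
}

# phi(z) = (e^z - 1)/z and psi(z) = (e^z - 1 - z)/z^2, series-stabilized
.phi_z <- function(z) {
  out <- ifelse(Mod(z) > 1e-6, (exp(z) - 1) / z, 1 + z / 2 + z^2 / 6)
  out
}
.psi_z <- function(z) {
  ifelse(Mod(z) > 1e-4, (exp(z) - 1 - z) / z^2, 1 / 2 + z / 6 + z^2 / 24)
}

# advance x' = A x + b over a step of length s from x0;
# returns the end state and the integral of x over the step
.advance <- function(ode, x0, b, s) {
  if (s <= 0) return(list(x = x0, ix = numeric(length(x0))))
  if (ode$diagonalizable) {
    z0 <- ode$Vinv %*% x0
    w <- ode$Vinv %*% b
    zs <- ode$d * s
    e <- exp(zs)
    phi <- s * .phi_z(zs)
    psi <- s^2 * .psi_z(zs)
    x1 <- Re(ode$V %*% (e * z0 + phi * w))
    ix <- Re(ode$V %*% (phi * z0 + psi * w))
    list(x = drop(x1), ix = drop(ix))
  } else {
    n <- length(x0)
    Z <- matrix(0, n, n)
    I <- diag(n)
    M <- rbind(cbind(ode$A, I, Z),
               cbind(Z, Z, I),
               cbind(Z, Z, Z))
    E <- as.matrix(Matrix::expm(M * s))
    eAs <- E[1:n, 1:n]
    G <- E[1:n, (n + 1):(2 * n)]        # int_0^s exp(Au) du
    H <- E[1:n, (2 * n + 1):(3 * n)]    # int_0^s int_0^u exp(Ar) dr du
    x1 <- eAs %*% x0 + G %*% b
    ix <- G %*% x0 + H %*% b
    list(x = drop(x1), ix = drop(ix))
  }
}

# normalize a regimen into bolus and infusion primitives for this model
.normalize_events <- function(model, regimen) {
  boluses <- list()   # (time, state, amount, administered)
  infusions <- list() # (start, end, rate)
  for (ev in regimen$events) {
    if (ev$amount <= 0) next
    if (ev$route == "oral") {
      if (is.na(model$i_depot))
        stop("oral dose event but the model has no absorption compartment (ka missing)")
      boluses[[length(boluses) + 1L]] <-
        list(time = ev$time + model$pk$tlag, state = model$i_depot,
             amount = ev$amount * model$pk$f)
    } else if (ev$route == "iv_bolus") {
      boluses[[length(boluses) + 1L]] <-
        list(time = ev$time, state = model$i_central, amount = ev$amount)
    } else { # iv_infusion
      infusions[[length(infusions) + 1L]] <-
        list(start = ev$time, end = ev$time + ev$duration,
             rate = ev$amount / ev$duration)
    }
  }
  list(boluses = boluses, infusions = infusions)
}

# cumulative administered amount (oral doses scaled by F) at given times
.dosed_cum <- function(evs, times) {
  out <- numeric(length(times))
  for (b in evs$boluses) out <- out + ifelse(times >= b$time - 1e-12, b$amount, 0)
  for (inf in evs$infusions) {
    run <- pmin(pmax(times - inf$start, 0), inf$end - inf$start)
    out <- out + inf$rate * run
  }
  out
}

# propagate over [t0, t1] recording states at all breakpoints
.propagate <- function(model, x0, evs, t0, t1, out_times) {
  bt <- vapply(evs$boluses, `[[`, numeric(1), "time")
  it <- unlist(lapply(evs$infusions, function(z) c(z$start, z$end)))
  breaks <- sort(unique(c(t0, t1, out_times, bt, it)))
  breaks <- breaks[breaks >= t0 - 1e-12 & breaks <= t1 + 1e-12]
  nb <- length(breaks)
  n <- length(x0)
  X <- matrix(0, nb, n, dimnames = list(NULL, model$states))
  elim <- numeric(nb)
  x <- x0
  el <- 0
  for (k in seq_len(nb)) {
    tb <- breaks[k]
    for (b in evs$boluses)
      if (abs(b$time - tb) < 1e-12) x[b$state] <- x[b$state] + b$amount
    X[k, ] <- x
    elim[k] <- el
    if (k == nb) break
    s <- breaks[k + 1] - tb
    rate <- 0
    for (inf in evs$infusions)
      if (inf$start <= tb + 1e-12 && inf$end >= breaks[k + 1] - 1e-12)
        rate <- rate + inf$rate
    b_vec <- numeric(n)
    b_vec[model$i_central] <- rate
    adv <- .advance(model$ode, x, b_vec, s)
    x <- adv$x
    scale <- max(1, max(abs(x)))
    if (min(x) < -1e-7 * scale)
      stop(sprintf("negative state detected at t = %.4g h (min %.3g); model inputs are inconsistent",
                   breaks[k + 1], min(x)))
    x[x < 0] <- 0
    el <- el + model$kel * adv$ix[model$i_central]
  }
  list(times = breaks, X = X, elim = elim)
}

.as_sim_result <- function(model, prop, evs, ss_flag = FALSE,
                           elim0 = 0, dosed0 = 0) {
  cp <- prop$X[, model$i_central] / model$pk$vc
  cm <- prop$X[, model$i_milk] / model$physio$v_milk
  structure(list(times = prop$times, c_plasma = cp, c_milk = cm,
                 amounts = prop$X,
                 cumulative_eliminated = prop$elim + elim0,
                 cumulative_dosed = .dosed_cum(evs, prop$times) + dosed0,
                 ss_flag = ss_flag),
            class = "sim_result")
}

#' Simulate plasma and milk concentration-time profiles
#'
#' Integrates the coupled maternal/milk system for an arbitrary dosing
#' regimen. Dose events are applied exactly at their event times (the
#' propagation is restarted at every discontinuity) and the reported
#' trajectory is right-continuous at dose times, so an IV bolus peak is
#' captured exactly. Output is given on the requested grid augmented with
#' all event times.
#'
#' @param model A `lactation_model` from [build_model()].
#' @param regimen A [regimen()].
#' @param t_end End of simulation, h; defaults to the last event time plus
#'   one dosing interval (or 24 h for explicit event lists).
#' @param dt_out Output grid spacing, h.
#' @return Object of class `sim_result` with fields `times` (h), `c_plasma`,
#'   `c_milk` (mg/L), `amounts` (mg, one column per state),
#'   `cumulative_eliminated` and `cumulative_dosed` (mg; oral doses scaled
#'   by bioavailability), and `ss_flag`.
#' @export
simulate_regimen <- function(model, regimen, t_end = NULL, dt_out = 0.1) {
  stopifnot(inherits(model, "lactation_model"), inherits(regimen, "regimen"))
  ev_times <- vapply(regimen$events, function(e) e$time + e$duration, numeric(1))
  if (is.null(t_end)) {
    t_end <- if (!is.null(regimen$interval)) max(ev_times) + regimen$interval
             else max(ev_times) + 24
  }
  if (length(ev_times) && t_end < max(ev_times))
    stop("'t_end' does not cover the dosing regimen")
  stopifnot(dt_out > 0)
  grid <- unique(c(seq(0, t_end, by = dt_out), t_end))
  evs <- .normalize_events(model, regimen)
  prop <- .propagate(model, numeric(n_states(model)), evs, 0, t_end, grid)
  .as_sim_result(model, prop, evs)
}

#' Simulate repeated dosing to periodic steady state
#'
#' Repeats one dosing cycle, carrying the state across cycles, until the
#' plasma AUC over consecutive intervals changes by less than `rel_tol`
#' (relative), then returns the final interval on a dense grid. The milk
#' interval AUC must satisfy the same criterion (a deliberate strengthening:
#' with weak reuptake coupling the milk compartment approaches its periodic
#' state more slowly than plasma). Times in the returned result are relative
#' to the start of that interval.
#'
#' @param model A `lactation_model`.
#' @param dose Dose per administration, mg.
#' @param tau Dosing interval, h.
#' @param route Administration route.
#' @param duration Infusion duration, h (infusion route only).
#' @param n_per_interval Output points per interval (default 200).
#' @param max_cycles Cycle cap (default 200); non-convergence is flagged and
#'   the partial result returned with a warning.
#' @param rel_tol Relative interval-AUC convergence tolerance (default 1e-3,
#'   i.e. 0.1 percent).
#' @return A `sim_result` for the final interval with `ss_flag` set when
#'   converged, and attributes `n_cycles`, `converged`, `auc_plasma`,
#'   `auc_milk`, `auc_plasma_first` and `accumulation_ratio`.
#' @export
simulate_to_steady_state <- function(model, dose, tau, route = "oral",
                                     duration = 0, n_per_interval = 200,
                                     max_cycles = 200, rel_tol = 1e-3) {
  stopifnot(inherits(model, "lactation_model"), dose > 0, tau > 0,
            n_per_interval >= 10, max_cycles >= 1, rel_tol > 0)
  cyc_reg <- regimen(events = list(dose_event(0, dose, route, duration)))
  evs <- .normalize_events(model, cyc_reg)
  grid <- seq(0, tau, length.out = n_per_interval + 1)
  x0 <- numeric(n_states(model))
  elim0 <- 0
  dosed0 <- 0
  auc_prev <- NA_real_
  auc_milk_prev <- NA_real_
  auc_first <- NA_real_
  converged <- FALSE
  n_cycles <- 0L
  prop <- NULL
  for (cyc in seq_len(max_cycles)) {
    n_cycles <- cyc
    prop <- .propagate(model, x0, evs, 0, tau, grid)
    cp <- prop$X[, model$i_central] / model$pk$vc
    cm <- prop$X[, model$i_milk] / model$physio$v_milk
    auc <- .trapz(prop$times, cp)
    auc_milk <- .trapz(prop$times, cm)
    if (cyc == 1L) auc_first <- auc
    if (!is.na(auc_prev) && auc_prev > 0 &&
        abs(auc - auc_prev) / auc_prev < rel_tol &&
        (auc_milk_prev == 0 ||
         abs(auc_milk - auc_milk_prev) / auc_milk_prev < rel_tol)) {
      converged <- TRUE
      break
    }
    auc_prev <- auc
    auc_milk_prev <- auc_milk
    if (cyc < max_cycles) {
      x0 <- prop$X[nrow(prop$X), ]
      elim0 <- elim0 + prop$elim[length(prop$elim)]
      dosed0 <- dosed0 + .dosed_cum(evs, tau)
    }
  }
  if (!converged)
    warning(sprintf("steady state not reached within %d cycles (last interval AUC change above %.2g)",
                    max_cycles, rel_tol), call. = FALSE)
  res <- .as_sim_result(model, prop, evs, ss_flag = converged,
                        elim0 = elim0, dosed0 = dosed0)
  cp <- res$c_plasma
  cm <- res$c_milk
  attr(res, "n_cycles") <- n_cycles
  attr(res, "converged") <- converged
  attr(res, "auc_plasma") <- .trapz(res$times, cp)
  attr(res, "auc_milk") <- .trapz(res$times, cm)
  attr(res, "auc_plasma_first") <- auc_first
  attr(res, "accumulation_ratio") <- attr(res, "auc_plasma") / auc_first
  res
}

#' Exact periodic steady-state interval
#'
#' For a linear model under a periodic regimen, the state just before a dose
#' at periodic steady state satisfies `x0 = expm(A*tau) %*% (x0 + inputs)`,
#' a linear fixed point that can be solved directly instead of iterating
#' dosing cycles. This matters for strongly milk-trapped (very lipophilic)
#' compounds whose milk compartment equilibrates over weeks to months:
#' [simulate_to_steady_state()] would need thousands of cycles, while the
#' direct solve is exact and immediate. Returns one dosing interval at the
#' true periodic steady state.
#'
#' @inheritParams simulate_to_steady_state
#' @return A `sim_result` (times relative to the interval start,
#'   `ss_flag = TRUE`) with attributes `auc_plasma`, `auc_milk`,
#'   `auc_plasma_first` and `accumulation_ratio` as in
#'   [simulate_to_steady_state()]; `n_cycles` is `Inf`.
#' @export
steady_state_interval <- function(model, dose, tau, route = "oral",
                                  duration = 0, n_per_interval = 200) {
  stopifnot(inherits(model, "lactation_model"), dose > 0, tau > 0)
  cyc_reg <- regimen(events = list(dose_event(0, dose, route, duration)))
  evs <- .normalize_events(model, cyc_reg)
  grid <- seq(0, tau, length.out = n_per_interval + 1)
  n <- n_states(model)
  # response of one cycle from an empty body: c = state at tau
  first <- .propagate(model, numeric(n), evs, 0, tau, grid)
  cvec <- first$X[nrow(first$X), ]
  # cycle-to-cycle propagator is expm(A * tau) (dose inputs are additive)
  Phi <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    .advance(model$ode, e, numeric(n), tau)$x
  }, numeric(n))
  x0 <- tryCatch(solve(diag(n) - Phi, cvec), error = function(e)
    stop("periodic steady state is singular (no elimination path?): ",
         conditionMessage(e)))
  prop <- .propagate(model, x0, evs, 0, tau, grid)
  res <- .as_sim_result(model, prop, evs, ss_flag = TRUE)
  auc_first <- .trapz(first$times, first$X[, model$i_central] / model$pk$vc)
  attr(res, "n_cycles") <- Inf
  attr(res, "converged") <- TRUE
  attr(res, "auc_plasma") <- .trapz(res$times, res$c_plasma)
  attr(res, "auc_milk") <- .trapz(res$times, res$c_milk)
  attr(res, "auc_plasma_first") <- auc_first
  attr(res, "accumulation_ratio") <- attr(res, "auc_plasma") / auc_first
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d time points over %.4g h%s\n",
              length(x$times), max(x$times) - min(x$times),
              if (isTRUE(x$ss_flag)) " (periodic steady state)" else ""))
  cat(sprintf("  plasma Cmax %.4g mg/L at %.3g h; milk Cmax %.4g mg/L at %.3g h\n",
              max(x$c_plasma), x$times[which.max(x$c_plasma)],
              max(x$c_milk), x$times[which.max(x$c_milk)]))
  invisible(x)
}

#' @export
as.data.frame.sim_result <- function(x, ...) {
  df <- data.frame(time_h = x$times,
                   c_plasma_mg_per_L = x$c_plasma,
                   c_milk_mg_per_L = x$c_milk)
  am <- as.data.frame(x$amounts)
  names(am) <- paste0("amount_", names(am), "_mg")
  cbind(df, am,
        eliminated_mg = x$cumulative_eliminated,
        dosed_mg = x$cumulative_dosed)
}

#' Worst-case relative mass-balance error of a simulation
#'
#' At every output time, administered drug (oral doses scaled by
#' bioavailability) must equal the sum of all compartment amounts plus the
#' cumulative amount eliminated. Returns the largest relative discrepancy,
#' normalized by the total administered amount.
#'
#' @param sim A `sim_result`.
#' @return Maximum relative mass-balance error (dimensionless).
#' @export
mass_balance_error <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  tot <- rowSums(sim$amounts) + sim$cumulative_eliminated
  denom <- max(sim$cumulative_dosed, 1e-300)
  max(abs(tot - sim$cumulative_dosed)) / denom
}

#' Terminal log-linear slope (lambda_z)
#'
#' Non-compartmental estimate of the terminal elimination rate constant:
#' ordinary least-squares regression of log concentration on time over the
#' last `n_points` strictly positive samples. Used e.g. to extrapolate a
#' milk AUC to infinity assuming the milk elimination slope matches plasma.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations, mg/L.
#' @param n_points Number of terminal points to regress on (>= 3).
#' @return `lambda_z` in 1/h (> 0). Errors if fewer than 3 positive terminal
#'   samples exist or the terminal phase is not declining.
#' @export
nca_terminal_slope <- function(times, conc, n_points = 3) {
  stopifnot(length(times) == length(conc), n_points >= 3)
  pos <- which(conc > 0)
  if (length(pos) < n_points)
    stop("need at least ", n_points, " positive concentrations for the terminal slope")
  idx <- utils::tail(pos, n_points)
  fit <- stats::lm(log(conc[idx]) ~ times[idx])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("terminal phase is not declining; lambda_z undefined")
  -slope
}

#' AUC extrapolated to infinity
#'
#' Linear-trapezoid AUC to the last positive sample plus the tail
#' `C_last / lambda_z` from the terminal log-linear slope.
#'
#' @inheritParams nca_terminal_slope
#' @return AUC from the first sample to infinity, mg*h/L.
#' @export
nca_auc_inf <- function(times, conc, n_points = 3) {
  lz <- nca_terminal_slope(times, conc, n_points)
  last <- max(which(conc > 0))
  .trapz(times[1:last], conc[1:last]) + conc[last] / lz
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
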