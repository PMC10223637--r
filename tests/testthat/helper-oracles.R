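# Independent numerical oracle: classic fixed-step RK4 on x' = A x,
# with bolus events, deliberately sharing no code with the package engine.
rk4_simulate <- function(A, boluses, t_end, dt = 0.002, record_every = 50) {
  n <- nrow(A)
  x <- numeric(n)
  deriv <- function(x) as.vector(A %*% x)
  nsteps <- round(t_end / dt)
  times <- numeric(0)
  X <- NULL
  record <- function(t, x) {
    times <<- c(times, t)
    X <<- rbind(X, x)
  }
  t <- 0
  for (b in boluses) if (abs(b$time - 0) < 1e-12) x[b$state] <- x[b$state] + b$amount
  record(0, x)
  for (i in seq_len(nsteps)) {
    k1 <- deriv(x)
    k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2)
    k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * dt
    for (b in boluses)
      if (abs(b$time - t) < dt / 2 && b$time > 0) x[b$state] <- x[b$state] + b$amount
    if (i %% record_every == 0) record(t, x)
  }
  list(times = times, X = X)
}

# simple transfer record for structural engine tests
flat_transfer <- function(clsec = 100, clre = 200, fu_plasma = 1,
                          fu_milk = 1) {
  milk_transfer_params(clsec = clsec, clre = clre, pmilk = 0,
                       fu_skim = 1, fu_milk_total = fu_milk,
                       fu_plasma = fu_plasma)
}

# one-compartment test model
one_cpt_model <- function(cl = 5, vc = 20, ka = NULL, f = 1, tlag = 0,
                          clsec = 0, clre = 0, fu_milk = 1) {
  drug <- drug_physchem("probe", mw = 200, logp = 0, hbd = 0, hba = 0,
                        psa = 50, fu_plasma = 1)
  pk <- maternal_pk_params(cl = cl, vc = vc, ka = ka, f = f, tlag = tlag)
  build_model(drug, pk, flat_transfer(clsec, clre, fu_milk = fu_milk))
}

# random maternal PK draw for property tests
random_pk <- function() {
  np <- sample(0:2, 1)
  peripherals <- lapply(seq_len(np), function(i)
    list(v = runif(1, 20, 200), q = runif(1, 2, 30)))
  maternal_pk_params(cl = runif(1, 1, 40), vc = runif(1, 10, 100),
                     peripherals = peripherals,
                     ka = runif(1, 0.3, 3), f = runif(1, 0.3, 1),
                     tlag = sample(c(0, 0.25), 1))
}
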