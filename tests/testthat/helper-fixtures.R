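## shared fixtures: small protocols and a reference drug record

fast_protocol <- function(n_beats = 30, ...) {
  pacing_protocol(n_beats = n_beats, ...)
}

## a hERG-trapping reference compound used across tests
ref_drug <- list(name = "refdrug", EFTPC = 10,
                 IC50_INa = 1000, h_INa = 1, IC50_INaL = 500, h_INaL = 1,
                 IC50_Ito = 2000, h_Ito = 1, IC50_IKs = 4000, h_IKs = 1,
                 IC50_ICaL = 10, h_ICaL = 1, IC50_IK1 = 8000, h_IK1 = 1,
                 Kmax = 4, IC50h = 20, h_herg = 1, Ku = 0.01, Vhalf = -60,
                 risk = "high", split = "training")

## brute-force two-sample KS oracle: evaluate |F1 - F2| on a fine grid
## spanning both samples (independent of the implementation's union-point
## evaluation)
ks_oracle <- function(x1, x2) {
  grid <- seq(min(x1, x2) - 1, max(x1, x2) + 1, length.out = 4001)
  grid <- sort(c(grid, x1, x2))
  max(abs(vapply(grid, function(q) mean(x1 <= q) - mean(x2 <= q),
                 numeric(1))))
}

## brute-force double-loop Monte Carlo Sobol oracle on independent U(0,1)
## inputs: V_i by conditioning on X_i, ST_i by conditioning on X_{~i}
sobol_oracle <- function(fn, k, n_outer = 400, n_inner = 400, seed = 99) {
  set.seed(seed)
  Vy <- stats::var(fn(matrix(stats::runif(20000 * k), ncol = k)))
  S1 <- ST <- numeric(k)
  for (i in seq_len(k)) {
    ## first order: Var_{X_i} E[Y | X_i]
    xi <- stats::runif(n_outer)
    cond_mean <- vapply(xi, function(x) {
      X <- matrix(stats::runif(n_inner * k), ncol = k)
      X[, i] <- x
      mean(fn(X))
    }, numeric(1))
    S1[i] <- stats::var(cond_mean) / Vy
    ## total: E_{X_~i} Var[Y | X_~i]
    cond_var <- vapply(seq_len(n_outer), function(j) {
      Xfix <- stats::runif(k)
      X <- matrix(rep(Xfix, each = n_inner), ncol = k)
      X[, i] <- stats::runif(n_inner)
      stats::var(fn(X))
    }, numeric(1))
    ST[i] <- mean(cond_var) / Vy
  }
  list(S1 = S1, ST = ST)
}
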