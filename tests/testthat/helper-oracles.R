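# Independent oracles, written directly from the model definition and kept
# free of the package's own integration/LP code paths.

# Fixed-step classical RK4 integration of the seven-state batch system.
# The derivative is hand-coded term by term; integration is split at the
# degradation onset so the step never straddles the switch.
rk4_oracle <- function(p, initial_sucrose_gL, X0 = 0.05, times, step = 1e-3) {
  deriv <- function(t, y) {
    S <- max(y[["S_reactor"]], 0)
    Fr <- max(y[["Fru"]], 0)
    L <- max(y[["Levan"]], 0)
    X <- y[["X"]]
    mu <- p$mu_max * S / (p$Ks + S)
    v1 <- mu * X / p$Y_XS
    E <- p$alpha * X
    v3 <- p$vmax_hyd * S / (p$KM_hyd + S)
    v4 <- (p$vmax_trans1 * S / p$KM_trans1 +
             p$vmax_trans2 * Fr * S / p$KM_trans2) /
      (1 + S / p$KM_trans1 + Fr * S / p$KM_trans2)
    Ld <- (1 - p$degradable_fraction_complement) * L
    v5 <- if (t >= p$t_levdeg_onset) {
      p$vmax_levdeg * Ld / (p$KM_levdeg + Ld)
    } else 0
    c(X = (mu - p$kd) * X,
      E = p$alpha * mu * X,
      S_cell = v1,
      Glc = (v3 + v4) * E,
      Fru = (v3 - v4 + v5) * E,
      S_reactor = -v1 - (v3 + v4) * E,
      Levan = (v4 - v5) * E)
  }
  y <- c(X = X0, E = 0, S_cell = 0, Glc = 0, Fru = 0,
         S_reactor = initial_sucrose_gL * 1000 / 342.30, Levan = 0)
  out <- matrix(NA_real_, length(times), length(y),
                dimnames = list(NULL, names(y)))
  t <- 0
  breaks <- sort(unique(c(times, p$t_levdeg_onset)))
  breaks <- breaks[breaks > 0 & breaks <= max(times)]
  if (0 %in% times) out[match(0, times), ] <- y
  for (b in breaks) {
    n_steps <- ceiling(round((b - t) / step, 6))
    h <- (b - t) / n_steps
    for (k in seq_len(n_steps)) {
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    t <- b
    if (b %in% times) out[match(b, times), ] <- y
  }
  cbind(time = times, as.data.frame(out))
}

# Brute-force minimal-total-flux by vertex enumeration. Splits reversible
# reactions itself, substitutes pinned fluxes (lb == ub) into the
# right-hand side, and enumerates basic solutions of {A v = b, v >= 0}.
# Assumes upper bounds are slack at every candidate vertex (checked).
enumerate_min_total_flux <- function(m, tol = 1e-9) {
  S <- m$S
  rev_idx <- which(m$lb < 0)
  A_full <- cbind(S, -S[, rev_idx, drop = FALSE])
  lb <- c(pmax(m$lb, 0), rep(0, length(rev_idx)))
  ub <- c(pmax(m$ub, 0), -pmin(m$lb[rev_idx], 0))
  fixed <- which(abs(ub - lb) < 1e-12)
  free <- setdiff(seq_len(ncol(A_full)), fixed)
  b <- -A_full[, fixed, drop = FALSE] %*% lb[fixed]
  A <- A_full[, free, drop = FALSE]
  qrA <- qr(A)
  r <- qrA$rank
  rows <- qrA$pivot
  best <- Inf
  for (cols in utils::combn(length(free), r, simplify = FALSE)) {
    B <- A[, cols, drop = FALSE]
    if (qr(B)$rank < r) next
    sol <- tryCatch(qr.solve(B, b), error = function(e) NULL)
    if (is.null(sol)) next
    if (any(sol < -tol)) next
    v <- numeric(length(free))
    v[cols] <- sol
    if (max(abs(A %*% v - b)) > 1e-7) next
    if (any(v > ub[free] + tol)) next
    total <- sum(v) + sum(lb[fixed])
    if (total < best) best <- total
  }
  best
}

# direct NRMSE recomputation (range-normalised, percent)
nrmse_oracle <- function(sim, obs) {
  100 * sqrt(sum((sim - obs)^2) / length(obs)) / (max(obs) - min(obs))
}

trapz_oracle <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
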