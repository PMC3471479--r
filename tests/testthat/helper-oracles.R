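# Independent oracles, deliberately naive: these re-derive quantities by
# brute force or through routines the implementation does not use.

# Benjamini-Hochberg by the definition: sort, multiply by m/rank, enforce
# monotonicity from the largest p downwards, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m / seq_len(m)) * p[o]
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Stouffer combination through the error function (pracma), not pnorm/qnorm:
# Phi(x) = erfc(-x / sqrt(2)) / 2, Phi^-1(p) = sqrt(2) * erfinv(2p - 1).
oracle_stouffer <- function(pa, pb) {
  za <- sqrt(2) * pracma::erfinv(1 - 2 * pa)   # Phi^-1(1 - pa)
  zb <- sqrt(2) * pracma::erfinv(1 - 2 * pb)
  0.5 * pracma::erfc((za + zb) / 2)            # 1 - Phi((za+zb)/sqrt(2))
}

# Breslow Cox partial log-likelihood by explicit loops over events.
oracle_pl <- function(gamma, x, time, status, offset = 0) {
  eta <- offset + gamma * x
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# central finite differences of the partial log-likelihood at gamma = 0
# (h balances truncation against rounding for the second difference)
oracle_score_info_fd <- function(x, time, status, offset = 0, h = 1e-4) {
  lp <- oracle_pl(h, x, time, status, offset)
  lm <- oracle_pl(-h, x, time, status, offset)
  l0 <- oracle_pl(0, x, time, status, offset)
  list(U = (lp - lm) / (2 * h), info = -(lp - 2 * l0 + lm) / h^2)
}

# reverse Kaplan-Meier by explicit loops (events precede censorings at ties)
oracle_censoring_km <- function(time, status, t) {
  ut <- sort(unique(time))
  G <- 1
  for (u in ut[ut <= t]) {
    r <- sum(time >= u)
    d <- sum(time == u & status == 1)
    cc <- sum(time == u & status == 0)
    if (cc > 0) G <- G * (1 - cc / (r - d))
  }
  G
}

oracle_censoring_km_left <- function(time, status, t) {
  ut <- sort(unique(time))
  G <- 1
  for (u in ut[ut < t]) {
    r <- sum(time >= u)
    d <- sum(time == u & status == 1)
    cc <- sum(time == u & status == 0)
    if (cc > 0) G <- G * (1 - cc / (r - d))
  }
  G
}

# IPCW prediction error curve by per-subject, per-time summation
oracle_pec <- function(sp, time, status, grid) {
  n <- length(time)
  vapply(seq_along(grid), function(k) {
    t <- grid[k]
    tot <- 0
    for (i in seq_len(n)) {
      if (time[i] <= t && status[i] == 1) {
        tot <- tot + sp[i, k]^2 / oracle_censoring_km_left(time, status,
                                                          time[i])
      } else if (time[i] > t) {
        tot <- tot + (1 - sp[i, k])^2 / oracle_censoring_km(time, status, t)
      }
    }
    tot / n
  }, numeric(1))
}
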