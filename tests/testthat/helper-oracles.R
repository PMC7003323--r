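# Independent oracles, coded directly from the defining formulas and kept
# free of the package's engine internals.

# Cox log partial likelihood by explicit risk-set summation.
oracle_coxll <- function(beta, X, time, event, ties = "efron") {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(w[R]))
    } else {
      for (l in 0:(d - 1))
        ll <- ll - log(sum(w[R]) - (l / d) * sum(w[D]))
    }
  }
  ll
}

# Global maximizer of the oracle likelihood by nested grid refinement over
# [-5, 5]^k, final resolution below the comparison tolerance.
oracle_grid_max <- function(X, time, event, ties = "efron") {
  k <- ncol(as.matrix(X))
  best <- rep(0, k)
  half <- 5
  for (st in c(1, 0.2, 0.04, 0.008)) {
    grids <- lapply(best, function(b) seq(b - half, b + half, by = st))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, function(b)
      oracle_coxll(b, X, time, event, ties = ties))
    best <- unname(cand[which.max(vals), ])
    half <- 2 * st
  }
  list(beta = best,
       loglik = oracle_coxll(best, X, time, event, ties = ties))
}

# Two-group log-rank chi-square by direct observed/expected/hypergeometric
# variance tabulation over the distinct event times.
oracle_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(m + n, m) rank assignments (no-ties case).
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(m)])
  E <- m * (N + 1) / 2
  sums <- combn(N, m, function(i) sum(r[i]))
  mean(abs(sums - E) >= abs(obs - E) - 1e-9)
}

# Product-limit estimator by hand.
oracle_km <- function(time, event) {
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    n_at <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at)
    out_t <- c(out_t, t); out_s <- c(out_s, s)
  }
  list(times = out_t, survival = out_s)
}

# Rank-based AUC of a score for a binary label.
oracle_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small reproducible survival dataset with a two-level subtype.
make_toy_surv <- function(n = 8, seed = 1, censor = 0.25, tie_times = FALSE) {
  set.seed(seed)
  subtype <- rep(c("c1", "c2"), each = n / 2)
  x <- round(rnorm(n), 2)
  time <- round(rexp(n, 0.1), if (tie_times) 0 else 3)
  time[time == 0] <- 1
  event <- as.integer(runif(n) > censor)
  if (sum(event) < 2) event[1:2] <- 1L
  list(x = x, subtype = subtype, time = time, event = event,
       ind = as.integer(subtype == "c2"))
}
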