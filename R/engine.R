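# Cox partial-likelihood engine shared by the per-gene interaction screen and
# the multivariate risk model.  Everything here works on an arbitrary n x k
# design matrix; the screening-specific 3-column design lives in screen.R.

revcumsum <- function(x) rev(cumsum(rev(x)))

#' Cox partial log-likelihood, gradient and observed information
#'
#' Evaluates the Cox proportional-hazards log partial likelihood at a given
#' coefficient vector, together with its analytic gradient and observed
#' information matrix (negative Hessian), under either the Efron or the
#' Breslow approximation for tied event times.  The probability form of the
#' partial likelihood is used, so the returned log-likelihood is always
#' less than or equal to zero.
#'
#' @param beta Numeric coefficient vector of length `ncol(design)`.
#' @param design Numeric matrix, one row per sample, one column per covariate.
#' @param time Follow-up times (nonnegative).
#' @param event Event indicators, 1 = event observed, 0 = right-censored.
#' @param ties_method `"efron"` (default) or `"breslow"`.  On tie-free data
#'   the two are algebraically identical.
#' @return A list with elements `loglik` (scalar), `gradient` (length-k
#'   vector) and `information` (k x k symmetric matrix, the observed
#'   information, i.e. minus the Hessian of the log partial likelihood).
#' @examples
#' t <- c(3, 1, 4, 1.5, 5, 2.5)
#' e <- c(1, 1, 1, 1, 1, 1)
#' X <- cbind(x = c(0.5, -1, 2, 0, 1, -0.5))
#' cox_partial_loglik(0.3, X, t, e)
#' @export
cox_partial_loglik <- function(beta, design, time, event,
                               ties_method = c("efron", "breslow")) {
  ties_method <- match.arg(ties_method)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- nrow(design)
  k <- ncol(design)
  if (length(beta) != k)
    stop("length(beta) must equal ncol(design)")
  if (length(time) != n || length(event) != n)
    stop("time/event length must match nrow(design)")
  if (anyNA(design) || any(!is.finite(design)))
    stop("design contains NA or non-finite covariate values")
  if (sum(event) < 1)
    stop("no events")

  o <- order(time)
  to <- time[o]
  eo <- event[o]
  Xo <- design[o, , drop = FALSE]

  eta <- drop(Xo %*% beta)
  # centring leaves the partial likelihood invariant but prevents overflow
  M <- max(eta)
  w <- exp(eta - M)

  # pair index for the lower triangle (incl. diagonal) of the k x k blocks
  pr <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  np <- nrow(pr)

  wX <- Xo * w
  wXX <- wX[, pr[, 1], drop = FALSE] * Xo[, pr[, 2], drop = FALSE]

  # risk-set sums: sum over all samples with time >= t
  S0 <- revcumsum(w)
  S1 <- apply(wX, 2, revcumsum)
  S2 <- apply(wXX, 2, revcumsum)
  if (n == 1) {
    S1 <- matrix(S1, nrow = 1)
    S2 <- matrix(S2, nrow = 1)
  }

  grp <- cumsum(!duplicated(to))
  gfirst <- which(!duplicated(to))
  ev <- eo == 1

  d <- unname(drop(rowsum(as.numeric(ev), grp)))
  etaD <- unname(drop(rowsum((eta - M) * ev, grp)))
  xD <- rowsum(Xo * ev, grp)
  S0D <- unname(drop(rowsum(w * ev, grp)))
  S1D <- rowsum(wX * ev, grp)
  S2D <- rowsum(wXX * ev, grp)

  S0R <- S0[gfirst]
  S1R <- S1[gfirst, , drop = FALSE]
  S2R <- S2[gfirst, , drop = FALSE]

  use_efron <- ties_method == "efron"
  # groups with a single event (or Breslow): fully vectorised
  simple <- if (use_efron) d == 1 else d >= 1
  multi <- which(use_efron & d > 1)

  ll <- sum(etaD)
  grad <- colSums(xD)
  ipair <- numeric(np)

  si <- which(simple)
  if (length(si)) {
    ds <- d[si]
    S0s <- S0R[si]
    m1 <- S1R[si, , drop = FALSE] / S0s           # k-vector means per group
    ll <- ll - sum(ds * log(S0s))
    grad <- grad - colSums(ds * m1)
    ipair <- ipair + colSums(ds * (S2R[si, , drop = FALSE] / S0s -
                                     m1[, pr[, 1], drop = FALSE] *
                                     m1[, pr[, 2], drop = FALSE]))
  }
  for (g in multi) {
    dg <- d[g]
    phi <- (seq_len(dg) - 1) / dg
    for (l in seq_len(dg)) {
      den <- S0R[g] - phi[l] * S0D[g]
      m1 <- (S1R[g, ] - phi[l] * S1D[g, ]) / den
      ll <- ll - log(den)
      grad <- grad - m1
      ipair <- ipair + (S2R[g, ] - phi[l] * S2D[g, ]) / den -
        m1[pr[, 1]] * m1[pr[, 2]]
    }
  }

  info <- matrix(0, k, k)
  info[cbind(pr[, 1], pr[, 2])] <- ipair
  info[cbind(pr[, 2], pr[, 1])] <- ipair
  dimnames(info) <- list(colnames(design), colnames(design))
  names(grad) <- colnames(design)
  list(loglik = ll, gradient = grad, information = info)
}

# Newton-Raphson with step-halving from beta = 0.  Returns estimates,
# covariance (inverse observed information at the optimum), convergence
# status and a human-readable message; never throws for monotone-likelihood
# or singular-information data.
cox_newton <- function(design, time, event, ties_method = "efron",
                       max_iter = 50L, tol = 1e-8, max_half = 30L,
                       beta_bound = 10) {
  design <- as.matrix(design)
  k <- ncol(design)
  beta <- numeric(k)
  pl <- cox_partial_loglik(beta, design, time, event, ties_method)
  ll <- pl$loglik
  converged <- FALSE
  msg <- "converged"
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    delta <- tryCatch(solve(pl$information, pl$gradient),
                      error = function(e) NULL)
    if (is.null(delta) || anyNA(delta)) {
      msg <- "singular information"
      break
    }
    step <- 1
    accepted <- FALSE
    for (h in 0:max_half) {
      beta_new <- beta + step * delta
      pl_new <- tryCatch(
        cox_partial_loglik(beta_new, design, time, event, ties_method),
        error = function(e) NULL)
      if (!is.null(pl_new) && is.finite(pl_new$loglik) &&
          pl_new$loglik >= ll) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      # cannot improve in the Newton direction: numerically at the optimum
      converged <- TRUE
      break
    }
    moved <- pl_new$loglik - ll
    beta <- beta_new
    pl <- pl_new
    ll <- pl_new$loglik
    if (any(abs(beta) > beta_bound)) {
      msg <- "monotone likelihood suspected"
      break
    }
    if (moved < tol * (abs(ll) + tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && msg == "converged")
    msg <- "maximum iterations reached"

  covariance <- tryCatch(solve(pl$information), error = function(e) {
    matrix(NA_real_, k, k)
  })
  dimnames(covariance) <- dimnames(pl$information)
  names(beta) <- colnames(design)
  list(beta = beta, covariance = covariance, loglik = ll,
       gradient = pl$gradient, information = pl$information,
       converged = converged, iterations = iter, message = msg)
}
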