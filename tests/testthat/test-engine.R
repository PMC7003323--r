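# The partial-likelihood engine: closed-form cases, agreement with an
# independent risk-set summation oracle, derivative consistency, ties
# methods, and the Newton solver against survival::coxph.

test_that("partial log-likelihood reduces to known closed forms", {
  # at beta = 0 with distinct event times, each event contributes
  # -log(size of its risk set)
  d <- make_toy_surv(n = 6, seed = 2, censor = 0)
  X <- cbind(d$ind, d$x, d$ind * d$x)
  pl <- cox_partial_loglik(c(0, 0, 0), X, d$time, d$event)
  sizes <- vapply(d$time[d$event == 1], function(t) sum(d$time >= t),
                  numeric(1))
  expect_equal(pl$loglik, -sum(log(sizes)))

  # one subject, one event: risk set of size one, any beta
  pl1 <- cox_partial_loglik(c(0.7), cbind(2), time = 3, event = 1)
  expect_equal(pl1$loglik, 0)
  expect_equal(unname(pl1$gradient), 0)
})

test_that("loglik matches the brute-force risk-set oracle on toy data", {
  # the spec-style n = 6 fixture: 3 per subtype, distinct times
  x <- c(0.5, -1, 2, 0, 1, -0.5)
  ind <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(ind, x, ind * x)
  time <- c(5, 2, 9, 4, 7, 1)
  event <- rep(1, 6)
  beta <- c(0.1, 0.2, -0.1)
  for (tm in c("efron", "breslow")) {
    pl <- cox_partial_loglik(beta, X, time, event, ties_method = tm)
    expect_equal(pl$loglik, oracle_coxll(beta, X, time, event, ties = tm),
                 tolerance = 1e-12)
  }
  # with ties and censoring
  d <- make_toy_surv(n = 10, seed = 5, censor = 0.4, tie_times = TRUE)
  X <- cbind(d$ind, d$x, d$ind * d$x)
  for (tm in c("efron", "breslow")) {
    for (beta in list(c(0, 0, 0), c(0.3, -0.5, 0.2), c(-1, 1, 0.5))) {
      pl <- cox_partial_loglik(beta, X, d$time, d$event, ties_method = tm)
      expect_equal(pl$loglik,
                   oracle_coxll(beta, X, d$time, d$event, ties = tm),
                   tolerance = 1e-10)
    }
  }
})

test_that("gradient and information agree with finite differences", {
  d <- make_toy_surv(n = 30, seed = 3, censor = 0.3, tie_times = TRUE)
  X <- cbind(d$ind, d$x, d$ind * d$x)
  beta <- c(0.2, -0.3, 0.1)
  h <- 1e-5
  for (tm in c("efron", "breslow")) {
    pl <- cox_partial_loglik(beta, X, d$time, d$event, ties_method = tm)
    for (j in 1:3) {
      bp <- bm <- beta
      bp[j] <- bp[j] + h
      bm[j] <- bm[j] - h
      gj <- (cox_partial_loglik(bp, X, d$time, d$event, tm)$loglik -
               cox_partial_loglik(bm, X, d$time, d$event, tm)$loglik) / (2 * h)
      expect_equal(unname(pl$gradient[j]), gj, tolerance = 1e-5)
      ij <- -(cox_partial_loglik(bp, X, d$time, d$event, tm)$gradient[j] -
                cox_partial_loglik(bm, X, d$time, d$event, tm)$gradient[j]) /
        (2 * h)
      expect_equal(unname(pl$information[j, j]), unname(ij),
                   tolerance = 1e-4)
    }
  }
})

test_that("Efron and Breslow are identical on tie-free data", {
  d <- make_toy_surv(n = 20, seed = 4, censor = 0.3)
  stopifnot(!anyDuplicated(d$time[d$event == 1]))
  X <- cbind(d$ind, d$x, d$ind * d$x)
  beta <- c(0.4, -0.2, 0.3)
  pe <- cox_partial_loglik(beta, X, d$time, d$event, "efron")
  pb <- cox_partial_loglik(beta, X, d$time, d$event, "breslow")
  expect_equal(pe$loglik, pb$loglik, tolerance = 1e-10)
  expect_equal(pe$gradient, pb$gradient, tolerance = 1e-10)
  expect_equal(pe$information, pb$information, tolerance = 1e-10)
  fe <- fit_cox_gene(d$x, d$subtype, d$time, d$event, ties_method = "efron")
  fb <- fit_cox_gene(d$x, d$subtype, d$time, d$event, ties_method = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
})

test_that("errors on degenerate likelihood inputs", {
  expect_error(cox_partial_loglik(0, cbind(1:4), time = 1:4,
                                  event = rep(0, 4)), "no events")
  expect_error(cox_partial_loglik(0, cbind(c(1, NA, 3)), time = 1:3,
                                  event = c(1, 1, 1)), "NA")
})

test_that("Newton fit matches survival::coxph and ascends from zero", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 80
    ind <- rep(0:1, each = n / 2)
    x <- rnorm(n)
    time <- round(rexp(n, exp(0.4 * x - 0.3 * ind + 0.3 * ind * x)), 2)
    time[time == 0] <- 0.01
    event <- rbinom(n, 1, 0.7)
    for (tm in c("efron", "breslow")) {
      ref <- survival::coxph(survival::Surv(time, event) ~ ind + x + ind:x,
                             ties = tm)
      fit <- fit_cox_gene(x, factor(ind, labels = c("c1", "c2")), time,
                          event, ties_method = tm)
      expect_true(fit$converged)
      expect_equal(unname(fit$beta), unname(coef(ref)[c("ind", "x", "ind:x")]),
                   tolerance = 1e-6)
      expect_equal(unname(fit$covariance), unname(vcov(ref)),
                   tolerance = 1e-5)
      # probability-form partial likelihood: maximized value <= 0, and at
      # least the value at beta = 0
      X <- cbind(ind, x, ind * x)
      ll0 <- cox_partial_loglik(c(0, 0, 0), X, time, event, tm)$loglik
      expect_lte(fit$loglik, 0)
      expect_gte(fit$loglik, ll0)
    }
  }
})

test_that("monotone likelihood is flagged, not silently reported", {
  # subtype c2 events ordered exactly by increasing expression: within c2,
  # higher expression always fails earlier, so beta2 + beta3 escapes to
  # -Inf (perfect concordance)
  x_c1 <- c(0.3, -0.2, 0.8, -0.5)
  t_c1 <- c(4, 7, 2, 9)
  x_c2 <- c(1, 2, 3, 4)
  t_c2 <- c(40, 30, 20, 10)
  fit <- fit_cox_gene(c(x_c1, x_c2), rep(c("c1", "c2"), each = 4),
                      c(t_c1, t_c2), rep(1, 8))
  expect_false(fit$converged)
  expect_match(fit$message, "monotone")
})

test_that("subtype label swap maps beta2 to beta2 + beta3 exactly", {
  d <- make_toy_surv(n = 40, seed = 21, censor = 0.3)
  fit <- fit_cox_gene(d$x, d$subtype, d$time, d$event)
  # relabel c1 <-> c2: under the default level order the indicator now
  # selects the original c1 samples
  swapped <- ifelse(d$subtype == "c1", "c2", "c1")
  fit_sw <- fit_cox_gene(d$x, swapped, d$time, d$event)
  expect_equal(unname(fit_sw$beta["beta2"]),
               unname(fit$beta["beta2"] + fit$beta["beta3"]),
               tolerance = 1e-6)
  p_c1 <- wald_linear_test(fit, c(0, 1, 0))$p
  p_c2 <- wald_linear_test(fit, c(0, 1, 1))$p
  p_c1_sw <- wald_linear_test(fit_sw, c(0, 1, 0))$p
  p_c2_sw <- wald_linear_test(fit_sw, c(0, 1, 1))$p
  expect_equal(p_c1_sw, p_c2, tolerance = 1e-6)
  expect_equal(p_c2_sw, p_c1, tolerance = 1e-6)
})
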