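# Downstream signature evaluation: risk scores, median split, Kaplan-Meier,
# log-rank and Wilcoxon, each against an independently coded oracle.

test_that("risk scores are the plain linear predictor", {
  m <- matrix(c(2, 4, 1, 3), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  model <- structure(list(gene_ids = c("gA", "gB"),
                          coefficients = c(gA = 0, gB = 0),
                          median_cutoff = 0), class = "risk_model")
  expect_equal(unname(risk_score(model, m)), c(0, 0))
  model$coefficients <- c(gA = 1, gB = 0)
  expect_equal(unname(risk_score(model, m)), c(2, 1))
  model$coefficients <- c(gA = 0.5, gB = -0.25)
  expect_equal(unname(risk_score(model, m))[1], 0)  # 1 - 1
  model$gene_ids <- c("gA", "gC")
  expect_error(risk_score(model, m), "absent")
})

test_that("median dichotomization sends ties to the low group", {
  expect_equal(as.character(dichotomize(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomize(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_error(dichotomize(c(5, 5, 5)), "degenerate")
  expect_error(dichotomize(3), "two samples")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  k1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$survival, c(2, 1, 0) / 3)
  # censoring shrinks later risk sets: S(3) = 2/3 * (1 - 1/1) = 0
  k2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k2$times, c(1, 3))
  expect_equal(k2$survival, c(2 / 3, 0))
  # all censored: no steps
  k3 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_length(k3$times, 0)
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
  # no censoring: equals 1 - ECDF at event times, exactly
  set.seed(13)
  t <- rexp(40)
  k <- km_curve(t, rep(1, 40))
  expect_equal(k$survival, 1 - ecdf(t)(k$times))
  # against the independent hand oracle, with censoring
  ev <- rbinom(40, 1, 0.6)
  k4 <- km_curve(t, ev)
  o <- oracle_km(t, ev)
  expect_equal(k4$times, o$times)
  expect_equal(k4$survival, o$survival, tolerance = 1e-12)
  # survival is non-increasing and within [0, 1]
  expect_true(all(diff(k4$survival) <= 0))
  expect_true(all(k4$survival >= 0 & k4$survival <= 1))
})

test_that("log-rank agrees with the hypergeometric tabulation oracle", {
  # perfect symmetry: equal groups, same single event time
  lr0 <- logrank_test(c(5, 5), c(1, 1), c("a", "b"))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)
  # fixed 8-sample fixture with censoring and ties
  time <- c(1, 2, 2, 4, 5, 6, 7, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), 4)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi2, oracle_logrank_chi2(time, event, group),
               tolerance = 1e-10)
  expect_equal(lr$df, 1)
  # label symmetry
  lr_sw <- logrank_test(time, event, rev(group))
  expect_equal(lr$chi2, lr_sw$chi2, tolerance = 1e-12)
  expect_error(logrank_test(time, event, rep("a", 8)), "two groups")
  # three groups: df = 2
  set.seed(3)
  lr3 <- logrank_test(rexp(30), rbinom(30, 1, 0.8),
                      rep(c("a", "b", "c"), 10))
  expect_equal(lr3$df, 2)
})

test_that("Wilcoxon switches between exact enumeration and approximation", {
  w <- wilcoxon_test(c(1, 2), c(3, 4))
  expect_equal(w$p, 2 / 6, tolerance = 1e-12)
  expect_equal(w$p, oracle_wilcoxon_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
  # identical multisets: p = 1
  expect_equal(wilcoxon_test(c(1, 2), c(1, 2))$p, 1)
  expect_error(wilcoxon_test(numeric(0), 1:3), "non-empty")
  # exact branch agrees with exhaustive enumeration on random tie-free data
  set.seed(27)
  for (i in 1:5) {
    x <- round(rnorm(sample(3:6, 1)), 6)
    y <- round(rnorm(sample(3:6, 1)) + 0.5, 6)
    expect_equal(wilcoxon_test(x, y)$p, oracle_wilcoxon_p(x, y),
                 tolerance = 1e-9)
  }
  # the approximate branch is calibrated near the nominal level
  set.seed(41)
  rej <- mean(replicate(1500, wilcoxon_test(rnorm(25), rnorm(25))$p < 0.05))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("multivariate Cox reduces to one covariate and flags collinearity", {
  set.seed(19)
  n <- 40
  expr <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:n)))
  time <- rexp(n, exp(0.5 * expr[1, ]))
  event <- rbinom(n, 1, 0.8)
  # k = 1: identical to a plain single-covariate coxph
  m1 <- fit_multivariate_cox(expr[1, , drop = FALSE], time, event)
  ref <- survival::coxph(survival::Surv(time, event) ~ x,
                         data = data.frame(x = expr[1, ]))
  expect_equal(unname(m1$coefficients), unname(coef(ref)), tolerance = 1e-6)
  # the stored cutoff is the median training score
  expect_equal(m1$median_cutoff,
               median(risk_score(m1, expr[1, , drop = FALSE])))
  # duplicated gene rows: singular information
  dup <- expr[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("g1", "g1b")
  expect_error(fit_multivariate_cox(dup, time, event), "singular")
  # more covariates than events draws a warning
  expect_warning(
    fit_multivariate_cox(expr, time, c(1, 1, rep(0, n - 2))),
    "events")
})

test_that("k = 2 multivariate fit matches the grid-search oracle", {
  set.seed(29)
  n <- 10
  expr <- matrix(round(rnorm(2 * n), 2), 2, n,
                 dimnames = list(c("gA", "gB"), paste0("s", 1:n)))
  time <- round(rexp(n, exp(0.8 * expr[1, ] - 0.5 * expr[2, ])), 3)
  event <- rep(1, n)
  fit <- fit_multivariate_cox(expr, time, event)
  o <- oracle_grid_max(t(expr), time, event)
  expect_lt(max(abs(unname(fit$coefficients) - o$beta)), 2e-2)
  expect_lt(abs(fit$loglik - o$loglik), 1e-4)
})

test_that("signature evaluation separates risk groups on planted signal", {
  cfg <- sim_config(n_genes = 20, n_c1 = 60, n_c2 = 60, sim_mode = "cohort",
                    frac_null = 0.75, frac_c1_only = 0, frac_c2_only = 0,
                    frac_shared = 0.25, beta2_effect = 1, seed = 55)
  coh <- generate_cohort(cfg)
  genes <- coh$truth$gene_id[coh$truth$class_label == "shared"]
  ev <- evaluate_signature(coh$expr, coh$clinical, genes)
  expect_named(ev$km, c("low", "high"))
  expect_lt(ev$logrank$p, 0.05)
  # high-risk curve sits below low-risk at the shared event grid
  common <- seq(0, min(max(ev$km$low$times), max(ev$km$high$times)),
                length.out = 20)[-1]
  sl <- stepfun(ev$km$low$times, c(1, ev$km$low$survival))(common)
  sh <- stepfun(ev$km$high$times, c(1, ev$km$high$survival))(common)
  expect_true(all(sh <= sl + 1e-12))
  # holdout split evaluates on unseen samples only
  set.seed(1)
  evh <- evaluate_signature(coh$expr, coh$clinical, genes,
                            split = "holdout")
  expect_equal(nrow(evh$scores), 60)
  expect_true(all(evh$scores$sample_id %in% coh$clinical$sample_id))
})
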