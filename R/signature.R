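# Downstream evaluation of a selected gene signature: multivariate Cox risk
# score, median dichotomization into high/low-risk groups, Kaplan-Meier
# curves, log-rank tests, and Wilcoxon rank-sum comparisons.

#' Fit a multivariate Cox risk model over a gene set
#'
#' Maximizes the k-covariate Cox partial likelihood (same Newton engine as
#' the single-gene screen) with the selected genes' expression values as
#' covariates, and records the median of the training-sample risk scores as
#' the dichotomization cutoff.
#'
#' @param expr_subset Numeric genes x samples matrix (rows = the signature
#'   genes).
#' @param time,event Survival outcome, one entry per sample (column).
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @return An object of class `risk_model`: `gene_ids`, `coefficients`,
#'   `median_cutoff`, `loglik`, `converged`, `message`.
#' @export
fit_multivariate_cox <- function(expr_subset, time, event,
                                 ties_method = "efron") {
  expr_subset <- as.matrix(expr_subset)
  k <- nrow(expr_subset)
  n <- ncol(expr_subset)
  stopifnot(k >= 1, length(time) == n, length(event) == n)
  if (sum(event) < k)
    warning(sprintf("only %d events for %d covariates; estimates unstable",
                    sum(event), k))
  X <- t(expr_subset)
  res <- cox_newton(X, time, event, ties_method = ties_method)
  if (res$message == "singular information" || anyNA(res$covariance)) {
    kap <- tryCatch(kappa(res$information), error = function(e) Inf)
    stop(sprintf(
      "singular information matrix (condition number %.3g); collinear genes?",
      kap))
  }
  coefs <- stats::setNames(res$beta, rownames(expr_subset))
  model <- structure(list(gene_ids = rownames(expr_subset),
                          coefficients = coefs, median_cutoff = NA_real_,
                          covariance = res$covariance, loglik = res$loglik,
                          converged = res$converged, message = res$message),
                     class = "risk_model")
  model$median_cutoff <- stats::median(risk_score(model, expr_subset))
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model: %d genes, median cutoff %.4g (%s)\n",
              length(x$gene_ids), x$median_cutoff, x$message))
  print(x$coefficients)
  invisible(x)
}

#' Per-sample risk score of a fitted risk model
#'
#' The linear predictor `sum_g coef_g * X_g` (no baseline term).
#'
#' @param model A `risk_model`.
#' @param expr_subset Genes x samples matrix containing every model gene.
#' @return Named numeric vector of scores, one per sample.
#' @export
risk_score <- function(model, expr_subset) {
  stopifnot(inherits(model, "risk_model"))
  expr_subset <- as.matrix(expr_subset)
  missing <- setdiff(model$gene_ids, rownames(expr_subset))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  drop(crossprod(expr_subset[model$gene_ids, , drop = FALSE],
                 model$coefficients))
}

#' Split samples into high- and low-risk groups at the median
#'
#' `high` iff the score strictly exceeds the cutoff; ties at the cutoff go
#' to `low`.
#'
#' @param scores Numeric risk scores (>= 2 values, not all identical).
#' @param cutoff Dichotomization threshold; defaults to `median(scores)`.
#' @return Factor with levels `low`, `high`.
#' @examples
#' dichotomize(c(1, 2, 3, 4))
#' @export
dichotomize <- function(scores, cutoff = stats::median(scores)) {
  if (length(scores) < 2)
    stop("need at least two samples")
  if (length(unique(scores)) == 1)
    stop("degenerate scores: all samples identical")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' Survival is reported at the distinct event times only (times with
#' censorings but no events do not create steps); S(0) = 1 by convention.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicators (1 = event).
#' @return An object of class `km_curve`: `times`, `survival`, `at_risk`,
#'   `n_events`.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 0, 1))
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(event) == length(time))
  if (any(time < 0))
    stop("negative survival times")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  structure(list(times = sf$time[keep], survival = sf$surv[keep],
                 at_risk = sf$n.risk[keep], n_events = sf$n.event[keep],
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d samples, %d event times\n", x$n,
              length(x$times)))
  print(data.frame(time = x$times, survival = x$survival,
                   at_risk = x$at_risk, events = x$n_events))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard log-rank statistic: observed minus hypergeometric-expected event
#' counts per group, accumulated over the distinct event times; chi-square
#' reference with `#groups - 1` degrees of freedom.
#'
#' @param time,event Survival outcome.
#' @param group Group labels (>= 2 observed levels).
#' @return A list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(g) < 2)
    stop("log-rank test needs at least two groups")
  df <- nlevels(g) - 1
  sd <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ g),
                 error = function(e) NULL)
  if (is.null(sd)) {
    # fully symmetric data give a singular variance matrix; when every
    # group's observed events equal its expectation the statistic is 0
    oe <- vapply(levels(g), function(l) {
      O <- 0; E <- 0
      for (t in sort(unique(time[event == 1]))) {
        at <- time >= t
        O <- O + sum(time == t & event == 1 & g == l)
        E <- E + sum(time == t & event == 1) * sum(at & g == l) / sum(at)
      }
      O - E
    }, numeric(1))
    if (max(abs(oe)) < 1e-12)
      return(list(chi2 = 0, df = df, p = 1))
    stop("degenerate log-rank variance")
  }
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Numeric value vectors for the two groups (both non-empty).
#' @return A list with `statistic` (the rank-sum U statistic for `x`) and
#'   `p`.
#' @examples
#' wilcoxon_test(c(1, 2), c(3, 4))$p  # exact 2/6
#' @export
wilcoxon_test <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Evaluate a gene signature's prognostic value
#'
#' The evaluation mirrors the standard signature workflow: fit a
#' multivariate Cox risk model on the signature genes, compute per-sample
#' risk scores, split at the training-set median into high/low-risk groups,
#' draw Kaplan-Meier curves per group, and compare them with a log-rank
#' test.  With `split = "none"` the model is trained and evaluated on the
#' full cohort (in-sample, as is common practice but optimistic); with
#' `split = "holdout"` the cohort is split in half at random, the model and
#' cutoff come from the training half, and the KM/log-rank evaluation uses
#' the held-out half only.
#'
#' @param matrix An [expr_matrix()] (log2 scale expected).
#' @param clinical Aligned clinical data frame (`os_time`, `os_event`).
#' @param genes Character vector of signature gene ids.
#' @param split `"none"` (default) or `"holdout"`.
#' @param ties_method Ties method for the Cox fits.
#' @return A list with `model`, `scores` (data frame: sample_id, score,
#'   group), `km` (list of `km_curve` per group), `logrank`, `split`.
#' @export
evaluate_signature <- function(matrix, clinical, genes,
                               split = c("none", "holdout"),
                               ties_method = "efron") {
  split <- match.arg(split)
  stopifnot(inherits(matrix, "expr_matrix"))
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("signature genes absent from matrix: ",
         paste(missing, collapse = ", "))
  n <- ncol(matrix)
  if (split == "holdout") {
    train <- sort(sample(n, floor(n / 2)))
    test <- setdiff(seq_len(n), train)
  } else {
    train <- test <- seq_len(n)
  }
  sub <- unclass(matrix)[genes, , drop = FALSE]
  model <- fit_multivariate_cox(sub[, train, drop = FALSE],
                                clinical$os_time[train],
                                clinical$os_event[train],
                                ties_method = ties_method)
  sc <- risk_score(model, sub[, test, drop = FALSE])
  grp <- dichotomize(sc, cutoff = model$median_cutoff)
  tt <- clinical$os_time[test]
  ee <- clinical$os_event[test]
  km <- lapply(levels(grp), function(l)
    km_curve(tt[grp == l], ee[grp == l]))
  names(km) <- levels(grp)
  lr <- logrank_test(tt, ee, grp)
  list(model = model,
       scores = data.frame(sample_id = clinical$sample_id[test],
                           score = unname(sc), group = as.character(grp),
                           stringsAsFactors = FALSE),
       km = km, logrank = lr, split = split)
}
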