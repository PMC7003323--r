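# The gene-by-gene interaction screen: for each feature g fit
#   lambda(t) = lambda0g(t) exp(beta1g I(c2) + beta2g X + beta3g I(c2) X)
# and test H0: beta2g = 0 (prognostic in c1) and H0: beta2g + beta3g = 0
# (prognostic in c2) with two-sided Wald tests, adjusted by
# Benjamini-Hochberg separately within each test family.

subtype_indicator <- function(subtype) {
  f <- if (is.factor(subtype)) droplevels(subtype) else factor(subtype)
  if (nlevels(f) != 2)
    stop("subtype must have exactly two observed levels (c1, c2)")
  as.integer(f == levels(f)[2])
}

unfit_gene <- function(gene_id, n_events, message) {
  structure(list(gene_id = gene_id,
                 beta = c(beta1 = NA_real_, beta2 = NA_real_,
                          beta3 = NA_real_),
                 covariance = matrix(NA_real_, 3, 3),
                 loglik = NA_real_, n_events = n_events,
                 converged = FALSE, iterations = 0L, message = message),
            class = "cox_gene_fit")
}

#' Fit the single-gene subtype-interaction Cox model
#'
#' Newton-Raphson (with step-halving, started from zero) maximization of the
#' Cox partial likelihood for the design `(I(c2), X, I(c2) * X)`.  The
#' second level of `subtype` plays the role of c2.  Degenerate inputs
#' (constant expression within both subtype strata, no events) and monotone
#' likelihoods yield `converged = FALSE` with an explanatory message, never
#' an error.
#'
#' @param gene_expr Numeric expression vector for one feature.
#' @param subtype Two-level factor (or coercible) of subtype labels.
#' @param time,event Survival outcome.
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param gene_id Optional feature identifier carried into the result.
#' @return An object of class `cox_gene_fit`: estimates `beta` (beta1,
#'   beta2, beta3), `covariance` (inverse observed information), `loglik`,
#'   `n_events`, `converged`, `iterations`, `message`.
#' @examples
#' coh <- generate_cohort(sim_config(n_genes = 1, frac_null = 0,
#'   frac_c1_only = 1, frac_c2_only = 0, frac_shared = 0, seed = 1))
#' fit_cox_gene(coh$expr[1, ], coh$clinical$subtype,
#'              coh$gene_survival$time[1, ], coh$gene_survival$event[1, ])
#' @export
fit_cox_gene <- function(gene_expr, subtype, time, event,
                         ties_method = "efron", max_iter = 50L, tol = 1e-8,
                         gene_id = NULL) {
  n <- length(gene_expr)
  stopifnot(length(time) == n, length(event) == n, length(subtype) == n)
  ind <- subtype_indicator(subtype)
  ne <- sum(event)
  if (ne < 1)
    return(unfit_gene(gene_id, 0L, "no events"))
  v1 <- stats::var(gene_expr[ind == 0])
  v2 <- stats::var(gene_expr[ind == 1])
  if ((is.na(v1) || v1 == 0) && (is.na(v2) || v2 == 0))
    return(unfit_gene(gene_id, ne, "degenerate covariate"))
  design <- cbind(beta1 = ind, beta2 = gene_expr, beta3 = ind * gene_expr)
  res <- cox_newton(design, time, event, ties_method = ties_method,
                    max_iter = max_iter, tol = tol)
  structure(list(gene_id = gene_id, beta = res$beta,
                 covariance = res$covariance, loglik = res$loglik,
                 n_events = ne, converged = res$converged,
                 iterations = res$iterations, message = res$message),
            class = "cox_gene_fit")
}

#' @export
print.cox_gene_fit <- function(x, ...) {
  cat(sprintf("cox_gene_fit%s: %s (%d events, %d iterations)\n",
              if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$message, x$n_events, x$iterations))
  if (x$converged) {
    se <- sqrt(diag(x$covariance))
    print(cbind(coef = x$beta, se = se))
  }
  invisible(x)
}

#' Wald test of a linear combination of Cox coefficients
#'
#' Tests `H0: w' beta = 0` with the two-sided normal-reference Wald
#' statistic `z = w' beta / sqrt(w' Cov w)`.  Weights `c(0, 1, 0)` test the
#' expression coefficient beta2 (prognostic value in subtype c1); weights
#' `c(0, 1, 1)` test beta2 + beta3 (prognostic value in subtype c2).
#'
#' @param fit A converged `cox_gene_fit` (or any list with `beta`,
#'   `covariance`, `converged`).
#' @param weights Numeric weight vector, same length as `fit$beta`.
#' @return A list with elements `z` and `p`.
#' @export
wald_linear_test <- function(fit, weights) {
  if (!isTRUE(fit$converged))
    stop("fit did not converge; Wald test unavailable")
  stopifnot(length(weights) == length(fit$beta))
  est <- sum(weights * fit$beta)
  v <- drop(t(weights) %*% fit$covariance %*% weights)
  if (!is.finite(v) || v <= 0)
    stop("non-positive variance")
  z <- est / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment of a p-value family
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]), validated to lie in
#' `[0, 1]`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (`NA` allowed and propagated).
#' @param method Only `"bh"` is supported.
#' @return Adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(pvals, method = "bh") {
  method <- match.arg(tolower(method), "bh")
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Classify a gene's subtype specificity
#'
#' Four-way label from the two adjusted p-values: `c1_specific` if only the
#' beta2 test is significant at `alpha`, `c2_specific` if only the
#' beta2 + beta3 test is, `shared` if both, `none` if neither.  `NA`
#' p-values (unfit genes) give `unfit`.  Vectorized.
#'
#' @param padj_c1,padj_c2 Adjusted p-values in `[0, 1]` (or `NA`).
#' @param alpha Significance cutoff (default 0.05).
#' @return Character vector of labels.
#' @examples
#' classify_gene(c(0.01, 0.01, 0.5), c(0.5, 0.01, 0.5), 0.05)
#' @export
classify_gene <- function(padj_c1, padj_c2, alpha = 0.05) {
  stopifnot(all(is.na(padj_c1) | (padj_c1 >= 0 & padj_c1 <= 1)),
            all(is.na(padj_c2) | (padj_c2 >= 0 & padj_c2 <= 1)))
  s1 <- !is.na(padj_c1) & padj_c1 < alpha
  s2 <- !is.na(padj_c2) & padj_c2 < alpha
  out <- ifelse(is.na(padj_c1) & is.na(padj_c2), "unfit",
         ifelse(s1 & s2, "shared",
         ifelse(s1, "c1_specific",
         ifelse(s2, "c2_specific", "none"))))
  out
}

#' Screen every gene for subtype-specific prognostic value
#'
#' Fits the single-gene interaction Cox model to every feature, computes
#' two-sided Wald p-values for beta2 (subtype c1) and beta2 + beta3
#' (subtype c2), adjusts each test family across genes by
#' Benjamini-Hochberg (separately by default, or pooled across both
#' families), and partitions the genes into c1-specific, c2-specific,
#' shared and non-prognostic sets at the adjusted cutoff `alpha`.
#' Unfit / non-converged genes are labelled `unfit` and excluded from the
#' adjustment families.
#'
#' @param matrix An [expr_matrix()] on the `log2p1` scale (a raw-scale
#'   matrix triggers a warning), or a `cox_cohort` from [generate_cohort()]
#'   (whose clinical table and, in per-gene mode, per-gene survival
#'   replicates are used automatically).
#' @param clinical Clinical data frame aligned to the matrix columns, with
#'   `os_time`, `os_event`, `subtype`.  Ignored when `matrix` is a cohort.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @param adjust_scope `"separate"` (default: each test family is its own
#'   genome-wide screen) or `"pooled"` (one family of 2 x n p-values).
#' @param gene_survival Optional list with `time` and `event` matrices
#'   (genes x samples) overriding the clinical outcome per gene.
#' @return An object of class `screen_result`: `table` (one row per gene:
#'   estimates, standard errors of the two tested contrasts, raw and
#'   adjusted p-values, label, convergence, events), `set_c1`, `set_c2`,
#'   `overlap`, `alpha`, `n_unfit`.
#' @export
screen_genes <- function(matrix, clinical = NULL, alpha = 0.05,
                         ties_method = "efron",
                         adjust_scope = c("separate", "pooled"),
                         gene_survival = NULL) {
  adjust_scope <- match.arg(adjust_scope)
  if (inherits(matrix, "cox_cohort")) {
    cohort <- matrix
    matrix <- cohort$expr
    clinical <- cohort$clinical
    if (is.null(gene_survival)) gene_survival <- cohort$gene_survival
  }
  stopifnot(inherits(matrix, "expr_matrix"), is.data.frame(clinical))
  if (expr_scale(matrix) == "raw")
    warning("screening a raw-FPKM matrix; log2(FPKM + 1) values expected")
  if (!identical(colnames(matrix), clinical$sample_id))
    stop("matrix columns and clinical rows are not aligned; run align_samples() first")
  if (!is.null(gene_survival) &&
      !identical(rownames(gene_survival$time), rownames(matrix)))
    stop("gene_survival rows do not match the expression matrix")

  G <- nrow(matrix)
  ids <- rownames(matrix)
  subtype <- clinical$subtype
  res <- vector("list", G)
  for (g in seq_len(G)) {
    if (is.null(gene_survival)) {
      tt <- clinical$os_time
      ee <- clinical$os_event
    } else {
      tt <- gene_survival$time[g, ]
      ee <- gene_survival$event[g, ]
    }
    fit <- fit_cox_gene(matrix[g, ], subtype, tt, ee,
                        ties_method = ties_method, gene_id = ids[g])
    if (fit$converged) {
      t1 <- wald_linear_test(fit, c(0, 1, 0))
      t2 <- wald_linear_test(fit, c(0, 1, 1))
      se2 <- sqrt(fit$covariance[2, 2])
      se23 <- sqrt(fit$covariance[2, 2] + fit$covariance[3, 3] +
                     2 * fit$covariance[2, 3])
      res[[g]] <- data.frame(gene_id = ids[g], beta1 = fit$beta[1],
                             beta2 = fit$beta[2], beta3 = fit$beta[3],
                             se_beta2 = se2, se_b2p3 = se23,
                             p_c1 = t1$p, p_c2 = t2$p,
                             converged = TRUE, n_events = fit$n_events,
                             message = fit$message)
    } else {
      res[[g]] <- data.frame(gene_id = ids[g], beta1 = NA_real_,
                             beta2 = NA_real_, beta3 = NA_real_,
                             se_beta2 = NA_real_, se_b2p3 = NA_real_,
                             p_c1 = NA_real_, p_c2 = NA_real_,
                             converged = FALSE, n_events = fit$n_events,
                             message = fit$message)
    }
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  if (all(!tab$converged))
    stop("all genes unfit; nothing to screen")

  fitted <- tab$converged
  tab$padj_c1 <- NA_real_
  tab$padj_c2 <- NA_real_
  if (adjust_scope == "separate") {
    tab$padj_c1[fitted] <- adjust_pvalues(tab$p_c1[fitted])
    tab$padj_c2[fitted] <- adjust_pvalues(tab$p_c2[fitted])
  } else {
    pool <- adjust_pvalues(c(tab$p_c1[fitted], tab$p_c2[fitted]))
    m <- sum(fitted)
    tab$padj_c1[fitted] <- pool[seq_len(m)]
    tab$padj_c2[fitted] <- pool[m + seq_len(m)]
  }
  tab$label <- classify_gene(tab$padj_c1, tab$padj_c2, alpha)
  tab <- tab[, c("gene_id", "beta1", "beta2", "beta3", "se_beta2",
                 "se_b2p3", "p_c1", "p_c2", "padj_c1", "padj_c2", "label",
                 "converged", "n_events", "message")]
  set_c1 <- tab$gene_id[!is.na(tab$padj_c1) & tab$padj_c1 < alpha]
  set_c2 <- tab$gene_id[!is.na(tab$padj_c2) & tab$padj_c2 < alpha]
  structure(list(table = tab, set_c1 = set_c1, set_c2 = set_c2,
                 overlap = intersect(set_c1, set_c2), alpha = alpha,
                 ties_method = ties_method, adjust_scope = adjust_scope,
                 n_unfit = sum(!fitted)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "screen_result: %d genes, alpha = %g (%s BH)\n", nrow(x$table),
    x$alpha, x$adjust_scope))
  cat(sprintf("  prognostic for c1: %d | for c2: %d | overlap: %d | unfit: %d\n",
              length(x$set_c1), length(x$set_c2), length(x$overlap),
              x$n_unfit))
  print(table(x$table$label))
  invisible(x)
}

#' Write screening results as TSV
#'
#' @param screen A `screen_result`.
#' @param path Output path.
#' @export
write_screen <- function(screen, path) {
  stopifnot(inherits(screen, "screen_result"))
  write_tsv(screen$table, path)
}
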