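# Synthetic two-subtype cohort generator.  Expression is i.i.d. normal on the
# log2(FPKM+1) scale; survival follows a proportional-hazards model with a
# constant (exponential) or Weibull baseline, planted per-gene effect classes
# and independent exponential right-censoring.

cf_config_error <- function(msg) {
  stop(errorCondition(msg, class = c("coxfilter_config_error", "error")))
}

#' Simulation configuration for a two-subtype survival cohort
#'
#' Collects and validates every knob of the synthetic cohort generator.
#' Defaults describe a balanced 81:83 two-subtype design with overall
#' survival on a scale of days (exponential baseline with median about 800
#' days and independent censoring giving roughly 40% observed events), and
#' planted gene classes of 70% null and 10% each of c1-only, c2-only and
#' shared prognostic genes.
#'
#' @param n_c1,n_c2 Sample counts for subtypes c1 and c2 (both >= 1).
#' @param n_genes Number of simulated features.
#' @param frac_null,frac_c1_only,frac_c2_only,frac_shared Class proportions;
#'   must be nonnegative and sum to 1.
#' @param beta1 Subtype main effect (log-hazard for c2 vs c1).
#' @param beta2_effect Log-hazard per expression unit for genes prognostic in
#'   c1 (classes `c1_only` and `shared`).
#' @param beta3_effect Interaction log-hazard for `c2_only` genes.
#' @param baseline_rate Baseline hazard rate (events per time unit; > 0).
#' @param censor_rate Rate of the independent exponential censoring time;
#'   0 disables random censoring.
#' @param weibull_shape Shape of the Weibull baseline; 1 (default) gives a
#'   constant, i.e. exponential, baseline hazard.
#' @param expr_mean,expr_sd Mean and standard deviation of per-gene
#'   expression on the log2 scale (`expr_sd >= 0`).
#' @param sim_mode `"per_gene"` (default): every gene receives its own
#'   survival replicate driven by that gene alone, so each gene's marginal
#'   model matches the fitted screening model exactly.  `"cohort"`: one
#'   shared survival outcome driven jointly by the planted signal genes.
#' @param n_drivers In cohort mode, cap on the number of signal genes that
#'   drive the shared hazard; excess signal genes are demoted to null (truth
#'   updated accordingly).  `NULL` (default) lets every signal gene drive.
#' @param emit_raw_fpkm If `TRUE`, expression is emitted on the raw FPKM
#'   scale as `2^X - 1` (floored at 0), to exercise the preprocessing steps.
#' @param admin_censor_time Optional administrative cutoff time.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_c1 = 81, n_c2 = 83, n_genes = 1000,
                       frac_null = 0.7, frac_c1_only = 0.1,
                       frac_c2_only = 0.1, frac_shared = 0.1,
                       beta1 = 0, beta2_effect = 1, beta3_effect = 1,
                       baseline_rate = log(2) / 800, censor_rate = 1.3e-3,
                       weibull_shape = 1, expr_mean = 2, expr_sd = 1,
                       sim_mode = c("per_gene", "cohort"), n_drivers = NULL,
                       emit_raw_fpkm = FALSE, admin_censor_time = Inf,
                       seed = NULL) {
  sim_mode <- match.arg(sim_mode)
  fr <- c(null = frac_null, c1_only = frac_c1_only,
          c2_only = frac_c2_only, shared = frac_shared)
  if (any(!is.finite(fr)) || any(fr < 0))
    cf_config_error("class fractions must be finite and nonnegative")
  if (abs(sum(fr) - 1) > 1e-12)
    cf_config_error("class fractions must sum to 1")
  if (n_c1 < 1 || n_c2 < 1 || n_genes < 1)
    cf_config_error("n_c1, n_c2 and n_genes must all be >= 1")
  if (!is.finite(baseline_rate) || baseline_rate <= 0)
    cf_config_error("baseline_rate must be > 0")
  if (!is.finite(censor_rate) || censor_rate < 0)
    cf_config_error("censor_rate must be >= 0 (0 disables censoring)")
  if (!is.finite(weibull_shape) || weibull_shape <= 0)
    cf_config_error("weibull_shape must be > 0")
  if (!is.finite(expr_sd) || expr_sd < 0)
    cf_config_error("expr_sd must be >= 0")
  if (!is.null(n_drivers) && n_drivers < 0)
    cf_config_error("n_drivers must be >= 0")
  structure(list(
    n_c1 = as.integer(n_c1), n_c2 = as.integer(n_c2),
    n_genes = as.integer(n_genes), fractions = fr,
    beta1 = beta1, beta2_effect = beta2_effect, beta3_effect = beta3_effect,
    baseline_rate = baseline_rate, censor_rate = censor_rate,
    weibull_shape = weibull_shape, expr_mean = expr_mean, expr_sd = expr_sd,
    sim_mode = sim_mode, n_drivers = n_drivers,
    emit_raw_fpkm = isTRUE(emit_raw_fpkm),
    admin_censor_time = admin_censor_time,
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d + %d samples (%s mode)\n",
              x$n_genes, x$n_c1, x$n_c2, x$sim_mode))
  cat("  class fractions:",
      paste(sprintf("%s=%.3g", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  cat(sprintf("  effects: beta1=%g beta2=%g beta3=%g\n",
              x$beta1, x$beta2_effect, x$beta3_effect))
  cat(sprintf("  hazards: baseline=%g censor=%g shape=%g\n",
              x$baseline_rate, x$censor_rate, x$weibull_shape))
  invisible(x)
}

#' Apportion gene classes by largest remainder
#'
#' Deterministically apportions `n_genes` features among the four effect
#' classes by the largest-remainder rule (ties broken by class order: null,
#' c1_only, c2_only, shared), then shuffles the order using the current RNG
#' state.
#'
#' @param n_genes Number of features.
#' @param fractions Length-4 nonnegative vector summing to 1, in class order
#'   (null, c1_only, c2_only, shared).
#' @return Character vector of length `n_genes` with class labels.
#' @examples
#' set.seed(1)
#' table(assign_gene_classes(10, c(0.5, 0.2, 0.2, 0.1)))
#' @export
assign_gene_classes <- function(n_genes, fractions) {
  classes <- c("null", "c1_only", "c2_only", "shared")
  fractions <- unname(fractions)
  if (length(fractions) != 4 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-12)
    cf_config_error("fractions must be 4 nonnegative values summing to 1")
  quota <- n_genes * fractions
  counts <- floor(quota + 1e-9)
  left <- n_genes - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  labels <- rep(classes, counts)
  sample(labels)
}

#' Simulate right-censored survival under a proportional-hazards model
#'
#' Event times are drawn by inverse-CDF sampling from a Weibull (default
#' exponential) baseline scaled by `exp(linear_predictor)`; censoring times
#' are independent exponential, optionally truncated by an administrative
#' cutoff.  Observed time is the minimum of the two.
#'
#' @param linear_predictor Per-sample log-hazard offset (finite).
#' @param baseline_rate Baseline hazard rate (> 0).
#' @param censor_rate Censoring hazard rate (>= 0; 0 disables censoring).
#' @param weibull_shape Baseline Weibull shape (1 = exponential).
#' @param admin_censor_time Administrative cutoff (default `Inf`).
#' @return A data frame with columns `time` and `event` (1 = event, 0 =
#'   censored), one row per element of `linear_predictor`.
#' @examples
#' set.seed(1)
#' s <- simulate_survival(rep(0, 1000), baseline_rate = 0.01,
#'                        censor_rate = 0)
#' mean(s$time)  # about 1 / 0.01
#' @export
simulate_survival <- function(linear_predictor, baseline_rate, censor_rate,
                              weibull_shape = 1, admin_censor_time = Inf) {
  if (any(!is.finite(linear_predictor)))
    stop("linear_predictor must be finite")
  if (baseline_rate <= 0) cf_config_error("baseline_rate must be > 0")
  if (censor_rate < 0) cf_config_error("censor_rate must be >= 0")
  n <- length(linear_predictor)
  ev <- stats::rexp(n) / (baseline_rate * exp(linear_predictor))
  T <- ev^(1 / weibull_shape)
  C <- if (censor_rate > 0) stats::rexp(n) / censor_rate else rep(Inf, n)
  C <- pmin(C, admin_censor_time)
  data.frame(time = pmin(T, C), event = as.integer(T <= C))
}

# per-class generative coefficients (beta1, beta2, beta3)
class_betas <- function(class_label, config) {
  b2 <- ifelse(class_label %in% c("c1_only", "shared"),
               config$beta2_effect, 0)
  b3 <- ifelse(class_label == "c1_only", -config$beta2_effect,
               ifelse(class_label == "c2_only", config$beta3_effect, 0))
  cbind(true_beta1 = rep(config$beta1, length(class_label)),
        true_beta2 = b2, true_beta3 = b3)
}

#' Generate a synthetic two-subtype expression + survival cohort
#'
#' Draws per-gene expression, assigns planted effect classes, and simulates
#' right-censored survival from the proportional-hazards model
#' `lambda0(t) * exp(beta1 * I(c2) + beta2 * X + beta3 * I(c2) * X)`.
#'
#' In `per_gene` mode (the default), every gene is the sole driver of its own
#' independent survival replicate, so the fitted single-gene interaction
#' model is exactly the generative model for that gene; the per-gene times
#' and event indicators are returned in `gene_survival` and are picked up
#' automatically by [screen_genes()].  The cohort-level clinical table then
#' carries a driver-free replicate (subtype main effect only).  In `cohort`
#' mode a single shared survival outcome is driven by all (or the first
#' `n_drivers`) planted signal genes jointly, and per-gene fits are
#' approximations.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cox_cohort`: a list with elements `expr`
#'   (an [expr_matrix()], genes x samples), `clinical` (data frame with
#'   `sample_id`, `os_time`, `os_event`, `subtype`), `truth` (data frame
#'   with `gene_id`, `class_label`, `true_beta1`, `true_beta2`,
#'   `true_beta3`), `gene_survival` (per-gene `time`/`event` matrices, or
#'   `NULL` in cohort mode) and `config`.
#' @examples
#' coh <- generate_cohort(sim_config(n_genes = 20, n_c1 = 30, n_c2 = 30,
#'                                   seed = 1))
#' table(coh$truth$class_label)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_c1 + config$n_c2
  G <- config$n_genes

  class_label <- assign_gene_classes(G, config$fractions)
  betas <- class_betas(class_label, config)

  subtype <- factor(rep(c("c1", "c2"), c(config$n_c1, config$n_c2)),
                    levels = c("c1", "c2"))
  ind <- as.integer(subtype == "c2")

  gene_id <- sprintf("G%05d", seq_len(G))
  sample_id <- sprintf("S%04d", seq_len(n))
  X <- matrix(stats::rnorm(G * n, config$expr_mean, config$expr_sd), G, n,
              dimnames = list(gene_id, sample_id))
  # hazards use mean-centred expression: a covariate shift only rescales the
  # baseline hazard (Cox estimates are invariant), and centring keeps the
  # configured event fraction independent of expr_mean
  Xc <- X - config$expr_mean

  if (config$sim_mode == "cohort") {
    drivers <- which(class_label != "null")
    if (!is.null(config$n_drivers) && length(drivers) > config$n_drivers) {
      demote <- drivers[-seq_len(config$n_drivers)]
      class_label[demote] <- "null"
      betas[demote, c("true_beta2", "true_beta3")] <- 0
      drivers <- drivers[seq_len(config$n_drivers)]
    }
    lp <- config$beta1 * ind
    if (length(drivers)) {
      lp <- lp +
        drop(crossprod(Xc[drivers, , drop = FALSE], betas[drivers, "true_beta2"])) +
        ind * drop(crossprod(Xc[drivers, , drop = FALSE], betas[drivers, "true_beta3"]))
    }
    surv <- simulate_survival(lp, config$baseline_rate, config$censor_rate,
                              config$weibull_shape, config$admin_censor_time)
    gene_survival <- NULL
  } else {
    time_mat <- matrix(NA_real_, G, n, dimnames = list(gene_id, sample_id))
    event_mat <- matrix(NA_integer_, G, n, dimnames = list(gene_id, sample_id))
    for (g in seq_len(G)) {
      lp <- config$beta1 * ind + betas[g, "true_beta2"] * Xc[g, ] +
        betas[g, "true_beta3"] * ind * Xc[g, ]
      s <- simulate_survival(lp, config$baseline_rate, config$censor_rate,
                             config$weibull_shape, config$admin_censor_time)
      time_mat[g, ] <- s$time
      event_mat[g, ] <- s$event
    }
    surv <- simulate_survival(config$beta1 * ind, config$baseline_rate,
                              config$censor_rate, config$weibull_shape,
                              config$admin_censor_time)
    gene_survival <- list(time = time_mat, event = event_mat)
  }

  values <- if (config$emit_raw_fpkm) pmax(2^X - 1, 0) else X
  expr <- expr_matrix(values,
                      scale_tag = if (config$emit_raw_fpkm) "raw" else "log2p1")

  truth <- data.frame(gene_id = gene_id, class_label = class_label,
                      betas, stringsAsFactors = FALSE, row.names = NULL)
  clinical <- data.frame(sample_id = sample_id, os_time = surv$time,
                         os_event = surv$event, subtype = as.character(subtype),
                         stringsAsFactors = FALSE)
  structure(list(expr = expr, clinical = clinical, truth = truth,
                 gene_survival = gene_survival, config = config),
            class = "cox_cohort")
}

#' @export
print.cox_cohort <- function(x, ...) {
  cat(sprintf("cox_cohort: %d genes x %d samples (%s mode), %d events in clinical table\n",
              nrow(x$expr), ncol(x$expr), x$config$sim_mode,
              sum(x$clinical$os_event)))
  print(table(x$truth$class_label))
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `expr.tsv` (first column `feature_id`, then one column per
#' sample), `clinical.tsv`, `truth.tsv` and, in per-gene simulation mode,
#' `gene_survival_time.tsv` / `gene_survival_event.tsv`, into `dir`.
#'
#' @param cohort A `cox_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cox_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expr.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$expr, paths["expr"])
  write_tsv(cohort$clinical, paths["clinical"])
  write_tsv(cohort$truth, paths["truth"])
  if (!is.null(cohort$gene_survival)) {
    tp <- file.path(dir, "gene_survival_time.tsv")
    ep <- file.path(dir, "gene_survival_event.tsv")
    write_matrix_tsv(cohort$gene_survival$time, tp)
    write_matrix_tsv(cohort$gene_survival$event, ep)
    paths <- c(paths, gene_survival_time = tp, gene_survival_event = ep)
  }
  invisible(paths)
}
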