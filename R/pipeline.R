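# One-command pipeline: simulate (or load) -> preprocess -> screen ->
# evaluate, with recovery scoring against the simulator's planted truth and
# a reproducibility manifest.

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Score a screen against the simulator's planted truth
#'
#' `set_c1` is scored against the genes with `true_beta2 != 0`, `set_c2`
#' against those with `true_beta2 + true_beta3 != 0`.  Reports per-set
#' confusion counts, empirical FDR (NA when a set is empty), per-class
#' sensitivity, and the full label-by-class confusion table.  Unfit genes
#' are excluded from the counts and reported separately.
#'
#' @param screen A `screen_result` from [screen_genes()].
#' @param truth Truth data frame from [generate_cohort()] (columns
#'   `gene_id`, `class_label`, `true_beta2`, `true_beta3`).
#' @return An object of class `recovery_report`: `sets` (per-set data frame
#'   with TP/FP/FN/TN, fdr, sensitivity), `class_sensitivity`, `confusion`
#'   (labels x classes), `n_unfit`.
#' @export
score_recovery <- function(screen, truth) {
  stopifnot(inherits(screen, "screen_result"), is.data.frame(truth))
  tab <- screen$table
  if (!setequal(tab$gene_id, truth$gene_id))
    stop("gene ids of screen and truth do not match")
  truth <- truth[match(tab$gene_id, truth$gene_id), ]
  fitted <- tab$label != "unfit"

  score_set <- function(selected, positive) {
    sel <- tab$gene_id %in% selected & fitted
    pos <- positive & fitted
    tp <- sum(sel & pos); fp <- sum(sel & !pos)
    fn <- sum(!sel & pos); tn <- sum(!sel & !pos)
    data.frame(TP = tp, FP = fp, FN = fn, TN = tn,
               n_rejected = tp + fp,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  pos_c1 <- truth$true_beta2 != 0
  pos_c2 <- (truth$true_beta2 + truth$true_beta3) != 0
  sets <- rbind(cbind(set = "set_c1", score_set(screen$set_c1, pos_c1)),
                cbind(set = "set_c2", score_set(screen$set_c2, pos_c2)))

  classes <- c("null", "c1_only", "c2_only", "shared")
  sens <- do.call(rbind, lapply(classes, function(cl) {
    in_cl <- truth$class_label == cl & fitted
    data.frame(class = cl, n = sum(in_cl),
               hit_c1 = if (sum(in_cl)) mean(tab$gene_id[in_cl] %in% screen$set_c1) else NA_real_,
               hit_c2 = if (sum(in_cl)) mean(tab$gene_id[in_cl] %in% screen$set_c2) else NA_real_)
  }))
  confusion <- table(label = factor(tab$label[fitted],
                                    levels = c("none", "c1_specific",
                                               "c2_specific", "shared")),
                     class = factor(truth$class_label[fitted],
                                    levels = classes))
  structure(list(sets = sets, class_sensitivity = sens,
                 confusion = confusion, n_unfit = sum(!fitted),
                 alpha = screen$alpha),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report (alpha = %g, %d unfit genes)\n", x$alpha,
              x$n_unfit))
  print(x$sets, row.names = FALSE)
  cat("per-class detection rates:\n")
  print(x$class_sensitivity, row.names = FALSE)
  cat("label vs truth confusion:\n")
  print(x$confusion)
  invisible(x)
}

default_pipeline_config <- function() {
  list(mode = "synthetic",
       simulation = list(),
       preprocess = list(fpkm_threshold = 4),
       screen = list(alpha = 0.05, ties = "efron", adjust = "separate"),
       signature = list(n_genes = 10, split = "none"))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$mode %in% c("synthetic", "user"))
    cf_config_error("mode must be 'synthetic' or 'user'")
  if (cfg$mode == "user" &&
      (is.null(cfg$expr) || is.null(cfg$clinical)))
    cf_config_error("user mode needs 'expr' and 'clinical' TSV paths")
  if (!is.null(cfg$screen$alpha) &&
      (cfg$screen$alpha < 0 || cfg$screen$alpha > 1))
    cf_config_error("screen alpha must lie in [0, 1]")
  invisible(cfg)
}

#' Run the full simulate/preprocess/screen/evaluate pipeline
#'
#' Reads a YAML configuration (or takes an equivalent nested list),
#' validates it before any computation, runs every stage, and writes all
#' stage outputs plus a recovery report (synthetic mode) and a
#' reproducibility manifest into `out_dir`.  Identical configuration and
#' seed reproduce byte-identical output tables.
#'
#' Configuration layout (all fields optional unless noted):
#' \preformatted{
#' mode: synthetic            # or "user"
#' simulation:                # sim_config() arguments (synthetic mode)
#'   n_c1: 81
#'   n_c2: 83
#'   n_genes: 200
#'   sim_mode: cohort
#' expr: path/to/expr.tsv     # user mode (raw FPKM)
#' clinical: path/to/clin.tsv # user mode
#' preprocess:
#'   fpkm_threshold: 4
#' screen:
#'   alpha: 0.05
#'   ties: efron
#'   adjust: separate
#' signature:
#'   n_genes: 10
#'   split: none
#' }
#'
#' @param config Path to a YAML file, or a nested list.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding `simulation$seed` and seeding the
#'   holdout split.
#' @return Invisibly, a list with the in-memory stage results (`cohort` or
#'   inputs, `screen`, `signature`, `recovery`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg_user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_pipeline_config(), cfg_user)
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- NULL
  truth <- NULL
  gene_survival <- NULL
  if (cfg$mode == "synthetic") {
    sim_args <- cfg$simulation
    if (!is.null(seed)) sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- generate_cohort(scfg)
    write_cohort(cohort, out_dir)
    log_stage("simulate", "%d genes x %d samples (%s mode), %d events",
              nrow(cohort$expr), ncol(cohort$expr), scfg$sim_mode,
              sum(cohort$clinical$os_event))
    expr <- cohort$expr
    clinical <- cohort$clinical
    truth <- cohort$truth
    gene_survival <- cohort$gene_survival
  } else {
    if (!is.null(seed)) set.seed(seed)
    expr <- read_expression(cfg$expr, scale_tag = "raw")
    clinical <- read_clinical(cfg$clinical)
    log_stage("load", "%d genes x %d samples read", nrow(expr), ncol(expr))
  }

  if (expr_scale(expr) == "raw") {
    n0 <- nrow(expr)
    expr <- filter_low_expression(expr, cfg$preprocess$fpkm_threshold)
    expr <- log_transform(expr)
    log_stage("preprocess", "low-expression filter dropped %d of %d features",
              n0 - nrow(expr), n0)
    if (!is.null(gene_survival)) {
      keep <- rownames(expr)
      gene_survival <- list(time = gene_survival$time[keep, , drop = FALSE],
                            event = gene_survival$event[keep, , drop = FALSE])
    }
  }
  al <- align_samples(expr, clinical)
  log_stage("align", "%d samples retained with complete clinical data",
            ncol(al$expr))

  screen <- screen_genes(al$expr, al$clinical, alpha = cfg$screen$alpha,
                         ties_method = cfg$screen$ties,
                         adjust_scope = cfg$screen$adjust,
                         gene_survival = gene_survival)
  write_screen(screen, file.path(out_dir, "screen_results.tsv"))
  log_stage("screen", "set_c1 = %d, set_c2 = %d, overlap = %d, unfit = %d",
            length(screen$set_c1), length(screen$set_c2),
            length(screen$overlap), screen$n_unfit)

  sig <- NULL
  hits <- screen$table[screen$table$label %in%
                         c("c1_specific", "c2_specific", "shared"), ]
  if (nrow(hits) > 0 && is.null(gene_survival)) {
    hits <- hits[order(pmin(hits$padj_c1, hits$padj_c2)), ]
    genes <- utils::head(hits$gene_id, cfg$signature$n_genes)
    sig <- evaluate_signature(al$expr, al$clinical, genes,
                              split = cfg$signature$split,
                              ties_method = cfg$screen$ties)
    write_tsv(sig$scores, file.path(out_dir, "risk_scores.tsv"))
    km_df <- do.call(rbind, lapply(names(sig$km), function(g) {
      k <- sig$km[[g]]
      if (!length(k$times)) return(NULL)
      data.frame(group = g, time = k$times, survival = k$survival,
                 at_risk = k$at_risk, events = k$n_events)
    }))
    if (!is.null(km_df))
      write_tsv(km_df, file.path(out_dir, "km_curves.tsv"))
    write_tsv(data.frame(test = "logrank_high_vs_low",
                         statistic = sig$logrank$chi2,
                         df = sig$logrank$df, p = sig$logrank$p),
              file.path(out_dir, "test_summary.tsv"))
    log_stage("evaluate", "%d-gene signature, log-rank p = %.3g",
              length(genes), sig$logrank$p)
  } else {
    log_stage("evaluate",
              "skipped (no significant genes or per-gene simulation mode)")
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- score_recovery(screen, truth)
    write_tsv(recovery$sets, file.path(out_dir, "recovery_sets.tsv"))
    write_tsv(recovery$class_sensitivity,
              file.path(out_dir, "recovery_class_sensitivity.tsv"))
    write_tsv(as.data.frame(recovery$confusion),
              file.path(out_dir, "recovery_confusion.tsv"))
    rej <- recovery$sets$n_rejected
    log_stage("recovery", "rejections c1/c2 = %d/%d, empirical FDR = %s/%s",
              rej[1], rej[2],
              format(recovery$sets$fdr[1]), format(recovery$sets$fdr[2]))
  }

  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_path)
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = if (is.null(seed)) NA else seed,
    package_version = as.character(utils::packageVersion("coxfilter")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done", "outputs written to %s", out_dir)
  invisible(list(cohort = cohort, screen = screen, signature = sig,
                 recovery = recovery, manifest = manifest))
}
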