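stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Build a gene-pair prognostic signature end to end
#'
#' Runs the whole training workflow: restrict the expression matrix to the
#' immune-gene list (when given), align samples with the clinical table,
#' enumerate and score all gene pairs, drop near-constant pairs, screen the
#' survivors by per-pair log-rank tests, select the stable lasso-Cox
#' signature, score the training samples, pick the Youden-optimal cutoff
#' from the IPCW time-dependent ROC at the horizon, assign risk groups, and
#' compare them (Kaplan-Meier + log-rank, univariate and multivariate Cox
#' with available clinical covariates). Fully reproducible from (inputs,
#' config, seed).
#'
#' @param expression Genes-x-samples matrix (see [read_expression()]).
#' @param clinical Clinical `data.frame` (`time` in years; see
#'   [read_clinical()]).
#' @param gene_list Optional character vector restricting the gene universe.
#' @param constancy_threshold Constancy-filter fraction (default 0.80).
#' @param alpha Log-rank screening threshold (default `1e-4`).
#' @param min_group_size Minimum per-group size in the screen (default 2).
#' @param repeats Stability-selection CV repetitions (default 1000).
#' @param nfolds CV folds (default 10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param horizon ROC horizon in years (default 1).
#' @param seed Master seed; all randomness derives from it.
#' @param output_dir Optional directory; when given, the signature, risk
#'   profile, evaluation report and a run manifest are written there.
#' @param verbose Print stage-count checkpoints (default `TRUE`).
#' @return `list` of class `irgp_build`: `signature`, `cutoff`, `roc`,
#'   `profile`, `survival_comparison`, `cox_univariate`, `cox_multivariate`,
#'   `counts` (pairs enumerated / after filter / screened / in signature),
#'   `screen`, `config`.
#' @export
run_build <- function(expression, clinical, gene_list = NULL,
                      constancy_threshold = 0.80, alpha = 1e-4,
                      min_group_size = 2L, repeats = 1000L, nfolds = 10L,
                      lambda_rule = c("min", "1se"), horizon = 1,
                      seed = 1L, output_dir = NULL, verbose = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  say <- function(...) if (verbose) message(...)

  if (!is.null(gene_list)) {
    expression <- stage("restrict_genes", restrict_to_gene_list(expression, gene_list))
  }
  aligned <- stage("align_cohort", align_cohort(expression, clinical))
  expression <- aligned$expression
  clinical <- aligned$clinical
  say("samples: ", ncol(expression), ", genes: ", nrow(expression))

  n_genes <- nrow(expression)
  n_pairs <- n_genes * (n_genes - 1) / 2
  im <- stage("pair_indicators",
              build_filtered_indicators(expression, threshold = constancy_threshold))
  say("pairs enumerated: ", n_pairs, ", after constancy filter: ", nrow(im))

  screen <- stage("logrank_screen",
                  screen_pairs(im, clinical, alpha = alpha, min_group_size = min_group_size))
  sel <- screen$pair[screen$selected]
  say("pairs passing log-rank screen (p < ", alpha, "): ", length(sel))
  if (length(sel) < 2L) {
    stop("stage 'logrank_screen': fewer than 2 pairs pass the screen; ",
         "weaken alpha or check the cohort", call. = FALSE)
  }

  sig <- stage("stability_select",
               stability_select(im[sel, , drop = FALSE], clinical,
                                repeats = repeats, nfolds = nfolds,
                                lambda_rule = lambda_rule, seed = seed))
  say("signature size: ", nrow(sig),
      " (modal-support frequency ", attr(sig, "provenance")$support_frequency, ")")

  profile <- stage("risk_score", risk_score(sig, expression))
  roc <- stage("timedep_roc", timedep_roc(profile, clinical, horizon = horizon))
  cutoff <- optimal_cutoff(roc)
  profile <- assign_groups(profile, cutoff)
  say("1-year AUC: ", round(roc$auc, 3), ", cutoff: ", round(cutoff, 3),
      " (high: ", sum(profile$group == "high"),
      ", low: ", sum(profile$group == "low"), ")")

  surv_cmp <- stage("compare_survival", compare_survival(profile, clinical))

  covars <- data.frame(risk_score = profile$score)
  clin_vars <- intersect(c("age", "gender", "grade", "stage"), colnames(clinical))
  if (length(clin_vars) > 0L) {
    covars <- cbind(covars, encode_covariates(clinical, clin_vars))
  }
  cox_uni <- stage("cox_univariate", cox_fit(covars, clinical, mode = "univariate"))
  cox_multi <- stage("cox_multivariate", cox_fit(covars, clinical, mode = "multivariate"))

  out <- structure(list(
    signature = sig, cutoff = cutoff, roc = roc, profile = profile,
    survival_comparison = surv_cmp,
    cox_univariate = cox_uni, cox_multivariate = cox_multi,
    screen = screen,
    counts = c(pairs_enumerated = n_pairs, pairs_after_filter = nrow(im),
               pairs_screened = length(sel), signature_size = nrow(sig)),
    config = list(constancy_threshold = constancy_threshold, alpha = alpha,
                  min_group_size = min_group_size, repeats = repeats,
                  nfolds = nfolds, lambda_rule = lambda_rule,
                  horizon = horizon, seed = seed)
  ), class = "irgp_build")

  if (!is.null(output_dir)) write_build(out, output_dir)
  out
}

write_build <- function(build, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_signature(build$signature, file.path(output_dir, "signature.tsv"))
  utils::write.table(build$profile, file.path(output_dir, "risk_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(build$screen, file.path(output_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    auc = build$roc$auc, cutoff = build$cutoff,
    n_high = build$survival_comparison$n_high,
    n_low = build$survival_comparison$n_low,
    logrank_p = build$survival_comparison$p,
    counts = as.list(build$counts),
    cox_univariate = build$cox_univariate,
    cox_multivariate = build$cox_multivariate,
    config = build$config
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(output_dir)
}

#' Validate a frozen signature on an independent cohort
#'
#' Scores a validation cohort with a frozen signature and cutoff — no
#' refitting, no renormalization, no contact with training data — then
#' compares the resulting risk groups by Kaplan-Meier curves and the
#' log-rank test. Because scores depend only on within-sample orderings,
#' the validation cohort may come from a different platform.
#'
#' @param signature Frozen signature (e.g. from [run_build()] or
#'   [read_signature()]).
#' @param cutoff Frozen score cutoff from the training build.
#' @param expression Validation genes-x-samples matrix (must contain every
#'   signature gene).
#' @param clinical Validation clinical `data.frame` (`time` in years).
#' @return `list` of class `irgp_validation`: `profile`, `km_high`,
#'   `km_low`, `logrank_chisq`, `logrank_p`, `n_high`, `n_low`.
#' @export
run_validate <- function(signature, cutoff, expression, clinical) {
  aligned <- stage("align_cohort", align_cohort(expression, clinical))
  profile <- stage("risk_score", risk_score(signature, aligned$expression))
  profile <- assign_groups(profile, cutoff)
  if (all(profile$group == "low")) {
    stop("stage 'assign_groups': high-risk group is empty at cutoff ", cutoff, call. = FALSE)
  }
  if (all(profile$group == "high")) {
    stop("stage 'assign_groups': low-risk group is empty at cutoff ", cutoff, call. = FALSE)
  }
  cmp <- stage("compare_survival", compare_survival(profile, aligned$clinical))
  structure(list(
    profile = profile,
    km_high = cmp$km_high, km_low = cmp$km_low,
    logrank_chisq = cmp$chisq, logrank_p = cmp$p,
    n_high = cmp$n_high, n_low = cmp$n_low
  ), class = "irgp_validation")
}
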