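# Half-up decimal rounding (R's round() is round-half-even); used for the
# cohort-table percentages. The epsilon guards binary representations of
# values that are exactly .x5 in decimal.
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

# Step-function lookup of a survfit curve: S(t) (or the left limit S(t-)).
surv_at <- function(fit, t, left = FALSE) {
  s <- c(1, fit$surv)
  k <- vapply(t, function(ti) {
    if (left) sum(fit$time < ti) else sum(fit$time <= ti)
  }, integer(1L))
  s[k + 1L]
}

#' Time-dependent ROC curve for a prognostic score under censoring
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' subjects with an observed event at or before the horizon, controls are
#' subjects still under observation beyond it. Subjects censored before the
#' horizon drop out of both sets and are accounted for by inverse
#' probability of censoring weights (IPCW) from the Kaplan-Meier estimate of
#' the censoring distribution: a case observed at time `t` gets weight
#' `1 / G(t-)`, every control gets `1 / G(horizon)`. The AUC is the
#' trapezoidal integral of the weighted ROC over all distinct score
#' thresholds, which equals the IPCW-weighted Mann-Whitney statistic (ties
#' credited 1/2). With no censoring before the horizon the estimator reduces
#' to the empirical ROC.
#'
#' @param scores `data.frame` with `sample_id`, `score` (see [risk_score()]),
#'   or a numeric vector aligned to `clin`.
#' @param clin Sample-aligned clinical `data.frame` (`time` in years,
#'   `event`).
#' @param horizon Evaluation time in years (default 1).
#' @param ipcw Set `FALSE` for the naive unweighted variant (sensitivity
#'   analysis only).
#' @return `list(horizon, thresholds, sensitivity, specificity, auc,
#'   n_cases, n_controls)` of class `timedep_roc`.
#' @export
timedep_roc <- function(scores, clin, horizon = 1, ipcw = TRUE) {
  stopifnot(horizon > 0)
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (length(s) != nrow(clin)) stop("scores and clinical table are not sample-aligned")
  time <- clin$time
  event <- clin$event
  is_case <- time <= horizon & event == 1L
  is_ctrl <- time > horizon
  if (!any(is_case)) stop("no cases (events by the horizon) - cannot form a ROC curve")
  if (!any(is_ctrl)) stop("no controls (subjects beyond the horizon) - cannot form a ROC curve")

  if (ipcw) {
    gfit <- survival::survfit(survival::Surv(time, 1L - event) ~ 1)
    w_case <- 1 / surv_at(gfit, time[is_case], left = TRUE)
    w_ctrl <- rep(1 / surv_at(gfit, horizon), sum(is_ctrl))
    w_case[!is.finite(w_case)] <- 0
    w_ctrl[!is.finite(w_ctrl)] <- 0
  } else {
    w_case <- rep(1, sum(is_case))
    w_ctrl <- rep(1, sum(is_ctrl))
  }
  s_case <- s[is_case]
  s_ctrl <- s[is_ctrl]

  thr <- c(-Inf, sort(unique(s)))
  sens <- vapply(thr, function(c) sum(w_case[s_case > c]) / sum(w_case), numeric(1L))
  spec <- vapply(thr, function(c) sum(w_ctrl[s_ctrl <= c]) / sum(w_ctrl), numeric(1L))

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)

  structure(
    list(horizon = horizon, thresholds = thr, sensitivity = sens,
         specificity = spec, auc = auc,
         n_cases = sum(is_case), n_controls = sum(is_ctrl)),
    class = "timedep_roc"
  )
}

#' Youden-optimal score cutoff from a time-dependent ROC
#'
#' Returns the finite threshold maximizing Youden's index (sensitivity +
#' specificity - 1); ties break toward the lower threshold, i.e. the larger
#' high-risk group. When all scores are equal, Youden's index is 0
#' everywhere and that single score value is returned.
#'
#' @param roc A `timedep_roc` object.
#' @return The cutoff (a score value).
#' @export
optimal_cutoff <- function(roc) {
  fin <- is.finite(roc$thresholds)
  thr <- roc$thresholds[fin]
  youden <- roc$sensitivity[fin] + roc$specificity[fin] - 1
  thr[which.max(youden)]  # which.max -> first maximum = lowest threshold
}

#' Assign high-/low-risk groups at a score cutoff
#'
#' A sample is high-risk when its score is strictly higher than the cutoff;
#' a score equal to the cutoff is low-risk.
#'
#' @param scores `data.frame` with `sample_id`, `score`.
#' @param cutoff Finite score cutoff.
#' @return The input with a `group` column (`"high"`/`"low"`) and the cutoff
#'   stored in `attr(, "cutoff")`.
#' @export
assign_groups <- function(scores, cutoff) {
  stopifnot(is.finite(cutoff))
  scores$group <- ifelse(scores$score > cutoff, "high", "low")
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Compare survival between risk groups
#'
#' Kaplan-Meier curves per group plus the two-group log-rank test.
#'
#' @param profile Grouped risk profile from [assign_groups()].
#' @param clin Sample-aligned clinical `data.frame`.
#' @return `list(km_high, km_low, chisq, p, n_high, n_low)`.
#' @export
compare_survival <- function(profile, clin) {
  if (is.null(profile$group)) stop("profile has no groups; call assign_groups() first")
  if (nrow(profile) != nrow(clin)) stop("profile and clinical table are not sample-aligned")
  hi <- profile$group == "high"
  if (!any(hi) || all(hi)) stop("both risk groups must be non-empty")
  lr <- logrank_test(clin$time[!hi], clin$event[!hi], clin$time[hi], clin$event[hi])
  list(
    km_high = km_estimate(clin$time[hi], clin$event[hi]),
    km_low = km_estimate(clin$time[!hi], clin$event[!hi]),
    chisq = lr$chisq, p = lr$p,
    n_high = sum(hi), n_low = sum(!hi)
  )
}

#' Encode clinical covariates for Cox regression
#'
#' Age stays numeric (years). Gender is coded 0 = female, 1 = male. Grade
#' and stage are coded as ordinal integers: `"Grade 1"`..`"Grade 4"` (or
#' `G1`..`G4`, or bare digits) map to 1-4, and `"Stage I"`..`"Stage IV"` (or
#' bare Roman numerals) map to 1-4, so each variable gets a single hazard
#' ratio per step. Unparseable values become `NA`.
#'
#' @param clin Clinical `data.frame`.
#' @param vars Covariate columns to encode (default: those of age/gender/
#'   grade/stage present).
#' @return Numeric `data.frame`, one encoded column per covariate.
#' @export
encode_covariates <- function(clin, vars = intersect(c("age", "gender", "grade", "stage"),
                                                     colnames(clin))) {
  miss <- setdiff(vars, colnames(clin))
  if (length(miss) > 0L) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  roman <- c(I = 1, II = 2, III = 3, IV = 4)
  enc_one <- function(v, x) {
    if (is.numeric(x)) return(as.numeric(x))
    x <- trimws(as.character(x))
    if (v == "gender") {
      out <- rep(NA_real_, length(x))
      out[tolower(x) %in% c("male", "m")] <- 1
      out[tolower(x) %in% c("female", "f")] <- 0
      return(out)
    }
    digits <- suppressWarnings(as.numeric(gsub("[^0-9]", "", x)))
    rom <- unname(roman[toupper(gsub("[^IVXivx]", "", x))])
    ifelse(!is.na(digits) & nzchar(gsub("[^0-9]", "", x)), digits, rom)
  }
  out <- as.data.frame(lapply(vars, function(v) enc_one(v, clin[[v]])),
                       col.names = vars)
  out
}

#' Univariate and multivariate Cox proportional-hazards analysis
#'
#' Fits Cox models by partial-likelihood maximization (Efron tie handling,
#' via [survival::coxph()]). `mode = "univariate"` fits each covariate
#' alone; `"multivariate"` fits them jointly. Hazard ratios carry Wald 95%
#' confidence intervals `exp(coef +/- 1.96 SE)` and Wald p-values.
#'
#' @param covars Numeric `data.frame` of per-sample covariates (rows aligned
#'   to `clin`), e.g. risk score plus [encode_covariates()] output.
#' @param clin Sample-aligned clinical `data.frame`.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param ties Tie correction, `"efron"` (default) or `"breslow"`.
#' @return `data.frame` with `variable`, `coef`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `n`, `mode`.
#' @export
cox_fit <- function(covars, clin, mode = c("univariate", "multivariate"),
                    ties = c("efron", "breslow")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  stopifnot(nrow(covars) == nrow(clin))
  if (sum(clin$event) == 0L) stop("no events in the cohort; cannot fit a Cox model")

  fit_one <- function(df) {
    dat <- cbind(data.frame(.time = clin$time, .event = clin$event), df)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- survival::coxph(
      survival::Surv(.time, .event) ~ .,
      data = dat, ties = ties
    )
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    if (any(!is.finite(co)) || any(!is.finite(se)) || any(se > 100)) {
      stop("Cox fit failed to converge (possible complete separation) for: ",
           paste(names(co)[!is.finite(co) | !is.finite(se) | se > 100], collapse = ", "))
    }
    data.frame(
      variable = names(co),
      coef = unname(co),
      hr = exp(unname(co)),
      ci_low = exp(unname(co) - 1.96 * se),
      ci_high = exp(unname(co) + 1.96 * se),
      p = 2 * stats::pnorm(-abs(unname(co) / se)),
      n = nrow(dat),
      stringsAsFactors = FALSE
    )
  }

  res <- if (mode == "univariate") {
    do.call(rbind, lapply(colnames(covars), function(v) fit_one(covars[, v, drop = FALSE])))
  } else {
    fit_one(covars)
  }
  res$mode <- mode
  rownames(res) <- NULL
  res
}

#' Cohort summary table (counts and percentages per category)
#'
#' Counts and percentages of non-missing values per category of each
#' categorical variable, percentages rounded half-up to one decimal.
#'
#' @param clin Clinical `data.frame`.
#' @param variables Columns to summarize.
#' @return Named list of `data.frame`s (`category`, `count`, `percent`).
#' @export
summarize_cohort <- function(clin, variables) {
  miss <- setdiff(variables, colnames(clin))
  if (length(miss) > 0L) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  out <- lapply(variables, function(v) {
    x <- clin[[v]]
    x <- x[!is.na(x) & x != ""]
    tab <- table(if (is.factor(x)) droplevels(x) else factor(x, levels = sort(unique(x))))
    data.frame(
      category = names(tab),
      count = as.integer(tab),
      percent = round_half_up(100 * as.integer(tab) / length(x), 1L),
      stringsAsFactors = FALSE
    )
  })
  names(out) <- variables
  out
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare per-sample features between risk groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test per feature (e.g. immune
#' cell fractions from an external deconvolution) between high- and low-risk
#' samples; direction from the median difference; significance stars at
#' p < .05 / .01 / .001. Constant features get p = 1 and direction `"n.s."`.
#'
#' @param features Features-x-samples numeric matrix, columns aligned to
#'   `profile` rows.
#' @param profile Grouped risk profile from [assign_groups()].
#' @return `data.frame` with `feature`, `statistic`, `p`, `direction`,
#'   `stars`.
#' @export
compare_feature_by_group <- function(features, profile) {
  if (is.null(profile$group)) stop("profile has no groups; call assign_groups() first")
  if (ncol(features) != nrow(profile)) stop("features and profile are not sample-aligned")
  hi <- profile$group == "high"
  if (!any(hi) || all(hi)) stop("both risk groups must be non-empty")
  rows <- lapply(seq_len(nrow(features)), function(i) {
    x <- features[i, ]
    if (length(unique(x)) == 1L) {
      return(data.frame(feature = rownames(features)[i], statistic = NA_real_,
                        p = 1, direction = "n.s.", stars = "",
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x[hi], x[!hi]))
    dmed <- stats::median(x[hi]) - stats::median(x[!hi])
    dir <- if (wt$p.value >= 0.05 || dmed == 0) {
      "n.s."
    } else if (dmed > 0) "higher in high-risk" else "lower in high-risk"
    data.frame(feature = rownames(features)[i], statistic = unname(wt$statistic),
               p = wt$p.value, direction = dir, stars = p_stars(wt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
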