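#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the curve at the
#' distinct event times only; censored times reduce the risk set without
#' introducing steps.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = death observed).
#' @return `list(time, survival, n_risk, n_event)` with `time` the increasing
#'   distinct event times and `survival` the non-increasing product-limit
#'   estimate just after each.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("no observations")
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  list(
    time = fit$time[keep],
    survival = fit$surv[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep]
  )
}

# Log-rank O-E and hypergeometric variance for many two-group splits at once.
# z: 0/1 group matrix (splits x samples); returns per-split chisq and p.
# Ties are handled the standard way: observed-minus-expected deaths and the
# variance term are accumulated per distinct event time.
logrank_stats <- function(z, time, event) {
  stopifnot(ncol(z) == length(time), length(time) == length(event))
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) {
    return(data.frame(chisq = rep(0, nrow(z)), p = rep(1, nrow(z))))
  }
  at_risk <- outer(time, ut, ">=") + 0              # samples x times
  death <- outer(time, ut, "==") * event            # samples x times
  n_k <- colSums(at_risk)
  d_k <- colSums(death)
  n1 <- z %*% at_risk                               # splits x times
  d1 <- z %*% death
  exp1 <- sweep(n1, 2L, d_k / n_k, "*")
  vmul <- ifelse(n_k > 1, d_k * (n_k - d_k) / (n_k - 1), 0)
  p1 <- sweep(n1, 2L, n_k, "/")
  v <- (p1 * (1 - p1)) %*% diag(vmul, length(ut))
  ome <- rowSums(d1 - exp1)
  vv <- rowSums(v)
  chisq <- ifelse(vv > 0, ome^2 / vv, 0)
  data.frame(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test: the chi-square statistic is
#' `(sum(O1 - E1))^2 / sum(V)` over distinct event times with the
#' hypergeometric variance, referred to a chi-square distribution with 1
#' degree of freedom. With zero events in both groups the statistic is 0 and
#' p = 1.
#'
#' @param time0,event0 Follow-up and event indicator for group 0.
#' @param time1,event1 Follow-up and event indicator for group 1.
#' @return `list(chisq, p)`.
#' @export
logrank_test <- function(time0, event0, time1, event1) {
  if (length(time0) == 0L || length(time1) == 0L) stop("both groups must be non-empty")
  time <- c(time0, time1)
  event <- c(event0, event1)
  z <- matrix(rep(c(0L, 1L), c(length(time0), length(time1))), nrow = 1L)
  res <- logrank_stats(z, time, event)
  list(chisq = res$chisq[1L], p = res$p[1L])
}

#' Screen pair indicators by per-pair log-rank tests
#'
#' Each pair splits the cohort into its indicator-0 and indicator-1 samples;
#' a two-group log-rank test is applied per pair and pairs with
#' `p < alpha` (strictly) and both groups of at least `min_group_size`
#' samples are selected. No multiple-testing correction is applied: the
#' screen operates on raw p-values at a stringent default `alpha = 1e-4`.
#'
#' @param im Pairs-x-samples 0/1 indicator matrix, columns aligned to `clin`.
#' @param clin Clinical `data.frame` with `time` and `event`, one row per
#'   column of `im` in the same order.
#' @param alpha Selection threshold on the raw p-value (default `1e-4`).
#' @param min_group_size Minimum samples required in each indicator group for
#'   a pair to be selectable (default 2; a singleton group makes the test
#'   numerically fragile).
#' @return `data.frame` with `pair`, `chisq`, `p`, `n0`, `n1`, `selected`.
#' @export
screen_pairs <- function(im, clin, alpha = 1e-4, min_group_size = 2L) {
  stopifnot(alpha > 0, alpha <= 1)
  if (ncol(im) != nrow(clin)) stop("indicator matrix and clinical table are not sample-aligned")
  if (nrow(im) == 0L) {
    return(data.frame(pair = character(0), chisq = numeric(0), p = numeric(0),
                      n0 = integer(0), n1 = integer(0), selected = logical(0)))
  }
  res <- logrank_stats(im, clin$time, clin$event)
  n1 <- as.integer(rowSums(im))
  n0 <- ncol(im) - n1
  data.frame(
    pair = rownames(im),
    chisq = res$chisq,
    p = res$p,
    n0 = n0,
    n1 = n1,
    selected = res$p < alpha & n0 >= min_group_size & n1 >= min_group_size,
    stringsAsFactors = FALSE
  )
}
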