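test_that("time-dependent ROC handles separation, null scores, and error contracts", {
  # perfect separation, no censoring: AUC 1 and the cutoff splits the clusters
  clin <- make_clin(time = c(0.2, 0.4, 0.6, 2, 3, 4), event = c(1, 1, 1, 1, 0, 1))
  scores <- data.frame(sample_id = clin$sample_id, score = c(5, 6, 7, 1, 2, 3))
  roc <- timedep_roc(scores, clin, horizon = 1)
  expect_equal(roc$auc, 1)
  cut <- optimal_cutoff(roc)
  expect_true(cut >= 3 && cut < 5)

  # scores independent of outcome: AUC near 1/2
  set.seed(13)
  n <- 500
  clin2 <- make_clin(rexp(n, 0.7), rep(1L, n))
  roc2 <- timedep_roc(rnorm(n), clin2, horizon = 1)
  expect_lt(abs(roc2$auc - 0.5), 0.06)

  # without any events by the horizon, or anyone beyond it, no ROC exists
  expect_error(timedep_roc(1:3, make_clin(c(2, 3, 4), c(1, 1, 1)), horizon = 1), "no cases")
  expect_error(timedep_roc(1:3, make_clin(c(0.1, 0.2, 0.3), c(1, 1, 1)), horizon = 1),
               "no controls")
})

test_that("IPCW AUC equals the exhaustive weighted pairwise oracle", {
  # 12-subject censored fixture
  time <- c(0.2, 0.5, 0.7, 0.8, 0.9, 1.2, 1.5, 2.0, 2.5, 3.0, 0.4, 0.6)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 0, 0, 1)
  score <- c(2.5, 1.8, 0.3, 2.2, 0.9, 1.1, 0.4, 0.2, 0.6, 0.1, 1.4, 1.9)
  clin <- make_clin(time, event)
  roc <- timedep_roc(score, clin, horizon = 1)
  expect_equal(roc$auc, bf_ipcw_auc(score, time, event, horizon = 1), tolerance = 1e-12)

  # and on random censored fixtures, including tied scores
  for (r in 1:20) {
    fx <- rand_fixture(20, seed = 400 + r, cens = 0.35)
    fx$score <- round(fx$score, 1)  # force some score ties
    h <- stats::median(fx$time)
    ok <- any(fx$time <= h & fx$event == 1) && any(fx$time > h)
    if (!ok) next
    roc_r <- timedep_roc(fx$score, make_clin(fx$time, fx$event), horizon = h)
    expect_equal(roc_r$auc, bf_ipcw_auc(fx$score, fx$time, fx$event, h), tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  fx <- rand_fixture(40, seed = 9, cens = 0.3)
  clin <- make_clin(fx$time, fx$event)
  h <- stats::median(fx$time)
  a1 <- timedep_roc(fx$score, clin, horizon = h)$auc
  a2 <- timedep_roc(exp(2 * fx$score) + 5, clin, horizon = h)$auc
  expect_equal(a1, a2)
})

test_that("Youden cutoff matches the brute-force scan and handles degeneracy", {
  for (r in 1:20) {
    fx <- rand_fixture(22, seed = 500 + r, cens = 0.3)
    h <- stats::median(fx$time)
    if (!(any(fx$time <= h & fx$event == 1) && any(fx$time > h))) next
    roc <- timedep_roc(fx$score, make_clin(fx$time, fx$event), horizon = h)
    expect_equal(optimal_cutoff(roc), bf_youden_cutoff(fx$score, fx$time, fx$event, h))
  }

  # all scores equal: Youden 0 everywhere, return that single value
  clin <- make_clin(c(0.5, 0.6, 2, 3), c(1, 1, 0, 1))
  roc <- timedep_roc(rep(1.3, 4), clin, horizon = 1)
  expect_equal(optimal_cutoff(roc), 1.3)
})

test_that("group assignment is strict at the cutoff and partitions samples", {
  sc <- data.frame(sample_id = c("a", "b", "c"), score = c(1.20, 1.057, 0.50))
  pr <- assign_groups(sc, cutoff = 1.057)
  expect_equal(pr$group, c("high", "low", "low"))
  expect_equal(sum(pr$group == "high") + sum(pr$group == "low"), nrow(sc))
  expect_equal(attr(pr, "cutoff"), 1.057)
})

test_that("risk-group survival comparison is symmetric and guards empty groups", {
  set.seed(19)
  n <- 80
  grp <- rep(c("high", "low"), each = n / 2)
  time <- rexp(n, ifelse(grp == "high", 1.2, 0.4))
  clin <- make_clin(time, rbinom(n, 1, 0.8))
  pr <- data.frame(sample_id = clin$sample_id, score = rnorm(n), group = grp)
  cmp <- compare_survival(pr, clin)
  pr_sw <- pr
  pr_sw$group <- ifelse(grp == "high", "low", "high")
  cmp_sw <- compare_survival(pr_sw, clin)
  expect_equal(cmp$p, cmp_sw$p)
  expect_equal(cmp$chisq, cmp_sw$chisq)
  expect_equal(cmp$n_high, cmp_sw$n_low)

  pr_all <- pr
  pr_all$group <- "high"
  expect_error(compare_survival(pr_all, clin), "non-empty")
})

test_that("Cox fits recover effects, negate cleanly, and distinguish tie methods", {
  set.seed(23)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.3 * exp(1.0 * x))
  cens <- rexp(n, 0.1)
  clin <- make_clin(pmin(time, cens), as.integer(time <= cens))
  cov <- data.frame(x = x)

  fit <- cox_fit(cov, clin, mode = "univariate")
  expect_lt(abs(fit$coef - 1.0), 0.2)
  expect_equal(fit$hr, exp(fit$coef))
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  fit_neg <- cox_fit(data.frame(x = -x), clin, mode = "univariate")
  expect_equal(fit_neg$coef, -fit$coef, tolerance = 1e-8)
  expect_equal(fit_neg$hr, 1 / fit$hr, tolerance = 1e-8)

  # multivariate mode fits jointly
  cov2 <- data.frame(x = x, z = rnorm(n))
  fitm <- cox_fit(cov2, clin, mode = "multivariate")
  expect_equal(nrow(fitm), 2)
  expect_equal(fitm$mode, rep("multivariate", 2))

  # Efron and Breslow differ once event times are tied
  clin_tied <- make_clin(ceiling(clin$time * 2) / 2, clin$event)
  fe <- cox_fit(cov, clin_tied, mode = "univariate", ties = "efron")
  fb <- cox_fit(cov, clin_tied, mode = "univariate", ties = "breslow")
  expect_false(isTRUE(all.equal(fe$coef, fb$coef)))
  fe_ref <- survival::coxph(survival::Surv(clin_tied$time, clin_tied$event) ~ x,
                            ties = "efron")
  expect_equal(fe$coef, unname(coef(fe_ref)))
})

test_that("covariate encoding follows the ordinal conventions", {
  clin <- data.frame(
    age = c(61L, 70L),
    gender = c("Male", "female"),
    grade = c("Grade 3", "G1"),
    stage = c("Stage IV", "Stage I")
  )
  enc <- encode_covariates(clin)
  expect_equal(enc$age, c(61, 70))
  expect_equal(enc$gender, c(1, 0))
  expect_equal(enc$grade, c(3, 1))
  expect_equal(enc$stage, c(4, 1))
  expect_error(encode_covariates(clin, "nope"), "unknown covariate")
})

test_that("cohort summaries count, percentage and round half-up per category", {
  clin <- data.frame(status = rep(c("Alive", "Dead"), c(3, 5)),
                     site = rep("pancreas", 8))
  sm <- summarize_cohort(clin, c("status", "site"))
  expect_equal(sm$status$count, c(3L, 5L))
  expect_equal(sm$status$percent, c(37.5, 62.5))
  expect_equal(sum(sm$status$percent), 100)
  expect_equal(sm$site$percent, 100.0)  # single-category variable
  expect_error(summarize_cohort(clin, "missing_var"), "unknown variable")
})

test_that("feature comparison between risk groups reports direction and stars", {
  set.seed(29)
  n <- 160
  grp <- rep(c("high", "low"), each = n / 2)
  pr <- data.frame(sample_id = sprintf("S%03d", 1:n), score = rnorm(n), group = grp)
  feats <- rbind(
    shifted = rnorm(n, mean = ifelse(grp == "high", 1, 0)),
    flat = rnorm(n),
    constant = rep(0.25, n)
  )
  colnames(feats) <- pr$sample_id
  res <- compare_feature_by_group(feats, pr)
  expect_equal(res$direction[res$feature == "shifted"], "higher in high-risk")
  expect_lt(res$p[res$feature == "shifted"], 0.001)
  expect_equal(res$stars[res$feature == "shifted"], "***")
  expect_equal(res$p[res$feature == "constant"], 1)
  expect_equal(res$direction[res$feature == "constant"], "n.s.")

  # star thresholds: a p-value in (.01, .05) earns one star
  expect_equal(irgpair:::p_stars(0.036), "*")
  expect_equal(irgpair:::p_stars(0.0099), "**")
  expect_equal(irgpair:::p_stars(0.05), "")
})
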