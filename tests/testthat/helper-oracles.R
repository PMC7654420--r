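# Brute-force reference implementations, written as plain loops so they stay
# independent of the package's vectorized code paths.

# Product-limit survival estimate at the distinct event times.
bf_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_k <- sum(time >= ut[k])
    d_k <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d_k / n_k)
    surv[k] <- s
  }
  list(time = ut, survival = surv)
}

# Two-group log-rank chi-square from per-time hypergeometric moments.
bf_logrank <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Constancy filter by direct per-row frequency count.
bf_filter_keep <- function(im, threshold) {
  keep <- logical(nrow(im))
  for (i in seq_len(nrow(im))) {
    f1 <- sum(im[i, ] == 1) / ncol(im)
    f0 <- sum(im[i, ] == 0) / ncol(im)
    keep[i] <- max(f0, f1) <= threshold
  }
  keep
}

# Censoring-distribution KM evaluated at t (or its left limit).
bf_censor_surv <- function(time, event, t, left = FALSE) {
  cens_times <- sort(unique(time[event == 0]))
  s <- 1
  for (ct in cens_times) {
    if ((left && ct < t) || (!left && ct <= t)) {
      n_k <- sum(time >= ct)
      d_k <- sum(time == ct & event == 0)
      s <- s * (1 - d_k / n_k)
    }
  }
  s
}

bf_ipcw_weights <- function(score, time, event, horizon) {
  is_case <- which(time <= horizon & event == 1)
  is_ctrl <- which(time > horizon)
  w_case <- vapply(is_case, function(i) {
    1 / bf_censor_surv(time, event, time[i], left = TRUE)
  }, numeric(1))
  w_ctrl <- rep(1 / bf_censor_surv(time, event, horizon), length(is_ctrl))
  list(case = is_case, ctrl = is_ctrl, w_case = w_case, w_ctrl = w_ctrl)
}

# IPCW AUC as an exhaustive weighted Mann-Whitney sum (ties credit 1/2).
bf_ipcw_auc <- function(score, time, event, horizon) {
  w <- bf_ipcw_weights(score, time, event, horizon)
  num <- 0
  den <- 0
  for (a in seq_along(w$case)) {
    for (b in seq_along(w$ctrl)) {
      si <- score[w$case[a]]
      sj <- score[w$ctrl[b]]
      ww <- w$w_case[a] * w$w_ctrl[b]
      num <- num + ww * (as.numeric(si > sj) + 0.5 * as.numeric(si == sj))
      den <- den + ww
    }
  }
  num / den
}

# Youden-optimal cutoff by exhaustive scan over the observed score values.
bf_youden_cutoff <- function(score, time, event, horizon) {
  w <- bf_ipcw_weights(score, time, event, horizon)
  thr <- sort(unique(score))
  best <- -Inf
  best_thr <- thr[1]
  for (c in thr) {
    sens <- sum(w$w_case[score[w$case] > c]) / sum(w$w_case)
    spec <- sum(w$w_ctrl[score[w$ctrl] <= c]) / sum(w$w_ctrl)
    y <- sens + spec - 1
    if (y > best + 1e-12) {
      best <- y
      best_thr <- c
    }
  }
  best_thr
}

# Small random censored-survival fixture.
rand_fixture <- function(n, seed, cens = 0.3, tie_prob = 0) {
  set.seed(seed)
  time <- stats::rexp(n, 0.5)
  if (tie_prob > 0) time <- round(time * 4) / 4 + 0.01
  event <- stats::rbinom(n, 1, 1 - cens)
  score <- stats::rnorm(n)
  data.frame(time = time, event = event, score = score)
}

make_clin <- function(time, event) {
  data.frame(sample_id = sprintf("S%03d", seq_along(time)), time = time, event = event,
             stringsAsFactors = FALSE)
}

# Random strictly increasing transforms, one per call.
rand_monotone <- function(seed) {
  set.seed(seed)
  a <- stats::runif(1, 0.2, 3)
  b <- stats::runif(1, -5, 5)
  p <- stats::runif(1, 0.3, 3)
  choice <- sample(3, 1)
  switch(choice,
    function(x) b + a * exp(0.3 * x),
    function(x) b + a * sign(x) * abs(x)^p,
    function(x) b + a * rank(x, ties.method = "average")
  )
}
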