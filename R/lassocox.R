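# Evaluate an expression with a temporary RNG state so that seeded internals
# never clobber the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

drop_constant_features <- function(x) {
  const <- apply(x, 1L, function(r) length(unique(r)) == 1L)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(utils::head(rownames(x)[const], 5L), collapse = ", "))
    x <- x[!const, , drop = FALSE]
  }
  x
}

#' Cross-validated lasso-penalized Cox regression on pair indicators
#'
#' Maximizes the L1-penalized Cox partial likelihood along a decreasing
#' lambda path (via glmnet) with k-fold cross-validated partial-likelihood
#' deviance. Binary indicator features are deliberately NOT standardized:
#' standardizing 0/1 columns would rescale the penalty toward balanced pairs.
#'
#' @param x Features-x-samples matrix (e.g. screened pair indicators).
#' @param clin Sample-aligned clinical `data.frame` with `time`, `event`.
#' @param nfolds CV folds (default 10).
#' @param nlambda Path length (default 100).
#' @param lambda Optional fixed lambda sequence (used by [stability_select()]
#'   to keep supports comparable across repeats).
#' @param lambda_rule `"min"` (CV-deviance minimizer, default) or `"1se"`.
#' @param seed Seed for the fold assignment (ignored when `foldid` given).
#' @param foldid Optional explicit fold assignment per sample.
#' @return `list(cv, lambda, lambda_rule, coef, support)` where `coef` is the
#'   named coefficient vector at the chosen lambda and `support` the names of
#'   its non-zero entries.
#' @export
fit_lasso_cox <- function(x, clin, nfolds = 10L, nlambda = 100L, lambda = NULL,
                          lambda_rule = c("min", "1se"), seed = 1L, foldid = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (ncol(x) != nrow(clin)) stop("features and clinical table are not sample-aligned")
  if (sum(clin$event) == 0L) stop("no events in the cohort; cannot fit a Cox model")
  x <- drop_constant_features(x)
  if (nrow(x) < 2L) stop("need at least 2 (non-constant) features")
  xt <- t(x)
  y <- survival::Surv(clin$time, clin$event)
  if (is.null(foldid)) {
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = ncol(x))))
  }
  cv <- glmnet::cv.glmnet(xt, y, family = "cox", standardize = FALSE,
                          nlambda = nlambda, lambda = lambda, foldid = foldid)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.vector(stats::coef(cv, s = lam))
  names(beta) <- rownames(x)
  list(cv = cv, lambda = lam, lambda_rule = lambda_rule,
       coef = beta[beta != 0], support = names(beta)[beta != 0])
}

#' Stability-selected lasso-Cox signature
#'
#' Repeats k-fold cross-validated lasso-Cox `repeats` times with freshly
#' shuffled fold assignments (fold seeds derived deterministically from
#' `seed`), records the non-zero support at the chosen lambda of each repeat,
#' and takes the modal (most frequent) support as the final signature.
#' Coefficients are the penalized estimates from the full-path fit at the
#' largest lambda whose support equals the modal set (shrunken coefficients,
#' not an unpenalized refit); frequency ties break toward the sparser
#' support.
#'
#' @inheritParams fit_lasso_cox
#' @param repeats Number of cross-validation repetitions (default 1000).
#' @return A signature `data.frame` with columns `gene_a`, `gene_b`,
#'   `coefficient` (class `irgp_signature`), carrying a `provenance`
#'   attribute (chosen lambda, seed, repeats, folds, modal-support
#'   frequency).
#' @export
stability_select <- function(x, clin, repeats = 1000L, nfolds = 10L,
                             nlambda = 100L, lambda_rule = c("min", "1se"),
                             seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(repeats >= 1L, nfolds >= 2L)
  x <- drop_constant_features(x)
  if (nrow(x) < 2L) stop("need at least 2 (non-constant) features")
  xt <- t(x)
  y <- survival::Surv(clin$time, clin$event)
  full <- glmnet::glmnet(xt, y, family = "cox", standardize = FALSE, nlambda = nlambda)
  lam_path <- full$lambda

  supports <- character(repeats)
  for (r in seq_len(repeats)) {
    fit <- fit_lasso_cox(x, clin, nfolds = nfolds, lambda = lam_path,
                         lambda_rule = lambda_rule, seed = seed + r)
    supports[r] <- paste(sort(fit$support), collapse = ";")
  }
  tab <- table(supports)
  top <- tab[tab == max(tab)]
  cand <- names(top)
  # frequency tie -> sparser support, then lexicographic for determinism
  sizes <- vapply(strsplit(cand, ";", fixed = TRUE),
                  function(s) length(s[nzchar(s)]), integer(1L))
  modal_key <- sort(cand[sizes == min(sizes)])[1L]
  modal <- strsplit(modal_key, ";", fixed = TRUE)[[1L]]
  modal <- modal[nzchar(modal)]
  if (length(modal) == 0L) {
    stop("modal support across repeats is empty; consider lambda_rule = 'min' ",
         "or a less stringent screen")
  }

  beta_path <- as.matrix(full$beta)
  matches <- vapply(seq_len(ncol(beta_path)), function(k) {
    setequal(rownames(beta_path)[beta_path[, k] != 0], modal)
  }, logical(1L))
  if (any(matches)) {
    k <- which(matches)[1L]           # lambda decreasing: first match = largest
    lam_sel <- lam_path[k]
    beta <- beta_path[modal, k]
  } else {
    # modal support (a CV consensus) need not sit on the full-path support
    # sequence exactly; refit the path on the modal features and take the
    # largest lambda at which all of them are active
    sub <- glmnet::glmnet(xt[, modal, drop = FALSE], y, family = "cox",
                          standardize = FALSE, nlambda = nlambda)
    bp <- as.matrix(sub$beta)
    allin <- which(colSums(bp != 0) == length(modal))
    k <- if (length(allin) > 0L) allin[1L] else ncol(bp)
    lam_sel <- sub$lambda[k]
    beta <- bp[modal, k]
  }

  sig <- cbind(split_pair_ids(modal),
               coefficient = unname(beta))
  sig <- sig[sig$coefficient != 0, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "provenance") <- list(
    lambda = lam_sel, lambda_rule = lambda_rule, seed = seed,
    repeats = repeats, nfolds = nfolds,
    support_frequency = as.integer(max(tab)) / repeats
  )
  class(sig) <- c("irgp_signature", "data.frame")
  sig
}

#' Score samples with a gene-pair signature
#'
#' The risk score of a sample is the sum of the signature coefficients over
#' the pairs whose first gene is expressed strictly above the second in that
#' sample. Because only within-sample orderings enter, the score needs no
#' normalization of `m` and is identical under any strictly increasing
#' per-sample transform — the basis for cross-platform validation.
#'
#' @param sig Signature with `gene_a`, `gene_b`, `coefficient` columns.
#' @param m Genes-x-samples expression matrix containing every signature
#'   gene (missing genes are an error naming the gene).
#' @return `data.frame` with `sample_id` and `score`.
#' @export
risk_score <- function(sig, m) {
  stopifnot(all(c("gene_a", "gene_b", "coefficient") %in% colnames(sig)))
  im <- compute_indicators(m, sig)
  data.frame(
    sample_id = colnames(m),
    score = as.vector(crossprod(im, sig$coefficient)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a signature as TSV plus a JSON provenance sidecar
#'
#' The TSV mirrors the published layout (`gene_a`, `gene_b`, `coefficient`);
#' fit provenance (lambda, seed, repeats, folds) goes to `<path>.json` when
#' present. Round-trips losslessly: scores from a re-read signature are
#' identical.
#'
#' @param sig Signature `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  out <- sig[, c("gene_a", "gene_b", "coefficient")]
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  out$coefficient <- sprintf("%.17g", out$coefficient)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(sig, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  sig <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = c("character", "character", "numeric"))
  stopifnot(identical(colnames(sig), c("gene_a", "gene_b", "coefficient")))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(sig, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  class(sig) <- c("irgp_signature", "data.frame")
  sig
}
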