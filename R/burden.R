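## Protein-domain mutation-burden risk model: burden aggregation and
## L1-penalized logistic case/control prediction under repeated
## 7:3 bootstrap splits.

#' Aggregate somatic mutations into protein-domain burdens
#'
#' `burden[s, d]` is the number of the sample's somatic mutations annotated
#' to domain `d`. Variants without a domain annotation are ignored;
#' multi-domain variants (comma-separated ids) count once per annotated
#' domain.
#'
#' @param variants Variant table with `sample` and `domain` columns
#'   (restrict to predicted-somatic records upstream).
#' @param vocabulary Character vector of domain ids defining the columns.
#' @param samples Optional sample ids fixing the row set/order (defaults to
#'   the samples present in `variants`).
#' @return samples x domains integer matrix.
#' @export
aggregateDomainBurden <- function(variants, vocabulary, samples = NULL) {
  if (!length(vocabulary)) stop("empty domain vocabulary", call. = FALSE)
  requireColumns(variants, c("sample", "domain"))
  if (is.null(samples)) samples <- unique(variants$sample)
  keep <- !is.na(variants$domain) & nzchar(variants$domain)
  v <- variants[keep, , drop = FALSE]
  doms <- strsplit(v$domain, ",", fixed = TRUE)
  long <- data.frame(sample = rep(v$sample, lengths(doms)),
                     domain = trimws(unlist(doms)),
                     stringsAsFactors = FALSE)
  long <- long[long$domain %in% vocabulary, , drop = FALSE]
  out <- table(factor(long$sample, levels = samples),
               factor(long$domain, levels = vocabulary))
  m <- matrix(as.integer(out), nrow = length(samples),
              dimnames = list(samples, vocabulary))
  m
}

.auc <- function(scores, isCase) {
  as.numeric(pROC::auc(pROC::roc(response = as.integer(isCase),
                                 predictor = as.numeric(scores),
                                 direction = "<", levels = c(0, 1),
                                 quiet = TRUE)))
}

#' Bootstrap AUC of the L1-penalized logistic burden model
#'
#' Repeats `runs` times: stratified random split of the samples at
#' `splitRatio` (train) versus the remainder (test); L1-penalized logistic
#' regression fit on the training split with the penalty chosen by internal
#' 5-fold cross-validation over a log-spaced grid; AUC measured on the test
#' split. Reports the per-run AUCs, their mean, and the 95% percentile
#' interval. Optional clinical covariates are appended to the feature
#' matrix (unpenalized modeling of covariates is not attempted; they enter
#' the penalized fit like any column).
#'
#' @param burden samples x domains numeric matrix.
#' @param labels case/control per sample ("case" is the positive class).
#' @param splitRatio Training fraction (default 0.7).
#' @param runs Number of bootstrap splits (default 10).
#' @param seed Integer seed.
#' @param covariates Optional data.frame of clinical covariates (numeric or
#'   factor) to append.
#' @param standardize Standardize columns inside glmnet (default TRUE).
#' @return List of class `BootstrapAucReport`: `aucs`, `meanAuc`, `ci`,
#'   `splitRatio`, `runs`, `seed`, `lambda` (selected penalty per run),
#'   `resplits` (count of degenerate splits that were redrawn).
#' @export
bootstrapAuc <- function(burden, labels, splitRatio = 0.7, runs = 10L,
                         seed = 1L, covariates = NULL, standardize = TRUE) {
  burden <- as.matrix(burden)
  y <- as.integer(as.character(labels) == "case")
  if (length(unique(y)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  runs <- assertCount(runs, "runs")
  if (runs < 2L) stop("'runs' must be >= 2", call. = FALSE)
  x <- burden
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    x <- cbind(x, cm[, colnames(cm) != "(Intercept)", drop = FALSE])
  }
  withSeed(seed, {
    aucs <- numeric(runs)
    lambdas <- numeric(runs)
    resplits <- 0L
    for (r in seq_len(runs)) {
      repeat {
        trainIdx <- stratifiedSplit(y, splitRatio)
        testIdx <- setdiff(seq_len(nrow(x)), trainIdx)
        if (length(unique(y[testIdx])) == 2L &&
            length(unique(y[trainIdx])) == 2L) break
        resplits <- resplits + 1L
      }
      cv <- glmnet::cv.glmnet(x[trainIdx, , drop = FALSE], y[trainIdx],
                              family = "binomial", alpha = 1, nfolds = 5,
                              lambda = exp(seq(log(1), log(1e-3),
                                               length.out = 30)),
                              standardize = standardize,
                              type.measure = "deviance")
      sc <- as.numeric(stats::predict(cv, x[testIdx, , drop = FALSE],
                                      s = "lambda.min", type = "link"))
      aucs[r] <- .auc(sc, y[testIdx] == 1L)
      lambdas[r] <- cv$lambda.min
    }
    structure(list(aucs = aucs, meanAuc = mean(aucs),
                   ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
                   splitRatio = splitRatio, runs = runs,
                   seed = as.integer(seed), lambda = lambdas,
                   resplits = resplits),
              class = "BootstrapAucReport")
  })
}

#' @export
print.BootstrapAucReport <- function(x, ...) {
  cat(sprintf(
    "BootstrapAucReport: %d runs at %.0f:%.0f split | mean AUC %.3f (95%% interval %.3f-%.3f)\n",
    x$runs, 10 * x$splitRatio, 10 * (1 - x$splitRatio), x$meanAuc,
    x$ci[1], x$ci[2]))
  invisible(x)
}
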