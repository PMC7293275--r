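## Somatic-vs-germline classification: truth labeling from the
## matched-normal subset, grid-searched model-family evaluation with
## five-fold cross-validation, and tumor-only classification.

#' Derive training labels from matched-normal call sets
#'
#' Tumor-only calls that overlap the sample's germline call set are labeled
#' germline; those that overlap the paired tumor-normal somatic call set are
#' labeled somatic. Calls in neither set, or in both (conflicting evidence),
#' are excluded, with exclusion counts reported as attributes.
#'
#' @param tumorOnly,pairedSomatic,germline Character vectors of variant keys
#'   (`sample:chrom:pos:ref:alt`), keyed identically.
#' @return data.frame with `key` and `label` columns; attributes
#'   `nConflicting` and `nUnlabeled` carry the exclusion counts.
#' @export
deriveTruthLabels <- function(tumorOnly, pairedSomatic, germline) {
  tumorOnly <- unique(as.character(tumorOnly))
  inGerm <- tumorOnly %in% germline
  inSom <- tumorOnly %in% pairedSomatic
  conflict <- inGerm & inSom
  keep <- xor(inGerm, inSom)
  out <- data.frame(key = tumorOnly[keep],
                    label = ifelse(inSom[keep], "somatic", "germline"),
                    stringsAsFactors = FALSE)
  attr(out, "nConflicting") <- sum(conflict)
  attr(out, "nUnlabeled") <- sum(!inGerm & !inSom)
  out
}

## ---- model-family wrappers -------------------------------------------
## Each fit function returns an object whose stored predict closure maps a
## standardized feature matrix to a somatic score in [0, 1]; predicted label
## is score >= 0.5.

.defaultGrids <- function() {
  list(
    lr = expand.grid(alpha = c(0, 1), lambda = c(1e-4, 1e-3, 1e-2)),
    svm_linear = expand.grid(cost = c(0.01, 0.1, 1)),
    rf = expand.grid(mtry = c(5, 10), ntree = 300),
    gbt = expand.grid(max_depth = c(3, 6), nrounds = 150, eta = 0.3),
    knn = expand.grid(k = c(5, 15, 31)),
    svm_rbf = expand.grid(cost = c(1, 10)),
    mlp = expand.grid(size = c(8, 16, 32), decay = 1e-4, maxit = 150)
  )
}

## e1071 decision values are signed toward the class named first in the
## "A/B" column label; map them so higher score = more somatic.
.svmWrapper <- function(x, yBin, kernel, cost) {
  fit <- e1071::svm(x, factor(yBin), kernel = kernel, cost = cost,
                    scale = FALSE)
  list(predictScore = function(newx) {
    pr <- stats::predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    posClass <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    d <- if (posClass == "1") dv[, 1] else -dv[, 1]
    stats::plogis(d)
  })
}

.fitFamily <- function(family, params, x, y, seed) {
  yBin <- as.integer(y == "somatic")
  set.seed(seed)
  switch(family,
    lr = {
      fit <- glmnet::glmnet(x, factor(yBin), family = "binomial",
                            alpha = params$alpha, lambda = params$lambda)
      list(predictScore = function(newx)
        as.numeric(stats::predict(fit, newx, type = "response",
                                  s = params$lambda)))
    },
    svm_linear = .svmWrapper(x, yBin, "linear", params$cost),
    rf = {
      fit <- randomForest::randomForest(x, factor(yBin),
                                        ntree = params$ntree,
                                        mtry = params$mtry)
      list(predictScore = function(newx)
        stats::predict(fit, newx, type = "prob")[, "1"])
    },
    gbt = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = yBin),
        nrounds = params$nrounds, verbose = 0)
      list(predictScore = function(newx)
        stats::predict(fit, xgboost::xgb.DMatrix(newx)))
    },
    knn = {
      list(predictScore = function(newx) {
        pr <- class::knn(x, newx, factor(yBin), k = params$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      })
    },
    svm_rbf = .svmWrapper(x, yBin, "radial", params$cost),
    mlp = {
      fit <- nnet::nnet(x, yBin, size = params$size, decay = params$decay,
                        maxit = params$maxit, MaxNWts = 20000,
                        entropy = TRUE, trace = FALSE)
      list(predictScore = function(newx)
        as.numeric(stats::predict(fit, newx)))
    },
    stop("unknown model family: ", family, call. = FALSE))
}

.confusion <- function(truth, predicted) {
  lev <- c("germline", "somatic")
  table(truth = factor(truth, lev), predicted = factor(predicted, lev))
}

.metricsFromConfusion <- function(cm) {
  tp <- cm["somatic", "somatic"]; fp <- cm["germline", "somatic"]
  fn <- cm["somatic", "germline"]; tn <- cm["germline", "germline"]
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(confusion = cm, precision = precision, recall = recall, f1 = f1,
       accuracy = (tp + tn) / sum(cm))
}

.standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(apply = function(newx) sweep(sweep(newx, 2, mu), 2, sdv, "/"))
}

#' Grid-searched model-family evaluation with five-fold cross-validation
#'
#' For each model family (penalized logistic regression, linear SVM, random
#' forest, gradient boosted trees, k-nearest neighbors, RBF SVM, multi-layer
#' perceptron), every grid point is scored by mean F1 over stratified
#' five-fold cross-validation on the training split (somatic is the positive
#' class); the best point per family is refit on the full training split and
#' evaluated on the held-out test split, and the family with the best
#' held-out F1 is selected. Features are standardized internally using
#' training-split statistics.
#'
#' @param features A `FeatureMatrix` (see [assembleFeatures()]) or numeric
#'   matrix.
#' @param labels Factor/character of `germline`/`somatic` labels (taken from
#'   `features$labels` when NULL).
#' @param families Model families to evaluate (default: all seven).
#' @param grids Named list of per-family parameter grids (default
#'   small fixed grids).
#' @param seed Integer seed controlling the split, the folds and every
#'   stochastic fit.
#' @param testFraction Held-out fraction for model selection (default 0.2,
#'   stratified).
#' @param nFolds Cross-validation folds (default 5).
#' @return List of class `ModelReport`: `cv` (per-family, per-grid-point
#'   fold scores), `heldout` (per-family test metrics), `bestFamily`,
#'   `bestParams`, and `model` (the selected fitted model, refit on the full
#'   training split, with its standardizer and schema).
#' @export
trainModels <- function(features, labels = NULL,
                        families = c("lr", "svm_linear", "rf", "gbt",
                                     "knn", "svm_rbf", "mlp"),
                        grids = .defaultGrids(), seed = 1L,
                        testFraction = 0.2, nFolds = 5L) {
  if (inherits(features, "FeatureMatrix")) {
    if (is.null(labels)) labels <- features$labels
    x <- features$x
  } else x <- as.matrix(features)
  if (is.null(labels)) stop("no labels supplied", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("germline", "somatic"))
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  labels <- factor(labels, levels = c("germline", "somatic"))

  withSeed(seed, {
    trainIdx <- stratifiedSplit(labels, 1 - testFraction)
    testIdx <- setdiff(seq_len(nrow(x)), trainIdx)
    std <- .standardizer(x[trainIdx, , drop = FALSE])
    xTrain <- std$apply(x[trainIdx, , drop = FALSE])
    xTest <- std$apply(x[testIdx, , drop = FALSE])
    yTrain <- labels[trainIdx]
    yTest <- labels[testIdx]
    folds <- stratifiedFolds(yTrain, nFolds)

    cvRows <- list()
    heldout <- list()
    bestPerFamily <- list()
    for (fam in families) {
      grid <- grids[[fam]]
      if (is.null(grid)) stop("no grid for family ", fam, call. = FALSE)
      meanF1 <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        foldF1 <- numeric(nFolds)
        for (f in seq_len(nFolds)) {
          inFold <- folds == f
          fit <- .fitFamily(fam, grid[g, , drop = FALSE],
                            xTrain[!inFold, , drop = FALSE],
                            yTrain[!inFold], seed = seed + 1000L * g + f)
          sc <- fit$predictScore(xTrain[inFold, , drop = FALSE])
          pred <- ifelse(sc >= 0.5, "somatic", "germline")
          foldF1[f] <- .metricsFromConfusion(
            .confusion(yTrain[inFold], pred))$f1
        }
        meanF1[g] <- mean(foldF1)
        cvRows[[length(cvRows) + 1L]] <- data.frame(
          family = fam, point = g, grid[g, , drop = FALSE],
          t(stats::setNames(foldF1, paste0("fold", seq_len(nFolds)))),
          meanF1 = meanF1[g], row.names = NULL)
      }
      best <- which.max(meanF1)
      bestPerFamily[[fam]] <- grid[best, , drop = FALSE]
      refit <- .fitFamily(fam, grid[best, , drop = FALSE], xTrain, yTrain,
                          seed = seed + 99L)
      sc <- refit$predictScore(xTest)
      pred <- ifelse(sc >= 0.5, "somatic", "germline")
      heldout[[fam]] <- c(list(params = grid[best, , drop = FALSE]),
                          .metricsFromConfusion(.confusion(yTest, pred)))
    }
    f1s <- vapply(heldout, function(h) h$f1, numeric(1))
    bestFamily <- names(which.max(f1s))
    finalFit <- .fitFamily(bestFamily, bestPerFamily[[bestFamily]],
                           xTrain, yTrain, seed = seed + 7L)
    structure(list(
      cv = do.call(rbind, lapply(cvRows, function(r) {
        r[setdiff(unlist(lapply(cvRows, names)), names(r))] <- NA
        r[unique(unlist(lapply(cvRows, names)))]
      })),
      heldout = heldout,
      bestFamily = bestFamily,
      bestParams = bestPerFamily[[bestFamily]],
      nFolds = nFolds,
      model = list(family = bestFamily, fit = finalFit,
                   standardize = std$apply, schema = colnames(x),
                   seed = seed)),
      class = "ModelReport")
  })
}

#' @export
print.ModelReport <- function(x, ...) {
  cat("ModelReport: best family =", x$bestFamily, "\n")
  f1s <- vapply(x$heldout, function(h) h$f1, numeric(1))
  for (fam in names(f1s))
    cat(sprintf("  %-10s held-out F1 = %.3f\n", fam, f1s[fam]))
  invisible(x)
}

#' Evaluate a fitted model on labeled data
#'
#' Computes the confusion matrix and precision/recall/F1/accuracy with
#' somatic as the positive class.
#'
#' @param model The `model` element of a `ModelReport` (or the report).
#' @param features `FeatureMatrix` or numeric matrix (raw scale).
#' @param labels germline/somatic labels.
#' @return List with `confusion`, `precision`, `recall`, `f1`, `accuracy`.
#' @export
evaluateModel <- function(model, features, labels) {
  pred <- classifyVariants(model, features)
  if (length(labels) != nrow(pred))
    stop("labels/features shape mismatch", call. = FALSE)
  .metricsFromConfusion(.confusion(as.character(labels), pred$label))
}

#' Classify variants with a fitted model
#'
#' @param model The `model` element of a `ModelReport` (or the report
#'   itself).
#' @param features `FeatureMatrix` or numeric matrix on the raw feature
#'   scale; columns must match the training schema.
#' @return data.frame with `key` (when available), `label`
#'   (somatic/germline) and `score` (somatic probability-like score in
#'   [0, 1], monotone in the model's decision function).
#' @export
classifyVariants <- function(model, features) {
  if (inherits(model, "ModelReport")) model <- model$model
  key <- NULL
  if (inherits(features, "FeatureMatrix")) {
    key <- features$key
    features <- features$x
  }
  features <- as.matrix(features)
  miss <- setdiff(model$schema, colnames(features))
  if (length(miss))
    stop("feature matrix is missing schema column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  features <- features[, model$schema, drop = FALSE]
  if (nrow(features) == 0L)
    return(data.frame(key = character(0), label = character(0),
                      score = numeric(0)))
  sc <- model$fit$predictScore(model$standardize(features))
  data.frame(key = if (is.null(key)) NA_character_ else key,
             label = ifelse(sc >= 0.5, "somatic", "germline"),
             score = as.numeric(sc), stringsAsFactors = FALSE)
}
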