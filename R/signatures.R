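## 96-channel mutation catalogs, NMF signature extraction with RSS-based
## rank selection, cosine matching to reference catalogs, and
## exposure-phenotype association.

#' Build a 96-channel mutation catalog from a variant table
#'
#' Bins every single-nucleotide variant into its pyrimidine-centered
#' trinucleotide channel (purine-centered records are folded to the reverse
#' complement). Non-SNV records are ignored and counted; SNVs whose context
#' middle base disagrees with the reference allele are skipped and reported.
#'
#' @param variants Variant table with `sample`, `ref`, `alt` and `context`
#'   columns.
#' @return A [MutationCatalog-class]; attributes `nNonSnv` and
#'   `nBadContext` report the skipped records.
#' @export
#' @examples
#' v <- data.frame(sample = "S1", ref = "C", alt = "T", context = "ACA")
#' catalogCounts(buildCatalog(v))[, "A[C>T]A"]
buildCatalog <- function(variants) {
  requireColumns(variants, c("sample", "ref", "alt", "context"))
  ref <- toupper(as.character(variants$ref))
  alt <- toupper(as.character(variants$alt))
  isSnv <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES & ref != alt
  channel <- trinucleotideChannel(ref, alt, variants$context)
  badContext <- isSnv & is.na(channel)
  samples <- unique(as.character(variants$sample))
  counts <- matrix(0, nrow = length(samples), ncol = 96,
                   dimnames = list(samples, sbsChannels()))
  ok <- isSnv & !is.na(channel)
  if (any(ok)) {
    tab <- table(factor(as.character(variants$sample[ok]), levels = samples),
                 factor(channel[ok], levels = sbsChannels()))
    counts[] <- as.numeric(tab)
  }
  out <- MutationCatalog(counts)
  attr(out, "nNonSnv") <- sum(!isSnv)
  attr(out, "nBadContext") <- sum(badContext)
  out
}

## Multiplicative-update NMF under Frobenius loss for a single start.
.nmfOnce <- function(V, k, maxIter, tol) {
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  lossPrev <- Inf
  loss <- sum((V - W %*% H)^2)
  iter <- 0L
  while (iter < maxIter) {
    for (j in seq_len(10L)) {
      H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      iter <- iter + 1L
      if (iter >= maxIter) break
    }
    lossPrev <- loss
    loss <- sum((V - W %*% H)^2)
    if (lossPrev - loss <= tol * max(lossPrev, eps)) break
  }
  list(W = W, H = H, rss = loss, iterations = iter)
}

## Best-of-restarts NMF; restart r uses seed + r so results are a pure
## function of the seed.
.nmfBest <- function(V, k, restarts, maxIter, tol, seed) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withSeed(seed + r, .nmfOnce(V, k, maxIter, tol))
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  best
}

#' Select the factorization rank from the RSS curve
#'
#' Fits NMF at each candidate rank and returns the first rank at which the
#' residual-sum-of-squares (RSS) curve presents its inflection,
#' operationalized as the interior candidate k maximizing the discrete
#' second difference `RSS(k-1) - 2 RSS(k) + RSS(k+1)`; ties break toward the
#' smallest rank. When the RSS curve is degenerate (all equal), the smallest
#' candidate is returned with a warning.
#'
#' @param catalog A [MutationCatalog-class] or samples x 96 matrix.
#' @param ranks At least three consecutive candidate ranks (default 2:6).
#' @param restarts NMF restarts per rank (default 5; rank selection needs
#'   the RSS trend, not a polished factorization).
#' @param maxIter,tol NMF iteration cap and relative convergence tolerance.
#' @param seed Integer seed.
#' @return The selected rank (integer); attribute `rss` holds the RSS per
#'   candidate rank.
#' @export
selectRank <- function(catalog, ranks = 2:6, restarts = 5L,
                       maxIter = 500L, tol = 1e-5, seed = 1L) {
  V <- if (is(catalog, "MutationCatalog")) catalogCounts(catalog)
       else as.matrix(catalog)
  ranks <- sort(unique(as.integer(ranks)))
  if (length(ranks) < 3L)
    stop("need at least 3 candidate ranks", call. = FALSE)
  rss <- vapply(ranks, function(k)
    .nmfBest(V, k, restarts, maxIter, tol, seed + 131L * k)$rss,
    numeric(1))
  names(rss) <- ranks
  if (diff(range(rss)) < .Machine$double.eps^0.5 * max(1, rss[1])) {
    warning("degenerate RSS curve; returning smallest candidate rank")
    k <- ranks[1]
  } else {
    inner <- seq(2L, length(ranks) - 1L)
    d2 <- rss[inner - 1L] - 2 * rss[inner] + rss[inner + 1L]
    k <- ranks[inner][which.max(d2)]  # which.max ties -> first (smallest k)
  }
  structure(as.integer(k), rss = rss)
}

#' Extract mutational signatures by NMF
#'
#' Best-of-restarts non-negative matrix factorization of the catalog under
#' Frobenius loss, with multiplicative updates. The returned `H` rows are
#' normalized to sum 1 and `W` columns rescaled so `W %*% H` is unchanged;
#' `W` entries are therefore attributed mutation counts.
#'
#' @param catalog A [MutationCatalog-class] or samples x 96 matrix.
#' @param k Factorization rank (>= 1, at most `min(samples, 96)`).
#' @param restarts Random restarts (default 30).
#' @param maxIter,tol Iteration cap (default 2000) and relative tolerance
#'   (default 1e-6).
#' @param seed Integer seed; restart r uses `seed + r`.
#' @return A [SignatureSet-class].
#' @export
extractSignatures <- function(catalog, k, restarts = 30L, maxIter = 2000L,
                              tol = 1e-6, seed = 1L) {
  V <- if (is(catalog, "MutationCatalog")) catalogCounts(catalog)
       else as.matrix(catalog)
  if (nrow(V) == 0L) stop("catalog is empty", call. = FALSE)
  k <- assertCount(k, "k", positive = TRUE)
  if (k > min(nrow(V), ncol(V)))
    stop(sprintf("k = %d exceeds min(samples, channels) = %d", k,
                 min(nrow(V), ncol(V))), call. = FALSE)
  fit <- .nmfBest(V, k, restarts, maxIter, tol, seed)
  scale <- rowSums(fit$H)
  scale[scale == 0] <- 1
  H <- fit$H / scale
  W <- sweep(fit$W, 2, scale, "*")
  rownames(H) <- paste0("Sig", seq_len(k))
  colnames(H) <- colnames(V)
  colnames(W) <- rownames(H)
  rownames(W) <- rownames(V)
  new("SignatureSet", W = W, H = H, rank = k,
      rss = c(final = fit$rss), seed = as.integer(seed))
}

#' Match extracted signatures to a reference catalog
#'
#' Computes cosine similarities between extracted and reference signatures
#' and finds the one-to-one assignment maximizing total similarity (optimal
#' bipartite matching). Extracted signatures whose assigned similarity falls
#' below `threshold` are flagged as uncatalogued.
#'
#' @param H k x 96 extracted signature matrix, a [SignatureSet-class], rows
#'   summing to 1.
#' @param reference m x 96 reference signature matrix with row names
#'   (rows normalized).
#' @param threshold Similarity below which an extracted signature is called
#'   uncatalogued (default 0.8).
#' @return data.frame with `signature`, `reference`, `cosine`,
#'   `uncatalogued`; attribute `cosines` holds the full k x m matrix.
#' @export
matchSignatures <- function(H, reference, threshold = 0.8) {
  if (is(H, "SignatureSet")) H <- signatures(H)
  H <- as.matrix(H)
  reference <- as.matrix(reference)
  if (nrow(reference) == 0L) stop("empty reference", call. = FALSE)
  if (ncol(H) != ncol(reference))
    stop("channel dimensions differ", call. = FALSE)
  k <- nrow(H); m <- nrow(reference)
  cosines <- matrix(0, k, m, dimnames = list(rownames(H),
                                             rownames(reference)))
  for (i in seq_len(k)) for (j in seq_len(m))
    cosines[i, j] <- cosineSim(H[i, ], reference[j, ])
  ## optimal assignment on the similarity matrix (pad to square cost)
  if (k <= m) {
    sol <- clue::solve_LSAP(cosines, maximum = TRUE)
    assigned <- as.integer(sol)[seq_len(k)]
  } else {
    sol <- clue::solve_LSAP(t(cosines), maximum = TRUE)
    assigned <- rep(NA_integer_, k)
    assigned[as.integer(sol)] <- seq_len(m)
  }
  sigNames <- if (!is.null(rownames(H))) rownames(H)
              else paste0("Sig", seq_len(k))
  refNames <- if (!is.null(rownames(reference))) rownames(reference)
              else paste0("Ref", seq_len(m))
  score <- ifelse(is.na(assigned), NA_real_,
                  cosines[cbind(seq_len(k), assigned)])
  out <- data.frame(
    signature = sigNames,
    reference = ifelse(is.na(assigned), NA_character_, refNames[assigned]),
    cosine = score,
    uncatalogued = is.na(score) | score < threshold,
    stringsAsFactors = FALSE)
  attr(out, "cosines") <- cosines
  out
}

#' Read a tab-separated 96-row reference signature table
#'
#' Expects a text table with a channel column (labels like `A[C>A]A`) and
#' one numeric column per signature; rows are reordered to the canonical
#' channel order and columns normalized to sum 1.
#'
#' @param path File path.
#' @return m x 96 matrix (signatures in rows).
#' @export
readReferenceSignatures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  chCol <- which(vapply(df, function(col)
    all(sbsChannels() %in% as.character(col)), logical(1)))[1]
  if (is.na(chCol))
    stop("no column containing the 96 channel labels", call. = FALSE)
  rownames(df) <- as.character(df[[chCol]])
  df <- df[sbsChannels(), -chCol, drop = FALSE]
  H <- t(as.matrix(df))
  H / rowSums(H)
}

#' Associate a signature exposure with a binary outcome
#'
#' Logistic regression of the outcome on the standardized exposure, with or
#' without covariate adjustment. Reports the Wald effect estimate (log-odds
#' per exposure standard deviation), its 95% confidence interval, and the
#' two-sided p-value. Perfect separation is detected and reported, with a
#' ridge-penalized fallback estimate.
#'
#' @param exposure Numeric exposure vector (one signature's column of W;
#'   attributed counts or proportions — it is standardized internally).
#' @param outcome Binary outcome (logical, 0/1, or two-level factor).
#' @param covariates Optional data.frame of covariates (e.g. age,
#'   menopausal status, histology class).
#' @return List with `estimate`, `ci` (length 2), `p`, `n`, `separation`
#'   (logical) and `model` (the glm fit, or NULL on fallback).
#' @export
associateExposure <- function(exposure, outcome, covariates = NULL) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L
       else as.integer(as.logical(outcome))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome must contain both classes", call. = FALSE)
  if (stats::sd(exposure) == 0 || !is.finite(stats::sd(exposure)))
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_, n = length(y), separation = FALSE,
                inestimable = TRUE, model = NULL))
  df <- data.frame(y = y, exposure = as.numeric(scale(exposure)))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  est <- sm["exposure", "Estimate"]
  se <- sm["exposure", "Std. Error"]
  separated <- !fit$converged || abs(est) > 15 || se > 100
  if (separated) {
    x <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
    x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
    if (ncol(x) < 2L) x <- cbind(x, .zero = 0)
    pen <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 0.01)
    est <- stats::coef(pen)["exposure", 1]
    return(list(estimate = unname(est), ci = c(NA_real_, NA_real_),
                p = NA_real_, n = length(y), separation = TRUE,
                inestimable = FALSE, model = NULL))
  }
  list(estimate = unname(est),
       ci = unname(est + c(-1, 1) * stats::qnorm(0.975) * se),
       p = unname(sm["exposure", "Pr(>|z|)"]),
       n = length(y), separation = FALSE, inestimable = FALSE,
       model = fit)
}

#' Compare signature exposures between two groups
#'
#' Two-sided Welch two-sample t-test of the exposures by group, with
#' per-group means and 95% confidence intervals.
#'
#' @param exposure Numeric exposure vector.
#' @param group Binary grouping (logical or two-level factor).
#' @return List with `p`, `means` (named), `ci` (2 x 2 matrix, one row per
#'   group), `nPerGroup`, and `test` (the htest object).
#' @export
exposureGroupTest <- function(exposure, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stop("'group' must have exactly two levels", call. = FALSE)
  g <- droplevels(g)
  ns <- table(g)
  if (any(ns < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  tt <- stats::t.test(exposure ~ g)
  means <- tapply(exposure, g, mean)
  ci <- t(vapply(levels(g), function(lev) {
    x <- exposure[g == lev]
    se <- stats::sd(x) / sqrt(length(x))
    mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) * se
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")
  list(p = tt$p.value, means = means, ci = ci,
       nPerGroup = as.vector(ns), test = tt)
}
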