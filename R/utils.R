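## Internal utilities shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the Mersenne-Twister seed, evaluates `expr`, and restores the caller's
#' RNG state afterwards, so that seeded operations never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

## Canonical variant key: unique within a sample-aware table.
variantKey <- function(sample, chrom, pos, ref, alt) {
  paste(sample, chrom, pos, ref, alt, sep = ":")
}

## Site key: ignores sample, used for PON matching and cohort recurrence.
siteKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## Dirichlet sampler via gamma normalization.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = k)
  sw <- rowSums(x)
  sw[sw == 0] <- 1
  x / sw
}

## Cosine similarity between two nonnegative vectors.
cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## Stratified fold assignment: returns integer fold id per observation.
stratifiedFolds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

## Stratified train indices for a given train fraction.
stratifiedSplit <- function(y, fraction) {
  y <- as.factor(y)
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    nTrain <- max(1L, round(fraction * length(idx)))
    train <- c(train, sample(idx, nTrain))
  }
  sort(train)
}

assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assertCount <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (positive) 1 else 0)
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  invisible(as.integer(x))
}

requireColumns <- function(df, cols, what = "variant table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
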