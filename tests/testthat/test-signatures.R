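test_that("catalog building bins and folds single variants correctly", {
  v <- data.frame(sample = "S1", ref = "C", alt = "T", context = "ACA")
  m <- catalogCounts(buildCatalog(v))
  expect_equal(unname(m[1, "A[C>T]A"]), 1)
  expect_equal(sum(m), 1)
  ## purine presentation folds to the reverse complement channel
  g <- data.frame(sample = "S1", ref = "G", alt = "A", context = "TGA")
  expect_equal(unname(catalogCounts(buildCatalog(g))[1, "T[C>T]A"]), 1)
  ## empty input
  e <- buildCatalog(v[0, ])
  expect_identical(nrow(catalogCounts(e)), 0L)
})

test_that("catalog counts match a brute-force fold table on random variants", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- 500
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  cx <- paste0(sample(bases, n, TRUE), ref, sample(bases, n, TRUE))
  v <- data.frame(sample = sample(c("A1", "A2"), n, TRUE),
                  ref = ref, alt = alt, context = cx)
  got <- catalogCounts(buildCatalog(v))
  ## oracle: fold by hand, tabulate
  oracle <- matrix(0, 2, 96, dimnames = list(c("A1", "A2"), sbsChannels()))
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; c3 <- strsplit(cx[i], "")[[1]]
    if (r %in% c("A", "G")) {
      r <- unname(comp[ref[i]]); a <- unname(comp[alt[i]])
      c3 <- rev(unname(comp[c3]))
    }
    chan <- paste0(c3[1], "[", r, ">", a, "]", c3[3])
    oracle[v$sample[i], chan] <- oracle[v$sample[i], chan] + 1
  }
  expect_equal(got[rownames(oracle), ], oracle)
  ## folding conservation: row sums = number of SNVs with valid context
  expect_equal(unname(rowSums(got)), unname(table(v$sample)[rownames(got)]),
               ignore_attr = TRUE)
})

test_that("records with inconsistent context are skipped and reported", {
  v <- data.frame(sample = "S1", ref = c("C", "C", "A"),
                  alt = c("T", "T", "AT"),
                  context = c("ACA", "AGA", NA))
  cat96 <- buildCatalog(v)
  expect_equal(sum(catalogCounts(cat96)), 1)
  expect_identical(attr(cat96, "nBadContext"), 1L)
  expect_identical(attr(cat96, "nNonSnv"), 1L)
})

test_that("rank selection recovers a noise-free planted rank", {
  set.seed(29)
  H0 <- defaultSignatures()
  W0 <- matrix(rgamma(204 * 3, 2, 0.05), 204, 3)
  V <- round(W0 %*% H0 * 10)
  rownames(V) <- sprintf("S%03d", 1:204)
  k <- selectRank(MutationCatalog(V), ranks = 2:6, seed = 1)
  expect_identical(as.integer(k), 3L)
  rss <- attr(k, "rss")
  expect_length(rss, 5)
  expect_true(all(diff(rss) <= 0))
  expect_error(selectRank(MutationCatalog(V), ranks = 2:3), "3 candidate")
})

test_that("degenerate all-equal RSS falls back to the smallest rank", {
  V <- matrix(0, 6, 96, dimnames = list(sprintf("S%d", 1:6), sbsChannels()))
  expect_warning(k <- selectRank(V, ranks = 2:4, restarts = 1,
                                 maxIter = 20, seed = 1),
                 "degenerate")
  expect_identical(as.integer(k), 2L)
})

test_that("extraction returns normalized signatures of the right shape", {
  sim <- simulateCatalogs(defaultSignatures(), c(2, 1.2, 0.8), 40, 120,
                          seed = 31)
  sig <- extractSignatures(sim$catalog, 3, restarts = 5, seed = 1)
  expect_identical(dim(signatures(sig)), c(3L, 96L))
  expect_identical(dim(exposures(sig)), c(40L, 3L))
  expect_equal(unname(rowSums(signatures(sig))), rep(1, 3),
               tolerance = 1e-9)
  expect_true(all(signatures(sig) >= 0) && all(exposures(sig) >= 0))
  ## reproducible given the seed
  sig2 <- extractSignatures(sim$catalog, 3, restarts = 5, seed = 1)
  expect_equal(signatures(sig), signatures(sig2))
  expect_error(extractSignatures(sim$catalog, 97), "exceeds")
})

test_that("a single-channel catalog at k = 1 yields a unit signature", {
  V <- matrix(0, 5, 96, dimnames = list(sprintf("S%d", 1:5), sbsChannels()))
  V[, 12] <- 7
  sig <- extractSignatures(V, 1, restarts = 2, maxIter = 500, seed = 2)
  expect_gt(signatures(sig)[1, 12], 0.999)
})

test_that("planted factors are recovered from a noise-free product", {
  set.seed(37)
  H0 <- defaultSignatures()
  W0 <- matrix(rgamma(60 * 3, 2, 0.05), 60, 3)
  V <- W0 %*% H0 * 5
  rownames(V) <- sprintf("S%02d", 1:60)
  ## noise-free input: run the updates to numerical convergence
  sig <- extractSignatures(V, 3, restarts = 10, maxIter = 20000,
                           tol = 1e-12, seed = 3)
  m <- matchSignatures(sig, H0)
  expect_true(all(m$cosine >= 0.99))
})

test_that("matching recovers permutations and flags novel signatures", {
  H0 <- defaultSignatures()
  m <- matchSignatures(H0, H0)
  expect_equal(m$cosine, rep(1, 3), tolerance = 1e-12)
  expect_identical(m$reference, rownames(H0))
  ## permuted reference
  perm <- c(3, 1, 2)
  mp <- matchSignatures(H0, H0[perm, ])
  expect_identical(mp$reference, rownames(H0))
  ## remove O/TN from the reference: it must fall below the 0.8 threshold
  mn <- matchSignatures(H0, H0[c("aging", "MMR"), ])
  expect_true(mn$uncatalogued[mn$signature == "OTN"])
  expect_false(any(mn$uncatalogued[mn$signature != "OTN"]))
  expect_error(matchSignatures(H0, H0[0, ]), "empty reference")
})

test_that("reference signature tables round-trip through the text format", {
  H0 <- defaultSignatures()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(Channel = colnames(H0), t(H0),
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readReferenceSignatures(path)
  expect_equal(back[rownames(H0), colnames(H0)], H0, tolerance = 1e-12)
})

test_that("exposure association estimates a planted logistic effect with coverage", {
  set.seed(41)
  covered <- 0; nSim <- 150; beta <- 1.5
  for (i in seq_len(nSim)) {
    expo <- rnorm(204)
    y <- rbinom(204, 1, plogis(-1 + beta * expo))
    res <- associateExposure(expo, y)
    ## estimate is per SD of exposure; expo already standardized here
    if (!res$separation && res$ci[1] <= beta && beta <= res$ci[2])
      covered <- covered + 1
  }
  expect_gt(covered / nSim, 0.90)  # ~95% nominal coverage
})

test_that("degenerate exposure association inputs are flagged", {
  y <- rep(c(0, 1), 20)
  res <- associateExposure(rep(2, 40), y)
  expect_true(res$inestimable)
  expect_error(associateExposure(rnorm(5), rep(1, 5)), "both classes")
  ## perfect separation reported as such with a finite fallback estimate
  expo <- c(rnorm(20, -3), rnorm(20, 3))
  sep <- associateExposure(expo, rep(c(0, 1), each = 20))
  expect_true(sep$separation)
  expect_true(is.finite(sep$estimate))
})

test_that("adjusted and unadjusted association modes agree on the sign", {
  st <- simulateExposureStudy(simConfig(seed = 43), catalog = FALSE)
  unadj <- associateExposure(st$W0[, "OTN"], st$metadata$tnbc)
  adj <- associateExposure(st$W0[, "OTN"], st$metadata$tnbc,
                           st$metadata[, c("age", "menopausal",
                                           "histology")])
  expect_gt(unadj$estimate, 0)
  expect_gt(adj$estimate, 0)
  expect_lt(adj$p, 0.05)
})

test_that("the exposure group test is symmetric and needs 2 per group", {
  set.seed(47)
  expo <- rnorm(26, 50, 10)
  grp <- rep(c("a", "b"), c(8, 18))
  r1 <- exposureGroupTest(expo, grp)
  swapped <- exposureGroupTest(expo, factor(grp, levels = c("b", "a")))
  expect_equal(r1$p, swapped$p)
  expect_identical(dim(r1$ci), c(2L, 2L))
  expect_true(all(r1$ci[, "lower"] < r1$means &
                    r1$means < r1$ci[, "upper"]))
  expect_error(exposureGroupTest(expo, rep(c("a", "b"), c(1, 25))),
               "at least 2")
})

test_that("group-test p-values are roughly uniform under the null", {
  set.seed(53)
  ps <- vapply(1:200, function(i)
    exposureGroupTest(rnorm(26), rep(c("x", "y"), 13))$p, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.07)
  expect_gt(min(ps), 0)  # sanity
})
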