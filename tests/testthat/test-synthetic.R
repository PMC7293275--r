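test_that("simulation is a pure function of config and seed", {
  a <- simulateVariantCohort(tinyConfig(seed = 42))
  b <- simulateVariantCohort(tinyConfig(seed = 42))
  expect_identical(a, b)
  c_ <- simulateVariantCohort(tinyConfig(seed = 43))
  expect_false(identical(a$variants, c_$variants))
  ## global RNG stream untouched
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(simulateVariantCohort(tinyConfig(seed = 1)))
  expect_identical(runif(3), before)
})

test_that("empty cohort gives empty tables", {
  sim <- simulateVariantCohort(simConfig(nCases = 0L, nControls = 0L))
  expect_identical(nrow(sim$variants), 0L)
  expect_identical(nrow(sim$truth$labels), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nCases = -1), "nCases")
  expect_error(simConfig(somaticVafMean = 1.5), "fraction")
  badH <- defaultSignatures(); badH[1, 1] <- badH[1, 1] + 0.1
  expect_error(simConfig(trueSignatures = badH), "sum to 1")
  expect_error(simConfig(informativeDomains = c(DOM0001 = 1, DOM0001 = 2)),
               "duplicate")
})

test_that("simulated VAF and depth match the configured generative scale", {
  ## n >= 10,000 somatic variants
  sim <- simulateVariantCohort(simConfig(nCases = 40L, nControls = 20L,
                                         seed = 9, germlineSitesPool = 150L))
  som <- sim$variants[sim$variants$label == "somatic", ]
  expect_gt(nrow(som), 10000)
  expect_lt(abs(mean(som$vaf) - 0.232), 0.02)
  expect_lt(abs(mean(sim$variants$totalDepth) - 99), 5)
  ## germline VAFs bimodal around the het/hom modes
  germ <- sim$variants[sim$variants$label == "germline", ]
  expect_gt(mean(germ$vaf > 0.35 & germ$vaf < 0.65), 0.3)
  expect_gt(mean(germ$vaf > 0.85), 0.1)
  expect_gt(mean(germ$vaf), mean(som$vaf))
  ## population frequency separates the classes
  expect_gt(mean(germ$populationAf), 10 * mean(som$populationAf))
})

test_that("simulated catalogs conserve per-sample SNV counts exactly", {
  sim <- simulateCatalogs(defaultSignatures(), c(2, 1.2, 0.8),
                          nSamples = 204, snvsPerSample = 180, seed = 3)
  counts <- catalogCounts(sim$catalog)
  expect_identical(dim(counts), c(204L, 96L))
  expect_true(all(rowSums(counts) == 180))
  expect_equal(sum(counts), 204 * 180)
  expect_equal(unname(rowSums(sim$W0)), rep(180, 204), tolerance = 1e-9)
})

test_that("degenerate catalog cases behave", {
  zero <- simulateCatalogs(defaultSignatures(), c(1, 1, 1), 5, 0, seed = 1)
  expect_true(all(catalogCounts(zero$catalog) == 0))
  ## single-signature exposure on a unit-vector signature: all mutations in
  ## that channel
  H <- matrix(0, 1, 96); H[1, 37] <- 1
  one <- simulateCatalogs(H, alpha = 1000, 4, 50, seed = 1)
  expect_true(all(catalogCounts(one$catalog)[, 37] == 50))
  expect_true(all(catalogCounts(one$catalog)[, -37] == 0))
  expect_error(simulateCatalogs(-H, 1, 4, 50, 1), "nonnegative")
})

test_that("array genotypes round the underlying dosage and flip at the error rate", {
  v <- data.frame(sample = "S1", chrom = "chr1", pos = 1:1000, ref = "A",
                  alt = "T", vaf = 0.5,
                  trueVaf = rep(c(0.5, 0.97, 0.23), length.out = 1000))
  noerr <- simulateArrayGenotypes(v, errorRate = 0, seed = 1)
  expect_identical(unique(noerr$arrayAf[v$trueVaf == 0.5]), 0.5)
  expect_identical(unique(noerr$arrayAf[v$trueVaf == 0.97]), 1)
  expect_identical(unique(noerr$arrayAf[v$trueVaf == 0.23]), 0)
  allerr <- simulateArrayGenotypes(v, errorRate = 1, seed = 1)
  expect_true(all(allerr$arrayAf != noerr$arrayAf))
  some <- simulateArrayGenotypes(v, errorRate = 0.15, seed = 1)
  flips <- sum(some$arrayAf != noerr$arrayAf)
  expect_lt(abs(flips - 150), 3 * sqrt(1000 * 0.15 * 0.85))
  expect_error(simulateArrayGenotypes(v, errorRate = 1.2, seed = 1),
               "errorRate")
})

test_that("CNV fixture plants the configured deletions", {
  all <- simulateCnvSegments(simConfig(deletionRate = 1), nSamples = 8,
                             seed = 2)
  expect_true(all(all$deleted[, "MLH3"]))
  none <- simulateCnvSegments(simConfig(deletionRate = 0), nSamples = 8,
                              seed = 2)
  expect_false(any(none$deleted[, "MLH3"]))
  ## deleted samples carry a deep segment over MLH3; shift raises exposure
  expect_gt(mean(all$mmrExposure), mean(none$mmrExposure))
  seg <- all$segments
  mlh3 <- all$genes[all$genes$gene == "MLH3", ]
  deep <- seg[seg$log2 < -0.5 & seg$chrom == mlh3$chrom, ]
  expect_setequal(unique(deep$sample), rownames(all$deleted))
})

test_that("domain burden cohort has the configured shape and effects", {
  sim <- simulateDomainBurdenCohort(simConfig(seed = 4))
  expect_identical(dim(sim$burden), c(204L, 1966L))
  expect_true(all(sim$burden >= 0))
  expect_true(all(sim$burden == round(sim$burden)))
  expect_identical(levels(sim$labels), c("control", "case"))
  ## informative domains are enriched in cases
  info <- names(sim$informativeDomains)
  isCase <- sim$labels == "case"
  expect_gt(mean(sim$burden[isCase, info]), mean(sim$burden[!isCase, info]))
  ## null cohort: no association structure planted
  null <- simulateDomainBurdenCohort(
    simConfig(seed = 4, informativeDomains = stats::setNames(
      numeric(0), character(0))))
  expect_identical(dim(null$burden), c(204L, 1966L))
})
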