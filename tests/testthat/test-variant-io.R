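test_that("variant tables round-trip through VCF plus sidecar", {
  sim <- simulateVariantCohort(tinyConfig(seed = 8))
  dir <- withr::local_tempdir()
  paths <- writeVariantVcf(sim$variants, dir)
  back <- readVariants(paths$vcf, paths$sidecar)
  orig <- sim$variants[, names(back)]
  key <- function(d) order(d$sample, d$chrom, d$pos, d$ref, d$alt)
  orig <- orig[key(orig), ]; rownames(orig) <- NULL
  back <- back[key(back), ]; rownames(back) <- NULL
  expect_equal(back$vaf, orig$vaf, tolerance = 1e-6)
  back$vaf <- orig$vaf
  expect_equal(back, orig, tolerance = 1e-6)
})

test_that("multi-allelic VCF records split into one row per ALT", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "S1.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tC,T\t.\tPASS\tDP=80",
               "chr2\t5\t.\tG\tA\t.\tPASS\tDP=60"), vcf)
  sidecar <- file.path(dir, "features.csv")
  utils::write.csv(data.frame(
    sample = "S1", chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 100L, 5L), ref = c("A", "A", "G"),
    alt = c("C", "T", "A"), vaf = c(0.1, 0.2, 0.5)), sidecar,
    row.names = FALSE)
  got <- readVariants(c(S1 = vcf), sidecar)
  expect_identical(nrow(got), 3L)
  expect_setequal(got$alt[got$pos == 100], c("C", "T"))
})

test_that("sidecar orphans abort with the offending keys", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "S1.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tC\t.\tPASS\tDP=80"), vcf)
  sidecar <- file.path(dir, "features.csv")
  utils::write.csv(data.frame(sample = "S1", chrom = "chr9", pos = 1L,
                              ref = "A", alt = "C", vaf = 0.1), sidecar,
                   row.names = FALSE)
  expect_error(readVariants(c(S1 = vcf), sidecar), "chr1:100")
})

test_that("panel of normals keeps exactly the sites seen in >= 2 normals", {
  pon <- buildPon(list(c("chr1:10:A:T", "chr1:20:C:G"),
                       c("chr1:10:A:T", "chr2:5:G:A"),
                       c("chr2:5:G:A")))
  expect_setequal(ponSites(pon), c("chr1:10:A:T", "chr2:5:G:A"))
  expect_identical(length(buildPon(list())), 0L)
  ## duplicate observations within one normal count once
  pon1 <- buildPon(list(c("chr1:10:A:T", "chr1:10:A:T")))
  expect_identical(length(pon1), 0L)
})

test_that("PON construction matches brute-force counting on random sets", {
  set.seed(21)
  for (i in 1:10) {
    universe <- siteKey("chr1", sample(1:400, 120), "A", "T")
    sets <- lapply(1:8, function(j)
      sample(universe, sample(10:60, 1)))
    pon <- buildPon(sets)
    counts <- table(unlist(lapply(sets, unique)))
    expect_setequal(ponSites(pon), names(counts)[counts >= 2])
    ## order-independent and idempotent over the normal list
    expect_identical(ponSites(buildPon(rev(sets))), ponSites(pon))
  }
})

test_that("PON filtering removes blacklisted sites and preserves order", {
  v <- handVariants()
  empty <- buildPon(list())
  expect_identical(applyPon(v, empty), v)
  all <- buildPon(list(siteKey(v$chrom, v$pos, v$ref, v$alt),
                       siteKey(v$chrom, v$pos, v$ref, v$alt)))
  expect_identical(nrow(applyPon(v, all)), 0L)
  one <- buildPon(list("chr1:100:C:T", "chr1:100:C:T"))
  out <- applyPon(v, one)
  expect_identical(out$pos, v$pos[!(v$chrom == "chr1" & v$pos == 100)])
})

test_that("depth filter boundary is inclusive at the threshold", {
  v <- data.frame(sample = "S", chrom = "chr1", pos = 1:3, ref = "A",
                  alt = "T", totalDepth = c(19L, 20L, 21L))
  out <- filterDepth(v, 20)
  expect_identical(out$totalDepth, c(20L, 21L))
  expect_identical(filterDepth(v, 0), v)
  set.seed(31)
  rv <- data.frame(sample = "S", chrom = "chr1", pos = 1:500, ref = "A",
                   alt = "T", totalDepth = sample(0:60, 500, TRUE))
  expect_identical(nrow(filterDepth(rv)), sum(rv$totalDepth >= 20))
})

test_that("PON and depth filters commute", {
  sim <- simulateVariantCohort(tinyConfig(seed = 12))
  v <- sim$variants
  sites <- unique(siteKey(v$chrom, v$pos, v$ref, v$alt))
  set.seed(5)
  pon <- buildPon(list(sample(sites, 200), sample(sites, 200)))
  a <- filterDepth(applyPon(v, pon), 90)
  b <- applyPon(filterDepth(v, 90), pon)
  expect_identical(a, b)
})

test_that("feature assembly produces the 31-column schema with no missing values", {
  sim <- simulateVariantCohort(tinyConfig(seed = 3))
  fm <- assembleFeatures(sim$variants)
  expect_identical(ncol(fm$x), 31L)
  expect_identical(colnames(fm$x), featureSchema())
  expect_false(anyNA(fm$x))
  expect_true(all(is.finite(fm$x)))
  expect_identical(nrow(fm$x), nrow(sim$variants))
  expect_error(assembleFeatures(sim$variants, schema = c("vaf", "bogus")),
               "unknown feature schema")
})

test_that("cohort recurrence counts carriers of the identical site", {
  base <- handVariants()
  ## plant one site carried by 7 samples
  extra <- do.call(rbind, lapply(1:7, function(i) {
    r <- base[2, ]; r$sample <- paste0("X", i); r
  }))
  tab <- rbind(base[-2, ], extra)
  fm <- assembleFeatures(tab)
  rec <- fm$x[, "cohortRecurrence"]
  expect_true(all(rec[tab$pos == 200 & tab$chrom == "chr1"] == 7))
  expect_true(all(rec[tab$sample %in% c("S1", "S2") &
                        tab$pos == 100] == 2))
})

test_that("an all-missing score column imputes to the default, not NaN", {
  v <- handVariants()
  v$sift <- NA_real_
  fm <- assembleFeatures(v)
  expect_true(all(fm$x[, "sift"] == 0.5))
})
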