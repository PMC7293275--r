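test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  ## order preserved
  p <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(bhFdr(p), rep(0.04, 4))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the exact fallback matches enumeration on the printed-scale table", {
  ## 15/135 mutated cases vs 4/69 mutated controls
  tab <- matrix(c(15, 120, 4, 65), 2)
  expect_equal(somaSift:::.exactTestP(tab),
               enumExactP(15, 120, 4, 65), tolerance = 1e-12)
})

test_that("per-gene testing reports fractions, FDR, and length-adjusted rates", {
  set.seed(59)
  n <- 204
  labels <- rep(c("case", "control"), c(135, 69))
  genes <- paste0("G", 1:12)
  mut <- matrix(rbinom(n * 12, 1, 0.1), n, 12,
                dimnames = list(sprintf("S%03d", 1:n), genes))
  mut[, "G1"] <- rbinom(n, 1, ifelse(labels == "case", 0.25, 0.03))
  mut[, "G12"] <- 0  # never mutated -> excluded
  lens <- stats::setNames(rep(2, 12), genes); lens["G2"] <- 4
  res <- perGeneCaseControl(mut, labels, lens)
  expect_identical(attr(res, "excluded"), "G12")
  expect_false("G12" %in% res$gene)
  expect_identical(res$gene[1], "G1")  # sorted by p
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$q <= 1))
  g1 <- res[res$gene == "G1", ]
  expect_equal(g1$fracCase, sum(mut[labels == "case", "G1"]) / 135)
  expect_equal(g1$log10p, log10(g1$p))
  ## doubling gene length halves the adjusted rate exactly
  g2 <- res[res$gene == "G2", ]
  expect_equal(g2$rateCaseKb,
               sum(mut[labels == "case", "G2"]) / (135 * 4))
})

test_that("gene results are invariant to sample order and label swap flips direction", {
  set.seed(61)
  n <- 60
  labels <- rep(c("case", "control"), each = 30)
  mut <- matrix(rbinom(n * 5, 1, 0.3), n, 5,
                dimnames = list(sprintf("S%02d", 1:n), paste0("G", 1:5)))
  res <- perGeneCaseControl(mut, labels)
  perm <- sample(n)
  resPerm <- perGeneCaseControl(mut[perm, ], labels[perm])
  expect_equal(res[order(res$gene), c("p", "fracCase", "fracControl")],
               resPerm[order(resPerm$gene),
                       c("p", "fracCase", "fracControl")],
               tolerance = 1e-9, ignore_attr = TRUE)
  flipped <- perGeneCaseControl(
    mut, ifelse(labels == "case", "control", "case"))
  f <- flipped[order(flipped$gene), ]
  r <- res[order(res$gene), ]
  expect_equal(f$p, r$p, tolerance = 1e-9)
  expect_equal(f$fracCase, r$fracControl)
})

test_that("hotspot-level subgroup enrichment finds a planted hotspot", {
  set.seed(67)
  samples <- sprintf("S%03d", 1:195)
  subgroups <- stats::setNames(rep(c("PDWA", "NP"), c(76, 119)), samples)
  carriers <- c(samples[1:19], samples[77:82])  # 25% vs 5%
  v <- data.frame(sample = carriers, gene = "PIK3CA",
                  proteinChange = "p.H1047R", class = "missense")
  bg <- data.frame(sample = sample(samples, 60, TRUE), gene = "OBSCN",
                   proteinChange = "p.A100V", class = "missense")
  silent <- data.frame(sample = samples[1:30], gene = "PIK3CA",
                       proteinChange = "p.L200L", class = "silent")
  res <- subgroupEnrichment(rbind(v, bg, silent), subgroups,
                            level = "hotspot")
  top <- res[1, ]
  expect_identical(top$unit, "PIK3CA p.H1047R")
  expect_lt(top$p, 0.001)
  ## silent records are dropped under the default toggle
  expect_false(any(grepl("L200L", res$unit)))
  withSilent <- subgroupEnrichment(rbind(v, bg, silent), subgroups,
                                   level = "hotspot",
                                   nonsynonymousOnly = FALSE)
  expect_true(any(grepl("L200L", withSilent$unit)))
  ## gene level aggregates carriers per gene
  geneRes <- subgroupEnrichment(rbind(v, bg), subgroups, level = "gene")
  expect_setequal(geneRes$unit, c("PIK3CA", "OBSCN"))
})

test_that("identical subgroup distributions give uniform p-values", {
  set.seed(71)
  samples <- sprintf("S%03d", 1:120)
  subgroups <- stats::setNames(rep(c("PDWA", "NP"), 60), samples)
  ps <- vapply(1:100, function(i) {
    carriers <- sample(samples, 30)
    v <- data.frame(sample = carriers, gene = "G1",
                    proteinChange = "p.A10V", class = "missense")
    subgroupEnrichment(v, subgroups, level = "gene")$p[1]
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("serine/threonine accounting parses and counts per definition", {
  v <- data.frame(class = "missense",
                  proteinChange = c("p.S100T", "p.H1047R", "p.T20A",
                                    "p.A30S", "p.S40S?", "p.G5T"))
  res <- serThrAccounting(v)
  expect_identical(res$n, 5L)
  expect_identical(res$nUnparseable, 1L)
  ## p.S100T: loss-S AND gain-T; p.H1047R: none
  expect_equal(unname(res$fractions["lossSer"]), 1 / 5)
  expect_equal(unname(res$fractions["lossThr"]), 1 / 5)
  expect_equal(unname(res$fractions["gainSer"]), 1 / 5)
  expect_equal(unname(res$fractions["gainThr"]), 2 / 5)
  expect_error(serThrAccounting(data.frame(class = "silent",
                                           proteinChange = "p.L1L")),
               "missense")
})

test_that("serine/threonine fractions equal a brute-force parse on random changes", {
  set.seed(73)
  aa <- c("A", "S", "T", "G", "H", "R")
  n <- 200
  ref <- sample(aa, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(aa, r), 1), character(1))
  pc <- paste0("p.", ref, sample(10:999, n, TRUE), alt)
  v <- data.frame(class = "missense", proteinChange = pc)
  res <- serThrAccounting(v, groups = rep(c("case", "control"),
                                          length.out = n))
  expect_equal(unname(res$fractions["lossSer"]),
               mean(ref == "S" & alt != "S"))
  expect_equal(unname(res$fractions["gainThr"]),
               mean(alt == "T" & ref != "T"))
  expect_length(res$p, 4)
  expect_true(all(res$p >= 0 & res$p <= 1))
})
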