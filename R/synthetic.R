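## Synthetic benign-biopsy cohort generators.
##
## Every generator is a pure function of (config, seed): the RNG is scoped
## with withSeed() so identical inputs give byte-identical outputs and the
## caller's random stream is never perturbed.

.VARIANT_CLASSES <- c("missense", "silent", "nonsense", "frameshift_insertion",
                      "frameshift_deletion", "splice_site", "inframe_indel",
                      "other")

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Built-in synthetic gene catalog
#'
#' A small catalog of genes with synthetic exome coordinates and coding
#' lengths, covering the genes the pipeline's downstream analyses refer to
#' (PIK3CA and its p.H1047R hotspot, MUC17, the mismatch-repair genes MLH1,
#' MLH3, MSH2, MSH3, MSH6, PMS2, ...) plus filler genes. Coordinates are
#' synthetic: they provide a consistent coordinate system for the simulator,
#' segment overlap calls, and length-adjusted enrichment rates, and do not
#' correspond to any reference assembly.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `codingKb`.
#' @export
geneCatalog <- function() {
  named <- c("PIK3CA", "MUC17", "OBSCN", "FLG", "FLG2", "GLTPD2", "ABCA13",
             "CTNNA2", "GNAS", "BCORL1", "AKT1", "HYDIN", "DNMT3B", "NCOA3",
             "FAT1", "ATR", "ETAA1", "MLH1", "MLH3", "MSH2", "MSH3", "MSH6",
             "PMS2", "MUTYH", "MYH11", "SETD2", "TGFBR2", "SLC7A4", "PGBD1",
             "PLA2G3", "ADAM30")
  genes <- c(named, sprintf("GENE%02d", seq_len(9)))
  n <- length(genes)
  ## deterministic pseudo-lengths in kb, heavy-tailed like real coding genes
  kb <- round(1.2 + 12 * ((seq_len(n) * 7919L) %% 97L) / 97L, 2)
  kb[genes == "MUC17"] <- 13.5
  kb[genes == "OBSCN"] <- 24.0
  kb[genes == "HYDIN"] <- 15.3
  kb[genes == "PIK3CA"] <- 3.2
  chrom <- paste0("chr", rep(1:22, length.out = n))
  start <- 1e6 + 3e6 * (seq_len(n) %/% 22)
  width <- round(kb * 1000 * 8)  # genomic footprint ~8x coding length
  data.frame(gene = genes, chrom = chrom,
             start = as.integer(start),
             end = as.integer(start + width),
             codingKb = kb, stringsAsFactors = FALSE)
}

.domainIds <- function(n) sprintf("DOM%04d", seq_len(n))

## Beta shapes with a given mean and first shape parameter.
.betaShapes <- function(mean, shape1) c(shape1, shape1 * (1 - mean) / mean)

## Beta shapes with a given mode and total concentration.
.betaModeShapes <- function(mode, conc) {
  a <- mode * (conc - 2) + 1
  c(a, conc - a)
}

.sampleDepth <- function(n, mu, size) {
  pmax(2L, stats::rnbinom(n, mu = mu, size = size))
}

.emptyVariantTable <- function() {
  data.frame(sample = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), vaf = numeric(0),
             altDepth = integer(0), refDepth = integer(0),
             totalDepth = integer(0), gene = character(0),
             proteinChange = character(0), class = character(0),
             context = character(0), populationAf = numeric(0),
             dbsnpCommon = integer(0), cosmicCount = integer(0),
             sift = numeric(0), polyphen = numeric(0), cadd = numeric(0),
             gerp = numeric(0), phylop = numeric(0), revel = numeric(0),
             domain = character(0), trueVaf = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

## Per-sample metadata including planted signature exposure weights.
.simulateMetadata <- function(config) {
  n <- config@nCases + config@nControls
  if (n == 0L) {
    return(list(metadata = data.frame(sample = character(0),
                                      group = character(0), age = numeric(0),
                                      menopausal = character(0),
                                      histology = character(0),
                                      tnbc = logical(0),
                                      hasMatchedNormal = logical(0)),
                weights = matrix(0, 0, nrow(config@trueSignatures))))
  }
  sampleIds <- sprintf("S%03d", seq_len(n))
  group <- c(rep("case", config@nCases), rep("control", config@nControls))
  age <- round(stats::rnorm(n, 49.7, 9.9), 1)
  menopausal <- ifelse(stats::runif(n) < 0.56, "pre", "post")
  histology <- ifelse(stats::runif(n) < config@pdwaFraction, "PDWA", "NP")
  tnbc <- group == "case" & stats::runif(n) < config@tnbcFraction
  ## matched germline available for a small subset (mirrors 20 cases + 6
  ## controls out of 204)
  matched <- rep(FALSE, n)
  nMatchCase <- min(20L, config@nCases)
  nMatchCtrl <- min(6L, config@nControls)
  if (nMatchCase > 0)
    matched[sample(which(group == "case"), nMatchCase)] <- TRUE
  if (nMatchCtrl > 0)
    matched[sample(which(group == "control"), nMatchCtrl)] <- TRUE

  weights <- rdirichlet(n, config@exposureConcentration)
  colnames(weights) <- rownames(config@trueSignatures)
  otn <- match("OTN", colnames(weights))
  if (!is.na(otn) && any(tnbc) && config@tnbcOtnShift != 0) {
    weights[tnbc, otn] <- weights[tnbc, otn] * exp(config@tnbcOtnShift)
    weights[tnbc, ] <- weights[tnbc, , drop = FALSE] /
      rowSums(weights[tnbc, , drop = FALSE])
  }
  rownames(weights) <- sampleIds
  list(metadata = data.frame(sample = sampleIds, group = group, age = age,
                             menopausal = menopausal, histology = histology,
                             tnbc = tnbc, hasMatchedNormal = matched,
                             stringsAsFactors = FALSE),
       weights = weights)
}

## Shared pool of polymorphic germline sites.
.germlinePool <- function(config, genes) {
  m <- config@germlineSitesPool
  if (m == 0L) return(NULL)
  chromIdx <- sample(nrow(genes), m, replace = TRUE, prob = genes$codingKb)
  pos <- genes$start[chromIdx] +
    floor(stats::runif(m) * (genes$end[chromIdx] - genes$start[chromIdx]))
  isIndel <- stats::runif(m) < 0.05
  ref <- sample(.BASES, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), character(1))
  alt[isIndel] <- paste0(ref[isIndel],
                         sample(.BASES, sum(isIndel), replace = TRUE))
  fl5 <- sample(.BASES, m, replace = TRUE)
  fl3 <- sample(.BASES, m, replace = TRUE)
  context <- ifelse(isIndel, NA_character_, paste0(fl5, ref, fl3))
  cls <- character(m)
  cls[!isIndel] <- sample(c("silent", "missense", "nonsense", "splice_site",
                            "other"), sum(!isIndel), replace = TRUE,
                          prob = c(0.66, 0.27, 0.01, 0.02, 0.04))
  cls[isIndel] <- sample(c("frameshift_insertion", "inframe_indel"),
                         sum(isIndel), replace = TRUE, prob = c(0.6, 0.4))
  data.frame(chrom = genes$chrom[chromIdx], pos = as.integer(pos),
             ref = ref, alt = alt, context = context, class = cls,
             gene = genes$gene[chromIdx],
             populationAf = stats::rbeta(m, 0.6, 1.6),
             stringsAsFactors = FALSE)
}

.randomProteinChange <- function(n, missense) {
  out <- rep(NA_character_, n)
  if (any(missense)) {
    k <- sum(missense)
    refAA <- sample(.AA, k, replace = TRUE)
    altAA <- vapply(refAA, function(a) sample(setdiff(.AA, a), 1),
                    character(1))
    out[missense] <- paste0("p.", refAA, sample(30:1500, k, replace = TRUE),
                            altAA)
  }
  out
}

.pathScores <- function(n, somatic) {
  ## six pathogenicity/conservation stand-ins; somatic calls skew slightly
  ## more damaging; ~5% missing to exercise imputation
  sim1 <- function() {
    x <- ifelse(somatic, stats::rbeta(n, 2.5, 2), stats::rbeta(n, 2, 2.5))
    x[stats::runif(n) < 0.05] <- NA_real_
    x
  }
  data.frame(sift = sim1(), polyphen = sim1(), cadd = 10 * sim1(),
             gerp = 6 * sim1() - 2, phylop = 4 * sim1() - 1, revel = sim1())
}

#' Simulate an annotated variant cohort with ground truth
#'
#' Generates per-sample variant tables with the statistical structure the
#' classifier exploits: germline variant allele frequencies (VAFs)
#' concentrated near the heterozygous (~0.5) and homozygous (~1.0) modes,
#' somatic VAFs from a low-mean Beta distribution (default mean 0.232), read
#' depths from a negative binomial with mean 99, cohort-shared germline sites
#' with realistic population allele frequencies, mostly-private somatic sites
#' whose trinucleotide channels are drawn from each sample's planted signature
#' mixture, a PIK3CA p.H1047R hotspot enriched in PDWA histology, and
#' class-dependent annotation scores.
#'
#' @param config A [SimConfig-class].
#' @return A list with components:
#'   \describe{
#'     \item{variants}{data.frame of all variant records (column `label` holds
#'       the true class).}
#'     \item{metadata}{per-sample phenotype/covariate table.}
#'     \item{truth}{list with `labels` (key/label data.frame),
#'       `exposureWeights`, `exposureCounts` (rows sum to the per-sample SNV
#'       count), and the planted `signatures`.}
#'   }
#' @export
#' @examples
#' sim <- simulateVariantCohort(simConfig(nCases = 4, nControls = 2, seed = 1))
#' table(sim$variants$label)
simulateVariantCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    meta <- .simulateMetadata(config)
    n <- nrow(meta$metadata)
    if (n == 0L) {
      return(list(variants = .emptyVariantTable(), metadata = meta$metadata,
                  truth = list(labels = data.frame(key = character(0),
                                                   label = character(0)),
                               exposureWeights = meta$weights,
                               exposureCounts = meta$weights,
                               signatures = config@trueSignatures)))
    }
    genes <- geneCatalog()
    pool <- .germlinePool(config, genes)
    H0 <- config@trueSignatures
    channels <- sbsChannels()
    parts <- vector("list", n)

    somShape <- .betaShapes(config@somaticVafMean, 2.5)
    hetShape <- .betaModeShapes(config@germlineVafModes[1], 100)
    homShape <- .betaModeShapes(config@germlineVafModes[2], 62)

    hotspot <- list(gene = "PIK3CA", proteinChange = "p.H1047R",
                    chrom = genes$chrom[genes$gene == "PIK3CA"],
                    pos = genes$start[genes$gene == "PIK3CA"] + 10471L,
                    ref = "A", alt = "G", context = "CAT")

    for (i in seq_len(n)) {
      sid <- meta$metadata$sample[i]
      rows <- list()

      ## -- germline variants from the shared pool (HWE carrier draw) --
      if (!is.null(pool)) {
        dosage <- stats::rbinom(nrow(pool), 2L, pool$populationAf)
        carried <- which(dosage > 0L)
        if (length(carried)) {
          het <- dosage[carried] == 1L
          trueVaf <- numeric(length(carried))
          trueVaf[het] <- stats::rbeta(sum(het), hetShape[1], hetShape[2])
          trueVaf[!het] <- stats::rbeta(sum(!het), homShape[1], homShape[2])
          g <- pool[carried, ]
          k <- nrow(g)
          rows$germ <- data.frame(
            sample = sid, chrom = g$chrom, pos = g$pos, ref = g$ref,
            alt = g$alt, trueVaf = trueVaf, gene = g$gene,
            proteinChange = .randomProteinChange(k, g$class == "missense"),
            class = g$class, context = g$context,
            populationAf = g$populationAf,
            cosmicCount = ifelse(stats::runif(k) < 0.005,
                                 stats::rpois(k, 2), 0L),
            label = "germline", stringsAsFactors = FALSE)
        }
      }

      ## -- somatic SNVs: channels drawn from the sample's exposure mixture --
      nSnv <- config@snvsPerSample
      if (nSnv > 0L) {
        p <- as.vector(meta$weights[i, , drop = FALSE] %*% H0)
        counts <- as.vector(stats::rmultinom(1, nSnv, p))
        chIdx <- rep.int(seq_len(96), counts)
        dec <- decodeChannel(channels[chIdx])
        ref <- dec$ref; alt <- dec$alt
        context <- paste0(dec$fivep, dec$ref, dec$threep)
        ## present about half on the purine strand to exercise folding
        flip <- stats::runif(nSnv) < 0.5
        ref[flip] <- unname(.COMP[ref[flip]])
        alt[flip] <- unname(.COMP[alt[flip]])
        context[flip] <- reverseComplement(context[flip])
        gIdx <- sample(nrow(genes), nSnv, replace = TRUE,
                       prob = genes$codingKb)
        cls <- sample(c("missense", "silent", "nonsense", "splice_site"),
                      nSnv, replace = TRUE, prob = c(0.52, 0.37, 0.06, 0.05))
        rows$snv <- data.frame(
          sample = sid, chrom = genes$chrom[gIdx],
          pos = genes$start[gIdx] +
            as.integer(floor(stats::runif(nSnv) *
                               (genes$end[gIdx] - genes$start[gIdx]))),
          ref = ref, alt = alt,
          trueVaf = stats::rbeta(nSnv, somShape[1], somShape[2]),
          gene = genes$gene[gIdx],
          proteinChange = .randomProteinChange(nSnv, cls == "missense"),
          class = cls, context = context,
          populationAf = ifelse(stats::runif(nSnv) < 0.97, 0,
                                stats::runif(nSnv, 0, 0.001)),
          cosmicCount = ifelse(stats::runif(nSnv) < 0.3,
                               stats::rpois(nSnv, 0.8), 0L),
          label = "somatic", stringsAsFactors = FALSE)
      }

      ## -- somatic indels --
      nInd <- config@indelsPerSample
      if (nInd > 0L) {
        gIdx <- sample(nrow(genes), nInd, replace = TRUE,
                       prob = genes$codingKb)
        ref <- sample(.BASES, nInd, replace = TRUE)
        ins <- stats::runif(nInd) < 0.5
        alt <- ifelse(ins, paste0(ref, sample(.BASES, nInd, replace = TRUE)),
                      ref)
        ref[!ins] <- paste0(ref[!ins],
                            sample(.BASES, sum(!ins), replace = TRUE))
        rows$ind <- data.frame(
          sample = sid, chrom = genes$chrom[gIdx],
          pos = genes$start[gIdx] +
            as.integer(floor(stats::runif(nInd) *
                               (genes$end[gIdx] - genes$start[gIdx]))),
          ref = ref, alt = alt,
          trueVaf = stats::rbeta(nInd, somShape[1], somShape[2]),
          gene = genes$gene[gIdx], proteinChange = NA_character_,
          class = sample(c("frameshift_insertion", "frameshift_deletion",
                           "inframe_indel"), nInd, replace = TRUE,
                         prob = c(0.45, 0.4, 0.15)),
          context = NA_character_,
          populationAf = 0, cosmicCount = 0L,
          label = "somatic", stringsAsFactors = FALSE)
      }

      ## -- PIK3CA p.H1047R hotspot, enriched in PDWA histology --
      hotRate <- if (meta$metadata$histology[i] == "PDWA") 0.28 else 0.05
      if (stats::runif(1) < hotRate) {
        rows$hot <- data.frame(
          sample = sid, chrom = hotspot$chrom, pos = hotspot$pos,
          ref = hotspot$ref, alt = hotspot$alt,
          trueVaf = stats::rbeta(1, somShape[1], somShape[2]),
          gene = hotspot$gene, proteinChange = hotspot$proteinChange,
          class = "missense", context = hotspot$context,
          populationAf = 0, cosmicCount = 120L,
          label = "somatic", stringsAsFactors = FALSE)
      }

      parts[[i]] <- do.call(rbind, rows)
    }

    variants <- do.call(rbind, parts)
    rownames(variants) <- NULL
    m <- nrow(variants)
    depth <- .sampleDepth(m, config@meanDepth, config@depthDispersion)
    altDepth <- stats::rbinom(m, depth, variants$trueVaf)
    altDepth <- pmax(altDepth, 1L)  # called variants have >= 1 alt read
    variants$vaf <- altDepth / depth
    variants$altDepth <- altDepth
    variants$refDepth <- depth - altDepth
    variants$totalDepth <- depth
    variants$dbsnpCommon <- as.integer(variants$populationAf > 0.01)
    variants <- cbind(variants,
                      .pathScores(m, variants$label == "somatic"))
    isMis <- variants$class == "missense"
    domain <- rep(NA_character_, m)
    getsDom <- isMis & stats::runif(m) < 0.35
    domain[getsDom] <- sample(.domainIds(config@nDomains), sum(getsDom),
                              replace = TRUE)
    two <- getsDom & stats::runif(m) < 0.03
    domain[two] <- paste(domain[two],
                         sample(.domainIds(config@nDomains), sum(two),
                                replace = TRUE), sep = ",")
    variants$domain <- domain
    ord <- c("sample", "chrom", "pos", "ref", "alt", "vaf", "altDepth",
             "refDepth", "totalDepth", "gene", "proteinChange", "class",
             "context", "populationAf", "dbsnpCommon", "cosmicCount",
             "sift", "polyphen", "cadd", "gerp", "phylop", "revel",
             "domain", "trueVaf", "label")
    variants <- variants[, ord]

    truthLabels <- data.frame(
      key = variantKey(variants$sample, variants$chrom, variants$pos,
                       variants$ref, variants$alt),
      label = variants$label, stringsAsFactors = FALSE)
    list(variants = variants, metadata = meta$metadata,
         truth = list(labels = truthLabels,
                      exposureWeights = meta$weights,
                      exposureCounts = meta$weights * config@snvsPerSample,
                      signatures = H0))
  })
}

#' Simulate mutation catalogs from planted signatures
#'
#' Draws per-sample exposure weights from a Dirichlet distribution and each
#' sample's 96-channel count vector from a multinomial with probability
#' vector `w %*% H0`, so that every row sums exactly to the per-sample SNV
#' count.
#'
#' @param H0 k x 96 nonnegative signature matrix with rows summing to 1.
#' @param alpha Dirichlet concentration parameters (length k).
#' @param nSamples Number of samples.
#' @param snvsPerSample SNV count per sample.
#' @param seed Integer seed.
#' @return List with `catalog` (a [MutationCatalog-class]), `W0` (true
#'   exposures scaled to counts; rows sum to `snvsPerSample`), and `weights`
#'   (the Dirichlet draws).
#' @export
#' @examples
#' sim <- simulateCatalogs(defaultSignatures(), c(5, 3, 2), 10, 180, seed = 1)
#' rowSums(catalogCounts(sim$catalog))
simulateCatalogs <- function(H0, alpha, nSamples, snvsPerSample, seed) {
  H0 <- as.matrix(H0)
  if (any(H0 < 0)) stop("H0 must be nonnegative", call. = FALSE)
  if (ncol(H0) != 96L) stop("H0 must have 96 columns", call. = FALSE)
  if (any(abs(rowSums(H0) - 1) > 1e-9))
    stop("H0 rows must sum to 1", call. = FALSE)
  nSamples <- assertCount(nSamples, "nSamples")
  snvsPerSample <- assertCount(snvsPerSample, "snvsPerSample")
  withSeed(seed, {
    weights <- rdirichlet(nSamples, alpha)
    P <- weights %*% H0
    counts <- t(vapply(seq_len(nSamples), function(i)
      as.vector(stats::rmultinom(1, snvsPerSample, P[i, ])),
      numeric(96)))
    if (nSamples == 0L) counts <- matrix(0, 0, 96)
    rownames(counts) <- sprintf("S%03d", seq_len(nSamples))
    W0 <- weights * snvsPerSample
    rownames(W0) <- rownames(counts)
    colnames(W0) <- rownames(H0)
    list(catalog = MutationCatalog(counts), W0 = W0, weights = weights)
  })
}

#' Simulate an exposure-phenotype study
#'
#' Convenience generator for exposure-association experiments: per-sample
#' metadata (case/control, TNBC flag, age, menopausal status, histology),
#' planted signature exposures with the configured O/TN shift in
#' TNBC-flagged samples, and the corresponding mutation catalog.
#'
#' @param config A [SimConfig-class]; `config@seed` drives the simulation.
#' @param catalog Logical; also draw the multinomial catalog (default TRUE).
#' @return List with `metadata`, `weights`, `W0` (exposure counts), and
#'   `catalog` (or NULL).
#' @export
simulateExposureStudy <- function(config, catalog = TRUE) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    meta <- .simulateMetadata(config)
    W0 <- meta$weights * config@snvsPerSample
    cat96 <- NULL
    if (catalog && nrow(meta$weights) > 0L) {
      P <- meta$weights %*% config@trueSignatures
      counts <- t(vapply(seq_len(nrow(P)), function(i)
        as.vector(stats::rmultinom(1, config@snvsPerSample, P[i, ])),
        numeric(96)))
      rownames(counts) <- meta$metadata$sample
      cat96 <- MutationCatalog(counts)
    }
    list(metadata = meta$metadata, weights = meta$weights, W0 = W0,
         catalog = cat96)
  })
}

#' Simulate genotyping-array calls for shared sites
#'
#' Each variant site is assigned the array allele frequency in
#' \{0, 0.5, 1\} nearest to its true underlying allele dosage, then flipped
#' to a uniformly chosen wrong state with probability `errorRate`.
#'
#' @param variants Variant table carrying `vaf` (and, if present, `trueVaf`
#'   which is preferred as the underlying dosage).
#' @param errorRate Flip probability in [0, 1].
#' @param seed Integer seed.
#' @return data.frame with `sample`, `chrom`, `pos`, `ref`, `alt`, `arrayAf`.
#' @export
simulateArrayGenotypes <- function(variants, errorRate, seed) {
  assertFraction(errorRate, "errorRate")
  requireColumns(variants, c("sample", "chrom", "pos", "ref", "alt", "vaf"))
  dosage <- if ("trueVaf" %in% names(variants)) variants$trueVaf
            else variants$vaf
  states <- c(0, 0.5, 1)
  withSeed(seed, {
    nearest <- states[max.col(-abs(outer(dosage, states, "-")),
                              ties.method = "first")]
    flip <- stats::runif(length(dosage)) < errorRate
    wrong <- vapply(nearest[flip], function(g)
      sample(setdiff(states, g), 1), numeric(1))
    arrayAf <- nearest
    arrayAf[flip] <- wrong
    data.frame(sample = variants$sample, chrom = variants$chrom,
               pos = variants$pos, ref = variants$ref, alt = variants$alt,
               arrayAf = arrayAf, stringsAsFactors = FALSE)
  })
}

#' Simulate copy-number segment tables with planted MLH3/PMS2 deletions
#'
#' Generates per-sample segments over the synthetic gene catalog's
#' chromosomes. Samples drawn as MLH3-deleted receive a focal segment with a
#' deep-deletion log2 copy ratio covering MLH3 (similarly PMS2, at a fixed
#' secondary rate), and their mismatch-repair signature exposure is shifted
#' upward by `config@deletionMmrShift` within-group standard deviations.
#'
#' @param config A [SimConfig-class].
#' @param nSamples Number of CNV-profiled samples (default 26, the matched
#'   germline subset size).
#' @param seed Seed; defaults to `config@seed`.
#' @return List with `segments` (SEG-convention data.frame: `sample`,
#'   `chrom`, `start`, `end`, `numMark`, `log2`), `deleted` (samples x genes
#'   logical matrix for MLH3 and PMS2), `mmrExposure` (numeric, attributed
#'   MMR mutation counts), and `genes` (the catalog rows used).
#' @export
simulateCnvSegments <- function(config, nSamples = 26L, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nSamples <- assertCount(nSamples, "nSamples")
  genes <- geneCatalog()
  withSeed(seed, {
    sampleIds <- sprintf("C%03d", seq_len(nSamples))
    ## plant an exact count of deletions (round(rate * n)) so the fixture's
    ## group sizes are stable across seeds
    delMlh3 <- delPms2 <- rep(FALSE, nSamples)
    delMlh3[sample(nSamples, round(config@deletionRate * nSamples))] <- TRUE
    delPms2[sample(nSamples, round(0.4 * nSamples))] <- TRUE
    chroms <- unique(genes$chrom)
    chromLo <- vapply(chroms, function(ch)
      min(genes$start[genes$chrom == ch]) - 5e5L, numeric(1))
    chromHi <- vapply(chroms, function(ch)
      max(genes$end[genes$chrom == ch]) + 5e5L, numeric(1))
    colS <- list(); colC <- list(); colA <- list(); colB <- list()
    colL <- list()
    for (i in seq_len(nSamples)) {
      for (j in seq_along(chroms)) {
        lo <- chromLo[j]; hi <- chromHi[j]
        nb <- sample(2:4, 1)
        inner <- lo + 1e4 + sample.int(max(hi - lo - 2e4, nb), nb - 1L,
                                       useHash = TRUE)
        brk <- sort(c(lo, inner, hi))
        k <- length(colS) + 1L
        colS[[k]] <- rep(sampleIds[i], nb)
        colC[[k]] <- rep(chroms[j], nb)
        colA[[k]] <- as.integer(brk[-length(brk)] + c(0L, rep(1L, nb - 1L)))
        colB[[k]] <- as.integer(brk[-1])
        colL[[k]] <- stats::rnorm(nb, 0, 0.05)
      }
      for (g in c("MLH3", "PMS2")) {
        if ((g == "MLH3" && delMlh3[i]) || (g == "PMS2" && delPms2[i])) {
          row <- genes[genes$gene == g, ]
          k <- length(colS) + 1L
          colS[[k]] <- sampleIds[i]
          colC[[k]] <- row$chrom
          colA[[k]] <- as.integer(row$start - 1e4L)
          colB[[k]] <- as.integer(row$end + 1e4L)
          colL[[k]] <- stats::rnorm(1, -1, 0.15)
        }
      }
    }
    segments <- data.frame(sample = unlist(colS), chrom = unlist(colC),
                           start = unlist(colA), end = unlist(colB),
                           log2 = unlist(colL), stringsAsFactors = FALSE)
    segments$numMark <- pmax(10L, (segments$end - segments$start) %/% 5000L)
    segments <- segments[, c("sample", "chrom", "start", "end", "numMark",
                             "log2")]
    rownames(segments) <- NULL

    ## MMR exposures: attributed counts for a process active in every
    ## sample — gamma with CV 1/3 around the mean attributed count, shifted
    ## by deletionMmrShift population SDs in MLH3-deleted samples
    alpha <- config@exposureConcentration
    mmrIdx <- match("MMR", rownames(config@trueSignatures))
    if (is.na(mmrIdx)) mmrIdx <- min(2L, length(alpha))
    mmrMean <- config@snvsPerSample * alpha[mmrIdx] / sum(alpha)
    shape <- 9
    mmr <- stats::rgamma(nSamples, shape = shape,
                         scale = mmrMean / shape)
    baseSd <- mmrMean / sqrt(shape)
    mmr[delMlh3] <- mmr[delMlh3] + config@deletionMmrShift * baseSd
    names(mmr) <- sampleIds

    deleted <- cbind(MLH3 = delMlh3, PMS2 = delPms2)
    rownames(deleted) <- sampleIds
    list(segments = segments, deleted = deleted, mmrExposure = mmr,
         genes = genes[genes$gene %in% c("MLH3", "PMS2"), ])
  })
}

#' Simulate a protein-domain burden cohort
#'
#' Per-domain baseline mutation rates are drawn from a heavy-tailed gamma so
#' most domains are rarely hit; informative domains get an elevated rate and
#' contribute their configured log-odds per mutation to the case
#' probability. Labels are Bernoulli draws from the resulting logistic model,
#' with the intercept calibrated so the expected case fraction matches
#' `nCases / (nCases + nControls)`.
#'
#' @param config A [SimConfig-class]; `informativeDomains` carries the
#'   planted per-mutation log-odds (set it to an empty vector for a null
#'   cohort).
#' @param seed Seed; defaults to `config@seed`.
#' @return List with `burden` (samples x nDomains integer matrix), `labels`
#'   (factor, levels control/case), and `informativeDomains`.
#' @export
simulateDomainBurdenCohort <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nCases + config@nControls
  doms <- .domainIds(config@nDomains)
  info <- config@informativeDomains
  if (length(info) && !all(names(info) %in% doms))
    stop("informativeDomains ids outside the domain vocabulary",
         call. = FALSE)
  withSeed(seed, {
    lambda <- stats::rgamma(config@nDomains, shape = 0.4, rate = 20)
    names(lambda) <- doms
    if (length(info)) lambda[names(info)] <- 0.8
    burden <- matrix(stats::rpois(n * config@nDomains,
                                  rep(lambda, each = n)),
                     nrow = n, ncol = config@nDomains,
                     dimnames = list(sprintf("S%03d", seq_len(n)), doms))
    signal <- if (length(info))
      as.vector(burden[, names(info), drop = FALSE] %*% info)
    else rep(0, n)
    target <- if (n > 0) config@nCases / n else 0.5
    target <- min(max(target, 0.01), 0.99)
    a0 <- if (n > 0) {
      stats::uniroot(function(a) mean(stats::plogis(a + signal)) - target,
                     interval = c(-30, 30))$root
    } else 0
    labels <- factor(ifelse(stats::runif(n) < stats::plogis(a0 + signal),
                            "case", "control"),
                     levels = c("control", "case"))
    list(burden = burden, labels = labels, informativeDomains = info)
  })
}
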