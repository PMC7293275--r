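#' @import methods
NULL

setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' Simulation configuration for the synthetic benign-biopsy cohort
#'
#' Holds every knob of the synthetic-data generators. Defaults reproduce the
#' scale of the motivating case-control design: 135 cases and 69 controls,
#' somatic variant allele frequency (VAF) averaging 0.232 at a mean read depth
#' of 99, 180 somatic single-nucleotide variants per sample drawn from three
#' planted mutational signatures, and 1966 protein domains for the
#' burden-based risk model.
#'
#' @slot nCases,nControls Cohort sizes.
#' @slot seed Integer seed; together with the config it fully determines every
#'   generated dataset.
#' @slot somaticVafMean Target mean of the somatic VAF distribution.
#' @slot germlineVafModes Two modes (heterozygous, homozygous) of the germline
#'   VAF mixture.
#' @slot meanDepth Mean sequencing depth (negative-binomial).
#' @slot depthDispersion Negative-binomial size parameter for depth.
#' @slot snvsPerSample Somatic SNVs simulated per sample.
#' @slot indelsPerSample Somatic small indels simulated per sample.
#' @slot germlineSitesPool Number of polymorphic germline sites shared by the
#'   cohort.
#' @slot trueSignatures 3 x 96 matrix of planted signatures, rows summing to 1.
#' @slot exposureConcentration Dirichlet concentration of per-sample signature
#'   exposures (one value per signature).
#' @slot tnbcFraction Fraction of cases flagged as preceding triple-negative
#'   breast cancer (TNBC).
#' @slot tnbcOtnShift Log-scale multiplicative shift applied to the O/TN
#'   exposure weight of TNBC-flagged samples.
#' @slot pdwaFraction Fraction of samples with proliferative disease without
#'   atypia (PDWA) histology; the rest are non-proliferative (NP).
#' @slot nDomains Size of the protein-domain vocabulary.
#' @slot informativeDomains Named numeric vector of per-mutation log-odds
#'   contributed by each informative domain (names are domain ids).
#' @slot deletionRate Fraction of CNV-profiled samples carrying an MLH3
#'   deletion.
#' @slot deletionMmrShift Upward shift (in within-group standard deviations)
#'   of the mismatch-repair signature exposure in deleted samples.
#' @slot arrayErrorRate Probability that a genotyping-array call is flipped to
#'   a wrong genotype state.
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimConfig", representation(
  nCases = "integer",
  nControls = "integer",
  seed = "integer",
  somaticVafMean = "numeric",
  germlineVafModes = "numeric",
  meanDepth = "numeric",
  depthDispersion = "numeric",
  snvsPerSample = "integer",
  indelsPerSample = "integer",
  germlineSitesPool = "integer",
  trueSignatures = "matrix",
  exposureConcentration = "numeric",
  tnbcFraction = "numeric",
  tnbcOtnShift = "numeric",
  pdwaFraction = "numeric",
  nDomains = "integer",
  informativeDomains = "numeric",
  deletionRate = "numeric",
  deletionMmrShift = "numeric",
  arrayErrorRate = "numeric"
))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nCases < 0L || object@nControls < 0L)
    msgs <- c(msgs, "nCases and nControls must be >= 0")
  for (f in c("somaticVafMean", "tnbcFraction", "pdwaFraction",
              "deletionRate", "arrayErrorRate")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must be a single fraction in [0, 1]", f))
  }
  if (length(object@germlineVafModes) != 2L ||
      any(object@germlineVafModes < 0 | object@germlineVafModes > 1))
    msgs <- c(msgs, "germlineVafModes must be two fractions in [0, 1]")
  if (object@meanDepth <= 0)
    msgs <- c(msgs, "meanDepth must be positive")
  H <- object@trueSignatures
  if (ncol(H) != 96L)
    msgs <- c(msgs, "trueSignatures must have 96 columns")
  else {
    if (any(H < 0)) msgs <- c(msgs, "trueSignatures must be nonnegative")
    if (any(abs(rowSums(H) - 1) > 1e-9))
      msgs <- c(msgs, "each trueSignatures row must sum to 1 (tol 1e-9)")
  }
  if (length(object@exposureConcentration) != nrow(H))
    msgs <- c(msgs,
              "exposureConcentration needs one value per signature row")
  if (any(object@exposureConcentration <= 0))
    msgs <- c(msgs, "exposureConcentration values must be positive")
  if (length(object@informativeDomains) &&
      anyDuplicated(names(object@informativeDomains)))
    msgs <- c(msgs, "informativeDomains has duplicate domain ids")
  if (length(object@informativeDomains) > object@nDomains)
    msgs <- c(msgs, "more informative domains than nDomains")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param nCases,nControls Cohort sizes (defaults 135/69).
#' @param seed Integer seed.
#' @param somaticVafMean Mean somatic VAF (default 0.232).
#' @param germlineVafModes Heterozygous/homozygous germline VAF modes
#'   (default `c(0.5, 0.97)`).
#' @param meanDepth Mean read depth (default 99).
#' @param depthDispersion Negative-binomial size (default 8).
#' @param snvsPerSample Somatic SNVs per sample (default 180).
#' @param indelsPerSample Somatic indels per sample (default 11).
#' @param germlineSitesPool Polymorphic germline site pool size (default 600).
#' @param trueSignatures Planted signature matrix (default
#'   [defaultSignatures()]).
#' @param exposureConcentration Dirichlet concentration (default
#'   `c(2, 1.2, 0.8)`: skewed, strongly dispersed per-sample signature
#'   activities, as seen in real cohorts).
#' @param tnbcFraction Fraction of cases flagged TNBC (default 0.17).
#' @param tnbcOtnShift O/TN exposure log-shift in TNBC samples (default 1).
#' @param pdwaFraction PDWA histology fraction (default 76/195).
#' @param nDomains Protein-domain vocabulary size (default 1966).
#' @param informativeDomains Named log-odds vector (default: five domains at
#'   log-odds 1).
#' @param deletionRate MLH3 deletion rate in the CNV subset (default 0.3).
#' @param deletionMmrShift MMR-exposure shift in deleted samples, in SD units
#'   (default 2).
#' @param arrayErrorRate Genotyping-array error rate (default 0.15).
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
simConfig <- function(nCases = 135L, nControls = 69L, seed = 1L,
                      somaticVafMean = 0.232,
                      germlineVafModes = c(0.5, 0.97),
                      meanDepth = 99, depthDispersion = 8,
                      snvsPerSample = 180L, indelsPerSample = 11L,
                      germlineSitesPool = 600L,
                      trueSignatures = defaultSignatures(),
                      exposureConcentration = c(2, 1.2, 0.8),
                      tnbcFraction = 0.17, tnbcOtnShift = 1,
                      pdwaFraction = 76 / 195,
                      nDomains = 1966L,
                      informativeDomains = stats::setNames(
                        rep(1, 5), sprintf("DOM%04d", 1:5)),
                      deletionRate = 0.3, deletionMmrShift = 2,
                      arrayErrorRate = 0.15) {
  new("SimConfig",
      nCases = assertCount(nCases, "nCases"),
      nControls = assertCount(nControls, "nControls"),
      seed = as.integer(seed),
      somaticVafMean = somaticVafMean,
      germlineVafModes = germlineVafModes,
      meanDepth = meanDepth,
      depthDispersion = depthDispersion,
      snvsPerSample = assertCount(snvsPerSample, "snvsPerSample"),
      indelsPerSample = assertCount(indelsPerSample, "indelsPerSample"),
      germlineSitesPool = assertCount(germlineSitesPool, "germlineSitesPool"),
      trueSignatures = trueSignatures,
      exposureConcentration = exposureConcentration,
      tnbcFraction = tnbcFraction,
      tnbcOtnShift = tnbcOtnShift,
      pdwaFraction = pdwaFraction,
      nDomains = assertCount(nDomains, "nDomains", positive = TRUE),
      informativeDomains = informativeDomains,
      deletionRate = deletionRate,
      deletionMmrShift = deletionMmrShift,
      arrayErrorRate = arrayErrorRate)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCases, "cases /", object@nControls,
      "controls, seed", object@seed, "\n")
  cat("  somatic VAF mean", object@somaticVafMean,
      "| depth", object@meanDepth,
      "|", object@snvsPerSample, "SNVs/sample\n")
  cat("  ", nrow(object@trueSignatures), "planted signatures; ",
      object@nDomains, " domains (", length(object@informativeDomains),
      " informative)\n", sep = "")
})

#' Mutation catalog: samples x 96 trinucleotide channel counts
#'
#' A nonnegative integer matrix of per-sample counts over the 96
#' pyrimidine-centered substitution channels, in the order given by
#' [sbsChannels()].
#'
#' @slot counts samples x 96 integer matrix; rownames are sample ids.
#' @seealso [buildCatalog()], [simulateCatalogs()], [catalogCounts()]
#' @export
setClass("MutationCatalog", representation(counts = "matrix"))

setValidity("MutationCatalog", function(object) {
  m <- object@counts
  msgs <- character(0)
  if (ncol(m) != 96L) msgs <- c(msgs, "counts must have 96 columns")
  if (!identical(colnames(m), sbsChannels()))
    msgs <- c(msgs, "counts columns must be sbsChannels() in order")
  if (any(m < 0)) msgs <- c(msgs, "counts must be nonnegative")
  if (any(m != round(m))) msgs <- c(msgs, "counts must be integers")
  if (nrow(m) > 0L && is.null(rownames(m)))
    msgs <- c(msgs, "counts must have sample rownames")
  if (length(msgs)) msgs else TRUE
})

#' Create a MutationCatalog from a counts matrix
#'
#' @param counts samples x 96 nonnegative integer matrix with sample rownames;
#'   columns must be the 96 channels of [sbsChannels()] (reordered if named).
#' @return A [MutationCatalog-class].
#' @export
MutationCatalog <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts)) &&
      setequal(colnames(counts), sbsChannels())) {
    counts <- counts[, sbsChannels(), drop = FALSE]
  } else {
    colnames(counts) <- sbsChannels()
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  storage.mode(counts) <- "double"
  new("MutationCatalog", counts = counts)
}

#' @describeIn MutationCatalog-class Extract the counts matrix.
#' @param object A `MutationCatalog`.
#' @export
setGeneric("catalogCounts", function(object) standardGeneric("catalogCounts"))

#' @rdname MutationCatalog-class
#' @export
setMethod("catalogCounts", "MutationCatalog", function(object) object@counts)

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog:", nrow(object@counts), "samples x 96 channels,",
      sum(object@counts), "mutations total\n")
})

setMethod("dim", "MutationCatalog", function(x) dim(x@counts))

#' Extracted signature set
#'
#' Result of non-negative matrix factorization of a [MutationCatalog-class]:
#' `H` (k x 96) holds the signature profiles with rows normalized to sum 1,
#' and `W` (samples x k) the per-sample attributed mutation counts
#' ("exposures"), rescaled so that `W %*% H` is unchanged by the
#' normalization.
#'
#' @slot W samples x k exposure matrix.
#' @slot H k x 96 signature matrix, rows summing to 1.
#' @slot rank The factorization rank k.
#' @slot rss Named numeric of residual sums of squares per candidate rank
#'   (filled by [selectRank()]), or the final reconstruction RSS.
#' @slot seed Seed used for the restarts.
#' @seealso [extractSignatures()], [selectRank()], [matchSignatures()]
#' @export
setClass("SignatureSet", representation(
  W = "matrix", H = "matrix", rank = "integer",
  rss = "numeric", seed = "integer"))

setValidity("SignatureSet", function(object) {
  msgs <- character(0)
  if (any(object@W < 0) || any(object@H < 0))
    msgs <- c(msgs, "W and H must be nonnegative")
  if (ncol(object@W) != nrow(object@H))
    msgs <- c(msgs, "ncol(W) must equal nrow(H)")
  if (nrow(object@H) != object@rank)
    msgs <- c(msgs, "nrow(H) must equal rank")
  if (nrow(object@H) &&
      any(abs(rowSums(object@H) - 1) > 1e-9))
    msgs <- c(msgs, "H rows must sum to 1 (tol 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SignatureSet-class Signature matrix H (k x 96, rows sum to 1).
#' @param object A `SignatureSet`.
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))

#' @rdname SignatureSet-class
#' @export
setMethod("signatures", "SignatureSet", function(object) object@H)

#' @describeIn SignatureSet-class Exposure matrix W (samples x k, attributed
#'   counts).
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))

#' @rdname SignatureSet-class
#' @export
setMethod("exposures", "SignatureSet", function(object) object@W)

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet: rank", object@rank, "|", nrow(object@W), "samples\n")
  cat("  reconstruction RSS:",
      format(object@rss[length(object@rss)], digits = 6), "\n")
})

#' Panel of normals
#'
#' A blacklist of variant sites observed in at least two of the contributing
#' normal samples, used to remove recurrent artifacts and common germline
#' sites from tumor-only calls.
#'
#' @slot sites Character vector of `chrom:pos:ref:alt` site keys.
#' @slot nNormals Number of contributing normal call sets.
#' @seealso [buildPon()], [applyPon()]
#' @export
setClass("PanelOfNormals",
         representation(sites = "character", nNormals = "integer"))

setMethod("show", "PanelOfNormals", function(object) {
  cat("PanelOfNormals:", length(object@sites), "sites from",
      object@nNormals, "normals\n")
})

#' @describeIn PanelOfNormals-class Number of blacklisted sites.
#' @param x A `PanelOfNormals`.
#' @export
setMethod("length", "PanelOfNormals", function(x) length(x@sites))

#' @describeIn PanelOfNormals-class Site keys (`chrom:pos:ref:alt`).
#' @param object A `PanelOfNormals`.
#' @export
setGeneric("ponSites", function(object) standardGeneric("ponSites"))

#' @rdname PanelOfNormals-class
#' @export
setMethod("ponSites", "PanelOfNormals", function(object) object@sites)
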