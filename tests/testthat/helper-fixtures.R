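## Shared fixtures, built in code at test time.

siteKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

tinyConfig <- function(seed = 1L, ...) {
  simConfig(nCases = 6L, nControls = 3L, seed = seed,
            germlineSitesPool = 120L, snvsPerSample = 60L,
            indelsPerSample = 4L, ...)
}

## Minimal hand-built variant table (no simulator involved).
handVariants <- function() {
  data.frame(
    sample = c("S1", "S1", "S2", "S2", "S2"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 200L, 100L, 50L, 60L),
    ref = c("C", "T", "C", "G", "A"),
    alt = c("T", "G", "T", "A", "AT"),
    vaf = c(0.48, 0.2, 0.51, 0.95, 0.3),
    altDepth = c(48L, 10L, 51L, 95L, 15L),
    refDepth = c(52L, 40L, 49L, 5L, 35L),
    totalDepth = c(100L, 50L, 100L, 100L, 50L),
    gene = c("MLH1", "PIK3CA", "MLH1", "GENE01", "MLH3"),
    proteinChange = c("p.S100T", "p.H1047R", "p.S100T", NA, NA),
    class = c("missense", "missense", "missense", "silent",
              "frameshift_insertion"),
    context = c("ACA", "TTC", "ACA", "TGA", NA),
    populationAf = c(0.3, 0, 0.3, 0.4, 0),
    dbsnpCommon = c(1L, 0L, 1L, 1L, 0L),
    cosmicCount = c(0L, 120L, 0L, 0L, 0L),
    sift = c(0.2, 0.9, 0.25, NA, 0.5),
    polyphen = c(0.1, 0.95, 0.2, 0.3, NA),
    cadd = c(2, 9, 2.5, 1, 5),
    gerp = c(1, 4, 1.2, 0.5, 2),
    phylop = c(0.5, 2, 0.6, 0.2, 1),
    revel = c(0.1, 0.9, 0.15, 0.2, 0.6),
    domain = c("DOM0001", "DOM0002,DOM0003", "DOM0001", NA, NA),
    label = c("germline", "somatic", "germline", "germline", "somatic"),
    stringsAsFactors = FALSE)
}

## Exact enumeration oracle for the two-sided 2x2 test: sum of hypergeometric
## probabilities not exceeding the observed one (with the conventional
## relative tolerance for floating-point ties).
enumExactP <- function(a, b, c_, d) {
  n1 <- a + b; r1 <- a + c_
  ks <- max(0L, r1 - (c_ + d)):min(n1, r1)
  probs <- stats::dhyper(ks, n1, c_ + d, r1)
  obs <- stats::dhyper(a, n1, c_ + d, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Independent rank-based AUC (Wilcoxon) oracle.
rankAuc <- function(scores, isCase) {
  r <- rank(scores)
  n1 <- sum(isCase); n0 <- sum(!isCase)
  (sum(r[isCase]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
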