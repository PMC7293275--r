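## WES-vs-genotyping-array concordance with an allele-frequency
## discrepancy allowance.

.sharedSites <- function(wes, array) {
  requireColumns(wes, c("sample", "chrom", "pos", "ref", "alt"),
                 "WES table")
  requireColumns(array, c("sample", "chrom", "pos", "ref", "alt", "arrayAf"),
                 "array table")
  wesAf <- if ("vaf" %in% names(wes)) wes$vaf else wes$wesAf
  if (is.null(wesAf))
    stop("WES table needs a 'vaf' (or 'wesAf') column", call. = FALSE)
  wk <- variantKey(wes$sample, wes$chrom, wes$pos, wes$ref, wes$alt)
  ak <- variantKey(array$sample, array$chrom, array$pos, array$ref,
                   array$alt)
  idx <- match(wk, ak)
  keep <- !is.na(idx)
  data.frame(sample = wes$sample[keep], wesAf = wesAf[keep],
             arrayAf = array$arrayAf[idx[keep]], stringsAsFactors = FALSE)
}

#' Platform overlap rate at a given discrepancy allowance
#'
#' Over the sites present on both platforms (matched on sample, chrom, pos,
#' ref, alt), returns the fraction whose absolute allele-frequency difference
#' is within the allowance. The boundary is inclusive, so an allowance of
#' 0.25 admits a discrepancy of exactly 0.25.
#'
#' @param wes Variant table with a `vaf` column.
#' @param array Array call table with an `arrayAf` column
#'   (values in \{0, 0.5, 1\}).
#' @param allowance Allele-frequency discrepancy allowance in [0, 1].
#' @return The overlap rate (fraction in [0, 1]); attribute `nShared` holds
#'   the shared-site count.
#' @export
overlapRate <- function(wes, array, allowance) {
  assertFraction(allowance, "allowance")
  shared <- .sharedSites(wes, array)
  if (nrow(shared) == 0L)
    stop("no sites shared between the two platforms; overlap rate undefined",
         call. = FALSE)
  rate <- mean(abs(shared$wesAf - shared$arrayAf) <= allowance + 1e-12)
  attr(rate, "nShared") <- nrow(shared)
  rate
}

#' Concordance curve over a grid of discrepancy allowances
#'
#' @param wes,array As in [overlapRate()].
#' @param grid Ascending vector of allowances (default `seq(0, 1, 0.05)`).
#' @param perSample Also compute per-sample overlap rates at each allowance
#'   (default TRUE; pooled rates remain the primary output).
#' @return data.frame of class `ConcordanceCurve` with columns `allowance`
#'   and `rate`; attributes `nShared` and (optionally) `perSample`.
#' @export
allowanceSweep <- function(wes, array, grid = seq(0, 1, by = 0.05),
                           perSample = TRUE) {
  if (is.unsorted(grid))
    stop("'grid' must be sorted ascending", call. = FALSE)
  shared <- .sharedSites(wes, array)
  if (nrow(shared) == 0L)
    stop("no sites shared between the two platforms", call. = FALSE)
  d <- abs(shared$wesAf - shared$arrayAf)
  rate <- vapply(grid, function(a) mean(d <= a + 1e-12), numeric(1))
  out <- data.frame(allowance = grid, rate = rate)
  class(out) <- c("ConcordanceCurve", "data.frame")
  attr(out, "nShared") <- nrow(shared)
  if (perSample) {
    bySample <- vapply(grid, function(a)
      tapply(d <= a + 1e-12, shared$sample, mean),
      numeric(length(unique(shared$sample))))
    attr(out, "perSample") <- bySample
  }
  out
}

#' Write a concordance curve as CSV
#' @param curve A `ConcordanceCurve`.
#' @param path Output path.
#' @export
writeConcordanceCurve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
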