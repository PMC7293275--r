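## Gene-level deletion calls from copy-number segment tables and their
## association with signature exposures and mutation status.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges reduce findOverlaps pintersect width
#' @importFrom S4Vectors queryHits subjectHits
NULL

.MMR_GENES <- c("MLH1", "MLH3", "MSH2", "MSH3", "MSH6", "PMS2", "MUTYH",
                "MYH11", "SETD2", "TGFBR2")

#' Call gene-level deletions from segment tables
#'
#' A gene is called deleted in a sample when at least `minOverlap` of its
#' interval is covered by segments whose log2 copy ratio is at or below
#' `log2Threshold`. Coordinates are 1-based inclusive (SEG convention); the
#' call is invariant to segment ordering and to splitting segments into
#' contiguous pieces of equal ratio.
#'
#' @param segments data.frame with `sample`, `chrom`, `start`, `end`,
#'   `log2` columns.
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` columns.
#' @param log2Threshold Deletion log2 ratio cutoff (default -0.3).
#' @param minOverlap Minimum covered fraction of the gene (default 0.5).
#' @return samples x genes logical matrix.
#' @export
callGeneDeletion <- function(segments, genes, log2Threshold = -0.3,
                             minOverlap = 0.5) {
  requireColumns(segments, c("sample", "chrom", "start", "end", "log2"),
                 "segment table")
  requireColumns(genes, c("gene", "chrom", "start", "end"), "gene table")
  if (any(!is.finite(segments$log2)))
    stop("segment log2 ratios must be finite", call. = FALSE)
  if (any(segments$start > segments$end))
    stop("segment start > end", call. = FALSE)
  unknown <- setdiff(unique(genes$chrom), unique(segments$chrom))
  if (length(unknown) == length(unique(genes$chrom)))
    stop("no segment chromosome matches the gene catalog; unknown: ",
         paste(unique(segments$chrom), collapse = ", "), call. = FALSE)
  samples <- unique(segments$sample)
  geneGr <- GRanges(genes$chrom, IRanges(genes$start, genes$end))
  out <- matrix(FALSE, length(samples), nrow(genes),
                dimnames = list(samples, genes$gene))
  del <- segments[segments$log2 <= log2Threshold, , drop = FALSE]
  if (nrow(del) == 0L) return(out)
  gr <- GRanges(del$chrom, IRanges(del$start, del$end))
  ## reduce per sample so split/piecewise segments merge before coverage
  grl <- reduce(S4Vectors::split(gr, factor(del$sample)))
  flat <- unlist(grl)
  segSample <- rep(names(grl), lengths(grl))
  hits <- findOverlaps(geneGr, flat)
  if (!length(hits)) return(out)
  w <- width(pintersect(geneGr[queryHits(hits)], flat[subjectHits(hits)]))
  covered <- tapply(w, list(gene = queryHits(hits),
                            sample = segSample[subjectHits(hits)]), sum)
  geneIdx <- as.integer(rownames(covered))
  for (r in seq_len(nrow(covered))) {
    frac <- covered[r, ] / width(geneGr)[geneIdx[r]]
    ok <- !is.na(frac) & frac >= minOverlap
    out[colnames(covered)[ok], geneIdx[r]] <- TRUE
  }
  out
}

#' Association between gene deletion status and a signature exposure
#'
#' Delegates to [exposureGroupTest()]: a two-sided Welch test of the
#' exposure between deleted and non-deleted samples, with per-group means
#' and 95% confidence intervals.
#'
#' @param deleted Logical deletion-status vector (one gene's column of the
#'   deletion matrix).
#' @param exposure Numeric signature exposure per sample, same order.
#' @return As [exposureGroupTest()], plus `nDeleted`.
#' @export
deletionSignatureAssociation <- function(deleted, exposure) {
  if (length(unique(deleted)) < 2L)
    stop("deletion status is constant; association undefined",
         call. = FALSE)
  res <- exposureGroupTest(exposure,
                           factor(deleted, levels = c(FALSE, TRUE),
                                  labels = c("intact", "deleted")))
  res$nDeleted <- sum(deleted)
  res
}

#' Per-sample deleterious mismatch-repair-gene mutation summary
#'
#' Flags samples carrying at least one deleterious mutation (truncating
#' classes, or missense predicted damaging by a score column) in any of the
#' listed mismatch-repair-associated genes.
#'
#' @param variants Variant table with `sample`, `gene`, `class` columns.
#' @param genes Gene list (default: the mismatch-repair-associated set
#'   MLH1, MLH3, MSH2, MSH3, MSH6, PMS2, MUTYH, MYH11, SETD2, TGFBR2).
#' @param deleteriousClasses Truncating classes counted as deleterious.
#' @param damagingScore Column used to call damaging missense (default
#'   `"revel"`); missense records with score >= `damagingThreshold` count.
#' @param damagingThreshold Default 0.5.
#' @return List with `flagged` (named logical per sample) and `perGene`
#'   (deleterious mutation count per gene).
#' @export
mmrGeneMutationSummary <- function(variants, genes = .MMR_GENES,
                                   deleteriousClasses =
                                     c("nonsense", "frameshift_insertion",
                                       "frameshift_deletion", "stop_gain",
                                       "splice_site"),
                                   damagingScore = "revel",
                                   damagingThreshold = 0.5) {
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  requireColumns(variants, c("sample", "gene", "class"))
  inGenes <- variants$gene %in% genes
  trunc <- variants$class %in% deleteriousClasses
  damMis <- variants$class == "missense" &
    damagingScore %in% names(variants) &
    !is.na(variants[[damagingScore]]) &
    variants[[damagingScore]] >= damagingThreshold
  hit <- inGenes & (trunc | damMis)
  samples <- unique(variants$sample)
  flagged <- stats::setNames(samples %in% variants$sample[hit], samples)
  perGene <- table(factor(variants$gene[hit], levels = genes))
  list(flagged = flagged, perGene = perGene)
}

#' Write a segment table in SEG format
#' @param segments data.frame with `sample`, `chrom`, `start`, `end`,
#'   `numMark`, `log2`.
#' @param path Output path.
#' @export
writeSeg <- function(segments, path) {
  requireColumns(segments, c("sample", "chrom", "start", "end", "numMark",
                             "log2"), "segment table")
  out <- segments[, c("sample", "chrom", "start", "end", "numMark", "log2")]
  names(out) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                  "seg.mean")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SEG-format segment table
#' @param path SEG file path.
#' @return data.frame with `sample`, `chrom`, `start`, `end`, `numMark`,
#'   `log2`.
#' @export
readSeg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("SEG file needs 6 columns", call. = FALSE)
  names(df)[1:6] <- c("sample", "chrom", "start", "end", "numMark", "log2")
  df
}
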