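## Case-control and subgroup mutation-enrichment statistics with FDR
## control.

.NONSILENT <- c("missense", "nonsense", "frameshift_insertion",
                "frameshift_deletion", "stop_gain", "splice_site")

## Exact two-sided test for a 2x2 table (the degenerate-case fallback).
.exactTestP <- function(tab) stats::fisher.test(tab)$p.value

## Two-group association p-value for a binary exposure: logistic Wald by
## default, exact fallback whenever the 2x2 table has a zero cell or the
## fit separates.
.caseControlP <- function(mutated, isCase) {
  a <- sum(mutated & isCase); b <- sum(!mutated & isCase)
  c_ <- sum(mutated & !isCase); d <- sum(!mutated & !isCase)
  tab <- matrix(c(a, c_, b, d), 2)
  if (any(tab == 0))
    return(list(p = .exactTestP(tab), method = "fisher"))
  fit <- suppressWarnings(stats::glm(isCase ~ mutated,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  if (!fit$converged || sm["mutatedTRUE", "Std. Error"] > 100)
    return(list(p = .exactTestP(tab), method = "fisher"))
  list(p = sm["mutatedTRUE", "Pr(>|z|)"], method = "wald")
}

#' Per-gene case-control mutation enrichment
#'
#' For each gene, tests association of mutation status with case/control by
#' logistic regression (Wald p); a two-sided Fisher exact test replaces it
#' automatically when the 2x2 table has a zero cell or the fit separates.
#' Results are Benjamini-Hochberg adjusted across genes and sorted by p.
#'
#' @param mutations samples x genes matrix of mutation counts (or 0/1
#'   indicators), rownames = samples.
#' @param labels case/control labels per sample (factor or character;
#'   "case" is the positive group).
#' @param geneLengthsKb Optional named vector of coding lengths in kb, used
#'   for length-adjusted rates (mutations per sample per kb).
#' @return data.frame of class `GeneTestResult` with columns `gene`,
#'   `nCase`, `nControl`, `fracCase`, `fracControl`, `direction`, `p`,
#'   `log10p`, `q`, `method`, `rateCaseKb`, `rateControlKb`; genes mutated
#'   in no sample are excluded (attribute `excluded`).
#' @export
perGeneCaseControl <- function(mutations, labels, geneLengthsKb = NULL) {
  mutations <- as.matrix(mutations)
  isCase <- as.character(labels) == "case"
  if (length(isCase) != nrow(mutations))
    stop("labels length must match mutation matrix rows", call. = FALSE)
  mutatedAny <- colSums(mutations > 0) > 0
  excluded <- colnames(mutations)[!mutatedAny]
  genes <- colnames(mutations)[mutatedAny]
  rows <- lapply(genes, function(g) {
    mut <- mutations[, g] > 0
    pv <- .caseControlP(mut, isCase)
    fracCase <- mean(mut[isCase])
    fracCtrl <- mean(mut[!isCase])
    kb <- if (!is.null(geneLengthsKb)) unname(geneLengthsKb[g]) else NA_real_
    data.frame(
      gene = g,
      nCase = sum(mut & isCase), nControl = sum(mut & !isCase),
      fracCase = fracCase, fracControl = fracCtrl,
      direction = ifelse(fracCase >= fracCtrl, "case", "control"),
      p = pv$p, log10p = log10(pv$p), method = pv$method,
      rateCaseKb = if (!is.na(kb))
        sum(mutations[isCase, g]) / (sum(isCase) * kb) else NA_real_,
      rateControlKb = if (!is.na(kb))
        sum(mutations[!isCase, g]) / (sum(!isCase) * kb) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhFdr(out$p)
  out <- out[order(out$p), c("gene", "nCase", "nControl", "fracCase",
                             "fracControl", "direction", "p", "log10p",
                             "q", "method", "rateCaseKb", "rateControlKb")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("GeneTestResult", "data.frame")
  out
}

#' Subgroup (e.g. PDWA vs NP) enrichment at gene or hotspot level
#'
#' At `level = "gene"` variants are grouped per gene; at `level = "hotspot"`
#' per (gene, protein change). For each unit the per-subgroup carrier
#' proportions and a two-sided p (same logistic/exact policy as
#' [perGeneCaseControl()]) are reported, BH-adjusted.
#'
#' @param variants Variant table with `sample`, `gene`, `class`, and (for
#'   hotspot level) `proteinChange` columns.
#' @param subgroups Named vector/factor of subgroup labels per sample (two
#'   levels, e.g. PDWA/NP); names are sample ids.
#' @param level `"gene"` or `"hotspot"`.
#' @param nonsynonymousOnly Drop silent variants first (default TRUE).
#' @return data.frame with unit, per-subgroup counts/proportions, `p`, `q`;
#'   attribute `nUnparseable` counts hotspot records without a usable
#'   protein change.
#' @export
subgroupEnrichment <- function(variants, subgroups,
                               level = c("gene", "hotspot"),
                               nonsynonymousOnly = TRUE) {
  level <- match.arg(level)
  requireColumns(variants, c("sample", "gene", "class"))
  if (is.null(names(subgroups)))
    stop("'subgroups' must be named by sample id", call. = FALSE)
  g <- droplevels(as.factor(subgroups))
  if (nlevels(g) != 2L)
    stop("'subgroups' must have exactly two levels", call. = FALSE)
  lev <- levels(g)
  if (nonsynonymousOnly)
    variants <- variants[variants$class %in% .NONSILENT, , drop = FALSE]
  nUnparseable <- 0L
  if (level == "hotspot") {
    requireColumns(variants, "proteinChange")
    ok <- !is.na(variants$proteinChange) & nzchar(variants$proteinChange)
    nUnparseable <- sum(!ok)
    variants <- variants[ok, , drop = FALSE]
    variants$unit <- paste0(variants$gene, " ", variants$proteinChange)
  } else variants$unit <- variants$gene
  variants <- variants[variants$sample %in% names(subgroups), ,
                       drop = FALSE]
  units <- unique(variants$unit)
  rows <- lapply(units, function(u) {
    carriers <- unique(variants$sample[variants$unit == u])
    mut <- names(subgroups) %in% carriers
    isA <- g == lev[1]
    pv <- .caseControlP(mut, isA)
    data.frame(unit = u,
               n1 = sum(mut & isA), n2 = sum(mut & !isA),
               prop1 = mean(mut[isA]), prop2 = mean(mut[!isA]),
               p = pv$p, method = pv$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit = character(0), n1 = integer(0), n2 = integer(0),
                      prop1 = numeric(0), prop2 = numeric(0), p = numeric(0),
                      method = character(0))
  names(out)[names(out) == "n1"] <- paste0("n_", lev[1])
  names(out)[names(out) == "n2"] <- paste0("n_", lev[2])
  names(out)[names(out) == "prop1"] <- paste0("prop_", lev[1])
  names(out)[names(out) == "prop2"] <- paste0("prop_", lev[2])
  out$q <- if (nrow(out)) bhFdr(out$p) else numeric(0)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "nUnparseable") <- nUnparseable
  out
}

#' Serine/threonine gain-loss accounting for a gene's missense mutations
#'
#' Parses protein changes of the form `p.S100T` and reports the fractions of
#' missense mutations producing loss of serine, loss of threonine, gain of
#' serine and gain of threonine (a Ser-to-Thr change counts as both a serine
#' loss and a threonine gain), plus a per-category exact-test comparison of
#' case versus control counts when group labels are supplied.
#'
#' @param variants Missense variant records of one gene with a
#'   `proteinChange` column (non-missense input is an error).
#' @param groups Optional case/control label per record.
#' @return List with `fractions` (named: lossSer, lossThr, gainSer,
#'   gainThr), `n` (parseable missense count), `nUnparseable`, and — with
#'   groups — `p` (named per category, Fisher exact).
#' @export
serThrAccounting <- function(variants, groups = NULL) {
  requireColumns(variants, c("class", "proteinChange"))
  if (any(variants$class != "missense"))
    stop("serThrAccounting expects missense records only", call. = FALSE)
  m <- regmatches(variants$proteinChange,
                  regexec("^p\\.([A-Z])([0-9]+)([A-Z])$",
                          variants$proteinChange))
  parsed <- lengths(m) == 4L
  refAA <- vapply(m[parsed], `[`, character(1), 2)
  altAA <- vapply(m[parsed], `[`, character(1), 4)
  cat4 <- cbind(lossSer = refAA == "S" & altAA != "S",
                lossThr = refAA == "T" & altAA != "T",
                gainSer = altAA == "S" & refAA != "S",
                gainThr = altAA == "T" & refAA != "T")
  n <- sum(parsed)
  fractions <- if (n) colMeans(cat4) else
    stats::setNames(rep(NA_real_, 4), colnames(cat4))
  out <- list(fractions = fractions, n = n,
              nUnparseable = sum(!parsed))
  if (!is.null(groups) && n) {
    grp <- droplevels(as.factor(groups[parsed]))
    if (nlevels(grp) == 2L) {
      out$p <- apply(cat4, 2, function(hit)
        stats::fisher.test(table(factor(hit, c(FALSE, TRUE)),
                                 grp))$p.value)
    }
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
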