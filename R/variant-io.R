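## Variant input/output, hard filters, and classifier feature assembly.

.SIDECAR_COLS <- c("sample", "chrom", "pos", "ref", "alt", "vaf", "altDepth",
                   "refDepth", "totalDepth", "gene", "proteinChange", "class",
                   "context", "populationAf", "dbsnpCommon", "cosmicCount",
                   "sift", "polyphen", "cadd", "gerp", "phylop", "revel",
                   "domain")

#' Write a variant table as per-sample VCF 4.2 plus a feature sidecar
#'
#' The VCF carries site coordinates and depth/allele-frequency INFO fields;
#' all annotation features travel in a single sidecar CSV keyed by
#' (sample, chrom, pos, ref, alt).
#'
#' @param variants Variant table as produced by [simulateVariantCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `vcf` (named vector of per-sample VCF
#'   paths) and `sidecar` (CSV path).
#' @export
writeVariantVcf <- function(variants, dir) {
  requireColumns(variants, c("sample", "chrom", "pos", "ref", "alt", "vaf",
                             "totalDepth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(variants$sample)
  paths <- character(0)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (s in samples) {
    v <- variants[variants$sample == s, ]
    v <- v[order(v$chrom, v$pos, v$ref, v$alt), ]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s",
                    v$chrom, v$pos, v$ref, v$alt, v$totalDepth,
                    format(v$vaf, digits = 6, trim = TRUE,
                           scientific = FALSE))
    p <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c(header, body), p)
    paths[s] <- p
  }
  sidecar <- file.path(dir, "features.csv")
  keep <- intersect(.SIDECAR_COLS, names(variants))
  utils::write.csv(variants[, keep], sidecar, row.names = FALSE)
  invisible(list(vcf = paths, sidecar = sidecar))
}

#' Read variants from VCF 4.2 plus a feature sidecar
#'
#' Multi-allelic records are split into one row per ALT allele; coordinates
#' stay 1-based throughout. Records are joined to the sidecar CSV on
#' (sample, chrom, pos, ref, alt); VCF records with no sidecar row abort
#' with the orphan keys listed.
#'
#' @param vcfPaths Named character vector of per-sample VCF paths (names are
#'   sample ids; unnamed paths use the file basename).
#' @param sidecarPath Path to the feature sidecar CSV.
#' @return A variant table (data.frame) in sidecar column order.
#' @export
readVariants <- function(vcfPaths, sidecarPath) {
  if (!all(file.exists(vcfPaths)))
    stop("missing VCF file(s): ",
         paste(vcfPaths[!file.exists(vcfPaths)], collapse = ", "),
         call. = FALSE)
  if (!file.exists(sidecarPath))
    stop("missing sidecar: ", sidecarPath, call. = FALSE)
  if (is.null(names(vcfPaths)))
    names(vcfPaths) <- sub("\\.vcf$", "", basename(vcfPaths))
  recs <- lapply(names(vcfPaths), function(s) {
    v <- vcfR::read.vcfR(vcfPaths[[s]], verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops to vector
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(NULL)
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(fix)), lengths(alts))
    data.frame(sample = s, chrom = fix$CHROM[idx],
               pos = as.integer(fix$POS[idx]), ref = fix$REF[idx],
               alt = unlist(alts), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, recs)
  sidecar <- utils::read.csv(sidecarPath, stringsAsFactors = FALSE)
  requireColumns(sidecar, c("sample", "chrom", "pos", "ref", "alt"),
                 "feature sidecar")
  ck <- variantKey(calls$sample, calls$chrom, calls$pos, calls$ref,
                   calls$alt)
  sk <- variantKey(sidecar$sample, sidecar$chrom, sidecar$pos, sidecar$ref,
                   sidecar$alt)
  orphans <- setdiff(ck, sk)
  if (length(orphans))
    stop("VCF records missing from sidecar: ",
         paste(utils::head(orphans, 5), collapse = "; "),
         if (length(orphans) > 5) sprintf(" (+%d more)", length(orphans) - 5),
         call. = FALSE)
  out <- sidecar[match(ck, sk), ]
  rownames(out) <- NULL
  out
}

#' Build a panel of normals
#'
#' Pools variant sites across normal call sets and keeps the sites observed
#' in at least two distinct normals (the conventional panel-of-normals
#' cutoff for tumor-only calling).
#'
#' @param normalSets List of character vectors of `chrom:pos:ref:alt` site
#'   keys (or data.frames with `chrom`, `pos`, `ref`, `alt` columns), one per
#'   normal sample.
#' @param minNormals Minimum number of normals a site must appear in
#'   (default 2).
#' @return A [PanelOfNormals-class].
#' @export
#' @examples
#' pon <- buildPon(list(c("chr1:10:A:T", "chr1:20:C:G"),
#'                      c("chr1:10:A:T")))
#' ponSites(pon)
buildPon <- function(normalSets, minNormals = 2L) {
  keys <- lapply(normalSets, function(s) {
    if (is.data.frame(s)) {
      requireColumns(s, c("chrom", "pos", "ref", "alt"), "normal call set")
      s <- siteKey(s$chrom, s$pos, s$ref, s$alt)
    }
    unique(as.character(s))
  })
  tab <- table(unlist(keys))
  sites <- sort(names(tab)[tab >= minNormals])
  new("PanelOfNormals", sites = as.character(sites),
      nNormals = length(normalSets))
}

#' Remove panel-of-normals sites from a variant table
#'
#' Drops every record whose (chrom, pos, ref, alt) site is blacklisted;
#' matching is exact on all four fields and row order is preserved.
#'
#' @param variants Variant table.
#' @param pon A [PanelOfNormals-class].
#' @return Filtered variant table.
#' @export
applyPon <- function(variants, pon) {
  stopifnot(is(pon, "PanelOfNormals"))
  requireColumns(variants, c("chrom", "pos", "ref", "alt"))
  keys <- siteKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  out <- variants[!(keys %in% pon@sites), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variants by read depth
#'
#' Removes records with total depth below `minDepth`; the boundary is
#' inclusive, so with the default of 20 a depth-20 record is retained and a
#' depth-19 record removed.
#'
#' @param variants Variant table with a `totalDepth` column.
#' @param minDepth Minimum retained depth (default 20).
#' @return Filtered variant table.
#' @export
filterDepth <- function(variants, minDepth = 20L) {
  if (minDepth < 0) stop("'minDepth' must be >= 0", call. = FALSE)
  requireColumns(variants, "totalDepth")
  out <- variants[variants$totalDepth >= minDepth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The default 31-column feature schema
#'
#' Names the numeric columns assembled for the somatic/germline classifier:
#' allele frequency and depths, cohort recurrence, population frequency and
#' dbSNP-common flag, somatic-catalog presence and count, six
#' pathogenicity/conservation scores, variant-class one-hot (8), base-change
#' one-hot (6), a GC-context flag and a homopolymer-context flag.
#'
#' @return Character vector of 31 column names.
#' @export
featureSchema <- function() {
  c("vaf", "altDepth", "refDepth", "totalDepth", "cohortRecurrence",
    "populationAf", "dbsnpCommon", "cosmicPresent", "cosmicCount",
    "sift", "polyphen", "cadd", "gerp", "phylop", "revel",
    paste0("class_", .VARIANT_CLASSES),
    "bc_CA", "bc_CG", "bc_CT", "bc_TA", "bc_TC", "bc_TG",
    "contextGc", "homopolymer")
}

#' Assemble the classifier feature matrix
#'
#' Builds the 31-column numeric feature matrix from a variant table. Cohort
#' recurrence is the number of distinct cohort samples carrying the identical
#' (chrom, pos, ref, alt) site, computed over `cohort` (which defaults to the
#' input table). Categorical annotations are one-hot encoded, base changes
#' are folded to the pyrimidine strand, and missing numeric scores are
#' imputed with the column median (0.5 when a column is entirely missing),
#' so the result never contains missing values.
#'
#' @param variants Variant table.
#' @param cohort Optional larger variant table used for recurrence counting.
#' @param schema Feature schema (must equal [featureSchema()]).
#' @return List of class `FeatureMatrix` with elements `x` (numeric matrix,
#'   rows keyed by variant), `key`, and `labels` (factor or NULL).
#' @export
assembleFeatures <- function(variants, cohort = variants,
                             schema = featureSchema()) {
  if (!identical(schema, featureSchema()))
    stop("unknown feature schema column(s): ",
         paste(setdiff(schema, featureSchema()), collapse = ", "),
         call. = FALSE)
  requireColumns(variants, c("sample", "chrom", "pos", "ref", "alt", "vaf",
                             "altDepth", "refDepth", "totalDepth", "class"))
  n <- nrow(variants)
  sites <- siteKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  cohortSites <- unique(data.frame(
    site = siteKey(cohort$chrom, cohort$pos, cohort$ref, cohort$alt),
    sample = cohort$sample, stringsAsFactors = FALSE))
  recur <- table(cohortSites$site)
  x <- matrix(0, nrow = n, ncol = length(schema),
              dimnames = list(NULL, schema))
  num <- function(col, default = 0) {
    if (col %in% names(variants)) {
      v <- suppressWarnings(as.numeric(variants[[col]]))
      v
    } else rep(NA_real_, n)
  }
  x[, "vaf"] <- variants$vaf
  x[, "altDepth"] <- variants$altDepth
  x[, "refDepth"] <- variants$refDepth
  x[, "totalDepth"] <- variants$totalDepth
  x[, "cohortRecurrence"] <- as.numeric(recur[sites])
  x[is.na(x[, "cohortRecurrence"]), "cohortRecurrence"] <- 0
  x[, "populationAf"] <- num("populationAf")
  x[, "dbsnpCommon"] <- num("dbsnpCommon")
  cc <- num("cosmicCount")
  x[, "cosmicCount"] <- cc
  x[, "cosmicPresent"] <- as.numeric(cc > 0)
  for (col in c("sift", "polyphen", "cadd", "gerp", "phylop", "revel"))
    x[, col] <- num(col)
  cls <- as.character(variants$class)
  cls[!(cls %in% .VARIANT_CLASSES)] <- "other"
  for (v in .VARIANT_CLASSES)
    x[, paste0("class_", v)] <- as.numeric(cls == v)
  channel <- trinucleotideChannel(variants$ref, variants$alt,
                                  if ("context" %in% names(variants))
                                    variants$context
                                  else rep(NA_character_, n))
  sub <- ifelse(is.na(channel), NA_character_,
                paste0(substr(channel, 3, 3), substr(channel, 5, 5)))
  for (s in c("CA", "CG", "CT", "TA", "TC", "TG"))
    x[, paste0("bc_", s)] <- as.numeric(!is.na(sub) & sub == s)
  if ("context" %in% names(variants)) {
    cx <- toupper(as.character(variants$context))
    ok <- !is.na(cx) & nchar(cx) == 3L
    gc <- integer(n)
    gc[ok] <- vapply(strsplit(cx[ok], ""), function(b)
      sum(b %in% c("G", "C")), integer(1))
    x[, "contextGc"] <- as.numeric(ok & gc >= 2L)
    x[, "homopolymer"] <- as.numeric(ok &
      substr(cx, 1, 1) == substr(cx, 2, 2) &
      substr(cx, 2, 2) == substr(cx, 3, 3))
  }
  ## median imputation keeps the matrix total and deterministic
  for (j in seq_len(ncol(x))) {
    bad <- is.na(x[, j]) | !is.finite(x[, j])
    if (any(bad)) {
      med <- stats::median(x[!bad, j])
      if (!length(med) || is.na(med)) med <- 0.5
      x[bad, j] <- med
    }
  }
  labels <- NULL
  if ("label" %in% names(variants) && any(!is.na(variants$label)))
    labels <- factor(variants$label, levels = c("germline", "somatic"))
  structure(list(
    x = x,
    key = variantKey(variants$sample, variants$chrom, variants$pos,
                     variants$ref, variants$alt),
    labels = labels), class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat("FeatureMatrix:", nrow(x$x), "variants x", ncol(x$x), "features",
      if (!is.null(x$labels)) sprintf("(%d labeled)", sum(!is.na(x$labels)))
      else "(unlabeled)", "\n")
  invisible(x)
}

#' Write a panel of normals as sorted TSV
#' @param pon A [PanelOfNormals-class].
#' @param path Output path.
#' @export
writePon <- function(pon, path) {
  stopifnot(is(pon, "PanelOfNormals"))
  parts <- do.call(rbind, strsplit(pon@sites, ":", fixed = TRUE))
  df <- if (length(pon@sites))
    data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4])
  else data.frame(chrom = character(0), pos = integer(0),
                  ref = character(0), alt = character(0))
  utils::write.table(df[order(df$chrom, df$pos, df$ref, df$alt), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
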