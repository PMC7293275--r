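## Trinucleotide substitution channels (96-channel convention) and the
## built-in signature stand-ins used by the synthetic cohort generator.

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 trinucleotide substitution channels
#'
#' Channel labels follow the standard pyrimidine-centered convention:
#' six substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each combined with
#' the 16 possible 5'/3' flanking-base contexts in alphabetical order, e.g.
#' `"A[C>A]A"`, `"A[C>A]C"`, ..., `"T[T>G]T"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbsChannels())
sbsChannels <- function() {
  unlist(lapply(.SUBS, function(s) {
    as.vector(t(outer(.BASES, .BASES, function(p, q)
      paste0(p, "[", s, "]", q))))
  }), use.names = FALSE)
}

reverseComplement <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(.COMP[b])), collapse = ""), character(1))
}

#' Fold a substitution into its pyrimidine-centered channel
#'
#' Single-base substitutions observed on the purine strand (reference A or G)
#' are folded to the reverse complement so every substitution maps onto one of
#' the 96 pyrimidine-centered channels. The middle base of `context` must equal
#' `ref`.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Reference trinucleotide context (3 characters, reference
#'   strand).
#' @return Channel label (e.g. `"T[C>T]A"`), or `NA` for non-SNVs or contexts
#'   whose middle base disagrees with `ref`.
#' @export
#' @examples
#' trinucleotideChannel("G", "A", "TGA")  # folds to "T[C>T]A"
trinucleotideChannel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- rep(NA_character_, n)
  snv <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    nchar(ref) == 1L & nchar(alt) == 1L & nchar(context) == 3L &
    ref %in% .BASES & alt %in% .BASES & ref != alt &
    substr(context, 2, 2) == ref
  if (!any(snv)) return(out)
  r <- ref[snv]; a <- alt[snv]; cx <- context[snv]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    r[pur] <- unname(.COMP[r[pur]])
    a[pur] <- unname(.COMP[a[pur]])
    cx[pur] <- reverseComplement(cx[pur])
  }
  out[snv] <- paste0(substr(cx, 1, 1), "[", r, ">", a, "]", substr(cx, 3, 3))
  out
}

## Decode channel labels back into (fivep, ref, alt, threep).
decodeChannel <- function(channel) {
  data.frame(
    fivep = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    threep = substr(channel, 7, 7),
    stringsAsFactors = FALSE
  )
}

#' Built-in signature stand-ins for the synthetic cohort
#'
#' Three 96-channel probability vectors with the qualitative shapes of the
#' processes the pipeline is designed to recover: an aging-like signature
#' concentrated on C>T at NpCpG sites (spontaneous 5-methylcytosine
#' deamination), a mismatch-repair-like signature with broad C>T plus C>A
#' weight, and an oxidation-like "O/TN" signature dominated by T>G changes
#' with T[T>G]C the single largest channel. These are deliberately simplified
#' stand-ins for planted-truth recovery experiments, not reproductions of any
#' curated catalog entry.
#'
#' @return A 3 x 96 matrix with rows `aging`, `MMR`, `OTN`, each summing to 1;
#'   columns are [sbsChannels()].
#' @export
#' @examples
#' rowSums(defaultSignatures())
defaultSignatures <- function() {
  ch <- sbsChannels()
  info <- decodeChannel(ch)
  sub <- paste0(info$ref, ">", info$alt)

  ## Sparse supports (as in curated signatures, where most channels are
  ## near zero); each process keeps substitution classes the others lack,
  ## which also makes the planted factorization identifiable.
  aging <- numeric(96)
  ncg <- sub == "C>T" & info$threep == "G"
  aging[ncg] <- 0.70 / sum(ncg)
  otherCT <- sub == "C>T" & !ncg
  aging[otherCT] <- 0.15 / sum(otherCT)
  aging[sub == "T>C"] <- 0.15 / 16

  mmr <- numeric(96)
  mmr[sub == "C>T"] <- 0.55 / 16
  mmr[sub == "C>A"] <- 0.40 / 16
  mmr[sub == "C>G"] <- 0.05 / 16

  otn <- numeric(96)
  top <- ch == "T[T>G]C"
  otn[top] <- 0.25
  otherTG <- sub == "T>G" & !top
  otn[otherTG] <- 0.35 / sum(otherTG)
  otn[sub == "T>A"] <- 0.40 / 16

  out <- rbind(aging = aging, MMR = mmr, OTN = otn)
  colnames(out) <- ch
  out
}
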