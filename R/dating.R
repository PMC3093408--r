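#' Configuration for LTR-divergence dating
#'
#' The two LTRs of a provirus are identical at integration and diverge
#' thereafter by neutral drift; their pairwise divergence therefore grows
#' at `lineages` (= 2) times the per-lineage neutral substitution rate,
#' and divides retroviral integrations into young / middle / old classes.
#'
#' @param substitution_rate neutral nucleotide substitution rate as a
#'   fraction per site per million years (default 0.002, i.e. 0.2%/mya).
#' @param young_max divergence below which an integration is "young"
#'   (default 0.05, about 12.5 mya under the default rate).
#' @param old_min divergence above which it is "old" (default 0.10, about
#'   25 mya); divergences in `[young_max, old_min]` are "middle".
#' @param lineages number of independently diverging LTR lineages
#'   (default 2; each LTR accumulates substitutions on its own).
#' @return a list of class `dating_config`.
#' @export
dating_config <- function(substitution_rate = 0.002, young_max = 0.05,
                          old_min = 0.10, lineages = 2) {
  stopifnot(substitution_rate > 0, young_max > 0, young_max <= old_min,
            lineages >= 1)
  structure(list(substitution_rate = substitution_rate,
                 young_max = young_max, old_min = old_min,
                 lineages = lineages), class = "dating_config")
}

AGE_CLASSES <- c("young", "middle", "old", "undatable")

#' Globally align a 5'/3' LTR pair
#'
#' Needleman-Wunsch global alignment with affine gap costs
#' (defaults: match +2, mismatch -1, gap open -5, gap extend -1 per
#' position), computed with `Biostrings::pairwiseAlignment`.
#'
#' @param seq5,seq3 nucleotide sequences (character or `DNAString`),
#'   ACGT plus ambiguity codes.
#' @param match,mismatch,gap_open,gap_extend scoring parameters; gap
#'   costs are penalties and must be `<= 0`.
#' @return list of class `ltr_alignment` with elements `seq5`, `seq3`
#'   (gapped strings of equal length) and `score`.
#' @export
align_ltrs <- function(seq5, seq3, match = 2, mismatch = -1,
                       gap_open = -5, gap_extend = -1) {
  seq5 <- toupper(as.character(seq5)); seq3 <- toupper(as.character(seq3))
  if (!nzchar(seq5) || !nzchar(seq3)) stop("LTR sequences must be non-empty")
  stopifnot(gap_open <= 0, gap_extend <= 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq5), Biostrings::DNAString(seq3),
    type = "global", substitutionMatrix = mat,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  structure(list(seq5 = as.character(Biostrings::alignedPattern(aln)),
                 seq3 = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln)),
            class = "ltr_alignment")
}

#' @export
print.ltr_alignment <- function(x, ...) {
  cat("ltr_alignment: length", nchar(x$seq5), "score", x$score, "\n")
  invisible(x)
}

#' LTR divergence from a pairwise alignment
#'
#' Gap-excluded p-distance: the fraction of mismatched columns among
#' columns where neither sequence has a gap and both bases are
#' unambiguous (ACGT).  No multiple-hit correction is applied; the
#' molecular clock used downstream is linear in this quantity.
#'
#' @param alignment an `ltr_alignment` from [align_ltrs].
#' @return divergence fraction in `[0, 1]`, or `NA` (undatable) when no
#'   comparable columns exist.
#' @export
ltr_divergence <- function(alignment) {
  stopifnot(inherits(alignment, "ltr_alignment"))
  a <- strsplit(alignment$seq5, "")[[1]]
  b <- strsplit(alignment$seq3, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Convert LTR divergence to integration age
#'
#' Both LTRs accumulate substitutions independently after integration, so
#' pairwise divergence grows at twice the per-lineage rate:
#' `age = divergence / (lineages * substitution_rate)`.  Under the default
#' 0.2%/mya rate, 5% divergence dates an integration to 12.5 mya and 10%
#' to 25 mya.
#'
#' @param divergence fraction in `[0, 1]` (NA allowed, returned as NA).
#' @param config a [dating_config].
#' @return age in million years.
#' @export
age_from_divergence <- function(divergence, config = dating_config()) {
  stopifnot(inherits(config, "dating_config"))
  if (any(!is.na(divergence) & divergence < 0))
    stop("divergence must be non-negative")
  divergence / (config$lineages * config$substitution_rate)
}

#' Assign an age class from LTR divergence
#'
#' Young: `d < young_max`; middle: `young_max <= d <= old_min`; old:
#' `d > old_min`; `NA` divergence (no QC-passing LTR pair) maps to
#' `"undatable"`.  The three dated classes partition `[0, 1]`.
#'
#' @param divergence fraction(s) in `[0, 1]` or NA.
#' @param config a [dating_config].
#' @return character vector over `young`, `middle`, `old`, `undatable`.
#' @export
classify_age <- function(divergence, config = dating_config()) {
  stopifnot(inherits(config, "dating_config"))
  out <- rep("undatable", length(divergence))
  d <- divergence
  out[!is.na(d) & d < config$young_max] <- "young"
  out[!is.na(d) & d >= config$young_max & d <= config$old_min] <- "middle"
  out[!is.na(d) & d > config$old_min] <- "old"
  out
}

#' Date every chain of a table from its LTR pair
#'
#' Runs [align_ltrs] and [ltr_divergence] on each chain with two
#' QC-passing LTR sequences (see [qc_ltrs]; chains never QC'd are treated
#' as passing when both sequences exist) and converts divergence to age
#' and age class.  Chains lacking a usable pair are carried through as
#' `undatable`, never dropped.
#'
#' @param x a [chain_table].
#' @param ltr_seqs named sequences (`<id>_5ltr` / `<id>_3ltr`), e.g. read
#'   with `Biostrings::readDNAStringSet`.
#' @param config a [dating_config].
#' @return data.frame with columns `chain_id`, `divergence`, `age_mya`,
#'   `age_class`.
#' @export
date_ltr_pairs <- function(x, ltr_seqs, config = dating_config()) {
  stopifnot(inherits(x, "chain_table"))
  seqs <- as_named_seqs(ltr_seqs)
  ids <- x$chains$id
  p5 <- if ("ltr5_pass" %in% names(x$chains)) x$chains$ltr5_pass else rep(NA, length(ids))
  p3 <- if ("ltr3_pass" %in% names(x$chains)) x$chains$ltr3_pass else rep(NA, length(ids))
  div <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    n5 <- paste0(ids[i], "_5ltr"); n3 <- paste0(ids[i], "_3ltr")
    if (!n5 %in% names(seqs) || !n3 %in% names(seqs)) next
    if (isFALSE(p5[i]) || isFALSE(p3[i])) next
    div[i] <- ltr_divergence(align_ltrs(seqs[[n5]], seqs[[n3]]))
  }
  data.frame(chain_id = ids, divergence = div,
             age_mya = age_from_divergence(div, config),
             age_class = classify_age(div, config),
             stringsAsFactors = FALSE)
}
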