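#' Retain chains scoring strictly above a threshold
#'
#' Detection scores separate true retroviral chains from chance motif
#' arrangements; the conventional cutoff of 300 is applied strictly
#' (a score of exactly 300 is removed).  Input order is preserved.
#'
#' @param x a [chain_table].
#' @param threshold positive score cutoff (default 300).
#' @return a [chain_table] with only chains whose `score > threshold`.
#' @export
filter_by_score <- function(x, threshold = 300) {
  stopifnot(inherits(x, "chain_table"), threshold > 0)
  subset_chains(x, x$chains$id[x$chains$score > threshold])
}

#' Collapse overlapping chains to one chain per locus
#'
#' Chains whose spans overlap on the same chromosome (transitive closure
#' of any >= 1 bp overlap) form a locus cluster; exactly one chain
#' survives per cluster, chosen by a three-stage cascade: (1) most
#' distinct putein genes present (of gag/pro/pol/env), (2) most total
#' annotated puteins, (3) highest score.  Residual ties fall to the
#' smallest start coordinate, then the smallest id, so the result is
#' deterministic.  Lower-ranking chains in a locus are dropped as
#' redundant copies of the same integration.
#'
#' @param x a [chain_table] from one genome.
#' @return a [chain_table] with one chain per locus, in genomic order of
#'   the survivors as they appeared in the input.
#' @export
dedup_loci <- function(x) {
  stopifnot(inherits(x, "chain_table"))
  ch <- x$chains
  if (nrow(ch) < 2) return(x)
  winners <- integer(0)
  for (chrom in unique(ch$chrom)) {
    sub <- ch[ch$chrom == chrom, , drop = FALSE]
    ord <- order(sub$start, sub$end, sub$id)
    sub <- sub[ord, , drop = FALSE]
    run_max_end <- cummax(c(-Inf, utils::head(sub$end, -1)))
    cluster <- cumsum(sub$start >= run_max_end)
    for (cl in split(sub$id, cluster))
      winners <- c(winners, pick_locus_winner(x, cl))
  }
  keep <- x$chains$id[x$chains$id %in% winners]
  subset_chains(x, keep)
}

pick_locus_winner <- function(x, ids) {
  if (length(ids) == 1) return(ids)
  ch <- x$chains[match(ids, x$chains$id), , drop = FALSE]
  pu <- x$puteins[x$puteins$chain_id %in% ids, , drop = FALSE]
  distinct <- vapply(ids, function(i)
    length(unique(pu$gene[pu$chain_id == i])), integer(1))
  total <- vapply(ids, function(i) sum(pu$chain_id == i), integer(1))
  ord <- order(-distinct, -total, -ch$score, ch$start, ch$id)
  ids[ord[[1]]]
}

#' Flag puteins with too many undetermined residues
#'
#' Gaps and sequencing errors in degraded reading frames yield
#' undetermined (`X`) residues; puteins with `max_undetermined` or more
#' are marked as failing QC (`qc_pass = FALSE`).  Chains themselves are
#' always retained; downstream protein analyses should subset to
#' `qc_pass` puteins (see [passing_puteins]).
#'
#' @param x a [chain_table].
#' @param max_undetermined exclusion threshold, inclusive (default 5:
#'   five or more X residues fail).
#' @return the [chain_table] with `puteins$qc_pass` filled in.
#' @export
qc_puteins <- function(x, max_undetermined = 5) {
  stopifnot(inherits(x, "chain_table"))
  x$puteins$qc_pass <- x$puteins$n_undetermined < max_undetermined
  x
}

#' Puteins that passed quality control
#' @param x a [chain_table] after [qc_puteins].
#' @param gene optionally restrict to one putein gene (e.g. `"pol"`).
#' @return the QC-passing rows of `x$puteins`.
#' @export
passing_puteins <- function(x, gene = NULL) {
  p <- x$puteins
  p <- p[!is.na(p$qc_pass) & p$qc_pass, , drop = FALSE]
  if (!is.null(gene)) p <- p[p$gene %in% gene, , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Flag LTRs with too many ambiguous nucleotides
#'
#' An LTR whose sequence contains `max_ambiguous_nt` or more ambiguous
#' (non-ACGT) positions is flagged; a chain whose 5' or 3' LTR fails (or
#' is absent) is excluded from LTR-divergence dating.
#'
#' @param x a [chain_table].
#' @param ltr_seqs named character vector or `Biostrings::DNAStringSet`
#'   with names `<id>_5ltr` / `<id>_3ltr`.
#' @param max_ambiguous_nt exclusion threshold, inclusive (default 15).
#' @return the [chain_table] with logical columns `ltr5_pass`,
#'   `ltr3_pass` added to `$chains` (NA where the sequence is absent).
#' @export
qc_ltrs <- function(x, ltr_seqs, max_ambiguous_nt = 15) {
  stopifnot(inherits(x, "chain_table"))
  seqs <- as_named_seqs(ltr_seqs)
  pass1 <- function(nm) {
    if (!nm %in% names(seqs)) return(NA)
    s <- toupper(seqs[[nm]])
    n_amb <- nchar(s) - nchar(gsub("[^ACGT]", "", s))
    n_amb < max_ambiguous_nt
  }
  x$chains$ltr5_pass <- vapply(paste0(x$chains$id, "_5ltr"), pass1, NA)
  x$chains$ltr3_pass <- vapply(paste0(x$chains$id, "_3ltr"), pass1, NA)
  x
}
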