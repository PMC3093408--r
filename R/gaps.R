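EXCLUDED_FLANK_CLASSES <- c("SINE", "LINE", "Simple_repeat")

#' Classify assembly gaps as possible ERV-containing gaps
#'
#' A gap is a candidate for harboring an undetected provirus iff all of:
#' (1) its AGP gap type is neither `clone` nor `contig` (those gaps arise
#' from assembly logistics, not repetitive insertions); (2) it is not
#' confidently sized too small to contain a provirus fragment — sized
#' (`N`) gaps shorter than `min_length` bp are excluded, while unsized
#' (`U`) gaps are never excluded on length since their recorded length is
#' a placeholder; (3) neither flank window contains a repeat of a known
#' non-ERV class (SINE, LINE, simple repeat) — a fragment of such a
#' repeat at the gap edge explains the gap without invoking an ERV.  LTR
#' class repeats at the flanks do not disqualify a gap: they are
#' consistent with a truncated provirus.
#'
#' @param gaps data.frame of gap rows (e.g. `read_agp(path)` subset to
#'   `is_gap`), with `chrom`, `start`, `end`, `gap_type` and optionally
#'   `sized` (missing treated as sized).
#' @param repeats repeat track data.frame (`chrom`, `start`, `end`,
#'   `class`), e.g. from [read_repeat_track].
#' @param flank_window bp inspected on each side of the gap (default 50).
#' @param min_length minimum candidate gap length in bp (default 1000).
#' @param genome optional [genome_index]; when given, a gap outside its
#'   chromosome bounds is an error.
#' @return the gap data.frame with added columns `length`,
#'   `flank_repeat_classes` (comma-joined, `""` when clean) and logical
#'   `candidate`.
#' @export
classify_gaps <- function(gaps, repeats, flank_window = 50,
                          min_length = 1000, genome = NULL) {
  g <- as.data.frame(gaps, stringsAsFactors = FALSE)
  r <- as.data.frame(repeats, stringsAsFactors = FALSE)
  if (!nrow(g)) {
    g$length <- numeric(0); g$flank_repeat_classes <- character(0)
    g$candidate <- logical(0)
    return(g)
  }
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_index"))
    bad <- !g$chrom %in% names(genome) | g$start < 0 |
      g$end > as.numeric(genome[g$chrom])
    if (any(bad))
      stop("gap(s) outside chromosome bounds: row ",
           paste(which(bad), collapse = ", "))
  }
  sized <- if ("sized" %in% names(g)) !isFALSE_vec(g$sized) else rep(TRUE, nrow(g))
  g$length <- g$end - g$start
  flanks <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    hit <- r$chrom == g$chrom[i] &
      ((r$end > g$start[i] - flank_window & r$start < g$start[i]) |
         (r$end > g$end[i] & r$start < g$end[i] + flank_window))
    flanks[i] <- paste(sort(unique(r$class[hit])), collapse = ",")
  }
  g$flank_repeat_classes <- flanks
  flank_bad <- vapply(strsplit(flanks, ",", fixed = TRUE),
                      function(cl) any(cl %in% EXCLUDED_FLANK_CLASSES),
                      logical(1))
  g$candidate <- !(g$gap_type %in% c("clone", "contig")) &
    (!sized | g$length >= min_length) & !flank_bad
  g
}

isFALSE_vec <- function(x) !is.na(x) & !x

#' Per-chromosome summary of candidate gaps
#'
#' @param gap_records output of [classify_gaps].
#' @param genome a [genome_index].
#' @return data.frame with `chrom`, `n_candidates`, `candidate_bp`,
#'   `density_per_mb` (candidates per Mbp of chromosome).
#' @export
gap_density_per_chromosome <- function(gap_records, genome) {
  stopifnot(inherits(genome, "genome_index"))
  g <- as.data.frame(gap_records, stringsAsFactors = FALSE)
  out <- lapply(names(genome), function(chrom) {
    sub <- g[g$chrom == chrom & g$candidate, , drop = FALSE]
    data.frame(chrom = chrom, n_candidates = nrow(sub),
               candidate_bp = sum(sub$length),
               density_per_mb = nrow(sub) / (genome[[chrom]] / 1e6),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
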