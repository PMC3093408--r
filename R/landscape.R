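#' Fraction of the genome occupied by ERVs
#'
#' Sum of (deduplicated) chain lengths over total genome length, as a
#' percentage.  3.7 Mbp of proviruses in a 2.5 Gbp genome is 0.148%,
#' i.e. about 0.15% after rounding.
#'
#' @param x a [chain_table] or data.frame of chains (deduplicated).
#' @param genome a [genome_index].
#' @return percentage in `[0, 100]`.
#' @export
genome_fraction <- function(x, genome) {
  stopifnot(inherits(genome, "genome_index"))
  ch <- erv_frame(x)
  total <- sum(as.numeric(genome))
  if (total <= 0) stop("genome length must be positive")
  100 * sum(ch$end - ch$start) / total
}

#' Bin feature counts along chromosomes
#'
#' Half-open bins of fixed width; a feature is counted in the bin
#' containing its start coordinate (features are never split across
#' bins).  All bins of every chromosome in the index are reported,
#' including empty ones, so bin counts always sum to the feature count.
#'
#' @param features data.frame with `chrom` and `start` columns.
#' @param genome a [genome_index].
#' @param bin bin width in bp (default 1e6).
#' @return data.frame with `chrom`, `bin` (0-based index), `bin_start`,
#'   `bin_end`, `count`.
#' @export
bin_density <- function(features, genome, bin = 1e6) {
  stopifnot(inherits(genome, "genome_index"), bin > 0)
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  out <- lapply(names(genome), function(chrom) {
    n_bins <- max(1L, as.integer(ceiling(genome[[chrom]] / bin)))
    starts <- (seq_len(n_bins) - 1) * bin
    counts <- integer(n_bins)
    st <- f$start[f$chrom == chrom]
    if (length(st)) {
      idx <- floor(st / bin) + 1
      tab <- table(factor(idx, levels = seq_len(n_bins)))
      counts <- as.integer(tab)
    }
    data.frame(chrom = chrom, bin = seq_len(n_bins) - 1L, bin_start = starts,
               bin_end = pmin(starts + bin, genome[[chrom]]), count = counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Minimum feature distance to each chromosome end
#'
#' For every chromosome carrying at least one feature: the start-side
#' distance is the smallest feature start, the end-side distance the
#' smallest `chromosome length - feature end`.  A value of 0 signals a
#' telomeric integration.  Chromosomes without features are absent from
#' the output.
#'
#' @param features data.frame with `chrom`, `start`, `end`.
#' @param genome a [genome_index].
#' @return data.frame with `chrom`, `start_distance`, `end_distance`.
#' @export
telomere_distances <- function(features, genome) {
  stopifnot(inherits(genome, "genome_index"))
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  chroms <- intersect(names(genome), unique(f$chrom))
  out <- lapply(chroms, function(chrom) {
    sub <- f[f$chrom == chrom, , drop = FALSE]
    data.frame(chrom = chrom, start_distance = min(sub$start),
               end_distance = min(genome[[chrom]] - sub$end),
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(chrom = character(), start_distance = numeric(),
                      end_distance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-ERV breakdown into exonic / UTR / intronic / intergenic bp
#'
#' Each ERV basepair receives exactly one label with precedence
#' CDS (exonic) > UTR > intronic > intergenic, where intronic means
#' inside a gene span but in neither CDS nor UTR.  Counts sum to the ERV
#' length by construction.
#'
#' @param x a [chain_table] or data.frame of chains.
#' @param annotation data.frame of annotation intervals with columns
#'   `chrom`, `start`, `end`, `type`, where `type` is `gene`, `CDS` or
#'   `UTR` (0-based half-open).
#' @return data.frame with one row per chain: `id`, `exonic`, `utr`,
#'   `intronic`, `intergenic`.
#' @export
region_breakdown <- function(x, annotation) {
  ch <- erv_frame(x)
  ann <- as.data.frame(annotation, stringsAsFactors = FALSE)
  stopifnot(all(ann$type %in% c("gene", "CDS", "UTR")))
  ir <- function(df) IRanges::reduce(IRanges::IRanges(df$start + 1, df$end))
  out <- lapply(seq_len(nrow(ch)), function(i) {
    ei <- ch[i, ]
    len <- ei$end - ei$start
    a <- ann[ann$chrom == ei$chrom, , drop = FALSE]
    erv <- IRanges::IRanges(ei$start + 1, ei$end)
    cds <- ir(a[a$type == "CDS", , drop = FALSE])
    utr <- IRanges::setdiff(ir(a[a$type == "UTR", , drop = FALSE]), cds)
    genic <- ir(a[a$type == "gene", , drop = FALSE])
    intron <- IRanges::setdiff(IRanges::setdiff(genic, cds), utr)
    bp <- function(set) sum(IRanges::width(IRanges::intersect(erv, set)))
    ex <- bp(cds); ut <- bp(utr); intr <- bp(intron)
    data.frame(id = ei$id, exonic = ex, utr = ut, intronic = intr,
               intergenic = len - ex - ut - intr)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(), exonic = numeric(), utr = numeric(),
               intronic = numeric(), intergenic = numeric())
  rownames(out) <- NULL
  out
}

#' Correlate per-chromosome ERV counts with a covariate
#'
#' Ordinary least-squares regression of counts on the covariate
#' (e.g. chromosome length or genes per chromosome), reporting r-squared
#' and the two-sided p-value for a non-zero slope.  Outlier chromosomes
#' are excluded only when named by the caller — the judgment is
#' recorded, not automated.
#'
#' @param counts named numeric vector: ERV count per chromosome.
#' @param covariate named numeric vector over (at least) the same
#'   chromosomes.
#' @param exclude chromosome names to drop before fitting.
#' @return object of class `correlation_result`: `r_squared`, `p_value`,
#'   `n`, `excluded_outliers`, `slope`, `intercept`.
#' @export
correlate_counts <- function(counts, covariate, exclude = character()) {
  chroms <- setdiff(intersect(names(counts), names(covariate)), exclude)
  if (length(chroms) < 3) stop("need at least 3 chromosomes after exclusion")
  y <- as.numeric(counts[chroms]); z <- as.numeric(covariate[chroms])
  fit <- stats::lm(y ~ z)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4]))
    NA_real_ else sm$coefficients[2, 4]
  structure(list(r_squared = sm$r.squared, p_value = p, n = length(chroms),
                 excluded_outliers = exclude,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation: r^2 = ", format(x$r_squared, digits = 3),
      ", p = ", format(x$p_value, digits = 3), ", n = ", x$n, sep = "")
  if (length(x$excluded_outliers))
    cat("  (excluded: ", paste(x$excluded_outliers, collapse = ", "), ")",
        sep = "")
  cat("\n")
  invisible(x)
}
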