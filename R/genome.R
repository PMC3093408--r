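#' Genome index: chromosome names and lengths
#'
#' A minimal sequence dictionary used for binning, telomere distances and
#' genome-fraction computations.  All coordinates in this package are
#' 0-based half-open.
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @return a named numeric vector of class `genome_index`.
#' @examples
#' gi <- genome_index(c(chr1 = 2e6, chr2 = 1e6))
#' sum(gi)
#' @export
genome_index <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(lengths, class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @export
`[.genome_index` <- function(x, i, ...) {
  out <- NextMethod()
  class(out) <- "genome_index"
  out
}
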