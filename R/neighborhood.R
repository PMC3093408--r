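#' Build composite (pseudo-transcript) gene models
#'
#' Per gene, the longest transcript is selected; any alternative
#' transcript of the same gene that overlaps the growing model and
#' extends it beyond either end is annexed, iteratively, so the final
#' model is the union interval of the overlap-connected component that
#' contains the longest transcript.  Non-overlapping alternative
#' transcripts are never annexed.  A gene with transcripts on both
#' strands is split into one model per strand, with a warning.
#'
#' @param transcripts data.frame as from [read_gff_genes]: `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end`, `strand`.
#' @return data.frame of composite models: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
build_composite_models <- function(transcripts) {
  tx <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  out <- data.frame(gene_id = character(), chrom = character(),
                    strand = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  if (!nrow(tx)) return(out)
  if (any(!tx$strand %in% c("+", "-"))) stop("strandless transcripts rejected")
  both <- tapply(tx$strand, tx$gene_id, function(s) length(unique(s)) > 1)
  if (any(both))
    warning("gene(s) with transcripts on both strands split into two models: ",
            paste(names(both)[both], collapse = ", "))
  key <- paste(tx$gene_id, tx$strand, sep = "\r")
  groups <- split(seq_len(nrow(tx)), key)
  span <- vapply(groups, function(ix) {
    s <- tx$start[ix]; e <- tx$end[ix]
    ord <- order(s, e)
    s <- s[ord]; e <- e[ord]
    # overlap-connected components among this gene's transcripts
    comp <- cumsum(s >= cummax(c(-Inf, e[-length(e)])))
    longest <- which.max(e - s)
    pick <- comp == comp[[longest]]
    c(min(s[pick]), max(e[pick]))
  }, numeric(2))
  first <- vapply(groups, `[[`, 0L, 1L)
  out <- data.frame(gene_id = tx$gene_id[first], chrom = tx$chrom[first],
                    strand = tx$strand[first], start = span[1, ],
                    end = span[2, ], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

erv_frame <- function(x) {
  if (inherits(x, "chain_table")) x$chains else as.data.frame(x)
}

#' Signed position of a gene model relative to an ERV
#'
#' Offsets are measured from the ERV's edges in the ERV's own reading
#' frame: positive means downstream of the ERV's 3' LTR, negative
#' upstream of its 5' LTR, so the sign flips with the ERV strand.  A
#' model overlapping any part of the ERV span is at position 0.
#'
#' @param erv one chain (1-row data.frame or list with `chrom`, `start`,
#'   `end`, `strand`).
#' @param model one composite model (same fields).
#' @return signed bp offset of the model's nearest edge (0 on overlap),
#'   or `NA` when the two lie on different chromosomes.
#' @export
erv_relative_position <- function(erv, model) {
  if (erv$chrom != model$chrom) return(NA_real_)
  if (model$start < erv$end && model$end > erv$start) return(0)
  gap <- if (model$end <= erv$start) -(erv$start - model$end + 1)
         else model$start - erv$end + 1
  if (erv$strand == "-") gap <- -gap
  gap
}

#' Sense/antisense gene-coverage profile around ERV integrations
#'
#' For every (ERV, model) pair on the same chromosome, every nucleotide
#' position of the composite model falling inside the ERV-centered window
#' `[-W, +W]` contributes one count at its signed offset — to the sense
#' array when the model's strand equals the ERV's, otherwise to the
#' antisense array.  Model positions overlapping the ERV span are pooled
#' at offset 0.  Offsets follow the ERV frame (see
#' [erv_relative_position]); a position covered by two gene models counts
#' twice.
#'
#' @param ervs a [chain_table] or data.frame of chains.
#' @param models composite models from [build_composite_models].
#' @param window half-width W in bp (default 100000, a 200-kb window).
#' @return object of class `neighborhood_profile`: list with `window`,
#'   integer vectors `sense` and `antisense` of length `2W + 1` (offsets
#'   `-W..W`), and `n_ervs`.
#' @export
neighborhood_profile <- function(ervs, models, window = 100000) {
  stopifnot(window >= 1)
  e <- erv_frame(ervs)
  m <- as.data.frame(models, stringsAsFactors = FALSE)
  W <- as.integer(window)
  len <- 2L * W + 1L
  ds <- numeric(len + 1L); da <- numeric(len + 1L)
  add_run <- function(d, o1, o2, w = 1) {
    # add w to offsets o1..o2 (inclusive), diff-array form
    d[o1 + W + 1L] <- d[o1 + W + 1L] + w
    d[o2 + W + 2L] <- d[o2 + W + 2L] - w
    d
  }
  for (i in seq_len(nrow(e))) {
    es <- e$start[i]; ee <- e$end[i]; plus <- e$strand[i] == "+"
    cand <- which(m$chrom == e$chrom[i] & m$end > es - W & m$start < ee + W)
    for (j in cand) {
      ms <- m$start[j]; me <- m$end[j]
      sense <- m$strand[j] == e$strand[i]
      ov <- min(me, ee) - max(ms, es)
      runs <- list()
      xl0 <- max(ms, es - W); xl1 <- min(me, es)
      if (xl1 > xl0)
        runs[[length(runs) + 1L]] <-
          if (plus) c(xl0 - es, xl1 - es - 1) else c(es - xl1 + 1, es - xl0)
      xr0 <- max(ms, ee); xr1 <- min(me, ee + W)
      if (xr1 > xr0)
        runs[[length(runs) + 1L]] <-
          if (plus) c(xr0 - ee + 1, xr1 - ee)
          else c(-(xr1 - ee), -(xr0 - ee + 1))
      if (ov > 0) runs[[length(runs) + 1L]] <- c(0, 0, ov)
      for (r in runs) {
        w <- if (length(r) == 3) r[[3]] else 1
        if (sense) ds <- add_run(ds, r[[1]], r[[2]], w)
        else da <- add_run(da, r[[1]], r[[2]], w)
      }
    }
  }
  structure(list(window = W,
                 sense = cumsum(ds)[seq_len(len)],
                 antisense = cumsum(da)[seq_len(len)],
                 n_ervs = nrow(e)),
            class = "neighborhood_profile")
}

#' @export
print.neighborhood_profile <- function(x, ...) {
  cat("neighborhood_profile: window +/-", x$window, "bp,", x$n_ervs,
      "ERV(s)\n  sense bp:", sum(x$sense),
      " antisense bp:", sum(x$antisense), "\n")
  invisible(x)
}

#' Plot a sense/antisense neighborhood profile
#' @param x a `neighborhood_profile`.
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.neighborhood_profile <- function(x, ...) {
  off <- seq(-x$window, x$window)
  graphics::plot(off, x$sense, type = "l", col = "blue",
                 xlab = "offset from ERV (bp, ERV frame)",
                 ylab = "gene-model coverage (bp)",
                 ylim = range(0, x$sense, x$antisense), ...)
  graphics::lines(off, x$antisense, col = "red")
  graphics::legend("topright", legend = c("sense", "antisense"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

chisq_5050 <- function(over, under) {
  n <- over + under
  if (n == 0) return(list(chi2 = NA_real_, p = NA_real_))
  e <- n / 2
  chi2 <- (over - e)^2 / e + (under - e)^2 / e
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Over/under comparison of the antisense and sense curves
#'
#' Counts window positions where the antisense curve exceeds the sense
#' curve ("over"), where sense exceeds antisense ("under"), and where
#' they are equal; a 1-df goodness-of-fit chi-square compares (over,
#' under) against a uniform 50:50 expectation, with equal positions
#' excluded from the test.  Note that neighboring positions are strongly
#' autocorrelated (the sign changes only at gene-model edges), so this
#' position-level statistic describes the curves but is not a calibrated
#' significance test; for inference use [over_under_by_erv], whose
#' sampling unit is the ERV.
#'
#' @param profile a [neighborhood_profile].
#' @return object of class `over_under` with `over`, `under`, `equal`,
#'   `chi2`, `p_value`, `unit = "position"`, `n_units`.
#' @export
over_under <- function(profile) {
  stopifnot(inherits(profile, "neighborhood_profile"))
  over <- sum(profile$antisense > profile$sense)
  under <- sum(profile$sense > profile$antisense)
  equal <- sum(profile$sense == profile$antisense)
  ch <- chisq_5050(over, under)
  structure(list(over = over, under = under, equal = equal,
                 chi2 = ch$chi2, p_value = ch$p, unit = "position",
                 n_units = 2L * profile$window + 1L),
            class = "over_under")
}

#' Over/under test with the ERV as sampling unit
#'
#' For each ERV, total sense and antisense gene-model coverage (bp)
#' within its window is compared; ERVs with more antisense than sense
#' coverage count as "over", the reverse as "under", ties as "equal".
#' The 1-df chi-square on (over, under) against 50:50 is a calibrated
#' test of orientation bias because distinct ERVs' neighborhoods are
#' (near-)independent, unlike window positions.
#'
#' @inheritParams neighborhood_profile
#' @return object of class `over_under` with `unit = "erv"`.
#' @export
over_under_by_erv <- function(ervs, models, window = 100000) {
  e <- erv_frame(ervs)
  m <- as.data.frame(models, stringsAsFactors = FALSE)
  W <- as.integer(window)
  over <- under <- equal <- 0L
  for (i in seq_len(nrow(e))) {
    lo <- e$start[i] - W; hi <- e$end[i] + W
    cand <- m$chrom == e$chrom[i] & m$end > lo & m$start < hi
    bp <- pmin(m$end[cand], hi) - pmax(m$start[cand], lo)
    same <- m$strand[cand] == e$strand[i]
    s_bp <- sum(bp[same]); a_bp <- sum(bp[!same])
    if (a_bp > s_bp) over <- over + 1L
    else if (s_bp > a_bp) under <- under + 1L
    else equal <- equal + 1L
  }
  ch <- chisq_5050(over, under)
  structure(list(over = over, under = under, equal = equal,
                 chi2 = ch$chi2, p_value = ch$p, unit = "erv",
                 n_units = nrow(e)),
            class = "over_under")
}

#' @export
print.over_under <- function(x, ...) {
  cat("over/under (unit = ", x$unit, "): over = ", x$over, ", under = ",
      x$under, ", equal = ", x$equal, "\n  chi-square(1) = ",
      format(x$chi2), ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Age-stratified neighborhood profiles
#'
#' One [neighborhood_profile] per LTR-divergence age class (young /
#' middle / old); undatable ERVs are excluded.  An empty class yields an
#' all-zero profile, not an error.
#'
#' @inheritParams neighborhood_profile
#' @param dating data.frame from [date_ltr_pairs] (`chain_id`,
#'   `age_class`).
#' @return named list of `neighborhood_profile` objects
#'   (`young`, `middle`, `old`).
#' @export
stratified_profiles <- function(ervs, models, dating, window = 100000) {
  e <- erv_frame(ervs)
  cls <- dating$age_class[match(e$id, dating$chain_id)]
  out <- lapply(c(young = "young", middle = "middle", old = "old"),
                function(k) {
    neighborhood_profile(e[!is.na(cls) & cls == k, , drop = FALSE],
                         models, window)
  })
  out
}

#' Genes containing or flanking ERV integrations
#'
#' Reports every composite model overlapping an ERV ("contained"
#' integration, distance 0) and every ERV lying within `flank` bp of a
#' model's 5' (upstream/promoter) or 3' (downstream) end, with the
#' relative orientation of the two.
#'
#' @inheritParams neighborhood_profile
#' @param flank maximum edge-to-edge distance in bp (default 5000,
#'   inclusive).
#' @return data.frame with columns `gene_id`, `erv_id`, `side`
#'   (`contained`/`upstream`/`downstream`, in the gene's frame),
#'   `orientation` (`sense`/`antisense`), `distance` (bp).
#' @export
proximal_genes <- function(ervs, models, flank = 5000) {
  e <- erv_frame(ervs)
  m <- as.data.frame(models, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(e))) {
    ei <- e[i, ]
    cand <- which(m$chrom == ei$chrom & m$end >= ei$start - flank &
                    m$start <= ei$end + flank)
    for (j in cand) {
      mj <- m[j, ]
      orient <- if (mj$strand == ei$strand) "sense" else "antisense"
      if (mj$start < ei$end && mj$end > ei$start) {
        side <- "contained"; dist <- 0
      } else if (ei$end <= mj$start) {
        dist <- mj$start - ei$end
        side <- if (mj$strand == "+") "upstream" else "downstream"
      } else {
        dist <- ei$start - mj$end
        side <- if (mj$strand == "+") "downstream" else "upstream"
      }
      if (dist > flank) next
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = mj$gene_id, erv_id = ei$id, side = side,
                   orientation = orient, distance = dist,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), erv_id = integer(),
                      side = character(), orientation = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
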