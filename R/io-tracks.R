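#' Read gene/transcript annotation from GFF3 or BED12
#'
#' Returns a flat transcript table, one row per transcript, grouped by gene
#' id.  GFF3 (1-based closed) is converted to the internal 0-based
#' half-open convention on read.  In GFF3, rows of type `mRNA` or
#' `transcript` are taken as transcripts and grouped by their `Parent`
#' attribute; a transcript without a parent gene is kept, grouped by its
#' own `ID`, with a warning.  In BED the `name` field may be
#' `geneId:transcriptId`; a bare name is used as both ids (warning).
#'
#' @param path file path; dialect chosen from the extension
#'   (`.gff`/`.gff3` vs `.bed`) unless `format` is given.
#' @param format `"gff3"` or `"bed"`, overriding extension detection.
#' @return data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  format <- match.arg(format, c("gff3", "bed"))
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  content <- readLines(path)
  if (!any(nzchar(content) & !grepl("^#", content))) return(empty)
  gr <- rtracklayer::import(path, format = format)
  if (!length(gr)) return(empty)
  if (format == "gff3") {
    type <- as.character(gr$type)
    tx <- gr[type %in% c("mRNA", "transcript")]
    if (!length(tx)) return(empty)
    ids <- as.character(tx$ID)
    parent <- vapply(seq_along(tx), function(i) {
      p <- tx$Parent[[i]]
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
    orphan <- is.na(parent)
    if (any(orphan)) {
      warning(sum(orphan), " transcript(s) without a parent gene; grouped by their own id")
      parent[orphan] <- ids[orphan]
    }
    out <- data.frame(gene_id = parent, transcript_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(tx)),
                      start = GenomicRanges::start(tx) - 1,
                      end = GenomicRanges::end(tx),
                      strand = as.character(GenomicRanges::strand(tx)),
                      stringsAsFactors = FALSE)
  } else {
    nm <- if (!is.null(gr$name)) as.character(gr$name)
          else paste0("tx", seq_along(gr))
    has_gene <- grepl(":", nm, fixed = TRUE)
    if (any(!has_gene))
      warning(sum(!has_gene), " BED record(s) without a gene id; grouped by their own id")
    out <- data.frame(gene_id = ifelse(has_gene, sub(":.*$", "", nm), nm),
                      transcript_id = ifelse(has_gene, sub("^[^:]*:", "", nm), nm),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  }
  if (any(!out$strand %in% c("+", "-")))
    stop("strandless transcript(s) in ", path,
         "; the neighborhood analysis is orientation-critical")
  rownames(out) <- NULL
  out
}

#' Write a transcript table as GFF3
#'
#' Emits one `gene` row per gene (spanning its transcripts) and one `mRNA`
#' row per transcript with a `Parent` attribute; internal 0-based
#' half-open coordinates are restored to GFF3 1-based closed on write.
#'
#' @param transcripts data.frame as returned by [read_gff_genes].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(transcripts, path) {
  tx <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  lines <- "##gff-version 3"
  if (nrow(tx)) {
    genes <- split(tx, tx$gene_id)
    for (g in genes) {
      gid <- g$gene_id[[1]]
      lines <- c(lines, paste(g$chrom[[1]], "ervscape", "gene",
                              min(g$start) + 1, max(g$end), ".", g$strand[[1]],
                              ".", paste0("ID=", gid), sep = "\t"))
      lines <- c(lines, paste(g$chrom, "ervscape", "mRNA", g$start + 1, g$end,
                              ".", g$strand, ".",
                              paste0("ID=", g$transcript_id, ";Parent=", gid),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

AGP_GAP_TYPES <- c("fragment", "clone", "contig", "centromere", "telomere",
                   "short_arm", "heterochromatin", "repeat", "scaffold",
                   "contamination")

#' Read an AGP assembly description (v1.1 or v2.0)
#'
#' Component and gap rows are returned together; gap rows (`N` sized, `U`
#' unsized) carry gap type and length.  Object coordinates are converted
#' to 0-based half-open.
#'
#' @param path AGP file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `part_number`,
#'   `component_type`, `is_gap`, `gap_type`, `gap_length`, `sized`,
#'   `component_id`, `orientation`.
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(p) < 8 || length(p) > 9)
      stop("AGP column-count mismatch at line ", lineno[i],
           ": got ", length(p), " fields")
    is_gap <- p[[5]] %in% c("N", "U")
    rows[[i]] <- data.frame(
      chrom = p[[1]], start = as.numeric(p[[2]]) - 1, end = as.numeric(p[[3]]),
      part_number = as.integer(p[[4]]), component_type = p[[5]],
      is_gap = is_gap,
      gap_type = if (is_gap) p[[7]] else NA_character_,
      gap_length = if (is_gap) as.numeric(p[[6]]) else NA_real_,
      sized = if (is_gap) p[[5]] == "N" else NA,
      component_id = if (is_gap) NA_character_ else p[[6]],
      orientation = if (is_gap) NA_character_ else if (length(p) >= 9) p[[9]] else "+",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               part_number = integer(), component_type = character(),
               is_gap = logical(), gap_type = character(),
               gap_length = numeric(), sized = logical(),
               component_id = character(), orientation = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an AGP v2.0 file
#' @param agp data.frame as returned by [read_agp].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  agp <- as.data.frame(agp, stringsAsFactors = FALSE)
  lines <- "##agp-version\t2.0"
  if (nrow(agp)) {
    fields <- vapply(seq_len(nrow(agp)), function(i) {
      r <- agp[i, ]
      if (isTRUE(r$is_gap))
        paste(r$chrom, format_bp(r$start + 1), format_bp(r$end), r$part_number,
              if (isTRUE(r$sized)) "N" else "U", format_bp(r$gap_length),
              r$gap_type, "yes", "na", sep = "\t")
      else
        paste(r$chrom, format_bp(r$start + 1), format_bp(r$end), r$part_number,
              r$component_type, r$component_id, 1,
              format_bp(r$end - r$start), r$orientation, sep = "\t")
    }, character(1))
    lines <- c(lines, fields)
  }
  writeLines(lines, path)
  invisible(path)
}

REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "Simple_repeat", "Other")

normalize_repeat_class <- function(cls) {
  base <- sub("/.*$", "", cls)
  base[base %in% c("Simple", "Simple_repeat")] <- "Simple_repeat"
  unknown <- !base %in% REPEAT_CLASSES
  if (any(unknown)) {
    warning("unrecognized repeat class(es) mapped to Other: ",
            paste(unique(cls[unknown]), collapse = ", "))
    base[unknown] <- "Other"
  }
  base
}

#' Read a repeat annotation track (RepeatMasker .out or BED)
#'
#' Repeat classes are normalized to `SINE`, `LINE`, `LTR`, `Simple_repeat`
#' or `Other` (unparseable classes map to `Other` with a warning).
#' RepeatMasker's 1-based closed query coordinates become 0-based
#' half-open.  In BED input the `name` column carries the class.
#'
#' @param path file path; `.out` vs BED chosen by extension unless
#'   `format` is given.
#' @param format `"out"` or `"bed"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `class`,
#'   `name`, `strand`.
#' @export
read_repeat_track <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.out$", path, ignore.case = TRUE)) "out" else "bed"
  format <- match.arg(format, c("out", "bed"))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      class = character(), name = character(),
                      strand = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  if (format == "out") {
    body <- grep("^\\s*\\d+\\s", lines, value = TRUE)
    if (!length(body)) return(empty)
    p <- strsplit(trimws(body), "\\s+")
    bad <- vapply(p, length, integer(1)) < 11
    if (any(bad)) stop("malformed RepeatMasker line(s): ",
                       paste(which(bad), collapse = ", "))
    out <- data.frame(chrom = vapply(p, `[[`, "", 5),
                      start = as.numeric(vapply(p, `[[`, "", 6)) - 1,
                      end = as.numeric(vapply(p, `[[`, "", 7)),
                      class = normalize_repeat_class(vapply(p, `[[`, "", 11)),
                      name = vapply(p, `[[`, "", 10),
                      strand = ifelse(vapply(p, `[[`, "", 9) == "C", "-", "+"),
                      stringsAsFactors = FALSE)
  } else {
    body <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
    if (!length(body)) return(empty)
    p <- strsplit(body, "\t", fixed = TRUE)
    bad <- vapply(p, length, integer(1)) < 4
    if (any(bad)) stop("BED repeat track needs >= 4 columns (class in name)")
    out <- data.frame(chrom = vapply(p, `[[`, "", 1),
                      start = as.numeric(vapply(p, `[[`, "", 2)),
                      end = as.numeric(vapply(p, `[[`, "", 3)),
                      class = normalize_repeat_class(vapply(p, `[[`, "", 4)),
                      name = vapply(p, `[[`, "", 4),
                      strand = vapply(p, function(x)
                        if (length(x) >= 6) x[[6]] else "+", ""),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a repeat track as BED6 (class in the name column)
#' @param repeats data.frame as returned by [read_repeat_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_track <- function(repeats, path) {
  r <- as.data.frame(repeats, stringsAsFactors = FALSE)
  if (!nrow(r)) { writeLines(character(), path); return(invisible(path)) }
  writeLines(paste(r$chrom, format_bp(r$start), format_bp(r$end), r$class, 0,
                   r$strand, sep = "\t"), path)
  invisible(path)
}
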