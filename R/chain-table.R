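GENUS_LEVELS <- c("gamma", "beta", "spuma", "gypsy", "unclassified")
PUTEIN_GENES <- c("gag", "pro", "pol", "env")

#' Construct a table of proviral chains
#'
#' A `chain_table` is the package's central container for detected proviral
#' chains: one row per chain with its genomic span, strand, detection score,
#' genus call, LTR sub-feature spans and primer-binding-site (PBS) label,
#' plus a companion long-format table of puteins (putative ancestral
#' protein sequences reconstructed from the gag/pro/pol/env reading
#' frames).  Coordinates are 0-based half-open.
#'
#' @param chains data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`), `score`, `genus` and optionally `pbs`,
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end` (NA when absent).
#' @param puteins data.frame with columns `chain_id`, `gene` (one of
#'   gag/pro/pol/env), `seq` (amino acids, `X` for undetermined); zero rows
#'   allowed.  `n_undetermined` and `qc_pass` are derived if missing.
#' @param genome_id free-text assembly label.
#' @return an object of class `chain_table`: a list with elements `chains`,
#'   `puteins`, `genome_id`, `coordinate_system`.
#' @export
chain_table <- function(chains, puteins = NULL, genome_id = "unknown") {
  chains <- as.data.frame(chains, stringsAsFactors = FALSE)
  needed <- c("id", "chrom", "start", "end", "strand", "score", "genus")
  miss <- setdiff(needed, names(chains))
  if (length(miss)) stop("chain table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("pbs", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end"))
    if (!col %in% names(chains)) chains[[col]] <- rep(NA, nrow(chains))
  chains$id <- as.integer(chains$id)
  chains$start <- as.numeric(chains$start)
  chains$end <- as.numeric(chains$end)
  chains$score <- as.numeric(chains$score)
  if (nrow(chains)) {
    if (anyDuplicated(chains$id)) stop("chain ids must be unique")
    if (any(is.na(chains$start) | is.na(chains$end) | chains$start >= chains$end))
      stop("every chain must have start < end")
    if (!all(chains$strand %in% c("+", "-")))
      stop("chain strand must be '+' or '-' (strandless chains are rejected)")
    if (any(is.na(chains$score) | chains$score < 0)) stop("scores must be >= 0")
    if (!all(chains$genus %in% GENUS_LEVELS))
      stop("genus must be one of: ", paste(GENUS_LEVELS, collapse = ", "))
    for (side in c("ltr5", "ltr3")) {
      s <- chains[[paste0(side, "_start")]]; e <- chains[[paste0(side, "_end")]]
      has <- !is.na(s) & !is.na(e)
      if (any(xor(is.na(s), is.na(e)))) stop(side, " span must have both ends or neither")
      if (any(has & (s >= e | s < chains$start | e > chains$end)))
        stop(side, " spans must lie inside their chain span")
    }
  }
  if (is.null(puteins))
    puteins <- data.frame(chain_id = integer(), gene = character(),
                          seq = character(), stringsAsFactors = FALSE)
  puteins <- as.data.frame(puteins, stringsAsFactors = FALSE)
  if (nrow(puteins)) {
    if (!all(c("chain_id", "gene", "seq") %in% names(puteins)))
      stop("putein table needs chain_id, gene, seq")
    puteins$chain_id <- as.integer(puteins$chain_id)
    if (!all(puteins$gene %in% PUTEIN_GENES))
      stop("putein gene must be one of: ", paste(PUTEIN_GENES, collapse = ", "))
    if (!all(puteins$chain_id %in% chains$id))
      stop("putein chain_id not present in chain table")
    if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", puteins$seq)))
      stop("putein sequences must use the amino-acid alphabet plus X")
  }
  if (!"n_undetermined" %in% names(puteins))
    puteins$n_undetermined <- count_x(puteins$seq)
  if (!"qc_pass" %in% names(puteins))
    puteins$qc_pass <- rep(NA, nrow(puteins))
  structure(list(chains = chains, puteins = puteins,
                 genome_id = as.character(genome_id),
                 coordinate_system = "0-based half-open"),
            class = "chain_table")
}

as_named_seqs <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}

count_x <- function(seq) {
  if (!length(seq)) return(integer())
  vapply(strsplit(seq, ""), function(ch) sum(ch == "X"), integer(1))
}

#' @export
print.chain_table <- function(x, ...) {
  cat("chain_table (", x$genome_id, "): ", nrow(x$chains), " chain(s), ",
      nrow(x$puteins), " putein(s), ", x$coordinate_system, "\n", sep = "")
  if (nrow(x$chains)) {
    tab <- table(x$chains$genus)
    cat("  genus:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    utils::head(x$chains[, c("id", "chrom", "start", "end", "strand", "score", "genus")])
  }
  invisible(x)
}

#' Number of chains
#' @param x a `chain_table`.
#' @return integer count of chains.
#' @export
n_chains <- function(x) nrow(x$chains)

#' Subset a chain table to a set of chain ids (order preserved as given)
#' @param x a `chain_table`.
#' @param ids chain ids to keep.
#' @return a `chain_table` with only those chains and their puteins.
#' @export
subset_chains <- function(x, ids) {
  keep <- x$chains[match(ids, x$chains$id), , drop = FALSE]
  if (any(is.na(keep$id))) stop("unknown chain id(s)")
  put <- x$puteins[x$puteins$chain_id %in% ids, , drop = FALSE]
  rownames(keep) <- rownames(put) <- NULL
  chain_table(keep, put, x$genome_id)
}

#' Read a proviral chain table (TSV dialect)
#'
#' The on-disk dialect is defined by this package (one row per chain,
#' sub-features as typed columns) and documented below; it stands in for
#' the native output of upstream provirus-detection software.  Columns:
#' `id chrom start end strand score genus pbs ltr5_start ltr5_end
#' ltr3_start ltr3_end puteins`, tab-separated with a header row.
#' Coordinates are written 0-based half-open.  Missing values are `.`;
#' the `puteins` field is `gene:SEQ` entries joined with `;` (a gene may
#' repeat when several puteins were annotated for it).
#'
#' @param path file path.
#' @param genome_id assembly label to attach (default taken from a
#'   `## genome_id=` header comment when present).
#' @return a [chain_table].
#' @export
read_chain_table <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  gid <- "unknown"
  meta <- grep("^## genome_id=", lines, value = TRUE)
  if (length(meta)) gid <- sub("^## genome_id=", "", meta[[1]])
  if (!is.null(genome_id)) gid <- genome_id
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(chain_table(empty_chain_df(), NULL, gid))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  want <- c("id", "chrom", "start", "end", "strand", "score", "genus", "pbs",
            "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end", "puteins")
  if (!all(want %in% header))
    stop("chain table header lacks column(s): ",
         paste(setdiff(want, header), collapse = ", "))
  body <- lines[-1]; lineno <- lineno[-1]
  if (!length(body)) return(chain_table(empty_chain_df(), NULL, gid))
  parts <- strsplit(body, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  puts <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != length(header))
      stop("malformed chain-table row at line ", lineno[i],
           ": expected ", length(header), " fields, got ", length(p))
    v <- stats::setNames(p, header)
    if (!v[["strand"]] %in% c("+", "-"))
      stop("unknown strand symbol '", v[["strand"]], "' at line ", lineno[i])
    num <- function(f) if (v[[f]] == ".") NA_real_ else suppressWarnings(as.numeric(v[[f]]))
    st <- num("start"); en <- num("end")
    if (is.na(st) || is.na(en) || en <= st)
      stop("malformed chain-table row at line ", lineno[i], ": end <= start")
    rows[[i]] <- data.frame(
      id = as.integer(v[["id"]]), chrom = v[["chrom"]], start = st, end = en,
      strand = v[["strand"]], score = num("score"), genus = v[["genus"]],
      pbs = if (v[["pbs"]] == ".") NA_character_ else v[["pbs"]],
      ltr5_start = num("ltr5_start"), ltr5_end = num("ltr5_end"),
      ltr3_start = num("ltr3_start"), ltr3_end = num("ltr3_end"),
      stringsAsFactors = FALSE)
    if (v[["puteins"]] != ".") {
      ent <- strsplit(v[["puteins"]], ";", fixed = TRUE)[[1]]
      gene <- sub(":.*$", "", ent); seq <- sub("^[^:]*:", "", ent)
      if (any(!nzchar(gene)) || any(!nzchar(seq)))
        stop("malformed putein field at line ", lineno[i])
      puts[[i]] <- data.frame(chain_id = as.integer(v[["id"]]), gene = gene,
                              seq = seq, stringsAsFactors = FALSE)
    }
  }
  chain_table(do.call(rbind, rows), do.call(rbind, puts), gid)
}

empty_chain_df <- function() {
  data.frame(id = integer(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(), score = numeric(),
             genus = character(), pbs = character(),
             ltr5_start = numeric(), ltr5_end = numeric(),
             ltr3_start = numeric(), ltr3_end = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a chain table in the package TSV dialect
#' @param x a [chain_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_chain_table] for the dialect definition.
#' @export
write_chain_table <- function(x, path) {
  stopifnot(inherits(x, "chain_table"))
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  pu <- vapply(x$chains$id, function(id) {
    p <- x$puteins[x$puteins$chain_id == id, , drop = FALSE]
    if (!nrow(p)) "." else paste(paste0(p$gene, ":", p$seq), collapse = ";")
  }, character(1))
  ch <- x$chains
  body <- paste(ch$id, ch$chrom, format_bp(ch$start), format_bp(ch$end),
                ch$strand, dot(ch$score), ch$genus, dot(ch$pbs),
                dot(format_bp(ch$ltr5_start)), dot(format_bp(ch$ltr5_end)),
                dot(format_bp(ch$ltr3_start)), dot(format_bp(ch$ltr3_end)),
                pu, sep = "\t")
  header <- paste(c("id", "chrom", "start", "end", "strand", "score", "genus",
                    "pbs", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                    "puteins"), collapse = "\t")
  writeLines(c(paste0("## genome_id=", x$genome_id), header, body), path)
  invisible(path)
}

format_bp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- format(x[ok], scientific = FALSE, trim = TRUE)
  out
}
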