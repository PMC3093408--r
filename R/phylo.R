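as_char_matrix <- function(aln) {
  if (inherits(aln, "XStringSet")) aln <- as.character(aln)
  if (is.matrix(aln)) return(aln)
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  n <- nchar(aln)
  if (length(unique(n)) != 1)
    stop("aligned sequences must have equal (padded) length")
  do.call(rbind, lapply(stats::setNames(aln, names(aln)),
                        function(s) strsplit(toupper(s), "")[[1]]))
}

GAP_CHARS <- c("-", ".")

#' Pairwise identity of two aligned sequences
#'
#' Identical columns divided by columns where both sequences are
#' non-gap.  Works for nucleotide or amino-acid alignments; `level` is
#' a bookkeeping tag only.
#'
#' @param a,b aligned sequences of equal padded length (`-`/`.` gaps).
#' @param level `"nt"` or `"aa"`.
#' @return identity fraction in `[0, 1]`, `NA` when no comparable
#'   columns exist.
#' @export
pairwise_identity <- function(a, b, level = c("nt", "aa")) {
  level <- match.arg(level)
  x <- strsplit(toupper(as.character(a)), "")[[1]]
  y <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned to equal length")
  ok <- !(x %in% GAP_CHARS) & !(y %in% GAP_CHARS)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] == y[ok]) / sum(ok)
}

#' All-vs-all identity matrix from a multiple alignment
#'
#' When a nucleotide and an amino-acid alignment of the same taxa are
#' both given, the upper triangle holds nucleotide identities and the
#' lower triangle amino-acid identities (the conventional dual-level
#' identity table); with one alignment the matrix is symmetric.
#'
#' @param nt_aln named character vector / `XStringSet` (nucleotide), or
#'   `NULL`.
#' @param aa_aln named character vector / `XStringSet` (amino acid), or
#'   `NULL`.
#' @return square numeric matrix with unit diagonal.
#' @export
identity_matrix <- function(nt_aln = NULL, aa_aln = NULL) {
  if (is.null(nt_aln) && is.null(aa_aln)) stop("need at least one alignment")
  ref <- if (!is.null(nt_aln)) as_char_matrix(nt_aln) else as_char_matrix(aa_aln)
  labs <- rownames(ref)
  if (!is.null(nt_aln) && !is.null(aa_aln) &&
      !identical(rownames(as_char_matrix(nt_aln)),
                 rownames(as_char_matrix(aa_aln))))
    stop("nt and aa alignments must carry the same taxa in the same order")
  n <- length(labs)
  out <- matrix(1, n, n, dimnames = list(labs, labs))
  ident <- function(m, i, j) {
    ok <- !(m[i, ] %in% GAP_CHARS) & !(m[j, ] %in% GAP_CHARS)
    if (!any(ok)) return(NA_real_)
    sum(m[i, ok] == m[j, ok]) / sum(ok)
  }
  up <- if (!is.null(nt_aln)) as_char_matrix(nt_aln) else as_char_matrix(aa_aln)
  lo <- if (!is.null(aa_aln)) as_char_matrix(aa_aln) else as_char_matrix(nt_aln)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- ident(up, i, j)
    out[j, i] <- ident(lo, i, j)
  }
  out
}

#' Kimura-corrected amino-acid distance
#'
#' Corrects an observed proportion of differing residues `p` for multiple
#' substitutions: `d = -ln(1 - p - 0.2 p^2)`.  Valid while
#' `1 - p - 0.2 p^2 > 0` (p < ~0.854); beyond that the distance is
#' saturated and returned as `NA`.
#'
#' @param p proportion(s) of differing residues, in `[0, 1]`.
#' @return corrected distance(s), `NA` where saturated.
#' @export
kimura_aa_distance <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  arg <- 1 - p - 0.2 * p^2
  out <- ifelse(!is.na(arg) & arg > 0, -log(arg), NA_real_)
  out[!is.na(p) & p == 0] <- 0
  out
}

#' Pairwise distance matrix from a protein alignment
#'
#' Per-pair gap exclusion ("pairwise deletion"): each pair's p-distance
#' uses only columns where both sequences are non-gap, optionally
#' Kimura-corrected.
#'
#' @param aln named character vector / `AAStringSet` multiple alignment.
#' @param correction `"kimura"` (default) or `"none"` (raw p-distance).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
aa_distance_matrix <- function(aln, correction = c("kimura", "none")) {
  correction <- match.arg(correction)
  m <- as_char_matrix(aln)
  n <- nrow(m)
  labs <- rownames(m)
  out <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    ok <- !(m[i, ] %in% GAP_CHARS) & !(m[j, ] %in% GAP_CHARS)
    p <- if (any(ok)) sum(m[i, ok] != m[j, ok]) / sum(ok) else NA_real_
    d <- if (correction == "kimura") kimura_aa_distance(p) else p
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.  Ties
#' in Q are broken deterministically by the lowest (row-major) index
#' pair.  Negative branch lengths are clamped to zero with the deficit
#' moved onto the sister branch, preserving the path length between the
#' joined pair.
#'
#' @param d symmetric numeric matrix (zero diagonal) with dimnames, or a
#'   `dist` object; at least 3 taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(d))) stop("distance matrix contains NA (saturated?) entries")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  # working nodes: positive = tip index, negative = internal node index
  active <- seq_len(n)
  node_id <- seq_len(n)            # tips 1..n; internals n+2.. (ape convention)
  next_internal <- n + 2L          # reserve n+1 for the final root-ish node
  edges <- matrix(0L, 0, 2); lens <- numeric(0)
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, max(0, len))
  }
  D <- d
  ids <- node_id
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    # clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new <- next_internal; next_internal <- next_internal + 1L
    add_edge(new, ids[i], vi)
    add_edge(new, ids[j], vj)
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    ids <- c(ids[keep], new)
    active <- c(active[keep], NA)
  }
  # final 3-node star joined at node n+1
  root <- n + 1L
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(root, ids[1], v1)
  add_edge(root, ids[2], v2)
  add_edge(root, ids[3], v3)
  n_internal <- next_internal - 1L - n
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Columns of the alignment are resampled with replacement `n_reps`
#' times; each replicate is run through [aa_distance_matrix] and
#' [nj_tree], and the support of each internal edge of the reference
#' tree is the fraction of replicate trees containing the same
#' bipartition.  Fully reproducible for a fixed `seed`.
#'
#' @param aln named character vector / `AAStringSet` multiple alignment
#'   (>= 2 columns).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param correction passed to [aa_distance_matrix].
#' @return the reference `phylo` tree with `node.label` holding support
#'   fractions (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = NULL,
                              correction = "kimura") {
  m <- as_char_matrix(aln)
  if (ncol(m) < 2) stop("alignment needs at least 2 columns")
  if (!is.null(seed)) set.seed(seed)
  to_aln <- function(mm) apply(mm, 1, paste, collapse = "")
  ref <- nj_tree(aa_distance_matrix(to_aln(m), correction))
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[b]] <- nj_tree(aa_distance_matrix(to_aln(m[, cols, drop = FALSE]),
                                             correction))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_reps
  ref
}

#' Dot-matrix comparison of two sequences
#'
#' Slides a window of `window` positions along both sequences; cell
#' `(i, j)` is TRUE when the windows starting at `i` in A and `j` in B
#' agree at at least `min_identity` of their positions.  Self-comparison
#' puts an unbroken run on the main diagonal; duplicated segments show
#' as off-diagonal runs.
#'
#' @param seq_a,seq_b character sequences (nt or aa).
#' @param window window length (>= 1, at most the shorter sequence).
#' @param min_identity fraction in `(0, 1]` (default 1: exact window
#'   match).
#' @return logical matrix of class `dot_matrix`,
#'   `(nchar(a)-window+1) x (nchar(b)-window+1)`.
#' @export
dot_matrix <- function(seq_a, seq_b, window = 10, min_identity = 1) {
  a <- strsplit(toupper(as.character(seq_a)), "")[[1]]
  b <- strsplit(toupper(as.character(seq_b)), "")[[1]]
  stopifnot(window >= 1, min_identity > 0, min_identity <= 1)
  if (window > length(a) || window > length(b))
    stop("window longer than a sequence")
  ni <- length(a) - window + 1L; nj <- length(b) - window + 1L
  eq <- outer(a, b, "==")
  acc <- matrix(0L, ni, nj)
  for (k in 0:(window - 1L))
    acc <- acc + eq[seq_len(ni) + k, seq_len(nj) + k, drop = FALSE]
  out <- acc >= ceiling(min_identity * window) - 1e-9
  structure(out, class = c("dot_matrix", class(out)))
}

#' Plot a dot matrix
#' @param x a `dot_matrix`.
#' @param ... passed to `image`.
#' @return `x`, invisibly.
#' @export
plot.dot_matrix <- function(x, ...) {
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)),
                  unclass(x) * 1, col = c("white", "black"),
                  xlab = "sequence A", ylab = "sequence B",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Write a tree in Newick format
#'
#' Optionally roots the tree on a designated outgroup for display; the
#' unrooted topology is unchanged.
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @param outgroup optional tip label to root on.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, outgroup = NULL) {
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::write.tree(tree, file = path)
  invisible(path)
}
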