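# Independent oracles used to validate the package implementations.
# Each is written as directly as possible (explicit loops, no shared code
# with the package internals).

# Exhaustive affine-gap global alignment score (Gotoh three-state DP).
# A gap of length k costs gap_open + k * gap_extend.
nw_affine_score <- function(a, b, match = 2, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (x[i] == y[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                           X[i, j + 1] + gap_extend,
                           Y[i, j + 1] + gap_open + gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                           Y[i + 1, j] + gap_extend,
                           X[i + 1, j] + gap_open + gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Brute-force one-chain-per-locus selection: explicit pairwise comparison
# over every chain of a chain_table, clusters found by BFS over the
# pairwise-overlap graph.
brute_force_dedup <- function(tab) {
  ch <- tab$chains; pu <- tab$puteins
  n <- nrow(ch)
  if (n == 0) return(integer())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- ch$chrom[i] == ch$chrom[j] &&
      ch$start[i] < ch$end[j] && ch$end[i] > ch$start[j]
  }
  seen <- rep(FALSE, n)
  winners <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    best <- comp[[1]]
    for (cand in comp[-1])
      if (beats(ch, pu, cand, best)) best <- cand
    winners <- c(winners, ch$id[best])
  }
  sort(winners)
}

beats <- function(ch, pu, i, j) {
  feat <- function(k) {
    p <- pu[pu$chain_id == ch$id[k], , drop = FALSE]
    c(length(unique(p$gene)), nrow(p), ch$score[k], -ch$start[k], -ch$id[k])
  }
  a <- feat(i); b <- feat(j)
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

# Quadratic per-basepair neighborhood oracle: for every ERV, every model,
# every model basepair, compute the signed offset one position at a time.
brute_profile <- function(ervs, models, window) {
  e <- if (inherits(ervs, "chain_table")) ervs$chains else ervs
  W <- window
  sense <- antisense <- numeric(2 * W + 1)
  for (i in seq_len(nrow(e))) {
    for (j in seq_len(nrow(models))) {
      if (models$chrom[j] != e$chrom[i]) next
      for (x in seq(models$start[j], models$end[j] - 1)) {
        if (x >= e$start[i] && x < e$end[i]) off <- 0
        else if (x < e$start[i]) off <- x - e$start[i]
        else off <- x - e$end[i] + 1
        if (e$strand[i] == "-") off <- -off
        if (abs(off) > W) next
        idx <- off + W + 1
        if (models$strand[j] == e$strand[i]) sense[idx] <- sense[idx] + 1
        else antisense[idx] <- antisense[idx] + 1
      }
    }
  }
  list(sense = sense, antisense = antisense)
}

# Random fixture for neighborhood property tests (small coordinates so the
# brute-force oracle stays cheap).
random_neighborhood_fixture <- function(n_ervs = 4, n_models = 8,
                                        chrom_len = 60000) {
  ervs <- data.frame(
    id = seq_len(n_ervs), chrom = "chr1",
    start = sort(sample.int(chrom_len - 3000, n_ervs)),
    strand = sample(c("+", "-"), n_ervs, TRUE),
    score = 400, genus = "gamma", stringsAsFactors = FALSE)
  ervs$end <- ervs$start + sample(500:2000, n_ervs, TRUE)
  models <- data.frame(
    gene_id = paste0("g", seq_len(n_models)), chrom = "chr1",
    strand = sample(c("+", "-"), n_models, TRUE),
    start = sample.int(chrom_len - 5000, n_models),
    stringsAsFactors = FALSE)
  models$end <- models$start + sample(200:4000, n_models, TRUE)
  list(ervs = ervs, models = models)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Exhaustive least-squares tree search over all unrooted topologies
# (phangorn::allTrees enumerates them); branch lengths by ordinary LS on
# the tip-pair path design matrix, best topology = minimal SSE.  The
# topology enumeration and design matrices depend only on the labels, so
# they are built once and reused across distance matrices.
make_ls_searcher <- function(labs) {
  topos <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  pairs <- t(utils::combn(length(labs), 2))
  designs <- lapply(seq_along(topos), function(t) {
    tr <- topos[[t]]
    A <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (r in seq_len(nrow(pairs))) {
      path <- ape::nodepath(tr, pairs[r, 1], pairs[r, 2])
      for (s in seq_len(length(path) - 1)) {
        hit <- which((tr$edge[, 1] == path[s] & tr$edge[, 2] == path[s + 1]) |
                       (tr$edge[, 2] == path[s] & tr$edge[, 1] == path[s + 1]))
        A[r, hit] <- 1
      }
    }
    A
  })
  function(D) {
    dvec <- D[labs, labs][pairs]
    sse <- vapply(designs, function(A)
      sum(stats::lm.fit(A, dvec)$residuals^2), numeric(1))
    topos[[which.min(sse)]]
  }
}

# Random additive distance matrix from a random unrooted topology with
# internal edges bounded away from zero.
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  list(tree = tr, D = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
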