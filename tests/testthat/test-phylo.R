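test_that("pairwise identity counts identical columns over non-gap columns", {
  expect_equal(pairwise_identity("MKVLW", "MKVLW", "aa"), 1)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  # hand count on a 12-column toy alignment:
  # pos:        123456789012
  a <- "MKV-LWQRSTAC"
  b <- "MKVFLW-RSAAC"
  # comparable columns (both non-gap): 1,2,3,5,6,8,9,10,11,12 -> 10
  # identical among them: M,K,V,L,W,R,S,A,C -> 9
  expect_equal(pairwise_identity(a, b, "aa"), 9 / 10)
  expect_true(is.na(pairwise_identity("---", "AC-")))
  expect_error(pairwise_identity("AC", "ACG"), "equal length")
})

test_that("identity matrices fill nt above and aa below the diagonal", {
  nt <- c(s1 = "ACGTAC", s2 = "ACGTAA", s3 = "TTGTAA")
  aa <- c(s1 = "MK", s2 = "ML", s3 = "QL")
  m <- identity_matrix(nt, aa)
  expect_equal(m["s1", "s2"], 5 / 6)     # nucleotide identity
  expect_equal(m["s2", "s1"], 1 / 2)     # amino-acid identity
  expect_equal(m["s1", "s3"], 3 / 6)
  expect_equal(m["s3", "s2"], 1 / 2)
  expect_equal(diag(m), c(s1 = 1, s2 = 1, s3 = 1))
  # single-level matrix is symmetric
  ms <- identity_matrix(nt_aln = nt)
  expect_equal(ms, t(ms))
})

test_that("the Kimura amino-acid correction behaves on its domain", {
  expect_equal(kimura_aa_distance(0), 0)
  expect_equal(kimura_aa_distance(0.1), -log(1 - 0.1 - 0.2 * 0.01))
  expect_equal(kimura_aa_distance(0.1), 0.10759, tolerance = 1e-4)
  p <- seq(0, 0.85, by = 0.01)
  d <- kimura_aa_distance(p)
  expect_true(all(d >= p))               # correction only stretches
  expect_true(all(diff(d) > 0))          # strictly increasing
  expect_true(is.na(kimura_aa_distance(0.9)))   # saturated
  expect_error(kimura_aa_distance(1.2))
})

test_that("distance matrices use pairwise deletion", {
  aln <- c(a = "MKVL-W", b = "MKML-W", c = "M--LQW")
  D <- aa_distance_matrix(aln, correction = "none")
  expect_equal(D["a", "b"], 1 / 5)   # 5 shared columns, 1 difference
  expect_equal(D["a", "c"], 0)       # shared columns M,L,W all identical
  expect_equal(D, t(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  Dk <- aa_distance_matrix(aln)
  expect_equal(Dk["a", "b"], kimura_aa_distance(0.2))
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4 taxa from tree ((a:1,b:2):3,(c:4,d:5))
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- 3; D["a", "c"] <- 8; D["a", "d"] <- 9
  D["b", "c"] <- 9; D["b", "d"] <- 10; D["c", "d"] <- 9
  D <- D + t(D)
  tr <- nj_tree(D)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_equal(sort(tr$edge.length), c(1, 2, 3, 4, 5))
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], D)
  # 3 taxa: closed-form branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(D3)
  expect_equal(ape::cophenetic.phylo(tr3)[c("x", "y", "z"), c("x", "y", "z")],
               D3)
  # errors: asymmetry and too few taxa
  expect_error(nj_tree(D3[1:2, 1:2]), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("neighbor joining matches ape and clamps negative branches", {
  set.seed(113)
  for (rep in 1:10) {
    fx <- random_additive_matrix(sample(5:8, 1))
    tr <- nj_tree(fx$D)
    expect_true(same_topology(tr, fx$tree))
    expect_true(same_topology(tr, ape::nj(fx$D)))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(fx$D), rownames(fx$D)],
                 fx$D, tolerance = 1e-8)
  }
  # noisy matrices: still matches ape's topology, lengths never negative
  for (rep in 1:10) {
    fx <- random_additive_matrix(6)
    noise <- matrix(runif(36, 0, 0.05), 6)
    D <- fx$D + noise + t(noise); diag(D) <- 0
    tr <- nj_tree(D)
    expect_true(all(tr$edge.length >= 0))
    expect_true(same_topology(tr, ape::nj(D)))
  }
})

planted_alignment <- function(n_per_clade = 4, n_cols = 60, d_between = 0.5,
                              d_within = 0.05) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc1 <- sample(aa, n_cols, TRUE)
  anc2 <- anc1
  flip <- runif(n_cols) < d_between
  anc2[flip] <- sample(aa, sum(flip), TRUE)
  mut <- function(anc) {
    s <- anc
    f <- runif(n_cols) < d_within
    s[f] <- sample(aa, sum(f), TRUE)
    paste(s, collapse = "")
  }
  c(stats::setNames(replicate(n_per_clade, mut(anc1)),
                    paste0("A", seq_len(n_per_clade))),
    stats::setNames(replicate(n_per_clade, mut(anc2)),
                    paste0("B", seq_len(n_per_clade))))
}

test_that("bootstrap supports find planted clades and are seed-stable", {
  set.seed(127)
  aln <- planted_alignment()
  tr <- bootstrap_support(aln, n_reps = 60, seed = 7)
  # the A/B split is an internal edge with high support
  ab_node <- ape::getMRCA(tr, paste0("A", 1:4))
  support <- tr$node.label[ab_node - ape::Ntip(tr)]
  ba_node <- ape::getMRCA(tr, paste0("B", 1:4))
  support2 <- tr$node.label[ba_node - ape::Ntip(tr)]
  expect_gt(max(support, support2, na.rm = TRUE), 0.9)
  tr2 <- bootstrap_support(aln, n_reps = 60, seed = 7)
  expect_equal(tr$node.label, tr2$node.label)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  # a single replicate gives supports in {0, 1}
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 3)
  expect_true(all(tr1$node.label %in% c(0, 1)))
})

test_that("signal-free (star-tree) alignments earn low bootstrap support", {
  set.seed(131)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc <- sample(aa, 80, TRUE)
  # every taxon mutated independently from one ancestor: no internal edges
  aln <- stats::setNames(replicate(6, {
    s <- anc
    f <- runif(80) < 0.1
    s[f] <- sample(aa, sum(f), TRUE)
    paste(s, collapse = "")
  }), paste0("t", 1:6))
  tr <- bootstrap_support(aln, n_reps = 50, seed = 11)
  internal <- tr$node.label[-1]          # drop the root pseudo-node
  expect_lt(median(internal), 0.7)
})

test_that("dot matrices mark the diagonal, planted repeats and reversals", {
  set.seed(137)
  s <- rand_dna(80)
  dm <- dot_matrix(s, s, window = 8)
  expect_true(all(diag(dm)))
  # planted duplicated segment -> off-diagonal run
  seg <- substr(s, 11, 30)
  s2 <- paste0(rand_dna(25), seg, rand_dna(25))
  dm2 <- dot_matrix(s, s2, window = 10)
  hits <- which(dm2, arr.ind = TRUE)
  run <- hits[hits[, 1] >= 11 & hits[, 1] <= 21, , drop = FALSE]
  expect_gte(nrow(run), 11)
  expect_true(all(run[, 2] - run[, 1] == 15))   # constant diagonal offset
  # reversing B mirrors every cell: diagonal runs become anti-diagonal
  s2r <- paste(rev(strsplit(s2, "")[[1]]), collapse = "")
  d1 <- unclass(dot_matrix(s, s2, window = 1))
  d1r <- unclass(dot_matrix(s, s2r, window = 1))
  expect_equal(d1r, d1[, rev(seq_len(ncol(d1)))], ignore_attr = TRUE)
  # partial identity threshold and window validation
  expect_true(dot_matrix("ACGTACGT", "ACGAACGT", window = 8,
                         min_identity = 0.8)[1, 1])
  expect_false(dot_matrix("ACGTACGT", "ACGAACGT", window = 8)[1, 1])
  expect_error(dot_matrix("ACG", "ACGT", window = 5), "window")
})

test_that("trees serialize to Newick with optional outgroup rooting", {
  fx <- {set.seed(139); random_additive_matrix(5)}
  tr <- nj_tree(fx$D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_true(same_topology(tr, back))
  out <- fx$tree$tip.label[1]
  write_newick(tr, f, outgroup = out)
  rooted <- ape::read.tree(f)
  expect_true(ape::is.rooted(rooted))
  expect_true(same_topology(tr, rooted))
})
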