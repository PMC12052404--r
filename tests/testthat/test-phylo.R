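# Distances and distance-based trees.

test_that("allele-sharing distance matches hand computations", {
  G <- toy_G(rbind(c(0L, 1L), c(2L, 1L), c(0L, 1L)))
  D <- ibs_distance(G)
  expect_equal(D["S1", "S2"], 0.5)        # (|0-2| + |1-1|) / (2 * 2)
  expect_equal(D["S1", "S3"], 0)          # identical rows
  G2 <- toy_G(rbind(rep(0L, 5), rep(2L, 5)))
  expect_equal(ibs_distance(G2)["S1", "S2"], 1)   # opposite homozygotes
  # missing entries: only shared non-missing SNPs count
  G3 <- toy_G(rbind(c(0L, NA, 2L), c(2L, 1L, 2L)))
  expect_equal(ibs_distance(G3)["S1", "S2"], (1 + 0) / 2 / 2 * 2 / 2 + 0.25)
  # = mean(|0-2|/2, |2-2|/2) = 0.5 -- spelled out:
  expect_equal(ibs_distance(G3)["S1", "S2"], 0.5)
  # a pair sharing no SNP errors with the pair named
  G4 <- toy_G(rbind(c(0L, NA), c(NA, 1L), c(1L, 1L)))
  expect_error(ibs_distance(G4), "S1.*S2")
})

test_that("nj recovers the generating additive tree exactly", {
  # hand example: ((A:1,B:2):1,(C:3,D:4)) -> pairwise path lengths
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-12)
  # the AB|CD split is the single internal edge, length 1
  splits <- ape::prop.part(tr)
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  # three taxa: closed-form star resolution e_A = (d_AB + d_AC - d_BC)/2
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(D3)
  el <- t3$edge.length[match(seq_len(3), t3$edge[, 2])]
  expect_equal(el[match(c("A", "B", "C"), t3$tip.label)], c(1, 2, 3))
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("random additive trees are rebuilt with exact branch lengths", {
  # oracle: generate a random tree, read off its exact path-length matrix,
  # rebuild with nj/bionj, compare path-length matrices
  set.seed(404)
  for (i in 1:10) {
    ntaxa <- sample(4:8, 1)
    true <- ape::rtree(ntaxa, rooted = FALSE,
                       br = function(n) runif(n, 0.1, 2))
    Dt <- ape::cophenetic.phylo(true)
    rebuilt <- nj_tree(Dt)
    expect_lt(max(abs(ape::cophenetic.phylo(rebuilt)[rownames(Dt),
                                                     colnames(Dt)] - Dt)),
              1e-9)
    # bionj runs in single precision internally, so its bound is float-scale
    reb2 <- bionj_tree(Dt)
    expect_lt(max(abs(ape::cophenetic.phylo(reb2)[rownames(Dt),
                                                  colnames(Dt)] - Dt)),
              1e-5)
  }
})

test_that("bionj equals nj when distances are exactly additive", {
  set.seed(17)
  true <- ape::rtree(6, rooted = FALSE, br = function(n) runif(n, 0.5, 2))
  Dt <- ape::cophenetic.phylo(true)
  t1 <- nj_tree(Dt); t2 <- bionj_tree(Dt)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(Dt), colnames(Dt)],
               ape::cophenetic.phylo(t1)[rownames(Dt), colnames(Dt)],
               tolerance = 1e-5)   # bionj single-precision internals
})

test_that("upgma is ultrametric with average-linkage heights", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(D)
  expect_equal(write_newick(ape::rotateConstr(tr, c("A", "B", "C"))),
               "((A:1,B:1):1,C:2);")
  # arbitrary (non-ultrametric-compatible) input still yields equal
  # root-to-leaf path lengths
  set.seed(5)
  M <- matrix(runif(49, 0.5, 3), 7, 7); M <- (M + t(M)) / 2; diag(M) <- 0
  dimnames(M) <- list(letters[1:7], letters[1:7])
  tu <- upgma_tree(M)
  depths <- ape::node.depth.edgelength(tu)[seq_len(7)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(ape::is.ultrametric(tu, tol = 1e-9))
  # deterministic under repetition
  expect_equal(write_newick(upgma_tree(M)), write_newick(tu))
})

test_that("tree builders are permutation-equivariant", {
  set.seed(31)
  M <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
  dimnames(M) <- list(letters[1:8], letters[1:8])
  perm <- sample(8)
  Mp <- M[perm, perm]
  for (builder in list(nj_tree, upgma_tree)) {
    t1 <- builder(M); t2 <- builder(Mp)
    c1 <- ape::cophenetic.phylo(t1)[letters[1:8], letters[1:8]]
    c2 <- ape::cophenetic.phylo(t2)[letters[1:8], letters[1:8]]
    expect_equal(c2, c1, tolerance = 1e-9)
  }
  # bionj's float internals make near-tied merge choices order-sensitive on
  # arbitrary matrices; on additive input it is equivariant
  true <- ape::rtree(8, rooted = FALSE, br = function(n) runif(n, 0.5, 2))
  Da <- ape::cophenetic.phylo(true)
  pa <- sample(8)
  b1 <- bionj_tree(Da); b2 <- bionj_tree(Da[pa, pa])
  expect_equal(ape::cophenetic.phylo(b2)[rownames(Da), colnames(Da)],
               ape::cophenetic.phylo(b1)[rownames(Da), colnames(Da)],
               tolerance = 1e-5)
})

test_that("negative nj branches are clamped with the deficit on the sibling", {
  # distances violating additivity can force negative NJ branches
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 5.9   # push toward negativity
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  raw <- attr(tr, "raw_edge_lengths")
  expect_equal(sum(raw), sum(tr$edge.length), tolerance = 1e-9) # mass moved, not lost
})

test_that("snp-bootstrap support is bounded, seeded, and maximal for fixed differences", {
  # two breeds with many fixed differences: every resample separates them
  set.seed(2)
  n <- 4; m <- 60
  dos <- rbind(matrix(0L, n, m), matrix(2L, n, m))
  extra <- matrix(sample(0:2, 2 * n * 10, replace = TRUE), 2 * n, 10)
  G <- toy_G(cbind(dos, extra))
  tr <- bootstrap_support(G, "nj", B = 10, seed = 1)
  sup <- attr(tr, "bootstrap")$support
  expect_true(all(sup >= 0 & sup <= 100))
  # the between-group bipartition is in the tree and fully supported
  parts <- ape::prop.part(tr)
  grp <- which(vapply(parts, function(p)
    setequal(tr$tip.label[p], paste0("S", 1:4)) ||
    setequal(tr$tip.label[p], paste0("S", 5:8)), logical(1)))
  expect_true(length(grp) >= 1)
  expect_true(any(sup == 100))
  tr2 <- bootstrap_support(G, "nj", B = 10, seed = 1)
  expect_identical(attr(tr2, "bootstrap")$support, sup)
})
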