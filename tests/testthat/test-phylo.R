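test_that("alignment distances: identical = 0, one mismatch in four = 0.25, symmetric", {
  D <- as.matrix(distanceMatrix(c(a = "AAAA", b = "AAAA", c = "AAAV")))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.25)
  expect_equal(D, t(D))
  expect_error(distanceMatrix(c(a = "MK", a = "MKV", b = "MK")), "duplicate")
  set.seed(11)
  for (k in 1:5) {
    s <- stats::setNames(vapply(1:3, function(i) randomSeq(25), ""),
                         c("x", "y", "z"))
    M1 <- as.matrix(distanceMatrix(s))
    M2 <- as.matrix(distanceMatrix(s[c(3, 1, 2)]))[names(s), names(s)]
    expect_equal(M1, M2)
  }
})

test_that("three-taxon NJ tree has the closed-form branch lengths", {
  D <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- njTree(D)
  expect_equal(ape::Ntip(tree), 3L)
  d <- ape::cophenetic.phylo(tree)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(d, D)
  ## x = (dAB + dAC - dBC) / 2 = 1
  tipEdge <- tree$edge.length[tree$edge[, 2] == match("A", tree$tip.label)]
  expect_equal(tipEdge, 1)
  expect_error(njTree(D[1:2, 1:2]), "n >= 3")
})

test_that("NJ recovers additive trees exactly (topology and branch lengths)", {
  set.seed(515)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(x) stats::runif(x, 0.05, 1))
    D <- ape::cophenetic.phylo(true)
    est <- njTree(D)
    Dhat <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(Dhat, D, tolerance = 1e-10)
  }
})

test_that("four-taxon NJ picks the least-squares-best quartet", {
  set.seed(616)
  for (k in 1:20) {
    ## additive matrix plus mild perturbation keeps a well-defined optimum
    true <- ape::rtree(4, br = function(x) stats::runif(x, 0.2, 1))
    D <- ape::cophenetic.phylo(true)
    D <- D + matrix(stats::runif(16, 0, 0.02), 4)
    D <- (D + t(D)) / 2; diag(D) <- 0
    est <- njTree(D)
    cherry <- treeCherryOf(est, rownames(D)[1])
    if (is.null(cherry)) next  # taxon 1 sits at the trifurcation
    expect_equal(cherry, sort(bestQuartet(D)))
  }
})

test_that("tree output is invariant to taxon order up to isomorphism", {
  set.seed(717)
  for (k in 1:10) {
    true <- ape::rtree(6, br = function(x) stats::runif(x, 0.1, 1))
    D <- ape::cophenetic.phylo(true)
    perm <- sample(rownames(D))
    t1 <- njTree(D)
    t2 <- njTree(D[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
    lab <- rownames(D)
    expect_equal(ape::cophenetic.phylo(t2)[lab, lab],
                 ape::cophenetic.phylo(t1)[lab, lab], tolerance = 1e-10)
  }
})

test_that("negative NJ branches are clamped with the deficit moved to the sibling", {
  ## classic non-additive matrix that produces a negative NJ branch
  D <- matrix(c(0, 2, 3, 4,
                2, 0, 1, 5,
                3, 1, 0, 2,
                4, 5, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(stats::as.dist(D))
  tree <- njTree(D)
  expect_true(all(tree$edge.length >= 0))
  if (any(raw$edge.length < 0)) {
    ## the path length between the joined pair is preserved
    i <- which(raw$edge.length < 0)[1]
    parent <- raw$edge[i, 1]
    kids <- raw$edge[raw$edge[, 1] == parent, 2]
    kids <- kids[kids <= 4]
    if (length(kids) == 2) {
      pair <- raw$tip.label[kids]
      expect_equal(ape::cophenetic.phylo(tree)[pair[1], pair[2]],
                   ape::cophenetic.phylo(raw)[pair[1], pair[2]])
    }
  }
})

test_that("Newick serialization round-trips and quotes awkward labels", {
  set.seed(818)
  for (k in 1:20) {
    tr <- ape::rtree(sample(4:10, 1))
    back <- readNewick(writeNewick(tr))
    ## dist.topo warns that it unroots rooted inputs; that is expected here
    expect_equal(as.numeric(suppressWarnings(ape::dist.topo(tr, back))), 0)
    lab <- tr$tip.label
    expect_equal(ape::cophenetic.phylo(back)[lab, lab],
                 ape::cophenetic.phylo(tr)[lab, lab], tolerance = 1e-8)
  }
  tr <- ape::rtree(3)
  tr$tip.label <- c("foo bar", "baz(1)", "plain")
  s <- writeNewick(tr)
  expect_match(s, "'foo bar'", fixed = TRUE)
  expect_match(s, "'baz(1)'", fixed = TRUE)
  expect_match(s, ";$")
})

test_that("position-II and position-I TE groups are monophyletic in the demo tree", {
  seqs <- demoTESet(seed = 42)
  tree <- njTree(distanceMatrix(seqs))
  rooted <- ape::root(tree, outgroup = "outgroup", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, paste0("posII_", 1:4)))
  expect_true(ape::is.monophyletic(rooted, paste0("posI_", 1:4)))
})
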