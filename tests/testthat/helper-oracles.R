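# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and Biostrings' C implementation): the alignment
# oracle is a top-down recursion over alignment prefixes, the two-sphere
# SASA oracle is the closed-form spherical-cap area, the quartet oracle is a
# least-squares fit over all three quartet topologies.

ANC <- sulmAnchors()

randomSeq <- function(n) paste(sample(names(lactamscan:::AA_FREQS), n,
                                      replace = TRUE), collapse = "")

# Optimal global alignment score by exhaustive recursion over alignment
# prefixes (memoized on position + previous move).  Gap of length L costs
# open + L * extend, matching the package's convention.
bruteGlobalScore <- function(a, b, mat, open = 11, extend = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= na)   # gap in b
      best <- max(best, -extend - (if (prev == "A") 0 else open) +
                    rec(i + 1, j, "A"))
    if (j <= nb)   # gap in a
      best <- max(best, -extend - (if (prev == "B") 0 else open) +
                    rec(i, j + 1, "B"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# Best local alignment score: maximum of the global score over all pairs of
# substrings (plus the empty alignment, score 0).  Exponential in effect, so
# only used on short sequences.
bruteLocalScore <- function(a, b, mat, open = 11, extend = 1) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) for (j1 in 1:nb) for (j2 in j1:nb) {
    s <- bruteGlobalScore(substr(a, i1, i2), substr(b, j1, j2),
                          mat, open, extend)
    if (s > best) best <- s
  }
  best
}

# Analytic SASA of two identical spheres with expanded radius R at centre
# distance d < 2R: each loses a cap of height h = R - d/2.
twoSphereSASA <- function(R, d) {
  h <- max(0, R - d / 2)
  4 * pi * R^2 - 2 * pi * R * h
}

# Least-squares residual of fitting a quartet topology (cherry = the pair
# grouped together) to a 4-taxon distance matrix; 5 branch lengths fit by
# ordinary least squares on the 6 pairwise distances.
quartetResidual <- function(D, cherry) {
  taxa <- rownames(D)
  others <- setdiff(taxa, cherry)
  pairs <- t(combn(taxa, 2))
  X <- matrix(0, nrow(pairs), 5,
              dimnames = list(NULL, c(cherry, others, "mid")))
  y <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    X[k, p[1]] <- 1; X[k, p[2]] <- 1
    sameSide <- all(p %in% cherry) || all(p %in% others)
    if (!sameSide) X[k, "mid"] <- 1
    y[k] <- D[p[1], p[2]]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

bestQuartet <- function(D) {
  taxa <- rownames(D)
  cherries <- list(taxa[c(1, 2)], taxa[c(1, 3)], taxa[c(1, 4)])
  res <- vapply(cherries, function(ch) quartetResidual(D, ch), 0)
  cherries[[which.min(res)]]
}

# Cherry containing taxon `t` in an unrooted 4-taxon tree: its sibling leaf.
treeCherryOf <- function(tree, t) {
  tip <- match(t, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == tip, 1]
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  sibs <- sibs[sibs <= length(tree$tip.label) & sibs != tip]
  if (length(sibs)) sort(c(t, tree$tip.label[sibs[1]])) else NULL
}

# internal shims
makeNRPSGeneForTest <- lactamscan:::makeNRPSGene
verdictToRowForTest <- lactamscan:::verdictToRow
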