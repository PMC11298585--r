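## Distance-based neighbor-joining phylogeny of TE-domain sequences.
## Distances come from pairwise global alignments (1 - fractional identity);
## tree construction is Saitou-Nei neighbor joining via ape::nj, with
## negative branch lengths clamped afterwards.

#' Pairwise distance matrix from global alignments
#'
#' `d(i, j) = 1 - identity(i, j)` where identity is the fraction of global
#' alignment columns with identical residues (see [alignPair()]).
#' Optionally applies a Jukes-Cantor-style correction
#' `-(19/20) * log(1 - 20/19 * d)` for multiple substitutions.
#'
#' @param sequences named character vector or `AAStringSet` (unique
#'   labels, >= 2 sequences).
#' @param params an [alignParams()] (mode forced to global).
#' @param correction `"none"` (default) or `"JC"`.
#' @return a [stats::dist] object with labels.
#' @examples
#' distanceMatrix(c(a = "AAAA", b = "AAAV", c = "AVVV"))
#' @export
distanceMatrix <- function(sequences, params = alignParams(),
                           correction = c("none", "JC")) {
  correction <- match.arg(correction)
  params$mode <- "global"
  seqs <- as.character(sequences)
  labels <- names(sequences)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("sequences must be named")
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- 1 - alignPair(seqs[i], seqs[j], params)@identity
      if (correction == "JC") {
        d <- min(d, 0.94)  # keep the log argument positive
        d <- -(19 / 20) * log(1 - 20 / 19 * d)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  stats::as.dist(D)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via [ape::nj()]).  The
#' returned tree is unrooted with a trifurcating root node.  Negative
#' branch lengths - an artifact NJ can produce on non-additive matrices -
#' are clamped to zero with the deficit moved to the sibling branch, which
#' preserves the path length between the joined pair.
#'
#' @param D a [stats::dist] or symmetric matrix with labels, n >= 3.
#' @return an [ape::phylo] tree.
#' @examples
#' D <- distanceMatrix(c(a = "AAAA", b = "AAAV", c = "AVVV"))
#' njTree(D)
#' @export
njTree <- function(D) {
  if (is.matrix(D)) D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (is.null(n) || n < 3L) stop("neighbor joining needs n >= 3 taxa")
  if (any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and non-negative")
  tree <- ape::nj(D)
  clampNegativeEdges(tree)
}

## Move each negative branch length onto its sibling (largest co-child of
## the same parent), then clamp at zero.
clampNegativeEdges <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (i in neg) {
    parent <- tree$edge[i, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), i)
    if (length(sibs)) {
      j <- sibs[which.max(el[sibs])]
      el[j] <- max(0, el[j] + el[i])
    }
    el[i] <- 0
  }
  tree$edge.length <- el
  tree
}

needsQuoting <- function(label) {
  grepl("[\\s()\\[\\]:;,']", label, perl = TRUE)
}

quoteLabel <- function(label) {
  if (needsQuoting(label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

#' Serialize a tree as Newick
#'
#' Standard Newick with branch lengths, semicolon-terminated.  Labels
#' containing Newick metacharacters (whitespace, parentheses, colon, comma,
#' semicolon, quotes) are single-quoted.  `readNewick(writeNewick(t))`
#' recovers the tree.
#'
#' @param tree an [ape::phylo] object.
#' @param path optional file path; when given the string is also written
#'   there.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `path` is given.
#' @export
writeNewick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  nTip <- length(tree$tip.label)
  rootNode <- nTip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, edgeIdx) {
    lab <- if (node <= nTip) quoteLabel(tree$tip.label[node]) else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, function(k)
        rec(tree$edge[k, 2], k), ""), collapse = ","), ")")
    }
    if (!is.null(edgeIdx) && !is.null(tree$edge.length))
      paste0(lab, ":", format(tree$edge.length[edgeIdx], digits = digits,
                              scientific = FALSE, trim = TRUE))
    else lab
  }
  s <- paste0(rec(rootNode, NULL), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string or file
#'
#' @param x a Newick string (containing "(") or a file path.
#' @return an [ape::phylo] object.
#' @export
readNewick <- function(x) {
  if (grepl("\\(", x)) ape::read.tree(text = x) else ape::read.tree(x)
}

#' Demo TE-domain sequence set
#'
#' Bundled demonstration set for the phylogeny stage: four position-II
#' TE-domain variants (reference-like: acid on the post-beta-7 loop, intact
#' Gln-Cys-Asn motif), four position-I variants derived from a strongly
#' diverged copy with the acid moved after strand beta-6, and a random
#' outgroup.  Group labels are encoded in the names (`posII_*`, `posI_*`,
#' `outgroup`).
#'
#' @param seed integer seed.
#' @return named character vector of protein sequences.
#' @export
demoTESet <- function(seed = 42L) {
  anchors <- sulmAnchors()
  posII <- lapply(1:4, function(i)
    makeTEVariant(seed + i, mutationRate = 0.08, indelRate = 0.005,
                  aspPosition = "II", anchors = anchors)$seq)
  ## the position-I group descends from one strongly diverged common
  ## ancestor so that the two groups separate cleanly in the tree
  posIBase <- makeTEVariant(seed + 100L, mutationRate = 0.35,
                            indelRate = 0.01, aspPosition = "I",
                            qcn = FALSE, anchors = anchors)$seq
  posI <- lapply(1:4, function(i)
    mutateSequence(posIBase, rate = 0.08, indelRate = 0.005,
                   seed = seed + 100L + i)$seq)
  out <- paste(withSeed(seed + 999L, randomResidues(260L)), collapse = "")
  seqs <- c(unlist(posII), unlist(posI), out)
  names(seqs) <- c(paste0("posII_", 1:4), paste0("posI_", 1:4), "outgroup")
  seqs
}
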