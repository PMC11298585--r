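## Seeded synthetic-data generators with planted ground truth.
##
## Design rules: planted edits are applied to anchor positions first and are
## then immune to random mutation, and indels are never placed within two
## residues of a protected position, so the returned truth labels and
## position maps stay valid by construction.  Identical seeds give identical
## outputs.

#' Mutate a protein sequence with a position map
#'
#' Applies seeded point mutations and indels to a sequence, keeping a map
#' from original to new positions.  Positions in `protect` receive no point
#' mutations, and no indel is placed within `indelPad` residues of them.
#' Call inside [withSeed()]-controlled code or pass `seed`.
#'
#' @param seq single sequence string.
#' @param rate per-residue point-mutation probability.
#' @param indelRate per-residue probability of an indel event (split evenly
#'   between a deletion at, and an insertion after, the position).
#' @param protect integer positions immune to mutation.
#' @param indelPad protection radius for indels (default 2).
#' @param seed optional integer seed (isolated from the global RNG).
#' @return list with `seq` (mutated string) and `map` (integer vector,
#'   `map[i]` = new position of original residue `i`, `NA` if deleted).
#' @export
mutateSequence <- function(seq, rate = 0, indelRate = 0, protect = integer(),
                           indelPad = 2L, seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed, mutateSequence(seq, rate, indelRate, protect,
                                         indelPad)))
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  prot <- logical(n); prot[protect[protect >= 1 & protect <= n]] <- TRUE
  nearProt <- logical(n)
  for (d in -indelPad:indelPad) {
    idx <- which(prot) + d
    nearProt[idx[idx >= 1 & idx <= n]] <- TRUE
  }
  ## point mutations
  hit <- which(stats::runif(n) < rate & !prot)
  if (length(hit)) {
    aa <- names(AA_FREQS)
    repl <- vapply(chars[hit],
                   function(old) sample(setdiff(aa, old), 1L), "")
    chars[hit] <- repl
  }
  ## indels
  ev <- stats::runif(n)
  del <- ev < indelRate / 2 & !nearProt
  ins <- ev >= indelRate / 2 & ev < indelRate & !nearProt
  keep <- !del
  map <- cumsum(keep) + c(0L, cumsum(ins)[-n])
  map[del] <- NA_integer_
  if (any(ins)) {
    pieces <- character(n)
    pieces[keep] <- chars[keep]
    pieces[ins] <- paste0(pieces[ins], randomResidues(sum(ins)))
    out <- paste(pieces, collapse = "")
  } else {
    out <- paste(chars[keep], collapse = "")
  }
  list(seq = out, map = as.integer(map))
}

## Planted edits for the TE-domain criteria, as author-position -> residue.
## aspPosition: "II" keeps the reference Asp2926; "I" ablates it and plants
## an Asp in the position-I window; "none" ablates it outright.
plantedTEEdits <- function(anchors, qcn = TRUE, aspPosition = "II",
                           nCationic = 3L) {
  stopifnot(aspPosition %in% c("I", "II", "none"), nCationic %in% 0:3)
  ed <- character()
  if (!qcn)
    ed[as.character(anchors@motifWindow[3])] <- "V"  # Asn -> hydrophobic
  if (aspPosition != "II")
    ed[as.character(anchors@triad[["asp"]])] <- "A"
  if (aspPosition == "I")
    ed[as.character(anchors@positionIWindow[1] + 7L)] <- "D"
  for (k in seq_len(3)) {
    if (k > nCationic)
      ed[as.character(anchors@cationicPos[k])] <- "A"
  }
  ed
}

teProtectedPositions <- function(anchors) {
  c(anchors@triad, anchors@motifWindow, anchors@cationicPos,
    anchors@positionIWindow[1] + 7L)
}

applyEdits <- function(chars, edits, offset = 0L) {
  if (length(edits)) {
    pos <- as.integer(names(edits)) - offset
    stopifnot(all(pos >= 1L & pos <= length(chars)))
    chars[pos] <- unname(edits)
  }
  chars
}

#' Synthetic TE-domain variant with planted features
#'
#' Copies the reference TE domain (SulTE stand-in, author residues
#' 2723-2984), plants or ablates the screened features, then applies seeded
#' random mutations everywhere else.  Contradictory requests (e.g. a planted
#' Gln-Cys-Asn motif together with a mutation of the catalytic cysteine via
#' `extraEdits`) are rejected.
#'
#' @param seed integer seed.
#' @param mutationRate,indelRate per-residue rates in \[0, 1\].
#' @param qcn keep the Gln-Cys-Asn motif (`FALSE` replaces the Asn with Val).
#' @param aspPosition `"II"` (reference arrangement), `"I"` (acid moved to
#'   the post-beta-6 window) or `"none"`.
#' @param nCationic how many of the three cationic positions keep R/K (0-3).
#' @param flank residues of random sequence appended on each side.
#' @param extraEdits optional named character vector of additional author
#'   position -> residue edits.
#' @param anchors a [ReferenceAnchors-class].
#' @return list with `seq` (variant string), `map` (author TE numbering ->
#'   variant position, `NA` if deleted), and `labels` (the planted flags).
#' @examples
#' v <- makeTEVariant(seed = 1, mutationRate = 0.05, indelRate = 0.005)
#' substr(v$seq, v$map[as.character(2818)], v$map[as.character(2818)])
#' @export
makeTEVariant <- function(seed, mutationRate = 0, indelRate = 0,
                          qcn = TRUE, aspPosition = "II", nCationic = 3L,
                          flank = 0L, extraEdits = character(),
                          anchors = sulmAnchors()) {
  edits <- plantedTEEdits(anchors, qcn, aspPosition, nCationic)
  clash <- intersect(names(extraEdits), names(edits))
  if (length(clash))
    stop("contradictory edits at position(s): ", paste(clash, collapse = ", "))
  if (qcn && any(as.integer(names(extraEdits)) %in% anchors@motifWindow))
    stop("extraEdits would overwrite the planted Gln-Cys-Asn motif")
  edits <- c(edits, extraEdits)
  chars <- strsplit(anchors@teSeq, "")[[1]]
  chars <- applyEdits(chars, edits, offset = anchors@teStart - 1L)
  prot <- unique(c(teProtectedPositions(anchors),
                   as.integer(names(edits)))) - anchors@teStart + 1L
  withSeed(seed, {
    mut <- mutateSequence(paste(chars, collapse = ""), mutationRate,
                          indelRate, protect = prot)
    pre <- if (flank > 0L) paste(randomResidues(flank), collapse = "") else ""
    post <- if (flank > 0L) paste(randomResidues(flank), collapse = "") else ""
    map <- mut$map + flank
    names(map) <- seq_along(map) + anchors@teStart - 1L
    list(seq = paste0(pre, mut$seq, post), map = map,
         labels = list(qcn = qcn, aspPosition = aspPosition,
                       nCationic = as.integer(nCationic)))
  })
}

## Full-length NRPS gene variant (SulM stand-in) with planted TE and
## A-domain features.  Map is author numbering (1..2984) -> variant position.
makeNRPSGene <- function(seed, mutationRate = 0, indelRate = 0,
                         qcn = TRUE, aspPosition = "II", nCationic = 3L,
                         dapCode = TRUE, anchors = sulmAnchors()) {
  edits <- plantedTEEdits(anchors, qcn, aspPosition, nCationic)
  if (!dapCode) {
    ## spoil the specificity code at three interior positions
    spoil <- anchors@codePositions[c(3L, 5L, 8L)]
    cur <- substring(referenceSulM(), spoil, spoil)
    repl <- vapply(cur, function(r) if (r == "A") "G" else "A", "")
    ed2 <- stats::setNames(repl, as.character(spoil))
    edits <- c(edits, ed2)
  }
  full <- referenceSulM()
  chars <- applyEdits(strsplit(full, "")[[1]], edits)
  prot <- unique(c(teProtectedPositions(anchors), anchors@codePositions,
                   seq(REF_LAYOUT$pcpPos, length.out = 5L),
                   as.integer(names(edits))))
  withSeed(seed, {
    mut <- mutateSequence(paste(chars, collapse = ""), mutationRate,
                          indelRate, protect = prot)
    names(mut$map) <- seq_along(mut$map)
    list(seq = mut$seq, map = mut$map,
         labels = list(qcn = qcn, aspPosition = aspPosition,
                       nCationic = as.integer(nCationic), dapCode = dapCode))
  })
}

#' Synthetic gene cluster with a known verdict
#'
#' Assembles a cluster around one full-length NRPS gene (SulM stand-in)
#' whose TE and adenylation-domain features are planted per the flags, an
#' optional sulfotransferase gene (annotated or left for the alignment path
#' to find), and random decoy genes.  The returned truth states what each
#' criterion should report.
#'
#' @inheritParams makeTEVariant
#' @param clusterId cluster id.
#' @param dapCode plant (`TRUE`) or spoil (`FALSE`) the DAP specificity
#'   code.
#' @param sulfotransferase include a sulfotransferase gene.
#' @param annotateSulfo annotate that gene as "sulfotransferase" (keyword
#'   path) rather than "hypothetical protein" (alignment path).
#' @param nDecoys number of random decoy genes.
#' @return list with `cluster` ([GeneCluster-class]) and `truth` (named
#'   logical vector over the four criteria plus `call`).
#' @examples
#' cl <- makeCluster(seed = 7)
#' cl$truth
#' @export
makeCluster <- function(seed, mutationRate = 0, indelRate = 0,
                        qcn = TRUE, aspPosition = "II", nCationic = 3L,
                        dapCode = TRUE, sulfotransferase = TRUE,
                        annotateSulfo = FALSE, nDecoys = 1L,
                        clusterId = paste0("syn", seed),
                        anchors = sulmAnchors()) {
  gene <- makeNRPSGene(seed, mutationRate, indelRate, qcn, aspPosition,
                       nCationic, dapCode, anchors)
  seqs <- c(nrps1 = gene$seq)
  ann <- "nonribosomal peptide synthetase"
  if (sulfotransferase) {
    sul <- withSeed(seed + 500000L,
                    mutateSequence(anchors@sulfoSeq, mutationRate, indelRate))
    seqs <- c(seqs, sulf1 = sul$seq)
    ann <- c(ann, if (annotateSulfo) "sulfotransferase" else
      "hypothetical protein")
  }
  if (nDecoys > 0L) {
    dec <- withSeed(seed + 900000L, vapply(seq_len(nDecoys), function(i)
      paste(randomResidues(sample(250:350, 1L)), collapse = ""), ""))
    names(dec) <- paste0("orf", seq_len(nDecoys))
    seqs <- c(seqs, dec)
    ann <- c(ann, rep("hypothetical protein", nDecoys))
  }
  truth <- c(triad_motif = qcn && aspPosition == "II",
             cationic_site = nCationic >= 2L,
             dap_code = dapCode,
             sulfotransferase = sulfotransferase)
  list(cluster = geneCluster(clusterId, seqs, ann),
       truth = truth,
       call = if (all(truth)) "candidate" else "rejected")
}

#' Seeded panel of synthetic clusters
#'
#' Draws `n` clusters with independently sampled feature flags (motif and
#' DAP code present with probability 1/2 each, acid position II with
#' probability 1/2, cationic count uniform on 0-3, sulfotransferase present
#' with probability 1/2, annotated half the time) at a common mutation rate.
#'
#' @param n number of clusters.
#' @param mutationRate,indelRate per-residue rates applied to every gene.
#' @param seed integer seed controlling both the flag draws and the
#'   per-cluster generator seeds.
#' @param anchors a [ReferenceAnchors-class].
#' @return list of [makeCluster()] outputs.
#' @export
makeClusterPanel <- function(n = 200L, mutationRate = 0, indelRate = 0,
                             seed = 1L, anchors = sulmAnchors()) {
  flags <- withSeed(seed, data.frame(
    sub = sample.int(2^30, n),
    qcn = stats::runif(n) < 0.5,
    aspPos = sample(c("II", "I", "none"), n, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25)),
    nCat = sample(0:3, n, replace = TRUE),
    dap = stats::runif(n) < 0.5,
    sulfo = stats::runif(n) < 0.5,
    annot = stats::runif(n) < 0.5))
  lapply(seq_len(n), function(i) {
    makeCluster(seed = flags$sub[i], mutationRate = mutationRate,
                indelRate = indelRate, qcn = flags$qcn[i],
                aspPosition = flags$aspPos[i],
                nCationic = flags$nCat[i], dapCode = flags$dap[i],
                sulfotransferase = flags$sulfo[i],
                annotateSulfo = flags$annot[i],
                clusterId = sprintf("panel%03d", i), anchors = anchors)
  })
}

## ---- toy coordinate generators ------------------------------------------

#' Ideal alpha-helix C-alpha trace
#'
#' C-alpha coordinates of an ideal alpha-helix along +z: rise 1.5 A per
#' residue, 100 degrees twist, helix radius 2.3 A.
#'
#' @param n number of residues (>= 5 for axis fitting).
#' @param rise rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param radius helix radius (Angstrom).
#' @return n x 3 coordinate matrix.
#' @export
makeToyHelix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n) - 1L
  th <- i * twist * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = i * rise)
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotationMatrix <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  a <- angle * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Apply a rigid transform to row-vector coordinates
#'
#' Computes `X %*% t(R) + t` row-wise.
#'
#' @param X n x 3 coordinate matrix.
#' @param R 3x3 rotation matrix.
#' @param t translation vector (length 3).
#' @return transformed n x 3 matrix.
#' @export
applyRigid <- function(X, R, t = c(0, 0, 0)) {
  sweep(X %*% t(R), 2, -t)
}

#' Random proper rotation
#'
#' Uniform random rotation built from a normalized quaternion.
#'
#' @return 3x3 proper rotation matrix (uses the current RNG stream).
#' @export
randomRotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

#' Toy structure with a recorded rigid transform
#'
#' Builds an ideal poly-Ala helix (or a seeded random coordinate cloud) and
#' a rigid-body transformed copy with optional Gaussian coordinate noise;
#' the applied transform is returned as ground truth.
#'
#' @param seed integer seed.
#' @param n number of residues / points.
#' @param kind `"helix"` or `"cloud"`.
#' @param noise coordinate noise s.d. in Angstrom applied to the copy.
#' @return list with `coords`, `copy` (n x 3 matrices), `rotation`,
#'   `translation`, and `structure` / `structureCopy` as
#'   [ProteinStructure-class] objects.
#' @export
makeToyStructure <- function(seed, n = 30L, kind = c("helix", "cloud"),
                             noise = 0) {
  kind <- match.arg(kind)
  withSeed(seed, {
    X <- if (kind == "helix") makeToyHelix(n) else
      matrix(stats::rnorm(n * 3, sd = 10), ncol = 3,
             dimnames = list(NULL, c("x", "y", "z")))
    R <- randomRotation()
    t <- stats::rnorm(3, sd = 20)
    Y <- applyRigid(X, R, t)
    if (noise > 0) Y <- Y + matrix(stats::rnorm(n * 3, sd = noise), ncol = 3)
    list(coords = X, copy = Y, rotation = R, translation = t,
         structure = caStructure(X), structureCopy = caStructure(Y, chain = "B"))
  })
}

#' C-alpha-only structure from coordinates
#'
#' Wraps a coordinate matrix as a poly-Ala C-alpha [ProteinStructure-class]
#' (residues numbered from `startRes`).
#'
#' @param coords n x 3 matrix.
#' @param chain chain id.
#' @param startRes first residue number.
#' @return a [ProteinStructure-class].
#' @export
caStructure <- function(coords, chain = "A", startRes = 1L) {
  n <- nrow(coords)
  new("ProteinStructure",
      atoms = data.frame(type = "ATOM", chain = chain,
                         resno = startRes + seq_len(n) - 1L,
                         insert = "", resid = "ALA", elety = "CA",
                         elesy = "C",
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         o = 1, stringsAsFactors = FALSE),
      title = "synthetic C-alpha trace")
}
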