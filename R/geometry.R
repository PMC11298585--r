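## Helix axes, inter-helix angles, catalytic-triad distances, radius of
## gyration.

#' Fit a helix axis
#'
#' The axis direction is estimated from the second differences of the
#' C-alpha trace: for a helix the second-difference vectors point from each
#' residue toward the local axis (they have no component along it), so the
#' cross products of successive second differences all lie along the axis;
#' their average is the axis estimate.  This is exact for an ideal helix of
#' any length, unlike the principal component of the coordinate covariance,
#' which is biased by incomplete final turns.  The result is sign-oriented
#' from the N- to the C-terminus of the span; a degenerate (straight-line)
#' trace falls back to the principal component.
#'
#' @param ca ordered n x 3 C-alpha coordinate matrix, n >= 5.
#' @return a [HelixAxis-class].
#' @examples
#' helixAxis(makeToyHelix(12))@direction   # ~ (0, 0, 1)
#' @export
helixAxis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 5L) stop("need at least 5 consecutive C-alpha atoms")
  ctr <- colMeans(ca)
  nc <- ca[n, ] - ca[1, ]
  d2 <- ca[seq_len(n - 2L) + 2L, , drop = FALSE] -
    2 * ca[seq_len(n - 2L) + 1L, , drop = FALSE] +
    ca[seq_len(n - 2L), , drop = FALSE]
  m <- nrow(d2) - 1L
  cr <- crossRows(d2[seq_len(m), , drop = FALSE],
                  d2[seq_len(m) + 1L, , drop = FALSE])
  flip <- sign(cr %*% nc)
  v <- colSums(cr * as.numeric(flip))
  if (sqrt(sum(v^2)) < 1e-8) {
    ev <- eigen(stats::cov(ca), symmetric = TRUE)
    v <- ev$vectors[, 1]
  }
  if (sum(v * nc) < 0) v <- -v
  new("HelixAxis", direction = v / sqrt(sum(v^2)), centroid = ctr,
      nRes = n)
}

crossRows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

#' Angle between two helix axes
#'
#' Reported in \[0, 180\] degrees with the N-to-C orientation of each axis
#' respected (no folding of obtuse angles onto acute ones).
#'
#' @param h1,h2 [HelixAxis-class] objects.
#' @return angle in degrees.
#' @export
interhelixAngle <- function(h1, h2) {
  d <- sum(h1@direction * h2@direction)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Helix axis for a residue span of a structure
#'
#' Convenience wrapper: extracts the C-alpha trace of `chain:from-to` and
#' fits the axis.
#'
#' @param s a [ProteinStructure-class].
#' @param selection selection string covering >= 5 residues.
#' @return a [HelixAxis-class].
#' @export
helixAxisFor <- function(s, selection) {
  tab <- caTable(s, selection)
  tab <- tab[order(tab$resno), ]
  helixAxis(as.matrix(tab[, c("x", "y", "z")]))
}

TRIAD_ATOMS <- list(nucleophile = c(CYS = "SG", SER = "OG", ALA = "CB"),
                    acid = c(ASP = "OD1|OD2", GLU = "OE1|OE2"),
                    his = "ND1|NE2")

#' Catalytic-triad geometry
#'
#' Distances characterizing the Ser/Cys-His-Asp triad: the minimum distance
#' from the histidine imidazole nitrogens (ND1/NE2) to the nucleophile
#' (Cys SG or Ser OG), and to the acid carboxylate oxygens (Asp OD1/OD2 or
#' Glu OE1/OE2).  Missing side-chain atoms are an error listing them.
#'
#' @param s a [ProteinStructure-class].
#' @param triad named residue numbers `c(nuc =, asp =, his =)` (author
#'   numbering).
#' @param chain chain id (default: the first chain carrying the histidine).
#' @return named numeric vector `c(his_nuc =, his_asp =)` in Angstrom.
#' @export
triadGeometry <- function(s, triad = c(nuc = 2818, asp = 2926, his = 2956),
                          chain = NULL) {
  a <- s@atoms
  if (is.null(chain)) {
    cand <- a$chain[a$resno == triad[["his"]] & a$resid == "HIS"]
    chain <- if (length(cand)) cand[1] else unique(a$chain)[1]
  }
  a <- a[a$chain == chain, ]
  sideAtoms <- function(resno, pattern) {
    r <- a[a$resno == resno & grepl(pattern, a$elety), ]
    as.matrix(r[, c("x", "y", "z")])
  }
  resName <- function(resno) {
    rn <- unique(a$resid[a$resno == resno])
    if (!length(rn)) stop("residue ", resno, " absent from chain ", chain)
    rn[1]
  }
  nucRes <- resName(triad[["nuc"]])
  nucPat <- switch(nucRes, CYS = "^SG$", SER = "^OG$",
                   stop("nucleophile residue ", triad[["nuc"]], " is ",
                        nucRes, ", expected CYS or SER"))
  aspRes <- resName(triad[["asp"]])
  aspPat <- switch(aspRes, ASP = "^OD[12]$", GLU = "^OE[12]$",
                   stop("acid residue ", triad[["asp"]], " is ", aspRes,
                        ", expected ASP or GLU"))
  hisN <- sideAtoms(triad[["his"]], "^N[DE][12]$")
  nucA <- sideAtoms(triad[["nuc"]], nucPat)
  aspO <- sideAtoms(triad[["asp"]], aspPat)
  missing <- c(if (!nrow(hisN)) sprintf("His%d ND1/NE2", triad[["his"]]),
               if (!nrow(nucA)) sprintf("%s%d side chain", nucRes,
                                        triad[["nuc"]]),
               if (!nrow(aspO)) sprintf("%s%d carboxylate", aspRes,
                                        triad[["asp"]]))
  if (length(missing))
    stop("missing side-chain atoms: ", paste(missing, collapse = "; "))
  c(his_nuc = minPairDist(hisN, nucA), his_asp = minPairDist(hisN, aspO))
}

minPairDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.97, F = 18.998,
                   CL = 35.45, BR = 79.904, I = 126.904)

#' Radius of gyration
#'
#' `Rg = sqrt(sum(m_i * |x_i - xbar|^2) / sum(m_i))`, mass-weighted by
#' default (unknown elements fall back to carbon mass with a warning).
#'
#' @param s a [ProteinStructure-class] or an n x 3 coordinate matrix.
#' @param massWeighted use atomic masses; otherwise unit weights.
#' @param selection optional selection string.
#' @return Rg in the coordinate units (Angstrom).
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1.0
#' @export
radiusOfGyration <- function(s, massWeighted = TRUE, selection = NULL) {
  if (is(s, "ProteinStructure")) {
    a <- s@atoms[selectAtoms(s, selection), ]
    xyz <- as.matrix(a[, c("x", "y", "z")])
    m <- if (massWeighted) {
      el <- toupper(a$elesy)
      known <- el %in% names(ATOMIC_MASSES)
      if (!all(known)) {
        warning("unknown element(s) ",
                paste(unique(el[!known]), collapse = ", "),
                "; using carbon mass")
        el[!known] <- "C"
      }
      unname(ATOMIC_MASSES[el])
    } else rep(1, nrow(xyz))
  } else {
    xyz <- as.matrix(s)
    m <- rep(1, nrow(xyz))
  }
  if (!nrow(xyz)) stop("no atoms selected")
  ctr <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
}
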