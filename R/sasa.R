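## Shrake-Rupley solvent-accessible surface area and buried interface area.
## No installed R package provides SASA directly, so the classic algorithm
## is implemented here: each atom's accessible fraction is estimated from
## test points on its solvent-expanded sphere that fall outside every
## neighbour's expanded sphere.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Van der Waals radius table
#'
#' Radii (Angstrom) used by [sasaAtoms()]: C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, Se 1.90 plus halogens.  Hydrogen atoms are ignored entirely
#' (united-atom convention).
#'
#' @return named numeric vector.
#' @export
vdwRadii <- function() VDW_RADII

## Deterministic quasi-uniform points on the unit sphere (golden spiral).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' For each heavy atom, `n_points` quasi-uniform test points are placed on
#' the sphere of radius `r_vdw + probe`; the accessible fraction (points
#' inside no neighbouring expanded sphere) times the sphere area
#' `4 pi (r + probe)^2` is the atom's SASA.  Hydrogens are skipped (area
#' 0); an unknown element is an error naming the atom.
#'
#' @param s a [ProteinStructure-class], or an atom data.frame with `x`,
#'   `y`, `z` and `elesy`.
#' @param probe probe radius in Angstrom (default 1.40, a water molecule).
#' @param nPoints test points per atom (default 960).
#' @param selection optional selection string limiting the atoms whose
#'   area is computed AND the occluders considered.
#' @return numeric vector of per-atom areas (Angstrom^2), one per selected
#'   atom row.
#' @examples
#' carbon <- proteinStructure(data.frame(chain = "A", resno = 1,
#'   elety = "C", x = 0, y = 0, z = 0))
#' sum(sasaAtoms(carbon))          # ~ 4*pi*(1.70+1.40)^2
#' @export
sasaAtoms <- function(s, probe = 1.4, nPoints = 960L, selection = NULL) {
  a <- if (is(s, "ProteinStructure")) {
    s@atoms[selectAtoms(s, selection), , drop = FALSE]
  } else s
  elem <- toupper(a$elesy)
  isH <- elem %in% c("H", "D")
  heavy <- which(!isH)
  unknown <- setdiff(unique(elem[heavy]), names(VDW_RADII))
  if (length(unknown)) {
    bad <- which(elem %in% unknown)[1]
    stop(sprintf("unknown element '%s' for atom %s %s%d",
                 elem[bad], a$elety[bad], a$chain[bad], a$resno[bad]))
  }
  out <- numeric(nrow(a))
  if (!length(heavy)) return(out)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  rads <- unname(VDW_RADII[elem[heavy]]) + probe
  pts <- spherePoints(nPoints)
  m <- length(heavy)
  maxR <- max(rads)
  for (k in seq_len(m)) {
    ck <- xyz[k, ]
    d2 <- (xyz[, 1] - ck[1])^2 + (xyz[, 2] - ck[2])^2 + (xyz[, 3] - ck[3])^2
    nb <- which(d2 < (rads[k] + rads)^2 & d2 > 1e-12)
    P <- sweep(pts * rads[k], 2, ck, "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rads[j]^2
    }
    out[heavy[k]] <- mean(acc) * 4 * pi * rads[k]^2
  }
  out
}

#' Total SASA
#'
#' @inheritParams sasaAtoms
#' @return total area (Angstrom^2).
#' @export
sasaTotal <- function(s, probe = 1.4, nPoints = 960L, selection = NULL) {
  sum(sasaAtoms(s, probe, nPoints, selection))
}

#' Buried interface area between two atom groups
#'
#' Computes `(SASA_A + SASA_B - SASA_AB) / 2`, the buried (interface) area
#' between two disjoint selections, with per-residue buried contributions
#' and the residue pairs in contact at `contactCutoff`.  Only protein
#' (ATOM) records are used by default, so cofactors such as the
#' phosphopantetheine arm are excluded.
#'
#' @param s a [ProteinStructure-class].
#' @param selA,selB disjoint selection strings.
#' @param probe,nPoints SASA parameters.
#' @param proteinOnly restrict to ATOM records (default TRUE).
#' @param contactCutoff heavy-atom distance (Angstrom) defining contact
#'   residue pairs (default 4.5).
#' @return an [InterfaceReport-class].
#' @export
interfaceArea <- function(s, selA, selB, probe = 1.4, nPoints = 960L,
                          proteinOnly = TRUE, contactCutoff = 4.5) {
  inA <- selectAtoms(s, selA, proteinOnly = proteinOnly)
  inB <- selectAtoms(s, selB, proteinOnly = proteinOnly)
  if (any(inA & inB)) stop("selections overlap")
  if (!any(inA) || !any(inB)) stop("empty selection")
  atomsA <- s@atoms[inA, ]; atomsB <- s@atoms[inB, ]
  sasaA <- sasaAtoms(atomsA, probe, nPoints)
  sasaB <- sasaAtoms(atomsB, probe, nPoints)
  ab <- rbind(atomsA, atomsB)
  sasaAB <- sasaAtoms(ab, probe, nPoints)
  nA <- nrow(atomsA)
  buriedPer <- c(sasaA, sasaB) - sasaAB
  area <- (sum(sasaA) + sum(sasaB) - sum(sasaAB)) / 2
  grp <- rep(c("A", "B"), c(nA, nrow(atomsB)))
  resKey <- paste(ab$chain, ab$resno, ab$insert)
  per <- stats::aggregate(buriedPer,
                          by = list(chain = ab$chain, resno = ab$resno,
                                    resid = ab$resid, group = grp),
                          FUN = sum)
  names(per)[5] <- "buried"
  per <- per[per$buried > 1e-6, ]
  per <- per[order(per$group, per$chain, per$resno), ]
  rownames(per) <- NULL
  contacts <- contactResidues(atomsA, atomsB, contactCutoff)
  new("InterfaceReport", area = max(area, 0), perResidue = per,
      contacts = contacts, probe = probe, nPoints = as.integer(nPoints))
}

contactResidues <- function(atomsA, atomsB, cutoff) {
  xa <- as.matrix(atomsA[, c("x", "y", "z")])
  xb <- as.matrix(atomsB[, c("x", "y", "z")])
  hits <- list()
  for (i in seq_len(nrow(xa))) {
    d2 <- (xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
      (xb[, 3] - xa[i, 3])^2
    j <- which(d2 <= cutoff^2)
    if (length(j))
      hits[[length(hits) + 1L]] <- data.frame(
        chainA = atomsA$chain[i], resnoA = atomsA$resno[i],
        residA = atomsA$resid[i],
        chainB = atomsB$chain[j], resnoB = atomsB$resno[j],
        residB = atomsB$resid[j], stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(chainA = character(), resnoA = integer(),
                      residA = character(), chainB = character(),
                      resnoB = integer(), residB = character(),
                      stringsAsFactors = FALSE))
  tab <- unique(do.call(rbind, hits))
  tab <- tab[order(tab$chainA, tab$resnoA, tab$chainB, tab$resnoB), ]
  rownames(tab) <- NULL
  tab
}
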