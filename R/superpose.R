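## Kabsch least-squares superposition with optional outlier-rejecting
## refinement, and alignment-mediated C-alpha RMSD between structures.

#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of paired coordinate sets
#' (Kabsch algorithm via SVD, proper rotation enforced).  With
#' `refine = TRUE` the fit is iterated up to `maxCycles` times, each cycle
#' rejecting pairs whose deviation exceeds `rejectFactor` times the current
#' RMSD and recomputing on the survivors — an approximation of the
#' outlier-trimming behaviour of structure-alignment "super" commands.  The
#' reported RMSD covers the final pair set.
#'
#' @param moving,fixed n x 3 coordinate matrices, paired row by row,
#'   n >= 3 and not collinear.
#' @param refine logical, run rejection cycles.
#' @param maxCycles maximum refinement cycles (default 5).
#' @param rejectFactor deviation multiple beyond which a pair is rejected
#'   (default 2).
#' @return a [SuperpositionResult-class]; apply with [applyRigid()] as
#'   `applyRigid(moving, rotation, translation)`.
#' @examples
#' X <- makeToyHelix(20)
#' sp <- kabschSuperpose(X, applyRigid(X, rotationMatrix("x", 30), c(1, 2, 3)))
#' sp@rmsd
#' @export
kabschSuperpose <- function(moving, fixed, refine = FALSE, maxCycles = 5L,
                            rejectFactor = 2) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3L)
    stop("moving and fixed must be equal-size n x 3 matrices")
  n <- nrow(moving)
  if (n < 3L) stop("need at least 3 paired atoms")
  kept <- rep(TRUE, n)
  fit <- kabschCore(moving, fixed)
  if (refine) {
    for (cycle in seq_len(maxCycles)) {
      dev <- sqrt(rowSums((applyRigid(moving, fit$R, fit$t) - fixed)^2))
      thr <- rejectFactor * fit$rmsd
      newKept <- kept & dev <= pmax(thr, 1e-12)
      if (sum(newKept) < 3L || identical(newKept, kept)) break
      kept <- newKept
      fit <- kabschCore(moving[kept, , drop = FALSE],
                        fixed[kept, , drop = FALSE])
    }
  }
  new("SuperpositionResult", rotation = fit$R, translation = fit$t,
      nPairs = as.integer(sum(kept)), rmsd = fit$rmsd,
      nRejected = as.integer(n - sum(kept)), kept = kept)
}

kabschCore <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))   # 3x3: t(Pc) %*% Qc
  if (sv$d[2] < 1e-10)
    stop("degenerate (collinear) coordinate set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cq - R %*% cp)
  rmsd <- sqrt(mean(rowSums((applyRigid(P, R, t) - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

## Residue-keyed CA pairing between two structures.  When map is NULL,
## residues are paired by identical (resno, insert) within the selections;
## otherwise map is a data.frame with columns refPos (numbering of `a`) and
## queryPos (numbering of `b`), e.g. from mapPositions().
pairCA <- function(a, b, selA = NULL, selB = NULL, map = NULL,
                   exclude = NULL) {
  ta <- caTable(a, selA); tb <- caTable(b, selB)
  if (!is.null(exclude)) {
    drop <- rep(FALSE, nrow(ta))
    for (i in seq_len(nrow(exclude)))
      drop <- drop | (ta$resno >= exclude$from[i] & ta$resno <= exclude$to[i])
    ta <- ta[!drop, ]
  }
  if (is.null(map)) {
    keyA <- paste(ta$resno, ta$insert)
    keyB <- paste(tb$resno, tb$insert)
    common <- intersect(keyA, keyB)
    ia <- match(common, keyA); ib <- match(common, keyB)
  } else {
    ok <- !is.na(map$queryPos)
    ia <- match(map$refPos[ok], ta$resno)
    ib <- match(map$queryPos[ok], tb$resno)
    use <- !is.na(ia) & !is.na(ib)
    ia <- ia[use]; ib <- ib[use]
  }
  list(A = as.matrix(ta[ia, c("x", "y", "z")]),
       B = as.matrix(tb[ib, c("x", "y", "z")]),
       resA = ta$resno[ia], resB = tb$resno[ib])
}

#' C-alpha RMSD between two structures
#'
#' Superposes paired C-alpha atoms of two structures and reports the RMSD
#' and pair count.  Residues are paired by author residue number within
#' the selections, or through an explicit alignment-derived map for
#' non-identical proteins (`refPos`/`queryPos` columns, e.g. from
#' [mapPositions()]).  Exclusion ranges (e.g. a flexible lid loop) are
#' removed before superposition; `exclude` uses the numbering of `a` and,
#' through the pairing, removes the partner residues too.
#'
#' @param a,b [ProteinStructure-class] objects.
#' @param selA,selB selection strings (see [parseSelection()]).
#' @param map optional pairing data.frame for alignment-mediated pairing.
#' @param exclude optional integer ranges to drop, as a list of length-2
#'   vectors or a `from`/`to` data.frame, in `a`'s numbering.
#' @param refine outlier-rejecting refinement (see [kabschSuperpose()]).
#' @return a [SuperpositionResult-class].
#' @export
rmsdCA <- function(a, b, selA = NULL, selB = NULL, map = NULL,
                   exclude = NULL, refine = FALSE) {
  if (!is.null(exclude) && !is.data.frame(exclude))
    exclude <- do.call(rbind, lapply(exclude, function(r)
      data.frame(from = r[1], to = r[2])))
  pr <- pairCA(a, b, selA, selB, map, exclude)
  if (nrow(pr$A) < 3L) stop("pairing yields fewer than 3 C-alpha pairs")
  kabschSuperpose(pr$A, pr$B, refine = refine)
}
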