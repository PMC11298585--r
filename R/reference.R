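## Synthetic reference proteins and the anchor frame.
##
## The real sulfazecin synthetase SulM (accession AOZ21320.1) is a 2984-residue
## NRPS whose terminal thioesterase domain (residues 2723-2984) carries the
## features this package screens for.  The packaged reference is a SYNTHETIC
## stand-in: a deterministic pseudo-random protein of the same length carrying
## the documented residues at the documented author positions (Gln2817-
## Cys2818-Asn2819 around the catalytic cysteine; triad acid Asp2926 on the
## post-beta-7 loop, His2956; cationic active-site residues Arg2849, Lys2854,
## Arg2858; lid loop 2844-2918; post-beta-7 loop 2923-2946; carrier-protein
## serine Ser2688), a module-3 adenylation domain with a planted specificity
## code, and a downstream numbering frame identical to the real protein.  It
## supports every positional computation in the package but is NOT the natural
## sequence.

AA_FREQS <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
              Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
              L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
              S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' generator calls never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

randomResidues <- function(n) {
  sample(names(AA_FREQS), n, replace = TRUE, prob = AA_FREQS)
}

## Author-position layout of the synthetic reference (full-protein frame).
REF_LAYOUT <- list(
  length = 2984L,
  aStart = 2060L, aEnd = 2619L,
  ## specificity-code offsets follow the classic GrsA-frame convention
  codeOffsets = c(235L, 236L, 239L, 278L, 299L, 301L, 322L, 330L, 331L, 517L),
  dapCode = "DVWHFSLVDK",
  pcpPos = 2685L, pcpSeq = "GGDSL",   # Ser2688 = attachment site
  teStart = 2723L, teEnd = 2984L,
  triad = c(nuc = 2818L, asp = 2926L, his = 2956L),
  motif = c(2817L, 2818L, 2819L),
  motifSeq = "QCN",
  cationic = c(2849L, 2854L, 2858L),
  lidSpan = c(2844L, 2918L),
  postBeta7Span = c(2923L, 2946L),
  positionIWindow = c(2838L, 2852L))

referenceCache <- new.env(parent = emptyenv())

#' Synthetic SulM-like reference protein
#'
#' Deterministic 2984-residue synthetic stand-in for the sulfazecin NRPS
#' SulM, carrying the documented anchor residues at the documented author
#' numbering (see [sulmAnchors()]).  Identical on every call.
#'
#' @return single protein sequence string.
#' @export
referenceSulM <- function() {
  if (!is.null(referenceCache$sulm)) return(referenceCache$sulm)
  lay <- REF_LAYOUT
  chars <- withSeed(190301L, randomResidues(lay$length))
  put <- function(pos, what) {
    s <- strsplit(what, "")[[1]]
    chars[pos + seq_along(s) - 1L] <<- s
  }
  ## adenylation-domain specificity code (module 3)
  codePos <- lay$aStart - 1L + lay$codeOffsets
  chars[codePos] <- strsplit(lay$dapCode, "")[[1]]
  ## carrier-protein serine motif
  put(lay$pcpPos, lay$pcpSeq)
  ## TE-domain anchors
  put(lay$motif[1], lay$motifSeq)
  chars[lay$cationic] <- c("R", "K", "R")
  chars[lay$triad[["asp"]]] <- "D"
  chars[lay$triad[["his"]]] <- "H"
  ## keep the position-I window free of acids so the reference frame is an
  ## unambiguous position-II arrangement
  win <- lay$positionIWindow[1]:lay$positionIWindow[2]
  acid <- chars[win] %in% c("D", "E")
  chars[win[acid]] <- "N"
  referenceCache$sulm <- paste(chars, collapse = "")
  referenceCache$sulm
}

#' Synthetic sulfotransferase reference
#'
#' Deterministic 300-residue synthetic stand-in for the cluster
#' sulfotransferase (SulN-like); used by the alignment path of
#' [findSulfotransferase()].
#'
#' @return single protein sequence string.
#' @export
referenceSulfotransferase <- function() {
  if (is.null(referenceCache$sulfo))
    referenceCache$sulfo <-
      paste(withSeed(190302L, randomResidues(300L)), collapse = "")
  referenceCache$sulfo
}

#' Reference anchors for the four-criteria screen
#'
#' Builds the [ReferenceAnchors-class] frame used by the classifier: the
#' synthetic SulM-like reference TE domain (author residues 2723-2984) with
#' its catalytic triad (Cys2818, Asp2926, His2956), Gln-Cys-Asn motif window
#' (2817-2819), cationic active-site positions (2849, 2854, 2858), lid span
#' (2844-2918), post-beta-7 loop (2923-2946, the "position II" frame), a
#' position-I window after strand beta-6 (2838-2852), the module-3
#' adenylation domain with its ten specificity-code positions, and the
#' sulfotransferase reference.
#'
#' @return a [ReferenceAnchors-class].
#' @examples
#' anc <- sulmAnchors()
#' anc@triad
#' @export
sulmAnchors <- function() {
  if (!is.null(referenceCache$anchors)) return(referenceCache$anchors)
  lay <- REF_LAYOUT
  full <- referenceSulM()
  anc <- new("ReferenceAnchors",
    refId = "SulM_synthetic",
    teSeq = substr(full, lay$teStart, lay$teEnd),
    teStart = lay$teStart,
    triad = lay$triad,
    motifWindow = lay$motif,
    cationicPos = lay$cationic,
    lidSpan = lay$lidSpan,
    postBeta7Span = lay$postBeta7Span,
    positionIWindow = lay$positionIWindow,
    aSeq = substr(full, lay$aStart, lay$aEnd),
    aStart = lay$aStart,
    codePositions = lay$aStart - 1L + lay$codeOffsets,
    sulfoSeq = referenceSulfotransferase())
  referenceCache$anchors <- anc
  anc
}

#' Specificity-code table
#'
#' Substrate -> 10-residue specificity-code strings used by
#' [matchDAPCode()].  The 2,3-diaminopropionate (DAP) entry is
#' self-extracted from the packaged reference adenylation domain; the decoy
#' entries are synthetic codes for common NRPS substrates, each differing
#' from the DAP code at >= 5 positions.
#'
#' @return named character vector of code strings.
#' @export
dapCodeTable <- function() {
  c(DAP = REF_LAYOUT$dapCode,
    Ala = "DLFNNALTYK",
    Gly = "DILQLGLIWK",
    Orn = "DMENLGLINK",
    Thr = "DFWNIGMVHK",
    Glu = "DAWQYGGITK")
}
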