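## End-to-end wrappers: mining reports, tree building, and the
## deposited-structure metric set.  These are the functions the
## command-line script (inst/scripts/lactamscan) dispatches to.

#' Screen cluster files and write a report
#'
#' Reads each cluster descriptor (JSON/TSV, see [readCluster()]), runs
#' [screenCluster()], and writes the TSV/JSON report.  Output is
#' deterministic given inputs and configuration.
#'
#' @param paths character vector of cluster descriptor files.
#' @param tsv,json report output paths (`NULL` = skip).
#' @param anchors,config,codeTable screening context.
#' @return list of [ClusterVerdict-class], invisibly.
#' @export
runMine <- function(paths, tsv = NULL, json = NULL,
                    anchors = sulmAnchors(), config = scanConfig(),
                    codeTable = dapCodeTable()) {
  if (!length(paths)) {
    warning("no cluster files given; writing header-only report")
    verdicts <- list()
  } else {
    verdicts <- lapply(paths, function(p)
      screenCluster(readCluster(p), anchors, config, codeTable))
  }
  writeReport(verdicts, tsv = tsv, json = json)
  invisible(verdicts)
}

#' Build a neighbor-joining tree from a FASTA file
#'
#' @param fasta protein FASTA with >= 3 sequences.
#' @param out optional Newick output path.
#' @param params alignment parameters for the distance matrix.
#' @param correction distance correction (see [distanceMatrix()]).
#' @return the [ape::phylo] tree, invisibly; the Newick string is printed
#'   when no output path is given.
#' @export
runTree <- function(fasta, out = NULL, params = alignParams(),
                    correction = "none") {
  prot <- readProteins(fasta)
  if (length(prot) < 3L) stop("tree building needs at least 3 sequences")
  seqs <- stats::setNames(as.character(prot), names(prot))
  tree <- njTree(distanceMatrix(seqs, params, correction))
  nwk <- writeNewick(tree, path = out)
  if (is.null(out)) cat(nwk, "\n")
  invisible(tree)
}

## 3-letter -> 1-letter residue codes (X for anything else)
AA_THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                     GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                     LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                     SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
                     MSE = "M")

#' Protein sequence of a structure chain
#'
#' One-letter sequence read off the C-alpha trace of a chain, with the
#' author residue numbers alongside (non-standard residues become X).
#'
#' @param s a [ProteinStructure-class].
#' @param chain chain id.
#' @return list with `seq` (string) and `resno` (integer vector).
#' @export
structureSequence <- function(s, chain) {
  a <- s@atoms[s@atoms$type == "ATOM" & s@atoms$chain == chain &
                 s@atoms$elety == "CA", ]
  a <- a[!duplicated(paste(a$resno, a$insert)), ]
  a <- a[order(a$resno), ]
  one <- AA_THREE_TO_ONE[a$resid]
  one[is.na(one)] <- "X"
  list(seq = paste(one, collapse = ""), resno = a$resno)
}

#' Locate the carrier-protein attachment serine on a structure chain
#'
#' Finds the conserved pantetheinylation serine by searching the chain
#' sequence for the carrier-domain `G-x-D-S-[LIV]` core motif and
#' returning the author number of its serine.
#'
#' @param s a [ProteinStructure-class].
#' @param chain chain id.
#' @return author residue number of the serine, or `NA` when the motif is
#'   absent.
#' @export
detectPCPSerine <- function(s, chain) {
  sq <- structureSequence(s, chain)
  m <- regexpr("G.DS[LIVM]", sq$seq)
  if (m < 0) m <- regexpr("DS[LIVM]", sq$seq)
  if (m < 0) return(NA_integer_)
  off <- if (attr(m, "match.length") == 5L) 3L else 1L
  sq$resno[m + off]
}

#' Recompute the deposited-structure metric set
#'
#' Given a directory containing locally downloaded copies of the deposited
#' coordinate files for the SulM TE domain (PDB 8W2C), the SulM PCP-TE
#' didomain (8W2D) and the EntF PCP-TE didomain (3TEJ), recomputes the
#' structural quantities the screen is anchored to: catalytic-triad
#' distances, chain A/B and TE-TE superposition RMSDs, the lid-excluded
#' cross-protein TE RMSD, the PCP alpha-2 inter-helix angle after TE-core
#' superposition, the two buried PCP-TE interface areas, and the carrier
#' serine C-alpha separation.  Files must be named `8W2C.pdb`, `8W2D.pdb`,
#' `3TEJ.pdb` (or `.cif`).  This requires the coordinate files to have
#' been fetched beforehand; no download is attempted.
#'
#' @param dir directory holding the coordinate files.
#' @param anchors a [ReferenceAnchors-class] (for the lid span and triad
#'   numbers).
#' @param nPoints SASA point count.
#' @return named list of metrics.
#' @export
reproduceDepositedMetrics <- function(dir, anchors = sulmAnchors(),
                                      nPoints = 960L) {
  findFile <- function(code) {
    for (ext in c(".pdb", ".cif", ".ent", ".mmcif")) {
      p <- file.path(dir, paste0(code, ext))
      if (file.exists(p)) return(p)
    }
    stop("deposited coordinate file for ", code, " not found under ", dir,
         " (download it first; no network access is assumed)")
  }
  te <- readStructure(findFile("8W2C"))      # SulM TE domain
  di <- readStructure(findFile("8W2D"))      # SulM PCP-TE, 2 chains
  entf <- readStructure(findFile("3TEJ"))    # EntF PCP-TE

  out <- list()
  out$triad_his_cys <- unname(triadGeometry(te, c(nuc = 2818, asp = 2926,
                                                  his = 2956))[["his_nuc"]])
  out$triad_his_asp <- unname(triadGeometry(te, c(nuc = 2818, asp = 2926,
                                                  his = 2956))[["his_asp"]])

  chains <- unique(atoms(di)$chain[atoms(di)$type == "ATOM"])
  spAB <- rmsdCA(di, di, selA = paste0(chains[1], ":2660-2979"),
                 selB = paste0(chains[2], ":2660-2979"), refine = TRUE)
  out$rmsd_8w2d_chainA_chainB <- spAB@rmsd

  teChain <- unique(atoms(te)$chain[atoms(te)$type == "ATOM"])[1]
  spTE <- rmsdCA(te, di, selA = paste0(teChain, ":2723-2979"),
                 selB = paste0(chains[1], ":2723-2979"), refine = TRUE)
  out$rmsd_te_free_vs_didomain <- spTE@rmsd
  out$n_ca_te_pairs <- spTE@nPairs

  ## cross-protein TE comparison (alignment-mediated), lid excluded
  entfChain <- unique(atoms(entf)$chain[atoms(entf)$type == "ATOM"])[1]
  sulSeq <- structureSequence(di, chains[1])
  entfSeq <- structureSequence(entf, entfChain)
  entfSer <- detectPCPSerine(entf, entfChain)
  sulSer <- detectPCPSerine(di, chains[1])
  if (is.na(entfSer) || is.na(sulSer))
    stop("could not locate the carrier serine on one of the structures")
  ## TE portion of each chain: everything downstream of the carrier domain
  sulTEsel <- paste0(chains[1], ":2723-2979")
  entfTEFrom <- entfSer + 35L
  entfTEsel <- paste0(entfChain, ":", entfTEFrom, "-",
                      max(entfSeq$resno))
  sulResno <- sulSeq$resno[sulSeq$resno >= 2723 & sulSeq$resno <= 2979]
  entfResno <- entfSeq$resno[entfSeq$resno >= entfTEFrom]
  aln <- alignPair(substrSeq(sulSeq, 2723, 2979),
                   substrSeq(entfSeq, entfTEFrom, max(entfSeq$resno)))
  map <- alignmentPositionTable(aln)
  map$refPos <- remapToResno(map$refPos, sulResno)
  map$queryPos <- remapToResno(map$queryPos, entfResno)
  lid <- list(anchors@lidSpan)
  spX <- rmsdCA(di, entf, selA = sulTEsel, selB = entfTEsel, map = map,
                exclude = lid, refine = TRUE)
  out$rmsd_sulte_vs_entf_te <- spX@rmsd

  ## PCP alpha-2 helix angle after TE-core superposition
  prX <- pairCA(di, entf, sulTEsel, entfTEsel, map = map,
                exclude = do.call(rbind, lapply(lid, function(r)
                  data.frame(from = r[1], to = r[2]))))
  spCore <- kabschSuperpose(prX$B, prX$A, refine = TRUE)
  entfT <- transformStructure(entf, spCore)
  a2Sul <- helixAxisFor(di, paste0(chains[1], ":", sulSer, "-",
                                   sulSer + 14L))
  a2Entf <- helixAxisFor(entfT, paste0(entfChain, ":", entfSer, "-",
                                       entfSer + 14L))
  out$pcp_a2_angle <- interhelixAngle(a2Sul, a2Entf)

  ## carrier serine CA separation after the same superposition
  caS <- atomCoords(di, paste0(chains[1], ":", sulSer, "-", sulSer), "CA")
  caE <- atomCoords(entfT, paste0(entfChain, ":", entfSer, "-", entfSer),
                    "CA")
  out$pcp_ser_ca_separation <- sqrt(sum((caS[1, ] - caE[1, ])^2))

  ## buried interface areas (protein atoms only)
  out$interface_sulm <- interfaceArea(
    di, paste0(chains[1], ":2660-2722"), paste0(chains[1], ":2723-2979"),
    nPoints = nPoints)@area
  entfPCPsel <- paste0(entfChain, ":", min(entfSeq$resno), "-",
                       entfTEFrom - 1L)
  out$interface_entf <- interfaceArea(entf, entfPCPsel, entfTEsel,
                                      nPoints = nPoints)@area
  out
}

substrSeq <- function(sq, from, to) {
  keep <- sq$resno >= from & sq$resno <= to
  paste(strsplit(sq$seq, "")[[1]][keep], collapse = "")
}

remapToResno <- function(idx, resno) {
  out <- rep(NA_integer_, length(idx))
  ok <- !is.na(idx) & idx >= 1 & idx <= length(resno)
  out[ok] <- resno[idx[ok]]
  out
}

#' Apply a superposition to a whole structure
#'
#' @param s a [ProteinStructure-class].
#' @param sp a [SuperpositionResult-class].
#' @return the transformed structure.
#' @export
transformStructure <- function(s, sp) {
  xyz <- applyRigid(as.matrix(s@atoms[, c("x", "y", "z")]),
                    sp@rotation, sp@translation)
  s@atoms$x <- xyz[, 1]; s@atoms$y <- xyz[, 2]; s@atoms$z <- xyz[, 3]
  s
}
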