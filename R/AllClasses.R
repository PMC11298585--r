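## Central S4 classes.  Sequence sets are held as Biostrings::AAStringSet;
## the classes below carry the pipeline's own evidence objects.

AA_ALPHABET_STRICT <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' GeneCluster: a biosynthetic gene cluster as mining input
#'
#' Ordered set of protein-coding genes from one candidate biosynthetic gene
#' cluster (BGC), each with a free-text annotation and a role tag.  Role tags
#' are pre-filled from annotation keywords on import (see [readCluster()]) and
#' default to `"unknown"`.
#'
#' @slot clusterId single cluster identifier.
#' @slot genes [Biostrings::AAStringSet] of protein sequences, named by
#'   gene id (unique).
#' @slot annotation character vector of free-text annotations, one per gene.
#' @slot role character vector, one per gene, each in
#'   `c("nrps", "sulfotransferase", "other", "unknown")`.
#' @export
setClass("GeneCluster",
  representation(clusterId = "character",
                 genes = "AAStringSet",
                 annotation = "character",
                 role = "character"))

CLUSTER_ROLES <- c("nrps", "sulfotransferase", "other", "unknown")

setValidity("GeneCluster", function(object) {
  n <- length(object@genes)
  msg <- character()
  if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
    msg <- c(msg, "clusterId must be a single non-empty string")
  if (n < 1L) msg <- c(msg, "cluster must contain at least one gene")
  ids <- names(object@genes)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "gene ids must be unique and non-empty")
  if (length(object@annotation) != n)
    msg <- c(msg, "one annotation per gene required")
  if (length(object@role) != n || !all(object@role %in% CLUSTER_ROLES))
    msg <- c(msg, sprintf("roles must be one of %s",
                          paste(CLUSTER_ROLES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PairAlignment: pairwise alignment of a reference against a query
#'
#' Result of [alignPair()]: the gapped alignment strings, the spans of the
#' two input sequences covered by the alignment (1-based, inclusive), the
#' raw score in substitution-matrix units, and fractional identity and
#' similarity computed over alignment columns.
#'
#' Identity is the fraction of columns whose two residues are identical;
#' similarity is the fraction whose residues are identical or score
#' positively under the substitution matrix, so identity <= similarity.
#' Both use the full alignment length (gap columns included) as denominator.
#'
#' @slot score alignment score (substitution-matrix units).
#' @slot alignedRef,alignedQuery gapped strings of equal length.
#' @slot refSpan,querySpan integer length-2 vectors, 1-based inclusive
#'   positions of the aligned region in the ungapped inputs.
#' @slot identity,similarity fractions in \[0, 1\].
#' @slot mode `"global"` or `"local"`.
#' @export
setClass("PairAlignment",
  representation(score = "numeric",
                 alignedRef = "character",
                 alignedQuery = "character",
                 refSpan = "integer",
                 querySpan = "integer",
                 identity = "numeric",
                 similarity = "numeric",
                 mode = "character"))

setValidity("PairAlignment", function(object) {
  msg <- character()
  if (nchar(object@alignedRef) != nchar(object@alignedQuery))
    msg <- c(msg, "gapped strings must have equal length")
  if (!(object@mode %in% c("global", "local")))
    msg <- c(msg, "mode must be 'global' or 'local'")
  if (object@identity < 0 || object@identity > 1 ||
      object@similarity < 0 || object@similarity > 1 ||
      object@identity > object@similarity + 1e-12)
    msg <- c(msg, "need 0 <= identity <= similarity <= 1")
  if (length(msg)) msg else TRUE
})

#' DomainHit: a located domain on a query protein
#'
#' A local-alignment hit of a reference domain (TE or adenylation) on a query
#' protein, together with the reference-number -> query-position map used by
#' all downstream criteria.
#'
#' @slot geneId query protein id.
#' @slot kind `"TE"` or `"A"`.
#' @slot querySpan integer length-2, hit span on the query (1-based).
#' @slot alignment the underlying [PairAlignment-class].
#' @slot positions data.frame with columns `refPos` (reference author
#'   numbering), `queryPos` (1-based query position or `NA` when the column
#'   has a query gap) and `queryResidue` (`NA` when unaligned), covering the
#'   aligned reference span.
#' @export
setClass("DomainHit",
  representation(geneId = "character",
                 kind = "character",
                 querySpan = "integer",
                 alignment = "PairAlignment",
                 positions = "data.frame"))

setValidity("DomainHit", function(object) {
  msg <- character()
  if (!(object@kind %in% c("TE", "A")))
    msg <- c(msg, "kind must be 'TE' or 'A'")
  if (length(object@querySpan) != 2L || object@querySpan[1] > object@querySpan[2])
    msg <- c(msg, "querySpan must be an ordered length-2 integer vector")
  need <- c("refPos", "queryPos", "queryResidue")
  if (!all(need %in% names(object@positions)))
    msg <- c(msg, "positions must have refPos, queryPos, queryResidue")
  qp <- object@positions$queryPos
  if (any(diff(qp[!is.na(qp)]) <= 0))
    msg <- c(msg, "mapped query positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' TriadAssignment: catalytic triad read off a TE-domain hit
#'
#' The nucleophile (Cys/Ser), aspartate and histidine of the Ser/Cys-His-Asp
#' catalytic triad as mapped onto a query TE domain, plus the position-I /
#' position-II classification of the acid.  "Position II" means the
#' aspartate sits on the loop following strand beta-7 (as in the reference);
#' "position I" means a loop-after-beta-6 acid, the arrangement seen in most
#' NRPS TE domains.
#'
#' @slot nucPos,aspPos,hisPos query residue numbers (`NA` if unaligned).
#' @slot nucResidue,aspResidue,hisResidue one-letter residues (`NA` if
#'   unaligned).
#' @slot aspPosition `"I"`, `"II"` or `"undetermined"`.
#' @slot note free-text evidence.
#' @export
setClass("TriadAssignment",
  representation(nucPos = "integer", nucResidue = "character",
                 aspPos = "integer", aspResidue = "character",
                 hisPos = "integer", hisResidue = "character",
                 aspPosition = "character", note = "character"))

setValidity("TriadAssignment", function(object) {
  if (!(object@aspPosition %in% c("I", "II", "undetermined")))
    return("aspPosition must be 'I', 'II' or 'undetermined'")
  TRUE
})

#' CriterionResult: outcome of one screening criterion
#'
#' @slot id one of `"triad_motif"`, `"cationic_site"`, `"dap_code"`,
#'   `"sulfotransferase"`.
#' @slot passed logical.
#' @slot evidence human-readable support (residues / genes); non-empty when
#'   passed.
#' @export
setClass("CriterionResult",
  representation(id = "character", passed = "logical", evidence = "character"))

CRITERION_IDS <- c("triad_motif", "cationic_site", "dap_code", "sulfotransferase")

setValidity("CriterionResult", function(object) {
  msg <- character()
  if (!(object@id %in% CRITERION_IDS))
    msg <- c(msg, sprintf("id must be one of %s",
                          paste(CRITERION_IDS, collapse = ", ")))
  if (isTRUE(object@passed) && !nzchar(object@evidence))
    msg <- c(msg, "evidence must be non-empty when passed")
  if (length(msg)) msg else TRUE
})

#' SpecificityCode: adenylation-domain specificity code residues
#'
#' The ~10 active-site residues of an adenylation (A) domain that predict its
#' amino-acid substrate (the Stachelhaus/Challis code), read off a query A
#' domain through the reference position map.  Unaligned positions render as
#' `"-"`.
#'
#' @slot code single string of length 10.
#' @slot geneId source gene.
#' @slot nMapped number of code positions that mapped (0-10).
#' @slot reliable `FALSE` when fewer than 6 positions mapped.
#' @export
setClass("SpecificityCode",
  representation(code = "character", geneId = "character",
                 nMapped = "integer", reliable = "logical"))

setValidity("SpecificityCode", function(object) {
  if (nchar(object@code) != 10L)
    return("code must be a string of length 10")
  TRUE
})

#' ClusterVerdict: aggregate four-criteria call for one cluster
#'
#' @slot clusterId cluster id.
#' @slot criteria named list of four [CriterionResult-class] objects
#'   (`triad_motif`, `cationic_site`, `dap_code`, `sulfotransferase`).
#' @slot nPassed integer 0-4.
#' @slot call `"candidate"` or `"rejected"`.
#' @slot teGene,aGene gene ids carrying the TE hit and the last-module A
#'   domain (`NA` when absent).
#' @export
setClass("ClusterVerdict",
  representation(clusterId = "character",
                 criteria = "list",
                 nPassed = "integer",
                 call = "character",
                 teGene = "character",
                 aGene = "character"))

setValidity("ClusterVerdict", function(object) {
  msg <- character()
  if (!identical(sort(names(object@criteria)), sort(CRITERION_IDS)))
    msg <- c(msg, "criteria must be a named list over the four criterion ids")
  if (!(object@call %in% c("candidate", "rejected")))
    msg <- c(msg, "call must be 'candidate' or 'rejected'")
  if (object@nPassed < 0L || object@nPassed > 4L)
    msg <- c(msg, "nPassed must be 0..4")
  if (length(msg)) msg else TRUE
})

#' ReferenceAnchors: the reference frame for all sequence criteria
#'
#' Bundles the reference TE-domain sequence and every author-numbered anchor
#' the classifier consults: the catalytic triad, the Gln-Cys-Asn motif
#' window, the cationic active-site positions, the lid-loop span, the
#' post-beta-7 loop span (position-II frame), a window after strand beta-6
#' where position-I acids sit, the reference adenylation domain with its ten
#' specificity-code positions, and a reference sulfotransferase sequence.
#'
#' All numbering is in the reference protein's author coordinates;
#' `teStart`/`aStart` give the author number of residue 1 of the
#' corresponding sub-sequence.  See [sulmAnchors()].
#'
#' @slot refId reference protein id.
#' @slot teSeq reference TE-domain sequence (character).
#' @slot teStart author number of the first TE residue.
#' @slot triad named integer, `c(nuc=, asp=, his=)`.
#' @slot motifWindow integer length-3 (Gln-Cys-Asn window, centred on the
#'   catalytic Cys).
#' @slot cationicPos integer length-3.
#' @slot lidSpan,postBeta7Span,positionIWindow integer length-2 spans.
#' @slot aSeq,aStart reference adenylation-domain sequence and offset.
#' @slot codePositions integer length-10, author numbers of the specificity
#'   code.
#' @slot sulfoSeq reference sulfotransferase sequence.
#' @export
setClass("ReferenceAnchors",
  representation(refId = "character",
                 teSeq = "character", teStart = "integer",
                 triad = "integer", motifWindow = "integer",
                 cationicPos = "integer",
                 lidSpan = "integer", postBeta7Span = "integer",
                 positionIWindow = "integer",
                 aSeq = "character", aStart = "integer",
                 codePositions = "integer",
                 sulfoSeq = "character"))

setValidity("ReferenceAnchors", function(object) {
  msg <- character()
  teEnd <- object@teStart + nchar(object@teSeq) - 1L
  nums <- c(object@triad, object@motifWindow, object@cationicPos,
            object@lidSpan, object@postBeta7Span, object@positionIWindow)
  if (any(nums < object@teStart | nums > teEnd))
    msg <- c(msg, "all TE anchor numbers must fall inside the TE span")
  if (!identical(sort(names(object@triad)), c("asp", "his", "nuc")))
    msg <- c(msg, "triad must be named c(nuc=, asp=, his=)")
  if (length(object@motifWindow) != 3L ||
      object@motifWindow[2] != object@triad[["nuc"]])
    msg <- c(msg, "motifWindow must be length 3 and centred on the nucleophile")
  if (length(object@codePositions) != 10L)
    msg <- c(msg, "codePositions must have length 10")
  aEnd <- object@aStart + nchar(object@aSeq) - 1L
  if (any(object@codePositions < object@aStart | object@codePositions > aEnd))
    msg <- c(msg, "codePositions must fall inside the A-domain span")
  if (length(msg)) msg else TRUE
})

#' ProteinStructure: atomic coordinates
#'
#' Flat atom table parsed from PDB or mmCIF (see [readStructure()]).  Author
#' residue numbering (with insertion codes) is used throughout; one altloc is
#' retained per atom.
#'
#' @slot atoms data.frame with columns `type` (ATOM/HETATM), `chain`,
#'   `resno`, `insert`, `resid`, `elety` (atom name), `elesy` (element),
#'   `x`, `y`, `z` (Angstrom), `o` (occupancy).
#' @slot title free-text provenance.
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", title = "character"))

setValidity("ProteinStructure", function(object) {
  need <- c("type", "chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o")
  msg <- character()
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (nrow(xyz) && !all(is.finite(xyz)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' SuperpositionResult: least-squares rigid superposition
#'
#' Output of [kabschSuperpose()]: the proper rotation and translation that
#' best map the moving set onto the fixed set, the RMSD over the final pair
#' set, and bookkeeping of refinement rejections.  The transform acts on row
#' vectors as `x' = x R^T + t`.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation numeric length-3 (Angstrom).
#' @slot nPairs atom pairs used in the final cycle.
#' @slot rmsd root-mean-square deviation (Angstrom) over the final pairs.
#' @slot nRejected pairs discarded by refinement.
#' @slot kept logical vector over the input pairs.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 nPairs = "integer", rmsd = "numeric",
                 nRejected = "integer", kept = "logical"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L)))
    msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' InterfaceReport: buried surface between two atom groups
#'
#' Buried area is half the solvent-accessible surface area (SASA) lost on
#' complex formation, `(SASA_A + SASA_B - SASA_AB) / 2`.
#'
#' @slot area buried area (Angstrom^2).
#' @slot perResidue data.frame (`chain`, `resno`, `resid`, `group`,
#'   `buried`) of per-residue buried contributions.
#' @slot contacts data.frame of residue pairs within the contact cutoff.
#' @slot probe,nPoints SASA parameters used.
#' @export
setClass("InterfaceReport",
  representation(area = "numeric", perResidue = "data.frame",
                 contacts = "data.frame", probe = "numeric",
                 nPoints = "integer"))

setValidity("InterfaceReport", function(object) {
  if (object@area < -1e-6) return("buried area must be >= 0")
  TRUE
})

#' HelixAxis: fitted axis of an alpha-helix
#'
#' Principal axis of the centred C-alpha covariance, sign-oriented from the
#' N- to the C-terminus of the span used.
#'
#' @slot direction unit vector (length 3).
#' @slot centroid numeric length-3.
#' @slot nRes number of C-alpha atoms used (>= 5).
#' @export
setClass("HelixAxis",
  representation(direction = "numeric", centroid = "numeric", nRes = "integer"))

setValidity("HelixAxis", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    msg <- c(msg, "direction must be a unit vector")
  if (object@nRes < 5L) msg <- c(msg, "at least 5 C-alpha atoms required")
  if (length(msg)) msg else TRUE
})
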