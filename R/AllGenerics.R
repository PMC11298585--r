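## Generics and accessors.  Slots are never reached into from user code;
## these accessors are the supported surface.

#' @rdname GeneCluster-class
#' @param object,x a package object.
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))
#' @rdname GeneCluster-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname GeneCluster-class
#' @export
setGeneric("geneRoles", function(x) standardGeneric("geneRoles"))
#' @rdname GeneCluster-class
#' @export
setGeneric("geneAnnotations", function(x) standardGeneric("geneAnnotations"))

#' @rdname GeneCluster-class
#' @export
setMethod("clusterId", "GeneCluster", function(x) x@clusterId)
#' @rdname GeneCluster-class
#' @export
setMethod("genes", "GeneCluster", function(x) x@genes)
#' @rdname GeneCluster-class
#' @export
setMethod("geneRoles", "GeneCluster",
          function(x) stats::setNames(x@role, names(x@genes)))
#' @rdname GeneCluster-class
#' @export
setMethod("geneAnnotations", "GeneCluster",
          function(x) stats::setNames(x@annotation, names(x@genes)))

setMethod("show", "GeneCluster", function(object) {
  cat(sprintf("GeneCluster '%s' with %d gene(s)\n",
              object@clusterId, length(object@genes)))
  tab <- data.frame(gene = names(object@genes),
                    length = Biostrings::width(object@genes),
                    role = object@role,
                    annotation = substr(object@annotation, 1, 40))
  print(tab, row.names = FALSE)
})

#' @rdname PairAlignment-class
#' @param x a `PairAlignment`.
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname PairAlignment-class
#' @export
setGeneric("pidentity", function(x) standardGeneric("pidentity"))
#' @rdname PairAlignment-class
#' @export
setGeneric("psimilarity", function(x) standardGeneric("psimilarity"))
#' @rdname PairAlignment-class
#' @export
setGeneric("refSpan", function(x) standardGeneric("refSpan"))
#' @rdname PairAlignment-class
#' @export
setGeneric("querySpan", function(x) standardGeneric("querySpan"))

#' @rdname PairAlignment-class
#' @export
setMethod("alignmentScore", "PairAlignment", function(x) x@score)
#' @rdname PairAlignment-class
#' @export
setMethod("pidentity", "PairAlignment", function(x) x@identity)
#' @rdname PairAlignment-class
#' @export
setMethod("psimilarity", "PairAlignment", function(x) x@similarity)
#' @rdname PairAlignment-class
#' @export
setMethod("refSpan", "PairAlignment", function(x) x@refSpan)
#' @rdname PairAlignment-class
#' @export
setMethod("querySpan", "PairAlignment", function(x) x@querySpan)
#' @rdname DomainHit-class
#' @export
setMethod("querySpan", "DomainHit", function(x) x@querySpan)

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment (%s): score %.1f, identity %.3f, similarity %.3f\n",
              object@mode, object@score, object@identity, object@similarity))
  cat(sprintf("  ref   %d-%d  %s\n", object@refSpan[1], object@refSpan[2],
              clipString(object@alignedRef)))
  cat(sprintf("  query %d-%d  %s\n", object@querySpan[1], object@querySpan[2],
              clipString(object@alignedQuery)))
})

clipString <- function(x, n = 60) {
  if (nchar(x) > n) paste0(substr(x, 1, n), "...") else x
}

#' @rdname DomainHit-class
#' @param x a `DomainHit`.
#' @export
setGeneric("hitPositions", function(x) standardGeneric("hitPositions"))
#' @rdname DomainHit-class
#' @export
setMethod("hitPositions", "DomainHit", function(x) x@positions)

setMethod("show", "DomainHit", function(object) {
  cat(sprintf("DomainHit: %s domain on '%s' at %d-%d (score %.1f, id %.2f)\n",
              object@kind, object@geneId, object@querySpan[1],
              object@querySpan[2], object@alignment@score,
              object@alignment@identity))
})

setMethod("show", "TriadAssignment", function(object) {
  fmt <- function(res, pos) {
    if (is.na(pos)) "unaligned" else paste0(res, pos)
  }
  cat(sprintf("TriadAssignment: nucleophile %s, Asp %s, His %s; acid position %s\n",
              fmt(object@nucResidue, object@nucPos),
              fmt(object@aspResidue, object@aspPos),
              fmt(object@hisResidue, object@hisPos),
              object@aspPosition))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @rdname TriadAssignment-class
#' @param x a `TriadAssignment`.
#' @export
setGeneric("aspPosition", function(x) standardGeneric("aspPosition"))
#' @rdname TriadAssignment-class
#' @export
setMethod("aspPosition", "TriadAssignment", function(x) x@aspPosition)

#' @rdname CriterionResult-class
#' @param x a `CriterionResult` or `ClusterVerdict`.
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))
#' @rdname CriterionResult-class
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))
#' @rdname CriterionResult-class
#' @export
setMethod("passed", "CriterionResult", function(x) x@passed)
#' @rdname CriterionResult-class
#' @export
setMethod("evidence", "CriterionResult", function(x) x@evidence)

setMethod("show", "CriterionResult", function(object) {
  cat(sprintf("[%s] %s: %s\n", ifelse(object@passed, "PASS", "fail"),
              object@id, object@evidence))
})

#' @rdname ClusterVerdict-class
#' @param x a `ClusterVerdict`.
#' @export
setGeneric("nPassed", function(x) standardGeneric("nPassed"))
#' @rdname ClusterVerdict-class
#' @export
setGeneric("verdictCall", function(x) standardGeneric("verdictCall"))
#' @rdname ClusterVerdict-class
#' @export
setGeneric("criteria", function(x) standardGeneric("criteria"))
#' @rdname ClusterVerdict-class
#' @export
setMethod("nPassed", "ClusterVerdict", function(x) x@nPassed)
#' @rdname ClusterVerdict-class
#' @export
setMethod("verdictCall", "ClusterVerdict", function(x) x@call)
#' @rdname ClusterVerdict-class
#' @export
setMethod("criteria", "ClusterVerdict", function(x) x@criteria)
#' @rdname ClusterVerdict-class
#' @export
setMethod("clusterId", "ClusterVerdict", function(x) x@clusterId)

setMethod("show", "ClusterVerdict", function(object) {
  cat(sprintf("ClusterVerdict '%s': %s (%d/4 criteria)\n",
              object@clusterId, object@call, object@nPassed))
  for (cr in object@criteria) show(cr)
})

#' @rdname SpecificityCode-class
#' @param x a `SpecificityCode`.
#' @export
setGeneric("codeString", function(x) standardGeneric("codeString"))
#' @rdname SpecificityCode-class
#' @export
setMethod("codeString", "SpecificityCode", function(x) x@code)

setMethod("show", "SpecificityCode", function(object) {
  cat(sprintf("SpecificityCode %s from '%s' (%d/10 mapped%s)\n",
              object@code, object@geneId, object@nMapped,
              if (object@reliable) "" else ", unreliable"))
})

#' @rdname ProteinStructure-class
#' @param x a `ProteinStructure`.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname ProteinStructure-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname ProteinStructure-class
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
#' @rdname ProteinStructure-class
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

setMethod("show", "ProteinStructure", function(object) {
  ch <- unique(object@atoms$chain)
  cat(sprintf("ProteinStructure: %d atoms, %d chain(s) [%s]%s\n",
              nrow(object@atoms), length(ch), paste(ch, collapse = ","),
              if (nzchar(object@title)) paste0(" - ", object@title) else ""))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.3f A over %d pairs (%d rejected)\n",
              object@rmsd, object@nPairs, object@nRejected))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport: buried area %.1f A^2 (probe %.2f, %d points); %d contact residue pairs\n",
              object@area, object@probe, object@nPoints, nrow(object@contacts)))
})

setMethod("show", "HelixAxis", function(object) {
  cat(sprintf("HelixAxis: direction (%.3f, %.3f, %.3f) over %d residues\n",
              object@direction[1], object@direction[2], object@direction[3],
              object@nRes))
})
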