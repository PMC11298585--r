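## Pairwise alignment and reference-number mapping.  The dynamic programming
## itself is Biostrings::pairwiseAlignment (Gotoh affine gaps); this module
## fixes the scoring conventions and derives the quantities the classifier
## needs: identity, similarity, spans, and the reference -> query position
## map that anchors every sequence criterion.

#' Alignment parameters
#'
#' Affine-gap scoring parameters.  A gap of length L costs
#' `gapOpen + L * gapExtend` (BLAST convention; the default 11/1 is the
#' standard BLOSUM62 pairing).  `gapOpen >= gapExtend > 0` is enforced.
#'
#' @param matrix substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or an actual
#'   numeric matrix.
#' @param gapOpen,gapExtend positive gap penalties (score units).
#' @param mode `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).
#' @return a list of class `"alignParams"`.
#' @export
alignParams <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                        mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!(gapOpen >= gapExtend && gapExtend > 0))
    stop("need gapOpen >= gapExtend > 0")
  structure(list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
                 mode = mode),
            class = "alignParams")
}

matrixCache <- new.env(parent = emptyenv())

#' Fetch a substitution matrix
#'
#' @param m a matrix name known to Biostrings or a numeric matrix, which is
#'   returned unchanged.
#' @return numeric substitution matrix.
#' @export
substitutionMatrix <- function(m) {
  if (is.matrix(m)) return(m)
  if (!is.null(matrixCache[[m]])) return(matrixCache[[m]])
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = m, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(m, envir = e))
    stop("unknown substitution matrix: ", m)
  matrixCache[[m]] <- get(m, envir = e)
  matrixCache[[m]]
}

#' Alignment score only
#'
#' Computes just the optimal alignment score (no traceback); used for fast
#' pre-screening before a full [alignPair()].
#'
#' @inheritParams alignPair
#' @return numeric score.
#' @export
alignScore <- function(ref, query, params = alignParams()) {
  ref <- checkResidues(as.character(ref), "ref")
  query <- checkResidues(as.character(query), "query")
  Biostrings::pairwiseAlignment(
    ref, query, type = params$mode,
    substitutionMatrix = substitutionMatrix(params$matrix),
    gapOpening = params$gapOpen, gapExtension = params$gapExtend,
    scoreOnly = TRUE)
}

checkResidues <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET_STRICT, collapse = "")),
                 seq)
  if (bad > 0)
    stop(sprintf("illegal residue '%s' at position %d of %s",
                 substr(seq, bad, bad), bad, what))
  invisible(seq)
}

#' Pairwise protein alignment
#'
#' Optimal global or local alignment of two protein sequences under affine
#' gap penalties (Gotoh dynamic programming via
#' [Biostrings::pairwiseAlignment()]).  Identity and similarity are
#' fractions over alignment columns (gap columns included in the
#' denominator); a column counts toward similarity when its residues are
#' identical or score positively under the substitution matrix, so
#' `identity <= similarity` always holds.
#'
#' @param ref,query protein sequences (single strings or `AAString`-like).
#' @param params an [alignParams()] list.
#' @return a [PairAlignment-class].
#' @examples
#' alignPair("MKV", "MKV")
#' alignPair("AAAWKLMKVLLA", "KVLL", alignParams(mode = "local"))
#' @export
alignPair <- function(ref, query, params = alignParams()) {
  ref <- checkResidues(as.character(ref), "ref")
  query <- checkResidues(as.character(query), "query")
  mat <- substitutionMatrix(params$matrix)
  aln <- Biostrings::pairwiseAlignment(
    ref, query, type = params$mode, substitutionMatrix = mat,
    gapOpening = params$gapOpen, gapExtension = params$gapExtend)
  gr <- as.character(Biostrings::pattern(aln))
  gq <- as.character(Biostrings::subject(aln))
  cr <- strsplit(gr, "")[[1]]
  cq <- strsplit(gq, "")[[1]]
  ncol <- length(cr)
  both <- cr != "-" & cq != "-"
  idn <- cr == cq & both
  pos <- idn
  if (any(both & !idn)) {
    ij <- cbind(cr[both & !idn], cq[both & !idn])
    pos[both & !idn] <- mat[ij] > 0
  }
  new("PairAlignment",
      score = Biostrings::score(aln),
      alignedRef = gr, alignedQuery = gq,
      refSpan = as.integer(c(start(Biostrings::pattern(aln)),
                             end(Biostrings::pattern(aln)))),
      querySpan = as.integer(c(start(Biostrings::subject(aln)),
                               end(Biostrings::subject(aln)))),
      identity = if (ncol) sum(idn) / ncol else 0,
      similarity = if (ncol) sum(pos) / ncol else 0,
      mode = params$mode)
}

## Column-walk of a PairAlignment: for every reference position in refSpan,
## the corresponding query position (NA on a query gap) and query residue.
## refStart offsets sequence position 1 of the reference input to author
## numbering.
alignmentPositionTable <- function(aln, refStart = 1L) {
  cr <- strsplit(aln@alignedRef, "")[[1]]
  cq <- strsplit(aln@alignedQuery, "")[[1]]
  refp <- cumsum(cr != "-") + aln@refSpan[1] - 1L
  qryp <- cumsum(cq != "-") + aln@querySpan[1] - 1L
  keep <- cr != "-"
  data.frame(refPos = refp[keep] + refStart - 1L,
             queryPos = ifelse(cq[keep] == "-", NA_integer_, qryp[keep]),
             queryResidue = ifelse(cq[keep] == "-", NA_character_, cq[keep]),
             stringsAsFactors = FALSE)
}

#' Map reference residue numbers onto a query
#'
#' Alignment-mediated transfer of reference residue numbers (e.g. the SulM
#' author numbering of the catalytic triad) onto a query sequence.  A
#' reference number maps to the query residue sharing its alignment column,
#' is `"unaligned"` when that column holds a query gap, and `"outside"` when
#' it falls outside the aligned reference span.
#'
#' @param aln a [PairAlignment-class] (reference = first sequence).
#' @param refNumbers integer vector of reference residue numbers (author
#'   numbering).
#' @param refStart author number of residue 1 of the reference input
#'   sequence (default 1).
#' @return data.frame with columns `refPos`, `queryPos` (`NA` when not
#'   mapped), `queryResidue`, `status` (`mapped` / `unaligned` / `outside`).
#' @examples
#' aln <- alignPair("MKVLL", "MKVLL")
#' mapPositions(aln, c(2, 5))
#' @export
mapPositions <- function(aln, refNumbers, refStart = 1L) {
  stopifnot(is(aln, "PairAlignment"))
  tab <- alignmentPositionTable(aln, refStart)
  i <- match(refNumbers, tab$refPos)
  out <- data.frame(refPos = as.integer(refNumbers),
                    queryPos = tab$queryPos[i],
                    queryResidue = tab$queryResidue[i],
                    stringsAsFactors = FALSE)
  out$status <- ifelse(is.na(i), "outside",
                       ifelse(is.na(out$queryPos), "unaligned", "mapped"))
  out
}
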