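## The four-criteria screen for beta-lactam-forming TE domains.
##
## Criterion 1: catalytic triad with the acid at position II (loop after
##   strand beta-7) AND the Gln-Cys-Asn motif housing a cysteine nucleophile.
## Criterion 2: positively charged residues at >= 2 of the 3 active-site
##   positions homologous to Arg2849/Lys2854/Arg2858.
## Criterion 3: adenylation-domain specificity code of the last module best
##   matching 2,3-diaminopropionate (DAP).
## Criterion 4: a sulfotransferase gene in the cluster.
##
## All residue-level decisions are made in the reference coordinate frame:
## reference author numbers are transferred onto the query through a local
## alignment (DomainHit position map), never by secondary-structure
## prediction on the query.

#' Screening configuration
#'
#' Thresholds and options for the four-criteria screen; defaults reproduce
#' the documented walkthrough.
#'
#' @param teScoreMin minimum local-alignment score (BLOSUM62 units, gap
#'   11/1) for a TE-domain hit.
#' @param aScoreMin minimum score for an adenylation-domain hit.
#' @param sulfoScoreMin minimum score for the sulfotransferase alignment
#'   path.
#' @param similarityMin similarity percentage used by
#'   [partitionBySimilarity()] to separate close homologs of the reference
#'   from divergent candidates (default 70).
#' @param codeMatchMin minimum matching specificity-code positions (of 10)
#'   for the DAP call.
#' @param cationicMin minimum cationic positions (of 3).
#' @param criteriaMin criteria needed for a `candidate` call (default 4).
#' @param strictCys require a cysteine nucleophile (`FALSE` also accepts
#'   serine).
#' @param maxHits cap on non-overlapping domain hits per protein.
#' @param align an [alignParams()] list used for domain screening (mode is
#'   forced to local).
#' @return a list of class `"scanConfig"`.
#' @export
scanConfig <- function(teScoreMin = 200, aScoreMin = 200,
                       sulfoScoreMin = 200, similarityMin = 70,
                       codeMatchMin = 8L, cationicMin = 2L,
                       criteriaMin = 4L, strictCys = TRUE,
                       maxHits = 3L, align = alignParams(mode = "local")) {
  align$mode <- "local"
  stopifnot(codeMatchMin >= 1L, codeMatchMin <= 10L,
            cationicMin >= 1L, cationicMin <= 3L,
            criteriaMin >= 1L, criteriaMin <= 4L,
            similarityMin > 0, similarityMin <= 100)
  structure(list(teScoreMin = teScoreMin, aScoreMin = aScoreMin,
                 sulfoScoreMin = sulfoScoreMin,
                 similarityMin = similarityMin,
                 codeMatchMin = as.integer(codeMatchMin),
                 cationicMin = as.integer(cationicMin),
                 criteriaMin = as.integer(criteriaMin),
                 strictCys = strictCys, maxHits = as.integer(maxHits),
                 align = align),
            class = "scanConfig")
}

## Iterative non-overlapping local hits of refSeq on query: after each hit
## the matched query span is masked with X and the search repeated (greedy
## by score) until the score drops below scoreMin or maxHits is reached.
domainHits <- function(query, refSeq, refStart, kind, geneId, scoreMin,
                       config, maxHits = config$maxHits) {
  hits <- list()
  masked <- query
  while (length(hits) < maxHits) {
    aln <- alignPair(refSeq, masked, config$align)
    if (aln@score < scoreMin) break
    pos <- alignmentPositionTable(aln, refStart)
    hit <- new("DomainHit", geneId = geneId, kind = kind,
               querySpan = aln@querySpan, alignment = aln, positions = pos)
    hits[[length(hits) + 1L]] <- hit
    span <- aln@querySpan
    substr(masked, span[1], span[2]) <-
      paste(rep("X", span[2] - span[1] + 1L), collapse = "")
  }
  if (length(hits) > 1L) {
    ord <- order(vapply(hits, function(h) -h@alignment@score, 0))
    hits <- hits[ord]
  }
  hits
}

#' Locate TE domains on a protein
#'
#' Screens a protein for regions locally alignable to the reference TE
#' domain above the score threshold; hits are non-overlapping (greedy by
#' score, found by masking earlier hits) and each carries the position map
#' that transfers every reference anchor number onto the query.
#'
#' @param sequence protein sequence (single string) or a length-1 named
#'   character vector.
#' @param anchors a [ReferenceAnchors-class].
#' @param config a [scanConfig()].
#' @param geneId id recorded on the hits.
#' @return list of [DomainHit-class] (possibly empty).
#' @examples
#' hit <- findTEDomains(referenceSulM(), geneId = "SulM")[[1]]
#' subset(hitPositions(hit), refPos %in% sulmAnchors()@triad)
#' @export
findTEDomains <- function(sequence, anchors = sulmAnchors(),
                          config = scanConfig(),
                          geneId = if (!is.null(names(sequence)))
                            names(sequence)[1] else "query") {
  domainHits(as.character(sequence)[1], anchors@teSeq, anchors@teStart,
             "TE", geneId, config$teScoreMin, config)
}

#' Locate adenylation domains on a protein
#'
#' @inheritParams findTEDomains
#' @return list of [DomainHit-class].
#' @export
findADomains <- function(sequence, anchors = sulmAnchors(),
                         config = scanConfig(),
                         geneId = if (!is.null(names(sequence)))
                           names(sequence)[1] else "query") {
  domainHits(as.character(sequence)[1], anchors@aSeq, anchors@aStart,
             "A", geneId, config$aScoreMin, config)
}

hitResidueAt <- function(hit, refPos) {
  i <- match(refPos, hit@positions$refPos)
  list(pos = hit@positions$queryPos[i], res = hit@positions$queryResidue[i])
}

#' Assign the catalytic triad of a TE-domain hit
#'
#' Reads the nucleophile, acid and histidine off the hit's position map and
#' classifies the acid position: `"II"` when the query residue anchored to
#' the reference post-beta-7 acid is Asp/Glu; `"I"` when, instead, an
#' Asp/Glu anchors inside the reference position-I window (loop after
#' strand beta-6); `"undetermined"` otherwise (including unaligned
#' anchors).
#'
#' @param hit a TE [DomainHit-class].
#' @param anchors a [ReferenceAnchors-class].
#' @return a [TriadAssignment-class].
#' @export
assignTriad <- function(hit, anchors = sulmAnchors()) {
  stopifnot(is(hit, "DomainHit"), hit@kind == "TE")
  nuc <- hitResidueAt(hit, anchors@triad[["nuc"]])
  asp <- hitResidueAt(hit, anchors@triad[["asp"]])
  his <- hitResidueAt(hit, anchors@triad[["his"]])
  note <- character()
  if (!is.na(asp$res) && asp$res %in% c("D", "E")) {
    pos <- "II"
  } else {
    win <- anchors@positionIWindow
    tab <- hit@positions
    inWin <- tab$refPos >= win[1] & tab$refPos <= win[2] &
      !is.na(tab$queryResidue) & tab$queryResidue %in% c("D", "E")
    if (any(inWin)) {
      pos <- "I"
      i <- which(inWin)[1]
      asp <- list(pos = tab$queryPos[i], res = tab$queryResidue[i])
      note <- sprintf("acid found in position-I window at query %d",
                      tab$queryPos[i])
    } else {
      pos <- "undetermined"
      note <- if (is.na(asp$res))
        "reference acid anchor unaligned" else
        sprintf("no acid at either anchor (position-II residue is %s)",
                asp$res)
    }
  }
  new("TriadAssignment",
      nucPos = as.integer(nuc$pos), nucResidue = as.character(nuc$res),
      aspPos = as.integer(asp$pos), aspResidue = as.character(asp$res),
      hisPos = as.integer(his$pos), hisResidue = as.character(his$res),
      aspPosition = pos,
      note = if (length(note)) note else "")
}

#' Check the Gln-Cys-Asn motif
#'
#' Passes iff the query residues mapped from the reference motif window
#' (2817-2819) are exactly Gln, Cys, Asn.
#'
#' @param hit a TE [DomainHit-class].
#' @param anchors a [ReferenceAnchors-class].
#' @return a [CriterionResult-class] (criterion id `triad_motif` evidence
#'   fragment; aggregation with the triad happens in [screenCluster()]).
#' @export
checkQCNMotif <- function(hit, anchors = sulmAnchors()) {
  stopifnot(is(hit, "DomainHit"), hit@kind == "TE")
  m <- mapWindow(hit, anchors@motifWindow)
  if (any(is.na(m$res)))
    return(new("CriterionResult", id = "triad_motif", passed = FALSE,
               evidence = "motif window unaligned"))
  got <- paste(m$res, collapse = "")
  ok <- got == "QCN"
  ev <- sprintf("motif %s at query %s", got,
                paste(m$pos, collapse = "/"))
  new("CriterionResult", id = "triad_motif", passed = ok, evidence = ev)
}

mapWindow <- function(hit, refPositions) {
  i <- match(refPositions, hit@positions$refPos)
  list(pos = hit@positions$queryPos[i], res = hit@positions$queryResidue[i])
}

#' Check the cationic active-site positions
#'
#' Passes iff at least `config$cationicMin` (default 2) of the three
#' positions homologous to the reference active-site basic residues carry
#' Arg or Lys; unaligned positions count as non-cationic.
#'
#' @param hit a TE [DomainHit-class].
#' @param anchors a [ReferenceAnchors-class].
#' @param config a [scanConfig()].
#' @return a [CriterionResult-class] with id `cationic_site`.
#' @export
checkCationicSite <- function(hit, anchors = sulmAnchors(),
                              config = scanConfig()) {
  stopifnot(is(hit, "DomainHit"), hit@kind == "TE")
  m <- mapWindow(hit, anchors@cationicPos)
  cat_ <- !is.na(m$res) & m$res %in% c("R", "K")
  ev <- paste(sprintf("%d:%s", anchors@cationicPos,
                      ifelse(is.na(m$res), "-", m$res)), collapse = " ")
  new("CriterionResult", id = "cationic_site",
      passed = sum(cat_) >= config$cationicMin,
      evidence = sprintf("%d/3 cationic (%s)", sum(cat_), ev))
}

#' Extract the adenylation-domain specificity code
#'
#' Finds adenylation-domain hits on the protein, takes the "last module" A
#' domain (the hit nearest upstream of the TE hit when one is supplied,
#' otherwise the most C-terminal hit), and reads the ten specificity-code
#' residues through its position map.  Unaligned positions render `"-"`;
#' a code with fewer than 6 mapped positions is flagged unreliable.
#'
#' @param sequence protein sequence.
#' @param anchors a [ReferenceAnchors-class].
#' @param config a [scanConfig()].
#' @param teHit optional TE [DomainHit-class] defining "upstream".
#' @param geneId id recorded on the result.
#' @return a [SpecificityCode-class]; errors when no A domain is found.
#' @export
extractACode <- function(sequence, anchors = sulmAnchors(),
                         config = scanConfig(), teHit = NULL,
                         geneId = if (!is.null(names(sequence)))
                           names(sequence)[1] else "query") {
  hits <- findADomains(sequence, anchors, config, geneId)
  if (!length(hits)) stop("no A-domain in '", geneId, "'")
  starts <- vapply(hits, function(h) h@querySpan[1], 0L)
  if (!is.null(teHit)) {
    up <- starts < teHit@querySpan[1]
    hits <- if (any(up)) hits[up] else hits
    starts <- starts[if (any(up)) up else TRUE]
  }
  hit <- hits[[which.max(starts)]]
  m <- mapWindow(hit, anchors@codePositions)
  res <- ifelse(is.na(m$res), "-", m$res)
  nMapped <- sum(!is.na(m$res))
  new("SpecificityCode", code = paste(res, collapse = ""),
      geneId = geneId, nMapped = as.integer(nMapped),
      reliable = nMapped >= 6L)
}

#' Score a specificity code against a code table
#'
#' Counts matching positions (ignoring `"-"`) against each substrate's
#' code(s); passes iff the best-matching substrate is DAP with at least
#' `config$codeMatchMin` matches (and no other substrate scores higher).
#'
#' @param code a [SpecificityCode-class] or a 10-character string.
#' @param table named character vector of substrate codes
#'   (default [dapCodeTable()]).
#' @param config a [scanConfig()].
#' @return a [CriterionResult-class] with id `dap_code`.
#' @export
matchDAPCode <- function(code, table = dapCodeTable(),
                         config = scanConfig()) {
  if (is(code, "SpecificityCode")) code <- code@code
  if (!length(table)) stop("empty code table")
  scores <- vapply(table, function(ref) codeMatches(code, ref), 0L)
  best <- max(scores)
  bestNames <- names(scores)[scores == best]
  ok <- "DAP" %in% bestNames && scores[["DAP"]] >= config$codeMatchMin
  ev <- sprintf("code %s; best %s (%d/10 matches)", code,
                paste(bestNames, collapse = "/"), best)
  new("CriterionResult", id = "dap_code", passed = ok, evidence = ev)
}

codeMatches <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  use <- ca != "-" & cb != "-"
  sum(ca[use] == cb[use])
}

#' Detect a sulfotransferase gene in a cluster
#'
#' Passes when any gene is annotated or role-tagged as a sulfotransferase
#' (keyword path) or aligns locally to the reference sulfotransferase above
#' `config$sulfoScoreMin` (alignment path).
#'
#' @param cluster a [GeneCluster-class].
#' @param anchors a [ReferenceAnchors-class].
#' @param config a [scanConfig()].
#' @return a [CriterionResult-class] with id `sulfotransferase`.
#' @export
findSulfotransferase <- function(cluster, anchors = sulmAnchors(),
                                 config = scanConfig()) {
  stopifnot(is(cluster, "GeneCluster"))
  ids <- names(cluster@genes)
  byKey <- cluster@role == "sulfotransferase" |
    grepl("sulfotransferase", cluster@annotation, ignore.case = TRUE)
  hitIds <- ids[byKey]
  how <- rep("annotation", sum(byKey))
  for (i in which(!byKey)) {
    sc <- alignScore(anchors@sulfoSeq, as.character(cluster@genes[[i]]),
                     config$align)
    if (sc >= config$sulfoScoreMin) {
      hitIds <- c(hitIds, ids[i])
      how <- c(how, sprintf("alignment score %.0f", sc))
    }
  }
  if (length(hitIds))
    new("CriterionResult", id = "sulfotransferase", passed = TRUE,
        evidence = paste(sprintf("%s (%s)", hitIds, how), collapse = "; "))
  else
    new("CriterionResult", id = "sulfotransferase", passed = FALSE,
        evidence = "no sulfotransferase gene detected")
}

#' Screen a cluster against the four criteria
#'
#' Runs the full screen: locates the best TE-domain hit across the
#' cluster's genes, evaluates (1) position-II triad plus Gln-Cys-Asn motif
#' with a cysteine nucleophile, (2) the cationic active site, (3) the DAP
#' specificity code of the last-module adenylation domain, and (4) the
#' sulfotransferase gene, then aggregates the verdict
#' (`candidate` iff at least `config$criteriaMin` criteria pass).  A
#' cluster with no TE hit is rejected with reason "no TE domain".
#'
#' @param cluster a [GeneCluster-class].
#' @param anchors a [ReferenceAnchors-class].
#' @param config a [scanConfig()].
#' @param codeTable substrate code table for criterion 3.
#' @return a [ClusterVerdict-class].
#' @examples
#' cl <- makeCluster(seed = 7)
#' screenCluster(cl$cluster)
#' @export
screenCluster <- function(cluster, anchors = sulmAnchors(),
                          config = scanConfig(),
                          codeTable = dapCodeTable()) {
  stopifnot(is(cluster, "GeneCluster"))
  ids <- names(cluster@genes)
  teHit <- NULL
  teScores <- vapply(seq_along(cluster@genes), function(i)
    alignScore(anchors@teSeq, as.character(cluster@genes[[i]]),
               config$align), 0)
  best <- which.max(teScores)
  if (length(best) && teScores[best] >= config$teScoreMin) {
    hits <- domainHits(as.character(cluster@genes[[best]]), anchors@teSeq,
                       anchors@teStart, "TE", ids[best], config$teScoreMin,
                       config, maxHits = 1L)
    if (length(hits)) teHit <- hits[[1]]
  }
  if (is.null(teHit)) return(emptyVerdict(cluster@clusterId))

  ## criterion 1: triad (strict Cys by default) + position II + QCN motif
  triad <- assignTriad(teHit, anchors)
  motif <- checkQCNMotif(teHit, anchors)
  nucOK <- !is.na(triad@nucResidue) &&
    (triad@nucResidue == "C" ||
       (!config$strictCys && triad@nucResidue == "S"))
  hisOK <- !is.na(triad@hisResidue) && triad@hisResidue == "H"
  c1pass <- triad@aspPosition == "II" && motif@passed && nucOK && hisOK
  c1 <- new("CriterionResult", id = "triad_motif", passed = c1pass,
            evidence = sprintf("%s; acid position %s; nucleophile %s; His %s",
                               motif@evidence, triad@aspPosition,
                               ifelse(is.na(triad@nucResidue), "-",
                                      triad@nucResidue),
                               ifelse(is.na(triad@hisResidue), "-",
                                      triad@hisResidue)))

  ## criterion 2
  c2 <- checkCationicSite(teHit, anchors, config)

  ## criterion 3: last-module A domain, preferring the TE-carrying gene
  c3 <- NULL; aGene <- NA_character_
  teSeqChar <- as.character(cluster@genes[[match(teHit@geneId, ids)]])
  code <- tryCatch(extractACode(teSeqChar, anchors, config, teHit,
                                teHit@geneId),
                   error = function(e) NULL)
  if (is.null(code)) {
    for (i in seq_along(cluster@genes)) {
      if (ids[i] == teHit@geneId) next
      code <- tryCatch(extractACode(as.character(cluster@genes[[i]]),
                                    anchors, config, NULL, ids[i]),
                       error = function(e) NULL)
      if (!is.null(code)) break
    }
  }
  if (is.null(code)) {
    c3 <- new("CriterionResult", id = "dap_code", passed = FALSE,
              evidence = "no A-domain found in cluster")
  } else {
    aGene <- code@geneId
    c3 <- matchDAPCode(code, codeTable, config)
    if (!code@reliable)
      c3 <- new("CriterionResult", id = "dap_code", passed = FALSE,
                evidence = paste0(c3@evidence, "; code unreliable (",
                                  code@nMapped, "/10 mapped)"))
  }

  ## criterion 4
  c4 <- findSulfotransferase(cluster, anchors, config)

  crit <- list(triad_motif = c1, cationic_site = c2, dap_code = c3,
               sulfotransferase = c4)
  n <- sum(vapply(crit, function(x) x@passed, logical(1)))
  new("ClusterVerdict", clusterId = cluster@clusterId, criteria = crit,
      nPassed = as.integer(n),
      call = if (n >= config$criteriaMin) "candidate" else "rejected",
      teGene = teHit@geneId, aGene = aGene)
}

#' Partition sequences by similarity to the reference TE domain
#'
#' Mirrors the screening step that separates close homologs of the
#' reference (similarity above the threshold, default 70%) from the more
#' divergent sequences that are then examined criterion by criterion.
#' Similarity is the fraction of local-alignment columns whose residues are
#' identical or score positively (see [alignPair()]), in percent.
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param anchors a [ReferenceAnchors-class].
#' @param config a [scanConfig()].
#' @return data.frame with columns `id`, `similarity` (percent), `group`
#'   (`"homolog"` / `"divergent"`).
#' @export
partitionBySimilarity <- function(sequences, anchors = sulmAnchors(),
                                  config = scanConfig()) {
  seqs <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  sim <- vapply(seqs, function(s)
    100 * alignPair(anchors@teSeq, s, config$align)@similarity, 0,
    USE.NAMES = FALSE)
  data.frame(id = ids, similarity = sim,
             group = ifelse(sim > config$similarityMin, "homolog",
                            "divergent"),
             stringsAsFactors = FALSE)
}
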