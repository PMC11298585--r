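CFG <- scanConfig()

test_that("the reference protein carries exactly one TE domain with the documented triad", {
  hits <- findTEDomains(referenceSulM(), ANC, CFG, geneId = "SulM")
  expect_length(hits, 1L)
  hit <- hits[[1]]
  tri <- subset(hitPositions(hit), refPos %in% ANC@triad)
  expect_equal(tri$queryPos, unname(ANC@triad[c("nuc", "asp", "his")]))
  expect_equal(tri$queryResidue, c("C", "D", "H"))
  ## reversed sequence is a negative control
  rev <- paste(rev(strsplit(referenceSulM(), "")[[1]]), collapse = "")
  expect_length(findTEDomains(rev, ANC, CFG), 0L)
})

test_that("TE domains embedded in flanking sequence are found and mapped", {
  ok <- 0L; totalAnchors <- 0L; mappedRight <- 0L
  anchorPos <- c(ANC@triad, ANC@motifWindow, ANC@cationicPos)
  for (k in 1:25) {
    v <- makeTEVariant(seed = 8000 + k, mutationRate = 0.05,
                       indelRate = 0.005, flank = 150, anchors = ANC)
    hits <- findTEDomains(v$seq, ANC, CFG)
    if (length(hits) == 1L) ok <- ok + 1L
    m <- subset(hitPositions(hits[[1]]), refPos %in% anchorPos)
    truth <- v$map[as.character(m$refPos)]
    totalAnchors <- totalAnchors + nrow(m)
    mappedRight <- mappedRight + sum(!is.na(m$queryPos) & m$queryPos == truth)
  }
  expect_equal(ok, 25L)
  expect_gte(mappedRight / totalAnchors, 0.95)
})

test_that("triad assignment distinguishes position I, II and undetermined", {
  hit <- findTEDomains(referenceSulM(), ANC, CFG)[[1]]
  tr <- assignTriad(hit, ANC)
  expect_equal(aspPosition(tr), "II")
  expect_equal(tr@nucResidue, "C")
  expect_equal(tr@aspPos, unname(ANC@triad[["asp"]]))

  vI <- makeTEVariant(seed = 21, aspPosition = "I", anchors = ANC)
  hI <- findTEDomains(vI$seq, ANC, CFG)[[1]]
  expect_equal(aspPosition(assignTriad(hI, ANC)), "I")

  vN <- makeTEVariant(seed = 22, aspPosition = "none", anchors = ANC)
  hN <- findTEDomains(vN$seq, ANC, CFG)[[1]]
  expect_equal(aspPosition(assignTriad(hN, ANC)), "undetermined")
})

test_that("Gln-Cys-Asn motif check is an exact match", {
  hit <- findTEDomains(referenceSulM(), ANC, CFG)[[1]]
  expect_true(passed(checkQCNMotif(hit, ANC)))

  vAsn <- makeTEVariant(seed = 23, qcn = FALSE, anchors = ANC)
  hAsn <- findTEDomains(vAsn$seq, ANC, CFG)[[1]]
  expect_false(passed(checkQCNMotif(hAsn, ANC)))

  ## catalytic Cys -> Ser also fails the strict motif
  vSer <- makeTEVariant(seed = 24, qcn = FALSE, anchors = ANC,
                        extraEdits = c("2818" = "S"))
  expect_error(makeTEVariant(seed = 24, qcn = TRUE,
                             extraEdits = c("2818" = "S"), anchors = ANC),
               "motif")
  hSer <- findTEDomains(vSer$seq, ANC, CFG)[[1]]
  expect_false(passed(checkQCNMotif(hSer, ANC)))
})

test_that("cationic-site criterion passes at 2 or 3 of 3 and fails below", {
  for (k in 0:3) {
    v <- makeTEVariant(seed = 30 + k, nCationic = k, anchors = ANC)
    h <- findTEDomains(v$seq, ANC, CFG)[[1]]
    cr <- checkCationicSite(h, ANC, CFG)
    expect_equal(passed(cr), k >= 2, info = paste("nCationic =", k))
  }
})

test_that("specificity-code extraction reads the planted code through the map", {
  code <- extractACode(referenceSulM(), ANC, CFG, geneId = "SulM")
  expect_equal(codeString(code), dapCodeTable()[["DAP"]])
  expect_true(code@reliable)

  g <- makeNRPSGeneForTest(seed = 55, mutationRate = 0.05)
  code2 <- extractACode(g$seq, ANC, CFG)
  expect_equal(codeString(code2), dapCodeTable()[["DAP"]])

  expect_error(extractACode(referenceSulfotransferase(), ANC, CFG),
               "no A-domain")
})

test_that("DAP code matching agrees with exhaustive best-match over the table", {
  tab <- dapCodeTable()
  expect_true(passed(matchDAPCode(tab[["DAP"]], tab, CFG)))
  ## three mismatches drop below the default threshold of 8
  spoiled <- tab[["DAP"]]
  substr(spoiled, 2, 4) <- "AAA"
  expect_false(passed(matchDAPCode(spoiled, tab, CFG)))
  expect_error(matchDAPCode(tab[["DAP"]], character(), CFG), "empty")

  set.seed(77)
  aa <- names(lactamscan:::AA_FREQS)
  for (k in 1:25) {
    code <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    res <- matchDAPCode(code, tab, CFG)
    scores <- vapply(tab, function(ref)
      sum(strsplit(code, "")[[1]] == strsplit(ref, "")[[1]]), 0L)
    bruteBest <- names(scores)[scores == max(scores)]
    brutePass <- "DAP" %in% bruteBest && scores[["DAP"]] >= CFG$codeMatchMin
    expect_equal(passed(res), brutePass, info = code)
  }
})

test_that("sulfotransferase detection works by keyword and by alignment", {
  byKey <- makeCluster(seed = 41, annotateSulfo = TRUE)$cluster
  r1 <- findSulfotransferase(byKey, ANC, CFG)
  expect_true(passed(r1))
  expect_match(evidence(r1), "annotation")

  byAln <- makeCluster(seed = 42, mutationRate = 0.10,
                       annotateSulfo = FALSE)$cluster
  r2 <- findSulfotransferase(byAln, ANC, CFG)
  expect_true(passed(r2))
  expect_match(evidence(r2), "alignment")

  none <- geneCluster("neg", stats::setNames(
    vapply(1:3, function(i) withSeed(600 + i,
      paste(lactamscan:::randomResidues(300), collapse = "")), ""),
    paste0("g", 1:3)))
  expect_false(passed(findSulfotransferase(none, ANC, CFG)))
})

test_that("cluster screening aggregates the four criteria", {
  full <- makeCluster(seed = 51)
  v <- screenCluster(full$cluster, ANC, CFG)
  expect_equal(verdictCall(v), "candidate")
  expect_equal(nPassed(v), 4L)
  expect_equal(v@teGene, "nrps1")

  noSulfo <- makeCluster(seed = 52, sulfotransferase = FALSE)
  v2 <- screenCluster(noSulfo$cluster, ANC, CFG)
  expect_equal(nPassed(v2), 3L)
  expect_equal(verdictCall(v2), "rejected")

  ## a cluster of random proteins has no TE domain at all
  none <- geneCluster("neg", stats::setNames(
    vapply(1:2, function(i) withSeed(700 + i,
      paste(lactamscan:::randomResidues(320), collapse = "")), ""),
    paste0("g", 1:2)))
  v3 <- screenCluster(none, ANC, CFG)
  expect_equal(verdictCall(v3), "rejected")
  expect_match(evidence(criteria(v3)$triad_motif), "no TE domain")
})

test_that("screening is deterministic and ablations never increase the criterion count", {
  base <- makeCluster(seed = 61)
  vBase <- screenCluster(base$cluster, ANC, CFG)
  vBase2 <- screenCluster(base$cluster, ANC, CFG)
  expect_equal(verdictToRowForTest(vBase), verdictToRowForTest(vBase2))
  expect_equal(nPassed(vBase), 4L)

  ablations <- list(list(qcn = FALSE), list(aspPosition = "I"),
                    list(aspPosition = "none"), list(nCationic = 1L),
                    list(dapCode = FALSE), list(sulfotransferase = FALSE))
  for (ab in ablations) {
    args <- utils::modifyList(list(seed = 61), ab)
    cl <- do.call(makeCluster, args)
    v <- screenCluster(cl$cluster, ANC, CFG)
    expect_lte(nPassed(v), nPassed(vBase))
    expect_lt(nPassed(v), 4L)
  }
})

test_that("verdicts match planted truth on a small noiseless panel", {
  panel <- makeClusterPanel(n = 20, mutationRate = 0, seed = 99,
                            anchors = ANC)
  for (p in panel) {
    v <- screenCluster(p$cluster, ANC, CFG)
    got <- vapply(criteria(v), passed, logical(1))[names(p$truth)]
    expect_equal(unname(got), unname(p$truth), info = clusterId(v))
    expect_equal(verdictCall(v), p$call, info = clusterId(v))
  }
})

test_that("similarity partition separates close homologs from divergent sequences", {
  seqs <- c(homolog = makeTEVariant(seed = 71, mutationRate = 0.03,
                                    anchors = ANC)$seq,
            divergent = makeTEVariant(seed = 72, mutationRate = 0.45,
                                      indelRate = 0.02, anchors = ANC)$seq)
  part <- partitionBySimilarity(seqs, ANC, CFG)
  expect_equal(part$group, c("homolog", "divergent"))
  expect_gt(part$similarity[1], CFG$similarityMin)
  expect_lt(part$similarity[2], CFG$similarityMin)
})
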