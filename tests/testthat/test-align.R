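B62 <- substitutionMatrix("BLOSUM62")

test_that("self-alignment and single-substitution scores follow the matrix", {
  a <- alignPair("MKV", "MKV")
  expect_equal(pidentity(a), 1)
  expect_equal(alignmentScore(a),
               B62["M", "M"] + B62["K", "K"] + B62["V", "V"])
  b <- alignPair("A", "G")
  expect_equal(alignmentScore(b), B62["A", "G"])
  expect_equal(nchar(b@alignedRef), 1L)
})

test_that("global scores equal exhaustive enumeration on random short pairs", {
  set.seed(101)
  for (k in 1:40) {
    a <- randomSeq(sample(3:12, 1))
    b <- randomSeq(sample(3:12, 1))
    got <- alignmentScore(alignPair(a, b))
    want <- bruteGlobalScore(a, b, B62)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("local scores equal exhaustive substring enumeration and are non-negative", {
  set.seed(202)
  loc <- alignParams(mode = "local")
  for (k in 1:8) {
    a <- randomSeq(sample(4:7, 1))
    b <- randomSeq(sample(4:7, 1))
    got <- alignmentScore(alignPair(a, b, loc))
    expect_gte(got, 0)
    expect_equal(got, bruteLocalScore(a, b, B62), info = paste(a, b))
  }
})

test_that("score is symmetric for a symmetric matrix and identity <= similarity", {
  set.seed(303)
  for (k in 1:20) {
    a <- randomSeq(sample(5:30, 1))
    b <- randomSeq(sample(5:30, 1))
    f <- alignPair(a, b)
    r <- alignPair(b, a)
    expect_equal(alignmentScore(f), alignmentScore(r))
    expect_lte(pidentity(f), psimilarity(f) + 1e-12)
    ## ungapping the gapped strings recovers the spanned subsequences
    expect_equal(gsub("-", "", f@alignedRef),
                 substr(a, refSpan(f)[1], refSpan(f)[2]))
    expect_equal(gsub("-", "", f@alignedQuery),
                 substr(b, querySpan(f)[1], querySpan(f)[2]))
  }
})

test_that("alignment parameters are validated", {
  expect_error(alignParams(gapOpen = 1, gapExtend = 2), "gapOpen")
  expect_error(alignPair("MK", "M1K"), "illegal residue")
  expect_error(alignPair("", "MK"), "non-empty")
  expect_error(substitutionMatrix("NOSUCH62"), "unknown substitution matrix")
})

test_that("position mapping: identity, single-indel shift, unaligned and outside flags", {
  aln <- alignPair("MKVLLAG", "MKVLLAG")
  m <- mapPositions(aln, c(1, 4, 7))
  expect_equal(m$queryPos, c(1L, 4L, 7L))
  expect_equal(m$status, rep("mapped", 3))

  ## reference has one extra residue before the anchor: query numbers shift
  ## down by one
  aln2 <- alignPair("MKKVLLAG", "MKVLLAG")
  m2 <- mapPositions(aln2, 8)
  expect_equal(m2$queryPos, 7L)
  expect_equal(m2$queryResidue, "G")

  ## query gap over a reference position -> unaligned
  aln3 <- alignPair("MKVWWWLLAG", "MKVLLAG")
  m3 <- mapPositions(aln3, 5)
  expect_equal(m3$status, "unaligned")
  expect_true(is.na(m3$queryPos))

  ## outside the aligned reference span
  loc <- alignPair("AAAWKLMKVLLA", "KVLL", alignParams(mode = "local"))
  expect_equal(mapPositions(loc, 1)$status, "outside")
})

test_that("mapped query positions are strictly increasing and respect refStart offsets", {
  set.seed(404)
  for (k in 1:10) {
    v <- makeTEVariant(seed = k, mutationRate = 0.1, indelRate = 0.02,
                       anchors = ANC)
    aln <- alignPair(ANC@teSeq, v$seq, alignParams(mode = "local"))
    m <- mapPositions(aln, ANC@triad, refStart = ANC@teStart)
    qp <- m$queryPos[!is.na(m$queryPos)]
    expect_true(all(diff(qp) > 0))
  }
})

test_that("planted anchors are recovered through the position map at 5% mutation", {
  anchorPos <- c(ANC@triad, ANC@motifWindow, ANC@cationicPos)
  n <- 120
  hits <- 0L; total <- 0L
  for (k in seq_len(n)) {
    v <- makeTEVariant(seed = 7000 + k, mutationRate = 0.05,
                       indelRate = 0.01, anchors = ANC)
    aln <- alignPair(ANC@teSeq, v$seq, alignParams(mode = "local"))
    m <- mapPositions(aln, anchorPos, refStart = ANC@teStart)
    truth <- v$map[as.character(anchorPos)]
    total <- total + length(anchorPos)
    hits <- hits + sum(!is.na(m$queryPos) & m$queryPos == truth)
  }
  expect_gte(hits / total, 0.99)
})
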