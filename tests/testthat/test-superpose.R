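test_that("self-superposition gives zero rmsd and the identity rotation", {
  X <- makeToyHelix(15)
  sp <- kabschSuperpose(X, X)
  expect_equal(sp@rmsd, 0, tolerance = 1e-10)
  expect_equal(sp@rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp@translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("seeded rigid transforms are recovered to machine precision", {
  for (seed in 1:25) {
    toy <- makeToyStructure(seed, n = 40, kind = "cloud")
    sp <- kabschSuperpose(toy$coords, toy$copy)
    expect_lt(sp@rmsd, 1e-8)
    expect_lt(max(abs(sp@rotation - toy$rotation)), 1e-6)
    expect_lt(max(abs(sp@translation - toy$translation)), 1e-6)
    ## rotations are always proper and orthonormal
    R <- sp@rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("kabsch agrees with an independent least-squares fit", {
  toy <- makeToyStructure(99, n = 25, kind = "cloud", noise = 0.8)
  sp <- kabschSuperpose(toy$coords, toy$copy)
  fitted <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.numeric(t(toy$copy)),
    mobile = as.numeric(t(toy$coords))))
  ref <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                              toy$copy)^2)))
  expect_equal(sp@rmsd, ref, tolerance = 1e-6)
})

test_that("rmsd is invariant under rigid motion of both sets", {
  toy <- makeToyStructure(5, n = 30, kind = "cloud", noise = 1.0)
  base <- kabschSuperpose(toy$coords, toy$copy)@rmsd
  for (seed in 1:5) {
    tr <- makeToyStructure(seed + 40, n = 30, kind = "cloud")
    moved <- applyRigid(toy$coords, tr$rotation, tr$translation)
    expect_equal(kabschSuperpose(moved, toy$copy)@rmsd, base,
                 tolerance = 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(kabschSuperpose(makeToyHelix(2), makeToyHelix(2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("refinement rejects planted outliers and tightens the rmsd", {
  toy <- makeToyStructure(7, n = 60, kind = "cloud", noise = 0.3)
  bad <- toy$copy
  bad[1:5, ] <- bad[1:5, ] + 25          # five gross outliers
  plain <- kabschSuperpose(toy$coords, bad)
  refined <- kabschSuperpose(toy$coords, bad, refine = TRUE)
  expect_gte(refined@nRejected, 5L)
  expect_false(any(refined@kept[1:5]))
  expect_lt(refined@rmsd, plain@rmsd / 5)
  expect_equal(refined@nPairs + refined@nRejected, 60L)
})

test_that("noisy copies give rmsd near the planted noise level", {
  rmsds <- vapply(1:25, function(seed)
    kabschSuperpose(makeToyStructure(seed, n = 100, kind = "cloud",
                                     noise = 0.5)$coords,
                    makeToyStructure(seed, n = 100, kind = "cloud",
                                     noise = 0.5)$copy)@rmsd, 0)
  ## E[rmsd] ~ sigma * sqrt(3) per-coordinate noise on one side, reduced by
  ## the fitted 6 dof; check within +-20%
  expect_equal(mean(rmsds), 0.5 * sqrt(3), tolerance = 0.2)
})

test_that("structure-level CA rmsd pairs residues by number and honours exclusions", {
  helix <- makeToyHelix(40)
  sA <- caStructure(helix, chain = "A", startRes = 100L)
  moved <- applyRigid(helix, rotationMatrix("y", 35), c(3, -2, 7))
  moved[10:15, ] <- moved[10:15, ] + 8   # a displaced loop
  sB <- caStructure(moved, chain = "B", startRes = 100L)
  full <- rmsdCA(sA, sB, "A:100-139", "B:100-139")
  excl <- rmsdCA(sA, sB, "A:100-139", "B:100-139",
                 exclude = list(c(109, 114)))
  expect_equal(excl@nPairs, 34L)
  expect_lt(excl@rmsd, 1e-8)
  expect_gt(full@rmsd, 1)
  expect_equal(rmsdCA(sA, sA, "A:100-139", "A:100-139")@rmsd, 0,
               tolerance = 1e-12)
  expect_error(rmsdCA(sA, sB, "A:100-101", "B:100-139"), "fewer than 3")
})

test_that("alignment-mediated pairing drives cross-protein CA rmsd", {
  helix <- makeToyHelix(30)
  sA <- caStructure(helix, chain = "A", startRes = 1L)
  ## partner protein: same fold, numbering offset by 500
  sB <- caStructure(applyRigid(helix, rotationMatrix("z", 60), c(1, 1, 1)),
                    chain = "B", startRes = 501L)
  map <- data.frame(refPos = 1:30, queryPos = 501:530)
  sp <- rmsdCA(sA, sB, map = map)
  expect_equal(sp@nPairs, 30L)
  expect_lt(sp@rmsd, 1e-8)
})
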