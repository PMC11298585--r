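test_that("an ideal helix built along z has axis (0,0,1)", {
  ax <- helixAxis(makeToyHelix(18))  # five full turns
  expect_equal(as.numeric(acos(min(1, ax@direction[3])) * 180 / pi), 0,
               tolerance = 1)
  expect_equal(sqrt(sum(ax@direction^2)), 1, tolerance = 1e-10)
  expect_error(helixAxis(makeToyHelix(4)), "at least 5")
})

test_that("a planted inter-helix rotation is recovered", {
  h <- makeToyHelix(18)
  a1 <- helixAxis(h)
  for (ang in c(20, 50, 90, 130)) {
    a2 <- helixAxis(applyRigid(h, rotationMatrix("x", ang), c(5, 5, 5)))
    expect_equal(interhelixAngle(a1, a2), ang, tolerance = 0.5,
                 info = paste("angle", ang))
  }
  ## orientation is respected: obtuse angles do not fold back
  a3 <- helixAxis(applyRigid(h, rotationMatrix("x", 130), c(0, 0, 0)))
  expect_gt(interhelixAngle(a1, a3), 120)
})

test_that("helixAxisFor reads a residue span off a structure", {
  s <- caStructure(makeToyHelix(30), chain = "A", startRes = 200L)
  ax <- helixAxisFor(s, "A:205-216")
  expect_equal(ax@nRes, 12L)
  expect_equal(abs(ax@direction[3]), 1, tolerance = 0.02)
})

test_that("triad geometry reports His-nucleophile and His-acid minimum distances", {
  ## toy active site: His ND1/NE2, Cys SG, Asp OD1/OD2 at known separations
  atoms <- data.frame(
    chain = "A",
    resno = c(56, 56, 18, 18, 26, 26),
    resid = c("HIS", "HIS", "CYS", "CYS", "ASP", "ASP"),
    elety = c("ND1", "NE2", "CB", "SG", "OD1", "OD2"),
    x = c(0, 1.4, 4.5, 3.2, -2.7, -3.5),
    y = 0, z = 0)
  s <- proteinStructure(atoms)
  d <- triadGeometry(s, c(nuc = 18, asp = 26, his = 56))
  expect_equal(unname(d[["his_nuc"]]), 3.2 - 1.4)   # NE2 is nearer SG
  expect_equal(unname(d[["his_asp"]]), 2.7)          # OD1 is nearer ND1
  ## missing side chain atoms are reported
  s2 <- proteinStructure(atoms[atoms$elety != "SG", ])
  expect_error(triadGeometry(s2, c(nuc = 18, asp = 26, his = 56)),
               "CYS18")
})

test_that("serine and glutamate triads are accepted, other residues rejected", {
  atoms <- data.frame(
    chain = "A", resno = c(5, 5, 1, 3, 3),
    resid = c("HIS", "HIS", "SER", "GLU", "GLU"),
    elety = c("ND1", "NE2", "OG", "OE1", "OE2"),
    x = c(0, 1.4, 4.0, -3.0, -4.0), y = 0, z = 0)
  s <- proteinStructure(atoms)
  d <- triadGeometry(s, c(nuc = 1, asp = 3, his = 5))
  expect_equal(unname(d[["his_nuc"]]), 2.6)
  bad <- atoms; bad$resid[3] <- "GLY"; bad$elety[3] <- "CA"
  expect_error(triadGeometry(proteinStructure(bad),
                             c(nuc = 1, asp = 3, his = 5)),
               "expected CYS or SER")
})

test_that("radius of gyration has its closed-form values and converges on a shell", {
  expect_equal(radiusOfGyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  ## uniform points on a radius-R sphere shell: Rg -> R
  set.seed(31)
  R <- 7
  for (n in c(200, 2000)) {
    v <- matrix(stats::rnorm(n * 3), ncol = 3)
    v <- R * v / sqrt(rowSums(v^2))
    expect_equal(radiusOfGyration(v), R, tolerance = 0.02)
  }
  ## mass weighting counts heavy atoms more
  s <- proteinStructure(data.frame(chain = "A", resno = 1:2,
                                   elety = c("C", "S"),
                                   elesy = c("C", "S"),
                                   x = c(0, 2), y = 0, z = 0))
  rgW <- radiusOfGyration(s)
  rgU <- radiusOfGyration(s, massWeighted = FALSE)
  expect_equal(rgU, 1)
  mC <- 12.011; mS <- 32.06
  com <- 2 * mS / (mC + mS)
  expect_equal(rgW, sqrt((mC * com^2 + mS * (2 - com)^2) / (mC + mS)))
})
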