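miniPDB <- c(
  "ATOM      1  N   ALA A  10      11.104   6.134  -6.504  1.00 10.00           N",
  "ATOM      2  CA  ALA A  10      11.639   6.071  -5.147  1.00 10.00           C",
  "ATOM      3  CB AALA A  10      12.919   6.877  -5.041  0.40 10.00           C",
  "ATOM      4  CB BALA A  10      12.900   6.900  -5.000  0.60 10.00           C",
  "HETATM    5  O   HOH A 101       1.000   2.000   3.000  1.00 20.00           O",
  "END")

miniCIF <- c(
  "data_mini", "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . ALA A 1 10 ? 11.104 6.134 -6.504 1.00 10.00 ? 10 ALA A N 1",
  "ATOM 2 C CA . ALA A 1 10 ? 11.639 6.071 -5.147 1.00 10.00 ? 10 ALA A CA 1",
  "ATOM 3 C CB A ALA A 1 10 ? 12.919 6.877 -5.041 0.40 10.00 ? 10 ALA A CB 1",
  "ATOM 4 C CB B ALA A 1 10 ? 12.900 6.900 -5.000 0.60 10.00 ? 10 ALA A CB 1",
  "HETATM 5 O O . HOH A 2 . ? 1.000 2.000 3.000 1.00 20.00 ? 101 HOH A O 1")

test_that("PDB parsing: coordinates, altloc by occupancy, water handling", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(miniPDB, tf)
  s <- readStructure(tf, dropWaters = FALSE)
  a <- atoms(s)
  expect_equal(nrow(a), 4L)      # one CB retained
  expect_equal(a$x[a$elety == "CA"], 11.639)
  cb <- a[a$elety == "CB", ]
  expect_equal(cb$o, 0.6)        # highest occupancy altloc wins
  expect_true("HOH" %in% a$resid)
  s2 <- readStructure(tf)
  expect_false("HOH" %in% atoms(s2)$resid)
  expect_error(readStructure("no/such/file.pdb"), "not found")
})

test_that("the same structure parses identically from PDB and mmCIF", {
  tp <- withr::local_tempfile(fileext = ".pdb")
  tc <- withr::local_tempfile(fileext = ".cif")
  writeLines(miniPDB, tp)
  writeLines(miniCIF, tc)
  sp <- readStructure(tp, dropWaters = FALSE)
  sc <- readStructure(tc, dropWaters = FALSE)
  cols <- c("type", "chain", "resno", "resid", "elety", "elesy",
            "x", "y", "z", "o")
  expect_equal(atoms(sp)[, cols], atoms(sc)[, cols])
})

test_that("PDB writing round-trips through the reader", {
  helix <- caStructure(makeToyHelix(12), chain = "Q", startRes = 100L)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writePDB(helix, tf)
  back <- readStructure(tf)
  expect_equal(atoms(back)$resno, atoms(helix)$resno)
  expect_equal(atoms(back)$chain, atoms(helix)$chain)
  expect_equal(atoms(back)$x, atoms(helix)$x, tolerance = 1e-3)
  expect_equal(atoms(back)$elesy, atoms(helix)$elesy)
})

test_that("selection strings select chains and residue ranges", {
  co <- rbind(makeToyHelix(10), makeToyHelix(10) + 50)
  s <- proteinStructure(data.frame(
    chain = rep(c("A", "B"), each = 10), resno = c(1:10, 1:10),
    elety = "CA", x = co[, 1], y = co[, 2], z = co[, 3]))
  expect_equal(sum(selectAtoms(s, "A")), 10)
  expect_equal(sum(selectAtoms(s, "A:3-5")), 3)
  expect_equal(sum(selectAtoms(s, "A:3-5,B:1-2")), 5)
  expect_equal(nrow(caTable(s, "B")), 10)
  expect_error(parseSelection("A:x-y"), "bad selection")
  sel <- parseSelection("A:3-5")
  expect_equal(sel$from, 3L)
  expect_equal(sel$to, 5L)
})
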