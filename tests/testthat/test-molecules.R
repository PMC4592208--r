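# Molecular graph container, SMILES/SDF parsing, round-trips.

test_that("SMILES parsing builds the expected annotated graphs", {
  m <- parseSmiles("CCO", id = "ethanol")
  expect_s4_class(m, "Molecule")
  expect_equal(heavyAtomCount(m), 3L)
  expect_equal(m@atoms$element, c("C", "C", "O"))
  expect_equal(m@atoms$nH, c(3L, 2L, 1L))
  expect_equal(nrow(m@bonds), 2L)

  benz <- parseSmiles("c1ccccc1")
  expect_equal(heavyAtomCount(benz), 6L)
  expect_true(all(benz@atoms$aromatic))
  expect_true(all(benz@bonds$order == "ar"))
  expect_equal(nrow(benz@bonds), 6L)
  expect_equal(benz@atoms$nH, rep(1L, 6))

  charged <- parseSmiles("C[N+](C)(C)C")
  expect_equal(charged@atoms$charge[2], 1L)
  expect_equal(charged@atoms$nH[2], 0L)

  pyrrole <- parseSmiles("c1cc[nH]c1")
  expect_equal(sum(pyrrole@atoms$element == "N"), 1L)
  expect_equal(pyrrole@atoms$nH[pyrrole@atoms$element == "N"], 1L)
})

test_that("malformed and unsupported records are rejected with position info", {
  expect_error(parseSmiles("C(C"), "unclosed branch")
  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("[Zz]"), "unsupported element|cannot parse")
  expect_error(parseSmiles("CC(=O)[Xe]C"), "unsupported element")
  # lowercase aromatic atom outside an aromatic ring is a hard error
  expect_error(parseSmiles("cC"), "aromatic")
})

test_that("reading a SMILES file preserves order, ids and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "", "# comment", "c1ccccc1 benzene",
               "CC methane-ish"), path)
  mols <- readMolecules(path)
  expect_length(mols, 3L)
  expect_equal(vapply(mols, function(m) m@id, character(1)),
               c("ethanol", "benzene", "methane-ish"))
  expect_equal(heavyAtomCount(mols[[2]]), 6L)

  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a", "CC b", "C(C broken"), bad)
  expect_error(readMolecules(bad), "line 3")

  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_warning(out <- readMolecules(empty), "no molecule records")
  expect_length(out, 0L)
})

test_that("multi-fragment records keep the largest fragment with a warning", {
  expect_warning(m <- parseSmiles("CCO.[Na+]"), "fragments")
  expect_equal(heavyAtomCount(m), 3L)
  expect_equal(m@atoms$element, c("C", "C", "O"))
  # harness bypass keeps everything
  both <- parseSmiles("CCO.CC", keepAllFragments = TRUE)
  expect_equal(heavyAtomCount(both), 5L)
})

test_that("heavy_atom_count equals a direct scan and survives reordering", {
  for (m in fixtureMolecules()) {
    expect_equal(heavyAtomCount(m), sum(m@atoms$element != "H"))
  }
  expect_equal(heavyAtomCount(parseSmiles("C")), 1L)
  # same molecule, different atom ordering in the record
  expect_equal(heavyAtomCount(parseSmiles("OCC")),
               heavyAtomCount(parseSmiles("CCO")))
  expect_equal(heavyAtomCount(parseSmiles("Cc1ccccc1")),
               heavyAtomCount(parseSmiles("c1ccc(C)cc1")))
})

test_that("canonical write + re-parse yields an isomorphic graph", {
  for (m in fixtureMolecules()) expectIsomorphicRoundTrip(m)
  # bracket atoms and charges survive
  expectIsomorphicRoundTrip(parseSmiles("C[N+](C)(C)CC([O-])=O"))
  expectIsomorphicRoundTrip(parseSmiles("c1cc[nH]c1"))
})

test_that("SDF V2000 records parse and agree with an independent reader", {
  # hand-written V2000 record for acetamide CC(=O)N with one explicit H
  sdf <- c(
    "acetamide", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000   -1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.5000   -1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    "  2  4  1  0  0  0  0",
    "  4  5  1  0  0  0  0",
    "M  END",
    "$$$$")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  mols <- readMolecules(path)
  expect_length(mols, 1L)
  m <- mols[[1]]
  expect_equal(m@id, "acetamide")
  expect_equal(heavyAtomCount(m), 4L)
  expect_equal(m@atoms$element, c("C", "C", "O", "N"))
  # N carries the explicit H plus one implicit H
  expect_equal(m@atoms$nH[4], 2L)
  expect_equal(nrow(m@bonds), 3L)

  skip_if_not_installed("ChemmineR")
  suppressWarnings(suppressMessages({
    sdfset <- ChemmineR::read.SDFset(path)
    ab <- ChemmineR::atomblock(sdfset[[1]])
    bb <- ChemmineR::bondblock(sdfset[[1]])
  }))
  expect_equal(heavyAtomCount(m),
               sum(!grepl("^H_", rownames(ab))))
  expect_equal(nrow(bb), 4L)  # raw record: includes the N-H bond
})

test_that("malformed SDF records name the failing record", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("bad", "", "", "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0 C", "$$$$"), path)
  expect_error(readMolecules(path), "record 1")
})
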