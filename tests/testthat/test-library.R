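test_that("duplicate SMILES spellings collapse to one canonical key", {
  lib <- canonicalizeAndIndex(data.frame(
    id = c("tol1", "tol2"), smiles = c("Cc1ccccc1", "c1ccccc1C")))
  expect_equal(nrow(libraryRecords(lib)), 1)
})

test_that("canonical key is invariant under atom-order permutation", {
  spellings <- list(
    c("Oc1ccccc1", "c1ccc(O)cc1", "c1(O)ccccc1"),
    c("CCCCc1ccccc1", "c1ccccc1CCCC"))
  for (sp in spellings) {
    lib <- canonicalizeAndIndex(data.frame(id = seq_along(sp), smiles = sp))
    expect_equal(nrow(libraryRecords(lib)), 1)
  }
})

test_that("molecular weight is computed from the anhydrous formula", {
  expect_equal(fibscreen:::.formulaWeight("C17H14N2O5S"), 358.4,
               tolerance = 0.001)
  expect_equal(fibscreen:::.formulaWeight("H2O"), 18.015, tolerance = 1e-3)
  expect_error(fibscreen:::.formulaWeight("C2Xx3"), "unknown element")
})

test_that("rotatable bond count matches exhaustive manual classification", {
  # n-butylbenzene: CH3-CH2 excluded (terminal CH3), ring bonds excluded,
  # leaving CH2-CH2, CH2-CH2, CH2-ring = 3
  lib <- canonicalizeAndIndex(data.frame(id = "nbb", smiles = "CCCCc1ccccc1"))
  expect_equal(libraryRecords(lib)$nRotatableBonds, 3)
  # amide C-N is not rotatable: acetanilide has only the N-ring bond
  lib2 <- canonicalizeAndIndex(data.frame(id = "aa", smiles = "CC(=O)Nc1ccccc1"))
  expect_equal(libraryRecords(lib2)$nRotatableBonds, 1)
  # phenol has none
  lib3 <- canonicalizeAndIndex(data.frame(id = "ph", smiles = "Oc1ccccc1"))
  expect_equal(libraryRecords(lib3)$nRotatableBonds, 0)
})

test_that("intersection keeps only shared canonical keys and merges tags", {
  a <- canonicalizeAndIndex(data.frame(
    id = paste0("a", 1:5),
    smiles = c("Cc1ccccc1", "Oc1ccccc1", "CCO", "c1ccncc1", "CCCCO"),
    source = "setA"))
  b <- canonicalizeAndIndex(data.frame(
    id = paste0("b", 1:4),
    smiles = c("c1ccccc1C", "c1ccc(O)cc1", "CC(C)=O", "CCCC"),
    source = "setB"))
  ab <- intersectLibraries(a, b)
  expect_equal(nrow(libraryRecords(ab)), 2)  # toluene + phenol, hand-checked
  expect_true(all(libraryRecords(ab)$key %in% libraryRecords(b)$key))
  expect_true(all(grepl("setB", libraryRecords(ab)$sourceTags)))
  # commutative on keys
  ba <- intersectLibraries(b, a)
  expect_setequal(libraryRecords(ab)$key, libraryRecords(ba)$key)
  # disjoint -> empty
  d <- canonicalizeAndIndex(data.frame(id = "d", smiles = "CCCCCC"))
  expect_equal(nrow(libraryRecords(intersectLibraries(a, d))), 0)
})

test_that("unparsable entries go to the rejects report, not errors", {
  lib <- canonicalizeAndIndex(data.frame(
    id = c("good", "bad"), smiles = c("CCO", "xx((")))
  expect_equal(nrow(libraryRecords(lib)), 1)
  expect_equal(libraryRejects(lib)$id, "bad")
})

test_that("flat filter matches a hand-classified 10-compound set", {
  smi <- c(
    phenol = "Oc1ccccc1",          # phenol, 0 rot     strict yes, broad no
    cresol = "Cc1ccc(O)cc1",       # phenol, 0 rot     strict yes
    hexyl_phenol = "CCCCCCc1ccc(O)cc1",  # phenol, 5 rot  strict no
    cyclohexane = "C1CCCCC1",      # no ring           both no
    naphthalene = "c1ccc2ccccc2c1",  # 2 rings          broad yes
    biphenyl = "c1ccccc1-c1ccccc1",  # 2 rings          broad yes
    nitrobenzene = "O=[N+]([O-])c1ccccc1",  # 1 ring + planar  broad yes
    toluene = "Cc1ccccc1",         # 1 ring, no group  broad no
    benzoic = "OC(=O)c1ccccc1",    # 1 ring + carboxyl broad yes
    hexane = "CCCCCC")             # nothing           both no
  lib <- canonicalizeAndIndex(data.frame(id = names(smi), smiles = smi))
  strict <- libraryRecords(flatFilter(lib, "strict"))$id
  broad <- libraryRecords(flatFilter(lib, "broad"))$id
  expect_setequal(strict, c("phenol", "cresol"))
  expect_setequal(broad, c("naphthalene", "biphenyl", "nitrobenzene",
                           "benzoic"))
  # idempotent subset
  again <- libraryRecords(flatFilter(flatFilter(lib, "broad"), "broad"))$id
  expect_equal(again, broad)
  expect_true(all(broad %in% libraryRecords(lib)$id))
  expect_error(flatFilter(lib, "bogus"), "unknown mode")
})

test_that("probe ligand construction honours separation and planarity", {
  pr <- fix_probe()
  a <- ligandAtoms(pr)
  acc <- atom_xyz(a[a$acceptor, ])
  expect_equal(sqrt(sum((acc[1, ] - acc[2, ])^2)), 9.6, tolerance = 0.1)
  expect_lt(pr@planarityDeviation, 0.1)
  expect_equal(sum(a$acceptor), 2)
  expect_true(all(a$charge[a$acceptor] < 0))
  # incompatible separations error
  expect_error(makeProbeLigand(30, 10), "geometry error")
  expect_error(makeProbeLigand(1.0, 10), "geometry error")
  expect_error(makeProbeLigand(9.6, 7), "nRingAtoms")
})
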