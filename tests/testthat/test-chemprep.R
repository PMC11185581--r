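# Compound preparation: filtering, standardization, protonation, keying,
# deduplication.

test_that("drug-likeness filter applies rules in order with named reasons", {
  out <- passesDruglikeFilter(c("CCO", "[Na+].[Cl-]", "badsmiles"))
  expect_equal(out$accept, c(TRUE, FALSE, FALSE))
  expect_equal(out$reason, c(NA, "no_carbon", "parse_error"))

  # glucose: accepted, molecular weight from standard atomic masses
  glc <- passesDruglikeFilter("OCC1OC(O)C(O)C(O)C1O")
  expect_true(glc$accept)
  expect_equal(obProperties("OCC1OC(O)C(O)C(O)C1O")$MW, 180.16,
               tolerance = 1e-3)

  # a multi-fault input (disconnected, metal-only, carbon-free) reports the
  # first rule in specification order
  multi <- passesDruglikeFilter("[Na+].[K+]")
  expect_equal(multi$reason, "no_carbon")

  # molecular weight ceiling on an otherwise acceptable molecule
  big <- paste(rep("C", 120L), collapse = "")
  expect_equal(passesDruglikeFilter(big)$reason, "molecular_weight")
  expect_true(passesDruglikeFilter(
    big, filterSpec(maxMolecularWeight = 5000))$accept)

  # salts resolvable to one organic principal fragment are kept
  expect_true(passesDruglikeFilter("CC(=O)[O-].[Na+]")$accept)
})

test_that("standardization canonicalizes, strips stereo and salts, and is idempotent", {
  expect_equal(as.character(standardizeSmiles("C(C)O")),
               as.character(standardizeSmiles("CCO")))
  # stereoisomers collapse to one representation
  expect_equal(as.character(standardizeSmiles("C[C@H](N)C(=O)O")),
               as.character(standardizeSmiles("CC(N)C(=O)O")))
  # salt: principal organic fragment retained and neutralized
  salt <- as.character(standardizeSmiles("CC(=O)[O-].[Na+]"))
  expect_equal(salt, as.character(standardizeSmiles("CC(=O)O")))
  expect_false(grepl(".", salt, fixed = TRUE))
  # isotopes are normalized away
  expect_equal(as.character(standardizeSmiles("[13CH4]")),
               as.character(standardizeSmiles("C")))

  # idempotence: re-standardizing the output returns the identical string
  mols <- c("C(C)O", "c1ccccc1C(=O)[O-].[Na+]", "C[C@@H](O)CC",
            "O=[N+]([O-])c1ccc(Cl)cc1", "CC(C)(C)c1ccc(O)cc1")
  std1 <- as.character(standardizeSmiles(mols))
  std2 <- as.character(standardizeSmiles(std1))
  expect_identical(std1, std2)

  # unparseable input fails with the step recorded
  bad <- standardizeSmiles("notasmiles")
  expect_true(is.na(bad[1]))
  expect_equal(attr(bad, "failedStep")[1], "parse")
})

test_that("pH protonation assigns expected ionization states", {
  # carboxylic acid (pKa ~ 4) deprotonated at pH 7
  expect_equal(obCanonical(as.character(protonateAtPH("CC(=O)O"))),
               obCanonical("CC(=O)[O-]"))
  # phenol (pKa ~ 10) stays neutral at pH 7
  expect_equal(obCanonical(as.character(protonateAtPH("Oc1ccccc1"))),
               obCanonical("Oc1ccccc1"))
  # nothing ionizable: unchanged
  expect_equal(as.character(protonateAtPH("CC")), "CC")
  # the rule table version is recorded
  expect_match(attr(protonateAtPH("CC"), "ruleTable"), "phmodel")
})

test_that("structure keys are 14 characters and stereo-insensitive", {
  expect_equal(hashKey("CCO"), "LFQSCWFLJHTTHZ")
  keys <- hashKey(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O", "CC(N)C(=O)O"))
  expect_equal(length(unique(keys)), 1L)
  expect_true(all(nchar(keys) == 14L))
  expect_true(is.na(hashKey("junk")))
})

test_that("deduplication resolves conflicts toward the active class", {
  recs <- data.frame(
    inchikey_hash = c("A", "B", "A", "C", "C", "C"),
    label = c(0, 1, 1, 0, 0, 0),
    sources = c("s1", "s1", "s2", "s1", "s2", "s3"),
    stringsAsFactors = FALSE
  )
  out <- dedupResolve(recs)
  expect_equal(out$inchikey_hash, c("A", "B", "C"))  # first-occurrence order
  expect_equal(out$label[out$inchikey_hash == "A"], 1)   # conflict -> active
  expect_equal(out$label[out$inchikey_hash == "C"], 0)   # no conflict
  expect_true(out$conflict[out$inchikey_hash == "A"])
  expect_equal(out$sources[out$inchikey_hash == "C"], "s1;s2;s3")

  # no duplicates: identity
  uni <- recs[1:2, ]
  expect_equal(dedupResolve(uni)$label, uni$label)

  # continuous conflicts resolve to the median, flagged
  cont <- data.frame(inchikey_hash = c("X", "X", "X"), label = c(1, 5, 2))
  expect_message(out2 <- dedupResolve(cont, task = "regression"), "median")
  expect_equal(out2$label, 2)
})

test_that("preparation conserves every input with a partitioned status", {
  smis <- c("CCO", "C(C)O", "[Na+].[Cl-]", "nonsense", "c1ccccc1",
            "CC(=O)[O-].[Na+]")
  prep <- prepareCompounds(smis)
  expect_equal(nrow(prep), length(smis))
  ok <- startsWith(prep$status, "ok")
  rejected <- startsWith(prep$status, "rejected")
  quarantined <- startsWith(prep$status, "quarantined")
  expect_equal(sum(ok) + sum(rejected) + sum(quarantined), length(smis))
  # keys exist exactly for accepted records
  expect_true(all(!is.na(prep$inchikey_hash[ok])))
  expect_true(all(is.na(prep$inchikey_hash[!ok])))
  # duplicate chemistry maps to one key
  expect_equal(prep$inchikey_hash[1], prep$inchikey_hash[2])
})

test_that("compound CSV round trip preserves records", {
  prep <- prepareCompounds(c("CCO", "CCN"))
  path <- tempfile(fileext = ".csv")
  writeCompoundCsv(prep, path)
  back <- readCompoundCsv(path)
  expect_equal(back$inchikey_hash, prep$inchikey_hash)
  expect_error(readCompoundCsv({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), p, row.names = FALSE)
    p
  }), "smiles")
})
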