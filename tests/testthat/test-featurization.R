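# Fingerprints, descriptors, physicochemical parameters, variance selection.

test_that("structural fingerprints have the 2214-bit layout and are deterministic", {
  fp <- computeStructural(c("CCO", "O=[N+]([O-])c1ccc(O)cc1"))
  expect_equal(ncol(fp), 2214L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_equal(sum(startsWith(colnames(fp), "morgan_")), 2048L)
  expect_equal(sum(startsWith(colnames(fp), "maccs_")), 166L)
  fp2 <- computeStructural(c("CCO", "O=[N+]([O-])c1ccc(O)cc1"))
  expect_identical(fp, fp2)
  # identical structures encoded differently give identical vectors
  fp3 <- computeStructural(obCanonical("C(C)O"))
  expect_identical(unname(fp[1, ]), unname(fp3[1, ]))
})

test_that("MACCS block agrees with direct evaluation of the key SMARTS table", {
  smis <- c("C", "CCO", "O=[N+]([O-])c1ccc(O)cc1", "NS(=O)(=O)c1ccccc1")
  fp <- computeStructural(smis)[, 2049:2214, drop = FALSE]
  keys <- maccsKeyTable()
  for (i in seq_along(smis)) {
    fired <- which(fp[i, ] == 1L)
    oracle <- integer(0)
    for (k in seq_len(nrow(keys))) {
      if (is.na(keys$smarts[k])) next
      n <- tryCatch(length(obSmartsAtoms(smis[i], keys$smarts[k])),
                    error = function(e) 0L)
      if (n > keys$mincount[k]) oracle <- c(oracle, keys$id[k])
    }
    expect_setequal(fired, oracle)
  }
})

test_that("descriptor corpus drops undefined columns and reports them", {
  # simple alkanes: all graph descriptors defined
  d <- computeDescriptors(c("CCC", "CCCC", "CCCCC", "CC(C)C"))
  expect_true(all(is.finite(d)))
  # a single-atom molecule leaves distance/shape indices undefined; those
  # columns (and only those) are dropped for the whole corpus
  d2 <- computeDescriptors(c("C", "CCC", "CCCC"))
  expect_true(all(is.finite(d2)))
  expect_true(length(attr(d2, "dropped")) > 0)
  expect_true("balabanJ" %in% attr(d2, "dropped"))
  expect_false(any(attr(d2, "dropped") %in% colnames(d2)))
})

test_that("physicochemical parameters match definitional counts", {
  ph <- computePhyschem(c("CCO", "c1ccccc1", "O=[N+]([O-])c1ccc(O)cc1"))
  expect_equal(colnames(ph)[1:5],
               c("TPSA", "HBondAcceptors", "HBondDonors", "FractionCSP3",
                 "logP"))
  # ethanol: one donor, one acceptor, no rotatable bonds, Ertl TPSA
  expect_equal(unname(ph[1, "HBondDonors"]), 1)
  expect_equal(unname(ph[1, "HBondAcceptors"]), 1)
  expect_equal(unname(ph[1, "RotatableBonds"]), 0)
  expect_equal(unname(ph[1, "TPSA"]), 20.23, tolerance = 1e-6)
  # benzene: one aromatic ring, no heteroatoms, no sp3 carbons
  expect_equal(unname(ph[2, "AromaticRings"]), 1)
  expect_equal(unname(ph[2, "Heteroatoms"]), 0)
  expect_equal(unname(ph[2, "FractionCSP3"]), 0)
  # nitrophenol: charged-atom counts from the zwitterionic nitro group
  expect_equal(unname(ph[3, "PositiveAtoms"]), 1)
  expect_equal(unname(ph[3, "NegativeAtoms"]), 1)
  expect_equal(unname(ph[3, "NOCount"]), 4)   # N + 3 O
  # counts are non-negative integers
  counts <- ph[, c("HBondAcceptors", "HBondDonors", "RotatableBonds",
                   "Rings", "AromaticRings", "Heteroatoms", "NHOHCount",
                   "NOCount")]
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("variance selection equals the brute-force rule and is strict", {
  set.seed(42)
  for (trial in 1:20) {
    n <- sample(20:60, 1)
    structural <- cbind(
      matrix(rbinom(n * 40L, 1L, runif(40, 0, 1)), n, byrow = TRUE),
      matrix(rbinom(n * 166L, 1L, runif(166, 0, 0.6)), n, byrow = TRUE)
    )
    desc <- matrix(rnorm(n * 15L, sd = rep(runif(15, 0, 1), each = n)), n)
    colnames(desc) <- paste0("d", 1:15)
    sel <- fitVarianceSelector(structural, desc, "trial")
    pM <- colMeans(structural[, 1:40, drop = FALSE])
    pK <- colMeans(structural[, 41:206, drop = FALSE])
    expect_identical(unname(sel@masks$morgan),
                     which(pM * (1 - pM) > 0.05))
    expect_identical(unname(sel@masks$maccs),
                     which(pK * (1 - pK) > 0.10))
    expect_identical(unname(sel@masks$descriptors),
                     unname(which(apply(desc, 2, var) > 0.10)))
    # Bernoulli variance never exceeds 0.25
    expect_true(all(pM * (1 - pM) <= 0.25 + 1e-12))
  }
  # a constant column is removed at any positive threshold; a balanced
  # binary column (variance 0.25) survives the 0.05 cutoff
  s <- cbind(rep(0L, 30), rep(c(0L, 1L), 15),
             matrix(rbinom(30 * 166, 1, 0.5), 30))
  d <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("a", "b")))
  sel <- fitVarianceSelector(s, d, "toy")
  expect_false(1L %in% sel@masks$morgan)
  expect_true(2L %in% sel@masks$morgan)
})

test_that("assembled tables have the fixed block layout and reuse masks unchanged", {
  smis <- c("CCO", "c1ccccc1O", "CC(N)Cc1ccccc1", "O=[N+]([O-])c1ccc(Cl)cc1",
            "CCCCCCCC", "NS(=O)(=O)c1ccccc1")
  structural <- computeStructural(smis)
  desc <- computeDescriptors(smis)
  phys <- computePhyschem(smis)
  sel <- fitVarianceSelector(structural, desc, "fitA")
  keys <- hashKey(smis)
  tab <- assembleFeatures(structural, desc, phys, sel, keys)
  expect_s4_class(tab, "FeatureTable")
  expect_equal(names(featureBlocks(tab)),
               c("morgan", "maccs", "descriptors", "physchem"))
  expect_equal(length(featureBlocks(tab)$physchem), 15L)
  expect_false(anyNA(featureMatrix(tab)))
  expect_equal(rowKeys(tab), keys)

  # applying the fitted selector to new compounds never changes mask widths
  smis2 <- c("CCCl", "c1ccncc1")
  tab2 <- assembleFeatures(computeStructural(smis2),
                           computeDescriptors(smis2),
                           computePhyschem(smis2), sel, hashKey(smis2))
  expect_equal(vapply(featureBlocks(tab2), length, 1L),
               vapply(featureBlocks(tab), length, 1L))

  # proxy block appended last when supplied
  proxy <- matrix(runif(length(smis) * 3), ncol = 3,
                  dimnames = list(NULL, paste0("proxy_", 1:3)))
  tab3 <- assembleFeatures(structural, desc, phys, sel, keys, proxy = proxy)
  expect_equal(length(featureBlocks(tab3)$proxy), 3L)
  expect_equal(max(featureBlocks(tab3)$proxy), ncol(featureMatrix(tab3)))
})
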