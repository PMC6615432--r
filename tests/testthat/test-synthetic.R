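test_that("generation is deterministic under a fixed seed", {
  d <- studyDesign(seed = 71)
  c1 <- generateReferenceCollection(d)
  c2 <- generateReferenceCollection(d)
  expect_identical(phenotypeMatrix(c1), phenotypeMatrix(c2))
  expect_identical(taxonomyTable(c1), taxonomyTable(c2))
  s1 <- generateStudy(d, c1)
  s2 <- generateStudy(d, c2)
  expect_identical(abundances(s1$profiles), abundances(s2$profiles))
  expect_identical(s1$truth$auxotrophy_pct, s2$truth$auxotrophy_pct)
})

test_that("heterogeneity controls strain-level phenotype mixing", {
  d0 <- studyDesign(seed = 72, heterogeneity = 0)
  c0 <- generateReferenceCollection(d0)
  tx <- taxonomyTable(c0); ph <- phenotypeMatrix(c0)
  for (s in unique(tx$species)) {
    block <- ph[tx$species == s, , drop = FALSE]
    expect_true(all(apply(block, 2,
                          function(x) length(unique(x)) == 1L)))
  }
  # all-prototroph endpoint: zero auxotrophy everywhere downstream
  d1 <- studyDesign(seed = 73, protoProb = rep(1, 8),
                    groups = c(AN = 2L))
  c1 <- generateReferenceCollection(d1)
  expect_true(all(phenotypeMatrix(c1) == 1L))
  st <- generateStudy(d1, c1)
  sig <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(st$profiles, c1), st$profiles, c1))
  expect_identical(unique(sig$auxotrophy_pct), 0)
  # an omni-prototroph species is guaranteed at positive probabilities
  d2 <- studyDesign(seed = 74, protoProb = rep(0.3, 8))
  c2 <- generateReferenceCollection(d2)
  expect_true(any(rowSums(speciesIndexMatrix(c2) == 1) == 8))
})

test_that("noise-free expectation path reproduces the truth ledger", {
  d <- studyDesign(seed = 75, depth = Inf, concentration = Inf,
                   groups = c(AD = 2L, AE = 2L),
                   effects = list(list(species = "Genus001 species001",
                                       groups = "AE", fold = 3)))
  cc <- generateReferenceCollection(d)
  st <- generateStudy(d, cc)
  # replicates of a group are identical on this path
  ab <- abundances(st$profiles)
  expect_equal(ab[, 1], ab[, 2], tolerance = 1e-15)
  sig <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(st$profiles, cc), st$profiles, cc))
  g <- sampleGroups(st$profiles)
  for (grp in c("AD", "AE")) {
    s1 <- sig[sig$sample_id == names(g)[g == grp][1], ]
    expect_equal(s1$auxotrophy_pct[match(colnames(
      st$truth$auxotrophy_pct), s1$vitamin)],
      unname(st$truth$auxotrophy_pct[grp, ]), tolerance = 1e-9)
  }
  # injected effect: 3x pre-renormalization, hence 3/(1+2*pi0) after
  comp <- st$truth$composition
  pi0 <- comp["Genus001 species001", "AD"]
  expect_equal(comp["Genus001 species001", "AE"] / pi0,
               3 / (1 + 2 * pi0), tolerance = 1e-12)
  expect_error(generateStudy(studyDesign(seed = 1,
    effects = list(list(species = "nope", groups = "AD", fold = 2))),
    cc), "unknown species")
})

test_that("table fixtures encode the printed communities", {
  fx2 <- tableFixture("table2")
  ab2 <- abundances(fx2$profile)[, 1]
  expect_equal(fx2$printed$abundance_pct[which.max(ab2)], 26.3)
  expect_equal(names(which.max(ab2)), "Akkermansia_muciniphila")
  expect_equal(sum(fx2$printed$abundance_pct), 79.7, tolerance = 1e-9)
  fx3 <- tableFixture("table3")
  ab3 <- abundances(fx3$profile)[, 1]
  expect_equal(names(which.max(ab3)), "Bacteroides_thetaiotaomicron")
  expect_equal(fx3$printed$abundance_pct[which.max(ab3)], 25.5)
  # genome totals match the printed Genomes column; the genus-level
  # rows' counts include the table's own same-genus species row, which
  # is shared rather than duplicated (one genome each table)
  expect_equal(length(fx2$collection), sum(fx2$printed$genomes) - 1L)
  expect_equal(length(fx3$collection), sum(fx3$printed$genomes) - 1L)
})
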