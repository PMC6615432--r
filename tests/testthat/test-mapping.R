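test_that("identity thresholds assign ranks as in 16S convention", {
  expect_equal(assignMappingLevel(c(98.5, 96, 90, 80)),
               c("species", "genus", "family", "unmapped"))
  # the species band is open at 98: 95-98 approximates genus rank
  expect_equal(assignMappingLevel(98), "genus")
  expect_equal(assignMappingLevel(95), "genus")
  expect_error(mappingThresholds(95, 98, 90), "strictly decreasing")
  expect_error(assignMappingLevel(150), "identity")
})

test_that("species-level mapping gives equal strain weights", {
  fx <- tableFixture("table2")
  m <- mapPhylotype("Akkermansia muciniphila", 99, fx$collection)
  expect_equal(m$mapping_level, "species")
  expect_length(m$weights, 4)
  expect_equal(unname(m$weights), rep(0.25, 4))
})

test_that("genus weights are hierarchical: equal per species, then genome", {
  tax <- data.frame(
    genome_id = paste0("g", 1:4),
    species = c("Gen spA", "Gen spA", "Gen spA", "Gen spB"),
    genus = "Gen", family = "Fam")
  cc <- ReferenceCollection(tax, matrix(1L, 4, 8))
  m <- mapPhylotype("Gen something", 96, cc)
  expect_equal(m$mapping_level, "genus")
  expect_equal(unname(m$weights[paste0("g", 1:4)]),
               c(1/6, 1/6, 1/6, 1/2))
  # grouped neighborhood structure: {spA: 3, spB: 1}
  expect_equal(as.vector(table(m$neighborhood$species)), c(3L, 1L))
})

test_that("hierarchical genus weights match brute-force enumeration", {
  set.seed(21)
  for (i in 1:25) {
    cc <- randomCollection(nSpecies = sample(3:8, 1),
                           maxGenomes = sample(2:5, 1))
    g <- sample(unique(taxonomyTable(cc)$genus), 1)
    m <- mapPhylotype(g, 96, cc)
    bw <- bruteGenusWeights(cc, g)
    expect_equal(m$weights[names(bw)], bw, tolerance = 1e-15)
    expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  }
})

test_that("weights of every mapped phylotype sum to one", {
  set.seed(22)
  for (i in 1:20) {
    cc <- randomCollection(nSpecies = 6)
    pr <- randomProfile(cc, unmappedFrac = runif(1, 0, 0.3))
    ms <- mapProfiles(pr, cc)
    for (w in mappingWeights(ms)[mappingTable(ms)$mapping_level !=
                                   "unmapped"])
      expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("missing names downgrade one rank; absent names unmap", {
  tax <- data.frame(genome_id = c("g1", "g2"),
                    species = c("Gen spA", "Gen spB"),
                    genus = "Gen", family = "Fam")
  cc <- ReferenceCollection(tax, matrix(1L, 2, 8))
  m <- mapPhylotype("Gen spC", 99, cc)  # species missing, genus known
  expect_equal(m$mapping_level, "genus")
  expect_true(m$downgraded)
  expect_equal(sum(m$weights), 1)
  m2 <- mapPhylotype("Other thing", 99, cc)
  expect_equal(m2$mapping_level, "unmapped")
  expect_length(m2$weights, 0)
  m3 <- mapPhylotype("Gen spA", 85, cc)  # below family floor
  expect_equal(m3$mapping_level, "unmapped")
  pr <- PhyloProfileSet(matrix(c(0.9, 0.1), 2, 1),
    info = data.frame(best_match_name = c("Gen spA", "Gen spC"),
                      identity = 99))
  expect_warning(ms <- mapProfiles(pr, cc), "downgraded")
  expect_true(mappingTable(ms)$downgraded[2])
})

test_that("mapped fraction is additive and threshold-monotone", {
  fx <- tableFixture("table2")
  expect_equal(unname(mappedFraction(mapProfiles(fx$profile,
    fx$collection), fx$profile)), 1, tolerance = 1e-12)
  set.seed(23)
  cc <- randomCollection(nSpecies = 5)
  pr <- randomProfile(cc, unmappedFrac = 0.02)
  expect_equal(unname(mappedFraction(mapProfiles(pr, cc), pr)), 0.98,
               tolerance = 1e-12)
  # single unmapped phylotype at abundance 1
  lone <- PhyloProfileSet(matrix(1, 1, 1),
    info = data.frame(best_match_name = "Unknown", identity = 70))
  expect_equal(unname(mappedFraction(mapProfiles(lone, cc), lone)), 0)
  # raising thresholds can only lower the mapped fraction
  fx3 <- tableFixture("table3")
  thrs <- list(mappingThresholds(98, 95, 90),
               mappingThresholds(98.5, 97, 93),
               mappingThresholds(99.5, 98.5, 97))
  mf <- vapply(thrs, function(th) unname(mappedFraction(
    suppressWarnings(mapProfiles(fx3$profile, fx3$collection, th)),
    fx3$profile)), numeric(1))
  expect_true(all(diff(mf) <= 1e-12))
})
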