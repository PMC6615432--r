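test_that("phenotype indices are weight-averaged genome binaries", {
  fx <- tableFixture("table2")
  ms <- mapProfiles(fx$profile, fx$collection)
  idx <- phenotypeIndex(ms, fx$collection)
  # 1 of 4 A. muciniphila strains encodes de novo B12 synthesis
  expect_equal(idx["Akkermansia_muciniphila", "B12"], 0.25)
  # 4 of 6 F. prausnitzii strains are B2 prototrophs
  expect_equal(idx["Faecalibacterium_prausnitzii", "B2"], 2/3,
               tolerance = 1e-12)
  # convexity endpoint: an all-prototroph neighborhood scores 1
  expect_equal(unname(idx["Parabacteroides_distasonis", ]), rep(1, 8))
  expect_true(all(idx >= 0 & idx <= 1))
})

test_that("phenotype index of an unmapped phylotype is undefined", {
  set.seed(31)
  cc <- randomCollection()
  lone <- PhyloProfileSet(matrix(1, 1, 1),
    info = data.frame(best_match_name = "Unknown", identity = 70))
  ms <- mapProfiles(lone, cc)
  expect_error(phenotypeIndex(ms, cc), "undefined")
  cpm <- communityPhenotypeMatrix(ms, lone, cc)
  expect_equal(nrow(indexMatrix(cpm)), 0L)
})

test_that("community signature sums abundance-weighted indices", {
  # single phylotype, A = 1, p_B12 = 0.25
  tax <- data.frame(genome_id = paste0("g", 1:4), species = "A m",
                    genus = "A", family = "F")
  ph <- matrix(1L, 4, 8, dimnames = list(NULL,
                                         vitamins(VitaminPanel())))
  ph[2:4, "B12"] <- 0L
  cc <- ReferenceCollection(tax, ph)
  pr <- PhyloProfileSet(matrix(1, 1, 1),
    info = data.frame(best_match_name = "A m", identity = 99))
  sig <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(pr, cc), pr, cc))
  expect_equal(sig$cpi_pct[sig$vitamin == "B12"], 25)
  expect_equal(sig$auxotrophy_pct[sig$vitamin == "B12"], 75)
  # two phylotypes, A = (0.6, 0.4), p = (1, 0)
  tax2 <- data.frame(genome_id = c("g1", "g2"),
                     species = c("A a", "B b"), genus = c("A", "B"),
                     family = c("F", "F"))
  ph2 <- matrix(c(1L, 0L), 2, 8, dimnames = list(NULL,
    vitamins(VitaminPanel())))
  cc2 <- ReferenceCollection(tax2, ph2)
  pr2 <- PhyloProfileSet(matrix(c(0.6, 0.4), 2, 1),
    info = data.frame(best_match_name = c("A a", "B b"),
                      identity = 99))
  sig2 <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(pr2, cc2), pr2, cc2))
  expect_equal(sig2$cpi_pct, rep(60, 8))
})

test_that("CPI and auxotrophy conserve the mapped abundance", {
  set.seed(32)
  for (i in 1:20) {
    cc <- randomCollection(nSpecies = sample(3:8, 1))
    pr <- randomProfile(cc, nSamples = 2,
                        unmappedFrac = runif(1, 0, 0.4))
    ms <- mapProfiles(pr, cc)
    sig <- communitySignature(communityPhenotypeMatrix(ms, pr, cc))
    expect_equal(sig$cpi_pct + sig$auxotrophy_pct, sig$mapped_pct,
                 tolerance = 1e-9)
    expect_true(all(sig$cpi_pct >= -1e-12 &
                      sig$cpi_pct <= sig$mapped_pct + 1e-12))
  }
})

test_that("vectorized CPI equals the naive double sum", {
  set.seed(33)
  for (i in 1:10) {
    cc <- randomCollection(nSpecies = sample(4:10, 1),
                           maxGenomes = sample(2:6, 1))
    pr <- randomProfile(cc, unmappedFrac = runif(1, 0, 0.2))
    ms <- mapProfiles(pr, cc)
    sig <- communitySignature(communityPhenotypeMatrix(ms, pr, cc))
    oracle <- naiveCPI(pr, ms, cc)
    expect_equal(sig$cpi_pct[match(names(oracle), sig$vitamin)],
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("splitting a phylotype into equal copies leaves CPI unchanged", {
  set.seed(34)
  cc <- randomCollection(nSpecies = 5)
  pr <- randomProfile(cc)
  sig <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(pr, cc), pr, cc))
  ab <- abundances(pr); info <- phylotypeInfo(pr)
  k <- 3
  ab2 <- rbind(ab[-1, , drop = FALSE],
               matrix(rep(ab[1, ] / k, each = k), k,
                      dimnames = list(paste0("split", 1:k), NULL)))
  info2 <- rbind(info[-1, ], info[rep(1, k), ])
  pr2 <- PhyloProfileSet(ab2, info2)
  sig2 <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(pr2, cc), pr2, cc))
  expect_equal(sig2$cpi_pct, sig$cpi_pct, tolerance = 1e-12)
})

test_that("all-prototroph communities have exactly zero auxotrophy", {
  tax <- data.frame(genome_id = paste0("g", 1:6),
                    species = rep(c("A a", "B b", "C c"), each = 2),
                    genus = rep(c("A", "B", "C"), each = 2),
                    family = "F")
  cc <- ReferenceCollection(tax, matrix(1L, 6, 8))
  pr <- randomProfile(cc)
  sig <- communitySignature(communityPhenotypeMatrix(
    mapProfiles(pr, cc), pr, cc))
  expect_identical(unique(sig$auxotrophy_pct), 0)
})

test_that("group aggregation uses the n-1 standard deviation", {
  sig <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    vitamin = "B1",
                    auxotrophy_pct = c(20, 30, 25, 40))
  groups <- c(s1 = "AD", s2 = "AD", s3 = "AD", s4 = "AE")
  agg <- aggregateGroups(sig, groups)
  ad <- agg[agg$group == "AD", ]
  expect_equal(ad$mean, 25)
  expect_equal(ad$sd, 5)
  expect_equal(ad$n, 3L)
  ae <- agg[agg$group == "AE", ]  # single replicate: SD 0, n flags it
  expect_equal(ae$sd, 0)
  expect_equal(ae$n, 1L)
  expect_warning(aggregateGroups(sig, groups[-4]), "without a group")
})

test_that("estimated auxotrophy converges to truth as depth grows", {
  f <- 0.3
  meanAbsErr <- function(depth) {
    errs <- vapply(1:4, function(s) {
      d <- studyDesign(seed = 400 + s, heterogeneity = 0,
                       groups = c(AN = 6L), depth = depth,
                       concentration = Inf)
      cc <- generateReferenceCollection(d)
      bc <- designBaseComposition(cc, "B1", f, seed = 500 + s)
      st <- generateStudy(d, cc, baseComposition = bc)
      sig <- communitySignature(communityPhenotypeMatrix(
        mapProfiles(st$profiles, cc), st$profiles, cc))
      mean(sig$auxotrophy_pct[sig$vitamin == "B1"]) - 100 * f
    }, numeric(1))
    mean(abs(errs))
  }
  errLow <- meanAbsErr(1e3)
  errHigh <- meanAbsErr(1e6)
  expect_lt(errHigh, errLow)
  expect_lt(errHigh, 0.2)
})
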