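# small profile set with explicit per-sample species abundances
mkProfiles <- function(abundByGroup) {
  mats <- lapply(names(abundByGroup), function(g) abundByGroup[[g]])
  ab <- do.call(cbind, mats)
  labels <- rep(names(abundByGroup),
                vapply(mats, ncol, integer(1)))
  colnames(ab) <- paste0(labels, "_", seq_along(labels))
  PhyloProfileSet(ab,
    info = data.frame(best_match_name = rownames(ab), identity = 99),
    groups = labels)
}

test_that("identical groups give fold change 1 and no significance", {
  set.seed(61)
  m <- matrix(rgamma(4 * 3, 1), 4, 3,
              dimnames = list(paste0("Sp", 1:4)))
  pr <- mkProfiles(list(D = m, E = m))
  cmp <- compareGroups(pr, "D", "E")
  expect_equal(cmp$fold_change, rep(1, 4))
  expect_true(all(cmp$p_value[cmp$tested] >= 0.05))
})

test_that("complete separation at n=3 vs 3 gives exact p = 0.1", {
  xD <- c(0.0010, 0.0020, 0.0015); xE <- c(0.0030, 0.0040, 0.0035)
  mD <- rbind(Spx = xD, Oth = 1 - xD)
  mE <- rbind(Spx = xE, Oth = 1 - xE)
  pr <- mkProfiles(list(D = mD, E = mE))
  cmp <- compareGroups(pr, "D", "E")
  spx <- cmp[cmp$species == "Spx", ]
  expect_equal(spx$fold_change, 0.0035 / 0.0015, tolerance = 1e-6)
  expect_equal(spx$p_value, 0.1)
  expect_false(spx$p_value < 0.04)
})

test_that("p-values are symmetric under exchanging group labels", {
  set.seed(62)
  mD <- matrix(rgamma(5 * 4, 1), 5, 4,
               dimnames = list(paste0("Sp", 1:5)))
  mE <- matrix(rgamma(5 * 4, 1), 5, 4,
               dimnames = list(paste0("Sp", 1:5)))
  pr <- mkProfiles(list(D = mD, E = mE))
  a <- compareGroups(pr, "D", "E")
  b <- compareGroups(pr, "E", "D")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
})

test_that("detection filter flags species below 0.01% untested", {
  mD <- rbind(Rare = c(1e-6, 2e-6), Common = c(0.9, 0.9))
  mE <- rbind(Rare = c(2e-6, 1e-6), Common = c(0.9, 0.9))
  pr <- mkProfiles(list(D = mD, E = mE))
  cmp <- compareGroups(pr, "D", "E")
  expect_false(cmp$tested[cmp$species == "Rare"])
  expect_true(is.na(cmp$p_value[cmp$species == "Rare"]))
  expect_error(compareGroups(mkProfiles(list(D = mD, E = mE)),
                             "D", "missing"), "at least 2 samples")
})

test_that("Welch alternative and BH adjustment are available", {
  set.seed(63)
  mD <- matrix(rgamma(3 * 5, 2), 3, 5,
               dimnames = list(paste0("Sp", 1:3)))
  mE <- matrix(rgamma(3 * 5, 2), 3, 5,
               dimnames = list(paste0("Sp", 1:3)))
  pr <- mkProfiles(list(D = mD, E = mE))
  cmp <- compareGroups(pr, "D", "E", test = "welch", adjust = TRUE)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$p_adj >= cmp$p_value - 1e-12))
})

test_that("an injected 2-fold shift ranks first by p-value", {
  gr <- c(D1 = 5L, D2 = 5L, D3 = 5L, E1 = 5L, E2 = 5L, E3 = 5L)
  rankFirst <- function(seed) {
    d0 <- studyDesign(nSpecies = 10L, seed = seed, groups = gr)
    cc <- generateReferenceCollection(d0)
    s0 <- generateStudy(d0, cc)
    # a detectable, non-dominant target (closest to 3% abundance)
    target <- rownames(s0$truth$composition)[
      which.min(abs(s0$truth$composition[, 1] - 0.03))]
    d1 <- studyDesign(nSpecies = 10L, seed = seed, groups = gr,
      effects = list(list(species = target,
                          groups = c("E1", "E2", "E3"), fold = 2)))
    st <- generateStudy(d1, cc)
    cmp <- compareGroups(st$profiles, groupsD = c("D1", "D2", "D3"),
                         groupsE = c("E1", "E2", "E3"))
    cmp <- cmp[cmp$tested, ]
    cmp$species[which.min(cmp$p_value)] == target
  }
  hits <- sum(vapply(1:20, rankFirst, logical(1)))
  expect_gte(hits, 19)
})
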