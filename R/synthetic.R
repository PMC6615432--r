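# Dirichlet draw via normalized gammas; a single shared RNG path keeps
# generation deterministic under the design seed.
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Construct a synthetic study design
#'
#' Defaults emulate the diet-variation study layout: seven diet/media
#' groups (AD, AN, AE, 4D4N, 4E4N, 7D1N, 7E1N) with five replicates
#' each, communities of 20 species with 1-7 reference genomes per
#' species, per-vitamin prototroph probabilities reflecting typical gut
#' auxotrophy rates (20-30\% for most vitamins, about half for B12), a
#' heavy-tailed Dirichlet base composition, overdispersed replicate
#' noise and multinomial sequencing noise at a depth of 1e5 reads.
#'
#' @param nSpecies number of species in the synthetic collection.
#' @param maxGenomes genomes per species are drawn uniformly from
#'   1..maxGenomes.
#' @param speciesPerGenus species are packed into genera of this size.
#' @param protoProb per-vitamin probability that a species is
#'   prototrophic.
#' @param heterogeneity probability that a multi-genome species carries
#'   mixed (strain-heterogeneous) binaries for a vitamin drawn
#'   prototrophic.
#' @param groups named integer vector of replicate counts.
#' @param depth multinomial sequencing depth (reads per replicate);
#'   \code{Inf} yields the noise-free expectation path.
#' @param alpha Dirichlet concentration of the base composition draw.
#' @param concentration Dirichlet concentration of per-replicate
#'   compositional noise around the group composition; \code{Inf}
#'   disables replicate-level noise so only sequencing noise remains.
#' @param effects list of injected effects, each
#'   \code{list(species=, groups=, fold=)}: the species' expected
#'   abundance is multiplied by \code{fold} in the named groups before
#'   renormalization.
#' @param seed mandatory integer seed.
#' @param panel a \linkS4class{VitaminPanel}.
#' @return A \linkS4class{StudyDesign}.
#' @export
studyDesign <- function(nSpecies = 20L, maxGenomes = 7L,
                        speciesPerGenus = 2L,
                        protoProb = c(B1 = 0.8, B2 = 0.75, B3 = 0.8,
                                      B5 = 0.75, B6 = 0.95, B7 = 0.7,
                                      B9 = 0.8, B12 = 0.5),
                        heterogeneity = 0.1,
                        groups = c(AD = 5L, AN = 5L, AE = 5L,
                                   `4D4N` = 5L, `4E4N` = 5L,
                                   `7D1N` = 5L, `7E1N` = 5L),
                        depth = 1e5, alpha = 0.5,
                        concentration = 500,
                        effects = list(), seed,
                        panel = VitaminPanel()) {
  if (missing(seed)) stop("a seed is mandatory for a study design")
  new("StudyDesign", nSpecies = as.integer(nSpecies),
      maxGenomes = as.integer(maxGenomes),
      speciesPerGenus = as.integer(speciesPerGenus),
      protoProb = if (is.null(names(protoProb))) unname(protoProb)
                  else unname(protoProb[vitamins(panel)]),
      heterogeneity = heterogeneity,
      groups = stats::setNames(as.integer(groups), names(groups)),
      depth = depth, alpha = alpha, concentration = concentration,
      effects = effects, seed = as.integer(seed), panel = panel)
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nSpecies, "species,",
      length(object@groups), "groups x",
      paste(unique(object@groups), collapse = "/"),
      "replicates, depth", object@depth, ", seed", object@seed, "\n")
})

#' Generate a synthetic reference collection
#'
#' Species get 1..maxGenomes genomes; per vitamin a species is drawn
#' prototrophic with the design probability, and with the
#' strain-heterogeneity rate a multi-genome prototrophic species is
#' given mixed binaries (a random proper subset of prototroph genomes,
#' prototrophs-first), yielding fractional downstream indices such as
#' 0.25. When every prototroph probability is positive, at least one
#' omni-prototroph species is guaranteed (the first species is promoted
#' if none arises). Deterministic for a given design seed.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return A \linkS4class{ReferenceCollection}.
#' @export
generateReferenceCollection <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  set.seed(design@seed)
  vits <- vitamins(design@panel)
  nSp <- design@nSpecies
  nGen <- sample.int(design@maxGenomes, nSp, replace = TRUE)
  genus <- paste0("Genus", sprintf("%03d",
    ceiling(seq_len(nSp) / design@speciesPerGenus)))
  species <- paste(genus, paste0("species", sprintf("%03d",
    seq_len(nSp))))
  family <- paste0("Family", sprintf("%03d",
    ceiling(seq_len(nSp) / (design@speciesPerGenus * 3L))))
  # species-level prototrophy draws
  proto <- matrix(stats::rbinom(nSp * length(vits), 1,
                                rep(design@protoProb, each = nSp)),
                  nSp, length(vits), dimnames = list(species, vits))
  if (all(design@protoProb > 0) && !any(rowSums(proto) == length(vits)))
    proto[1, ] <- 1L
  omni <- rowSums(proto) == length(vits)
  firstOmni <- if (any(omni)) which(omni)[1] else 0L
  rows <- lapply(seq_len(nSp), function(s) {
    n <- nGen[s]
    ph <- matrix(rep(proto[s, ], each = n), n, length(vits),
                 dimnames = list(NULL, vits))
    for (v in seq_along(vits)) {
      # strain heterogeneity: a prototroph species may carry a mixed
      # strain set, except at the exact endpoint (probability 1) and
      # for the guaranteed omni-prototroph species
      if (ph[1, v] == 1L && n > 1L && design@protoProb[v] < 1 &&
          s != firstOmni && stats::runif(1) < design@heterogeneity) {
        k <- sample.int(n - 1L, 1L)  # 1..n-1 prototrophs: mixed
        ph[, v] <- as.integer(seq_len(n) <= k)
      }
    }
    list(tax = data.frame(
           genome_id = paste0("g", sprintf("%03d", s), "_",
                              seq_len(n)),
           species = species[s], genus = genus[s], family = family[s],
           stringsAsFactors = FALSE),
         ph = ph)
  })
  ReferenceCollection(do.call(rbind, lapply(rows, `[[`, "tax")),
                      do.call(rbind, lapply(rows, `[[`, "ph")),
                      design@panel)
}

#' Calibrate a base composition to a designed auxotrophy fraction
#'
#' Draws a heavy-tailed composition and rescales the auxotroph and
#' prototroph blocks so the community auxotrophy fraction for one
#' vitamin equals \code{auxFraction} exactly. Requires every species'
#' index for that vitamin to be binary (a heterogeneity-0 collection);
#' with fractional indices no exact two-block calibration exists.
#'
#' @param collection a \linkS4class{ReferenceCollection}.
#' @param vitamin vitamin code to calibrate on.
#' @param auxFraction designed community auxotrophy fraction in (0, 1).
#' @param seed integer seed for the composition draw.
#' @param alpha Dirichlet concentration of the draw.
#' @return named numeric base composition over species (sums to 1),
#'   with attribute \code{truth}: the exact per-vitamin auxotrophy
#'   fractions it implies.
#' @export
designBaseComposition <- function(collection, vitamin, auxFraction,
                                  seed, alpha = 0.5) {
  stopifnot(auxFraction > 0, auxFraction < 1)
  idx <- speciesIndexMatrix(collection)
  if (!vitamin %in% colnames(idx)) stop("unknown vitamin: ", vitamin)
  p <- idx[, vitamin]
  if (!all(p %in% c(0, 1)))
    stop("exact calibration needs binary species indices for ", vitamin)
  if (!any(p == 0) || !any(p == 1))
    stop("calibration needs both auxotrophic and prototrophic species")
  set.seed(as.integer(seed))
  pi0 <- .rdirichlet(rep(alpha, nrow(idx)))
  aux <- p == 0
  pi0[aux] <- pi0[aux] / sum(pi0[aux]) * auxFraction
  pi0[!aux] <- pi0[!aux] / sum(pi0[!aux]) * (1 - auxFraction)
  names(pi0) <- rownames(idx)
  attr(pi0, "truth") <- as.numeric(pi0 %*% (1 - idx))
  pi0
}

#' Species-level phenotype index matrix of a collection
#'
#' Mean binary phenotype over each species' strain genomes (the index a
#' species-level phylotype inherits).
#'
#' @param collection a \linkS4class{ReferenceCollection}.
#' @return numeric matrix species x vitamins.
#' @export
speciesIndexMatrix <- function(collection) {
  tx <- taxonomyTable(collection)
  ph <- phenotypeMatrix(collection)
  m <- rowsum(ph, tx$species) / as.numeric(table(tx$species)[
    sort(unique(tx$species))])
  m[unique(tx$species), , drop = FALSE]
}

#' Generate a synthetic multi-replicate study
#'
#' One community profile per replicate per group. The base composition
#' is drawn once from a Dirichlet (or supplied); injected effects
#' multiply the target species' expected abundance in the stated groups
#' before renormalization; each replicate then draws a composition from
#' a Dirichlet centered on the group composition (skipped when the
#' design concentration is infinite) and multinomial counts at the
#' design depth (skipped when the depth is infinite, the noise-free
#' expectation path). All phylotypes are emitted as exact species
#' matches (identity 99).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param collection the collection generated from the design (or any
#'   collection whose species are to be profiled).
#' @param baseComposition optional composition over the collection's
#'   species (e.g. from \code{\link{designBaseComposition}}).
#' @return list with \code{profiles} (a
#'   \linkS4class{PhyloProfileSet}, one column per replicate, group
#'   labels attached) and \code{truth}: the study ground truth
#'   (per-group compositions, exact per-group per-vitamin auxotrophy
#'   percentages, the species index matrix, the effect ledger and the
#'   seed).
#' @export
generateStudy <- function(design, collection, baseComposition = NULL) {
  stopifnot(is(design, "StudyDesign"), is(collection, "ReferenceCollection"))
  idx <- speciesIndexMatrix(collection)
  speciesNames <- rownames(idx)
  nSp <- length(speciesNames)
  set.seed(design@seed + 1L)
  pi0 <- if (is.null(baseComposition)) {
    stats::setNames(.rdirichlet(rep(design@alpha, nSp)), speciesNames)
  } else {
    if (!setequal(names(baseComposition), speciesNames))
      stop("baseComposition species do not match the collection")
    baseComposition[speciesNames] / sum(baseComposition)
  }
  for (e in design@effects)
    if (!e$species %in% speciesNames)
      stop("effect on unknown species: ", e$species)
  groupComp <- sapply(names(design@groups), function(g) {
    p <- pi0
    for (e in design@effects)
      if (g %in% e$groups) p[e$species] <- p[e$species] * e$fold
    p / sum(p)
  })
  ab <- NULL; labels <- character(0)
  for (g in names(design@groups)) {
    for (r in seq_len(design@groups[[g]])) {
      p <- groupComp[, g]
      if (is.finite(design@concentration))
        p <- .rdirichlet(design@concentration * p)
      a <- if (is.finite(design@depth)) {
        as.numeric(stats::rmultinom(1, size = design@depth, prob = p)) /
          design@depth
      } else p
      ab <- cbind(ab, a)
      labels <- c(labels, g)
    }
  }
  rownames(ab) <- speciesNames
  colnames(ab) <- paste0(labels, "_r", stats::ave(seq_along(labels),
    labels, FUN = seq_along))
  keep <- rowSums(ab) >= 0  # keep all species rows, zeros included
  profiles <- PhyloProfileSet(ab[keep, , drop = FALSE],
    info = data.frame(best_match_name = speciesNames[keep],
                      identity = 99),
    groups = labels)
  truthAux <- t(100 * t(groupComp) %*% (1 - idx))
  truth <- list(
    composition = groupComp,
    auxotrophy_pct = t(truthAux),   # groups x vitamins
    species_index = idx,
    effects = design@effects,
    seed = design@seed)
  list(profiles = profiles, truth = truth)
}
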