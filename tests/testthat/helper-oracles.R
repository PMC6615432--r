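# Shared fixture builders and independent oracles.

# Random reference collection: species packed two per genus, three
# genera per family, random binary phenotypes per genome.
randomCollection <- function(nSpecies = 6, maxGenomes = 4,
                             panel = VitaminPanel()) {
  nGen <- sample.int(maxGenomes, nSpecies, replace = TRUE)
  genus <- paste0("Gen", sprintf("%02d", ceiling(seq_len(nSpecies) / 2)))
  family <- paste0("Fam", sprintf("%02d", ceiling(seq_len(nSpecies) / 6)))
  species <- paste(genus, paste0("sp", sprintf("%02d", seq_len(nSpecies))))
  tax <- do.call(rbind, lapply(seq_len(nSpecies), function(s)
    data.frame(genome_id = paste0("g", s, "_", seq_len(nGen[s])),
               species = species[s], genus = genus[s],
               family = family[s])))
  ph <- matrix(rbinom(nrow(tax) * length(vitamins(panel)), 1, 0.6),
               nrow(tax), length(vitamins(panel)))
  ReferenceCollection(tax, ph, panel)
}

# Random profile over a collection: species-level phylotypes at the
# given identities (99 = species hit); optionally an extra unmapped
# phylotype carrying `unmappedFrac` of the community.
randomProfile <- function(collection, nSamples = 1,
                          unmappedFrac = 0) {
  sp <- unique(taxonomyTable(collection)$species)
  ab <- matrix(rgamma(length(sp) * nSamples, 1), length(sp), nSamples)
  ab <- sweep(ab, 2, colSums(ab), "/") * (1 - unmappedFrac)
  info <- data.frame(best_match_name = sp, identity = 99)
  if (unmappedFrac > 0) {
    ab <- rbind(ab, unmappedFrac)
    info <- rbind(info, data.frame(best_match_name = "Unknown taxon",
                                   identity = 80))
  }
  rownames(ab) <- paste0("pt", seq_len(nrow(ab)))
  PhyloProfileSet(ab, info)
}

# Naive CPI oracle: explicit double sum over phylotypes and genomes,
# scalar loops only (independent of the vectorized implementation).
naiveCPI <- function(profiles, mapping, collection, sample = 1) {
  ab <- abundances(profiles)[, sample]
  tb <- mappingTable(mapping)
  w <- mappingWeights(mapping)
  ph <- phenotypeMatrix(collection)
  vits <- vitamins(vitaminPanel(collection))
  cpi <- setNames(numeric(length(vits)), vits)
  for (v in vits) {
    total <- 0
    for (i in seq_len(nrow(tb))) {
      if (tb$mapping_level[i] == "unmapped") next
      wi <- w[[i]]
      inner <- 0
      for (m in names(wi)) inner <- inner + wi[[m]] * ph[m, v]
      total <- total + ab[[tb$phylotype_id[i]]] * inner
    }
    cpi[v] <- 100 * total
  }
  cpi
}

# Brute-force hierarchical genus weights: each species s of the genus
# contributes weight (1/S) split equally over its n_s genomes.
bruteGenusWeights <- function(collection, genusName) {
  tx <- taxonomyTable(collection)
  tx <- tx[tx$genus == genusName, ]
  S <- length(unique(tx$species))
  w <- numeric(0)
  for (s in unique(tx$species)) {
    g <- tx$genome_id[tx$species == s]
    w <- c(w, setNames(rep(1 / S / length(g), length(g)), g))
  }
  w
}
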