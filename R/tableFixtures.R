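# Expansion of the printed 20-species index tables into per-genome
# binary reference collections plus the matching community profile.
#
# Printed fractional indices determine per-genome binary assignments:
# for a species-level row with n genomes and index p, k = round(p*n)
# genomes are prototrophic, listed prototrophs-first (any ordering
# yields the same species mean, which is all downstream math uses).
# Genus- and family-level rows are expanded into hierarchical genus /
# family structures whose equal-per-child weighting reproduces every
# printed cell after 2-decimal rounding; two genus rows (Blautia
# faecis, Pseudoflavonifractor phocaeensis) admit no flat expansion
# (e.g. no k/23 rounds to 0.75), so their genera are built from a small
# species partition, including the table's own same-genus species-level
# rows, with per-vitamin prototroph counts found by exact enumeration.

.flatOK <- function(p, n) all(round(round(p * n) / n, 2) == p)

# First (lexicographically smallest) per-species prototroph counts k
# with mean((fixed, k/sizes)) rounding to the target at 2 decimals.
.searchCounts <- function(target, fixed, sizes) {
  S <- length(fixed) + length(sizes)
  grid <- expand.grid(lapply(sizes, function(n) 0:n))
  for (r in seq_len(nrow(grid))) {
    k <- as.numeric(grid[r, ])
    if (round((sum(fixed) + sum(k / sizes)) / S, 2) == target)
      return(k)
  }
  stop("no genus structure reproduces printed index ", target)
}

# species partitions (genome counts of synthetic member species) for
# genus rows that cannot be expanded flat; the remaining genomes of the
# printed total are covered by the table's own same-genus species rows
.genusPartitions <- list(
  "Blautia faecis" = c(8, 7, 7),
  "Pseudoflavonifractor phocaeensis" = c(2))

.binaryBlock <- function(n, k, vits) {
  m <- vapply(k, function(kv) as.integer(seq_len(n) <= kv),
              integer(n))
  if (is.null(dim(m))) m <- matrix(m, nrow = n)
  colnames(m) <- vits
  m
}

#' Printed worked-example fixtures
#'
#' Builds the reference collection and community profile encoding the
#' two printed 20-species worked examples: the humanized gnotobiotic
#' mouse community (\code{"table2"}) and the anaerobic fecal subculture
#' community (\code{"table3"}). Genome counts and fractional indices
#' are expanded deterministically into binary per-genome phenotypes
#' (prototrophs-first); the profile carries the printed abundances
#' renormalized to sum to 1, with identities placing each phylotype at
#' its printed mapping level (99/96/92 for S/G/F). Running the fixture
#' through mapping and phenotype indexing reproduces the printed index
#' matrix cell-for-cell after 2-decimal rounding.
#'
#' @param name \code{"table2"} or \code{"table3"}.
#' @return list with \code{collection}
#'   (\linkS4class{ReferenceCollection}), \code{profile}
#'   (\linkS4class{PhyloProfileSet}, single sample) and \code{printed}
#'   (the printed table as a data.frame).
#' @export
tableFixture <- function(name = c("table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_printed.tsv"),
                      package = "phenosig", mustWork = TRUE)
  printed <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  panel <- VitaminPanel()
  vits <- vitamins(panel)
  pm <- as.matrix(printed[, vits])
  tok <- .genusToken(printed$species)
  tax <- list(); phen <- list()
  add <- function(tx, ph) {
    tax[[length(tax) + 1L]] <<- tx
    phen[[length(phen) + 1L]] <<- ph
  }
  for (i in seq_len(nrow(printed))) {
    sp <- printed$species[i]; lev <- printed$level[i]
    n <- printed$genomes[i]; p <- pm[i, ]
    fam <- paste0("fam_", tok[i])
    gid <- function(j) paste0(gsub("[^A-Za-z0-9]", "", sp), "_g", j)
    if (lev == "S") {
      k <- round(p * n)
      stopifnot(.flatOK(p, n))
      add(data.frame(genome_id = gid(seq_len(n)), species = sp,
                     genus = tok[i], family = fam),
          .binaryBlock(n, k, vits))
    } else if (lev == "G") {
      fixedRows <- which(printed$level == "S" & tok == tok[i])
      if (length(fixedRows) == 0L && .flatOK(p, n)) {
        # flat genus: n member species of one genome each
        for (j in seq_len(n)) {
          kj <- as.integer(j <= round(p * n))
          add(data.frame(genome_id = paste0(gid(j)),
                         species = paste0(tok[i], " sp",
                                          sprintf("%03d", j)),
                         genus = tok[i], family = fam),
              matrix(as.integer(j <= round(p * n)), 1,
                     length(vits), dimnames = list(NULL, vits)))
        }
      } else {
        sizes <- .genusPartitions[[sp]]
        if (is.null(sizes))
          stop("no expansion rule for genus row ", sp)
        stopifnot(sum(printed$genomes[fixedRows]) + sum(sizes) == n)
        fixedIdx <- pm[fixedRows, , drop = FALSE]
        for (v in seq_along(vits)) {
          k <- .searchCounts(p[v], fixedIdx[, v], sizes)
          for (s in seq_along(sizes)) {
            key <- paste0(sp, "_syn", s)
            if (is.null(phen[[key]])) {
              tax[[key]] <- data.frame(
                genome_id = paste0(gid(paste0(s, "_",
                                              seq_len(sizes[s])))),
                species = paste0(tok[i], " sp", sprintf("%03d", s)),
                genus = tok[i], family = fam)
              phen[[key]] <- matrix(0L, sizes[s], length(vits),
                                    dimnames = list(NULL, vits))
            }
            phen[[key]][, v] <- as.integer(seq_len(sizes[s]) <= k[s])
          }
        }
      }
    } else if (lev == "F") {
      k <- round(p * n)
      stopifnot(.flatOK(p, n))
      nbrGenus <- c(tok[i], paste0(tok[i], "Nbr",
                                   sprintf("%04d", seq_len(n - 1))))
      nbrSpecies <- c(sp, paste0(nbrGenus[-1], " sp"))
      add(data.frame(genome_id = gid(seq_len(n)),
                     species = nbrSpecies, genus = nbrGenus,
                     family = fam),
          .binaryBlock(n, k, vits))
    } else stop("unknown mapping level: ", lev)
  }
  taxonomy <- do.call(rbind, tax)
  rownames(taxonomy) <- NULL
  collection <- ReferenceCollection(taxonomy, do.call(rbind, phen),
                                    panel)
  idents <- c(S = 99, G = 96, F = 92)[printed$level]
  ab <- matrix(printed$abundance_pct, ncol = 1,
               dimnames = list(gsub("[^A-Za-z0-9]", "_",
                                    printed$species),
                               paste0(name, "_community")))
  profile <- PhyloProfileSet(ab,
    info = data.frame(best_match_name = printed$species,
                      identity = unname(idents)))
  list(collection = collection, profile = profile, printed = printed)
}
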