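#' @describeIn VitaminPanel-class vitamin codes.
#' @export
setMethod("vitamins", "VitaminPanel", function(x) x@vitamins)

#' @describeIn VitaminPanel-class cofactor display labels, named by
#'   vitamin.
#' @export
setMethod("cofactorLabels", "VitaminPanel",
          function(x) stats::setNames(x@cofactors, x@vitamins))

setMethod("show", "VitaminPanel", function(object) {
  cat("VitaminPanel of", length(object@vitamins), "vitamins:",
      paste(object@vitamins, collapse = ", "), "\n")
})

#' @describeIn ReferenceCollection-class genome identifiers.
#' @export
setMethod("genomeIds", "ReferenceCollection",
          function(x) x@taxonomy$genome_id)

#' @describeIn ReferenceCollection-class taxonomy data.frame
#'   (genome_id, species, genus, family).
#' @export
setMethod("taxonomyTable", "ReferenceCollection", function(x) x@taxonomy)

#' @describeIn ReferenceCollection-class the binary genome x vitamin
#'   phenotype matrix (the BPM).
#' @export
setMethod("phenotypeMatrix", "ReferenceCollection",
          function(x) x@phenotypes)

#' @describeIn ReferenceCollection-class the vitamin panel.
#' @export
setMethod("vitaminPanel", "ReferenceCollection", function(x) x@panel)

#' @describeIn ReferenceCollection-class number of genomes.
#' @export
setMethod("length", "ReferenceCollection", function(x) nrow(x@taxonomy))

setMethod("show", "ReferenceCollection", function(object) {
  tx <- object@taxonomy
  cat("ReferenceCollection:", nrow(tx), "genomes,",
      length(unique(.normName(tx$species))), "species,",
      length(unique(.normName(tx$genus))), "genera,",
      length(unique(.normName(tx$family))), "families\n")
  cat("  panel:", paste(object@panel@vitamins, collapse = ", "), "\n")
})

#' Read a reference collection (BPM) from TSV
#'
#' Expects a tab-separated file with header
#' \code{genome_id species genus family <one column per vitamin>} and
#' strictly binary phenotype cells. Malformed cells and duplicated
#' genome ids are rejected with the offending row/column named;
#' taxonomic inconsistencies (a species under two genera) are rejected
#' by the class validity check.
#'
#' @param path TSV file path.
#' @param panel a \linkS4class{VitaminPanel}; its vitamins must all be
#'   present as columns.
#' @return A \linkS4class{ReferenceCollection}.
#' @export
readReferenceCollection <- function(path, panel = VitaminPanel()) {
  if (!file.exists(path))
    stop("reference collection file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = "character")
  need <- c("genome_id", "species", "genus", "family", panel@vitamins)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("reference collection is missing columns: ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("reference collection file has a header only; ",
            "returning an empty collection")
    return(ReferenceCollection(
      taxonomy = data.frame(genome_id = character(0),
                            species = character(0),
                            genus = character(0),
                            family = character(0)),
      phenotypes = matrix(integer(0), 0, length(panel@vitamins),
                          dimnames = list(NULL, panel@vitamins)),
      panel = panel))
  }
  ph <- as.matrix(df[, panel@vitamins, drop = FALSE])
  bad <- which(matrix(!(ph %in% c("0", "1")), nrow(ph)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "malformed phenotype cell at row %d, column %s: '%s' (must be 0 or 1)",
      bad[1, 1], panel@vitamins[bad[1, 2]], ph[bad[1, , drop = FALSE]]))
  }
  storage.mode(ph) <- "integer"
  dup <- duplicated(df$genome_id)
  if (any(dup))
    stop("duplicate genome_id: ",
         paste(unique(df$genome_id[dup]), collapse = ", "))
  ReferenceCollection(df[, c("genome_id", "species", "genus", "family")],
                      ph, panel)
}

#' Write a reference collection to TSV
#'
#' Inverse of \code{\link{readReferenceCollection}}: the round trip
#' reproduces cell-identical content (modulo row order).
#'
#' @param x a \linkS4class{ReferenceCollection}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceCollection <- function(x, path) {
  df <- cbind(x@taxonomy, as.data.frame(x@phenotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validation report for a reference collection
#'
#' Report-only summary: genome counts per species, genus and family,
#' per-vitamin prototroph/auxotroph counts, and any taxonomy
#' inconsistencies detected (a collection constructed through the class
#' validity check has none; the report re-derives them for collections
#' assembled by hand).
#'
#' @param x a \linkS4class{ReferenceCollection}.
#' @return A list with elements \code{genomes_per_species},
#'   \code{genomes_per_genus}, \code{genomes_per_family},
#'   \code{prototroph_counts} (data.frame: vitamin, prototrophs,
#'   auxotrophs, genomes) and \code{inconsistencies} (character).
#' @export
validateCollection <- function(x) {
  stopifnot(is(x, "ReferenceCollection"))
  tx <- x@taxonomy
  ph <- x@phenotypes
  counts <- data.frame(
    vitamin = x@panel@vitamins,
    prototrophs = if (nrow(ph)) as.integer(colSums(ph)) else 0L,
    auxotrophs = if (nrow(ph)) as.integer(nrow(ph) - colSums(ph)) else 0L,
    genomes = nrow(ph))
  inc <- character(0)
  if (nrow(tx)) {
    sp2g <- tapply(tx$genus, tx$species, function(g) length(unique(g)))
    inc <- c(inc, paste0("species '", names(sp2g)[sp2g > 1],
                         "' assigned to multiple genera")[sp2g > 1])
    g2f <- tapply(tx$family, tx$genus, function(f) length(unique(f)))
    inc <- c(inc, paste0("genus '", names(g2f)[g2f > 1],
                         "' assigned to multiple families")[g2f > 1])
  }
  list(
    genomes_per_species = if (nrow(tx)) table(tx$species) else table(character(0)),
    genomes_per_genus = if (nrow(tx)) table(tx$genus) else table(character(0)),
    genomes_per_family = if (nrow(tx)) table(tx$family) else table(character(0)),
    prototroph_counts = counts,
    inconsistencies = inc)
}

#' @describeIn neighborhood genomes reachable from \code{name} at
#'   \code{rank}, with their full taxonomy for hierarchical grouping.
#' @export
setMethod("neighborhood", "ReferenceCollection",
function(x, name, rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  tx <- x@taxonomy
  hit <- .normName(tx[[rank]]) == .normName(name)
  if (!any(hit))
    stop("no '", name, "' at rank '", rank, "' in the collection")
  tx[hit, , drop = FALSE]
})

#' Hierarchical equal weights over a phylogenetic neighborhood
#'
#' Computes per-genome weights for phenotype averaging at a given rank:
#' at species rank every strain genome of the species gets equal weight;
#' at genus rank each species within the genus gets equal weight, split
#' equally among its genomes; at family rank each genus gets equal
#' weight, then each species within the genus, then each genome.
#' Weights always sum to 1.
#'
#' @param nbhd a taxonomy data.frame as returned by
#'   \code{\link{neighborhood}}.
#' @param rank the rank the neighborhood was drawn at.
#' @return named numeric vector of weights over \code{genome_id}.
#' @export
hierarchicalWeights <- function(nbhd,
                                rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  n <- nrow(nbhd)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  sp <- .normName(nbhd$species)
  gn <- .normName(nbhd$genus)
  if (rank == "species") {
    w <- rep(1 / n, n)
  } else if (rank == "genus") {
    nSp <- length(unique(sp))
    perSp <- table(sp)
    w <- 1 / nSp / as.numeric(perSp[sp])
  } else {
    nGn <- length(unique(gn))
    spPerGn <- tapply(sp, gn, function(s) length(unique(s)))
    genomesPerSp <- table(sp)
    w <- 1 / nGn / as.numeric(spPerGn[gn]) / as.numeric(genomesPerSp[sp])
  }
  stats::setNames(w, nbhd$genome_id)
}
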