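#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# Internal name normalization used everywhere taxa are matched:
# trim, drop square-bracket conventions ("[Eubacterium] rectale"),
# collapse whitespace, lowercase. Exact match after normalization only.
.normName <- function(x) {
  x <- gsub("\\[|\\]", "", as.character(x))
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

# First token of a binomial (bracket conventions stripped) = genus name guess.
.genusToken <- function(x) {
  x <- gsub("\\[|\\]", "", as.character(x))
  vapply(strsplit(trimws(x), "\\s+"), `[`, character(1), 1L)
}

#' Vitamin panel
#'
#' Ordered set of vitamin codes over which all phenotype matrices are
#' defined, with a display label for the cofactor each vitamin is a
#' biosynthetic precursor of. The default eight-vitamin B panel covers
#' B1 (thiamine/TPP), B2 (riboflavin/FMN-FAD), B3 (niacin/NAD-NADP),
#' B5 (pantothenate/coenzyme A), B6 (pyridoxine/PLP-PMP),
#' B7 (biotin/biotinyl-ACP), B9 (folate/THF-DHF) and
#' B12 (cobalamin/Ado-Cob).
#'
#' @slot vitamins character vector of unique vitamin codes.
#' @slot cofactors character vector of cofactor display labels, parallel
#'   to \code{vitamins}.
#' @export
setClass("VitaminPanel",
  representation(vitamins = "character", cofactors = "character"))

setValidity("VitaminPanel", function(object) {
  msg <- character(0)
  if (length(object@vitamins) == 0L)
    msg <- c(msg, "panel must contain at least one vitamin")
  if (anyDuplicated(object@vitamins))
    msg <- c(msg, "vitamin codes must be unique")
  if (length(object@cofactors) != length(object@vitamins))
    msg <- c(msg, "cofactors must be parallel to vitamins")
  if (length(msg)) msg else TRUE
})

#' Construct a vitamin panel
#'
#' @param vitamins character vector of vitamin codes.
#' @param cofactors character vector of cofactor labels (display only);
#'   recycled to empty strings when not supplied.
#' @return A \linkS4class{VitaminPanel}.
#' @examples
#' VitaminPanel()
#' @export
VitaminPanel <- function(vitamins = c("B1", "B2", "B3", "B5",
                                      "B6", "B7", "B9", "B12"),
                         cofactors = NULL) {
  default <- c(B1 = "TPP", B2 = "FMN/FAD", B3 = "NAD/NADP",
               B5 = "Coenzyme A", B6 = "PLP/PMP", B7 = "Biotinyl-ACP",
               B9 = "THF/DHF", B12 = "(Ado)-Cob")
  if (is.null(cofactors)) {
    cofactors <- unname(default[vitamins])
    cofactors[is.na(cofactors)] <- ""
  }
  new("VitaminPanel", vitamins = as.character(vitamins),
      cofactors = as.character(cofactors))
}

#' Reference collection of genomes with binary phenotypes
#'
#' Holds the Binary Phenotype Matrix (BPM): a set of reference genomes,
#' each with a three-level taxonomy (species, genus, family) and a
#' strictly binary phenotype vector over a vitamin panel (1 = prototrophy,
#' the genome encodes a complete de novo biosynthesis pathway;
#' 0 = auxotrophy, it depends on salvage). Fractional phenotype indices
#' (e.g. 0.25) are never stored here; they arise only downstream as
#' weighted averages over a phylogenetic neighborhood.
#'
#' @slot taxonomy data.frame with columns \code{genome_id}, \code{species},
#'   \code{genus}, \code{family}; one row per genome, \code{genome_id}
#'   unique.
#' @slot phenotypes integer matrix (genomes x vitamins) of 0/1 cells,
#'   rownames = genome ids, colnames = panel vitamins.
#' @slot panel the \linkS4class{VitaminPanel}.
#' @export
setClass("ReferenceCollection",
  representation(taxonomy = "data.frame", phenotypes = "matrix",
                 panel = "VitaminPanel"))

setValidity("ReferenceCollection", function(object) {
  msg <- character(0)
  tx <- object@taxonomy
  need <- c("genome_id", "species", "genus", "family")
  if (!all(need %in% colnames(tx)))
    return(paste("taxonomy must have columns",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(tx$genome_id))
    msg <- c(msg, "duplicate genome_id in collection")
  if (nrow(tx) > 0 &&
      any(!nzchar(tx$species) | !nzchar(tx$genus) | !nzchar(tx$family)))
    msg <- c(msg, "species/genus/family must be nonempty")
  ph <- object@phenotypes
  if (nrow(ph) != nrow(tx))
    msg <- c(msg, "phenotype matrix rows must match taxonomy rows")
  if (!identical(colnames(ph), object@panel@vitamins))
    msg <- c(msg, "phenotype columns must match the vitamin panel")
  if (length(ph) && !all(ph %in% c(0L, 1L)))
    msg <- c(msg, "phenotype cells must be 0 or 1")
  # taxonomy consistency: a species under one genus, a genus under one family
  if (nrow(tx) > 0) {
    sp2g <- tapply(tx$genus, .normName(tx$species),
                   function(g) length(unique(g)))
    if (any(sp2g > 1))
      msg <- c(msg, paste0("species mapped to multiple genera: ",
        paste(names(sp2g)[sp2g > 1], collapse = ", ")))
    g2f <- tapply(tx$family, .normName(tx$genus),
                  function(f) length(unique(f)))
    if (any(g2f > 1))
      msg <- c(msg, paste0("genus mapped to multiple families: ",
        paste(names(g2f)[g2f > 1], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a reference collection
#'
#' @param taxonomy data.frame with columns \code{genome_id},
#'   \code{species}, \code{genus}, \code{family}.
#' @param phenotypes numeric/integer 0-1 matrix, one row per genome in
#'   \code{taxonomy} order, one column per panel vitamin.
#' @param panel a \linkS4class{VitaminPanel}; defaults to the eight
#'   B vitamins.
#' @return A \linkS4class{ReferenceCollection}.
#' @export
ReferenceCollection <- function(taxonomy, phenotypes,
                                panel = VitaminPanel()) {
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  phenotypes <- as.matrix(phenotypes)
  storage.mode(phenotypes) <- "integer"
  rownames(phenotypes) <- taxonomy$genome_id
  colnames(phenotypes) <- panel@vitamins
  rownames(taxonomy) <- NULL
  new("ReferenceCollection", taxonomy = taxonomy,
      phenotypes = phenotypes, panel = panel)
}

#' Community abundance profiles
#'
#' A phylotype x sample relative-abundance container built on
#' \linkS4class{SummarizedExperiment}. The single assay
#' \code{"abundance"} holds fractional relative abundances (each sample
#' column sums to 1); \code{rowData} carries the phylotype annotation
#' used for mapping (\code{best_match_name}: taxon name of the closest
#' reference 16S sequence, and \code{identity}: percent identity of that
#' best match); \code{colData$group} optionally carries the diet/media
#' group code of each sample.
#'
#' @export
setClass("PhyloProfileSet", contains = "SummarizedExperiment")

setValidity("PhyloProfileSet", function(object) {
  msg <- character(0)
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0)) msg <- c(msg, "abundances must be non-negative")
  if (ncol(a) > 0) {
    cs <- colSums(a)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "each sample's abundances must sum to 1 (tol 1e-9)")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("best_match_name", "identity") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry best_match_name and identity")
  else {
    id <- rd$identity
    if (any(!is.na(id) & (id < 0 | id > 100)))
      msg <- c(msg, "identity must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a profile set
#'
#' @param abundance numeric matrix, phylotypes x samples. Values may be
#'   percentages or fractions; each column is renormalized to sum to 1
#'   (percent inputs are thereby converted on load).
#' @param info data.frame with one row per phylotype: columns
#'   \code{best_match_name} and \code{identity} (percent identity of the
#'   best 16S match, 0-100).
#' @param groups optional character vector of group labels, one per
#'   sample (recycled names from \code{colnames(abundance)}).
#' @return A \linkS4class{PhyloProfileSet}.
#' @export
PhyloProfileSet <- function(abundance, info, groups = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("pt", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample", seq_len(ncol(abundance)))
  cs <- colSums(abundance)
  if (any(cs <= 0)) stop("each sample must have positive total abundance")
  abundance <- sweep(abundance, 2, cs, "/")
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  cd <- S4Vectors::DataFrame(row.names = colnames(abundance))
  if (!is.null(groups)) cd$group <- as.character(groups)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = S4Vectors::DataFrame(info, row.names = rownames(abundance)),
    colData = cd)
  new("PhyloProfileSet", se)
}

#' Phylotype-to-reference mapping result
#'
#' One row per phylotype of a profile set, recording the resolved
#' taxonomic mapping level (\code{species}, \code{genus}, \code{family}
#' or \code{unmapped}), the matched reference name at that level, whether
#' the phylotype was downgraded a rank because its name was absent from
#' the collection, and the per-genome weights of its phylogenetic
#' neighborhood (equal within a species; equal per species then per
#' genome at genus rank; equal per genus, per species, per genome at
#' family rank). Weights of every mapped phylotype sum to 1.
#'
#' @slot table data.frame: \code{phylotype_id}, \code{mapping_level},
#'   \code{matched_name}, \code{downgraded}.
#' @slot weights named list, per phylotype, of named numeric weight
#'   vectors over genome ids (empty for unmapped phylotypes).
#' @slot thresholds numeric mapping thresholds used.
#' @export
setClass("MappingSet",
  representation(table = "data.frame", weights = "list",
                 thresholds = "numeric"))

setValidity("MappingSet", function(object) {
  msg <- character(0)
  tb <- object@table
  if (nrow(tb) != length(object@weights))
    msg <- c(msg, "one weight vector per phylotype required")
  mapped <- tb$mapping_level != "unmapped"
  ok <- vapply(seq_along(object@weights), function(i) {
    w <- object@weights[[i]]
    if (!mapped[i]) return(length(w) == 0L)
    length(w) > 0L && all(w >= 0) && abs(sum(w) - 1) <= 1e-12
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "mapped weights must be >= 0 and sum to 1 (tol 1e-12)")
  if (length(msg)) msg else TRUE
})

#' Community phenotype matrix
#'
#' Pairs the per-phylotype phenotype index matrix (rows = mapped
#' phylotypes, columns = vitamins; each cell the weight-averaged
#' probability of prototrophy in [0,1]) with the per-sample abundances of
#' those phylotypes. Phenotype indices are abundance-independent, so one
#' index matrix serves all samples of a study.
#'
#' @slot index numeric matrix, mapped phylotypes x vitamins, cells in
#'   [0,1].
#' @slot abundance numeric matrix, mapped phylotypes x samples
#'   (fractions of the full community, i.e. columns sum to the mapped
#'   fraction of each sample).
#' @slot panel the \linkS4class{VitaminPanel}.
#' @export
setClass("CommunityPhenotypeMatrix",
  representation(index = "matrix", abundance = "matrix",
                 panel = "VitaminPanel"))

setValidity("CommunityPhenotypeMatrix", function(object) {
  msg <- character(0)
  if (length(object@index) &&
      (any(object@index < -1e-12) || any(object@index > 1 + 1e-12)))
    msg <- c(msg, "phenotype indices must lie in [0,1]")
  if (nrow(object@index) != nrow(object@abundance))
    msg <- c(msg, "index and abundance must have matching rows")
  if (!identical(colnames(object@index), object@panel@vitamins))
    msg <- c(msg, "index columns must match the vitamin panel")
  if (length(msg)) msg else TRUE
})

#' Synthetic study design
#'
#' Parameters of a simulated multi-replicate community study: the
#' reference collection to synthesize (species count, genome counts per
#' species, per-vitamin prototroph probabilities, strain-heterogeneity
#' rate), the group structure (named replicate counts, following the
#' diet/media codes AD/AN/AE/4D4N/4E4N/7D1N/7E1N), the sequencing noise
#' model (Dirichlet base composition, per-replicate Dirichlet
#' concentration, multinomial depth) and optional injected abundance
#' effects. The seed is mandatory: all generation is deterministic.
#'
#' @export
setClass("StudyDesign",
  representation(nSpecies = "integer", maxGenomes = "integer",
                 speciesPerGenus = "integer", protoProb = "numeric",
                 heterogeneity = "numeric", groups = "integer",
                 depth = "numeric", alpha = "numeric",
                 concentration = "numeric", effects = "list",
                 seed = "integer", panel = "VitaminPanel"))

setValidity("StudyDesign", function(object) {
  msg <- character(0)
  if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be >= 1")
  if (object@maxGenomes < 1L) msg <- c(msg, "maxGenomes must be >= 1")
  if (any(object@protoProb < 0 | object@protoProb > 1))
    msg <- c(msg, "prototroph probabilities must lie in [0,1]")
  if (length(object@protoProb) != length(object@panel@vitamins))
    msg <- c(msg, "one prototroph probability per panel vitamin required")
  if (object@heterogeneity < 0 || object@heterogeneity > 1)
    msg <- c(msg, "heterogeneity must lie in [0,1]")
  if (length(object@groups) == 0L || any(object@groups < 1L))
    msg <- c(msg, "each group needs at least one replicate")
  if (is.null(names(object@groups)) || any(!nzchar(names(object@groups))))
    msg <- c(msg, "groups must be named")
  if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (object@concentration <= 0)
    msg <- c(msg, "concentration must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a single integer seed is mandatory")
  for (e in object@effects) {
    if (!all(c("species", "groups", "fold") %in% names(e)))
      msg <- c(msg, "each effect needs species, groups and fold")
    else if (e$fold <= 0) msg <- c(msg, "effect fold must be positive")
  }
  if (length(msg)) msg else TRUE
})
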