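#' @rdname VitaminPanel-class
#' @param object,x a phenosig object.
#' @export
setGeneric("vitamins", function(x) standardGeneric("vitamins"))

#' @rdname VitaminPanel-class
#' @export
setGeneric("cofactorLabels", function(x) standardGeneric("cofactorLabels"))

#' @rdname ReferenceCollection-class
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname ReferenceCollection-class
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname ReferenceCollection-class
#' @export
setGeneric("phenotypeMatrix", function(x) standardGeneric("phenotypeMatrix"))

#' @rdname ReferenceCollection-class
#' @export
setGeneric("vitaminPanel", function(x) standardGeneric("vitaminPanel"))

#' Phylogenetic neighborhood of a taxon
#'
#' Returns the reference genomes a phylotype mapped to \code{name} at
#' \code{rank} would be averaged over, as a taxonomy data.frame
#' (grouped hierarchically through its species/genus/family columns).
#'
#' @param x a \linkS4class{ReferenceCollection}.
#' @param name taxon name (matched case-insensitively, bracket
#'   conventions stripped).
#' @param rank one of \code{"species"}, \code{"genus"}, \code{"family"}.
#' @return data.frame with columns \code{genome_id}, \code{species},
#'   \code{genus}, \code{family}.
#' @export
setGeneric("neighborhood",
           function(x, name, rank) standardGeneric("neighborhood"))

#' @rdname PhyloProfileSet-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname PhyloProfileSet-class
#' @export
setGeneric("phylotypeInfo", function(x) standardGeneric("phylotypeInfo"))

#' @rdname PhyloProfileSet-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname MappingSet-class
#' @export
setGeneric("mappingTable", function(x) standardGeneric("mappingTable"))

#' @rdname MappingSet-class
#' @export
setGeneric("mappingWeights", function(x) standardGeneric("mappingWeights"))

#' @rdname CommunityPhenotypeMatrix-class
#' @export
setGeneric("indexMatrix", function(x) standardGeneric("indexMatrix"))

#' @rdname CommunityPhenotypeMatrix-class
#' @export
setGeneric("abundanceMatrix",
           function(x) standardGeneric("abundanceMatrix"))
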