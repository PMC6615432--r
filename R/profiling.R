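#' Per-phylotype phenotype indices
#'
#' For each mapped phylotype, the probability of prototrophy per vitamin
#' is the weight-averaged binary phenotype over its phylogenetic
#' neighborhood: \eqn{p_{i,v} = \sum_m w_{i,m} p_{m,v}}. Each index is a
#' convex combination of genome binaries and therefore lies in [0, 1];
#' a species with 1 of 4 prototrophic strain genomes, for instance, gets
#' index 0.25.
#'
#' @param mapping a \linkS4class{MappingSet}.
#' @param collection the \linkS4class{ReferenceCollection} mapped
#'   against.
#' @return numeric matrix, mapped phylotypes x vitamins. Requesting
#'   indices when no phylotype mapped is an error (the index of an
#'   unmapped phylotype is undefined).
#' @export
phenotypeIndex <- function(mapping, collection) {
  tb <- mappingTable(mapping)
  mapped <- tb$mapping_level != "unmapped"
  if (!any(mapped))
    stop("no mapped phylotypes: phenotype indices are undefined")
  ph <- phenotypeMatrix(collection)
  vits <- vitamins(vitaminPanel(collection))
  w <- mappingWeights(mapping)[mapped]
  idx <- t(vapply(w, function(wi) {
    as.numeric(wi %*% ph[names(wi), , drop = FALSE])
  }, numeric(length(vits))))
  # convex combinations of binaries: clip float round-off at the ends
  idx[idx > 1] <- 1
  idx[idx < 0] <- 0
  dimnames(idx) <- list(tb$phylotype_id[mapped], vits)
  idx
}

#' Community phenotype matrix
#'
#' Joins the phenotype index matrix of the mapped phylotypes with their
#' per-sample relative abundances. Each index cell is the phylotype's
#' relative contribution per unit abundance to the community prototrophy
#' of one vitamin; unmapped phylotypes contribute no row.
#'
#' @param mapping a \linkS4class{MappingSet}.
#' @param profiles the \linkS4class{PhyloProfileSet} the mapping was
#'   computed from (same phylotypes, same order).
#' @param collection the \linkS4class{ReferenceCollection}.
#' @return A \linkS4class{CommunityPhenotypeMatrix}.
#' @export
communityPhenotypeMatrix <- function(mapping, profiles, collection) {
  tb <- mappingTable(mapping)
  if (!identical(tb$phylotype_id, rownames(profiles)))
    stop("mapping and profiles disagree on phylotypes")
  mapped <- tb$mapping_level != "unmapped"
  ab <- abundances(profiles)[mapped, , drop = FALSE]
  idx <- if (any(mapped)) phenotypeIndex(mapping, collection) else
    matrix(numeric(0), 0, length(vitamins(vitaminPanel(collection))),
           dimnames = list(NULL, vitamins(vitaminPanel(collection))))
  new("CommunityPhenotypeMatrix", index = idx, abundance = ab,
      panel = vitaminPanel(collection))
}

#' @describeIn CommunityPhenotypeMatrix-class phenotype index matrix of
#'   the mapped phylotypes.
#' @export
setMethod("indexMatrix", "CommunityPhenotypeMatrix", function(x) x@index)

#' @describeIn CommunityPhenotypeMatrix-class per-sample abundances of
#'   the mapped phylotypes (columns sum to the mapped fraction).
#' @export
setMethod("abundanceMatrix", "CommunityPhenotypeMatrix",
          function(x) x@abundance)

setMethod("show", "CommunityPhenotypeMatrix", function(object) {
  cat("CommunityPhenotypeMatrix:", nrow(object@index),
      "mapped phylotypes x", length(object@panel@vitamins),
      "vitamins,", ncol(object@abundance), "samples\n")
})

#' Per-sample community phenotype signature
#'
#' The Community Phenotype Index per vitamin is the abundance-weighted
#' total of phenotype indices over the mapped phylotypes,
#' \eqn{CPI_v = 100 \sum_i A_i \sum_m w_{i,m} p_{m,v}} (percent of the
#' community estimated prototrophic); the auxotrophy representation is
#' the complementary total over inverse indices,
#' \eqn{100 \sum_i A_i (1 - p_{i,v})}. Both sum to 100 times the mapped
#' fraction. Renormalized columns divide by the mapped fraction so the
#' two conventions (raw community percent vs percent of the mapped
#' sub-community) are both available.
#'
#' @param cpm a \linkS4class{CommunityPhenotypeMatrix}.
#' @return data.frame in long format: \code{sample_id}, \code{vitamin},
#'   \code{cpi_pct}, \code{auxotrophy_pct}, \code{mapped_pct},
#'   \code{cpi_renorm_pct}, \code{auxotrophy_renorm_pct}.
#' @export
communitySignature <- function(cpm) {
  stopifnot(is(cpm, "CommunityPhenotypeMatrix"))
  idx <- indexMatrix(cpm)
  ab <- abundanceMatrix(cpm)
  vits <- vitamins(cpm@panel)
  samples <- colnames(ab)
  # CPI matrix: samples x vitamins = t(ab) %*% idx
  cpi <- if (nrow(idx)) 100 * crossprod(ab, idx) else
    matrix(0, length(samples), length(vits),
           dimnames = list(samples, vits))
  mf <- 100 * colSums(ab)
  aux <- matrix(rep(mf, length(vits)), ncol = length(vits)) - cpi
  out <- data.frame(
    sample_id = rep(samples, times = length(vits)),
    vitamin = rep(vits, each = length(samples)),
    cpi_pct = as.numeric(cpi),
    auxotrophy_pct = as.numeric(aux),
    mapped_pct = rep(mf, times = length(vits)),
    stringsAsFactors = FALSE)
  out$cpi_renorm_pct <- ifelse(out$mapped_pct > 0,
                               100 * out$cpi_pct / out$mapped_pct, NA)
  out$auxotrophy_renorm_pct <- ifelse(out$mapped_pct > 0,
                                      100 * out$auxotrophy_pct /
                                        out$mapped_pct, NA)
  out
}

#' Aggregate signatures over replicate groups
#'
#' Per group and vitamin: arithmetic mean and sample standard deviation
#' (n-1 denominator) of the auxotrophy representation over replicates.
#' Groups with a single replicate report SD 0 and are flagged by
#' \code{n = 1}; samples without a group label are dropped with a
#' warning.
#'
#' @param signature data.frame from \code{\link{communitySignature}}.
#' @param groups named character vector: group label per sample id
#'   (e.g. from \code{\link{sampleGroups}} or
#'   \code{\link{readSampleMetadata}}).
#' @param value which signature column to aggregate.
#' @return data.frame: \code{group}, \code{vitamin}, \code{mean},
#'   \code{sd}, \code{n}.
#' @export
aggregateGroups <- function(signature, groups,
                            value = "auxotrophy_pct") {
  stopifnot(value %in% colnames(signature))
  g <- groups[signature$sample_id]
  if (any(is.na(g))) {
    warning("dropping ",
            length(unique(signature$sample_id[is.na(g)])),
            " sample(s) without a group label")
    signature <- signature[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  if (nrow(signature) == 0L)
    stop("no labeled samples to aggregate")
  key <- interaction(g, signature$vitamin, drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(signature)), key),
    function(i) {
      x <- signature[[value]][i]
      data.frame(group = g[i[1]], vitamin = signature$vitamin[i[1]],
                 mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 n = length(x), stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg
}
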