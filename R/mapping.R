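#' Mapping thresholds
#'
#' Percent-identity cutoffs for rank assignment. Following the
#' conventional 16S interpretation, a best match above the species
#' threshold (strictly greater than 98 by default) is mapped at species
#' rank; identities in the genus band (at least 95) approximate genus
#' rank; the family floor defaults to 90, a conventional family-level
#' 16S cutoff. Below the family floor a phylotype is unmapped and
#' excluded from phenotype prediction.
#'
#' @param species,genus,family percent-identity cutoffs; must be
#'   strictly decreasing.
#' @return named numeric vector of thresholds.
#' @examples
#' mappingThresholds()
#' @export
mappingThresholds <- function(species = 98, genus = 95, family = 90) {
  thr <- c(species = unname(species), genus = unname(genus),
           family = unname(family))
  if (any(is.na(thr)) || any(thr < 0 | thr > 100))
    stop("thresholds must lie in [0, 100]")
  if (!(thr["species"] > thr["genus"] && thr["genus"] > thr["family"]))
    stop("thresholds must be strictly decreasing ",
         "(species > genus > family)")
  thr
}

#' Assign a mapping level from percent identity
#'
#' Identity strictly above the species threshold maps at species rank;
#' at or above the genus threshold at genus rank; at or above the family
#' floor at family rank; anything lower is unmapped.
#'
#' @param identity numeric vector of percent identities in [0, 100].
#' @param thresholds output of \code{\link{mappingThresholds}}.
#' @return character vector: \code{"species"}, \code{"genus"},
#'   \code{"family"} or \code{"unmapped"}.
#' @examples
#' assignMappingLevel(c(98.5, 96, 80))
#' @export
assignMappingLevel <- function(identity, thresholds = mappingThresholds()) {
  thresholds <- mappingThresholds(thresholds["species"],
                                  thresholds["genus"],
                                  thresholds["family"])
  if (any(!is.na(identity) & (identity < 0 | identity > 100)))
    stop("identity must lie in [0, 100]")
  out <- rep("unmapped", length(identity))
  out[!is.na(identity) & identity >= thresholds["family"]] <- "family"
  out[!is.na(identity) & identity >= thresholds["genus"]] <- "genus"
  out[!is.na(identity) & identity > thresholds["species"]] <- "species"
  out
}

# Resolve `name` at `level` against the collection; returns the matched
# reference name (canonical spelling) or NA. At genus rank a binomial
# best-match name is reduced to its genus token; at family rank the
# family is recovered through the species or genus the name belongs to.
.resolveName <- function(name, level, collection) {
  tx <- collection@taxonomy
  if (nrow(tx) == 0L) return(NA_character_)
  nn <- .normName(name)
  if (level == "species") {
    i <- match(nn, .normName(tx$species))
    if (!is.na(i)) return(tx$species[i])
  } else if (level == "genus") {
    i <- match(nn, .normName(tx$genus))
    if (is.na(i)) i <- match(.normName(.genusToken(name)),
                             .normName(tx$genus))
    if (!is.na(i)) return(tx$genus[i])
  } else if (level == "family") {
    i <- match(nn, .normName(tx$family))
    if (is.na(i)) {
      j <- match(nn, .normName(tx$species))
      if (!is.na(j)) i <- j
    }
    if (is.na(i)) {
      j <- match(.normName(.genusToken(name)), .normName(tx$genus))
      if (!is.na(j)) i <- j
    }
    if (!is.na(i)) return(tx$family[i])
  }
  NA_character_
}

#' Map a single phylotype to the reference collection
#'
#' Assigns a rank from the percent identity (or uses a declared rank),
#' resolves the best-match name at that rank and attaches the weighted
#' phylogenetic neighborhood. A name absent from the collection at the
#' assigned rank is downgraded one rank at a time
#' (species to genus to family), with the downgrade flagged; a name
#' absent at every rank is unmapped.
#'
#' @param name best-match taxon name.
#' @param identity percent identity of the best match (may be NA when
#'   \code{declaredRank} is given).
#' @param collection a \linkS4class{ReferenceCollection}.
#' @param thresholds see \code{\link{mappingThresholds}}.
#' @param declaredRank optional explicit rank overriding the identity
#'   rule.
#' @return list with \code{mapping_level}, \code{matched_name},
#'   \code{downgraded}, \code{weights} (named over genome ids; empty if
#'   unmapped) and \code{neighborhood} (taxonomy data.frame).
#' @export
mapPhylotype <- function(name, identity, collection,
                         thresholds = mappingThresholds(),
                         declaredRank = NULL) {
  level <- if (!is.null(declaredRank)) {
    match.arg(declaredRank, c("species", "genus", "family"))
  } else {
    assignMappingLevel(identity, thresholds)
  }
  ranks <- c("species", "genus", "family")
  empty <- list(mapping_level = "unmapped",
                matched_name = NA_character_,
                downgraded = FALSE,
                weights = stats::setNames(numeric(0), character(0)),
                neighborhood = collection@taxonomy[0, , drop = FALSE])
  if (level == "unmapped") return(empty)
  tryRanks <- ranks[seq(match(level, ranks), length(ranks))]
  for (r in tryRanks) {
    matched <- .resolveName(name, r, collection)
    if (!is.na(matched)) {
      nb <- neighborhood(collection, matched, r)
      return(list(mapping_level = r, matched_name = matched,
                  downgraded = (r != level),
                  weights = hierarchicalWeights(nb, r),
                  neighborhood = nb))
    }
  }
  empty
}

#' Map all phylotypes of a profile set
#'
#' One mapping per phylotype; unmapped phylotypes are retained in the
#' result but flagged so downstream phenotype computation excludes
#' them. Downgrades (name missing at the assigned rank) are reported
#' with a warning naming the phylotypes.
#'
#' @param profiles a \linkS4class{PhyloProfileSet}.
#' @param collection a \linkS4class{ReferenceCollection}.
#' @param thresholds see \code{\link{mappingThresholds}}.
#' @return A \linkS4class{MappingSet}.
#' @export
mapProfiles <- function(profiles, collection,
                        thresholds = mappingThresholds()) {
  info <- phylotypeInfo(profiles)
  ids <- rownames(profiles)
  res <- lapply(seq_along(ids), function(i) {
    mapPhylotype(info$best_match_name[i], info$identity[i],
                 collection, thresholds)
  })
  tb <- data.frame(
    phylotype_id = ids,
    mapping_level = vapply(res, `[[`, character(1), "mapping_level"),
    matched_name = vapply(res, `[[`, character(1), "matched_name"),
    downgraded = vapply(res, `[[`, logical(1), "downgraded"),
    stringsAsFactors = FALSE)
  if (any(tb$downgraded))
    warning("mapping level downgraded for: ",
            paste(tb$phylotype_id[tb$downgraded], collapse = ", "))
  new("MappingSet", table = tb,
      weights = stats::setNames(lapply(res, `[[`, "weights"), ids),
      thresholds = thresholds)
}

#' @describeIn MappingSet-class per-phylotype mapping table.
#' @export
setMethod("mappingTable", "MappingSet", function(x) x@table)

#' @describeIn MappingSet-class named list of per-genome weight vectors.
#' @export
setMethod("mappingWeights", "MappingSet", function(x) x@weights)

setMethod("show", "MappingSet", function(object) {
  lv <- table(factor(object@table$mapping_level,
                     levels = c("species", "genus", "family",
                                "unmapped")))
  cat("MappingSet:", nrow(object@table), "phylotypes (",
      paste(names(lv), lv, sep = ":", collapse = " "), ")\n")
})

#' Mapped abundance fraction per sample
#'
#' Total relative abundance covered by phylotypes that mapped at any
#' rank; the complement is excluded from phenotype prediction.
#'
#' @param mapping a \linkS4class{MappingSet}.
#' @param profiles the \linkS4class{PhyloProfileSet} the mapping was
#'   computed from.
#' @return named numeric vector (fractions in [0, 1]) per sample.
#' @export
mappedFraction <- function(mapping, profiles) {
  tb <- mappingTable(mapping)
  if (!identical(tb$phylotype_id, rownames(profiles)))
    stop("mapping and profiles disagree on phylotypes")
  mapped <- tb$mapping_level != "unmapped"
  ab <- abundances(profiles)
  colSums(ab[mapped, , drop = FALSE])
}
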