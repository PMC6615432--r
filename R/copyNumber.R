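#' Read a 16S copy-number table
#'
#' Tab-separated \code{taxon rank mean_copy_number} table of pan-taxa
#' mean 16S rRNA gene copy numbers (rrnDB-style means at species, genus
#' or family rank). The default copy number used when no rank matches a
#' phylotype is the unweighted mean of all table entries, unless
#' overridden.
#'
#' @param path TSV path.
#' @param default optional fallback copy number; defaults to the mean
#'   of all entries.
#' @return data.frame with columns \code{taxon}, \code{rank},
#'   \code{mean_copy_number} and attribute \code{default}.
#' @export
readCopyNumberTable <- function(path, default = NULL) {
  if (!file.exists(path)) stop("copy-number file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  copyNumberTable(df, default = default)
}

#' Construct a copy-number table
#'
#' @param entries data.frame with columns \code{taxon}, \code{rank}
#'   (species/genus/family) and \code{mean_copy_number}.
#' @param default see \code{\link{readCopyNumberTable}}.
#' @return validated copy-number data.frame.
#' @export
copyNumberTable <- function(entries, default = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("taxon", "rank", "mean_copy_number")
  miss <- setdiff(need, colnames(entries))
  if (length(miss))
    stop("copy-number table is missing columns: ",
         paste(miss, collapse = ", "))
  entries$mean_copy_number <- as.numeric(entries$mean_copy_number)
  if (any(!is.finite(entries$mean_copy_number)) ||
      any(entries$mean_copy_number <= 0))
    stop("copy numbers must be positive")
  if (!all(entries$rank %in% c("species", "genus", "family")))
    stop("rank must be species, genus or family")
  if (is.null(default)) default <- mean(entries$mean_copy_number)
  if (!is.finite(default) || default <= 0)
    stop("default copy number must be positive")
  attr(entries, "default") <- default
  entries
}

#' Look up a phylotype's mean 16S copy number
#'
#' Best-match order: a species entry for the taxon name, then a genus
#' entry, then a family entry, then the table-wide default.
#'
#' @param species,genus,family taxon names at the three ranks (any may
#'   be NA).
#' @param table a table from \code{\link{copyNumberTable}}.
#' @return positive copy number (vectorized over the inputs).
#' @export
lookupCopyNumber <- function(species, genus = NA, family = NA, table) {
  n <- max(length(species), length(genus), length(family))
  species <- rep_len(species, n); genus <- rep_len(genus, n)
  family <- rep_len(family, n)
  keyOf <- function(rank) {
    sel <- table$rank == rank
    stats::setNames(table$mean_copy_number[sel],
                    .normName(table$taxon[sel]))
  }
  sp <- keyOf("species"); gn <- keyOf("genus"); fm <- keyOf("family")
  out <- unname(sp[.normName(species)])
  out[is.na(out)] <- unname(gn[.normName(genus)])[is.na(out)]
  out[is.na(out)] <- unname(fm[.normName(family)])[is.na(out)]
  out[is.na(out)] <- attr(table, "default")
  out
}

# Species/genus/family strings for each phylotype row: species = the
# best-match name, genus = its leading token, family = from the
# collection when the phylotype resolves there.
.phylotypeTaxonomy <- function(profiles, collection = NULL) {
  info <- phylotypeInfo(profiles)
  sp <- info$best_match_name
  gn <- .genusToken(sp)
  fm <- rep(NA_character_, length(sp))
  if (!is.null(collection) && nrow(collection@taxonomy)) {
    tx <- collection@taxonomy
    i <- match(.normName(sp), .normName(tx$species))
    fm[!is.na(i)] <- tx$family[i[!is.na(i)]]
    j <- match(.normName(gn), .normName(tx$genus))
    fm[is.na(fm) & !is.na(j)] <- tx$family[j[is.na(fm) & !is.na(j)]]
  }
  data.frame(species = sp, genus = gn, family = fm,
             stringsAsFactors = FALSE)
}

#' Renormalize abundances for 16S gene copy number
#'
#' Divides each phylotype's relative abundance by its mean 16S rRNA
#' gene copy number and rescales every sample to sum to one:
#' \eqn{A'_i = (A_i / c_i) / \sum_j (A_j / c_j)}. With uniform copy
#' numbers the profile is unchanged. This stage is optional and off by
#' default in the pipeline; read-based illustrations are conventionally
#' shown without it.
#'
#' @param profiles a \linkS4class{PhyloProfileSet}.
#' @param table a copy-number table
#'   (\code{\link{readCopyNumberTable}}).
#' @param collection optional \linkS4class{ReferenceCollection} used to
#'   resolve family names for the fallback lookup.
#' @return a renormalized \linkS4class{PhyloProfileSet}.
#' @export
renormalizeProfiles <- function(profiles, table, collection = NULL) {
  txp <- .phylotypeTaxonomy(profiles, collection)
  cn <- lookupCopyNumber(txp$species, txp$genus, txp$family, table)
  if (any(!is.finite(cn)) || any(cn <= 0))
    stop("resolved copy numbers must be positive")
  ab <- abundances(profiles) / cn
  g <- sampleGroups(profiles)
  PhyloProfileSet(ab, info = phylotypeInfo(profiles),
                  groups = if (all(is.na(g))) NULL else unname(g))
}
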