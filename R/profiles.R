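#' @describeIn PhyloProfileSet-class fractional abundance matrix
#'   (phylotypes x samples; columns sum to 1).
#' @export
setMethod("abundances", "PhyloProfileSet",
          function(x) SummarizedExperiment::assay(x, "abundance"))

#' @describeIn PhyloProfileSet-class phylotype annotation data.frame
#'   (best_match_name, identity).
#' @export
setMethod("phylotypeInfo", "PhyloProfileSet", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @describeIn PhyloProfileSet-class sample group labels (NA when no
#'   metadata was attached), named by sample.
#' @export
setMethod("sampleGroups", "PhyloProfileSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  g <- if ("group" %in% colnames(cd)) as.character(cd$group)
       else rep(NA_character_, nrow(cd))
  stats::setNames(g, rownames(cd))
})

setMethod("show", "PhyloProfileSet", function(object) {
  cat("PhyloProfileSet:", nrow(object), "phylotypes x",
      ncol(object), "samples\n")
  g <- sampleGroups(object)
  if (!all(is.na(g)))
    cat("  groups:", paste(names(table(g)), table(g), sep = ":",
                           collapse = " "), "\n")
})

#' Read community profiles from TSV
#'
#' Accepts the wide profile format
#' \code{phylotype_id best_match_name identity_pct <sample_1> ...
#' <sample_n>}. Abundances may be percentages or fractions; each sample
#' column is renormalized to sum to 1 on load. Optional sample metadata
#' (\code{sample_id group}) attaches diet/media group labels.
#'
#' @param path profile TSV path.
#' @param metadata optional path to a \code{sample_id<TAB>group} TSV.
#' @return A \linkS4class{PhyloProfileSet}.
#' @export
readProfiles <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  need <- c("phylotype_id", "best_match_name", "identity_pct")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("profile table is missing columns: ",
         paste(miss, collapse = ", "))
  sampleCols <- setdiff(colnames(df), need)
  if (length(sampleCols) == 0L)
    stop("profile table has no sample columns")
  ab <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(ab) <- df$phylotype_id
  groups <- NULL
  if (!is.null(metadata)) {
    md <- readSampleMetadata(metadata)
    groups <- unname(md[colnames(ab)])
  }
  PhyloProfileSet(ab,
                  info = data.frame(best_match_name = df$best_match_name,
                                    identity = as.numeric(df$identity_pct)),
                  groups = groups)
}

#' Read sample metadata
#'
#' @param path TSV with columns \code{sample_id} and \code{group}
#'   (group codes are free labels; the diet/media study uses
#'   AD, AN, AE, 4D4N, 4E4N, 7D1N, 7E1N).
#' @return named character vector: group by sample id.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(md)))
    stop("metadata must have columns sample_id and group")
  stats::setNames(md$group, md$sample_id)
}

#' Read community profiles from a BIOM file
#'
#' Thin adapter over \pkg{biomformat}: observation metadata fields carry
#' the best-match name and identity of each phylotype.
#'
#' @param path BIOM file path.
#' @param nameField,identityField observation-metadata fields, given
#'   as names or column positions (BIOM JSON round trips may drop
#'   metadata column names, in which case positions 1 and 2 are the
#'   fallback).
#' @param metadata optional sample metadata TSV (see
#'   \code{\link{readSampleMetadata}}).
#' @return A \linkS4class{PhyloProfileSet}.
#' @export
readProfilesBiom <- function(path, nameField = "best_match_name",
                             identityField = "identity",
                             metadata = NULL) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required for BIOM input")
  b <- biomformat::read_biom(path)
  ab <- as(biomformat::biom_data(b), "matrix")
  om <- biomformat::observation_metadata(b)
  pick <- function(field, pos) {
    if (is.numeric(field)) return(om[[field]])
    if (!is.null(om) && field %in% colnames(om)) return(om[[field]])
    if (!is.null(om) && ncol(om) >= pos) return(om[[pos]])
    stop("BIOM observation metadata must carry fields '", nameField,
         "' and '", identityField, "'")
  }
  om <- as.data.frame(om)
  nm <- pick(nameField, 1L)
  idn <- pick(identityField, 2L)
  groups <- NULL
  if (!is.null(metadata)) {
    md <- readSampleMetadata(metadata)
    groups <- unname(md[colnames(ab)])
  }
  PhyloProfileSet(ab,
                  info = data.frame(best_match_name = as.character(nm),
                                    identity = as.numeric(idn)),
                  groups = groups)
}
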