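#' Write community profiles to TSV
#'
#' Wide format readable by \code{\link{readProfiles}}; abundances are
#' emitted as percentages with full precision.
#'
#' @param profiles a \linkS4class{PhyloProfileSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  info <- phylotypeInfo(profiles)
  df <- cbind(data.frame(phylotype_id = rownames(profiles),
                         best_match_name = info$best_match_name,
                         identity_pct = info$identity),
              as.data.frame(100 * abundances(profiles)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @param groups named character vector (group by sample id).
#' @export
writeSampleMetadata <- function(groups, path) {
  utils::write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML with fields: \code{profiles}, \code{bpm}, optional
#' \code{metadata} and \code{copy_number} (input TSV paths);
#' \code{outdir}; optional \code{thresholds}
#' (\code{species}/\code{genus}/\code{family}), \code{classification}
#' (\code{aux}/\code{proto}/\code{multi_min}) and \code{comparison}
#' (\code{groups_d}, \code{groups_e}, \code{min_abundance},
#' \code{test}).
#'
#' @param path YAML file path.
#' @return config list for \code{\link{runPipeline}}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the phylotype-to-phenotype pipeline
#'
#' End to end: read inputs, optional copy-number renormalization,
#' mapping, phenotype profiling, per-sample signatures, group
#' aggregation and (when configured) diet-group comparison. Writes
#' \code{signatures.tsv}, \code{cpm.tsv}, \code{classes.tsv}, and when
#' metadata/comparison are configured \code{group_signatures.tsv} and
#' \code{comparison.tsv}, plus \code{report.json}. Percentages are
#' written with 4 decimals; the pipeline itself is deterministic, so
#' re-running an identical configuration reproduces every output file.
#'
#' @param config list (see \code{\link{readPipelineConfig}}) or a YAML
#'   path.
#' @return the run report (mapped fraction per sample, downgrade and
#'   fallback warnings, config echo), invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  for (f in c("profiles", "bpm"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ",
           if (is.null(config[[f]])) "(unset)" else config[[f]])
  for (f in c("metadata", "copy_number"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  collection <- readReferenceCollection(config$bpm)
  profiles <- readProfiles(config$profiles, metadata = config$metadata)
  thr <- do.call(mappingThresholds,
                 as.list(config$thresholds %||% list()))
  notes <- character(0)
  if (!is.null(config$copy_number)) {
    cn <- readCopyNumberTable(config$copy_number)
    profiles <- renormalizeProfiles(profiles, cn, collection)
    notes <- c(notes, "abundances renormalized for 16S copy number")
  }
  mapping <- withCallingHandlers(
    mapProfiles(profiles, collection, thr),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cpm <- communityPhenotypeMatrix(mapping, profiles, collection)
  sig <- communitySignature(cpm)
  mf <- mappedFraction(mapping, profiles)

  fmt <- function(x) ifelse(is.na(x), NA, sprintf("%.4f", x))
  sigOut <- sig
  if (isTRUE(config$raw_fractions)) {
    # emit fractions instead of percentages
    for (cc in c("cpi_pct", "auxotrophy_pct", "mapped_pct",
                 "cpi_renorm_pct", "auxotrophy_renorm_pct"))
      sigOut[[cc]] <- sigOut[[cc]] / 100
    names(sigOut) <- sub("_pct$", "_frac", names(sigOut))
    fmt <- function(x) ifelse(is.na(x), NA, sprintf("%.6f", x))
  }
  for (cc in setdiff(colnames(sigOut), c("sample_id", "vitamin")))
    sigOut[[cc]] <- fmt(sigOut[[cc]])
  utils::write.table(sigOut, file.path(outdir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  idx <- indexMatrix(cpm)
  cpmOut <- cbind(data.frame(phylotype_id = rownames(idx)),
                  as.data.frame(round(idx, 4)),
                  as.data.frame(round(100 * abundanceMatrix(cpm), 4)))
  utils::write.table(cpmOut, file.path(outdir, "cpm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cls <- classifyTaxa(idx,
    auxThreshold = config$classification$aux %||% 0,
    protoThreshold = config$classification$proto %||% 1,
    multiMin = config$classification$multi_min %||% 3L)
  utils::write.table(cls, file.path(outdir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- sampleGroups(profiles)
  if (!all(is.na(groups))) {
    agg <- aggregateGroups(sig, groups)
    agg$mean <- fmt(agg$mean); agg$sd <- fmt(agg$sd)
    utils::write.table(agg, file.path(outdir, "group_signatures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cmpCfg <- config$comparison
  if (!is.null(cmpCfg)) {
    cmp <- compareGroups(profiles,
      groupsD = cmpCfg$groups_d, groupsE = cmpCfg$groups_e,
      minAbundance = cmpCfg$min_abundance %||% 1e-4,
      test = cmpCfg$test %||% "mannwhitney")
    utils::write.table(cmp, file.path(outdir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    mapped_fraction = as.list(mf),
    mapping_levels = as.list(table(mappingTable(mapping)$mapping_level)),
    notes = notes,
    config = config,
    package_version = as.character(utils::packageVersion("phenosig")))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a synthetic study as pipeline input files
#'
#' Generates a collection and study from a design and writes the
#' pipeline's input TSVs (\code{bpm.tsv}, \code{profiles.tsv},
#' \code{metadata.tsv}) plus the ground-truth ledger
#' (\code{truth.json}) into a directory.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param dir output directory.
#' @return list of written paths, invisibly; the truth ledger as the
#'   \code{truth} element.
#' @export
simulateStudyFiles <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  collection <- generateReferenceCollection(design)
  study <- generateStudy(design, collection)
  paths <- list(
    bpm = writeReferenceCollection(collection,
                                   file.path(dir, "bpm.tsv")),
    profiles = writeProfiles(study$profiles,
                             file.path(dir, "profiles.tsv")),
    metadata = writeSampleMetadata(sampleGroups(study$profiles),
                                   file.path(dir, "metadata.tsv")))
  jsonlite::write_json(
    list(auxotrophy_pct = as.data.frame(study$truth$auxotrophy_pct),
         seed = study$truth$seed,
         effects = study$truth$effects),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  paths$truth <- study$truth
  invisible(paths)
}
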