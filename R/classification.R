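#' Classify taxa by auxotrophy pattern
#'
#' Per vitamin, a taxon is called auxotrophic when its phenotype index
#' is at or below \code{auxThreshold} and prototrophic at or above
#' \code{protoThreshold}; indices in between are ambiguous calls. Under
#' the strict defaults (0 and 1) only unambiguous binary indices are
#' called, matching the restriction of species-level comparisons to
#' taxa with unambiguous auxotrophy; relaxed thresholds such as 0.2/0.8
#' can be used for exploratory work. A taxon prototrophic for every
#' panel vitamin is an omni-prototroph; auxotrophic for exactly one, a
#' mono-auxotroph (reported with the vitamin); auxotrophic for at least
#' \code{multiMin} (default 3), a multi-auxotroph (reported with the
#' count and vitamin set). Taxa fitting none of these patterns (any
#' ambiguous call, or 2 auxotrophies under the default
#' \code{multiMin}) fall in the residual \code{ambiguous} class, so the
#' classes always partition the mapped taxa.
#'
#' @param index numeric matrix of phenotype indices (taxa x vitamins),
#'   e.g. from \code{\link{phenotypeIndex}}, or a single index vector.
#' @param auxThreshold,protoThreshold call thresholds with
#'   \code{0 <= auxThreshold < protoThreshold <= 1}.
#' @param multiMin minimum number of auxotrophies for the
#'   multi-auxotroph class.
#' @return data.frame: \code{phylotype_id}, \code{class}
#'   (\code{omni_prototroph}, \code{mono_auxotroph},
#'   \code{multi_auxotroph}, \code{ambiguous}), \code{n_auxotrophies},
#'   \code{aux_vitamins} (comma-separated), plus the thresholds used as
#'   attributes.
#' @examples
#' idx <- rbind(Muribaculum = c(1, 1, 1, 1, 1, 1, 1, 0))
#' colnames(idx) <- vitamins(VitaminPanel())
#' classifyTaxa(idx)
#' @export
classifyTaxa <- function(index, auxThreshold = 0, protoThreshold = 1,
                         multiMin = 3L) {
  if (is.null(dim(index))) index <- matrix(index, nrow = 1,
    dimnames = list("taxon", names(index)))
  if (!(auxThreshold >= 0 && auxThreshold < protoThreshold &&
        protoThreshold <= 1))
    stop("thresholds must satisfy 0 <= auxThreshold < protoThreshold <= 1")
  vits <- colnames(index)
  call1 <- function(x) {
    aux <- x <= auxThreshold
    proto <- x >= protoThreshold
    nAux <- sum(aux)
    cls <- if (all(proto)) "omni_prototroph"
      else if (any(!aux & !proto)) "ambiguous"
      else if (nAux == 1L) "mono_auxotroph"
      else if (nAux >= multiMin) "multi_auxotroph"
      else "ambiguous"
    data.frame(class = cls, n_auxotrophies = nAux,
               aux_vitamins = paste(vits[aux], collapse = ","),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, apply(index, 1, call1, simplify = FALSE))
  out <- cbind(data.frame(phylotype_id = rownames(index),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  attr(out, "auxThreshold") <- auxThreshold
  attr(out, "protoThreshold") <- protoThreshold
  attr(out, "multiMin") <- multiMin
  out
}

#' Aggregate abundance per phenotype class
#'
#' Sums relative abundance within each phenotype class; the classes
#' partition the mapped phylotypes, so per-class abundances add up to
#' the mapped abundance of each sample. With several samples the
#' per-sample class totals are averaged.
#'
#' @param classes data.frame from \code{\link{classifyTaxa}}.
#' @param profiles the matching \linkS4class{PhyloProfileSet}.
#' @return data.frame: \code{class}, \code{abundance_pct} (mean over
#'   samples), \code{n_taxa}.
#' @export
classAbundanceSummary <- function(classes, profiles) {
  ab <- abundances(profiles)[classes$phylotype_id, , drop = FALSE]
  perSample <- rowsum(ab, classes$class)
  data.frame(class = rownames(perSample),
             abundance_pct = 100 * rowMeans(perSample),
             n_taxa = as.integer(table(classes$class)[rownames(perSample)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare species abundances between aggregated groups
#'
#' Per species (best-match name; phylotypes sharing a name are summed),
#' compares relative abundances between two aggregated sample sides,
#' e.g. the vitamin-deficient diets (AD, 4D4N, 7D1N) against the
#' vitamin-excess diets (AE, 4E4N, 7E1N). Species are tested only when
#' reliably detectable: mean abundance at or above \code{minAbundance}
#' (default 1e-4, i.e. 0.01\%) on at least one side. The default test
#' is the exact two-sided Mann-Whitney U (normal approximation above 20
#' samples per side or under ties), a nonparametric choice suited to
#' compositional percent data at modest replication; Welch's t is
#' available as an alternative. Raw p-values are reported by default;
#' Benjamini-Hochberg adjustment is optional.
#'
#' @param profiles a \linkS4class{PhyloProfileSet} with group labels.
#' @param groupsD,groupsE group labels aggregated into the two sides
#'   (each side needs at least 2 samples).
#' @param minAbundance detection filter (fraction).
#' @param test \code{"mannwhitney"} or \code{"welch"}.
#' @param adjust if TRUE, add Benjamini-Hochberg adjusted p-values.
#' @return data.frame: \code{species}, \code{mean_D}, \code{mean_E}
#'   (fractions), \code{diff}, \code{fold_change} (E over D),
#'   \code{p_value}, \code{tested}; plus \code{p_adj} when
#'   \code{adjust}.
#' @export
compareGroups <- function(profiles, groupsD, groupsE,
                          minAbundance = 1e-4,
                          test = c("mannwhitney", "welch"),
                          adjust = FALSE) {
  test <- match.arg(test)
  g <- sampleGroups(profiles)
  selD <- !is.na(g) & g %in% groupsD
  selE <- !is.na(g) & g %in% groupsE
  if (sum(selD) < 2L || sum(selE) < 2L)
    stop("each side needs at least 2 samples (got ", sum(selD),
         " and ", sum(selE), ")")
  ab <- abundances(profiles)
  sp <- phylotypeInfo(profiles)$best_match_name
  ab <- rowsum(ab, sp)
  res <- do.call(rbind, lapply(rownames(ab), function(s) {
    xD <- ab[s, selD]; xE <- ab[s, selE]
    mD <- mean(xD); mE <- mean(xE)
    tested <- max(mD, mE) >= minAbundance
    p <- NA_real_
    if (tested) {
      p <- if (test == "mannwhitney") {
        exact <- length(xD) <= 20 && length(xE) <= 20 &&
          !anyDuplicated(c(xD, xE))
        suppressWarnings(stats::wilcox.test(xE, xD, exact = exact,
          correct = !exact)$p.value)
      } else {
        stats::t.test(xE, xD, var.equal = FALSE)$p.value
      }
    }
    data.frame(species = s, n_D = length(xD), n_E = length(xE),
               mean_D = mD, mean_E = mE, diff = mE - mD,
               fold_change = if (mD > 0) mE / mD else NA_real_,
               p_value = p, tested = tested,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (adjust)
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res
}
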