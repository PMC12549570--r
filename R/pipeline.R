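#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the study
#' defaults: adjusted-p 0.05, fold-change calls at 5 (up) and 0.2
#' (down), ALC% filter 80, database-search priority score 30,
#' Smith-Waterman acceptance 30, E-value 1, minimum 3 CDR residues,
#' m/z window 0.01 Th, RT window 1 min, 3-fold cross-validation with 50
#' repeats, and the RF-negative disease controls as reference group.
#'
#' @param ... Overrides of any default field.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    alpha = 0.05, fcUp = 5, fcDown = 0.2,
    alcMin = 80, mascotMin = 30, swMin = 30, evalueMax = 1,
    minCdrResidues = 3L,
    mzTol = 0.01, rtTol = 1.0,
    contrast = c("RFposCCPpos_RA", "RFneg_control"),
    referenceGroup = "RFneg_control",
    tune = TRUE, ncomp = 2L, keepX = c(10L, 10L),
    Hgrid = 2:5, keepXgrid = c(1L, 2L, 3L, 5L, 10L, 20L, 50L),
    folds = 3L, repeats = 50L,
    occMin = 0.5, seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

.stage_log <- function(log, stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%d out=%d %s", stage, n_in, n_out, note))
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        note = note, stringsAsFactors = FALSE))
}

#' Run the complete analysis pipeline
#'
#' Executes all stages in dependency order on one experiment:
#' normalization, identification merging (de novo filter, confident-Ig
#' exclusion, priority resolution), germline annotation (constant-region
#' precedence, variable-region allocation), per-peptide differential
#' testing and fold-change calling, sparse PLS-DA stability selection
#' and discriminative-peptide flagging, and isotype quantification with
#' positivity calls.  Every stage writes its table under `outDir`
#' together with a per-stage record-count log and a manifest recording
#' the seed and a hash of the configuration; a re-run with the same
#' inputs and seed reproduces the outputs exactly.
#'
#' @param sim An experiment as returned by [simulateExperiment()], or a
#'   list with the same `features`/`abundance`/`idents`/`samples`
#'   elements assembled from files via the table readers.
#' @param germlines A [GermlineSet].
#' @param config A [pipelineConfig()].
#' @param outDir Output directory; `NULL` suppresses file output.
#' @return Invisible list with all stage results (`factors`,
#'   `normalized`, `resolved`, `annotation`, `differential`, `volcano`,
#'   `splsda`, `discriminative`, `isotype`, `positivity`,
#'   `isotypeTests`, `log`, `manifest`).
#' @export
runPipeline <- function(sim, germlines = loadGermlineSet(),
                        config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer(), note = character(),
                    stringsAsFactors = FALSE)
  features <- sim$features; ab <- sim$abundance
  samples <- sim$samples; idents <- sim$idents
  groups <- samples$group[match(colnames(ab), samples$sample_id)]

  ## normalization
  norm <- normalizeAbundance(ab)
  log <- .stage_log(log, "normalize", nrow(ab), nrow(ab),
                    sprintf("reference factor range %.2f-%.2f",
                            min(norm$factors), max(norm$factors)))

  ## identification merging
  db <- idents[idents$engine == "database_search", , drop = FALSE]
  dn <- idents[idents$engine == "de_novo", , drop = FALSE]
  db_ann <- annotatePeptides(db$sequence, germlines,
                             evalueMax = config$evalueMax,
                             swMin = config$swMin,
                             minCdrResidues = config$minCdrResidues)
  dn2 <- excludeIgMascotFromDeNovo(dn, db, db_ann$ig_related,
                                   mascotMin = config$mascotMin)
  dn3 <- filterDeNovo(dn2, alcMin = config$alcMin)
  log <- .stage_log(log, "de_novo_filter", nrow(dn), nrow(dn3),
                    "ALC>80, length>=3, confident-Ig excluded")
  resolved <- resolveIdentifications(features$feature_id, db, dn3,
                                     mascotMin = config$mascotMin,
                                     alcMin = config$alcMin)
  log <- .stage_log(log, "resolve_idents", nrow(features),
                    sum(resolved$provenance != "unidentified"),
                    "resolved sequence per feature")

  ## annotation of resolved sequences (I/L folding for de novo)
  has_seq <- !is.na(resolved$sequence)
  ann <- resolved[c("feature_id", "sequence", "provenance")]
  ann_res <- annotatePeptides(resolved$sequence[has_seq], germlines,
                              ilEquivalent =
                                resolved$provenance[has_seq] == "de_novo",
                              evalueMax = config$evalueMax,
                              swMin = config$swMin,
                              minCdrResidues = config$minCdrResidues)
  annotation <- cbind(ann[has_seq, ],
                      ann_res[setdiff(names(ann_res), "sequence")])
  log <- .stage_log(log, "annotate", sum(has_seq),
                    sum(annotation$category != "non_ig"),
                    "Ig-related peptides")

  ## differential testing on identified features
  idf <- annotation$feature_id
  diff <- differentialAbundance(norm$abundance[idf, , drop = FALSE],
                                groups, contrast = config$contrast,
                                alpha = config$alpha, fcUp = config$fcUp,
                                fcDown = config$fcDown)
  volcano <- volcanoTable(diff$results)
  log <- .stage_log(log, "differential", length(idf),
                    sum(diff$results$call != "ns"),
                    sprintf("up=%d down=%d",
                            sum(diff$results$call == "up"),
                            sum(diff$results$call == "down")))

  ## multivariate on Ig-related peptides
  ig_ids <- annotation$feature_id[annotation$category != "non_ig"]
  X <- imputePeptideMeans(t(norm$abundance[ig_ids, , drop = FALSE]))
  if (config$tune) {
    fit <- splsdaTune(X, groups, Hgrid = config$Hgrid,
                      keepXgrid = config$keepXgrid,
                      folds = config$folds, repeats = config$repeats,
                      seed = config$seed)
  } else {
    keepX <- pmin(as.integer(config$keepX), ncol(X))
    fit <- splsda(X, groups, ncomp = config$ncomp, keepX = keepX)
    stab <- splsdaCV(X, groups, ncomp = config$ncomp, keepX = keepX,
                     folds = config$folds, repeats = config$repeats,
                     seed = config$seed)
    fit@ber <- stab$ber
    fit@occurrence <- stab$occurrence
  }
  vregion <- stats::setNames(annotation$category == "variable",
                             annotation$feature_id)
  disc <- selectDiscriminative(
    diff$results, fit@occurrence, vregion, diff$z, groups,
    controlGroup = config$referenceGroup, alpha = config$alpha,
    fcMin = config$fcUp, occMin = config$occMin)
  log <- .stage_log(log, "splsda", length(ig_ids),
                    sum(disc$discriminative), "discriminative peptides")

  ## isotype quantification
  iso <- quantifyIsotypes(annotation, norm$abundance)
  posi <- positivityCalls(iso$abundance, groups,
                          referenceGroup = config$referenceGroup)
  iso_tests <- isotypeGroupTests(iso$abundance, groups)
  log <- .stage_log(log, "isotypes", nrow(iso$abundance),
                    sum(posi$summary$n_positive), "positive samples")

  result <- list(factors = norm$factors, normalized = norm$abundance,
                 resolved = resolved, annotation = annotation,
                 differential = diff$results, volcano = volcano,
                 z = diff$z, splsda = fit, discriminative = disc,
                 isotype = iso, positivity = posi,
                 isotypeTests = iso_tests, log = log)

  if (!is.null(outDir)) {
    tables <- list(
      sample_factors = data.frame(sample_id = names(norm$factors),
                                  factor = unname(norm$factors)),
      resolved_idents = resolved,
      annotation = annotation,
      differential = diff$results,
      volcano = volcano,
      splsda_occurrence = data.frame(
        feature_id = names(fit@occurrence),
        occurrence = unname(fit@occurrence)),
      discriminative = disc,
      isotype_abundance = data.frame(isotype = rownames(iso$abundance),
                                     iso$abundance, check.names = FALSE),
      isotype_positivity = posi$summary,
      isotype_tests = iso_tests,
      pipeline_log = log)
    paths <- writeResultTables(outDir, tables)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
    cfg_file <- file.path(outDir, "config.json")
    writeLines(cfg_json, cfg_file)
    manifest <- list(
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      tables_md5 = as.list(stats::setNames(
        tools::md5sum(unname(paths)), basename(unname(paths)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}
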