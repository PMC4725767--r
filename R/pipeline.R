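#' Default pipeline configuration
#'
#' Every stage parameter of [runPipeline()] with its default. A serialized
#' configuration (the manifest) reproduces a run exactly.
#'
#' @param matrixPath,annotationPath,gmtPath,parentsPath input file paths
#'   (NULL where unused). \code{matrixPath}/\code{annotationPath} are
#'   ignored when \code{simulate} is given.
#' @param dialect,ratioOrientation,logAlready passed to
#'   [readExpressionMatrix()].
#' @param simulate NULL, or a [syntheticConfig()] list: simulate instead of
#'   reading (the simulated inputs are also written to the run directory).
#' @param minValidFraction valid-value filter threshold (NULL disables),
#'   with \code{filterScope} as in [filterMinValid()].
#' @param filterScope see [filterMinValid()].
#' @param impute run [imputeDownshift()] before ANOVA/classification
#'   (enrichment and correlation always use unimputed values).
#' @param widthFactor,downshiftFactor imputation parameters.
#' @param enrichMinSize,enrichFdr,enrichPThreshold enrichment parameters.
#' @param stat,nPermutations,fdrLevel,s0 differential-expression
#'   parameters (see [permutationFDR()]).
#' @param testFraction,nRuns,featureGrid,cost,stratified classification
#'   parameters (see [cvFeatureSelection()]).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return named list of class \code{"runConfig"}.
#' @export
runConfig <- function(matrixPath = NULL, annotationPath = NULL,
                      gmtPath = NULL, parentsPath = NULL,
                      dialect = "generic", ratioOrientation = NULL,
                      logAlready = FALSE, simulate = NULL,
                      minValidFraction = 0.7, filterScope = "all_samples",
                      impute = TRUE, widthFactor = 0.3, downshiftFactor = 1.8,
                      enrichMinSize = 5, enrichFdr = 0.05,
                      enrichPThreshold = NULL,
                      stat = "anovaF", nPermutations = 250, fdrLevel = 0.05,
                      s0 = 0, testFraction = 0.15, nRuns = 250,
                      featureGrid = 1:30, cost = 1, stratified = TRUE,
                      seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "runConfig"
  cfg
}

#' @noRd
stageSeed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes read (or simulate) -> valid-value filter -> sample correlation
#' -> annotation enrichment -> ANOVA with permutation FDR -> imputation ->
#' cross-validated feature selection -> signature extraction -> ROC, and
#' writes every result as a self-describing TSV plus a JSON manifest
#' (parameters, seed, package version, input checksums, per-stage record
#' counts) into \code{outDir}. Two runs from the same configuration are
#' byte-identical on every output.
#'
#' @param config a [runConfig()] list.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{matrix}, \code{filtered}, \code{correlation}, \code{enrichment},
#'   \code{diffexpr}, \code{curve}, \code{counts}, \code{signature},
#'   \code{roc}, \code{manifest}).
#' @export
runPipeline <- function(config = runConfig(), outDir) {
  cfg <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "proteoSig",
                   version = as.character(packageVersion("proteoSig")),
                   config = cfg[!vapply(cfg, is.null, logical(1))],
                   counts = list())
  log <- function(...) message("[proteoSig] ", ...)

  categories <- NULL
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    log("simulate: generating synthetic cohort")
    sim <- generateSynthetic(do.call(syntheticConfig, cfg$simulate))
    pset <- sim$matrix
    categories <- sim$categories
    truth <- sim$truth
    writeExpressionMatrix(pset, file.path(outDir, "matrix.tsv"))
    writeResultTable(data.frame(sample = sampleIds(pset),
                                subtype = as.character(subtypes(pset))),
                     file.path(outDir, "annotation.tsv"))
  } else {
    if (is.null(cfg$matrixPath) || !file.exists(cfg$matrixPath))
      stop("stage read: expression matrix file not found: ",
           if (is.null(cfg$matrixPath)) "(unset)" else cfg$matrixPath)
    if (is.null(cfg$annotationPath) || !file.exists(cfg$annotationPath))
      stop("stage read: annotation file not found: ",
           if (is.null(cfg$annotationPath)) "(unset)" else cfg$annotationPath)
    pset <- readExpressionMatrix(cfg$matrixPath, dialect = cfg$dialect,
                                 ratioOrientation = cfg$ratioOrientation,
                                 logAlready = cfg$logAlready)
    subtypes(pset) <- readSampleAnnotation(cfg$annotationPath)
    manifest$inputs <- list(
      matrix = unname(tools::md5sum(cfg$matrixPath)),
      annotation = unname(tools::md5sum(cfg$annotationPath)))
    if (!is.null(cfg$gmtPath))
      categories <- readGMT(cfg$gmtPath, parentsPath = cfg$parentsPath)
  }
  log("read: ", nrow(pset), " proteins x ", ncol(pset), " samples")
  manifest$counts$proteins <- nrow(pset)
  manifest$counts$samples <- ncol(pset)

  filtered <- pset
  if (!is.null(cfg$minValidFraction)) {
    filtered <- filterMinValid(pset, cfg$minValidFraction, cfg$filterScope)
    log("filter: ", nrow(filtered), " proteins exceed valid fraction ",
        cfg$minValidFraction)
  }
  manifest$counts$proteins_filtered <- nrow(filtered)

  corr <- correlationStructure(filtered)
  corrDf <- data.frame(sample = rownames(corr$correlations),
                       as.data.frame(corr$correlations, optional = TRUE),
                       check.names = FALSE)
  writeResultTable(corrDf, file.path(outDir, "correlation.tsv"),
                   params = list(linkage = corr$linkage))

  enr <- NULL
  if (!is.null(categories) && length(categories)) {
    enr <- hierarchyEnrichment(filtered, categories,
                               minSize = cfg$enrichMinSize,
                               fdr = cfg$enrichFdr,
                               pThreshold = cfg$enrichPThreshold)
    writeResultTable(enr, file.path(outDir, "enrichment.tsv"),
                     params = list(minSize = cfg$enrichMinSize,
                                   fdr = cfg$enrichFdr, seed = cfg$seed))
    log("enrichment: ", nrow(enr), " category tests, ",
        sum(enr$significant), " significant")
    manifest$counts$enrichment_tests <- nrow(enr)
    manifest$counts$enrichment_significant <- sum(enr$significant)
  }

  imputed <- filtered
  if (isTRUE(cfg$impute)) {
    imputed <- imputeDownshift(filtered, cfg$widthFactor,
                               cfg$downshiftFactor,
                               seed = stageSeed(cfg$seed, 1L))
    log("impute: downshift ", cfg$downshiftFactor, ", width ",
        cfg$widthFactor)
  }

  de <- permutationFDR(imputed, statistic = cfg$stat,
                       nPermutations = cfg$nPermutations,
                       level = cfg$fdrLevel, s0 = cfg$s0,
                       seed = stageSeed(cfg$seed, 2L))
  writeResultTable(de, file.path(outDir, "diffexpr.tsv"),
                   params = list(stat = cfg$stat,
                                 n_permutations = cfg$nPermutations,
                                 fdr = cfg$fdrLevel,
                                 imputed = isTRUE(cfg$impute),
                                 seed = stageSeed(cfg$seed, 2L)))
  log("diffexpr: ", sum(de$significant), " significant at permutation FDR ",
      cfg$fdrLevel)
  manifest$counts$diffexpr_significant <- sum(de$significant)

  curve <- cvFeatureSelection(imputed, testFraction = cfg$testFraction,
                              nRuns = cfg$nRuns,
                              featureGrid = cfg$featureGrid, cost = cfg$cost,
                              stratified = cfg$stratified,
                              seed = stageSeed(cfg$seed, 3L))
  writeResultTable(accuracyCurve(curve), file.path(outDir, "accuracy_curve.tsv"),
                   params = list(test_fraction = cfg$testFraction,
                                 n_runs = cfg$nRuns, cost = cfg$cost,
                                 stratified = cfg$stratified,
                                 seed = stageSeed(cfg$seed, 3L)))
  counts <- optimalFeatureCounts(curve)
  log("classify: optimal counts ",
      paste(names(counts), counts, sep = "=", collapse = ", "))
  sig <- extractSignature(imputed, counts, cost = cfg$cost)
  writeResultTable(signatureEntries(sig), file.path(outDir, "signature.tsv"),
                   params = list(counts = paste(names(counts), counts,
                                                sep = ":", collapse = ","),
                                 cost = cfg$cost, seed = cfg$seed))
  manifest$counts$signature_proteins <- nrow(signatureEntries(sig))

  # resubstitution ROC per class (scores of the final full-data models on
  # the same data; labelled as such)
  pred <- predict(sig, imputed, scores = TRUE)
  sc <- attr(pred, "scores")
  st <- subtypes(imputed)
  roc <- list()
  for (cl in levels(st)) {
    roc[[cl]] <- rocCurve(sc[, cl], st == cl, positiveClass = cl)
    writeResultTable(roc[[cl]]@points,
                     file.path(outDir, paste0("roc_", cl, ".tsv")),
                     params = list(class = cl, auc = roc[[cl]]@auc,
                                   mode = "resubstitution"))
  }
  manifest$counts$auc <- lapply(roc, function(r) r@auc)
  writeResultTable(data.frame(sample = sampleIds(imputed),
                              truth = as.character(st),
                              predicted = as.character(pred)),
                   file.path(outDir, "predictions.tsv"),
                   params = list(seed = cfg$seed))

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(matrix = pset, filtered = filtered, correlation = corr,
                 enrichment = enr, diffexpr = de, curve = curve,
                 counts = counts, signature = sig, roc = roc,
                 truth = truth, manifest = manifest))
}
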