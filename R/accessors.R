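#' @rdname ProteomeSet-class
#' @param x a \linkS4class{ProteomeSet}.
#' @return \code{logRatios}: the numeric matrix with \code{NA} for missing.
#' @export
logRatios <- function(x) SummarizedExperiment::assay(x, "logratio")

#' @rdname ProteomeSet-class
#' @return \code{missingMask}: logical matrix, \code{TRUE} where missing.
#' @export
missingMask <- function(x) is.na(logRatios(x))

#' @rdname ProteomeSet-class
#' @export
proteinIds <- function(x) rownames(x)

#' @rdname ProteomeSet-class
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname ProteomeSet-class
#' @return \code{subtypes}: factor of per-sample class labels (or NULL).
#' @export
subtypes <- function(x) {
  st <- SummarizedExperiment::colData(x)$subtype
  if (is.null(st)) NULL else factor(st, levels = levels(st))
}

#' @rdname ProteomeSet-class
#' @param value subtype labels: vector along columns, or named covering all
#'   samples (a data.frame from [readSampleAnnotation()] also works).
#' @export
`subtypes<-` <- function(x, value) {
  if (is.data.frame(value))
    value <- setNames(factor(value[[2]], levels = unique(as.character(value[[2]]))),
                      as.character(value[[1]]))
  if (!is.null(names(value))) {
    missing <- setdiff(sampleIds(x), names(value))
    if (length(missing))
      stop("samples without subtype annotation: ", paste(missing, collapse = ", "))
    value <- value[sampleIds(x)]
  } else if (length(value) != ncol(x)) {
    stop("subtype vector length (", length(value),
         ") does not match sample count (", ncol(x), ")")
  }
  lev <- if (is.factor(value)) levels(droplevels(value)) else unique(as.character(value))
  SummarizedExperiment::colData(x)$subtype <-
    factor(as.character(value), levels = lev)
  validObject(x)
  x
}

#' @rdname ProteomeSet-class
#' @return \code{classLevels}: the ordered class labels.
#' @export
classLevels <- function(x) levels(subtypes(x))

setMethod("show", "ProteomeSet", function(object) {
  cat("ProteomeSet:", nrow(object), "proteins x", ncol(object), "samples\n")
  cat(sprintf("  missing: %.1f%% of entries\n", 100 * mean(missingMask(object))))
  st <- subtypes(object)
  if (!is.null(st)) {
    tab <- table(st)
    cat("  subtypes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @rdname CategoryMap-class
#' @param x a \linkS4class{CategoryMap}.
#' @export
categoryNames <- function(x) names(x@members)

#' @rdname CategoryMap-class
#' @export
categoryMembers <- function(x) x@members

#' @rdname CategoryMap-class
#' @export
categoryParents <- function(x) x@parents

#' @rdname CategoryMap-class
#' @export
categorySizes <- function(x) lengths(x@members)

setMethod("length", "CategoryMap", function(x) length(x@members))

setMethod("show", "CategoryMap", function(object) {
  cat("CategoryMap:", length(object), "categories")
  if (length(object@parents))
    cat(",", length(unique(object@parents)), "parents over",
        length(object@parents), "linked children")
  cat("\n")
  if (length(object))
    cat("  sizes:", paste(range(categorySizes(object)), collapse = "-"),
        "members\n")
})

#' @rdname AccuracyCurve-class
#' @param x an \linkS4class{AccuracyCurve}.
#' @return \code{accuracyCurve}: the underlying data.frame.
#' @export
accuracyCurve <- function(x) x@curve

setMethod("show", "AccuracyCurve", function(object) {
  cat("AccuracyCurve:", length(object@classes), "classes, sizes",
      paste(range(object@featureGrid), collapse = "-"),
      "over", object@nRuns, "CV runs\n")
  best <- optimalFeatureCounts(object)
  for (cl in object@classes) {
    sub <- object@curve[object@curve$class == cl, ]
    cat(sprintf("  %s: max mean accuracy %.3f at %d features\n",
                cl, max(sub$mean_accuracy), best[[cl]]))
  }
})

#' @rdname SubtypeSignature-class
#' @param x a \linkS4class{SubtypeSignature}.
#' @return \code{signatureEntries}: data.frame of (class, protein, direction).
#' @export
signatureEntries <- function(x) x@entries

setMethod("show", "SubtypeSignature", function(object) {
  cat("SubtypeSignature:", nrow(object@entries), "proteins across",
      length(object@classes), "classes\n")
  for (cl in object@classes) {
    e <- object@entries[object@entries$class == cl, ]
    cat(sprintf("  %s (%d): %s\n", cl, nrow(e),
                paste(sprintf("%s%s", ifelse(e$direction == "positive", "+", "-"),
                              e$protein), collapse = " ")))
  }
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve (positive = %s): AUC = %.4f, %d points\n",
              object@positiveClass, object@auc, nrow(object@points)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@markers), "planted markers,",
      nrow(object@categories), "enriched categories\n")
  cat(sprintf("  realized missing fraction: %.3f\n",
              object@realizedMissingFraction))
})

#' @rdname SyntheticTruth-class
#' @param x a \linkS4class{SyntheticTruth}.
#' @export
truthMarkers <- function(x) x@markers

#' @rdname SyntheticTruth-class
#' @export
truthCategories <- function(x) x@categories

#' @rdname SyntheticTruth-class
#' @export
truthCompleteMatrix <- function(x) x@completeMatrix
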