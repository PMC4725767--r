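#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay "assay<-" assayNames colData
#'   "colData<-"
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pnorm pt pf p.adjust rnorm runif sd cor hclust as.dist
#'   setNames plogis uniroot median quantile predict
#' @importFrom utils read.delim write.table packageVersion combn head
NULL

#' Proteome expression set
#'
#' The central container of the package: a proteins x samples matrix of
#' log2(tumour / internal standard) SILAC ratios stored as the
#' \code{"logratio"} assay of a \linkS4class{SummarizedExperiment}. Missing
#' quantifications are encoded as \code{NA} and excluded from every statistic
#' unless an operation explicitly imputes them. Sample subtype labels, when
#' assigned, live in \code{colData(x)$subtype} as a factor whose level order
#' is the class order used for one-vs-rest decompositions and tie-breaking.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @seealso [ProteomeSet()], [logRatios()], [subtypes()], [imputeDownshift()]
#' @export
setClass("ProteomeSet", contains = "SummarizedExperiment")

setValidity("ProteomeSet", function(object) {
  msg <- character()
  if (!"logratio" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logratio' is required")
  else {
    a <- SummarizedExperiment::assay(object, "logratio")
    if (!is.numeric(a))
      msg <- c(msg, "'logratio' assay must be numeric")
  }
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || is.null(cn))
    msg <- c(msg, "protein and sample identifiers are required as dimnames")
  if (anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicate protein identifiers: %s",
                          paste(unique(rn[duplicated(rn)])[1:min(3, sum(duplicated(rn)))],
                                collapse = ", ")))
  if (anyDuplicated(cn))
    msg <- c(msg, sprintf("duplicate sample identifiers: %s",
                          paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  st <- SummarizedExperiment::colData(object)$subtype
  if (!is.null(st)) {
    if (anyNA(st))
      msg <- c(msg, "subtype labels contain NA")
    else {
      tab <- table(factor(st))
      if (length(tab) >= 2 && any(tab < 2))
        msg <- c(msg, sprintf("every subtype needs >= 2 samples (violated by %s)",
                              paste(names(tab)[tab < 2], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteomeSet
#'
#' @param values numeric matrix (proteins x samples) of log2 sample/standard
#'   ratios; \code{NA} marks missing quantifications. Row and column names are
#'   mandatory and must be unique.
#' @param subtype optional subtype labels, either a vector along the columns
#'   of \code{values} or a named vector/factor covering every sample. Level
#'   order (for factors) or first-appearance order (otherwise) defines the
#'   class order.
#' @return a \linkS4class{ProteomeSet}.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
#' ProteomeSet(m)
#' @export
ProteomeSet <- function(values, subtype = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logratio = values), colData = cd)
  obj <- new("ProteomeSet", se)
  if (!is.null(subtype)) subtypes(obj) <- subtype
  obj
}

#' Named protein-set collection with optional two-level hierarchy
#'
#' Gene-set annotations (GMT-style): a named list of member protein
#' identifiers, plus an optional child -> parent map. Hierarchies are at most
#' two levels deep: a category that is somebody's parent may not itself have
#' a parent.
#'
#' @slot members named list of character vectors (unique, non-empty).
#' @slot parents named character vector mapping category -> parent category;
#'   may be empty.
#' @seealso [readGMT()], [enrichment1D()], [hierarchyEnrichment()]
#' @export
setClass("CategoryMap",
         representation(members = "list", parents = "character"))

setValidity("CategoryMap", function(object) {
  msg <- character()
  m <- object@members
  if (length(m)) {
    if (is.null(names(m)) || any(names(m) == ""))
      msg <- c(msg, "all categories must be named")
    if (anyDuplicated(names(m)))
      msg <- c(msg, sprintf("duplicate category name: %s",
                            names(m)[duplicated(names(m))][1]))
    if (!all(vapply(m, is.character, logical(1))))
      msg <- c(msg, "members must be character vectors")
    if (any(lengths(m) == 0))
      msg <- c(msg, "member sets must be non-empty")
  }
  p <- object@parents
  if (length(p)) {
    if (is.null(names(p)) || any(names(p) == ""))
      msg <- c(msg, "parent links must be named by child category")
    if (anyDuplicated(names(p)))
      msg <- c(msg, "a category may have at most one parent")
    if (any(p %in% names(p)))
      msg <- c(msg, "hierarchy deeper than two levels (a parent has a parent)")
  }
  if (length(msg)) msg else TRUE
})

#' @param members named list of character vectors of protein identifiers;
#'   duplicates within a set are removed.
#' @param parents named character vector (child category -> parent category).
#' @rdname CategoryMap-class
#' @export
CategoryMap <- function(members = list(), parents = character()) {
  members <- lapply(members, function(x) unique(as.character(x)))
  new("CategoryMap", members = members, parents = parents)
}

#' Cross-validated accuracy as a function of signature size
#'
#' Per class, the mean and s.d. (over cross-validation runs) of held-out
#' one-vs-rest accuracy when the classifier uses the top-g ranked features,
#' for every g on the feature grid.
#'
#' @slot curve data.frame with columns \code{class}, \code{size},
#'   \code{mean_accuracy}, \code{sd_accuracy}, \code{n_runs}.
#' @slot classes class label order.
#' @slot featureGrid the evaluated signature sizes.
#' @slot nRuns number of cross-validation runs.
#' @seealso [cvFeatureSelection()], [optimalFeatureCounts()]
#' @export
setClass("AccuracyCurve",
         representation(curve = "data.frame", classes = "character",
                        featureGrid = "integer", nRuns = "integer"))

setValidity("AccuracyCurve", function(object) {
  cv <- object@curve
  need <- c("class", "size", "mean_accuracy", "sd_accuracy", "n_runs")
  if (!all(need %in% names(cv)))
    return(sprintf("curve must have columns %s", paste(need, collapse = ", ")))
  if (nrow(cv) && (any(cv$mean_accuracy < 0) || any(cv$mean_accuracy > 1)))
    return("accuracies must lie in [0, 1]")
  TRUE
})

#' Multi-class protein marker signature with trained one-vs-rest models
#'
#' The end product of the feature-selection framework: per class, the
#' top-ranked proteins (with the sign of their class-vs-rest mean difference
#' as direction) and a linear maximum-margin model trained on exactly those
#' proteins. A protein may mark more than one class; (class, protein) pairs
#' are unique.
#'
#' @slot entries data.frame with columns \code{class}, \code{protein},
#'   \code{rank}, \code{direction} ("positive"/"negative"), \code{p_value}.
#' @slot models per-class list of linear decision models
#'   (weights, intercept, standardization constants, feature list).
#' @slot classes class label order (used for prediction tie-breaks).
#' @seealso [extractSignature()], [predict,SubtypeSignature-method]
#' @export
setClass("SubtypeSignature",
         representation(entries = "data.frame", models = "list",
                        classes = "character"))

setValidity("SubtypeSignature", function(object) {
  e <- object@entries
  if (!all(c("class", "protein", "direction") %in% names(e)))
    return("entries must have columns class, protein, direction")
  if (anyDuplicated(e[c("class", "protein")]))
    return("(class, protein) pairs must be unique")
  if (nrow(e) && !all(e$direction %in% c("positive", "negative")))
    return("direction must be 'positive' or 'negative'")
  if (!all(names(object@models) %in% object@classes))
    return("model names must match classes")
  TRUE
})

#' Receiver operating characteristic curve
#'
#' Threshold sweep over distinct decision scores; the AUC is the
#' Mann-Whitney probability estimate (ties count one half) and equals the
#' trapezoidal area under the curve points.
#'
#' @slot points data.frame with columns \code{fpr}, \code{tpr},
#'   \code{threshold}; starts at (0,0), ends at (1,1), non-decreasing.
#' @slot auc area under the curve.
#' @slot positiveClass label treated as positive.
#' @seealso [rocCurve()]
#' @export
setClass("RocCurve",
         representation(points = "data.frame", auc = "numeric",
                        positiveClass = "character"))

setValidity("RocCurve", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr") %in% names(p)))
    return("points must have fpr and tpr columns")
  n <- nrow(p)
  if (n < 2 || p$fpr[1] != 0 || p$tpr[1] != 0 || p$fpr[n] != 1 || p$tpr[n] != 1)
    return("curve must start at (0,0) and end at (1,1)")
  if (any(diff(p$fpr) < 0) || any(diff(p$tpr) < 0))
    return("curve must be non-decreasing in both coordinates")
  trap <- sum(diff(p$fpr) * (head(p$tpr, -1) + p$tpr[-1]) / 2)
  if (abs(trap - object@auc) > 1e-12)
    return("auc must equal the trapezoidal area of the points")
  TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Everything the generator planted: marker assignments with signed effects,
#' enriched categories with their class and shift, the complete
#' (pre-censoring) value matrix, per-protein baselines and per-class effect
#' offsets (which allow drawing further samples from the same population),
#' the realized missing fraction, the missingness threshold, and the
#' generating configuration.
#'
#' @slot markers data.frame: \code{class}, \code{protein}, \code{effect}.
#' @slot categories data.frame: \code{category}, \code{class}, \code{shift}.
#' @slot completeMatrix the value matrix before censoring.
#' @slot baselines per-protein baseline log-ratios.
#' @slot classEffects proteins x classes matrix of additive effects.
#' @slot realizedMissingFraction fraction of entries censored.
#' @slot tau missingness threshold of the logistic censoring model.
#' @slot config the generating configuration list (seed included).
#' @seealso [generateSynthetic()], [generateFromTruth()]
#' @export
setClass("SyntheticTruth",
         representation(markers = "data.frame", categories = "data.frame",
                        completeMatrix = "matrix", baselines = "numeric",
                        classEffects = "matrix",
                        realizedMissingFraction = "numeric",
                        tau = "numeric", config = "list"))
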