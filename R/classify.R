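#' Train a linear maximum-margin (SVM) decision function
#'
#' Fits a linear soft-margin support vector machine (libsvm via
#' \pkg{e1071}) on standardized features and returns a self-contained
#' decision model: per-feature training mean and s.d. (the standardization
#' is part of the model), weight vector, intercept, and the positive label.
#' Scores are oriented so that score > 0 predicts the positive class.
#' Features with zero training variance are dropped with a warning before
#' standardization.
#'
#' @param values samples x features numeric matrix (no missing values),
#'   with feature column names.
#' @param positive logical vector along rows: \code{TRUE} for the positive
#'   class. Both classes must be present.
#' @param cost soft-margin regularization constant C (default 1).
#' @return an object of class \code{"marginClassifier"}: list with
#'   \code{features}, \code{center}, \code{scale}, \code{weights},
#'   \code{intercept}, \code{cost}. Score new samples with
#'   [decisionScores()].
#' @export
trainMarginClassifier <- function(values, positive, cost = 1) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("training matrix must not contain missing values")
  positive <- as.logical(positive)
  if (!any(positive) || all(positive))
    stop("both classes must be present in the training labels")
  sds <- apply(values, 2, sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(values)[drop], collapse = ", "))
    values <- values[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (ncol(values) == 0) stop("no features with non-zero variance remain")
  ctr <- colMeans(values)
  z <- scale(values, center = ctr, scale = sds)
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(x = z, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values towards the first label it encountered;
  # flip so that positive scores mean the positive class
  dv <- attr(predict(fit, z[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (startsWith(colnames(dv)[1], "neg")) -1 else 1
  structure(list(features = colnames(values), center = ctr, scale = sds,
                 weights = flip * w, intercept = flip * b, cost = cost),
            class = "marginClassifier")
}

#' Decision scores of a margin classifier on new samples
#'
#' @param model a \code{"marginClassifier"} from [trainMarginClassifier()].
#' @param values samples x features matrix containing at least the model's
#'   features (by column name).
#' @return numeric vector of signed decision scores (> 0: positive class).
#' @export
decisionScores <- function(model, values) {
  values <- as.matrix(values)
  missing <- setdiff(model$features, colnames(values))
  if (length(missing))
    stop("feature(s) absent from the input: ", paste(missing, collapse = ", "))
  z <- scale(values[, model$features, drop = FALSE],
             center = model$center, scale = model$scale)
  drop(z %*% model$weights) + model$intercept
}

# One-vs-rest t-test ranking on a plain matrix (samples in columns),
# vectorized; used inside CV loops where x is already split.
#' @noRd
rankFeaturesMatrix <- function(m, inside) {
  a <- rowStats(m[, inside, drop = FALSE])
  b <- rowStats(m[, !inside, drop = FALSE])
  vp <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
  se <- sqrt(vp * (1 / a$n + 1 / b$n))
  tt <- (a$mean - b$mean) / se
  p <- 2 * pt(-abs(tt), a$n + b$n - 2)
  ok <- a$n >= 2 & b$n >= 2 & is.finite(tt)
  p[!ok] <- NA_real_
  ord <- order(p, -abs(tt), rownames(m), na.last = TRUE)
  data.frame(protein = rownames(m)[ord], statistic = tt[ord],
             p_value = p[ord], stringsAsFactors = FALSE)
}

#' Rank proteins by one-vs-rest discriminative power
#'
#' Proteins sorted by ascending p-value of the one-vs-rest two-sample t-test
#' for \code{targetClass} (see [ttestOVR()]); ties broken by descending
#' absolute t, then lexicographic protein identifier, so the ranking is
#' fully deterministic.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation.
#' @param targetClass class whose markers are sought.
#' @return data.frame: \code{protein}, \code{statistic}, \code{p_value},
#'   best first.
#' @export
rankFeatures <- function(x, targetClass) {
  st <- needSubtypes(x)
  checkClass(st, targetClass)
  rankFeaturesMatrix(logRatios(x), st == targetClass)
}

# Stratified (or plain) test-set index draw; redraws until every class is
# represented in training with >= 2 samples.
#' @noRd
drawTestSet <- function(st, testFraction, stratified) {
  N <- length(st)
  if (stratified) {
    idx <- unlist(lapply(levels(st), function(cl) {
      cand <- which(st == cl)
      sample(cand, max(1, round(testFraction * length(cand))))
    }))
    return(sort(idx))
  }
  for (tries in 1:100) {
    idx <- sort(sample(N, round(testFraction * N)))
    trainTab <- table(st[-idx])
    if (all(trainTab >= 2)) return(idx)
  }
  stop("could not draw a test set leaving >= 2 training samples per class")
}

#' Cross-validated one-vs-rest feature selection
#'
#' The core resampling loop of the signature-discovery framework: in each of
#' \code{nRuns} cross-validation runs a test set of \code{testFraction} of
#' the samples is drawn at random (stratified by class by default), features
#' are ranked \emph{on the training set only} (one-vs-rest t-test per
#' class), and for every signature size on \code{featureGrid} a linear SVM
#' is trained on the training set's top-ranked features and its one-vs-rest
#' accuracy recorded on the test set. The returned curve holds, per class
#' and size, the mean and s.d. of test accuracy over runs; its earliest
#' maximum (see [optimalFeatureCounts()]) defines the optimal signature
#' size.
#'
#' Accuracy here is the fraction of correct binary (class vs rest) calls of
#' that class's model on the test samples.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation and no
#'   missing values (impute first, see [imputeDownshift()]).
#' @param testFraction fraction of samples held out per run (default 0.15).
#' @param nRuns number of random resampling runs (default 250).
#' @param featureGrid increasing signature sizes to evaluate (default 1:30);
#'   truncated with a warning if it exceeds the protein count.
#' @param cost SVM regularization constant (default 1).
#' @param stratified draw test sets per class (default TRUE); unstratified
#'   draws redraw runs whose training set lacks a class.
#' @param seed integer seed; the whole procedure is reproducible from it.
#' @return an \linkS4class{AccuracyCurve}.
#' @export
cvFeatureSelection <- function(x, testFraction = 0.15, nRuns = 250,
                               featureGrid = 1:30, cost = 1,
                               stratified = TRUE, seed = NULL) {
  st <- needSubtypes(x)
  m <- logRatios(x)
  if (anyNA(m))
    stop("matrix contains missing values; impute before classification")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  featureGrid <- sort(unique(as.integer(featureGrid)))
  if (any(featureGrid < 1)) stop("featureGrid must be positive")
  if (max(featureGrid) > nrow(m)) {
    warning("featureGrid truncated to the available ", nrow(m), " proteins")
    featureGrid <- featureGrid[featureGrid <= nrow(m)]
  }
  classes <- levels(st)
  acc <- array(NA_real_,
               c(nRuns, length(classes), length(featureGrid)),
               dimnames = list(NULL, classes, featureGrid))
  withSeed(seed, {
    for (r in seq_len(nRuns)) {
      testIdx <- drawTestSet(st, testFraction, stratified)
      trainM <- m[, -testIdx, drop = FALSE]
      testM <- t(m[, testIdx, drop = FALSE])
      trainSt <- st[-testIdx]
      testSt <- st[testIdx]
      for (ci in seq_along(classes)) {
        cl <- classes[ci]
        ranked <- rankFeaturesMatrix(trainM, trainSt == cl)$protein
        truth <- testSt == cl
        for (gi in seq_along(featureGrid)) {
          g <- featureGrid[gi]
          feats <- ranked[seq_len(g)]
          model <- suppressWarnings(
            trainMarginClassifier(t(trainM[feats, , drop = FALSE]),
                                  trainSt == cl, cost = cost))
          pred <- decisionScores(model, testM) > 0
          acc[r, ci, gi] <- mean(pred == truth)
        }
      }
    }
  })
  curve <- do.call(rbind, lapply(seq_along(classes), function(ci)
    data.frame(class = classes[ci], size = featureGrid,
               mean_accuracy = apply(acc[, ci, , drop = FALSE], 3, mean),
               sd_accuracy = apply(acc[, ci, , drop = FALSE], 3, sd),
               n_runs = nRuns, stringsAsFactors = FALSE)))
  rownames(curve) <- NULL
  new("AccuracyCurve", curve = curve, classes = classes,
      featureGrid = featureGrid, nRuns = as.integer(nRuns))
}

#' Optimal signature size per class
#'
#' The smallest feature count attaining the maximum mean cross-validated
#' accuracy for each class — i.e. the minimum number of proteins that
#' classify with the smallest error.
#'
#' @param curve an \linkS4class{AccuracyCurve}.
#' @return named integer vector (one entry per class).
#' @export
optimalFeatureCounts <- function(curve) {
  cv <- curve@curve
  vapply(curve@classes, function(cl) {
    sub <- cv[cv$class == cl, ]
    sub <- sub[order(sub$size), ]
    sub$size[which.max(sub$mean_accuracy)]
  }, integer(1))
}

#' Extract the final multi-class marker signature
#'
#' Re-ranks features per class on the \emph{full} data, takes the top
#' \code{counts[class]} proteins as that class's markers (direction =
#' sign of the class-vs-rest mean difference), and trains the final
#' one-vs-rest models on exactly those proteins. A protein may legitimately
#' mark more than one class.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation, no missing
#'   values.
#' @param counts named integer vector of per-class signature sizes,
#'   typically from [optimalFeatureCounts()].
#' @param cost SVM regularization constant (default 1).
#' @return a \linkS4class{SubtypeSignature}.
#' @export
extractSignature <- function(x, counts, cost = 1) {
  st <- needSubtypes(x)
  m <- logRatios(x)
  if (anyNA(m))
    stop("matrix contains missing values; impute before classification")
  classes <- levels(st)
  if (is.null(names(counts))) {
    if (length(counts) == 1) counts <- setNames(rep(counts, length(classes)), classes)
    else stop("counts must be named by class")
  }
  missing <- setdiff(classes, names(counts))
  if (length(missing))
    stop("no signature size for class(es): ", paste(missing, collapse = ", "))
  entries <- list()
  models <- list()
  for (cl in classes) {
    ranked <- rankFeatures(x, cl)
    g <- as.integer(counts[[cl]])
    top <- ranked[seq_len(g), ]
    delta <- meanDifference(x, cl)[top$protein]
    entries[[cl]] <- data.frame(
      class = cl, protein = top$protein, rank = seq_len(g),
      direction = ifelse(delta >= 0, "positive", "negative"),
      p_value = top$p_value, stringsAsFactors = FALSE)
    models[[cl]] <- suppressWarnings(
      trainMarginClassifier(t(m[top$protein, , drop = FALSE]),
                            st == cl, cost = cost))
  }
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL
  new("SubtypeSignature", entries = entries, models = models,
      classes = classes)
}

#' Predict subtypes with a trained signature
#'
#' Scores every sample with each class's one-vs-rest model and assigns the
#' label with the largest decision score; exact ties go to the earlier class
#' in the signature's class order. All signature proteins must be present
#' (and non-missing) in the input.
#'
#' @param object a \linkS4class{SubtypeSignature}.
#' @param newdata a \linkS4class{ProteomeSet} or a proteins x samples
#'   matrix.
#' @param scores if \code{TRUE}, also return the per-class decision scores.
#' @return factor of predicted labels (plus a \code{"scores"} attribute when
#'   requested).
#' @aliases predict
#' @export
setMethod("predict", "SubtypeSignature",
          function(object, newdata, scores = FALSE) {
  m <- if (is(newdata, "ProteomeSet")) logRatios(newdata) else as.matrix(newdata)
  needed <- unique(object@entries$protein)
  absent <- setdiff(needed, rownames(m))
  if (length(absent))
    stop("signature feature(s) missing from the input: ",
         paste(absent, collapse = ", "))
  if (anyNA(m[needed, , drop = FALSE])) {
    bad <- needed[rowSums(is.na(m[needed, , drop = FALSE])) > 0]
    stop("missing value(s) for signature feature(s): ",
         paste(bad, collapse = ", "))
  }
  vals <- t(m)
  sc <- vapply(object@classes, function(cl)
    decisionScores(object@models[[cl]], vals), numeric(ncol(m)))
  if (ncol(m) == 1) sc <- matrix(sc, nrow = 1, dimnames = list(colnames(m), object@classes))
  labels <- factor(object@classes[apply(sc, 1, which.max)],
                   levels = object@classes)
  names(labels) <- colnames(m)
  if (scores) attr(labels, "scores") <- sc
  labels
})

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps the decision threshold over the distinct scores (ties grouped) and
#' computes the AUC as the Mann-Whitney probability estimate: the fraction
#' of (positive, negative) pairs in which the positive scores higher, ties
#' counting one half. This equals the trapezoidal area under the returned
#' points.
#'
#' @param scoreValues numeric decision scores, larger = more positive.
#' @param labels logical (TRUE = positive) or a factor/vector with
#'   \code{positiveClass} naming the positive label.
#' @param positiveClass the positive label when \code{labels} is not
#'   logical.
#' @return a \linkS4class{RocCurve}.
#' @export
rocCurve <- function(scoreValues, labels, positiveClass = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positiveClass))
      stop("positiveClass is required for non-logical labels")
    labels <- as.character(labels) == positiveClass
  } else if (is.null(positiveClass)) positiveClass <- "TRUE"
  if (length(scoreValues) != length(labels))
    stop("scores and labels differ in length")
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("both positive and negative labels must be present")
  ord <- order(scoreValues, decreasing = TRUE)
  s <- scoreValues[ord]; l <- labels[ord]
  boundary <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tpr <- c(0, cumsum(l)[boundary] / nPos)
  fpr <- c(0, cumsum(!l)[boundary] / nNeg)
  pts <- data.frame(fpr = fpr, tpr = tpr,
                    threshold = c(Inf, s[boundary]))
  r <- rank(scoreValues)                 # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  new("RocCurve", points = pts, auc = auc,
      positiveClass = as.character(positiveClass))
}
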