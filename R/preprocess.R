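#' Filter proteins by fraction of valid (non-missing) values
#'
#' Retains proteins whose non-missing fraction \emph{strictly} exceeds
#' \code{minFraction} — either across all samples, or (with
#' \code{scope = "per_class"}) in at least one class. The strict inequality
#' matches the usual ">70\% of all samples" phrasing of valid-value filters
#' in quantitative proteomics. Idempotent; never touches the sample set.
#'
#' @param x a \linkS4class{ProteomeSet}.
#' @param minFraction required valid fraction, in (0, 1].
#' @param scope \code{"all_samples"} or \code{"per_class"} (the latter needs
#'   a subtype annotation).
#' @return the filtered \linkS4class{ProteomeSet}.
#' @export
filterMinValid <- function(x, minFraction = 0.7,
                           scope = c("all_samples", "per_class")) {
  scope <- match.arg(scope)
  if (!is.numeric(minFraction) || length(minFraction) != 1 ||
      minFraction <= 0 || minFraction > 1)
    stop("minFraction must lie in (0, 1]")
  obs <- !missingMask(x)
  if (scope == "all_samples") {
    keep <- rowMeans(obs) > minFraction
  } else {
    st <- needSubtypes(x)
    fracs <- vapply(levels(st), function(cl)
      rowMeans(obs[, st == cl, drop = FALSE]), numeric(nrow(x)))
    keep <- apply(fracs, 1, max) > minFraction
  }
  x[keep, ]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Replaces each sample's missing entries by independent draws from
#' \eqn{N(m_s - d \cdot sd_s, (w \cdot sd_s)^2)}, where \eqn{m_s} and
#' \eqn{sd_s} are the mean and standard deviation of that sample's observed
#' values, \eqn{d} the downshift and \eqn{w} the width factor. This encodes
#' the assumption that values are missing because the protein is of low
#' abundance in that sample (missing not at random): imputed values sit in
#' the low tail of the observed distribution, narrowed so they do not inflate
#' variance. Observed entries are never altered, and a fixed seed makes the
#' result reproducible bit for bit.
#'
#' The defaults (width 0.3, downshift 1.8, in units of the per-sample s.d.)
#' are the established defaults of this imputation family in proteomics
#' practice.
#'
#' @param x a \linkS4class{ProteomeSet}; every sample needs >= 2 observed
#'   values.
#' @param widthFactor positive: imputed s.d. as a fraction of the observed
#'   per-sample s.d.
#' @param downshiftFactor non-negative: shift of the imputed mean below the
#'   observed mean, in units of the observed per-sample s.d.
#' @param seed integer seed (NULL: use, and advance, the current RNG stream).
#' @return a \linkS4class{ProteomeSet} without missing values.
#' @export
imputeDownshift <- function(x, widthFactor = 0.3, downshiftFactor = 1.8,
                            seed = NULL) {
  if (!is.numeric(widthFactor) || widthFactor <= 0)
    stop("widthFactor must be > 0")
  if (!is.numeric(downshiftFactor) || downshiftFactor < 0)
    stop("downshiftFactor must be >= 0")
  m <- logRatios(x)
  nObs <- colSums(!is.na(m))
  if (any(nObs < 2))
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(m)[nObs < 2], collapse = ", "))
  withSeed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      obs <- m[!miss, j]
      mu <- mean(obs); s <- sd(obs)
      m[miss, j] <- rnorm(sum(miss),
                          mean = mu - downshiftFactor * s,
                          sd = widthFactor * s)
    }
  })
  out <- x
  SummarizedExperiment::assay(out, "logratio") <- m
  out
}

#' Pairwise sample correlation and hierarchical clustering
#'
#' Pearson correlation between every pair of samples on proteins observed in
#' both (pairwise-complete, so unimputed data can be used), followed by
#' agglomerative hierarchical clustering on the distance \eqn{1 - r}. Sample
#' pairs sharing fewer than 3 observed proteins get a missing correlation and
#' the samples involved are excluded from the clustering, with a warning.
#'
#' @param x a \linkS4class{ProteomeSet} with >= 2 samples.
#' @param linkage \code{"average"} or \code{"complete"}.
#' @return list with elements \code{correlations} (symmetric matrix,
#'   diagonal 1), \code{nShared} (shared observed-protein counts),
#'   \code{clustering} (an \code{\link[stats]{hclust}} object, or NULL if
#'   fewer than 2 samples were clusterable) and \code{linkage}.
#' @export
correlationStructure <- function(x, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  m <- logRatios(x)
  if (ncol(m) < 2) stop("at least 2 samples are required")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(m))
  low <- shared < 3
  diag(low) <- FALSE
  if (any(low)) {
    warning("sample pair(s) with < 3 shared observed proteins; ",
            "correlation set to NA and sample(s) excluded from clustering")
    r[low] <- NA_real_
  }
  diag(r) <- 1
  # greedily drop the samples responsible for missing correlations
  usable <- colnames(r)
  repeat {
    sub <- r[usable, usable, drop = FALSE]
    naCount <- colSums(is.na(sub))
    if (!any(naCount > 0) || length(usable) <= 2) break
    usable <- usable[-which.max(naCount)]
  }
  clustering <- NULL
  if (length(usable) >= 2 &&
      !anyNA(r[usable, usable])) {
    d <- as.dist(1 - r[usable, usable, drop = FALSE])
    clustering <- hclust(d, method = linkage)
  }
  list(correlations = r, nShared = shared, clustering = clustering,
       linkage = linkage)
}
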