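#' One-vs-rest mean expression difference per protein
#'
#' For every protein, the mean of its observed values in \code{targetClass}
#' minus the mean of its observed values in all other classes. Proteins
#' lacking an observed value on either side get \code{NA}.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation.
#' @param targetClass class label to contrast against the rest.
#' @return named numeric vector of mean differences (log2 units).
#' @export
meanDifference <- function(x, targetClass) {
  st <- needSubtypes(x)
  checkClass(st, targetClass)
  m <- logRatios(x)
  inside <- st == targetClass
  sIn <- rowStats(m[, inside, drop = FALSE])
  sOut <- rowStats(m[, !inside, drop = FALSE])
  d <- sIn$mean - sOut$mean
  d[sIn$n < 1 | sOut$n < 1] <- NA_real_
  setNames(d, rownames(m))
}

# Two-sided p for the rank-sum shift of the members at memberIdx: exact
# enumeration of all C(n, n_in) placements among the (possibly tied) ranks
# when n <= 12, else normal approximation with tie and continuity correction.
#' @noRd
rankShiftP <- function(ranks, memberIdx) {
  n <- length(ranks)
  nIn <- length(memberIdx)
  W <- sum(ranks[memberIdx])
  mu <- nIn * (n + 1) / 2
  if (n <= 12) {
    sums <- combn(ranks, nIn, FUN = sum)
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-12)
  } else {
    nOut <- n - nIn
    ties <- table(ranks)
    tieAdj <- sum(ties^3 - ties)
    sigma2 <- nIn * nOut / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
  }
  max(p, .Machine$double.xmin)
}

#' One-dimensional annotation enrichment over protein-level values
#'
#' Rank-based test asking, for every category, whether the values of its
#' member proteins are shifted relative to the global value distribution.
#' Proteins are ranked ascending (average ranks for ties); with \eqn{n}
#' scored proteins of which \eqn{n_{in}} are members, the enrichment score is
#' \deqn{s = 2 (\bar r_{in} - (n+1)/2) / (n - n_{in}),}
#' which is +1 exactly when the members occupy the \eqn{n_{in}} highest ranks
#' and -1 for the lowest. Significance is the two-sided Wilcoxon-Mann-Whitney
#' test: exact enumeration of all rank placements for \eqn{n \le 12}, a
#' normal approximation with tie and continuity correction above. P-values
#' are Benjamini-Hochberg corrected across all tested categories.
#'
#' Proteins without a value (e.g. no mean difference computable) are dropped
#' from the ranking; categories with fewer than \code{minSize} scored members
#' or spanning all scored proteins are excluded.
#'
#' @param values named numeric vector (typically from [meanDifference()]);
#'   NAs are dropped.
#' @param categories a \linkS4class{CategoryMap}.
#' @param minSize minimum member count with data (default 5).
#' @param fdr Benjamini-Hochberg level for the \code{significant} flag
#'   (default 0.05).
#' @param pThreshold optional raw p-value cutoff; when given, the
#'   \code{significant} flag uses \code{p_value < pThreshold} instead of the
#'   BH criterion (some analyses of this kind were historically reported at a
#'   raw p cutoff).
#' @return data.frame: \code{category}, \code{n_in}, \code{score},
#'   \code{p_value}, \code{q_value}, \code{significant}, ordered by p.
#' @export
enrichment1D <- function(values, categories, minSize = 5, fdr = 0.05,
                         pThreshold = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (length(unique(values)) < 2)
    stop("values must contain at least 2 distinct finite entries")
  ranks <- rank(values, ties.method = "average")
  idx <- seq_len(n)
  names(idx) <- names(values)
  res <- lapply(categoryNames(categories), function(nm) {
    memberIdx <- idx[intersect(categoryMembers(categories)[[nm]], names(idx))]
    nIn <- length(memberIdx)
    if (nIn < minSize || nIn == n) return(NULL)
    meanRankIn <- mean(ranks[memberIdx])
    s <- 2 * (meanRankIn - (n + 1) / 2) / (n - nIn)
    p <- rankShiftP(ranks, memberIdx)
    data.frame(category = nm, n_in = nIn, score = s, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(category = character(), n_in = integer(),
                      score = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- if (is.null(pThreshold)) res$q_value <= fdr
                     else res$p_value < pThreshold
  res <- res[order(res$p_value, res$category), ]
  rownames(res) <- NULL
  res
}

#' Two-level hierarchical enrichment across all classes
#'
#' For every class: computes the one-vs-rest mean difference per protein,
#' then runs [enrichment1D()] once at the leaf level and once at the parent
#' level of the category hierarchy. A parent category's member set is the
#' union of its children's members (a protein shared by several children
#' counts once). Categories without a parent link are tested alongside the
#' leaves but labelled hierarchy level \code{"none"} (warned once per call).
#' BH correction is applied independently per class and level.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation.
#' @param categories a \linkS4class{CategoryMap}; parent links required for
#'   the parent level (without any, only the leaf level is produced).
#' @param minSize,fdr,pThreshold passed to [enrichment1D()].
#' @param classes classes to test (default: all).
#' @return data.frame with the [enrichment1D()] columns plus \code{class}
#'   and \code{level} ("leaf", "parent" or "none").
#' @export
hierarchyEnrichment <- function(x, categories, minSize = 5, fdr = 0.05,
                                pThreshold = NULL, classes = NULL) {
  st <- needSubtypes(x)
  if (is.null(classes)) classes <- levels(st)
  parents <- categoryParents(categories)
  members <- categoryMembers(categories)
  orphan <- setdiff(names(members), names(parents))
  if (length(parents) && length(orphan))
    warning("categor(ies) without a parent link treated as level 'none': ",
            paste(head(orphan, 5), collapse = ", "),
            if (length(orphan) > 5) ", ...")
  parentMembers <- list()
  if (length(parents)) {
    for (pa in unique(parents)) {
      kids <- names(parents)[parents == pa]
      parentMembers[[pa]] <- unique(unlist(members[kids], use.names = FALSE))
    }
  }
  out <- lapply(classes, function(cl) {
    vals <- meanDifference(x, cl)
    leaf <- enrichment1D(vals, categories, minSize = minSize, fdr = fdr,
                         pThreshold = pThreshold)
    if (nrow(leaf))
      leaf$level <- ifelse(leaf$category %in% names(parents) |
                             length(parents) == 0, "leaf", "none")
    else leaf$level <- character(0)
    res <- leaf
    if (length(parentMembers)) {
      par <- enrichment1D(vals, CategoryMap(parentMembers), minSize = minSize,
                          fdr = fdr, pThreshold = pThreshold)
      if (nrow(par)) par$level <- "parent" else par$level <- character(0)
      res <- rbind(res, par)
    }
    if (nrow(res)) res$class <- cl else res$class <- character(0)
    res
  })
  out <- do.call(rbind, out)
  cols <- c("class", "level", "category", "n_in", "score", "p_value",
            "q_value", "significant")
  out <- out[, cols]
  rownames(out) <- NULL
  out
}
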