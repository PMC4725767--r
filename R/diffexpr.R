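#' One-vs-rest two-sample t-tests per protein
#'
#' Student's two-sample t-test (pooled variance, two-sided) of every
#' protein's expression in \code{targetClass} against all remaining samples.
#' The statistic is positive when the target-class mean is higher. Proteins
#' with fewer than 2 observed values on either side are reported with
#' \code{NA} statistic and p-value rather than dropped.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation.
#' @param targetClass class label to contrast against the rest.
#' @param s0 variance fudge constant added to the denominator of the
#'   t-statistic (0 = plain t); stabilizes small-variance proteins in the
#'   SAM tradition. The p-value always refers to the plain statistic.
#' @return data.frame: \code{protein}, \code{statistic}, \code{p_value},
#'   \code{n_in}, \code{n_out}, in matrix row order.
#' @export
ttestOVR <- function(x, targetClass, s0 = 0) {
  st <- needSubtypes(x)
  checkClass(st, targetClass)
  m <- logRatios(x)
  inside <- st == targetClass
  if (sum(!inside) == 0) stop("no samples outside class '", targetClass, "'")
  a <- rowStats(m[, inside, drop = FALSE])
  b <- rowStats(m[, !inside, drop = FALSE])
  ok <- a$n >= 2 & b$n >= 2
  vp <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
  se <- sqrt(vp * (1 / a$n + 1 / b$n))
  tt <- (a$mean - b$mean) / se
  df <- a$n + b$n - 2
  p <- 2 * pt(-abs(tt), df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  stat <- if (s0 > 0) (a$mean - b$mean) / (se + s0) else tt
  stat[!ok] <- NA_real_
  p[!ok] <- NA_real_
  data.frame(protein = rownames(m), statistic = stat, p_value = p,
             n_in = a$n, n_out = b$n, stringsAsFactors = FALSE)
}

# Vectorized one-way fixed-effects ANOVA over the classes of `st`.
# Returns F, p, df1, df2 per row; rows where any class has < 2 observed
# values get NA. All-equal rows follow the F = 0, p = 1 convention.
#' @noRd
anovaFVec <- function(m, st) {
  k <- nlevels(st)
  groups <- lapply(levels(st), function(cl) rowStats(m[, st == cl, drop = FALSE]))
  ns <- vapply(groups, `[[`, numeric(nrow(m)), "n")
  mus <- vapply(groups, `[[`, numeric(nrow(m)), "mean")
  vars <- vapply(groups, `[[`, numeric(nrow(m)), "var")
  if (nrow(m) == 1) { ns <- rbind(ns); mus <- rbind(mus); vars <- rbind(vars) }
  ok <- rowSums(ns >= 2) == k
  N <- rowSums(ns)
  grand <- rowSums(ns * mus) / N
  ssb <- rowSums(ns * (mus - grand)^2)
  ssw <- rowSums((ns - 1) * vars)
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  # degenerate: no within- and no between-variance => non-significant
  zero <- ok & ssw <= 0 & ssb <= 1e-300
  f[zero] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[zero] <- 1
  f[!ok] <- NA_real_
  p[!ok] <- NA_real_
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' One-way ANOVA across all classes, per protein
#'
#' Fixed-effects one-way analysis of variance of each protein over the
#' \eqn{k} subtype classes, with p-values from the F distribution on
#' \eqn{(k-1, N-k)} degrees of freedom (\eqn{N} = observed values for that
#' protein). Proteins where any class has fewer than 2 observed values are
#' reported with \code{NA}. A protein with zero within- and between-class
#' variance gets \eqn{F = 0}, \eqn{p = 1}.
#'
#' @param x a \linkS4class{ProteomeSet} with >= 2 annotated classes.
#' @return data.frame: \code{protein}, \code{statistic} (F), \code{p_value},
#'   \code{df1}, \code{df2}.
#' @export
anovaF <- function(x) {
  st <- needSubtypes(x)
  m <- logRatios(x)
  r <- anovaFVec(m, st)
  data.frame(protein = rownames(m), statistic = r$f, p_value = r$p,
             df1 = r$df1, df2 = rowSums(!is.na(m)) - nlevels(st),
             stringsAsFactors = FALSE)
}

# All distinct permutations of a label multiset (used when the requested
# permutation count exceeds the number of distinct relabelings).
#' @noRd
multisetPermutations <- function(labels) {
  rec <- function(counts, lev) {
    if (sum(counts) == 0) return(list(character(0)))
    out <- list()
    for (i in seq_along(lev)) {
      if (counts[i] == 0) next
      counts2 <- counts
      counts2[i] <- counts2[i] - 1
      for (tail in rec(counts2, lev))
        out[[length(out) + 1]] <- c(lev[i], tail)
    }
    out
  }
  lev <- levels(factor(labels))
  counts <- as.integer(table(factor(labels, levels = lev)))
  rec(counts, lev)
}

#' Permutation-based false discovery rate for per-protein statistics
#'
#' Computes the observed statistic vector once (ANOVA F across classes, or
#' the absolute one-vs-rest t), then recomputes it under random relabelings
#' of the samples that preserve class sizes. For a threshold \eqn{c}, the
#' estimated FDR is the median over permutations of the number of
#' permutation statistics \eqn{\ge c}, divided by the number of observed
#' statistics \eqn{\ge c}. Each protein's q-value is the smallest estimated
#' FDR over all candidate thresholds at or below its own statistic
#' (candidate thresholds are the observed statistics themselves), which
#' makes q non-increasing in the statistic by construction.
#'
#' When fewer distinct relabelings exist than requested, all distinct ones
#' are used, with a warning. Proteins with insufficient data for the
#' observed statistic carry \code{NA} and are excluded from both counts.
#'
#' @param x a \linkS4class{ProteomeSet} with subtype annotation.
#' @param statistic \code{"anovaF"} or \code{"ttestOVR"}.
#' @param targetClass required for \code{"ttestOVR"}; ignored otherwise.
#' @param nPermutations number of relabelings (>= 25; default 250).
#' @param level FDR level for the \code{significant} flag (default 0.05).
#' @param s0 variance fudge constant for the t route (see [ttestOVR()]);
#'   ignored for the F route.
#' @param seed integer seed for the relabelings.
#' @return data.frame: \code{protein}, \code{statistic} (F or t, signed),
#'   \code{p_value} (parametric), \code{q_value} (permutation FDR),
#'   \code{significant}.
#' @export
permutationFDR <- function(x, statistic = c("anovaF", "ttestOVR"),
                           targetClass = NULL, nPermutations = 250,
                           level = 0.05, s0 = 0, seed = NULL) {
  statistic <- match.arg(statistic)
  if (nPermutations < 25) stop("nPermutations must be >= 25")
  st <- needSubtypes(x)
  m <- logRatios(x)

  if (statistic == "anovaF") {
    statFun <- function(lab) anovaFVec(m, lab)$f
    obsTab <- anovaF(x)
  } else {
    if (is.null(targetClass)) stop("targetClass is required for ttestOVR")
    checkClass(st, targetClass)
    tFun <- function(lab) {
      inside <- lab == targetClass
      a <- rowStats(m[, inside, drop = FALSE])
      b <- rowStats(m[, !inside, drop = FALSE])
      ok <- a$n >= 2 & b$n >= 2
      vp <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
      se <- sqrt(vp * (1 / a$n + 1 / b$n))
      tt <- (a$mean - b$mean) / (se + s0)
      tt[!ok] <- NA_real_
      tt
    }
    statFun <- function(lab) abs(tFun(lab))
    obsTab <- ttestOVR(x, targetClass, s0 = s0)
  }
  obsSigned <- obsTab$statistic
  obs <- if (statistic == "anovaF") obsSigned else abs(obsSigned)

  nDistinctLog <- lgamma(length(st) + 1) - sum(lgamma(table(st) + 1))
  permLabels <- NULL
  if (nDistinctLog <= log(nPermutations)) {
    warning("only ", round(exp(nDistinctLog)),
            " distinct relabelings exist; using all of them")
    permLabels <- lapply(multisetPermutations(as.character(st)),
                         function(l) factor(l, levels = levels(st)))
  }
  permStats <- withSeed(seed, {
    if (is.null(permLabels))
      permLabels <- replicate(nPermutations, sample(st), simplify = FALSE)
    lapply(permLabels, statFun)
  })

  ok <- !is.na(obs)
  so <- sort(obs[ok])
  thr <- unique(so)
  nObsGE <- length(so) - findInterval(thr, so, left.open = TRUE)
  permGE <- vapply(permStats, function(ps) {
    sp <- sort(ps[!is.na(ps)])
    length(sp) - findInterval(thr, sp, left.open = TRUE)
  }, numeric(length(thr)))
  if (length(thr) == 1) permGE <- matrix(permGE, nrow = 1)
  medPerm <- apply(permGE, 1, median)
  fdrAt <- pmin(1, medPerm / nObsGE)
  # q for a protein at threshold thr[j] = min FDR over thresholds at or
  # below its statistic = running minimum over ascending thresholds; this
  # is non-increasing in the statistic by construction
  qAt <- cummin(fdrAt)
  q <- rep(NA_real_, length(obs))
  q[ok] <- qAt[match(obs[ok], thr)]
  data.frame(protein = obsTab$protein, statistic = obsSigned,
             p_value = obsTab$p_value, q_value = q,
             significant = !is.na(q) & q <= level,
             stringsAsFactors = FALSE)
}
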