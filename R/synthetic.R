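#' Configuration of the synthetic cohort generator
#'
#' Builds a validated configuration list for [generateSynthetic()]. The
#' defaults describe a tumour-cohort-like scenario: 3 subtype classes of
#' 14/15/11 samples, 2,000 proteins, 5 markers per class at 2.5 times the
#' noise s.d., and 20\% abundance-dependent (missing-not-at-random)
#' missingness.
#'
#' @param nClasses number of subtype classes.
#' @param samplesPerClass per-class sample counts (scalar recycled).
#' @param nProteins number of proteins.
#' @param markersPerClass planted markers per class (drawn without
#'   replacement across classes).
#' @param markerEffect absolute marker effect, log2 units; each marker's
#'   sign is random and recorded in the truth.
#' @param nEnrichedCategories number of planted shifted categories.
#' @param categorySize members per category (disjoint, non-marker
#'   proteins).
#' @param categoryShift additive shift of category members in their class
#'   (log2 units).
#' @param nNullCategories additional unshifted categories emitted alongside
#'   the planted ones (default: same number).
#' @param noiseSd sample-level Gaussian noise s.d. (log2 units).
#' @param proteinBaselineSd s.d. of per-protein baseline log-ratios.
#' @param missingTargetFraction target fraction of censored entries, in
#'   [0, 1).
#' @param mnarSteepness steepness of the logistic abundance-dependent
#'   censoring; 0 means missingness is uniform (value-independent).
#' @param seed integer seed.
#' @return a named list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(nClasses = 3,
                            samplesPerClass = c(14, 15, 11),
                            nProteins = 2000,
                            markersPerClass = 5,
                            markerEffect = 2.0,
                            nEnrichedCategories = 10,
                            categorySize = 30,
                            categoryShift = 0.5,
                            nNullCategories = nEnrichedCategories,
                            noiseSd = 0.8,
                            proteinBaselineSd = 1.0,
                            missingTargetFraction = 0.2,
                            mnarSteepness = 2,
                            seed = 1) {
  cfg <- list(nClasses = as.integer(nClasses),
              samplesPerClass = rep_len(as.integer(samplesPerClass), nClasses),
              nProteins = as.integer(nProteins),
              markersPerClass = as.integer(markersPerClass),
              markerEffect = markerEffect,
              nEnrichedCategories = as.integer(nEnrichedCategories),
              categorySize = as.integer(categorySize),
              categoryShift = categoryShift,
              nNullCategories = as.integer(nNullCategories),
              noiseSd = noiseSd,
              proteinBaselineSd = proteinBaselineSd,
              missingTargetFraction = missingTargetFraction,
              mnarSteepness = mnarSteepness,
              seed = as.integer(seed))
  if (cfg$nClasses < 2) stop("nClasses must be >= 2")
  if (any(cfg$samplesPerClass < 2)) stop("every class needs >= 2 samples")
  if (cfg$markersPerClass * cfg$nClasses > cfg$nProteins)
    stop("more markers than proteins")
  needed <- cfg$markersPerClass * cfg$nClasses +
    (cfg$nEnrichedCategories + cfg$nNullCategories) * cfg$categorySize
  if (needed > cfg$nProteins)
    stop("markers plus disjoint categories exceed the protein count (",
         needed, " > ", cfg$nProteins, ")")
  if (cfg$missingTargetFraction < 0 || cfg$missingTargetFraction >= 1)
    stop("missingTargetFraction must lie in [0, 1)")
  if (cfg$mnarSteepness < 0) stop("mnarSteepness must be >= 0")
  if (cfg$noiseSd <= 0 || cfg$proteinBaselineSd < 0)
    stop("noiseSd must be > 0 and proteinBaselineSd >= 0")
  class(cfg) <- "syntheticConfig"
  cfg
}

#' @noRd
classNamesFor <- function(k) {
  if (k == 3) c("ERPR", "Her2", "TN") else paste0("class", seq_len(k))
}

# Censor `complete` with P(missing) = plogis(steepness * (tau - value)),
# tau solved so the expected missing fraction hits the target; steepness 0
# degenerates to uniform Bernoulli(target) censoring.
#' @noRd
censorMNAR <- function(complete, targetFraction, steepness) {
  if (targetFraction == 0)
    return(list(mask = matrix(FALSE, nrow(complete), ncol(complete)),
                tau = -Inf))
  if (steepness == 0) {
    mask <- matrix(runif(length(complete)) < targetFraction,
                   nrow(complete), ncol(complete))
    return(list(mask = mask, tau = NA_real_))
  }
  v <- as.vector(complete)
  f <- function(tau) mean(plogis(steepness * (tau - v))) - targetFraction
  lo <- min(v) - 40 / steepness
  hi <- max(v) + 40 / steepness
  tau <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  prob <- plogis(steepness * (tau - complete))
  mask <- matrix(runif(length(complete)) < prob,
                 nrow(complete), ncol(complete))
  list(mask = mask, tau = tau)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emulates the statistical structure of a super-SILAC tumour-cohort
#' log-ratio matrix: each protein has a baseline log2 ratio
#' \eqn{b_p \sim N(0, \sigma_b^2)}; a sample of class \eqn{c} observes
#' \eqn{b_p + e_{p,c} + \epsilon} with \eqn{\epsilon \sim N(0, \sigma^2)}.
#' Planted markers carry a signed effect of magnitude \code{markerEffect}
#' in their class; members of planted enriched categories carry
#' \code{categoryShift} in theirs. Entries are then censored missing with
#' probability \eqn{logistic(steepness (\tau - value))}, \eqn{\tau} chosen
#' so the expected missing fraction equals the target — low-abundance
#' values go missing preferentially, as in real data. The complete
#' (pre-censoring) matrix, all planted effects and the censoring threshold
#' are retained in the truth object, so recovery and imputation behaviour
#' can be tested exactly. Identical configuration (seed included) gives
#' bit-identical output.
#'
#' @param config a list from [syntheticConfig()].
#' @return list with elements \code{matrix} (\linkS4class{ProteomeSet} with
#'   subtypes assigned), \code{categories} (\linkS4class{CategoryMap}:
#'   planted and null categories, grouped in pairs under two-level parent
#'   links), and \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
generateSynthetic <- function(config = syntheticConfig()) {
  cfg <- config
  k <- cfg$nClasses
  classes <- classNamesFor(k)
  st <- factor(rep(classes, cfg$samplesPerClass), levels = classes)
  N <- length(st)
  sampleNames <- paste0(st, "_", unlist(lapply(cfg$samplesPerClass, seq_len)))
  proteins <- sprintf("P%05d", seq_len(cfg$nProteins))

  withSeed(cfg$seed, {
    baselines <- rnorm(cfg$nProteins, 0, cfg$proteinBaselineSd)
    names(baselines) <- proteins

    effects <- matrix(0, cfg$nProteins, k, dimnames = list(proteins, classes))
    pool <- seq_len(cfg$nProteins)
    markerIdx <- sample(pool, cfg$markersPerClass * k)
    pool <- setdiff(pool, markerIdx)
    markers <- data.frame(class = rep(classes, each = cfg$markersPerClass),
                          protein = proteins[markerIdx],
                          effect = sample(c(-1, 1), cfg$markersPerClass * k,
                                          replace = TRUE) * cfg$markerEffect,
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(markers)))
      effects[markers$protein[i], markers$class[i]] <- markers$effect[i]

    nCat <- cfg$nEnrichedCategories + cfg$nNullCategories
    members <- list()
    catTruth <- data.frame(category = character(), class = character(),
                           shift = numeric(), stringsAsFactors = FALSE)
    if (nCat > 0) {
      catIdx <- sample(pool, nCat * cfg$categorySize)
      catMat <- matrix(catIdx, nrow = cfg$categorySize)
      for (j in seq_len(nCat)) {
        nm <- if (j <= cfg$nEnrichedCategories)
          sprintf("SHIFTED_%02d", j) else
          sprintf("NULL_%02d", j - cfg$nEnrichedCategories)
        members[[nm]] <- proteins[catMat[, j]]
        if (j <= cfg$nEnrichedCategories) {
          cl <- classes[(j - 1) %% k + 1]
          effects[members[[nm]], cl] <- effects[members[[nm]], cl] +
            cfg$categoryShift
          catTruth <- rbind(catTruth, data.frame(
            category = nm, class = cl, shift = cfg$categoryShift,
            stringsAsFactors = FALSE))
        }
      }
    }
    # two-level hierarchy: consecutive pairs of categories share a parent
    parents <- character()
    if (length(members) >= 2) {
      nms <- names(members)
      parents <- setNames(sprintf("PARENT_%02d",
                                  (seq_along(nms) - 1) %/% 2 + 1), nms)
    }

    complete <- baselines + effects[, as.integer(st)] +
      matrix(rnorm(cfg$nProteins * N, 0, cfg$noiseSd), cfg$nProteins, N)
    dimnames(complete) <- list(proteins, sampleNames)

    cens <- censorMNAR(complete, cfg$missingTargetFraction, cfg$mnarSteepness)
    observed <- complete
    observed[cens$mask] <- NA_real_

    truth <- new("SyntheticTruth",
                 markers = markers, categories = catTruth,
                 completeMatrix = complete, baselines = baselines,
                 classEffects = effects,
                 realizedMissingFraction = mean(cens$mask),
                 tau = cens$tau, config = unclass(cfg))
    pset <- ProteomeSet(observed, subtype = st)
    list(matrix = pset,
         categories = CategoryMap(members, parents),
         truth = truth)
  })
}

#' Draw additional samples from an existing synthetic population
#'
#' Uses the baselines, planted effects, noise level and censoring threshold
#' stored in a \linkS4class{SyntheticTruth} to generate new samples from the
#' same population — e.g. an honest held-out test cohort for a classifier
#' trained on the original draw.
#'
#' @param truth a \linkS4class{SyntheticTruth} from [generateSynthetic()].
#' @param samplesPerClass per-class sample counts (default: the original
#'   configuration's).
#' @param seed integer seed (should differ from the generating seed).
#' @return a \linkS4class{ProteomeSet} with subtypes assigned.
#' @export
generateFromTruth <- function(truth, samplesPerClass = NULL, seed = 1) {
  cfg <- truth@config
  classes <- colnames(truth@classEffects)
  if (is.null(samplesPerClass)) samplesPerClass <- cfg$samplesPerClass
  samplesPerClass <- rep_len(as.integer(samplesPerClass), length(classes))
  st <- factor(rep(classes, samplesPerClass), levels = classes)
  N <- length(st)
  proteins <- names(truth@baselines)
  sampleNames <- paste0("new_", st, "_",
                        unlist(lapply(samplesPerClass, seq_len)))
  withSeed(seed, {
    complete <- truth@baselines + truth@classEffects[, as.integer(st)] +
      matrix(rnorm(length(proteins) * N, 0, cfg$noiseSd), length(proteins), N)
    dimnames(complete) <- list(proteins, sampleNames)
    if (cfg$missingTargetFraction > 0) {
      if (cfg$mnarSteepness == 0) {
        mask <- matrix(runif(length(complete)) < cfg$missingTargetFraction,
                       nrow(complete), ncol(complete))
      } else {
        prob <- plogis(cfg$mnarSteepness * (truth@tau - complete))
        mask <- matrix(runif(length(complete)) < prob,
                       nrow(complete), ncol(complete))
      }
      complete[mask] <- NA_real_
    }
    ProteomeSet(complete, subtype = st)
  })
}

#' The default synthetic study
#'
#' A fixed full-study-scale scenario: 3 classes (ERPR/Her2/TN) of 14/15/11
#' samples, 7,000 proteins, 5 markers per class at 0.8 log2 units (markers
#' with sub-twofold differences, as typical of macrodissected tumour
#' tissue), 10 enriched categories of 30 proteins, and 15\% missingness
#' with abundance-dependent censoring (steepness 2).
#'
#' @param seed integer seed.
#' @return as [generateSynthetic()].
#' @export
makeDefaultStudy <- function(seed = 1) {
  generateSynthetic(syntheticConfig(
    nClasses = 3, samplesPerClass = c(14, 15, 11), nProteins = 7000,
    markersPerClass = 5, markerEffect = 0.8,
    nEnrichedCategories = 10, categorySize = 30, categoryShift = 0.5,
    noiseSd = 0.8, proteinBaselineSd = 1.0,
    missingTargetFraction = 0.15, mnarSteepness = 2, seed = seed))
}
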