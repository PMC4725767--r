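# Shared fixture builders; everything is generated in code.

# Small ProteomeSet with controllable missingness.
makeTinySet <- function(nProteins = 20, nSamples = 9, classes = c("A", "B", "C"),
                        missingFraction = 0, seed = 42) {
  stopifnot(nSamples %% length(classes) == 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- matrix(rnorm(nProteins * nSamples), nProteins, nSamples,
              dimnames = list(sprintf("P%03d", seq_len(nProteins)),
                              sprintf("S%02d", seq_len(nSamples))))
  if (missingFraction > 0)
    m[sample(length(m), round(missingFraction * length(m)))] <- NA
  ProteomeSet(m, subtype = rep(classes, each = nSamples / length(classes)))
}

# Independent brute-force oracle for the 1D enrichment score and two-sided
# p-value: full enumeration of index subsets.
oracleEnrichment <- function(values, memberIdx) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  nIn <- length(memberIdx)
  s <- 2 * (mean(r[memberIdx]) - (n + 1) / 2) / (n - nIn)
  W <- sum(r[memberIdx])
  mu <- nIn * (n + 1) / 2
  subsets <- utils::combn(n, nIn)
  allW <- apply(subsets, 2, function(j) sum(r[j]))
  p <- mean(abs(allW - mu) >= abs(W - mu) - 1e-12)
  list(score = s, p = p)
}

# Independent pairwise AUC oracle: fraction of (positive, negative) pairs
# won by the positive, ties counting one half.
oracleAUC <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

writeTempTable <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
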