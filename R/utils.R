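# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL uses (and advances) the current stream.
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  seed <- as.integer(seed)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Row-wise mean/var/count over a matrix with NAs, vectorized.
#' @noRd
rowStats <- function(m) {
  obs <- !is.na(m)
  n <- rowSums(obs)
  s <- rowSums(m, na.rm = TRUE)
  mu <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(m^2, na.rm = TRUE)
  v <- ifelse(n > 1, (ss - n * mu^2) / (n - 1), NA_real_)
  v[!is.na(v) & v < 0] <- 0  # guard tiny negative from cancellation
  list(n = n, mean = mu, var = v)
}

# Resolve a subtype factor, erroring when absent.
#' @noRd
needSubtypes <- function(x) {
  st <- subtypes(x)
  if (is.null(st))
    stop("ProteomeSet has no subtype annotation; assign with subtypes(x) <- ...")
  if (nlevels(st) < 2) stop("at least 2 classes are required")
  st
}

#' @noRd
checkClass <- function(st, targetClass) {
  if (!targetClass %in% levels(st))
    stop("class '", targetClass, "' not present in the annotation")
  if (sum(st == targetClass) == 0) stop("class '", targetClass, "' has no samples")
}
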