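#' Read a proteins x samples expression table
#'
#' Reads tab-separated quantitative proteomics tables into a
#' \linkS4class{ProteomeSet} in log2 sample/standard orientation, whatever the
#' orientation on disk. Two dialects are supported: \code{"generic"} (first
#' column protein identifiers, remaining columns one sample each) and
#' \code{"maxquant"} (a protein-groups export, whose ratio columns are
#' recognized by a column-name prefix and whose sample names are the
#' remainders after that prefix).
#'
#' Non-numeric cells, empty cells, non-finite values and (before logging)
#' zeros all become missing: a zero SILAC ratio is a non-detection artifact,
#' not a measurement. Super-SILAC protein-groups tables conventionally report
#' normalized heavy/light ratios, i.e. standard over sample, so the maxquant
#' dialect defaults to \code{ratioOrientation = "standard_over_sample"}
#' (sign-inverted after log); the generic dialect defaults to
#' \code{"sample_over_standard"}. Both defaults can be overridden.
#'
#' @param path path to a tab-separated file.
#' @param dialect \code{"generic"} or \code{"maxquant"}.
#' @param ratioOrientation \code{"sample_over_standard"} or
#'   \code{"standard_over_sample"}; default depends on \code{dialect} (see
#'   Details).
#' @param logAlready if \code{TRUE}, values on disk are already log2 ratios
#'   and are not re-logged (orientation inversion is then a sign flip).
#' @param ratioPrefix maxquant dialect only: prefix identifying ratio columns
#'   (default \code{"Ratio H/L normalized "}).
#' @param idColumn identifier column name; default: first column (generic) or
#'   \code{"Majority protein IDs"} when present (maxquant).
#' @return a \linkS4class{ProteomeSet}.
#' @seealso [writeExpressionMatrix()] for the round-trip writer.
#' @export
readExpressionMatrix <- function(path,
                                 dialect = c("generic", "maxquant"),
                                 ratioOrientation = NULL,
                                 logAlready = FALSE,
                                 ratioPrefix = "Ratio H/L normalized ",
                                 idColumn = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(ratioOrientation))
    ratioOrientation <- if (dialect == "maxquant") "standard_over_sample"
                        else "sample_over_standard"
  ratioOrientation <- match.arg(ratioOrientation,
                                c("sample_over_standard", "standard_over_sample"))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (dialect == "generic") {
    if (is.null(idColumn)) idColumn <- names(tab)[1]
    valueIdx <- which(names(tab) != idColumn)
  } else {
    if (is.null(idColumn))
      idColumn <- if ("Majority protein IDs" %in% names(tab))
        "Majority protein IDs" else names(tab)[1]
    valueIdx <- which(startsWith(names(tab), ratioPrefix))
    if (length(valueIdx) == 0)
      stop("no ratio columns with prefix '", ratioPrefix, "' found in ", path)
  }
  ids <- tab[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate protein identifier: ", ids[duplicated(ids)][1])
  valueCols <- names(tab)[valueIdx]
  sampleNames <- if (dialect == "maxquant")
    substring(valueCols, nchar(ratioPrefix) + 1) else valueCols
  if (anyDuplicated(sampleNames))
    stop("duplicate sample identifier: ", sampleNames[duplicated(sampleNames)][1])
  vals <- suppressWarnings(
    vapply(valueIdx, function(ci) as.numeric(tab[[ci]]), numeric(nrow(tab))))
  if (nrow(tab) == 1) vals <- matrix(vals, nrow = 1)
  vals[!is.finite(vals)] <- NA_real_
  if (!logAlready) {
    vals[!is.na(vals) & vals == 0] <- NA_real_  # zero ratio = non-detection
    vals <- log2(vals)
    vals[!is.finite(vals)] <- NA_real_
  }
  if (ratioOrientation == "standard_over_sample") vals <- -vals
  dimnames(vals) <- list(ids, sampleNames)
  ProteomeSet(vals)
}

#' Write an expression matrix as a generic tab-separated table
#'
#' Values are written at full double precision (17 significant digits) so a
#' read-back with \code{logAlready = TRUE} is bit-identical; missing entries
#' are written as empty cells.
#'
#' @param x a \linkS4class{ProteomeSet}.
#' @param path output path.
#' @param idHeader name of the identifier column (default "Protein").
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path, idHeader = "Protein") {
  m <- logRatios(x)
  chr <- matrix("", nrow(m), ncol(m))
  ok <- !is.na(m)
  chr[ok] <- formatC(m[ok], digits = 17, format = "g")
  out <- cbind(rownames(m), chr)
  colnames(out) <- c(idHeader, colnames(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample annotation table
#'
#' First column sample identifier, second column class label (header row
#' required). The class order is the order of first appearance.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with columns \code{sample} and \code{subtype} (factor,
#'   levels in first-appearance order); assign to a matrix with
#'   \code{subtypes(x) <- ann}.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("annotation table needs two columns (sample, class)")
  samples <- tab[[1]]
  if (anyDuplicated(samples))
    stop("sample listed twice in annotation: ", samples[duplicated(samples)][1])
  cls <- tab[[2]]
  data.frame(sample = samples,
             subtype = factor(cls, levels = unique(cls)),
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' Broad-style GMT: one category per line — name, description, then member
#' identifiers, tab-separated. The description is discarded and duplicate
#' members within a line are removed.
#'
#' @param path path to a GMT file. An empty file yields an empty map.
#' @param parentsPath optional two-column tab-separated table (child
#'   category, parent category) establishing a two-level hierarchy.
#' @return a \linkS4class{CategoryMap}.
#' @export
readGMT <- function(path, parentsPath = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  members <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(members)) stop("duplicate category name: ", nm)
    mem <- unique(f[-(1:2)])
    mem <- mem[nzchar(mem)]
    if (length(mem) == 0)
      stop("GMT format error at line ", i, ": no members")
    members[[nm]] <- mem
  }
  parents <- character()
  if (!is.null(parentsPath)) {
    pt <- read.delim(parentsPath, check.names = FALSE, header = TRUE,
                     stringsAsFactors = FALSE, colClasses = "character")
    parents <- setNames(pt[[2]], pt[[1]])
  }
  CategoryMap(members, parents)
}

#' Write a result table with a parameter-recording comment header
#'
#' All result tables of the pipeline go through this writer: a single
#' \code{#}-prefixed header line records the generating parameters (seed
#' included) so every table is self-describing and reruns are comparable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded in the comment line.
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(p)
      paste(format(p, trim = TRUE, scientific = FALSE), collapse = ","),
      character(1)), sep = "=", collapse = "; ")
    writeLines(paste0("# ", kv), con)
  }
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- rep(NA_character_, length(v))
    out[!is.na(v)] <- formatC(v[!is.na(v)], digits = 17, format = "g")
    out
  })
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}
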