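# internal helpers

#' Derive a per-stage seed from the global seed
#'
#' All pipeline randomness flows from one global seed; each stage draws from a
#' seed derived by mixing the stage name into the global seed, so toggling one
#' stage never changes another stage's draws. The derivation is a fixed
#' integer hash kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @examples
#' stageSeed(1L, "qc")
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003
  as.integer((abs(seed) %% 1000003) * 2063 + h * 97 + 17) %% 2147483587L
}

# floor(f * n) with protection against floating-point representation error,
# so e.g. 0.04 * 5000 counts as exactly 200.
.quota <- function(f, n) as.integer(floor(f * n + 1e-9))

# karyotype ordering of chromosome names: 1..22, X, Y, then others
# alphabetically; tolerant of a "chr" prefix.
.chromRank <- function(chroms) {
  s <- sub("^chr", "", as.character(chroms))
  num <- suppressWarnings(as.integer(s))
  r <- ifelse(!is.na(num), num,
              ifelse(s == "X", 23L, ifelse(s == "Y", 24L, NA_integer_)))
  other <- is.na(r)
  if (any(other)) {
    lv <- sort(unique(s[other]))
    r[other] <- 24L + match(s[other], lv)
  }
  r
}

.asMatrix <- function(x, layer = NULL) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(layer)) layer <- SummarizedExperiment::assayNames(x)[1]
    if (!layer %in% SummarizedExperiment::assayNames(x))
      stop("assay '", layer, "' not found; run the corresponding step first")
    x <- SummarizedExperiment::assay(x, layer)
  }
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) stop("expected a matrix or SummarizedExperiment")
  x
}

# local RNG scope: evaluate expr under a seed without disturbing the caller's
# RNG stream
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% 2147483587L, expr)
}

.checkCounts <- function(counts) {
  v <- if (is(counts, "sparseMatrix")) counts@x else counts
  if (any(v < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}
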