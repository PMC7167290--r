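#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats pt pnorm qnorm median kmeans rnorm runif setNames
#'   quantile mad
#' @importFrom utils read.delim write.table write.csv read.csv combn
#'   modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Every stochastic component of the package draws from its own RNG stream,
#' seeded by hashing the master seed together with a component label (and
#' optional indices). Adding arrays, runs or samples therefore never perturbs
#' the draws of earlier components. The hash is plain 32-bit-safe integer
#' arithmetic, so streams are identical across platforms.
#'
#' @param seed Master integer seed.
#' @param ... Labels (character or integer) identifying the component.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' deriveSeed(1L, "arrays", 3)
deriveSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- (abs(seed) %% 2147483647)
  for (p in parts) {
    for (code in utf8ToInt(p)) {
      h <- (h * 31 + code) %% 2147483647
    }
    h <- (h * 37 + 17) %% 2147483647
  }
  as.integer(h %% 2147483645L + 1L)
}

# run expr under a local RNG state so package internals never disturb the
# caller's RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Geometric mean
#'
#' @param x Positive numeric vector; `NA` removed.
#' @return The geometric mean `exp(mean(log(x)))`.
#' @export
geometricMean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geometricMean() requires strictly positive values")
  exp(mean(log(x)))
}

# rbind data.frames whose columns differ; absent columns filled with NA
rbindFill <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[, cols, drop = FALSE]
  }))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
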