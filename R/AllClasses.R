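#' @import SummarizedExperiment
#' @import S4Vectors
NULL

#' UbLArraySet: protein-array intensities with array metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container holding
#' one intensity matrix per modifier channel (e.g. `"ubiquitin"`,
#' `"SUMO1"`), optionally with matching local-background matrices
#' (`"<modifier>.bg"`) while at spot level. Columns are arrays; rows are
#' duplicate spots (spot level) or proteins (after [averageDuplicates()]).
#' `colData` carries the array metadata (`array_id`, `experiment`,
#' `cell_line`, `condition`, `nem_control`); `metadata(x)$transformLog`
#' is an append-only record of the preprocessing steps applied.
#'
#' @slot level `"spot"` or `"protein"`.
#' @export
setClass("UbLArraySet",
         contains = "SummarizedExperiment",
         slots = c(level = "character"),
         prototype = prototype(level = "spot"))

setValidity("UbLArraySet", function(object) {
  msgs <- character()
  cd <- colData(object)
  need <- c("array_id", "experiment", "cell_line", "condition", "nem_control")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste("colData lacks column(s):",
                          paste(miss, collapse = ", ")))
  if (!object@level %in% c("spot", "protein"))
    msgs <- c(msgs, "level must be 'spot' or 'protein'")
  if ("nem_control" %in% colnames(cd)) {
    bad <- cd$nem_control & cd$condition != "parental"
    if (any(bad))
      msgs <- c(msgs, "NEM-control arrays must have condition 'parental'")
  }
  if (length(assayNames(object)) == 0L)
    msgs <- c(msgs, "at least one assay (modifier channel) is required")
  if (anyDuplicated(cd$array_id))
    msgs <- c(msgs, "array_id values must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Modifier channels of a UbLArraySet
#'
#' @param x A `UbLArraySet`.
#' @return Character vector of modifier assay names (background assays
#'   excluded).
#' @export
modifierNames <- function(x) {
  nm <- assayNames(x)
  nm[!endsWith(nm, ".bg")]
}

#' Array metadata as a data.frame
#'
#' @param x A `UbLArraySet`.
#' @return `colData(x)` as a base data.frame.
#' @export
arrayMeta <- function(x) as.data.frame(colData(x))

#' Preprocessing transform log
#'
#' @param x A `UbLArraySet`.
#' @return Character vector of applied steps, in execution order.
#' @export
transformLog <- function(x) metadata(x)$transformLog %||% character()

appendLog <- function(x, step) {
  metadata(x)$transformLog <- c(transformLog(x), step)
  x
}

#' Spot/protein level of a UbLArraySet
#'
#' @param x A `UbLArraySet`.
#' @return `"spot"` while duplicate spots are distinct rows, `"protein"`
#'   after duplicate averaging.
#' @export
intensityLevel <- function(x) x@level

setMethod("show", "UbLArraySet", function(object) {
  cat(sprintf("UbLArraySet (%s level): %d row(s) x %d array(s)\n",
              object@level, nrow(object), ncol(object)))
  cat("  modifiers:", paste(modifierNames(object), collapse = ", "), "\n")
  cd <- colData(object)
  cat(sprintf("  experiments: %s; NEM controls: %d\n",
              paste(unique(cd$experiment), collapse = ", "),
              sum(cd$nem_control)))
  tl <- transformLog(object)
  if (length(tl)) cat("  transforms:", paste(tl, collapse = " -> "), "\n")
})

#' VariableMatrix: samples x (protein, modifier) variables for scoring
#'
#' @slot X Numeric matrix, samples in rows, variables in columns. Column
#'   names are `"<protein>|<modifier>"`.
#' @slot labels Factor with levels `sensitive`, `resistant`; `NA` for
#'   unlabeled samples.
#' @export
setClass("VariableMatrix",
         slots = c(X = "matrix", labels = "factor"))

setValidity("VariableMatrix", function(object) {
  msgs <- character()
  if (length(object@labels) != nrow(object@X))
    msgs <- c(msgs, "one label per sample row required")
  if (!identical(levels(object@labels), c("sensitive", "resistant")))
    msgs <- c(msgs, "label levels must be c('sensitive', 'resistant')")
  if (anyDuplicated(colnames(object@X)))
    msgs <- c(msgs, "variable ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VariableMatrix
#'
#' @param X Samples x variables numeric matrix with unique column names.
#' @param labels Character/factor of `"sensitive"`/`"resistant"` (or `NA`).
#' @return A [VariableMatrix-class] object.
#' @export
VariableMatrix <- function(X, labels) {
  labels <- factor(as.character(labels), levels = c("sensitive", "resistant"))
  new("VariableMatrix", X = as.matrix(X), labels = labels)
}

#' @export
setMethod("dim", "VariableMatrix", function(x) dim(x@X))

#' Variable identifiers of a VariableMatrix
#' @param x A `VariableMatrix`.
#' @return Character vector of `"<protein>|<modifier>"` ids.
#' @export
variableNames <- function(x) colnames(x@X)

#' Sample class labels of a VariableMatrix
#' @param x A `VariableMatrix`.
#' @return Factor of labels (NA = unlabeled).
#' @export
sampleLabels <- function(x) x@labels

setMethod("show", "VariableMatrix", function(object) {
  cat(sprintf("VariableMatrix: %d sample(s) x %d variable(s); %d labeled\n",
              nrow(object@X), ncol(object@X), sum(!is.na(object@labels))))
})

#' LDAModel: two-class linear discriminant decision rule
#'
#' Stores the fitted linear score `alpha x R1 + ... + omega x Rn`: the
#' coefficient vector over the chosen variables, the intercept, class means,
#' the (possibly shrunk) pooled within-class covariance and class priors.
#' The posterior probability of the resistant class follows from Gaussian
#' class-conditionals with the shared covariance.
#'
#' @slot coefficients Named numeric coefficient vector.
#' @slot intercept Numeric scalar.
#' @slot classMeans 2 x p matrix, rows `sensitive`, `resistant`.
#' @slot pooledCov p x p shrunk pooled covariance.
#' @slot priors Named numeric, sums to 1.
#' @slot shrinkage Shrinkage intensity actually used, in `[0, 1]`.
#' @export
setClass("LDAModel",
         slots = c(coefficients = "numeric", intercept = "numeric",
                   classMeans = "matrix", pooledCov = "matrix",
                   priors = "numeric", shrinkage = "numeric"))

setValidity("LDAModel", function(object) {
  msgs <- character()
  if (length(object@coefficients) != ncol(object@classMeans))
    msgs <- c(msgs, "coefficient count must equal number of variables")
  if (abs(sum(object@priors) - 1) > 1e-8)
    msgs <- c(msgs, "priors must sum to 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d variable(s), shrinkage %.3f\n",
              length(object@coefficients), object@shrinkage))
  cat("  priors:", paste(sprintf("%s=%.2f", names(object@priors),
                                 object@priors), collapse = ", "), "\n")
})

#' Coefficients of an LDAModel
#' @param object An `LDAModel`.
#' @param ... Ignored.
#' @return Named numeric coefficient vector.
#' @export
setMethod("coef", "LDAModel", function(object, ...) object@coefficients)

#' GASolutionSet: best-of-run subsets from repeated GA feature selection
#'
#' @slot solutions List (length = number of runs) of character vectors of
#'   selected variable ids.
#' @slot fitness Numeric best fitness per run.
#' @slot frequency Named numeric selection frequency per variable
#'   (fraction of runs whose best subset contains the variable).
#' @slot config List: the GA configuration used.
#' @export
setClass("GASolutionSet",
         slots = c(solutions = "list", fitness = "numeric",
                   frequency = "numeric", config = "list"))

setValidity("GASolutionSet", function(object) {
  if (length(object@solutions) != length(object@fitness))
    return("one fitness value per run required")
  TRUE
})

setMethod("show", "GASolutionSet", function(object) {
  cat(sprintf("GASolutionSet: %d run(s); %d variable(s) selected >= once\n",
              length(object@solutions), sum(object@frequency > 0)))
})

#' Per-variable selection frequencies
#' @param x A `GASolutionSet`.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
selectionFrequency <- function(x) x@frequency

#' Best-of-run subsets
#' @param x A `GASolutionSet`.
#' @return List of character vectors, one per GA run.
#' @export
gaSolutions <- function(x) x@solutions
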