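# Preprocessing chain: background correction, duplicate-spot averaging,
# within-experiment quantile normalization, cross-experiment batch
# adjustment. All steps are deterministic; each appends to the transform
# log and to the normalization report held in metadata().

recordStep <- function(x, step, params, pre, post) {
  rep_ <- metadata(x)$report %||% list()
  rep_[[length(rep_) + 1L]] <- list(step = step, params = params,
                                    arrays = ncol(x),
                                    pre_median = pre, post_median = post)
  metadata(x)$report <- rep_
  appendLog(x, step)
}

#' Normalization report of an UbLArraySet
#'
#' @param x A `UbLArraySet` after preprocessing steps.
#' @return List of per-step summaries (step name, parameters, arrays
#'   touched, pre/post medians), in execution order.
#' @export
normalizationReport <- function(x) metadata(x)$report %||% list()

medianOf <- function(x) {
  vals <- unlist(lapply(modifierNames(x), function(m)
    as.vector(assay(x, m))), use.names = FALSE)
  median(vals, na.rm = TRUE)
}

#' Background-correct a spot-level UbLArraySet
#'
#' Per spot, `intensity = max(foreground - background, floor)`; the floor is
#' strictly positive so later log transforms are defined. Background assays
#' are dropped afterwards.
#'
#' @param x Spot-level `UbLArraySet` with `<modifier>.bg` assays.
#' @param floor Minimum corrected intensity (default 1).
#' @return The corrected `UbLArraySet`.
#' @export
correctBackground <- function(x, floor = 1) {
  stopifnot(is(x, "UbLArraySet"), floor > 0)
  mods <- modifierNames(x)
  pre <- medianOf(x)
  keep <- list()
  for (m in mods) {
    bgName <- paste0(m, ".bg")
    if (!bgName %in% assayNames(x))
      stopf("no background assay '%s'; already corrected?", bgName)
    keep[[m]] <- pmax(assay(x, m) - assay(x, bgName), floor)
  }
  assays(x) <- keep
  recordStep(x, "correctBackground", list(floor = floor), pre, medianOf(x))
}

#' Average duplicate spots to protein level
#'
#' Each protein may have at most two sub-rows (duplicate spots). Available
#' duplicates are averaged arithmetically; a single surviving duplicate
#' passes through; two missing duplicates stay missing but the protein row
#' is retained.
#'
#' @param x Spot-level `UbLArraySet`.
#' @return Protein-level `UbLArraySet`.
#' @export
averageDuplicates <- function(x) {
  stopifnot(is(x, "UbLArraySet"))
  if (x@level != "spot") stopf("already at protein level")
  pid <- rowData(x)$protein_id
  counts <- table(pid)
  if (any(counts > 2L))
    stopf("grid violation: >2 duplicate spots for protein(s): %s",
          paste(names(counts)[counts > 2L], collapse = ", "))
  proteins <- unique(pid)
  pre <- medianOf(x)
  newAssays <- lapply(assays(x), function(a) {
    g <- rowsum(ifelse(is.na(a), 0, a), pid, reorder = FALSE)
    n <- rowsum((!is.na(a)) * 1, pid, reorder = FALSE)
    out <- g / n  # 0/0 -> NaN where both duplicates missing
    out[n == 0] <- NA_real_
    out[match(proteins, rownames(g)), , drop = FALSE]
  })
  se <- SummarizedExperiment(
    assays = newAssays,
    rowData = DataFrame(protein_id = proteins, row.names = proteins),
    colData = colData(x))
  metadata(se) <- metadata(x)
  y <- new("UbLArraySet", se, level = "protein")
  recordStep(y, "averageDuplicates", list(), pre, medianOf(y))
}

# quantile-normalize the columns of one matrix to their common reference;
# ties receive the mean of the reference values at their rank positions,
# missing values are excluded from the reference and stay missing
qnormMatrix <- function(mat) {
  n <- nrow(mat)
  grid <- (seq_len(n) - 0.5) / n
  colQ <- apply(mat, 2L, function(v) {
    s <- sort(v[!is.na(v)])
    m <- length(s)
    if (m == 0L) return(rep(NA_real_, n))
    if (m == n) return(s)
    stats::approx((seq_len(m) - 0.5) / m, s, xout = grid, rule = 2)$y
  })
  ref <- rowMeans(colQ, na.rm = TRUE)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    ok <- !is.na(v)
    m <- sum(ok)
    if (m == 0L) next
    refC <- if (m == n) ref else
      stats::approx(grid, ref, xout = (seq_len(m) - 0.5) / m, rule = 2)$y
    w <- numeric(m)
    o <- order(v[ok])
    w[o] <- refC
    w <- stats::ave(w, v[ok], FUN = mean)  # ties -> mean of their refs
    out[ok, j] <- w
  }
  out
}

#' Within-experiment quantile normalization
#'
#' Arrays are partitioned into groups (by experiment, by default) and each
#' group's columns are forced onto the group's mean-of-sorted-values
#' reference distribution, preserving within-array ranks. Groups of size 1
#' pass through with a warning. The operation is idempotent and conserves
#' each group's pooled quantile profile.
#'
#' @param x Protein- or spot-level `UbLArraySet`.
#' @param groupBy `colData` column defining the groups (default
#'   `"experiment"`).
#' @return The normalized `UbLArraySet`.
#' @export
quantileNormalize <- function(x, groupBy = "experiment") {
  stopifnot(is(x, "UbLArraySet"))
  groups <- as.character(colData(x)[[groupBy]])
  if (is.null(groups)) stopf("no colData column '%s'", groupBy)
  pre <- medianOf(x)
  for (m in modifierNames(x)) {
    a <- assay(x, m)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2L) {
        warnf("quantileNormalize: group '%s' has a single array; passing through", g)
        next
      }
      a[, idx] <- qnormMatrix(a[, idx, drop = FALSE])
    }
    assay(x, m) <- a
  }
  recordStep(x, "quantileNormalize", list(groupBy = groupBy), pre,
             medianOf(x))
}

#' Cross-experiment batch adjustment
#'
#' Default method: per-batch median-centering in log2 space. Each batch's
#' pooled log2 median is mapped onto the global log2 median by a
#' multiplicative factor, so within-batch rank order is preserved and the
#' operation is idempotent. The alternative `"eb_location_scale"` method
#' applies empirical-Bayes location/scale adjustment (ComBat, via the
#' \pkg{sva} package) on the log2 scale.
#'
#' @param x `UbLArraySet` with positive intensities.
#' @param batches Optional character vector of batch labels, one per array;
#'   defaults to `colData(x)$experiment`.
#' @param method `"median_center"` (default) or `"eb_location_scale"`.
#' @return The adjusted `UbLArraySet`.
#' @export
batchAdjust <- function(x, batches = NULL,
                        method = c("median_center", "eb_location_scale")) {
  method <- match.arg(method)
  stopifnot(is(x, "UbLArraySet"))
  if (is.null(batches)) batches <- as.character(colData(x)$experiment)
  if (length(batches) != ncol(x))
    stopf("need one batch label per array (%d given, %d arrays)",
          length(batches), ncol(x))
  known <- unique(as.character(colData(x)$experiment))
  unknown <- setdiff(unique(batches), known)
  if (length(unknown))
    stopf("unknown batch label(s): %s", paste(unknown, collapse = ", "))
  pre <- medianOf(x)
  for (m in modifierNames(x)) {
    a <- assay(x, m)
    if (any(a[!is.na(a)] <= 0))
      stopf("batchAdjust needs positive intensities; run correctBackground first")
    la <- log2(a)
    if (method == "median_center") {
      globalMed <- median(la, na.rm = TRUE)
      for (b in unique(batches)) {
        idx <- which(batches == b)
        la[, idx] <- la[, idx] +
          (globalMed - median(la[, idx], na.rm = TRUE))
      }
    } else {
      if (!requireNamespace("sva", quietly = TRUE))
        stopf("method 'eb_location_scale' requires the sva package")
      if (length(unique(batches)) < 2L)
        stopf("eb_location_scale needs >= 2 batches")
      la <- sva::ComBat(dat = la, batch = factor(batches))
    }
    assay(x, m) <- 2^la
  }
  recordStep(x, "batchAdjust", list(method = method), pre, medianOf(x))
}

#' Run the full preprocessing chain
#'
#' [correctBackground()] -> [averageDuplicates()] -> [quantileNormalize()]
#' -> [batchAdjust()], with default parameters overridable via `config`
#' (keys `background.floor`, `qnorm.group_by`, `batch.method`).
#'
#' @param x Spot-level `UbLArraySet` as returned by [assembleMatrix()].
#' @param config Optional named list of parameter overrides.
#' @return Protein-level, normalized `UbLArraySet`.
#' @export
preprocessChain <- function(x, config = list()) {
  x <- correctBackground(x, floor = config[["background.floor"]] %||% 1)
  x <- averageDuplicates(x)
  x <- quantileNormalize(x,
                         groupBy = config[["qnorm.group_by"]] %||%
                           "experiment")
  batchAdjust(x, method = config[["batch.method"]] %||% "median_center")
}
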