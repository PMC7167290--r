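# Two-stage calling: (1) robustly UbL-modified proteins vs NEM controls
# (dual Welch + Wilcoxon-Mann-Whitney filter with an intensity floor);
# (2) differentially modified proteins between resistant and parental
# conditions, globally (pooled, signed-rank + one-sample t, ratio gate
# 1.25/0.8) and separated per cell line x drug (one-sample t only, gate
# 1.5/0.66); merged into the chemoresistance signature.

#' Call robustly UbL-modified proteins against NEM controls
#'
#' For each (protein, modifier), intensities from conjugation-permissive
#' arrays are compared with averaged NEM-control signals (control arrays
#' are averaged within each experiment, yielding one control replicate per
#' experiment). A protein is called modified when both the Welch and the
#' Wilcoxon-Mann-Whitney two-sided p-values fall below `alpha`, its mean
#' permissive intensity exceeds `intensityFloor` (default 800 a.u.), and
#' the permissive mean exceeds the control mean.
#'
#' @param x Protein-level, normalized `UbLArraySet`.
#' @param alpha Significance threshold (default 0.05).
#' @param intensityFloor Mean-intensity filter (default 800).
#' @param bhCorrect Apply Benjamini-Hochberg correction per modifier before
#'   thresholding (default FALSE, matching raw-p usage).
#' @return data.frame with one row per (protein, modifier):
#'   `mean_permissive`, `mean_control`, `p_welch`, `p_mww`, `called`.
#' @export
callModified <- function(x, alpha = 0.05, intensityFloor = 800,
                         bhCorrect = FALSE) {
  stopifnot(is(x, "UbLArraySet"))
  if (x@level != "protein")
    stopf("callModified needs a protein-level matrix (run averageDuplicates)")
  cd <- colData(x)
  if (!any(cd$nem_control)) stopf("no NEM-control arrays in the matrix")
  if (sum(!cd$nem_control) < 2L)
    stopf("need >= 2 conjugation-permissive arrays")
  permIdx <- which(!cd$nem_control)
  out <- list()
  for (mod in modifierNames(x)) {
    a <- assay(x, mod)
    perm <- a[, permIdx, drop = FALSE]
    # average NEM controls within each experiment
    nemIdx <- which(cd$nem_control)
    ctrlExp <- as.character(cd$experiment[nemIdx])
    ctrl <- t(rowsum(t(a[, nemIdx, drop = FALSE]), ctrlExp)) /
      as.vector(table(ctrlExp)[sort(unique(ctrlExp))])[
        col(matrix(0, nrow(a), length(unique(ctrlExp))))]
    np <- nrow(a)
    pW <- pM <- rep(NA_real_, np)
    mP <- rowMeans(perm, na.rm = TRUE)
    mC <- rowMeans(ctrl, na.rm = TRUE)
    for (i in seq_len(np)) {
      pv <- perm[i, ]; cv <- ctrl[i, ]
      pv <- pv[!is.na(pv)]; cv <- cv[!is.na(cv)]
      if (length(pv) < 2L || length(cv) < 2L) next
      pW[[i]] <- tTest(pv, cv, mode = "welch_two_sample")$p.value
      pM[[i]] <- mannWhitneyU(pv, cv)$p.value
    }
    if (bhCorrect) {
      pW <- stats::p.adjust(pW, "BH")
      pM <- stats::p.adjust(pM, "BH")
    }
    called <- !is.na(pW) & !is.na(pM) & pW < alpha & pM < alpha &
      mP > intensityFloor & mP > mC
    out[[mod]] <- data.frame(
      protein = rownames(a), modifier = mod,
      mean_permissive = unname(mP), mean_control = unname(mC),
      p_welch = pW, p_mww = pM, called = called)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# resistant/parental pair table: one row per (experiment, cell line, drug)
pairTable <- function(cd) {
  cd <- as.data.frame(cd)
  res <- cd[!cd$nem_control & cd$condition != "parental", , drop = FALSE]
  if (!nrow(res)) stopf("no resistant arrays present")
  pairs <- lapply(seq_len(nrow(res)), function(i) {
    r <- res[i, ]
    p <- cd[!cd$nem_control & cd$condition == "parental" &
              cd$cell_line == r$cell_line &
              cd$experiment == r$experiment, , drop = FALSE]
    if (nrow(p) != 1L)
      stopf("no same-experiment parental partner for array '%s'",
            r$array_id)
    data.frame(resistant = r$array_id, parental = p$array_id,
               experiment = r$experiment, cell_line = r$cell_line,
               drug = r$condition)
  })
  do.call(rbind, pairs)
}

#' Resistant/parental intensity ratios for called proteins
#'
#' For every called (protein, modifier), computes one ratio per
#' (resistant array, same-experiment same-cell-line parental array) pair.
#' Pairing within experiment cancels batch effects by construction. The
#' returned long table covers all pairs; the global analysis pools them,
#' the separated analysis subsets per cell line x drug.
#'
#' @param x Protein-level `UbLArraySet`.
#' @param calls [callModified()] output (only `called` rows enter).
#' @param scope `"global"` or `"separated"`; recorded on the result.
#' @return data.frame `protein`, `modifier`, `experiment`, `cell_line`,
#'   `drug`, `ratio`, with `attr(, "scope")`.
#' @export
computeRatios <- function(x, calls, scope = c("global", "separated")) {
  scope <- match.arg(scope)
  stopifnot(is(x, "UbLArraySet"))
  pairs <- pairTable(colData(x))
  keep <- calls[calls$called, , drop = FALSE]
  out <- list()
  for (mod in unique(keep$modifier)) {
    a <- assay(x, mod)
    prots <- keep$protein[keep$modifier == mod]
    num <- a[prots, pairs$resistant, drop = FALSE]
    den <- a[prots, pairs$parental, drop = FALSE]
    ratio <- num / den
    out[[mod]] <- data.frame(
      protein = rep(prots, times = nrow(pairs)),
      modifier = mod,
      experiment = rep(pairs$experiment, each = length(prots)),
      cell_line = rep(pairs$cell_line, each = length(prots)),
      drug = rep(pairs$drug, each = length(prots)),
      ratio = as.vector(ratio))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(protein = character(),
                                      modifier = character(),
                                      experiment = character(),
                                      cell_line = character(),
                                      drug = character(), ratio = numeric())
  rownames(res) <- NULL
  if (any(!is.na(res$ratio) & res$ratio <= 0))
    stopf("non-positive ratio encountered; intensities must be positive")
  attr(res, "scope") <- scope
  res
}

differentialOne <- function(lr, alpha, hi, lo, useSignedRank) {
  gm <- 2^mean(lr)
  pT <- tTest(lr, 0, mode = "one_sample")$p.value
  pS <- if (useSignedRank) wilcoxonSignedRank(lr, 0)$p.value else NA_real_
  sig <- if (useSignedRank) (pS < alpha && pT < alpha) else (pT < alpha)
  list(ratio_gm = gm, p_signed_rank = pS, p_t = pT,
       direction = if (gm >= 1) "up" else "down",
       called = isTRUE(sig && (gm > hi || gm < lo)))
}

differentialCall <- function(ratios, alpha, hi, lo, useSignedRank,
                             groupCols, scopeTag, bhCorrect = FALSE) {
  rat <- ratios[!is.na(ratios$ratio), , drop = FALSE]
  keys <- do.call(paste, c(rat[c("protein", "modifier", groupCols)],
                           sep = "\r"))
  rows <- list()
  for (k in unique(keys)) {
    sub <- rat[keys == k, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warnf("skipping %s/%s: fewer than 2 ratios",
            sub$protein[[1L]], sub$modifier[[1L]])
      next
    }
    r <- differentialOne(log2(sub$ratio), alpha, hi, lo, useSignedRank)
    rec <- data.frame(protein = sub$protein[[1L]],
                      modifier = sub$modifier[[1L]], scope = scopeTag)
    for (gc in groupCols) rec[[gc]] <- sub[[gc]][[1L]]
    rows[[length(rows) + 1L]] <-
      cbind(rec, as.data.frame(r[c("ratio_gm", "p_signed_rank", "p_t",
                                   "direction", "called")]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(), modifier = character(),
                      scope = character(), ratio_gm = numeric(),
                      p_signed_rank = numeric(), p_t = numeric(),
                      direction = character(), called = logical())
  if (bhCorrect && nrow(out)) {
    for (mod in unique(out$modifier)) {
      i <- out$modifier == mod
      adjT <- stats::p.adjust(out$p_t[i], "BH")
      adjS <- if (useSignedRank)
        stats::p.adjust(out$p_signed_rank[i], "BH") else NA_real_
      sig <- if (useSignedRank) (adjT < alpha & adjS < alpha) else
        (adjT < alpha)
      out$called[i] <- sig & (out$ratio_gm[i] > hi | out$ratio_gm[i] < lo)
      out$p_t[i] <- adjT
      if (useSignedRank) out$p_signed_rank[i] <- adjS
    }
  }
  rownames(out) <- NULL
  out
}

#' Global differential-modification calling
#'
#' Pools resistant/parental log2 ratios across all resistant lines and
#' drugs; a (protein, modifier) is called differentially modified when both
#' the Wilcoxon signed-rank and the one-sample t test on the log2 ratios
#' (vs 0) give `p < alpha` and the geometric-mean ratio exceeds `hi`
#' (default 1.25) or falls below `lo` (default 0.8).
#'
#' @param ratios [computeRatios()] output (global scope).
#' @param alpha Significance threshold.
#' @param hi,lo Ratio gates (default 1.25 / 0.8).
#' @param bhCorrect Benjamini-Hochberg adjust per modifier before calling.
#' @return data.frame of differential records with `ratio_gm`,
#'   `p_signed_rank`, `p_t`, `direction`, `called`.
#' @export
callDifferentialGlobal <- function(ratios, alpha = 0.05, hi = 1.25,
                                   lo = 0.8, bhCorrect = FALSE) {
  differentialCall(ratios, alpha, hi, lo, useSignedRank = TRUE,
                   groupCols = character(), scopeTag = "global",
                   bhCorrect = bhCorrect)
}

#' Separated (per cell line x drug) differential calling
#'
#' As [callDifferentialGlobal()] but restricted to one cell line and one
#' drug resistance at a time; with the smaller sample size only the
#' one-sample t test is applied, with wider ratio gates (1.5 / 0.66).
#'
#' @param ratios [computeRatios()] output.
#' @param alpha Significance threshold.
#' @param hi,lo Ratio gates (default 1.5 / 0.66).
#' @param bhCorrect Benjamini-Hochberg adjust per modifier before calling.
#' @return data.frame of differential records, one per
#'   (protein, modifier, cell line, drug).
#' @export
callDifferentialSeparated <- function(ratios, alpha = 0.05, hi = 1.5,
                                      lo = 0.66, bhCorrect = FALSE) {
  differentialCall(ratios, alpha, hi, lo, useSignedRank = FALSE,
                   groupCols = c("cell_line", "drug"),
                   scopeTag = "separated", bhCorrect = bhCorrect)
}

#' Merge global and separated differential calls into the signature
#'
#' Per modifier, the signature is the union (keyed by protein) of proteins
#' called in the global analysis and in at least one separated analysis.
#' Proteins present in both modifier lists are counted once in the
#' distinct-protein total.
#'
#' @param globalRecords [callDifferentialGlobal()] output.
#' @param separatedRecords [callDifferentialSeparated()] output.
#' @return A `SignatureTable` data.frame (`protein`, `modifier`, `source`,
#'   `scopes`) with `attr(, "counts")`: per-modifier counts and
#'   `distinct_proteins`.
#' @export
mergeSignature <- function(globalRecords, separatedRecords) {
  g <- globalRecords[globalRecords$called, , drop = FALSE]
  s <- separatedRecords[separatedRecords$called, , drop = FALSE]
  mods <- sort(unique(c(g$modifier, s$modifier)))
  rows <- list()
  for (mod in mods) {
    gp <- unique(g$protein[g$modifier == mod])
    sSub <- s[s$modifier == mod, , drop = FALSE]
    sp <- unique(sSub$protein)
    prots <- sort(union(gp, sp))
    if (!length(prots)) next
    src <- ifelse(prots %in% gp & prots %in% sp, "both",
                  ifelse(prots %in% gp, "global", "separated"))
    scopes <- vapply(prots, function(p) {
      sc <- character()
      if (p %in% gp) sc <- "global"
      sub <- sSub[sSub$protein == p, , drop = FALSE]
      if (nrow(sub))
        sc <- c(sc, paste0(sub$cell_line, ":", sub$drug))
      paste(sc, collapse = ";")
    }, character(1))
    rows[[mod]] <- data.frame(protein = prots, modifier = mod,
                              source = src, scopes = unname(scopes))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(), modifier = character(),
                      source = character(), scopes = character())
  rownames(out) <- NULL
  counts <- as.list(table(out$modifier))
  counts$distinct_proteins <- length(unique(out$protein))
  attr(out, "counts") <- counts
  class(out) <- c("SignatureTable", "data.frame")
  out
}

#' Venn counts of called proteins across modifiers
#'
#' Per-modifier counts plus the overlap, for any calls table with
#' `protein`, `modifier` and `called` columns (modification calls or
#' differential records).
#'
#' @param calls data.frame with `protein`, `modifier`, `called`.
#' @return List: one count per modifier (proteins called for that
#'   modifier only), `both` (called for two or more), `total` (distinct).
#' @export
vennCounts <- function(calls) {
  d <- unique(calls[calls$called, c("protein", "modifier"), drop = FALSE])
  perProt <- table(d$protein)
  mods <- sort(unique(d$modifier))
  out <- lapply(mods, function(m) {
    sum(names(perProt)[perProt == 1L] %in% d$protein[d$modifier == m])
  })
  names(out) <- mods
  out$both <- sum(perProt >= 2L)
  out$total <- length(perProt)
  out
}

#' Signature counts
#'
#' @param sig A `SignatureTable` from [mergeSignature()].
#' @return List of per-modifier protein counts and `distinct_proteins`.
#' @export
signatureCounts <- function(sig) attr(sig, "counts")

#' @export
print.SignatureTable <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("UbL chemoresistance signature:",
      paste(sprintf("%s = %d", setdiff(names(cnt), "distinct_proteins"),
                    unlist(cnt[setdiff(names(cnt), "distinct_proteins")])),
            collapse = ", "),
      sprintf("(%d distinct proteins)\n", cnt$distinct_proteins))
  NextMethod()
}
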