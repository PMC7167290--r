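# Multiplexed bead-assay quantification: bead-region gating in the
# classification channels, per-region median fluorescence (MFI),
# NEM-background subtraction, resistant/parental ratios, group
# comparisons, and per-patient high-modification flagging.

#' Assign bead events to regions
#'
#' Events are assigned to the nearest region centroid in the
#' classification channels (`CL1`, `CL2`). Centroids may be supplied
#' directly or estimated with seeded k-means when only `k` is given.
#' Events farther from their centroid than the distance gate are marked
#' unassigned (`NA`); by default the gate per region is
#' `median + 5 * mad` of the assigned distances.
#'
#' @param events data.frame with `CL1`, `CL2` columns.
#' @param centroids Matrix (regions x 2, rownames = region ids), or NULL.
#' @param k Number of regions for k-means estimation (used when
#'   `centroids` is NULL).
#' @param maxDist Fixed distance gate, or NULL for the robust per-region
#'   default.
#' @param seed Seed for k-means.
#' @return `events` with added `region` (character, `NA` = unassigned)
#'   and `dist` columns.
#' @export
assignBeadRegions <- function(events, centroids = NULL, k = NULL,
                              maxDist = NULL, seed = 1L) {
  stopifnot(is.data.frame(events), all(c("CL1", "CL2") %in% names(events)))
  cl <- as.matrix(events[, c("CL1", "CL2")])
  if (is.null(centroids)) {
    if (is.null(k)) stopf("supply centroids or k")
    if (k > nrow(events)) stopf("k (%d) exceeds event count (%d)", k,
                                nrow(events))
    km <- withSeed(deriveSeed(seed, "bead_kmeans"),
                   kmeans(cl, centers = k, nstart = 10L))
    centroids <- km$centers
    rownames(centroids) <- sprintf("B%02d", order(order(
      centroids[, 1L] + 1e6 * centroids[, 2L])))
  }
  if (is.null(rownames(centroids)))
    rownames(centroids) <- sprintf("B%02d", seq_len(nrow(centroids)))
  d2 <- outer(rowSums(cl^2), rep(1, nrow(centroids))) -
    2 * cl %*% t(centroids) +
    outer(rep(1, nrow(cl)), rowSums(centroids^2))
  nearest <- max.col(-d2)
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(cl)), nearest)], 0))
  region <- rownames(centroids)[nearest]
  if (is.null(maxDist)) {
    gate <- vapply(split(dist, region), function(d)
      median(d) + 5 * mad(d), numeric(1))
    off <- dist > gate[region]
  } else {
    off <- dist > maxDist
  }
  region[off] <- NA_character_
  events$region <- region
  events$dist <- dist
  events
}

#' Per-(sample, region) median fluorescence intensities
#'
#' Median of each reporter channel over the assigned events of one region
#' in one sample (even event counts use the midpoint mean). Regions with
#' fewer than `minEvents` events are flagged unusable.
#'
#' @param events Labeled events ([assignBeadRegions()] output) with
#'   `sample_id`, `region` and reporter columns.
#' @param reporters Reporter channel columns (default
#'   `c(ubiquitin = "RP_ub", SUMO1 = "RP_sumo1")`; names = modifiers).
#' @param minEvents Minimum events per region (default 30).
#' @return data.frame `sample_id`, `biomarker`, `modifier`, `mfi`,
#'   `n_events`, `usable`.
#' @export
computeMFI <- function(events,
                       reporters = c(ubiquitin = "RP_ub",
                                     SUMO1 = "RP_sumo1"),
                       minEvents = 30L) {
  ev <- events[!is.na(events$region), , drop = FALSE]
  if (!nrow(ev)) stopf("no assigned events")
  out <- list()
  for (mod in names(reporters)) {
    agg <- aggregate(ev[[reporters[[mod]]]],
                     by = list(sample_id = ev$sample_id,
                               biomarker = ev$region),
                     FUN = median)
    cnt <- aggregate(ev[[reporters[[mod]]]],
                     by = list(sample_id = ev$sample_id,
                               biomarker = ev$region),
                     FUN = length)
    out[[mod]] <- data.frame(agg[1:2], modifier = mod, mfi = agg$x,
                             n_events = cnt$x,
                             usable = cnt$x >= minEvents)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' NEM-background subtraction and resistant/parental ratios
#'
#' Per (sample, biomarker, modifier), `adjusted = max(mfi - nem_mfi,
#' floor)`; the ratio for each (resistant, parental) pair is
#' `adjusted_resistant / adjusted_parental`. Pairs whose parental adjusted
#' value sits at the floor are flagged unstable.
#'
#' @param mfi [computeMFI()] output.
#' @param controlMap Named character vector: `sample_id -> NEM control
#'   sample id`.
#' @param pairs data.frame with `resistant`, `parental` sample ids.
#' @param floor Background-subtraction floor (default 1 a.u.).
#' @return List: `adjusted` (per-sample background-subtracted MFI table),
#'   `ratios` (per pair x biomarker x modifier, with `unstable` flag).
#' @export
nemSubtractAndRatio <- function(mfi, controlMap, pairs, floor = 1) {
  mfi <- mfi[mfi$usable, , drop = FALSE]
  key <- function(s, b, m) paste(s, b, m, sep = "\r")
  mfiOf <- setNames(mfi$mfi, key(mfi$sample_id, mfi$biomarker,
                                 mfi$modifier))
  samples <- unique(mfi$sample_id[!mfi$sample_id %in% controlMap])
  adj <- mfi[mfi$sample_id %in% names(controlMap), , drop = FALSE]
  nem <- unname(mfiOf[key(controlMap[adj$sample_id], adj$biomarker,
                          adj$modifier)])
  if (anyNA(nem))
    stopf("missing NEM-control MFI for sample(s): %s",
          paste(unique(adj$sample_id[is.na(nem)]), collapse = ", "))
  adj$nem_mfi <- nem
  adj$adjusted <- pmax(adj$mfi - adj$nem_mfi, floor)
  adjOf <- setNames(adj$adjusted, key(adj$sample_id, adj$biomarker,
                                      adj$modifier))
  combos <- unique(adj[, c("biomarker", "modifier")])
  ratioRows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(combos))) {
      b <- combos$biomarker[[j]]; m <- combos$modifier[[j]]
      num <- adjOf[key(pairs$resistant[[i]], b, m)]
      den <- adjOf[key(pairs$parental[[i]], b, m)]
      if (is.na(num) || is.na(den)) next
      ratioRows[[length(ratioRows) + 1L]] <- data.frame(
        resistant = pairs$resistant[[i]], parental = pairs$parental[[i]],
        biomarker = b, modifier = m, ratio = unname(num / den),
        unstable = unname(den <= floor))
    }
  }
  ratios <- do.call(rbind, ratioRows)
  if (is.null(ratios))
    ratios <- data.frame(resistant = character(), parental = character(),
                         biomarker = character(), modifier = character(),
                         ratio = numeric(), unstable = logical())
  list(adjusted = adj, ratios = ratios)
}

#' Group comparison of bead measurements
#'
#' Compares two groups of per-sample values with the matching t-test mode:
#' `"unpaired_welch"` (e.g. responder vs refractory patients) or
#' `"paired"` (e.g. resistant vs parental ratios per experiment).
#'
#' @param x,y Numeric vectors of per-sample values.
#' @param design `"unpaired_welch"` or `"paired"`.
#' @return A `ublTest` result from [tTest()].
#' @export
compareGroups <- function(x, y, design = c("unpaired_welch", "paired")) {
  design <- match.arg(design)
  if (design == "paired") tTest(x, y, mode = "paired")
  else tTest(x, y, mode = "welch_two_sample")
}

#' Flag patients with high modification of any biomarker
#'
#' A patient's biomarker is flagged when its (background-subtracted) MFI
#' exceeds `mean + kSd * sd` of the reference (responder) group for that
#' biomarker; a patient is flagged when at least one biomarker is flagged.
#' A zero reference SD degenerates to "strictly above the reference mean".
#'
#' @param values data.frame `sample_id`, `biomarker`, `value`.
#' @param reference Character vector of reference-group sample ids
#'   (>= 3 per biomarker required).
#' @param kSd Threshold multiplier (default 2).
#' @return List: `biomarker_flags` (per sample x biomarker), `patient_flags`
#'   (per sample).
#' @export
flagHighModification <- function(values, reference, kSd = 2) {
  ref <- values[values$sample_id %in% reference, , drop = FALSE]
  refN <- table(ref$biomarker)
  if (any(refN < 3L))
    stopf("need >= 3 reference patients per biomarker (got %s)",
          paste(sprintf("%s=%d", names(refN), refN), collapse = ", "))
  thr <- do.call(rbind, lapply(split(ref, ref$biomarker), function(d)
    data.frame(biomarker = d$biomarker[[1L]], mean = mean(d$value),
               sd = sd(d$value))))
  v <- merge(values, thr, by = "biomarker")
  v$flag <- ifelse(v$sd > 0, v$value > v$mean + kSd * v$sd,
                   v$value > v$mean)
  patient <- aggregate(flag ~ sample_id, v, any)
  list(biomarker_flags = v[order(v$sample_id, v$biomarker),
                           c("sample_id", "biomarker", "value", "flag")],
       patient_flags = setNames(patient$flag, patient$sample_id))
}
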