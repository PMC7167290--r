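# Background correction, duplicate averaging, quantile normalization,
# batch adjustment: exact rules, hand oracles, idempotence.

spotSet <- function(fg, bg, meta = NULL) {
  if (is.null(meta))
    meta <- data.frame(array_id = colnames(fg), experiment = "exp1",
                       cell_line = "U937", condition = "parental",
                       nem_control = FALSE)
  makeArraySet(list(ubiquitin = fg, ubiquitin.bg = bg), meta,
               level = "spot")
}

test_that("background correction subtracts with a positive floor", {
  fg <- matrix(c(1000, 100, 500), 3, 1,
               dimnames = list(c("PA.1", "PA.2", "PB.1"), "A1"))
  bg <- matrix(c(200, 200, 0), 3, 1, dimnames = dimnames(fg))
  x <- correctBackground(spotSet(fg, bg))
  expect_equal(unname(assay(x, "ubiquitin")[, 1]), c(800, 1, 500))
  expect_false("ubiquitin.bg" %in% assayNames(x))
  expect_equal(transformLog(x), "correctBackground")

  # zero background everywhere: unchanged apart from flooring
  xb0 <- correctBackground(spotSet(fg, bg * 0))
  expect_equal(unname(assay(xb0, "ubiquitin")[, 1]), c(1000, 100, 500))
})

test_that("duplicate averaging follows the mean / pass-through / missing rules", {
  fg <- matrix(c(100, 200, 300, NA, NA, NA), 6, 1,
               dimnames = list(c("PA.1", "PA.2", "PB.1", "PB.2",
                                 "PC.1", "PC.2"), "A1"))
  x <- spotSet(fg, fg * 0)
  x <- correctBackground(x)
  y <- averageDuplicates(x)
  expect_equal(intensityLevel(y), "protein")
  vals <- assay(y, "ubiquitin")[, 1]
  expect_equal(unname(vals["PA"]), 150)   # mean of duplicates
  expect_equal(unname(vals["PB"]), 300)   # surviving duplicate passes
  expect_true(is.na(vals["PC"]))          # both missing -> missing
  expect_equal(rownames(y), c("PA", "PB", "PC"))  # protein retained

  fg3 <- rbind(fg, "PA.3" = 5)
  expect_error(averageDuplicates(correctBackground(spotSet(fg3,
                                                           fg3 * 0))),
               "grid violation.*PA")
})

test_that("quantile normalization matches the sorted-mean oracle", {
  fg <- cbind(A1 = c(1, 2, 3), A2 = c(2, 4, 6))
  rownames(fg) <- c("PA.1", "PB.1", "PC.1")
  meta <- data.frame(array_id = c("A1", "A2"), experiment = "exp1",
                     cell_line = "U937",
                     condition = c("parental", "ARA-R"),
                     nem_control = FALSE)
  x <- makeArraySet(list(ubiquitin = fg), meta, level = "protein")
  y <- quantileNormalize(x)
  expect_equal(unname(assay(y, "ubiquitin")[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(assay(y, "ubiquitin")[, 2]), c(1.5, 3, 4.5))

  # identical columns are unchanged
  fg2 <- cbind(A1 = c(5, 1, 9), A2 = c(5, 1, 9))
  rownames(fg2) <- rownames(fg)
  x2 <- makeArraySet(list(ubiquitin = fg2), meta, level = "protein")
  expect_equal(assay(quantileNormalize(x2), "ubiquitin"), fg2)
})

test_that("quantile normalization equalizes within-group distributions exactly and is idempotent", {
  set.seed(5)
  meta <- toyMeta(2)
  fg <- matrix(rlnorm(50 * nrow(meta), 6, 1), 50, nrow(meta),
               dimnames = list(sprintf("P%03d", 1:50), meta$array_id))
  x <- makeArraySet(list(ubiquitin = fg), meta, level = "protein")
  y <- quantileNormalize(x)
  a <- assay(y, "ubiquitin")
  for (g in unique(meta$experiment)) {
    cols <- a[, meta$experiment == g, drop = FALSE]
    ref <- unname(sort(cols[, 1]))
    for (j in 2:ncol(cols)) expect_equal(unname(sort(cols[, j])), ref)
    # pooled quantile profile conserved: reference is the mean of sorted
    expect_equal(ref, unname(rowMeans(apply(fg[, meta$experiment == g],
                                            2, sort))))
  }
  y2 <- quantileNormalize(y)
  expect_equal(assay(y2, "ubiquitin"), a, tolerance = 1e-9)
  # ranks within each array preserved
  for (j in seq_len(ncol(a)))
    expect_equal(rank(a[, j]), rank(fg[, j]))
})

test_that("quantile normalization agrees with limma on complete data", {
  set.seed(7)
  m <- matrix(rlnorm(400, 5, 1), 100, 4)
  expect_equal(UbLsig:::qnormMatrix(m),
               unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a single-array group passes through with a warning", {
  meta <- data.frame(array_id = c("A1", "A2", "B1"),
                     experiment = c("exp1", "exp1", "exp2"),
                     cell_line = "U937",
                     condition = "parental", nem_control = FALSE)
  fg <- cbind(A1 = c(1, 5, 3), A2 = c(1, 5, 3), B1 = c(2, 8, 4))
  rownames(fg) <- c("PA", "PB", "PC")
  x <- makeArraySet(list(ubiquitin = fg), meta, level = "protein")
  expect_warning(y <- quantileNormalize(x), "single array")
  expect_equal(assay(y, "ubiquitin"), fg)
})

test_that("batch adjustment removes a constructed x2 factor exactly", {
  meta <- toyMeta(2)
  set.seed(9)
  base <- matrix(rlnorm(40 * 8, 7, 0.8), 40, 8)
  fg <- cbind(base, base * 2)  # second experiment globally doubled
  dimnames(fg) <- list(sprintf("P%03d", 1:40), meta$array_id)
  x <- makeArraySet(list(ubiquitin = fg), meta, level = "protein")
  y <- batchAdjust(x)
  a <- assay(y, "ubiquitin")
  expect_equal(a[, 1:8], a[, 9:16], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(median(log2(a[, 1:8])), median(log2(a[, 9:16])),
               tolerance = 1e-9)
  # rank order within each array unchanged (monotone transform)
  for (j in seq_len(ncol(a))) expect_equal(rank(a[, j]), rank(fg[, j]))
  # idempotent
  expect_equal(assay(batchAdjust(y), "ubiquitin"), a, tolerance = 1e-9)
})

test_that("single batch and unknown batch labels are handled", {
  meta <- toyMeta(1)
  fg <- matrix(rlnorm(10 * 8, 6, 1), 10, 8,
               dimnames = list(sprintf("P%03d", 1:10), meta$array_id))
  x <- makeArraySet(list(ubiquitin = fg), meta, level = "protein")
  expect_equal(assay(batchAdjust(x), "ubiquitin"), fg, tolerance = 1e-12)
  expect_error(batchAdjust(x, batches = rep("nope", 8)), "unknown batch")
})

test_that("the full chain is deterministic and logged in order", {
  cfg <- simulationConfig(n_proteins = 30, rng_seed = 13)
  sim <- simulateProtoarrayStudy(cfg)
  x1 <- preprocessChain(assembleMatrix(sim$spots, sim$meta))
  x2 <- preprocessChain(assembleMatrix(sim$spots, sim$meta))
  expect_equal(assay(x1, "ubiquitin"), assay(x2, "ubiquitin"))
  expect_equal(transformLog(x1),
               c("correctBackground", "averageDuplicates",
                 "quantileNormalize", "batchAdjust"))
  expect_equal(length(normalizationReport(x1)), 4)
})
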