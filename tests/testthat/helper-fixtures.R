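# Shared fixture builders. Everything is generated in code; no data files.

# construct a protein-level UbLArraySet directly from assay matrices
makeArraySet <- function(assays, meta, level = "protein") {
  cd <- S4Vectors::DataFrame(meta, row.names = meta$array_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(
      protein_id = sub("\\.[0-9]+$", "", rownames(assays[[1]])),
      row.names = rownames(assays[[1]])),
    colData = cd)
  S4Vectors::metadata(se)$transformLog <- character()
  new("UbLArraySet", se, level = level)
}

# standard 24-array metadata (3 experiments x 2 lines x 3 conditions + 2 NEM)
toyMeta <- function(nExp = 3) {
  rows <- list()
  for (e in seq_len(nExp)) {
    for (line in c("HL-60", "U937"))
      for (cond in c("parental", "ARA-R", "DNR-R"))
        rows[[length(rows) + 1]] <- data.frame(
          array_id = sprintf("E%d_%s_%s", e, sub("-", "", line), cond),
          experiment = paste0("exp", e), cell_line = line,
          condition = cond, nem_control = FALSE)
    for (k in 1:2)
      rows[[length(rows) + 1]] <- data.frame(
        array_id = sprintf("E%d_NEM%d", e, k),
        experiment = paste0("exp", e),
        cell_line = c("HL-60", "U937")[k], condition = "parental",
        nem_control = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimal two-protein GPR spot table for writer/reader round-trips
toyGPRSpots <- function() {
  data.frame(
    block = 1L, column = rep(c(1L, 2L), 2),
    row = rep(1:2, each = 2),
    name = rep(c("protein_A", "protein_B"), each = 2),
    id = rep(c("PA", "PB"), each = 2),
    F635 = c(1000, 1100, 500, 520), B635 = c(100, 110, 90, 95),
    F532 = c(2000, 2100, 800, 820), B532 = c(120, 115, 100, 105),
    flags = 0L)
}

# independently coded Welch-Satterthwaite closed form (test oracle)
welchOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  list(statistic = stat, df = df, p = 2 * stats::pt(-abs(stat), df))
}

# brute-force two-sided Mann-Whitney p by full enumeration (test oracle)
mwwEnumOracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  us <- apply(sets, 2, function(i) sum(r[i]) - n * (n + 1) / 2)
  lower <- mean(us <= uObs + 1e-9); upper <- mean(us >= uObs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# brute-force signed-rank p over all 2^n sign patterns (test oracle)
signedRankEnumOracle <- function(values, mu = 0) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  lower <- mean(ws <= wObs + 1e-9); upper <- mean(ws >= wObs - 1e-9)
  min(1, 2 * min(lower, upper))
}
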