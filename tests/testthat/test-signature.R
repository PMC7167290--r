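# Two-stage calling: modification calls vs NEM controls, ratio pairing,
# differential thresholds, signature merging.

# protein-level set over the standard 24-array design with given per-array
# means (rows = proteins)
proteinSet <- function(values, meta = toyMeta(3)) {
  makeArraySet(list(ubiquitin = values), meta, level = "protein")
}

test_that("the 800 a.u. floor gates otherwise significant proteins", {
  meta <- toyMeta(3)
  nem <- meta$nem_control
  set.seed(3)
  mkRow <- function(permMean, nemMean, noise = 1) {
    v <- numeric(nrow(meta))
    v[!nem] <- permMean + rnorm(sum(!nem), 0, noise)
    v[nem] <- nemMean + rnorm(sum(nem), 0, noise)
    v
  }
  vals <- rbind(P1 = mkRow(799, 100),   # significant but below floor
                P2 = mkRow(2000, 100),  # significant and above floor
                P3 = mkRow(2000, 2000)) # identical in both groups
  colnames(vals) <- meta$array_id
  calls <- callModified(proteinSet(vals))
  expect_false(calls$called[calls$protein == "P1"])
  expect_lt(calls$p_welch[calls$protein == "P1"], 0.05)
  expect_true(calls$called[calls$protein == "P2"])
  expect_false(calls$called[calls$protein == "P3"])
})

test_that("modification calling requires NEM controls", {
  meta <- toyMeta(1)
  meta <- meta[!meta$nem_control, ]
  vals <- matrix(1000, 2, nrow(meta),
                 dimnames = list(c("P1", "P2"), meta$array_id))
  expect_error(callModified(proteinSet(vals, meta)), "NEM")
})

test_that("monotonicity: stricter thresholds never enlarge the called set", {
  sim <- simulateProtoarrayStudy(simulationConfig(n_proteins = 150,
                                                  rng_seed = 37))
  x <- preprocessChain(assembleMatrix(sim$spots, sim$meta))
  base <- callModified(x, alpha = 0.05, intensityFloor = 800)
  higherFloor <- callModified(x, alpha = 0.05, intensityFloor = 1200)
  lowerAlpha <- callModified(x, alpha = 0.01, intensityFloor = 800)
  key <- function(d) paste(d$protein, d$modifier)[d$called]
  expect_true(all(key(higherFloor) %in% key(base)))
  expect_true(all(key(lowerAlpha) %in% key(base)))
})

test_that("ratios pair resistant arrays with same-experiment parental partners", {
  meta <- toyMeta(3)
  vals <- matrix(0, 2, nrow(meta),
                 dimnames = list(c("P1", "P2"), meta$array_id))
  vals["P1", ] <- ifelse(meta$condition == "parental", 100, 250)
  vals["P2", ] <- 1000
  calls <- data.frame(protein = c("P1", "P2"), modifier = "ubiquitin",
                      called = TRUE)
  rat <- computeRatios(proteinSet(vals), calls, scope = "global")
  expect_equal(nrow(rat), 2 * 12)  # 3 exp x 2 lines x 2 drugs per protein
  expect_equal(unique(rat$ratio[rat$protein == "P1"]), 2.5)
  expect_equal(unique(rat$ratio[rat$protein == "P2"]), 1)

  # missing parental partner is a hard error naming the array
  meta2 <- meta[!(meta$condition == "parental" & !meta$nem_control &
                    meta$cell_line == "U937" &
                    meta$experiment == "exp2"), ]
  vals2 <- vals[, meta2$array_id]
  expect_error(computeRatios(proteinSet(vals2, meta2), calls),
               "parental partner.*U937_ARA-R|U937")
})

test_that("within-experiment pairing cancels batch effects", {
  meta <- toyMeta(3)
  set.seed(41)
  base <- matrix(rlnorm(20 * nrow(meta), 7, 0.5), 20, nrow(meta),
                 dimnames = list(sprintf("P%02d", 1:20), meta$array_id))
  offsets <- c(exp1 = 1, exp2 = 2, exp3 = 0.5)
  shifted <- sweep(base, 2, offsets[meta$experiment], `*`)
  calls <- data.frame(protein = rownames(base), modifier = "ubiquitin",
                      called = TRUE)
  r1 <- computeRatios(proteinSet(base), calls)
  r2 <- computeRatios(proteinSet(shifted), calls)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-9)
})

test_that("global differential calling applies the dual test and 1.25/0.8 gate", {
  jitter <- c(-0.02, 0.015, -0.01, 0.02, -0.015, 0.01,
              0.02, -0.02, 0.01, -0.01, 0.015, -0.005)
  mkRatios <- function(gm) data.frame(
    protein = "P1", modifier = "ubiquitin", experiment = rep(1:3, 4),
    cell_line = "U937", drug = "ARA-R", ratio = gm * 2^jitter)
  rec <- callDifferentialGlobal(mkRatios(1.30))
  expect_true(rec$called)
  expect_equal(rec$direction, "up")
  expect_lt(rec$p_t, 0.05)
  expect_lt(rec$p_signed_rank, 0.05)

  # significant but inside the ratio gate -> not called
  rec2 <- callDifferentialGlobal(mkRatios(1.10))
  expect_false(rec2$called)
  expect_lt(rec2$p_t, 0.05)

  # all ratios exactly 1: p ~ 1, not called
  flat <- mkRatios(1.0); flat$ratio <- 1
  rec3 <- callDifferentialGlobal(flat)
  expect_false(rec3$called)
  expect_equal(rec3$p_t, 1)

  # down-regulated calls mirror up-regulated ones
  rec4 <- callDifferentialGlobal(mkRatios(0.7))
  expect_true(rec4$called)
  expect_equal(rec4$direction, "down")
})

test_that("separated calling uses the one-sample t only, with the 1.5/0.66 gate", {
  mk <- function(gm) data.frame(
    protein = "P1", modifier = "SUMO1", experiment = 1:3,
    cell_line = "HL-60", drug = "DNR-R",
    ratio = gm * 2^c(-0.02, 0.01, 0.01))
  rec <- callDifferentialSeparated(mk(1.6))
  expect_true(rec$called)
  expect_true(is.na(rec$p_signed_rank))
  rec2 <- callDifferentialSeparated(mk(1.4))
  expect_false(rec2$called)  # gate, despite tiny p
  expect_lt(rec2$p_t, 0.05)
  # zero-variance ratios hit the degenerate-convention path, no crash
  con <- mk(2); con$ratio <- 2
  rec3 <- callDifferentialSeparated(con)
  expect_true(rec3$called)
  expect_equal(rec3$p_t, 0)
})

test_that("proteins with fewer than two ratios are skipped with a warning", {
  one <- data.frame(protein = "P1", modifier = "ubiquitin",
                    experiment = 1, cell_line = "U937", drug = "ARA-R",
                    ratio = 2)
  expect_warning(rec <- callDifferentialGlobal(one), "fewer than 2")
  expect_equal(nrow(rec), 0)
})

test_that("signature merge unions per modifier and annotates sources", {
  g <- data.frame(protein = c("A", "B"), modifier = "ubiquitin",
                  scope = "global", ratio_gm = 2, p_signed_rank = 0.01,
                  p_t = 0.01, direction = "up", called = TRUE)
  s <- data.frame(protein = c("B", "C"), modifier = "ubiquitin",
                  scope = "separated", cell_line = "U937",
                  drug = "ARA-R", ratio_gm = 2, p_signed_rank = NA,
                  p_t = 0.01, direction = "up", called = TRUE)
  sig <- mergeSignature(g, s)
  expect_setequal(sig$protein, c("A", "B", "C"))
  expect_equal(sig$source[sig$protein == "B"], "both")
  expect_equal(signatureCounts(sig)$ubiquitin, 3)

  # idempotent and commutative in its inputs
  sig2 <- mergeSignature(g[c(2, 1), ], s[c(2, 1), ])
  expect_equal(as.data.frame(sig), as.data.frame(sig2))
})

test_that("merging the published component counts reproduces 94/35/122", {
  mkRec <- function(proteins, modifier, scope) {
    d <- data.frame(protein = proteins, modifier = modifier,
                    scope = scope, ratio_gm = 2,
                    p_signed_rank = ifelse(scope == "global", 0.01, NA),
                    p_t = 0.01, direction = "up", called = TRUE)
    if (scope == "separated") { d$cell_line <- "U937"; d$drug <- "ARA-R" }
    d
  }
  # ubiquitin: 52 global; 65 separated of which 42 new -> 94 distinct
  ubGlobal <- sprintf("U%03d", 1:52)
  ubSep <- c(sprintf("U%03d", 1:23), sprintf("N%03d", 1:42))
  # SUMO-1: 27 global; 12 separated of which 8 new -> 35 distinct
  suGlobal <- sprintf("S%03d", 1:27)
  suSep <- c(sprintf("S%03d", 1:4), sprintf("T%03d", 1:8))
  # 7 proteins modified by both UbLs -> 122 distinct proteins overall
  # (replace SUMO-only globals not reused by the separated analysis)
  suGlobal[21:27] <- ubGlobal[1:7]
  g <- rbind(mkRec(ubGlobal, "ubiquitin", "global"),
             mkRec(suGlobal, "SUMO1", "global"))
  s <- rbind(mkRec(ubSep, "ubiquitin", "separated"),
             mkRec(suSep, "SUMO1", "separated"))
  sig <- mergeSignature(g, s)
  cnt <- signatureCounts(sig)
  expect_equal(cnt$ubiquitin, 94)
  expect_equal(cnt$SUMO1, 35)
  expect_equal(cnt$distinct_proteins, 122)
})

test_that("Venn counts split called proteins by modifier overlap", {
  calls <- data.frame(
    protein = c("A", "B", "C", "A", "D", "E"),
    modifier = c(rep("ubiquitin", 3), rep("SUMO1", 3)),
    called = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  v <- vennCounts(calls)
  expect_equal(v$ubiquitin, 2)  # B, C exclusive
  expect_equal(v$SUMO1, 1)      # D exclusive (E not called)
  expect_equal(v$both, 1)       # A
  expect_equal(v$total, 4)
})

test_that("on null data, few modified proteins are called differential", {
  # planted modification without differential signal: the dual test plus
  # ratio gate keeps the false differential fraction well below nominal
  falseFrac <- c()
  for (seed in 1:5) {
    sim <- simulateProtoarrayStudy(simulationConfig(
      n_proteins = 200, frac_differential = 0, rng_seed = seed))
    x <- preprocessChain(assembleMatrix(sim$spots, sim$meta))
    calls <- callModified(x)
    rat <- computeRatios(x, calls)
    g <- callDifferentialGlobal(rat)
    if (nrow(g)) falseFrac <- c(falseFrac, mean(g$called))
  }
  expect_lt(mean(falseFrac), 0.01)
})
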