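# Variable expansion, LDA fit/posterior, cross-validation, GA selection,
# nested subsets.

test_that("variable expansion reproduces the 7/9/7 -> 30 structure", {
  sumoOnly <- sprintf("S%d", 1:7); ubOnly <- sprintf("U%d", 1:9)
  dual <- sprintf("D%d", 1:7)
  selection <- rbind(
    data.frame(protein = sumoOnly, modifier = "SUMO1"),
    data.frame(protein = ubOnly, modifier = "ubiquitin"),
    data.frame(protein = dual, modifier = "SUMO1"),
    data.frame(protein = dual, modifier = "ubiquitin"))
  samples <- sprintf("CL%02d", 1:4)
  meas <- expand.grid(sample_id = samples,
                      key = paste0(selection$protein, "|",
                                   selection$modifier),
                      stringsAsFactors = FALSE)
  meas$protein <- sub("\\|.*", "", meas$key)
  meas$modifier <- sub(".*\\|", "", meas$key)
  meas$value <- seq_len(nrow(meas))
  X <- expandVariables(selection, meas,
                       labels = setNames(rep(c("sensitive", "resistant"),
                                             2), samples))
  expect_equal(ncol(X), 30)
  expect_equal(nrow(X), 4)
  # a dual-flagged protein contributes two variables
  expect_length(grep("^D1\\|", variableNames(X)), 2)

  # missing measurement is a named error
  expect_error(expandVariables(selection, meas[-1, ]),
               "missing measurement")
})

test_that("LDA matches the closed form for known Gaussians", {
  set.seed(101)
  n <- 10000
  Sigma <- matrix(c(1, 0.5, 0.5, 2), 2)
  L <- chol(Sigma)
  Xs <- matrix(rnorm(2 * n), n) %*% L
  Xr <- sweep(matrix(rnorm(2 * n), n) %*% L, 2, c(1.5, 1), `+`)
  X <- rbind(Xs, Xr)
  colnames(X) <- c("v1|ubiquitin", "v2|SUMO1")
  lab <- rep(c("sensitive", "resistant"), each = n)
  fit <- ldaFit(X, lab, shrinkage = 0)
  wTrue <- solve(Sigma, c(1.5, 1))
  expect_equal(unname(coef(fit)), unname(wTrue), tolerance = 0.05)
  # against the empirical closed form (same sample) to 1e-6
  m1 <- colMeans(Xs); m2 <- colMeans(Xr)
  S <- (crossprod(sweep(Xs, 2, m1)) + crossprod(sweep(Xr, 2, m2))) /
    (2 * n - 2)
  expect_equal(unname(coef(fit)), unname(solve(S, m2 - m1)),
               tolerance = 1e-6)
})

test_that("LDA agrees with an independent reference implementation", {
  set.seed(103)
  X <- rbind(matrix(rnorm(40 * 3), 40),
             matrix(rnorm(40 * 3, 1), 40))
  colnames(X) <- paste0("v", 1:3)
  lab <- rep(c("sensitive", "resistant"), each = 40)
  fit <- ldaFit(X, lab, shrinkage = 0)
  ref <- MASS::lda(X, grouping = factor(lab,
                                        c("sensitive", "resistant")))
  # identical posteriors (coefficients agree up to scale)
  post <- ldaPredictProba(fit, X)$probability_resistant
  refPost <- predict(ref, X)$posterior[, "resistant"]
  expect_equal(post, unname(refPost), tolerance = 1e-8)
})

test_that("the 1-D posterior equals the logistic closed form", {
  set.seed(105)
  x <- c(rnorm(50, 0), rnorm(50, 2))
  lab <- rep(c("sensitive", "resistant"), each = 50)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "v|ubiquitin"))
  fit <- ldaFit(X, lab, shrinkage = 0)
  m1 <- mean(x[1:50]); m2 <- mean(x[51:100])
  s2 <- (sum((x[1:50] - m1)^2) + sum((x[51:100] - m2)^2)) / 98
  bayes <- function(z) plogis((m2 - m1) / s2 * z -
                                (m2^2 - m1^2) / (2 * s2))
  grid <- seq(-2, 4, length.out = 21)
  got <- ldaPredictProba(fit, matrix(grid, ncol = 1))
  expect_equal(got$probability_resistant, bayes(grid), tolerance = 1e-9)
  # midpoint of class means has posterior exactly 0.5 under equal priors
  mid <- ldaPredictProba(fit, matrix((m1 + m2) / 2, 1, 1))
  expect_equal(mid$probability_resistant, 0.5, tolerance = 1e-12)
  expect_equal(mid$class, "indeterminate")
})

test_that("posteriors are proper probabilities and the 50% rule is strict", {
  set.seed(107)
  X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 2), 10))
  colnames(X) <- c("a|ubiquitin", "b|SUMO1")
  fit <- ldaFit(X, rep(c("sensitive", "resistant"), each = 10))
  p <- ldaPredictProba(fit, matrix(rnorm(40), 20))$probability_resistant
  expect_true(all(p >= 0 & p <= 1))
  atR <- ldaPredictProba(fit, fit@classMeans["resistant", ])
  expect_gt(atR$probability_resistant, 0.5)
  expect_equal(atR$class, "resistant")
  expect_error(ldaPredictProba(fit, rnorm(3)), "dimension mismatch")
})

test_that("LDA accuracy is invariant to affine rescaling of a variable", {
  set.seed(109)
  sim <- simulateScoreCohort(nPerClass = 10, nVariables = 5,
                             nInformative = 3, seed = 7)
  acc1 <- cvAccuracy(sim$X, variableNames(sim$X))
  X2 <- sim$X@X
  X2[, 1] <- X2[, 1] * 100 + 7
  acc2 <- cvAccuracy(VariableMatrix(X2, sim$X@labels),
                     variableNames(sim$X))
  expect_equal(acc1, acc2, tolerance = 1e-9)
  # coefficients transform inversely under scaling
  f1 <- ldaFit(sim$X, shrinkage = 0)
  f2 <- ldaFit(VariableMatrix(X2, sim$X@labels), shrinkage = 0)
  expect_equal(coef(f2)[[1]] * 100, coef(f1)[[1]], tolerance = 1e-8)
})

test_that("degenerate LDA inputs raise informative errors", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a|u", "b|u")))
  expect_error(ldaFit(X, rep("resistant", 10)), "both classes")
  Xdup <- cbind(X, X[, 1, drop = FALSE])
  colnames(Xdup) <- c("a|u", "b|u", "c|u")
  expect_error(ldaFit(Xdup, rep(c("sensitive", "resistant"), each = 5),
                      shrinkage = 0), "singular")
  # with shrinkage the same fit succeeds
  expect_s4_class(ldaFit(Xdup, rep(c("sensitive", "resistant"), each = 5),
                         shrinkage = "auto"), "LDAModel")
  Xc <- X; Xc[, 2] <- 3
  expect_warning(ldaFit(Xc, rep(c("sensitive", "resistant"), each = 5)),
                 "zero-variance")
})

test_that("LOOCV matches manual fold-by-fold computation on a hand-sized set", {
  X <- matrix(c(0, 0.1, -0.1, 1.9, 2, 2.1,
                0.05, 0, 0.1, 2.1, 2, 1.95), 6, 2,
              dimnames = list(NULL, c("a|u", "b|u")))
  lab <- rep(c("sensitive", "resistant"), each = 3)
  vm <- VariableMatrix(X, lab)
  got <- cvAccuracy(vm, scheme = list(type = "loocv"), shrinkage = 0.1)
  manual <- mean(vapply(1:6, function(i) {
    fit <- ldaFit(X[-i, , drop = FALSE], lab[-i], shrinkage = 0.1)
    ldaPredictProba(fit, X[i, , drop = FALSE])$class == lab[i]
  }, logical(1)))
  expect_equal(got, manual)
  # perfectly separated data: LOOCV accuracy 1
  expect_equal(got, 1)
  expect_error(cvAccuracy(VariableMatrix(X, c("sensitive", rep(
    "resistant", 5))), scheme = list(type = "loocv")), "singleton")
  expect_error(cvAccuracy(vm, character()), "empty variable subset")
})

test_that("GA frequency bookkeeping and determinism hold", {
  sim <- simulateScoreCohort(nPerClass = 8, nVariables = 6,
                             nInformative = 2, seed = 3)
  cfg <- gaConfig(popSize = 12, generations = 8, nRuns = 4, seed = 11,
                  cvScheme = list(type = "split", train_frac = 0.75,
                                  n_rep = 4, seed = 5))
  s1 <- gaSelect(sim$X, cfg)
  s2 <- gaSelect(sim$X, cfg)
  expect_identical(gaSolutions(s1), gaSolutions(s2))
  expect_identical(s1@fitness, s2@fitness)
  # frequency = fraction of runs selecting the variable
  counts <- table(unlist(gaSolutions(s1)))
  for (v in names(counts))
    expect_equal(selectionFrequency(s1)[[v]],
                 unname(counts[v]) / 4)
  expect_true(all(selectionFrequency(s1) >= 0 &
                    selectionFrequency(s1) <= 1))
})

test_that("the parsimony penalty shrinks selected subsets on noise data", {
  set.seed(113)
  X <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(NULL, paste0("n", 1:8, "|u")))
  vm <- VariableMatrix(X, rep(c("sensitive", "resistant"), each = 10))
  scheme <- list(type = "split", train_frac = 0.7, n_rep = 4, seed = 9)
  s0 <- gaSelect(vm, gaConfig(popSize = 14, generations = 10, nRuns = 5,
                              lambda = 0, seed = 21, cvScheme = scheme))
  s1 <- gaSelect(vm, gaConfig(popSize = 14, generations = 10, nRuns = 5,
                              lambda = 0.3, seed = 21, cvScheme = scheme))
  expect_lt(mean(lengths(gaSolutions(s1))),
            mean(lengths(gaSolutions(s0))))
})

test_that("nested subsets are strictly nested with documented tie-breaks", {
  sols <- new("GASolutionSet",
              solutions = list(c("a|u", "b|u"), c("a|u", "c|u"),
                               c("a|u", "b|u", "d|u"), c("b|u")),
              fitness = rep(0.9, 4),
              frequency = c("a|u" = 0.75, "b|u" = 0.75, "c|u" = 0.25,
                            "d|u" = 0.25, "e|u" = 0),
              config = list())
  ns <- buildNestedSubsets(sols, cutPoints = c(2, 4))
  expect_equal(lengths(ns$subsets), c(subset1 = 2L, subset2 = 4L))
  expect_true(all(ns$subsets[[1]] %in% ns$subsets[[2]]))
  # frequency ties resolved lexicographically when no data given
  expect_equal(ns$subsets[[1]], c("a|u", "b|u"))
  expect_equal(ns$ranking[3:4], c("c|u", "d|u"))
  # e never selected: excluded entirely
  expect_false("e|u" %in% ns$ranking)
  expect_warning(buildNestedSubsets(sols, cutPoints = c(2, 10)),
                 "truncated")
  # deterministic across repeated calls
  expect_identical(ns, buildNestedSubsets(sols, cutPoints = c(2, 4)))
})

test_that("default cut points fix the second subset at seven variables", {
  freq <- setNames(seq(0.9, 0.1, length.out = 20),
                   sprintf("v%02d|u", 1:20))
  sols <- new("GASolutionSet", solutions = list(names(freq)),
              fitness = 1, frequency = freq, config = list())
  ns <- buildNestedSubsets(sols)
  expect_equal(lengths(ns$subsets)[[2]], 7L)
  expect_true(all(diff(lengths(ns$subsets)) > 0))
})

test_that("subset evaluation prefers smaller subsets on ties", {
  sim <- simulateScoreCohort(nPerClass = 10, nVariables = 6,
                             nInformative = 6, seed = 5)
  ns <- structure(list(ranking = variableNames(sim$X),
                       subsets = list(s1 = variableNames(sim$X)[1:3],
                                      s2 = variableNames(sim$X)),
                       cutPoints = c(3L, 6L)),
                  class = "NestedSubsets")
  ev <- evaluateSubsets(sim$X, ns)
  expect_equal(nrow(ev), 2)
  if (ev$accuracy[1] == ev$accuracy[2])
    expect_equal(attr(ev, "best"), "s1")
  # a single subset is trivially the best
  ns1 <- structure(list(ranking = ns$ranking,
                        subsets = ns$subsets[1], cutPoints = 3L),
                   class = "NestedSubsets")
  expect_equal(attr(evaluateSubsets(sim$X, ns1), "best"), "s1")
})

test_that("classification follows the strict 50% rule", {
  fit <- ldaFit(matrix(c(0, 0.1, 1.9, 2), 4, 1,
                       dimnames = list(NULL, "v|u")),
                c("sensitive", "sensitive", "resistant", "resistant"),
                shrinkage = 0)
  low <- classifySample(fit, matrix(0.9, 1, 1))
  high <- classifySample(fit, matrix(1.1, 1, 1))
  expect_true(low$probability_resistant < 0.5)
  expect_equal(low$class, "sensitive")
  expect_true(high$probability_resistant > 0.5)
  expect_equal(high$class, "resistant")
})
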