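# UbL score: variable expansion over the signature, GA feature selection
# with selection-frequency ranking and nested subsets, LDA fitting with
# cross-validation and the 50% posterior classification rule.

#' Expand a signature selection into a variable matrix
#'
#' Each (protein, modifier) flag becomes one variable; a protein flagged
#' for both modifiers contributes two variables (so 7 SUMO-only + 9
#' Ub-only + 7 dual-flagged proteins yield 30 variables). Variable ids are
#' `"<protein>|<modifier>"`.
#'
#' @param selection data.frame with columns `protein`, `modifier` (one row
#'   per flag; every protein must appear with >= 1 modifier).
#' @param measurements Long data.frame `sample_id`, `protein`, `modifier`,
#'   `value`: the measured modification level of the protein in the sample.
#' @param labels Named vector/factor of `"sensitive"`/`"resistant"` per
#'   sample id (`NA` or absent = unlabeled).
#' @return A [VariableMatrix-class].
#' @export
expandVariables <- function(selection, measurements, labels = NULL) {
  stopifnot(is.data.frame(selection),
            all(c("protein", "modifier") %in% names(selection)))
  if (!nrow(selection)) stopf("empty signature selection")
  vars <- unique(paste0(selection$protein, "|", selection$modifier))
  samples <- unique(measurements$sample_id)
  mkey <- paste0(measurements$protein, "|", measurements$modifier)
  X <- matrix(NA_real_, length(samples), length(vars),
              dimnames = list(samples, vars))
  idx <- cbind(match(measurements$sample_id, samples), match(mkey, vars))
  ok <- !is.na(idx[, 2L])
  X[idx[ok, , drop = FALSE]] <- measurements$value[ok]
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stopf("missing measurement for sample '%s', variable '%s'",
          samples[[bad[[1L]]]], vars[[bad[[2L]]]])
  }
  lab <- rep(NA_character_, length(samples))
  if (!is.null(labels)) {
    lab <- as.character(labels)[match(samples, names(labels))]
  }
  VariableMatrix(X, lab)
}

# lean two-class LDA core used inside CV loops: returns list(w, b) or NULL
# on singular covariance without shrinkage
.ldaCore <- function(Xm, y, shrinkage = "auto", priors = NULL) {
  i1 <- y == "sensitive"
  n1 <- sum(i1); n2 <- length(y) - n1
  p <- ncol(Xm)
  X1 <- Xm[i1, , drop = FALSE]; X2 <- Xm[!i1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  xc <- rbind(X1 - rep(m1, each = n1), X2 - rep(m2, each = n2))
  n <- n1 + n2
  S <- crossprod(xc) / (n - 2L)
  lam <- shrinkage
  if (identical(shrinkage, "auto")) {
    if (p == 1L) lam <- 0 else {
      # Schafer-Strimmer estimate of the off-diagonal shrinkage intensity
      W <- crossprod(xc)        # sum_k x_ki x_kj
      W2 <- crossprod(xc * xc)  # sum_k (x_ki x_kj)^2
      varS <- n / ((n - 1L)^3) * (W2 - W * W / n)
      off <- upper.tri(S)
      denom <- sum(S[off]^2)
      lam <- if (denom <= 0) 1 else min(1, max(0, sum(varS[off]) / denom))
    }
  }
  Sl <- (1 - lam) * S + lam * diag(diag(S), p)
  w <- tryCatch(solve(Sl, m2 - m1), error = function(e) NULL)
  if (is.null(w)) return(NULL)
  if (is.null(priors)) priors <- c(n1, n2) / n
  b <- -sum(w * (m1 + m2)) / 2 + log(priors[[2L]] / priors[[1L]])
  list(w = w, b = b, m1 = m1, m2 = m2, S = Sl, priors = priors,
       lambda = lam)
}

#' Fit the linear discriminant score
#'
#' Two-class LDA with pooled within-class covariance, optionally shrunk
#' toward its diagonal (`shrinkage = "auto"` uses an analytic
#' Schafer-Strimmer-type estimate of the off-diagonal shrinkage intensity,
#' appropriate when the variable count approaches the sample count).
#' Coefficients are `solve(Sigma, mu_R - mu_S)`; the resulting score
#' `alpha x R1 + ... + omega x Rn` feeds the logistic posterior of the
#' resistant class.
#'
#' @param X A [VariableMatrix-class] (unlabeled rows are ignored) or a
#'   numeric matrix.
#' @param labels Required when `X` is a bare matrix.
#' @param shrinkage `"auto"`, or a number in `[0, 1]` (0 = none).
#' @param priors Optional named class priors (default: class proportions).
#' @return An [LDAModel-class].
#' @export
ldaFit <- function(X, labels = NULL, shrinkage = "auto", priors = NULL) {
  if (is(X, "VariableMatrix")) {
    labels <- X@labels
    X <- X@X
  }
  y <- factor(as.character(labels), levels = c("sensitive", "resistant"))
  keep <- !is.na(y)
  X <- as.matrix(X)[keep, , drop = FALSE]
  y <- y[keep]
  tab <- table(y)
  if (any(tab == 0L))
    stopf("both classes must be present (got %s)",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (any(tab < 2L)) stopf("need >= 2 samples per class")
  v <- apply(X, 2L, var)
  if (any(v == 0)) {
    warnf("dropping %d zero-variance variable(s): %s", sum(v == 0),
          paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
    if (!ncol(X)) stopf("no variables left after dropping constants")
  }
  core <- .ldaCore(X, as.character(y), shrinkage, priors)
  if (is.null(core))
    stopf("singular pooled covariance; use shrinkage = 'auto' or > 0")
  cm <- rbind(sensitive = core$m1, resistant = core$m2)
  colnames(cm) <- colnames(X)
  new("LDAModel",
      coefficients = setNames(core$w, colnames(X)),
      intercept = core$b, classMeans = cm, pooledCov = core$S,
      priors = setNames(core$priors, c("sensitive", "resistant")),
      shrinkage = core$lambda)
}

#' Posterior probability of resistance and class call
#'
#' Posterior from Gaussian class-conditionals with the shared covariance,
#' i.e. `plogis(score + intercept)`. Classification follows the 50% rule:
#' below 0.5 sensitive, above 0.5 resistant, exactly 0.5 indeterminate.
#'
#' @param model An [LDAModel-class].
#' @param x Numeric vector (one sample) or matrix (samples in rows) with
#'   the model's variables.
#' @return data.frame `sample`, `probability_resistant`, `class`.
#' @export
ldaPredictProba <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list("sample1", names(x)))
  vars <- names(model@coefficients)
  if (ncol(x) != length(vars))
    stopf("dimension mismatch: model has %d variable(s), input has %d",
          length(vars), ncol(x))
  if (!is.null(colnames(x)) && all(vars %in% colnames(x)))
    x <- x[, vars, drop = FALSE]
  p <- stats::plogis(as.vector(x %*% model@coefficients) + model@intercept)
  cls <- ifelse(p < 0.5, "sensitive",
                ifelse(p > 0.5, "resistant", "indeterminate"))
  data.frame(sample = rownames(x) %||% paste0("sample", seq_along(p)),
             probability_resistant = p, class = cls)
}

#' @rdname ldaPredictProba
#' @export
classifySample <- function(model, x) ldaPredictProba(model, x)

#' Cross-validated classification accuracy of a variable subset
#'
#' Fits the LDA on training folds and scores held-out samples by the 50%
#' rule. `scheme = list(type = "loocv")` performs leave-one-out (an error
#' if a class has a single member); `list(type = "split", train_frac,
#' n_rep, seed)` performs seeded stratified train/test splits, redrawing
#' folds whose training set loses a class.
#'
#' @param X A [VariableMatrix-class].
#' @param subset Character vector of variable ids (non-empty).
#' @param scheme Cross-validation scheme list (see Details).
#' @param shrinkage Passed to the internal LDA fit.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
cvAccuracy <- function(X, subset = variableNames(X),
                       scheme = list(type = "loocv"), shrinkage = "auto") {
  stopifnot(is(X, "VariableMatrix"))
  if (!length(subset)) stopf("empty variable subset")
  miss <- setdiff(subset, variableNames(X))
  if (length(miss))
    stopf("unknown variable(s): %s", paste(miss, collapse = ", "))
  keep <- !is.na(X@labels)
  Xm <- X@X[keep, subset, drop = FALSE]
  y <- as.character(X@labels[keep])
  n <- length(y)
  predOne <- function(fitIdx, testIdx) {
    core <- .ldaCore(Xm[fitIdx, , drop = FALSE], y[fitIdx], shrinkage)
    if (is.null(core)) return(rep(NA, length(testIdx)))
    p <- stats::plogis(as.vector(Xm[testIdx, , drop = FALSE] %*% core$w) +
                         core$b)
    ifelse(p > 0.5, "resistant", ifelse(p < 0.5, "sensitive", "none"))
  }
  if (identical(scheme$type %||% "loocv", "loocv")) {
    tab <- table(y)
    if (any(tab < 2L))
      stopf("LOOCV with a singleton class is undefined")
    hits <- vapply(seq_len(n), function(i) {
      cl <- predOne(setdiff(seq_len(n), i), i)
      isTRUE(cl == y[[i]])
    }, logical(1))
    return(mean(hits))
  }
  if (!identical(scheme$type, "split"))
    stopf("unknown CV scheme '%s'", scheme$type)
  trainFrac <- scheme$train_frac %||% 2 / 3
  nRep <- scheme$n_rep %||% 20L
  seed <- scheme$seed %||% 1L
  accs <- withSeed(deriveSeed(seed, "cv_split"), {
    vapply(seq_len(nRep), function(r) {
      for (try_ in 1:100) {
        trainIdx <- unlist(lapply(unique(y), function(cl) {
          i <- which(y == cl)
          sample(i, max(2L, round(trainFrac * length(i))))
        }))
        if (length(unique(y[trainIdx])) == 2L &&
            length(trainIdx) < n) break
      }
      testIdx <- setdiff(seq_len(n), trainIdx)
      cl <- predOne(trainIdx, testIdx)
      mean(cl == y[testIdx])
    }, numeric(1))
  })
  mean(accs, na.rm = TRUE)
}

#' GA configuration
#'
#' Defaults: population 50, 100 generations, crossover 0.8, per-bit
#' mutation 0.1, 5% elitism, parsimony weight `lambda` 0.05, 40 runs with
#' the mutation rate jittered uniformly in `[0.05, 0.2]` across runs
#' (emulating repeated runs under different parameter settings).
#'
#' @param popSize,generations,pCrossover,pMutation,elitism,lambda,nRuns
#'   GA parameters (see Description).
#' @param mutationJitter Range the per-run mutation rate is drawn from.
#' @param initProb Per-bit inclusion probability of the initial population
#'   (default 0.3; sparse initialization suits feature selection where
#'   informative subsets are expected to be small).
#' @param cvScheme Cross-validation scheme used inside the fitness.
#' @param shrinkage LDA shrinkage used inside the fitness.
#' @param seed Master seed; each run uses a derived sub-seed.
#' @return Validated config list of class `GAConfig`.
#' @export
gaConfig <- function(popSize = 50L, generations = 100L, pCrossover = 0.8,
                     pMutation = 0.1, elitism = 0.05, lambda = 0.05,
                     nRuns = 40L, mutationJitter = c(0.05, 0.2),
                     initProb = 0.3,
                     cvScheme = list(type = "loocv"), shrinkage = "auto",
                     seed = 1L) {
  probs <- c(pCrossover, pMutation, elitism, initProb)
  if (any(probs < 0 | probs > 1))
    stopf("GA probabilities must lie in [0, 1]")
  if (nRuns < 1L) stopf("nRuns must be >= 1")
  structure(list(popSize = as.integer(popSize),
                 generations = as.integer(generations),
                 pCrossover = pCrossover, pMutation = pMutation,
                 elitism = elitism, lambda = lambda,
                 nRuns = as.integer(nRuns),
                 mutationJitter = mutationJitter, initProb = initProb,
                 cvScheme = cvScheme,
                 shrinkage = shrinkage, seed = as.integer(seed)),
            class = "GAConfig")
}

#' Subset fitness used by the GA
#'
#' `fitness(S) = cvAccuracy(X, S) - lambda * |S| / n_variables`; the
#' parsimony penalty steers the search toward small predictive subsets.
#' The empty subset has fitness `-Inf`.
#'
#' @param X A [VariableMatrix-class].
#' @param subset Character vector of variable ids.
#' @param lambda Parsimony weight.
#' @param cvScheme,shrinkage As in [cvAccuracy()].
#' @return Numeric fitness.
#' @export
subsetFitness <- function(X, subset, lambda = 0.05,
                          cvScheme = list(type = "loocv"),
                          shrinkage = "auto") {
  if (!length(subset)) return(-Inf)
  cvAccuracy(X, subset, cvScheme, shrinkage) -
    lambda * length(subset) / ncol(X)
}

#' Genetic-algorithm variable selection with selection-frequency ranking
#'
#' Binary-chromosome GA over the variables of `X`: tournament selection,
#' uniform crossover, bit-flip mutation, elitism. The GA is run
#' `config$nRuns` times with per-run jittered mutation rates and distinct
#' derived sub-seeds; each run contributes its best subset. Per-variable
#' selection frequency = fraction of runs whose best subset contains the
#' variable. Fitness values are memoised across runs (the fitness of a
#' subset does not depend on the run), making repeated runs cheap.
#'
#' @param X A [VariableMatrix-class] with >= 2 variables.
#' @param config A [gaConfig()].
#' @return A [GASolutionSet-class].
#' @export
gaSelect <- function(X, config = gaConfig()) {
  stopifnot(is(X, "VariableMatrix"), inherits(config, "GAConfig"))
  p <- ncol(X)
  if (p < 2L) stopf("need >= 2 variables")
  vars <- variableNames(X)
  cache <- new.env(parent = emptyenv())
  evalBits <- function(bits) {
    if (!any(bits)) return(-Inf)
    key <- paste(which(bits), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- subsetFitness(X, vars[bits], config$lambda, config$cvScheme,
                       config$shrinkage)
    cache[[key]] <- f
    f
  }
  nElite <- max(1L, round(config$elitism * config$popSize))
  solutions <- vector("list", config$nRuns)
  bestFit <- numeric(config$nRuns)
  baseScheme <- config$cvScheme
  for (run in seq_len(config$nRuns)) {
    # each run draws its own cross-validation folds (split scheme), so
    # spurious selections decorrelate across runs and the selection
    # frequency concentrates on genuinely predictive variables
    if (identical(baseScheme$type, "split")) {
      config$cvScheme <- baseScheme
      config$cvScheme$seed <- deriveSeed(config$seed, "cvfolds", run)
      cache <- new.env(parent = emptyenv())  # fitness is fold-specific
    }
    res <- withSeed(deriveSeed(config$seed, "ga_run", run), {
      pMut <- runif(1, config$mutationJitter[[1L]],
                    config$mutationJitter[[2L]])
      pop <- matrix(runif(config$popSize * p) < config$initProb,
                    config$popSize, p)
      fit <- apply(pop, 1L, evalBits)
      for (gen in seq_len(config$generations)) {
        ord <- order(fit, decreasing = TRUE)
        elite <- pop[ord[seq_len(nElite)], , drop = FALSE]
        newPop <- matrix(FALSE, config$popSize, p)
        newPop[seq_len(nElite), ] <- elite
        i <- nElite
        while (i < config$popSize) {
          # binary tournaments
          pick <- function() {
            c2 <- sample.int(config$popSize, 2L)
            c2[[which.max(fit[c2])]]
          }
          pa <- pop[pick(), ]; pb <- pop[pick(), ]
          if (runif(1) < config$pCrossover) {
            mask <- runif(p) < 0.5
            ch1 <- ifelse(mask, pa, pb)
            ch2 <- ifelse(mask, pb, pa)
          } else {
            ch1 <- pa; ch2 <- pb
          }
          for (ch in list(ch1, ch2)) {
            if (i >= config$popSize) break
            flip <- runif(p) < pMut
            ch <- xor(ch, flip)
            i <- i + 1L
            newPop[i, ] <- ch
          }
        }
        pop <- newPop
        fit <- apply(pop, 1L, evalBits)
      }
      best <- which.max(fit)
      list(bits = pop[best, ], fit = fit[[best]])
    })
    solutions[[run]] <- vars[res$bits]
    bestFit[[run]] <- res$fit
  }
  freq <- setNames(numeric(p), vars)
  for (s in solutions) freq[s] <- freq[s] + 1
  freq <- freq / config$nRuns
  new("GASolutionSet", solutions = solutions, fitness = bestFit,
      frequency = freq, config = unclass(config))
}

#' Nested (embedded) variable subsets from selection frequencies
#'
#' Variables with frequency > 0 are ranked by descending selection
#' frequency, ties broken by descending marginal single-variable CV
#' accuracy (when `X` is supplied) and then lexicographic id. Cut points
#' (default sizes 4, 7, 11, 17, all-selected) define strictly nested
#' subsets; cut points beyond the available variables are truncated with a
#' warning.
#'
#' @param solutions A [GASolutionSet-class].
#' @param cutPoints Integer subset sizes (default `c(4, 7, 11, 17, all)`).
#' @param X Optional [VariableMatrix-class] for the accuracy tie-break.
#' @param scheme CV scheme for the tie-break (default LOOCV).
#' @return List of class `NestedSubsets`: `ranking`, `subsets`,
#'   `cutPoints`.
#' @export
buildNestedSubsets <- function(solutions, cutPoints = NULL, X = NULL,
                               scheme = list(type = "loocv")) {
  freq <- selectionFrequency(solutions)
  freq <- freq[freq > 0]
  if (!length(freq)) stopf("no variable was ever selected")
  ids <- names(freq)
  margAcc <- rep(0, length(ids))
  if (!is.null(X)) {
    tied <- duplicated(freq) | duplicated(freq, fromLast = TRUE)
    margAcc[tied] <- vapply(ids[tied], function(v)
      cvAccuracy(X, v, scheme), numeric(1))
  }
  ord <- order(-freq, -margAcc, ids)
  ranking <- ids[ord]
  if (is.null(cutPoints))
    cutPoints <- unique(pmin(c(4L, 7L, 11L, 17L, length(ranking)),
                             length(ranking)))
  cutPoints <- as.integer(cutPoints)
  if (any(cutPoints > length(ranking))) {
    warnf("cut point(s) beyond %d available variable(s); truncated",
          length(ranking))
    cutPoints <- pmin(cutPoints, length(ranking))
  }
  cutPoints <- sort(unique(cutPoints))
  subsets <- lapply(cutPoints, function(k) ranking[seq_len(k)])
  names(subsets) <- paste0("subset", seq_along(subsets))
  structure(list(ranking = ranking, subsets = subsets,
                 cutPoints = cutPoints),
            class = "NestedSubsets")
}

#' @export
print.NestedSubsets <- function(x, ...) {
  cat(sprintf("NestedSubsets: %d subset(s) of sizes %s over %d variable(s)\n",
              length(x$subsets), paste(x$cutPoints, collapse = ", "),
              length(x$ranking)))
  invisible(x)
}

#' Evaluate nested subsets and pick the most predictive one
#'
#' Cross-validated accuracy per subset; the best subset is the accuracy
#' argmax, ties resolved in favour of the smaller subset (parsimony).
#'
#' @param X A [VariableMatrix-class].
#' @param subsets A `NestedSubsets` from [buildNestedSubsets()].
#' @param scheme,shrinkage As in [cvAccuracy()].
#' @return data.frame `subset`, `size`, `accuracy`, with
#'   `attr(, "best")` = name of the winning subset.
#' @export
evaluateSubsets <- function(X, subsets, scheme = list(type = "loocv"),
                            shrinkage = "auto") {
  stopifnot(inherits(subsets, "NestedSubsets"))
  acc <- vapply(subsets$subsets, function(s)
    cvAccuracy(X, s, scheme, shrinkage), numeric(1))
  out <- data.frame(subset = names(subsets$subsets),
                    size = lengths(subsets$subsets), accuracy = acc)
  out <- out[order(out$size), ]
  rownames(out) <- NULL
  attr(out, "best") <- out$subset[[which.max(out$accuracy)]]
  out
}

#' Simulate a labeled scoring cohort with a planted linear rule
#'
#' Generates a samples x variables measurement matrix in which
#' `nInformative` variables carry a between-class mean shift sized so that
#' the Bayes-optimal linear rule achieves `bayesAccuracy`; the remaining
#' variables are pure noise. Used to exercise the GA -> nested subsets ->
#' LDA chain against a known truth.
#'
#' @param nPerClass Samples per class.
#' @param nVariables Total variables (default 30).
#' @param nInformative Number of informative variables (default 7).
#' @param bayesAccuracy Bayes accuracy of the optimal rule (default 0.95).
#' @param seed Integer seed.
#' @return List: `X` (a [VariableMatrix-class]), `informative` (ids).
#' @export
simulateScoreCohort <- function(nPerClass = 12L, nVariables = 30L,
                                nInformative = 7L, bayesAccuracy = 0.95,
                                seed = 1L) {
  stopifnot(nInformative <= nVariables)
  delta <- 2 * qnorm(bayesAccuracy) / sqrt(nInformative)
  withSeed(deriveSeed(seed, "score_cohort"), {
    n <- 2L * nPerClass
    X <- matrix(rnorm(n * nVariables), n, nVariables)
    lab <- rep(c("sensitive", "resistant"), each = nPerClass)
    X[lab == "resistant", seq_len(nInformative)] <-
      X[lab == "resistant", seq_len(nInformative)] + delta
    vars <- sprintf("V%02d|%s", seq_len(nVariables),
                    rep(c("ubiquitin", "SUMO1"),
                        length.out = nVariables))
    dimnames(X) <- list(sprintf("S%02d", seq_len(n)), vars)
    list(X = VariableMatrix(X, lab), informative = vars[seq_len(nInformative)])
  })
}
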