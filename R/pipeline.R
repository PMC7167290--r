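# End-to-end orchestration: discovery (arrays -> preprocessing ->
# signature), scoring (variables -> GA -> nested subsets -> LDA ->
# predictions) and bead quantification, with config, a run report and
# TSV/JSON artifacts. A single global seed fans out to named sub-seeds per
# stage (deriveSeed), so stages are independently re-runnable.

configHash <- function(config) {
  # hash the analysis parameters only; input/output locations may vary
  # between re-runs of the same analysis
  config <- config[setdiff(names(config),
                           c("outdir", "gpr_dir", "meta_path"))]
  txt <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (code in utf8ToInt(txt)) h <- (h * 16777619 + code) %% 2^31
  sprintf("%08x", as.integer(h))
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

writeArtifact <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s", hash), con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  close(con)
  path
}

#' Run the discovery pipeline: arrays to signature
#'
#' Executes simulate (optional) -> GPR reading -> matrix assembly ->
#' preprocessing -> modification calling -> ratio computation ->
#' differential calling (global and separated) -> signature merge.
#' Artifacts (modification calls, differential records, signature,
#' Venn-count JSON, run report) are written under `config$outdir` when
#' given.
#'
#' @param config Named list. Either `simulate` (a [simulationConfig()] or
#'   `TRUE` for defaults) or `gpr_dir` + `meta_path` must be supplied.
#'   Optional: `outdir`, `seed`, `alpha`, `intensity_floor`,
#'   `ratio_hi`/`ratio_lo` (global), `ratio_hi_sep`/`ratio_lo_sep`,
#'   `bh_correct`, preprocessing keys (see [preprocessChain()]).
#' @return List: `report`, `matrix`, `calls`, `global`, `separated`,
#'   `signature`, and `truth` when simulated.
#' @export
runDiscovery <- function(config = list()) {
  hash <- configHash(config)
  seed <- config$seed %||% 1L
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- withStage("simulate", {
      sc <- config$simulate
      if (isTRUE(sc)) sc <- simulationConfig(rng_seed = seed)
      simulateProtoarrayStudy(sc, dir = config$gpr_dir)
    })
    spots <- sim$spots; meta <- sim$meta; truth <- sim$truth
  } else {
    if (is.null(config$gpr_dir) || is.null(config$meta_path))
      stopf("stage 'array_io' failed: missing artifact: need gpr_dir + meta_path (or enable simulate)")
    spots <- withStage("array_io", {
      files <- list.files(config$gpr_dir, pattern = "\\.gpr$",
                          full.names = TRUE)
      if (!length(files)) stopf("no GPR files in %s", config$gpr_dir)
      lapply(files, readGPR)
    })
    meta <- withStage("array_io", read.csv(config$meta_path))
  }
  x <- withStage("assemble", assembleMatrix(spots, meta))
  x <- withStage("preprocess", preprocessChain(x, config))
  calls <- withStage("call_modified",
                     callModified(x, alpha = config$alpha %||% 0.05,
                                  intensityFloor =
                                    config$intensity_floor %||% 800,
                                  bhCorrect = isTRUE(config$bh_correct)))
  ratios <- withStage("ratios", computeRatios(x, calls, scope = "global"))
  glob <- withStage("differential_global",
                    callDifferentialGlobal(ratios,
                                           alpha = config$alpha %||% 0.05,
                                           hi = config$ratio_hi %||% 1.25,
                                           lo = config$ratio_lo %||% 0.8))
  sep <- withStage("differential_separated",
                   callDifferentialSeparated(
                     ratios, alpha = config$alpha %||% 0.05,
                     hi = config$ratio_hi_sep %||% 1.5,
                     lo = config$ratio_lo_sep %||% 0.66))
  sig <- withStage("signature", mergeSignature(glob, sep))
  report <- list(
    config_hash = hash, seed = seed,
    arrays = ncol(x), proteins = nrow(x),
    modified_called = as.list(table(calls$modifier[calls$called])),
    differential_global = as.list(table(glob$modifier[glob$called])),
    differential_separated =
      as.list(table(sep$modifier[sep$called])),
    signature = signatureCounts(sig))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    writeArtifact(calls, file.path(config$outdir,
                                   "modification_calls.tsv"), hash)
    writeArtifact(rbindFill(glob, sep) %||% glob,
                  file.path(config$outdir, "differential_records.tsv"),
                  hash)
    writeArtifact(as.data.frame(sig),
                  file.path(config$outdir, "signature.tsv"), hash)
    jsonlite::write_json(
      list(config_hash = hash, modified = vennCounts(calls),
           differential_global = vennCounts(glob)),
      file.path(config$outdir, "venn_counts.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(report,
                         file.path(config$outdir, "discovery_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, matrix = x, calls = calls, ratios = ratios,
       global = glob, separated = sep, signature = sig, truth = truth)
}

#' Run the scoring pipeline: variables to predictions
#'
#' Executes variable expansion (or takes a ready [VariableMatrix-class])
#' -> GA selection -> frequency ranking and nested subsets -> subset
#' evaluation -> LDA fit on the winning subset -> classification of all
#' samples (cross-validated calls could be added for training samples;
#' unlabeled samples are scored by the fitted model).
#'
#' @param config Named list: either `X` (a `VariableMatrix`) or
#'   `selection` + `measurements` + `labels` for [expandVariables()];
#'   optional `ga` (list of [gaConfig()] overrides), `cut_points`,
#'   `cv` (scheme list), `outdir`, `seed`.
#' @return List: `report`, `solutions`, `subsets`, `evaluation`, `model`,
#'   `predictions`.
#' @export
runScore <- function(config = list()) {
  hash <- configHash(config)
  seed <- config$seed %||% 1L
  X <- withStage("expand_variables", {
    if (!is.null(config$X)) config$X
    else {
      if (is.null(config$selection) || is.null(config$measurements))
        stopf("missing artifact: need X, or selection + measurements")
      expandVariables(config$selection, config$measurements,
                      config$labels)
    }
  })
  gaCfg <- do.call(gaConfig, modifyList(
    list(seed = deriveSeed(seed, "ga")), config$ga %||% list()))
  sols <- withStage("ga_select", gaSelect(X, gaCfg))
  scheme <- config$cv %||% list(type = "loocv")
  subsets <- withStage("nested_subsets",
                       buildNestedSubsets(sols, config$cut_points, X,
                                          scheme))
  evalTab <- withStage("evaluate_subsets",
                       evaluateSubsets(X, subsets, scheme))
  best <- attr(evalTab, "best")
  bestVars <- subsets$subsets[[best]]
  model <- withStage("lda_fit", ldaFit(
    VariableMatrix(X@X[, bestVars, drop = FALSE], X@labels)))
  preds <- withStage("classify", ldaPredictProba(
    model, X@X[, names(coef(model)), drop = FALSE]))
  preds$label <- as.character(X@labels)
  report <- list(config_hash = hash, seed = seed,
                 n_samples = nrow(X@X), n_variables = ncol(X@X),
                 ga_runs = length(gaSolutions(sols)),
                 best_subset = best, best_size = length(bestVars),
                 subset_accuracies = setNames(evalTab$accuracy,
                                              evalTab$subset))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config_hash = hash,
           solutions = gaSolutions(sols), fitness = sols@fitness),
      file.path(config$outdir, "ga_solutions.json"), auto_unbox = TRUE,
      digits = NA)
    writeArtifact(data.frame(variable = names(selectionFrequency(sols)),
                             frequency = selectionFrequency(sols)),
                  file.path(config$outdir, "selection_frequency.tsv"),
                  hash)
    writeArtifact(preds, file.path(config$outdir, "predictions.tsv"),
                  hash)
    jsonlite::write_json(
      list(config_hash = hash, coefficients = as.list(coef(model)),
           intercept = model@intercept, shrinkage = model@shrinkage),
      file.path(config$outdir, "lda_model.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(report,
                         file.path(config$outdir, "score_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, solutions = sols, subsets = subsets,
       evaluation = evalTab, model = model, predictions = preds)
}

#' Run the bead-assay pipeline: events to comparisons and flags
#'
#' Executes region gating -> MFI computation -> NEM subtraction and
#' resistant/parental ratios -> group comparisons -> patient flagging.
#'
#' @param config Named list: `events` (event table) and `samples`
#'   (metadata with `sample_id`, `control_id`, optional `pairs`
#'   data.frame(resistant, parental), optional `responder` logical
#'   column), `centroids` or `k`; optional `outdir`, `seed`, `k_sd`,
#'   `min_events`, `floor`.
#' @return List: `report`, `labeled`, `mfi`, `adjusted`, `ratios`,
#'   `comparisons`, `flags`.
#' @export
runBead <- function(config = list()) {
  hash <- configHash(config)
  seed <- config$seed %||% 1L
  events <- config$events
  samples <- config$samples
  if ((is.null(events) && is.null(config$mfi)) || is.null(samples) ||
      !nrow(samples))
    stopf("stage 'bead_io' failed: missing artifact: events (or mfi) + samples required")
  controlMap <- setNames(samples$control_id, samples$sample_id)
  knownSamples <- if (!is.null(events)) unique(events$sample_id) else
    unique(config$mfi$sample_id)
  missingNem <- samples$sample_id[!samples$control_id %in% knownSamples]
  if (length(missingNem))
    stopf("stage 'bead_io' failed: no NEM-control events for sample(s): %s",
          paste(missingNem, collapse = ", "))
  if (!is.null(config$mfi)) {
    # pre-gated MFI table supplied: bypass gating
    labeled <- NULL
    mfi <- config$mfi
    if (is.null(mfi$usable)) mfi$usable <- TRUE
  } else {
    labeled <- withStage("gating",
                         assignBeadRegions(events, config$centroids,
                                           config$k,
                                           seed = deriveSeed(seed,
                                                             "gate")))
    mfi <- withStage("mfi", computeMFI(labeled,
                                       minEvents = config$min_events %||%
                                         30L))
  }
  pairs <- config$pairs %||%
    data.frame(resistant = character(), parental = character())
  adj <- withStage("nem_subtract",
                   nemSubtractAndRatio(mfi, controlMap, pairs,
                                       floor = config$floor %||% 1))
  comparisons <- NULL
  flags <- NULL
  if (!is.null(samples$responder)) {
    ub <- adj$adjusted[adj$adjusted$modifier == "ubiquitin", ,
                       drop = FALSE]
    resp <- samples$sample_id[samples$responder]
    refr <- samples$sample_id[!samples$responder]
    comparisons <- withStage("compare_groups", do.call(rbind, lapply(
      unique(ub$biomarker), function(b) {
        d <- ub[ub$biomarker == b, ]
        t_ <- compareGroups(d$adjusted[d$sample_id %in% refr],
                            d$adjusted[d$sample_id %in% resp],
                            design = "unpaired_welch")
        data.frame(biomarker = b, statistic = t_$statistic,
                   p = t_$p.value, test = t_$method)
      })))
    flags <- withStage("flag_patients", flagHighModification(
      data.frame(sample_id = ub$sample_id, biomarker = ub$biomarker,
                 value = ub$adjusted),
      reference = resp, kSd = config$k_sd %||% 2))
  }
  report <- list(config_hash = hash, seed = seed,
                 n_events = if (!is.null(events)) nrow(events) else NA,
                 n_assigned = if (!is.null(labeled))
                   sum(!is.na(labeled$region)) else NA,
                 n_samples = nrow(samples),
                 n_biomarkers = length(unique(mfi$biomarker)),
                 n_ratios = nrow(adj$ratios),
                 n_flagged = if (!is.null(flags))
                   sum(flags$patient_flags) else NA)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    writeArtifact(mfi, file.path(config$outdir, "bead_mfi.tsv"), hash)
    writeArtifact(adj$ratios, file.path(config$outdir,
                                        "bead_ratios.tsv"), hash)
    if (!is.null(comparisons))
      writeArtifact(comparisons,
                    file.path(config$outdir, "bead_comparisons.tsv"),
                    hash)
    jsonlite::write_json(report,
                         file.path(config$outdir, "bead_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, labeled = labeled, mfi = mfi,
       adjusted = adj$adjusted, ratios = adj$ratios,
       comparisons = comparisons, flags = flags)
}
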