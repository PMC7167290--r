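# Synthetic-data module: protein-array scans (GPR + metadata) and bead-assay
# event tables with planted ground truth, mirroring the 3-experiment x
# (2 cell lines x 3 conditions + NEM controls) = 24-array study design.
#
# Signal model (log2 scale): intensity = protein baseline N(9, 1)
# + modification effect (conjugation-permissive arrays only)
# + differential effect (resistant conditions in scope) + batch offset
# + multiplicative spot noise; emitted as 2^(log2 value) plus additive
# scanner background. NEM-control arrays are parental extracts with all
# conjugation activity inhibited, so they carry no modification signal.

.knownConditions <- c("parental", "ARA-R", "DNR-R")

#' Configuration for the synthetic protein-array study
#'
#' Defaults mirror the study design: 3 independent experiments, HL-60 and
#' U937 cell lines each as parental, Ara-C-resistant (ARA-R) and
#' DNR-resistant (DNR-R), plus 2 NEM-control arrays per experiment
#' (24 arrays in total), duplicate spots, two modifier channels.
#' `n_proteins` defaults to 1000 (the real arrays carry >9,000 proteins;
#' scaled for speed, configurable up).
#'
#' @param n_proteins Number of distinct proteins on the array.
#' @param n_experiments Number of independent experiments (batches).
#' @param cell_lines Character vector of cell line labels.
#' @param conditions Subset of `c("parental", "ARA-R", "DNR-R")`;
#'   must include `"parental"`.
#' @param nem_controls_per_experiment NEM-control arrays per experiment
#'   (parental extracts, conjugation inhibited).
#' @param channels Named character vector wavelength -> modifier.
#' @param frac_modified Named fraction of proteins carrying each modifier
#'   (names = modifiers), or a single fraction for all.
#' @param frac_differential Fraction of each modified set that is
#'   differentially modified between resistant and parental conditions.
#' @param log2_modification_effect Planted modification effect, log2 units.
#' @param log2_differential_effect Planted differential effect, log2 units.
#' @param differential_scope `"global"`, `"per-line"` or `"per-drug"`.
#' @param batch_log2_sd SD of per-experiment batch offsets (log2 units).
#' @param spot_cv Lognormal coefficient of variation of duplicate-spot noise.
#' @param background_mean,background_sd Additive scanner background (a.u.).
#' @param rng_seed Positive integer master seed.
#' @return A validated `SimulationConfig` list.
#' @export
simulationConfig <- function(n_proteins = 1000L,
                             n_experiments = 3L,
                             cell_lines = c("HL-60", "U937"),
                             conditions = .knownConditions,
                             nem_controls_per_experiment = 2L,
                             channels = defaultChannelMap(),
                             frac_modified = c(ubiquitin = 0.10,
                                               SUMO1 = 0.04),
                             frac_differential = 0.10,
                             log2_modification_effect = 2.0,
                             log2_differential_effect = 1.0,
                             differential_scope = c("global", "per-line",
                                                    "per-drug"),
                             batch_log2_sd = 0.5,
                             spot_cv = 0.15,
                             background_mean = 100,
                             background_sd = 20,
                             rng_seed = 1L) {
  differential_scope <- match.arg(differential_scope)
  mods <- unname(channels)
  if (length(frac_modified) == 1L && is.null(names(frac_modified)))
    frac_modified <- setNames(rep(frac_modified, length(mods)), mods)
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_experiments = as.integer(n_experiments),
              cell_lines = cell_lines, conditions = conditions,
              nem_controls_per_experiment =
                as.integer(nem_controls_per_experiment),
              channels = channels, frac_modified = frac_modified,
              frac_differential = frac_differential,
              log2_modification_effect = log2_modification_effect,
              log2_differential_effect = log2_differential_effect,
              differential_scope = differential_scope,
              batch_log2_sd = batch_log2_sd, spot_cv = spot_cv,
              background_mean = background_mean,
              background_sd = background_sd,
              rng_seed = as.integer(rng_seed))
  validateSimulationConfig(cfg)
  structure(cfg, class = "SimulationConfig")
}

validateSimulationConfig <- function(cfg) {
  if (cfg$n_proteins < 1L) stopf("config error: n_proteins must be >= 1")
  if (cfg$n_experiments < 1L) stopf("config error: n_experiments must be >= 1")
  if (cfg$nem_controls_per_experiment < 1L)
    stopf("config error: nem_controls_per_experiment must be >= 1")
  unknown <- setdiff(cfg$conditions, .knownConditions)
  if (length(unknown))
    stopf("config error: unknown condition label(s): %s",
          paste(unknown, collapse = ", "))
  if (!"parental" %in% cfg$conditions)
    stopf("config error: conditions must include 'parental'")
  fracs <- c(cfg$frac_modified, cfg$frac_differential)
  if (any(fracs < 0 | fracs > 1))
    stopf("config error: fractions must lie in [0, 1]")
  miss <- setdiff(unname(cfg$channels), names(cfg$frac_modified))
  if (length(miss))
    stopf("config error: frac_modified lacks modifier(s): %s",
          paste(miss, collapse = ", "))
  if (cfg$log2_modification_effect < 0 || cfg$log2_differential_effect < 0)
    stopf("config error: effects must be >= 0")
  if (is.na(cfg$rng_seed) || cfg$rng_seed < 1L)
    stopf("config error: rng_seed must be a positive integer")
  invisible(cfg)
}

resistantConditions <- function(conds) setdiff(conds, "parental")

# array design table for a config: one row per physical array
arrayDesign <- function(cfg) {
  rows <- list()
  for (e in seq_len(cfg$n_experiments)) {
    for (line in cfg$cell_lines) {
      for (cond in cfg$conditions) {
        id <- sprintf("E%d_%s_%s", e, gsub("[^A-Za-z0-9]", "", line), cond)
        rows[[length(rows) + 1L]] <- data.frame(
          array_id = id, experiment = paste0("exp", e), cell_line = line,
          condition = cond, nem_control = FALSE)
      }
    }
    for (k in seq_len(cfg$nem_controls_per_experiment)) {
      line <- cfg$cell_lines[[(k - 1L) %% length(cfg$cell_lines) + 1L]]
      id <- sprintf("E%d_NEM%d_%s", e, k, gsub("[^A-Za-z0-9]", "", line))
      rows[[length(rows) + 1L]] <- data.frame(
        array_id = id, experiment = paste0("exp", e), cell_line = line,
        condition = "parental", nem_control = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the full protein-array study
#'
#' Generates the planted ground truth, the array design, and per-array
#' two-channel spot tables with duplicate spots. When `dir` is given, each
#' array is written as a GPR file together with an `array_metadata.csv`;
#' intensities are rounded to 6 significant digits at generation so the
#' in-memory values round-trip exactly through [writeGPR()]/[readGPR()].
#' Each array draws from its own derived RNG stream (see [deriveSeed()]),
#' so output is bitwise-reproducible and adding arrays never perturbs
#' earlier draws.
#'
#' @param config A [simulationConfig()].
#' @param dir Optional output directory for GPR files + metadata CSV.
#' @return List with `spots` (list of per-array spot data.frames in
#'   [readGPR()] layout), `meta` (array metadata), `truth`
#'   (`UbLGroundTruth`), and `files` (paths, when `dir` given).
#' @export
simulateProtoarrayStudy <- function(config, dir = NULL) {
  cfg <- validateSimulationConfig(config)
  mods <- unname(cfg$channels)
  proteins <- sprintf("P%05d", seq_len(cfg$n_proteins))
  baseline <- withSeed(deriveSeed(cfg$rng_seed, "baseline"),
                       setNames(rnorm(cfg$n_proteins, 9, 1), proteins))
  modified <- list(); differential <- list()
  resConds <- resistantConditions(cfg$conditions)
  for (mod in mods) {
    nMod <- round(cfg$frac_modified[[mod]] * cfg$n_proteins)
    modSet <- withSeed(deriveSeed(cfg$rng_seed, "modified", mod),
                       sort(sample(proteins, nMod)))
    modified[[mod]] <- modSet
    nDiff <- round(cfg$frac_differential * nMod)
    differential[[mod]] <- withSeed(
      deriveSeed(cfg$rng_seed, "differential", mod), {
        dp <- sort(sample(modSet, nDiff))
        if (!length(dp)) {
          data.frame(protein = character(), modifier = character(),
                     scope = character(), direction = character(),
                     cell_line = character(), drug = character())
        } else {
          dir_ <- sample(c("up", "down"), nDiff, replace = TRUE)
          line <- if (cfg$differential_scope == "per-line")
            sample(cfg$cell_lines, nDiff, replace = TRUE) else
              rep(NA_character_, nDiff)
          drug <- if (cfg$differential_scope == "per-drug")
            sample(resConds, nDiff, replace = TRUE) else
              rep(NA_character_, nDiff)
          data.frame(protein = dp, modifier = mod,
                     scope = cfg$differential_scope, direction = dir_,
                     cell_line = line, drug = drug)
        }
      })
  }
  design <- arrayDesign(cfg)
  batches <- expand.grid(experiment = paste0("exp",
                                             seq_len(cfg$n_experiments)),
                         modifier = mods, stringsAsFactors = FALSE)
  # one derived stream per (experiment, modifier) so extra experiments or
  # channels never perturb existing offsets
  batches$offset <- vapply(seq_len(nrow(batches)), function(i)
    withSeed(deriveSeed(cfg$rng_seed, "batch", batches$experiment[[i]],
                        batches$modifier[[i]]),
             rnorm(1, 0, cfg$batch_log2_sd)), numeric(1))
  diffAll <- do.call(rbind, differential)
  truth <- structure(list(
    modified = do.call(rbind, lapply(mods, function(m)
      if (length(modified[[m]]))
        data.frame(protein = modified[[m]], modifier = m)
      else data.frame(protein = character(), modifier = character()))),
    differential = diffAll,
    batch = batches,
    baseline = data.frame(protein = proteins, log2_mean = unname(baseline))),
    class = "UbLGroundTruth")
  wavelengths <- as.integer(names(cfg$channels))
  spotsPerArray <- vector("list", nrow(design))
  names(spotsPerArray) <- design$array_id
  nSpot <- cfg$n_proteins * 2L
  for (i in seq_len(nrow(design))) {
    a <- design[i, ]
    log2sig <- matrix(rep(baseline, each = 2L), nrow = nSpot,
                      ncol = length(mods),
                      dimnames = list(NULL, mods))
    for (m in seq_along(mods)) {
      mod <- mods[[m]]
      off <- batches$offset[batches$experiment == a$experiment &
                              batches$modifier == mod]
      log2sig[, m] <- log2sig[, m] + off
      if (!a$nem_control) {
        isMod <- rep(proteins %in% modified[[mod]], each = 2L)
        log2sig[isMod, m] <- log2sig[isMod, m] +
          cfg$log2_modification_effect
        if (a$condition != "parental" && nrow(diffAll)) {
          dm <- diffAll[diffAll$modifier == mod, , drop = FALSE]
          inScope <- switch(cfg$differential_scope,
            "global" = rep(TRUE, nrow(dm)),
            "per-line" = dm$cell_line == a$cell_line,
            "per-drug" = dm$drug == a$condition)
          dm <- dm[inScope, , drop = FALSE]
          if (nrow(dm)) {
            sgn <- ifelse(dm$direction == "up", 1, -1)
            delta <- setNames(sgn * cfg$log2_differential_effect,
                              dm$protein)
            isDiff <- rep(proteins %in% dm$protein, each = 2L)
            log2sig[isDiff, m] <- log2sig[isDiff, m] +
              delta[rep(proteins, each = 2L)[isDiff]]
          }
        }
      }
    }
    spotsPerArray[[a$array_id]] <- withSeed(
      deriveSeed(cfg$rng_seed, "array", a$array_id), {
        noise <- matrix(exp(rnorm(nSpot * length(mods), 0, cfg$spot_cv)),
                        nSpot, length(mods))
        bgDraw <- matrix(pmax(rnorm(nSpot * length(mods),
                                    cfg$background_mean,
                                    cfg$background_sd), 0),
                         nSpot, length(mods))
        bgEst <- matrix(pmax(rnorm(nSpot * length(mods),
                                   cfg$background_mean,
                                   cfg$background_sd), 0),
                        nSpot, length(mods))
        fg <- signif(2^log2sig * noise + bgDraw, 6)
        bgEst <- signif(bgEst, 6)
        colnames(bgEst) <- mods
        d <- data.frame(
          array_id = a$array_id, block = 1L,
          column = rep(c(1L, 2L), cfg$n_proteins),
          row = rep(seq_len(cfg$n_proteins), each = 2L),
          protein_id = rep(proteins, each = 2L),
          protein_name = rep(paste0("protein_", proteins), each = 2L),
          flags = 0L, mapped = TRUE)
        out <- do.call(rbind, lapply(seq_along(wavelengths), function(w) {
          mod <- cfg$channels[[as.character(wavelengths[[w]])]]
          dd <- d
          dd$wavelength <- wavelengths[[w]]
          dd$fg <- fg[, mod]
          dd$bg <- bgEst[, mod]
          dd
        }))
        rownames(out) <- NULL
        out[, c("array_id", "block", "column", "row", "protein_id",
                "protein_name", "wavelength", "fg", "bg", "flags",
                "mapped")]
      })
  }
  meta <- design
  meta$channel_map <- paste(sprintf("%s:%s", names(cfg$channels),
                                    cfg$channels), collapse = ";")
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(nrow(design))
    for (i in seq_len(nrow(design))) {
      sp <- spotsPerArray[[design$array_id[[i]]]]
      wide <- sp[sp$wavelength == wavelengths[[1L]],
                 c("block", "column", "row", "protein_name", "protein_id",
                   "flags")]
      names(wide)[names(wide) == "protein_name"] <- "name"
      names(wide)[names(wide) == "protein_id"] <- "id"
      for (w in wavelengths) {
        sub <- sp[sp$wavelength == w, ]
        wide[[paste0("F", w)]] <- sub$fg
        wide[[paste0("B", w)]] <- sub$bg
      }
      files[[i]] <- file.path(dir, paste0(design$array_id[[i]], ".gpr"))
      writeGPR(wide, files[[i]], wavelengths = wavelengths,
               header = c(ArrayID = design$array_id[[i]],
                          Experiment = design$experiment[[i]]))
    }
    write.csv(meta, file.path(dir, "array_metadata.csv"),
              row.names = FALSE, quote = TRUE)
    files <- c(files, file.path(dir, "array_metadata.csv"))
  }
  list(spots = spotsPerArray, meta = meta, truth = truth, files = files)
}

#' Write / read a ground-truth object as TSV tables
#'
#' `writeTruth()` writes one TSV per truth table (`modified`,
#' `differential`, `batch`, `baseline`) under `dir`; `readTruth()` restores
#' them losslessly.
#'
#' @param truth A `UbLGroundTruth` (from [simulateProtoarrayStudy()]).
#' @param dir Directory to write to / read from.
#' @return `writeTruth()`: the paths, invisibly. `readTruth()`: the truth
#'   object.
#' @export
writeTruth <- function(truth, dir) {
  stopifnot(inherits(truth, "UbLGroundTruth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    write.table(truth[[nm]], p, sep = "\t", row.names = FALSE,
                quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname writeTruth
#' @export
readTruth <- function(dir) {
  nms <- c("modified", "differential", "batch", "baseline")
  classes <- list(
    modified = c(protein = "character", modifier = "character"),
    differential = c(protein = "character", modifier = "character",
                     scope = "character", direction = "character",
                     cell_line = "character", drug = "character"),
    batch = c(experiment = "character", modifier = "character",
              offset = "numeric"),
    baseline = c(protein = "character", log2_mean = "numeric"))
  out <- lapply(nms, function(nm) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    if (!file.exists(p)) stopf("missing truth table: %s", p)
    read.delim(p, stringsAsFactors = FALSE, colClasses = classes[[nm]])
  })
  names(out) <- nms
  structure(out, class = "UbLGroundTruth")
}

#' Simulate a multiplexed bead-assay study
#'
#' Generates event-level cytometry tables: each biomarker's beads form one
#' cluster in the two classification channels (`CL1`, `CL2`); reporter
#' channels carry `RP_ub` (ubiquitin, anti-Flag reporter) and `RP_sumo1`
#' signal. For every sample a paired NEM control sample
#' (`<sample_id>_NEM`) is generated whose reporter signal is
#' background-only. Planted effects act on the ubiquitin reporter.
#'
#' @param n_biomarkers Number of bead regions (>= 1).
#' @param samples data.frame with at least `sample_id`; optional `group`
#'   and `responder` columns are carried through.
#' @param effects Samples x biomarkers matrix of log2 shifts on the
#'   ubiquitin reporter (or a scalar, recycled). Row order follows
#'   `samples`.
#' @param noise List overriding defaults: `events_per_bead` (200),
#'   `centroid_spacing` (1500), `cluster_sd` (60), `reporter_cv` (0.25),
#'   `base_log2_mfi` (10), `background_mfi` (50).
#' @param rng_seed Positive integer seed.
#' @param dir Optional directory; one `events_<sample>.csv` per sample plus
#'   `bead_samples.csv`.
#' @return List with `events` (event table incl. NEM controls), `samples`
#'   (augmented metadata with `control_id`), `truth` (list: `regions`
#'   per-event true region, `effects` per sample x biomarker log2 shift),
#'   `centroids`.
#' @export
simulateBeadStudy <- function(n_biomarkers, samples, effects = 0,
                              noise = list(), rng_seed = 1L, dir = NULL) {
  if (n_biomarkers < 1L) stopf("config error: need >= 1 biomarker")
  if (!is.data.frame(samples) || nrow(samples) == 0L)
    stopf("config error: empty sample table")
  if (rng_seed < 1L) stopf("config error: rng_seed must be positive")
  nz <- list(events_per_bead = 200L, centroid_spacing = 1500,
             cluster_sd = 60, reporter_cv = 0.25, base_log2_mfi = 10,
             background_mfi = 50)
  nz[names(noise)] <- noise
  ns <- nrow(samples)
  if (length(effects) == 1L)
    effects <- matrix(effects, ns, n_biomarkers)
  effects <- as.matrix(effects)
  stopifnot(nrow(effects) == ns, ncol(effects) == n_biomarkers)
  biomarkers <- sprintf("B%02d", seq_len(n_biomarkers))
  centroids <- cbind(
    CL1 = 500 + nz$centroid_spacing * ((seq_len(n_biomarkers) - 1L) %% 4L),
    CL2 = 500 + nz$centroid_spacing * ((seq_len(n_biomarkers) - 1L) %/% 4L))
  rownames(centroids) <- biomarkers
  samples$control_id <- paste0(samples$sample_id, "_NEM")
  allIds <- c(samples$sample_id, samples$control_id)
  isNem <- c(rep(FALSE, ns), rep(TRUE, ns))
  srcRow <- c(seq_len(ns), seq_len(ns))
  evList <- vector("list", length(allIds))
  for (i in seq_along(allIds)) {
    sid <- allIds[[i]]
    evList[[i]] <- withSeed(deriveSeed(rng_seed, "bead_sample", sid), {
      nEv <- nz$events_per_bead
      reg <- rep(biomarkers, each = nEv)
      cl <- centroids[reg, , drop = FALSE] +
        matrix(rnorm(2L * length(reg), 0, nz$cluster_sd),
               ncol = 2L)
      if (isNem[[i]]) {
        mfiUb <- rep(0, n_biomarkers)
      } else {
        mfiUb <- 2^(nz$base_log2_mfi + effects[srcRow[[i]], ])
      }
      rpUb <- nz$background_mfi *
        exp(rnorm(length(reg), 0, nz$reporter_cv)) +
        rep(mfiUb, each = nEv) * exp(rnorm(length(reg), 0, nz$reporter_cv))
      rpSu <- nz$background_mfi *
        exp(rnorm(length(reg), 0, nz$reporter_cv)) +
        (!isNem[[i]]) * 2^(nz$base_log2_mfi - 2) *
        exp(rnorm(length(reg), 0, nz$reporter_cv))
      data.frame(sample_id = sid, event = seq_along(reg),
                 CL1 = signif(cl[, 1L], 6), CL2 = signif(cl[, 2L], 6),
                 RP_ub = signif(rpUb, 6), RP_sumo1 = signif(rpSu, 6),
                 true_region = reg)
    })
  }
  events <- do.call(rbind, evList)
  rownames(events) <- NULL
  truth <- list(regions = events[, c("sample_id", "event", "true_region")],
                effects = data.frame(
                  sample_id = rep(samples$sample_id, n_biomarkers),
                  biomarker = rep(biomarkers, each = ns),
                  log2_effect = as.vector(effects)))
  names(truth$regions)[3L] <- "region"
  evOut <- events[, setdiff(names(events), "true_region")]
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (sid in allIds)
      write.csv(evOut[evOut$sample_id == sid, ],
                file.path(dir, paste0("events_", sid, ".csv")),
                row.names = FALSE, quote = FALSE)
    write.csv(samples, file.path(dir, "bead_samples.csv"),
              row.names = FALSE, quote = FALSE)
  }
  list(events = evOut, samples = samples, truth = truth,
       centroids = centroids)
}
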