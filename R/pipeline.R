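# Pipeline orchestration: one config object drives generate / train /
# predict / evaluate / relevance, each a thin composition of the module
# functions, with stage-level logging and seeded determinism.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline. Defaults follow the
#' package's standing choices: `k = 1` (the default false-negative
#' weight), threshold 0.5, Laplace smoothing 1, 2000 Monte-Carlo
#' replicates and a 0.05 relevance level with the "any"-test selection
#' rule.
#'
#' @param caseTable,schema input CSV / schema paths (may be `NULL` when
#'   memories are passed directly to the run functions).
#' @param modelOut path for the trained model JSON.
#' @param reportDir directory for evaluation and relevance reports.
#' @param k false-negative weight of the mixture objective.
#' @param threshold decision threshold.
#' @param smoothing CPT pseudo-count.
#' @param tabu a [tabuConfig()].
#' @param ci a [ciConfig()].
#' @param mcReplicates Monte-Carlo replicates of the relevance battery.
#' @param alphaLevel relevance significance level.
#' @param selectionMode `"any"` or `"all"` relevance selection rule.
#' @param looRelearnStructure if `TRUE`, leave-one-out relearns both
#'   structures on every fold; default `FALSE` learns them once and refits
#'   CPTs and weights per fold (one case barely moves the DAG at clinic
#'   scale, while full relearning multiplies cost by n).
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param verbose log stages with timings and seeds via `message()`.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(caseTable = NULL, schema = NULL,
                           modelOut = NULL, reportDir = NULL,
                           k = 1, threshold = 0.5, smoothing = 1,
                           tabu = tabuConfig(), ci = ciConfig(),
                           mcReplicates = 2000L, alphaLevel = 0.05,
                           selectionMode = "any",
                           looRelearnStructure = FALSE,
                           seed = 1L, verbose = TRUE) {
  stopifnot(k >= 0, threshold >= 0, threshold <= 1, smoothing >= 0,
            inherits(tabu, "tabuConfig"), inherits(ci, "ciConfig"))
  structure(list(caseTable = caseTable, schema = schema,
                 modelOut = modelOut, reportDir = reportDir,
                 k = k, threshold = threshold, smoothing = smoothing,
                 tabu = tabu, ci = ci,
                 mcReplicates = as.integer(mcReplicates),
                 alphaLevel = alphaLevel, selectionMode = selectionMode,
                 looRelearnStructure = isTRUE(looRelearnStructure),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML/JSON file
#'
#' Top-level keys mirror the [pipelineConfig()] arguments (snake_case
#' accepted); `tabu` and `ci` are nested maps passed to their
#' constructors.
#'
#' @param path config file path.
#' @param ... overrides applied after reading (e.g. `seed = 7`).
#' @return A `pipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  snake <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(raw) <- snake(names(raw))
  if (!is.null(raw$tabu)) {
    names(raw$tabu) <- snake(names(raw$tabu))
    raw$tabu <- do.call(tabuConfig, raw$tabu)
  }
  if (!is.null(raw$ci)) {
    names(raw$ci) <- snake(names(raw$ci))
    raw$ci <- do.call(ciConfig, raw$ci)
  }
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipelineConfig, raw)
}

stageLog <- function(config, stage, ...) {
  if (config$verbose)
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}

withStage <- function(config, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  stageLog(config, stage,
           sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
  res
}

loadMemory <- function(config, memory = NULL) {
  if (!is.null(memory)) return(memory)
  if (is.null(config$caseTable) || is.null(config$schema))
    stop("no case memory: supply `memory` or set caseTable/schema paths")
  loadCaseTable(config$caseTable, config$schema)
}

# seeded configs for the two component searches
componentConfigs <- function(config) {
  s <- deriveSeeds(config$seed, 2L)
  tabu <- config$tabu; tabu$seed <- s[1L]
  ci <- config$ci; ci$seed <- s[2L]
  list(tabu = tabu, ci = ci)
}

#' Generate the synthetic dataset configured for the pipeline
#'
#' @param config a `pipelineConfig` with `caseTable`/`schema` output paths.
#' @param fixture generator fixture, default [table1Fixture()].
#' @return The generated [CaseMemory-class], invisibly.
#' @export
runGenerate <- function(config, fixture = table1Fixture()) {
  stageLog(config, "generate", "seed ", config$seed)
  withStage(config, "generate",
    writeSyntheticDataset(config$caseTable, config$schema,
                          seed = config$seed, fixture = fixture))
}

#' Train the mixture model end-to-end
#'
#' Retrieve stage (keep retreatment cases), tabu-search and
#' conditional-independence structure learning, CPT fitting, component
#' posteriors on the training memory, and the closed-form solution of the
#' false-negative-averse weight problem. The model is written to
#' `config$modelOut` when set.
#'
#' @param config a `pipelineConfig`.
#' @param memory optional [CaseMemory-class] (otherwise loaded from the
#'   configured paths).
#' @return The trained [MixtureModel-class].
#' @export
runTrain <- function(config, memory = NULL) {
  memory <- withStage(config, "load", loadMemory(config, memory))
  retrieved <- withStage(config, "retrieve", retrieveRetreatmentCases(memory))
  stageLog(config, "retrieve", nCases(retrieved), " of ", nCases(memory),
           " cases are retreatments")
  if (nCases(retrieved) < 2L) stop("stage 'retrieve' failed: fewer than 2 retreatment cases")
  cc <- componentConfigs(config)
  stageLog(config, "reuse", "seeds: tabu ", cc$tabu$seed, ", ci ", cc$ci$seed)
  model <- withStage(config, "reuse",
    trainMixture(retrieved, tabu = cc$tabu, ci = cc$ci,
                 smoothing = config$smoothing, k = config$k,
                 threshold = config$threshold))
  stageLog(config, "reuse", "alpha = ",
           paste(sprintf("%.4f", model@solution@alpha), collapse = ", "),
           "; objective = ", format(model@solution@objective))
  if (!is.null(config$modelOut))
    withStage(config, "serialize", writeMixtureModel(model, config$modelOut))
  model
}

#' Predict new cases with a trained model
#'
#' @param config a `pipelineConfig` (used for `modelOut` when `model` is
#'   not given).
#' @param queryTable path to a query CSV validating against the training
#'   schema, or a [CaseMemory-class].
#' @param model optional [MixtureModel-class]; default: read from
#'   `config$modelOut`.
#' @param out optional path for the predictions CSV.
#' @return data.frame: case id, per-component posteriors, mixture score,
#'   predicted label.
#' @export
runPredict <- function(config, queryTable, model = NULL, out = NULL) {
  if (is.null(model)) {
    if (is.null(config$modelOut)) stop("no model: supply `model` or modelOut")
    model <- readMixtureModel(config$modelOut)
  }
  qmem <- if (is(queryTable, "CaseMemory")) queryTable
          else loadCaseTable(queryTable, config$schema)
  preds <- withStage(config, "predict", mixturePredict(model, qmem))
  if (!is.null(out))
    utils::write.csv(preds, out, row.names = FALSE)
  preds
}

# trainer factories conforming to the component-classifier interface
trainerTabu <- function(config) {
  force(config)
  function(mem) {
    m <- fitCPTs(mem, tabuSearchStructure(mem, config$tabu),
                 smoothing = config$smoothing, method = "tabu")
    function(q) predictPosteriors(m, q)
  }
}

trainerCI <- function(config) {
  force(config)
  function(mem) {
    m <- fitCPTs(mem, ciSearchStructure(mem, config$ci),
                 smoothing = config$smoothing, method = "ci")
    function(q) predictPosteriors(m, q)
  }
}

trainerMixture <- function(config) {
  force(config)
  function(mem) {
    m <- trainMixture(mem, tabu = config$tabu, ci = config$ci,
                      smoothing = config$smoothing, k = config$k,
                      threshold = config$threshold)
    function(q) mixturePredict(m, q)$score
  }
}

#' Evaluate the pipeline: leave-one-out, 5x2 CV and the comparison matrix
#'
#' Runs the full evaluation harness on the retrieved memory for the two
#' component classifiers, the mixture, and any extra baselines supplied
#' through the pluggable trainer interface. Leave-one-out scores the
#' mixture; by default the structures are learned once on the full memory
#' and CPTs + weights are refit on every fold (see
#' [pipelineConfig()]`$looRelearnStructure`).
#'
#' @param config a `pipelineConfig`.
#' @param memory optional [CaseMemory-class].
#' @param extraTrainers named list of additional trainer functions.
#' @return list with `loo` (correct count, accuracy), `cv` (list of
#'   [CVResult-class]), `cvTable` (20-column layout), `comparison`
#'   (pairwise p-value matrices) and `trainObjectives` (mixture and
#'   pure-component objectives on the training memory). CSV reports are
#'   written to `config$reportDir` when set.
#' @export
runEvaluate <- function(config, memory = NULL, extraTrainers = list()) {
  memory <- withStage(config, "load", loadMemory(config, memory))
  retrieved <- retrieveRetreatmentCases(memory)
  y <- caseLabels(retrieved)
  if (length(unique(y)) < 2L)
    stop("stage 'evaluate' failed: only one outcome class present")
  cc <- componentConfigs(config)
  cfgS <- config; cfgS$tabu <- cc$tabu; cfgS$ci <- cc$ci

  # training objectives: mixture vs pure components (feasibility check)
  model <- withStage(config, "train-full",
    trainMixture(retrieved, tabu = cc$tabu, ci = cc$ci,
                 smoothing = config$smoothing, k = config$k,
                 threshold = config$threshold))
  x <- t(vapply(model@components, predictPosteriors,
                numeric(nCases(retrieved)), memory = retrieved))
  pure <- vapply(seq_len(nrow(x)), function(j) {
    a <- numeric(nrow(x)); a[j] <- 1
    objectiveValue(a, x, y, config$k)
  }, numeric(1))
  trainObjectives <- c(mixture = model@solution@objective,
                       stats::setNames(pure, rownames(x)))

  # leave-one-out on the mixture
  looSeeds <- deriveSeeds(config$seed + 1L, 2L)
  looTrainer <- if (config$looRelearnStructure) {
    trainerMixture(cfgS)
  } else {
    force(model)
    function(mem) {
      comps <- lapply(model@components, function(cm)
        fitCPTs(mem, cm@parents, smoothing = config$smoothing,
                method = cm@method))
      xm <- t(vapply(comps, predictPosteriors, numeric(nCases(mem)),
                     memory = mem))
      sol <- solveWeights(xm, caseLabels(mem), k = config$k)
      function(q) {
        pq <- vapply(comps, predictPosteriors, numeric(nCases(q)),
                     memory = q)          # cases x components
        if (is.null(dim(pq))) pq <- matrix(pq, nrow = nCases(q))
        drop(pq %*% sol@alpha)
      }
    }
  }
  loo <- withStage(config, "leave-one-out",
                   leaveOneOut(retrieved, looTrainer,
                               threshold = config$threshold))
  stageLog(config, "leave-one-out", loo$correct, "/", nCases(retrieved),
           " correct (accuracy ", sprintf("%.3f", loo$accuracy), ")")

  trainers <- c(list(tabu = trainerTabu(cfgS), ci = trainerCI(cfgS),
                     mixture = trainerMixture(cfgS)), extraTrainers)
  cv <- withStage(config, "5x2cv",
                  fiveByTwoCV(retrieved, trainers, seed = looSeeds[1L]))
  cmp <- withStage(config, "comparison", comparisonMatrix(cv))

  out <- list(loo = loo[c("correct", "accuracy")], cv = cv,
              cvTable = cvTable(cv), comparison = cmp,
              trainObjectives = trainObjectives)
  if (!is.null(config$reportDir)) {
    dir.create(config$reportDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$cvTable,
                     file.path(config$reportDir, "cv_auc.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(out$comparison$matrix),
                     file.path(config$reportDir, "comparison_matrix.csv"))
    utils::write.csv(data.frame(classifier = "mixture",
                                correct = loo$correct,
                                n = nCases(retrieved),
                                accuracy = loo$accuracy),
                     file.path(config$reportDir, "leave_one_out.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the revise-stage relevance battery and write its report
#'
#' @param config a `pipelineConfig`.
#' @param memory optional [CaseMemory-class].
#' @return The relevance report data.frame (see [relevantVariables()]);
#'   written to `reportDir/relevance.csv` when a report directory is set.
#' @export
runRelevance <- function(config, memory = NULL) {
  memory <- withStage(config, "load", loadMemory(config, memory))
  retrieved <- retrieveRetreatmentCases(memory)
  stageLog(config, "revise", "selection mode: ", config$selectionMode,
           "; B = ", config$mcReplicates, "; seed ", config$seed)
  rep <- withStage(config, "revise",
    relevantVariables(retrieved, alphaLevel = config$alphaLevel,
                      mcReplicates = config$mcReplicates,
                      seed = config$seed, mode = config$selectionMode))
  if (!is.null(config$reportDir)) {
    dir.create(config$reportDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rep, file.path(config$reportDir, "relevance.csv"),
                     row.names = FALSE)
  }
  rep
}
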