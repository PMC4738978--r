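# Synthetic clinic-like categorical data with known ground truth: a
# generating Bayesian network over the case-table schema, ancestral
# sampling, and the fixture reproducing the preprocessed clinical
# variable list at its published scale (205 cases, 105 failures).

#' Configuration of the synthetic generator
#'
#' @param nCases number of cases to sample.
#' @param nVariables number of input variables (dependent + noise),
#'   ignored when an explicit `schema` is supplied.
#' @param arities integer vector of per-variable category counts (recycled
#'   to `nVariables`); each in 2..5, matching the preprocessed clinical
#'   table where variables carry "around 3 or 4" values.
#' @param nNoiseVariables how many input variables are generated
#'   independent of the target (parentless, target-disconnected).
#' @param maxParents cap on parent-set size of dependent variables.
#' @param effectStrength minimum absolute deviation of dependent-node CPT
#'   rows from the uniform distribution, in (0, 0.5]; larger values give
#'   structure learning a stronger signal.
#' @param targetPrevalence marginal probability of the positive (failure)
#'   class; the target is generated as a root node so the model marginal
#'   equals this exactly.
#' @param seed RNG seed.
#' @return A validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nCases = 205L, nVariables = 10L,
                            arities = c(2L, 3L, 4L),
                            nNoiseVariables = 4L, maxParents = 2L,
                            effectStrength = 0.3,
                            targetPrevalence = 105 / 205, seed = 1L) {
  stopifnot(nCases >= 1, nVariables >= 1,
            all(arities >= 2), all(arities <= 5),
            nNoiseVariables >= 0, nNoiseVariables < nVariables,
            maxParents >= 1,
            effectStrength > 0, effectStrength <= 0.5,
            targetPrevalence > 0, targetPrevalence < 1)
  structure(list(nCases = as.integer(nCases),
                 nVariables = as.integer(nVariables),
                 arities = as.integer(arities),
                 nNoiseVariables = as.integer(nNoiseVariables),
                 maxParents = as.integer(maxParents),
                 effectStrength = effectStrength,
                 targetPrevalence = targetPrevalence,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

# a CPT column bounded away from uniform by at least `effect` (max-abs)
skewedColumn <- function(r, effect) {
  eMax <- (r - 1) / r            # keeps every entry in [0, 1]
  e <- stats::runif(1L, effect, eMax)
  fav <- sample.int(r, 1L)
  col <- rep((1 - (1 / r + e)) / (r - 1), r)
  col[fav] <- 1 / r + e
  col
}

#' Generate a ground-truth Bayesian network
#'
#' Builds a fully specified network over the target plus
#' `nVariables` inputs. The target is a root node whose CPT equals the
#' requested prevalence exactly, so the model marginal matches by
#' construction. Dependent inputs draw 1..`maxParents` parents from the
#' target and earlier dependent variables; every CPT column of a dependent
#' node deviates from uniform by at least `effectStrength` (max-abs).
#' Noise inputs are parentless and disconnected from the target. An
#' optional schema (list of `{name, categories, role}`) fixes names and
#' arities; otherwise variables are named `V1..Vp` with recycled arities
#' and the target is called `outcome`.
#'
#' @param config a [syntheticConfig()].
#' @param schema optional schema, e.g. from [table1Fixture()].
#' @param dependentVars names of the schema variables to connect to the
#'   target (only with `schema`); the rest become noise. Variables named
#'   in `constantVars` are forced to their last category with probability
#'   one (used for the retreatment flag of a post-retrieve population).
#' @param constantVars see above.
#' @return A [BayesNetModel-class] carrying structure, CPTs and levels
#'   (method `"ground_truth"`).
#' @export
generateGroundTruth <- function(config, schema = NULL,
                                dependentVars = NULL,
                                constantVars = character(0)) {
  set.seed(config$seed)
  if (is.null(schema)) {
    arity <- rep_len(config$arities, config$nVariables)
    vnames <- paste0("V", seq_len(config$nVariables))
    target <- "outcome"
    levs <- c(stats::setNames(lapply(arity, function(r)
                if (r == 2L) c("no", "yes") else paste0("c", seq_len(r))),
              vnames),
              list(outcome = c("success", "failure")))
    nNoise <- config$nNoiseVariables
    depVars <- vnames[seq_len(length(vnames) - nNoise)]
    noiseVars <- setdiff(vnames, depVars)
  } else {
    roles <- vapply(schema, `[[`, character(1), "role")
    vnames <- vapply(schema, `[[`, character(1), "name")
    target <- vnames[roles == "target"]
    levs <- stats::setNames(lapply(schema, function(s)
      as.character(s$categories)), vnames)
    vnames <- setdiff(vnames, target)
    depVars <- intersect(dependentVars %||% vnames, vnames)
    depVars <- setdiff(depVars, constantVars)
    noiseVars <- setdiff(vnames, c(depVars, constantVars))
  }
  if (length(levs[[target]]) != 2L)
    stop("ground-truth target must be binary")

  nodes <- c(target, depVars, noiseVars, intersect(constantVars, names(levs)))
  parents <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  for (i in seq_along(depVars)) {
    pool <- c(target, depVars[seq_len(i - 1L)])
    np <- sample.int(min(config$maxParents, length(pool)), 1L)
    # keep the target a frequent parent so the planted signal reaches it
    pa <- if (stats::runif(1) < 0.7 || length(pool) == 1L)
      c(target, sample(setdiff(pool, target), np - 1L))
    else sample(pool, np)
    parents[[depVars[i]]] <- unique(pa)
  }

  arity <- vapply(levs, length, integer(1))
  cpts <- list()
  for (v in nodes) {
    r <- arity[[v]]
    q <- if (length(parents[[v]])) prod(arity[parents[[v]]]) else 1L
    if (v == target) {
      m <- matrix(c(1 - config$targetPrevalence, config$targetPrevalence),
                  nrow = 2L)
    } else if (v %in% constantVars) {
      m <- matrix(c(rep(0, r - 1L), 1), nrow = r, ncol = q)
    } else if (v %in% noiseVars) {
      m <- matrix(stats::runif(r, 0.5, 1.5), nrow = r, ncol = q)
      m <- m / rep(colSums(m), each = r)
    } else {
      m <- vapply(seq_len(q), function(j)
        skewedColumn(r, config$effectStrength), numeric(r))
      dim(m) <- c(r, q)
    }
    rownames(m) <- levs[[v]]
    attr(m, "parents") <- parents[[v]]
    cpts[[v]] <- m
  }
  new("BayesNetModel", nodes = nodes, parents = parents,
      levels = levs[nodes], cpts = cpts, smoothing = 0,
      method = "ground_truth")
}

#' Exact marginal distribution of one node by full-joint enumeration
#'
#' Enumerates every configuration of the network's variables and sums the
#' joint factorisation; intended for small ground-truth models (checks the
#' prevalence calibration).
#'
#' @param model a fitted [BayesNetModel-class].
#' @param node node name.
#' @return Named probability vector over the node's categories.
#' @export
exactMarginal <- function(model, node) {
  arity <- vapply(model@levels, length, integer(1))
  grid <- as.matrix(expand.grid(lapply(arity, seq_len)))
  colnames(grid) <- model@nodes
  lp <- numeric(nrow(grid))
  for (v in model@nodes) {
    cpt <- model@cpts[[v]]
    cfg <- configIndex(grid, attr(cpt, "parents"), arity)
    lp <- lp + log(cpt[cbind(grid[, v], cfg)])
  }
  pr <- exp(lp)
  out <- vapply(seq_len(arity[[node]]), function(t)
    sum(pr[grid[, node] == t]), numeric(1))
  stats::setNames(out / sum(out), model@levels[[node]])
}

#' Sample cases from a ground-truth network
#'
#' Ancestral sampling in topological order. The sampled memory flags every
#' case as a retreatment, emulating the post-retrieve population the
#' classifiers are built on (when `retreatmentVar` names a generated
#' constant variable the flag comes from that column).
#'
#' @param model a [BayesNetModel-class] with CPTs (typically from
#'   [generateGroundTruth()]).
#' @param n number of cases.
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @param target,targetPositive target variable and positive category;
#'   defaults: the model node named `outcome` if present else the last
#'   binary node, and its last category.
#' @param retreatmentVar optional retreatment-flag variable name.
#' @return A [CaseMemory-class] of `n` cases.
#' @export
sampleCases <- function(model, n, seed = 1L,
                        target = NULL, targetPositive = NULL,
                        retreatmentVar = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  arity <- vapply(model@levels, length, integer(1))
  ord <- dagTopoOrder(model@parents)
  codes <- matrix(0L, n, length(model@nodes),
                  dimnames = list(NULL, model@nodes))
  for (v in ord) {
    cpt <- model@cpts[[v]]
    cfg <- configIndex(codes, attr(cpt, "parents"), arity)
    cum <- apply(cpt, 2L, cumsum)
    u <- stats::runif(n)
    cc <- cum[, cfg, drop = FALSE]
    codes[, v] <- colSums(cc < rep(u, each = nrow(cc))) + 1L
  }
  df <- as.data.frame(lapply(model@nodes, function(v)
    factor(model@levels[[v]][codes[, v]], levels = model@levels[[v]])),
    col.names = model@nodes, check.names = FALSE)
  rownames(df) <- paste0("case", seq_len(n))
  if (is.null(target))
    target <- if ("outcome" %in% model@nodes) "outcome"
              else rev(model@nodes[arity[model@nodes] == 2L])[1L]
  if (is.null(targetPositive))
    targetPositive <- rev(model@levels[[target]])[1L]
  new("CaseMemory", cases = df, target = target,
      targetPositive = targetPositive,
      retreatmentVar = as.character(retreatmentVar %||% character(0)))
}

#' The preprocessed clinical variable list, as a reusable fixture
#'
#' Returns the schema of the final preprocessed case table of the clinical
#' study this package models: 42 input variables with 2-5 categories each
#' plus the binary target "Failures in retreatment", and a default
#' generator configuration at the study's scale (205 cases, prevalence
#' 105/205). The planted dependent variables are the ones the study's
#' relevance screen reported as associated with the outcome, so the
#' synthetic data carries signal in realistic places; "Retreatments" is
#' generated constant-positive (a post-retrieve population). One variable
#' whose category count the source lists only as "Discrete" (Sessions) is
#' given 4 categories, in line with the 3-4 categories of the other
#' preprocessed variables.
#'
#' @return list with `schema` (variable descriptors), `config` (a
#'   [syntheticConfig()]), `dependentVars`, `constantVars`, and
#'   `retreatmentVar`.
#' @export
table1Fixture <- function() {
  spec <- list(
    c("Habits-parafunctions", 2), c("General pathology", 2),
    c("Total current treatments", 2), c("Allergy", 2), c("Sessions", 4),
    c("Mechanical/manual instrumentation", 2), c("Lateral or vertical", 2),
    c("Anesthetic", 3), c("Clamps", 4), c("Ranking difficulty level", 3),
    c("Student course", 4), c("Tooth position", 3),
    c("Anatomical characteristics of the crown", 3), c("Root anatomy", 3),
    c("Anomalies", 2), c("Type of restoration: Perno", 2), c("Perno", 2),
    c("Type", 2), c("Diametro diameter", 5), c("Length", 3),
    c("Time endodontics-restoration", 4), c("Type of pain", 4),
    c("Inflammation", 2), c("Fistula", 2), c("Number of roots", 3),
    c("Number of tubes", 4), c("Root morphology", 2), c("Curvatures", 2),
    c("Degree", 3), c("Bone level", 3), c("Stable occlusion", 3),
    c("Fracture type", 2), c("Location", 5),
    c("Signs of fissure/fracture", 2), c("Probing", 2), c("Movility", 2),
    c("visible crack", 2), c("Level", 2), c("Time to failure", 4),
    c("Retreatments", 2), c("Percha solvent", 2), c("Use of rotary", 2))
  schema <- lapply(spec, function(s) {
    r <- as.integer(s[2])
    list(name = s[1],
         categories = if (r == 2L) c("no", "yes") else paste0("c", seq_len(r)),
         role = "input")
  })
  schema <- c(schema, list(list(name = "Failures in retreatment",
                                categories = c("no", "yes"),
                                role = "target")))
  dependentVars <- c("Allergy", "Mechanical/manual instrumentation",
                     "Anesthetic", "Ranking difficulty level",
                     "Root anatomy", "Type of restoration: Perno", "Perno",
                     "Type", "Time endodontics-restoration", "Length",
                     "Number of roots", "Curvatures")
  list(schema = schema,
       config = syntheticConfig(nCases = 205L,
                                nVariables = length(schema) - 1L,
                                nNoiseVariables = length(schema) - 1L -
                                  length(dependentVars) - 1L,
                                maxParents = 2L, effectStrength = 0.3,
                                targetPrevalence = 105 / 205, seed = 20160114L),
       dependentVars = dependentVars,
       constantVars = "Retreatments",
       retreatmentVar = "Retreatments")
}

#' Generate and write a synthetic dataset to disk
#'
#' Samples a case table from a ground-truth network (default: the
#' clinic-scale fixture of [table1Fixture()]) and writes the CSV/schema
#' pair consumed by [loadCaseTable()].
#'
#' @param tablePath,schemaPath output paths.
#' @param seed RNG seed for both the network and the sampling.
#' @param fixture list as returned by [table1Fixture()]; pass a modified
#'   copy to change scale or signal.
#' @return The generated [CaseMemory-class], invisibly.
#' @export
writeSyntheticDataset <- function(tablePath, schemaPath, seed = 20160114L,
                                  fixture = table1Fixture()) {
  cfg <- fixture$config
  cfg$seed <- as.integer(seed)
  gt <- generateGroundTruth(cfg, schema = fixture$schema,
                            dependentVars = fixture$dependentVars,
                            constantVars = fixture$constantVars)
  tgt <- vapply(fixture$schema, function(s)
    if (s$role == "target") s$name else NA_character_, character(1))
  tgt <- tgt[!is.na(tgt)]
  mem <- sampleCases(gt, cfg$nCases, seed = seed + 1L,
                     target = tgt, targetPositive = "yes",
                     retreatmentVar = fixture$retreatmentVar)
  writeCaseTable(mem, tablePath, schemaPath)
  invisible(mem)
}
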