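#' @import methods
NULL

#' Case memory: a schema-validated table of categorical clinical cases
#'
#' The central CBR container. Every column of `cases` is a factor whose
#' levels are the variable's declared categories; row names are case ids.
#' Exactly one column is the binary prediction target and one of its two
#' levels is designated the positive (clinically costly) class.
#'
#' @slot cases data.frame of factors, one row per case, row names = case ids.
#' @slot target name of the binary target column.
#' @slot targetPositive the target level coded as 1 ("failure of retreatment").
#' @slot retreatmentVar optional name of the binary variable whose last
#'   level flags a case as a retreatment (used by the retrieve stage);
#'   `character(0)` when every case counts as a retreatment.
#'
#' @export
setClass("CaseMemory",
  representation(
    cases = "data.frame",
    target = "character",
    targetPositive = "character",
    retreatmentVar = "character"
  )
)

setValidity("CaseMemory", function(object) {
  df <- object@cases
  msgs <- character(0)
  if (!all(vapply(df, is.factor, logical(1))))
    msgs <- c(msgs, "all case columns must be factors")
  bad <- names(df)[vapply(df, function(x) is.factor(x) && nlevels(x) < 2, logical(1))]
  if (length(bad))
    msgs <- c(msgs, paste0("variables must declare >= 2 categories: ",
                           paste(bad, collapse = ", ")))
  if (anyNA(df))
    msgs <- c(msgs, "missing values are not allowed in a case memory")
  if (length(object@target) != 1L || !(object@target %in% names(df)))
    msgs <- c(msgs, "target must name exactly one column")
  else {
    if (nlevels(df[[object@target]]) != 2L)
      msgs <- c(msgs, "target variable must have exactly 2 categories")
    if (!(object@targetPositive %in% levels(df[[object@target]])))
      msgs <- c(msgs, "targetPositive must be one of the target's categories")
  }
  if (anyDuplicated(rownames(df)))
    msgs <- c(msgs, "case ids must be unique")
  if (length(object@retreatmentVar) > 1L ||
      (length(object@retreatmentVar) == 1L && !(object@retreatmentVar %in% names(df))))
    msgs <- c(msgs, "retreatmentVar must be absent or name one column")
  if (length(msgs)) msgs else TRUE
})

#' Discrete Bayesian network: DAG structure plus conditional probability tables
#'
#' @slot nodes variable names, in the column order of the memory the model
#'   was learned from.
#' @slot parents named list mapping each node to its parent nodes (the
#'   parent sets of the directed acyclic structure).
#' @slot levels named list of category labels per node.
#' @slot cpts named list; each element is a matrix with one row per node
#'   category and one column per parent configuration (columns sum to 1).
#'   Parent configurations are indexed with the first listed parent varying
#'   fastest. Empty before [fitCPTs()] is applied.
#' @slot smoothing Laplace pseudo-count used when the CPTs were fitted.
#' @slot method label of the structure-search method ("tabu", "ci", ...).
#'
#' @export
setClass("BayesNetModel",
  representation(
    nodes = "character",
    parents = "list",
    levels = "list",
    cpts = "list",
    smoothing = "numeric",
    method = "character"
  )
)

setValidity("BayesNetModel", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@parents)), sort(object@nodes)))
    msgs <- c(msgs, "parents must be a named list with one entry per node")
  if (!all(unlist(object@parents) %in% object@nodes))
    msgs <- c(msgs, "parent sets must be subsets of the node set")
  for (v in object@nodes)
    if (v %in% object@parents[[v]])
      msgs <- c(msgs, paste0("node ", v, " cannot be its own parent"))
  if (length(dagTopoOrder(object@parents)) == 0L && length(object@nodes) > 0L)
    msgs <- c(msgs, "structure contains a directed cycle")
  if (length(object@cpts)) {
    for (v in names(object@cpts)) {
      cs <- colSums(object@cpts[[v]])
      if (any(abs(cs - 1) > 1e-9))
        msgs <- c(msgs, paste0("CPT columns of ", v, " must sum to 1"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Solution of the constrained false-negative-averse mixture problem
#'
#' Weights `alpha` minimise the asymmetric squared loss
#' `sum_i (1 + k*y_i) * (alpha . x_i - y_i)^2` subject to `sum(alpha) = 1`,
#' solved in closed form via Lagrange multipliers.
#'
#' @slot alpha component weights summing to 1 (negative weights are legal).
#' @slot lambda Lagrange multiplier of the sum-to-one constraint.
#' @slot objective value of the objective at `alpha`.
#' @slot k false-negative weight used.
#'
#' @export
setClass("MixtureSolution",
  representation(alpha = "numeric", lambda = "numeric",
                 objective = "numeric", k = "numeric"))

setValidity("MixtureSolution", function(object) {
  msgs <- character(0)
  if (abs(sum(object@alpha) - 1) > 1e-9)
    msgs <- c(msgs, "mixture weights must sum to 1")
  if (object@objective < -1e-12)
    msgs <- c(msgs, "objective must be non-negative")
  if (object@k < 0) msgs <- c(msgs, "k must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Fitted mixture of posterior-producing classifiers
#'
#' @slot components named list of fitted component classifiers (normally two
#'   [BayesNetModel-class] objects, one per structure-search method).
#' @slot solution the [MixtureSolution-class] holding the weights.
#' @slot threshold decision threshold on the mixture score.
#'
#' @export
setClass("MixtureModel",
  representation(components = "list", solution = "MixtureSolution",
                 threshold = "numeric"))

setValidity("MixtureModel", function(object) {
  if (length(object@components) != length(object@solution@alpha))
    "component count must equal the number of mixture weights" else TRUE
})

#' One method's 5x2 cross-validation AUC record
#'
#' Holds the 20 AUC values of Dietterich-style 5x2 cross-validation: five
#' replicates, each splitting the data into halves S1/S2; per replicate the
#' classifier is trained on S1 (fold "A") and evaluated on both halves, then
#' trained on S2 (fold "B") and evaluated on both halves.
#'
#' @slot method method identifier.
#' @slot auc numeric array `dim = c(5, 2, 2)` indexed by
#'   (replicate, trained-on A/B, evaluated-on S1/S2).
#' @slot seed seed that generated the splits.
#'
#' @export
setClass("CVResult",
  representation(method = "character", auc = "array", seed = "numeric"))

setValidity("CVResult", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@auc), c(5L, 2L, 2L)))
    msgs <- c(msgs, "auc must be a 5 x 2 x 2 array (20 values)")
  if (any(object@auc < 0 | object@auc > 1, na.rm = TRUE))
    msgs <- c(msgs, "AUC values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
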