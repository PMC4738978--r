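# JSON serialisation of fitted models: component networks (structure,
# CPTs, smoothing, search method) and the mixture solution (alpha, lambda,
# k, threshold). Numeric values are written at full precision so a
# write/read round trip reproduces the model exactly.

bnToList <- function(model) {
  list(nodes = model@nodes,
       structure = model@parents,
       levels = model@levels,
       cpts = lapply(model@cpts, function(m) {
         list(prob = as.vector(m), nrow = nrow(m),
              parents = attr(m, "parents"))
       }),
       smoothing = model@smoothing,
       search_method = model@method)
}

bnFromList <- function(x) {
  nodes <- unlist(x$nodes)
  parents <- lapply(x$structure, function(p) as.character(unlist(p)))
  names(parents) <- names(x$structure)
  levels <- lapply(x$levels, function(l) as.character(unlist(l)))
  cpts <- list()
  for (v in names(x$cpts)) {
    e <- x$cpts[[v]]
    m <- matrix(unlist(e$prob), nrow = e$nrow)
    rownames(m) <- levels[[v]]
    attr(m, "parents") <- as.character(unlist(e$parents))
    cpts[[v]] <- m
  }
  new("BayesNetModel", nodes = nodes, parents = parents[nodes],
      levels = levels[nodes], cpts = cpts,
      smoothing = as.numeric(x$smoothing),
      method = as.character(x$search_method))
}

#' Write and read a mixture model as JSON
#'
#' The document embeds each component network (structure, levels, CPTs,
#' smoothing, search method) together with the mixture solution: `alpha`,
#' `lambda`, `k`, `objective` and the decision `threshold`. Reloading
#' reproduces the model exactly.
#'
#' @param model a [MixtureModel-class].
#' @param path output path.
#' @return `writeMixtureModel`: the path, invisibly;
#'   `readMixtureModel`: the restored [MixtureModel-class].
#' @export
writeMixtureModel <- function(model, path) {
  doc <- list(
    mixture = list(alpha = model@solution@alpha,
                   lambda = model@solution@lambda,
                   objective = model@solution@objective,
                   k = model@solution@k,
                   threshold = model@threshold,
                   component_refs = names(model@components)),
    components = lapply(model@components, bnToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeMixtureModel
#' @export
readMixtureModel <- function(path) {
  doc <- jsonlite::read_json(path)
  comps <- lapply(doc$components, bnFromList)
  sol <- new("MixtureSolution",
             alpha = as.numeric(unlist(doc$mixture$alpha)),
             lambda = as.numeric(doc$mixture$lambda),
             objective = as.numeric(doc$mixture$objective),
             k = as.numeric(doc$mixture$k))
  new("MixtureModel", components = comps, solution = sol,
      threshold = as.numeric(doc$mixture$threshold))
}
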