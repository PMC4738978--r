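# The false-negative-averse mixture of classifiers: asymmetric quadratic
# objective, sum-to-one constraint, closed-form Lagrange solution, and
# mixture prediction.

#' Asymmetric mixture objective
#'
#' Value of the mixture loss
#' `f(alpha) = sum_i (alpha . x_i - y_i)^2 + k * (alpha . x_i - y_i)^2 * y_i`
#' `         = sum_i (1 + k * y_i) * (alpha . x_i - y_i)^2`,
#' where `x_i` stacks the component posteriors on case `i`, `y_i` is the
#' true 0/1 label and `k >= 0` up-weights the residuals of positive
#' (failure) cases so that missing a genuinely failing retreatment costs
#' more than a false alarm. `k = 0` recovers the plain sum of squared
#' errors.
#'
#' @param alpha numeric weight vector, one entry per component.
#' @param x numeric matrix of component posteriors, `x[j, i]` = posterior
#'   of component `j` on case `i` (components x cases).
#' @param y 0/1 vector of true labels, length `ncol(x)`.
#' @param k non-negative false-negative weight (default 1).
#' @return Non-negative scalar.
#' @export
objectiveValue <- function(alpha, x, y, k = 1) {
  x <- rbind(x)
  if (length(alpha) != nrow(x))
    stop("dimension mismatch: length(alpha) != number of components")
  if (length(y) != ncol(x))
    stop("dimension mismatch: length(y) != number of cases")
  stopifnot(k >= 0, all(y %in% c(0, 1)))
  resid <- drop(crossprod(x, alpha)) - y
  sum((1 + k * y) * resid^2)
}

#' Solve the constrained mixture weights in closed form
#'
#' Minimises [objectiveValue()] subject to `sum(alpha) = 1` by the method
#' of Lagrange multipliers. Writing `w_i = 1 + k * y_i`, stationarity gives
#' the linear system
#' `2 * sum_i w_i x_i x_i' alpha - lambda * 1 = 2 * sum_i w_i y_i x_i`
#' together with `1' alpha = 1`, i.e. one symmetric KKT system in
#' `(alpha, lambda)`. A non-singular system is solved directly; a singular
#' one (e.g. duplicated components) is resolved by the minimum-norm
#' solution, which reduces to equal weights for identical components.
#' Weights are not clamped: only the sum-to-one constraint is enforced and
#' negative weights are legal.
#'
#' @inheritParams objectiveValue
#' @return A [MixtureSolution-class] with `alpha`, `lambda`, the attained
#'   `objective` and `k`.
#' @export
solveWeights <- function(x, y, k = 1) {
  x <- rbind(x)
  m <- nrow(x); n <- ncol(x)
  if (n < 1L) stop("no cases to fit mixture weights on")
  if (length(y) != n) stop("dimension mismatch: length(y) != number of cases")
  stopifnot(k >= 0, all(y %in% c(0, 1)))
  w <- 1 + k * y
  A <- x %*% (w * t(x))          # sum_i w_i x_i x_i'
  b <- drop(x %*% (w * y))       # sum_i w_i y_i x_i
  K <- rbind(cbind(2 * A, -1), c(rep(1, m), 0))
  rhs <- c(2 * b, 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)))
    sol <- drop(MASS::ginv(K) %*% rhs)
  alpha <- sol[seq_len(m)]
  # guard: renormalise away any numerical drift in the constraint
  alpha <- alpha / sum(alpha)
  new("MixtureSolution", alpha = alpha, lambda = sol[m + 1L],
      objective = objectiveValue(alpha, x, y, k), k = k)
}

setMethod("show", "MixtureSolution", function(object) {
  cat("MixtureSolution (k =", object@k, ")\n")
  cat("  alpha:", paste(sprintf("%.4f", object@alpha), collapse = ", "), "\n")
  cat("  lambda:", format(object@lambda), " objective:",
      format(object@objective), "\n")
  if (any(object@alpha < 0))
    cat("  note: negative weights present (legal; only sum-to-one is enforced)\n")
})

#' Train the two-component Bayesian-network mixture
#'
#' Learns one structure by tabu search and one by conditional-independence
#' search on the (already retrieved) case memory, fits CPTs for both,
#' computes each component's posterior for every training case, and solves
#' the constrained asymmetric least-squares problem for the component
#' weights.
#'
#' @param memory a labeled [CaseMemory-class] (post-retrieve).
#' @param tabu a [tabuConfig()].
#' @param ci a [ciConfig()].
#' @param smoothing Laplace pseudo-count for the CPTs.
#' @param k false-negative weight of the mixture objective.
#' @param threshold decision threshold on the mixture score (default 0.5).
#' @return A [MixtureModel-class] with components `tabu` and `ci`.
#' @export
trainMixture <- function(memory, tabu = tabuConfig(), ci = ciConfig(),
                         smoothing = 1, k = 1, threshold = 0.5) {
  mTabu <- fitCPTs(memory, tabuSearchStructure(memory, tabu),
                   smoothing = smoothing, method = "tabu")
  mCI <- fitCPTs(memory, ciSearchStructure(memory, ci),
                 smoothing = smoothing, method = "ci")
  comps <- list(tabu = mTabu, ci = mCI)
  x <- t(vapply(comps, predictPosteriors, numeric(nCases(memory)),
                memory = memory))
  sol <- solveWeights(x, caseLabels(memory), k = k)
  new("MixtureModel", components = comps, solution = sol,
      threshold = threshold)
}

#' Mixture prediction for new cases
#'
#' Scores are the weighted sum of the component posteriors,
#' `score = sum_j alpha_j * posterior_j(case)`; the predicted label is the
#' positive class iff `score >= threshold`.
#'
#' @param model a trained [MixtureModel-class].
#' @param memory a [CaseMemory-class] of query cases (labels, if present,
#'   are ignored).
#' @return data.frame with the case id, one posterior column per component,
#'   the mixture `score`, and the predicted `label`.
#' @export
mixturePredict <- function(model, memory) {
  if (!length(model@components)) stop("mixture model has no components")
  n <- nCases(memory)
  post <- vapply(model@components, predictPosteriors, numeric(n),
                 memory = memory)
  if (n == 0L)
    post <- matrix(numeric(0), 0L, length(model@components),
                   dimnames = list(NULL, names(model@components)))
  if (is.null(dim(post)))
    post <- matrix(post, nrow = n,
                   dimnames = list(NULL, names(model@components)))
  score <- drop(post %*% model@solution@alpha)
  tLev <- levels(caseData(memory)[[targetVariable(memory)]])
  negLevel <- setdiff(tLev, targetPositive(memory))
  out <- data.frame(case_id = rownames(caseData(memory)),
                    post, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("posterior_", names(model@components))
  out$score <- score
  out$label <- ifelse(score >= model@threshold, targetPositive(memory), negLevel)
  rownames(out) <- NULL
  out
}

setMethod("show", "MixtureModel", function(object) {
  cat("MixtureModel with", length(object@components), "components:",
      paste(names(object@components), collapse = ", "), "\n")
  cat("  alpha:", paste(sprintf("%.4f", object@solution@alpha),
                        collapse = ", "),
      " (k =", object@solution@k, ")\n")
  cat("  threshold:", object@threshold, "\n")
})
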