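# Revise-stage relevance battery: chi-square (plain and Yates-corrected),
# Monte-Carlo chi-square, and Fisher's exact test of each input variable
# against the binary target.

#' Contingency table of a variable versus the target
#'
#' @param memory a labeled [CaseMemory-class].
#' @param variable input variable name.
#' @param target target variable name (defaults to the memory's target).
#' @return Integer matrix of counts, rows = observed variable categories,
#'   columns = observed target categories. Declared but never-observed
#'   levels are pruned with a warning.
#' @export
contingencyTable <- function(memory, variable,
                             target = targetVariable(memory)) {
  if (variable == target) stop("variable must differ from the target")
  df <- caseData(memory)
  stopifnot(variable %in% names(df), target %in% names(df))
  full <- table(df[[variable]], df[[target]])
  keepR <- rowSums(full) > 0
  keepC <- colSums(full) > 0
  if (!all(keepR) || !all(keepC))
    warning("empty categories pruned for ", variable, " vs ", target, ": ",
            paste(c(rownames(full)[!keepR], colnames(full)[!keepC]),
                  collapse = ", "))
  m <- unclass(full[keepR, keepC, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = (r-1)(c-1)` and an
#' upper-tail chi-square p-value. The Yates continuity correction (defined
#' for 2x2 tables only) subtracts 0.5 from each `|O - E|`, floored at 0; it
#' is the paper-of-record remedy when expected counts drop below 5.
#'
#' @param table contingency matrix of counts.
#' @param correction `"none"` or `"yates"`.
#' @return list with `statistic`, `df`, `p`.
#' @export
chiSquareTest <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("degenerate contingency table: need >= 2 rows and columns")
  if (correction == "yates" && !(nrow(table) == 2L && ncol(table) == 2L))
    stop("Yates correction is defined for 2x2 tables only")
  res <- suppressWarnings(
    stats::chisq.test(table, correct = correction == "yates"))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Monte-Carlo chi-square p-value under the fixed-margins null
#'
#' Simulates `replicates` tables with the observed margins (Patefield
#' sampling), and reports
#' `p = (#\{simulated statistic >= observed\} + 1) / (replicates + 1)`.
#' The attainable minimum is therefore `1 / (replicates + 1)`; with the
#' default 2000 replicates that floor is 1/2001 = 0.00049975.
#'
#' @param table contingency matrix of counts.
#' @param replicates number of simulated tables (B).
#' @param seed RNG seed; the p-value is deterministic given the seed.
#' @return The Monte-Carlo p-value, an integer multiple of
#'   `1/(replicates+1)`.
#' @export
chiSquareMonteCarlo <- function(table, replicates = 2000L, seed = 1L) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("degenerate contingency table: need >= 2 rows and columns")
  stopifnot(replicates >= 1)
  set.seed(seed)
  suppressWarnings(
    stats::chisq.test(table, simulate.p.value = TRUE,
                      B = as.integer(replicates)))$p.value
}

#' Fisher's exact test (exact 2x2, Monte-Carlo r x c)
#'
#' For a 2x2 table the exact two-sided p-value sums the hypergeometric
#' probabilities of all margin-consistent tables no more probable than the
#' observed one. Larger tables use the seeded Monte-Carlo estimate with
#' the `(r + 1)/(B + 1)` estimator over fixed-margins sampling. All-zero
#' rows/columns are pruned first; a table degenerate after pruning returns
#' p = 1.
#'
#' @param table contingency matrix of counts.
#' @param mcReplicates Monte-Carlo replicates for tables larger than 2x2.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return Two-sided p-value.
#' @export
fisherExact <- function(table, mcReplicates = 2000L, seed = 1L) {
  table <- as.matrix(table)
  table <- table[rowSums(table) > 0, , drop = FALSE]
  table <- table[, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) return(1)
  if (nrow(table) == 2L && ncol(table) == 2L)
    return(stats::fisher.test(table)$p.value)
  set.seed(seed)
  stats::fisher.test(table, simulate.p.value = TRUE,
                     B = as.integer(mcReplicates))$p.value
}

#' Relevance report over all input variables
#'
#' Runs the full battery of each input variable against the target:
#' Yates-corrected chi-square for 2x2 tables (uncorrected chi-square for
#' larger ones), the Monte-Carlo chi-square, and Fisher's exact test. A
#' variable is `selected` when its battery p-values fall below
#' `alphaLevel` -- under `mode = "any"` (default) at least one test must
#' fire, under `mode = "all"` all three must.
#'
#' Variables degenerate after pruning (e.g. constant columns such as the
#' retreatment flag in a post-retrieve memory) get p = 1 on every test and
#' are never selected.
#'
#' @param memory a labeled [CaseMemory-class].
#' @param alphaLevel significance level for selection.
#' @param mcReplicates Monte-Carlo replicates (default 2000).
#' @param seed RNG seed; sub-seeds per variable keep the report
#'   reproducible and independent of evaluation order.
#' @param mode `"any"` or `"all"` selection rule.
#' @return data.frame with one row per input variable and columns
#'   `variable`, `p_yates`, `p_monte_carlo`, `p_fisher`, `selected`;
#'   attributes record `alphaLevel`, `mcReplicates`, `seed` and `mode`.
#' @export
relevantVariables <- function(memory, alphaLevel = 0.05,
                              mcReplicates = 2000L, seed = 1L,
                              mode = c("any", "all")) {
  mode <- match.arg(mode)
  vars <- inputVariables(memory)
  seeds <- deriveSeeds(seed, 2L * length(vars))
  rows <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    tab <- suppressWarnings(contingencyTable(memory, v))
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      rows[[i]] <- data.frame(variable = v, p_yates = 1, p_monte_carlo = 1,
                              p_fisher = 1, selected = FALSE)
      next
    }
    pY <- if (nrow(tab) == 2L && ncol(tab) == 2L)
      chiSquareTest(tab, "yates")$p else chiSquareTest(tab, "none")$p
    pMC <- chiSquareMonteCarlo(tab, mcReplicates, seed = seeds[2L * i - 1L])
    pF <- fisherExact(tab, mcReplicates, seed = seeds[2L * i])
    ps <- c(pY, pMC, pF)
    sel <- if (mode == "any") any(ps < alphaLevel) else all(ps < alphaLevel)
    rows[[i]] <- data.frame(variable = v, p_yates = pY, p_monte_carlo = pMC,
                            p_fisher = pF, selected = sel)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alphaLevel") <- alphaLevel
  attr(out, "mcReplicates") <- as.integer(mcReplicates)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "mode") <- mode
  out
}
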