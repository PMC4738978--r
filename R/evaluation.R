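# Evaluation harness: ROC AUC, leave-one-out, 5x2 cross-validation,
# Dietterich's 5x2cv paired t-test, Mann-Whitney U, and the pairwise
# comparison matrix.

#' Area under the ROC curve
#'
#' Rank-sum (midrank) formulation: the probability that a random positive
#' case outscores a random negative one, counting ties as one half.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 vector, 1 = positive class; both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)   # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out evaluation of a trainer
#'
#' For each case, trains on the remaining `n - 1` cases and classifies the
#' held-out case; reports the count of correct classifications and the
#' accuracy. A `trainer` is a function taking a [CaseMemory-class] and
#' returning a classifier: a function mapping a query memory to numeric
#' positive-class scores.
#'
#' @param memory a labeled [CaseMemory-class] with `n >= 2`.
#' @param trainer trainer function as described above.
#' @param threshold score threshold for calling the positive class.
#' @return list with `correct` (integer), `accuracy`, and the per-case
#'   logical vector `hits`.
#' @export
leaveOneOut <- function(memory, trainer, threshold = 0.5) {
  n <- nCases(memory)
  stopifnot(n >= 2)
  y <- caseLabels(memory)
  hits <- logical(n)
  for (i in seq_len(n)) {
    cls <- tryCatch(trainer(subsetCases(memory, -i)),
                    error = function(e)
                      stop("trainer failed on fold ", i, ": ",
                           conditionMessage(e)))
    s <- cls(subsetCases(memory, i))
    hits[i] <- as.integer(s >= threshold) == y[i]
  }
  list(correct = sum(hits), accuracy = mean(hits), hits = hits)
}

# stratified half/half split indices; both classes present in each half
stratifiedHalves <- function(y) {
  s1 <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    take <- sample(idx, floor(length(idx) / 2))
    s1 <- c(s1, take)
  }
  sort(s1)
}

#' 5x2 cross-validation of one or more trainers
#'
#' Dietterich's protocol: five replicates, each drawing a stratified
#' half/half split S1/S2 of the cases. Per replicate every trainer is
#' trained on S1 and evaluated (AUC) on both S1 and S2 (fold "A"), then
#' trained on S2 and evaluated on both halves (fold "B"), giving the
#' 20-value record of a [CVResult-class]. All trainers share the same
#' splits; results are deterministic under the seed.
#'
#' @param memory a labeled [CaseMemory-class], `n >= 4`, both classes with
#'   at least 2 cases each.
#' @param trainers named list of trainer functions (see [leaveOneOut()]).
#' @param seed RNG seed controlling the splits and any trainer randomness.
#' @return Named list of [CVResult-class], one per trainer.
#' @export
fiveByTwoCV <- function(memory, trainers, seed = 1L) {
  n <- nCases(memory)
  y <- caseLabels(memory)
  stopifnot(n >= 4, length(trainers) >= 1)
  if (min(table(y)) < 2L)
    stop("each class needs >= 2 cases for stratified 5x2 cross-validation")
  if (is.null(names(trainers)))
    names(trainers) <- paste0("method", seq_along(trainers))
  set.seed(seed)
  splits <- lapply(1:5, function(r) stratifiedHalves(y))
  fitSeeds <- deriveSeeds(seed + 1L, 5L * 2L * length(trainers))

  results <- vector("list", length(trainers))
  names(results) <- names(trainers)
  for (m in seq_along(trainers)) {
    auc <- array(NA_real_, c(5L, 2L, 2L),
                 dimnames = list(paste0("R", 1:5), c("A", "B"),
                                 c("S1", "S2")))
    for (r in 1:5) {
      s1 <- splits[[r]]
      s2 <- setdiff(seq_len(n), s1)
      halves <- list(S1 = s1, S2 = s2)
      for (f in 1:2) {                      # fold A trains on S1, B on S2
        trainIdx <- halves[[f]]
        set.seed(fitSeeds[(m - 1L) * 10L + (r - 1L) * 2L + f])
        cls <- trainers[[m]](subsetCases(memory, trainIdx))
        for (e in 1:2) {
          idx <- halves[[e]]
          auc[r, f, e] <- rocAuc(cls(subsetCases(memory, idx)), y[idx])
        }
      }
    }
    results[[m]] <- new("CVResult", method = names(trainers)[m],
                        auc = auc, seed = as.numeric(seed))
  }
  results
}

#' Test-fold AUC matrix of a CV record
#'
#' The held-out evaluations of a 5x2 record: fold A (trained on S1) scored
#' on S2, fold B (trained on S2) scored on S1.
#'
#' @param result a [CVResult-class].
#' @return 5 x 2 matrix, columns = folds (test side).
#' @export
testFoldAuc <- function(result) {
  cbind(fold1 = result@auc[, "A", "S2"], fold2 = result@auc[, "B", "S1"])
}

#' Flatten CV records into the 20-column report layout
#'
#' One row per method: columns `R1A.S1, R1A.S2, ..., R5B.S2` plus the mean
#' over the test-fold evaluations (`avg_test`).
#'
#' @param results list of [CVResult-class].
#' @return data.frame in the report layout.
#' @export
cvTable <- function(results) {
  rows <- lapply(results, function(res) {
    vals <- numeric(0)
    for (r in 1:5) for (f in c("A", "B")) for (e in c("S1", "S2")) {
      v <- res@auc[r, f, e]
      names(v) <- sprintf("R%d%s.%s", r, f, e)
      vals <- c(vals, v)
    }
    data.frame(method = res@method, t(vals), avg_test = mean(testFoldAuc(res)),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "CVResult", function(object) {
  cat("CVResult for", object@method, "(seed", object@seed, ")\n")
  cat("  mean test-fold AUC:",
      sprintf("%.4f", mean(testFoldAuc(object))), "\n")
})

#' Dietterich's 5x2cv paired t-test
#'
#' With `p_i^(j)` the test-fold AUC difference (method a minus method b) on
#' fold `j` of replicate `i`, per-replicate variance
#' `s_i^2 = (p_i^(1) - pbar_i)^2 + (p_i^(2) - pbar_i)^2`, the statistic is
#' `t = p_1^(1) / sqrt((1/5) * sum_i s_i^2)` with 5 degrees of freedom.
#' Only held-out (test-fold) evaluations enter. Identical records (all
#' `s_i^2 = 0` with zero numerator) raise a degenerate-statistic error
#' rather than returning NaN.
#'
#' @param resultA,resultB [CVResult-class] records computed on matched
#'   splits (same seed).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (orientation of method a versus method b).
#' @return list with `t`, `df = 5`, `p`.
#' @export
dietterichT <- function(resultA, resultB,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!isTRUE(all.equal(resultA@seed, resultB@seed)))
    stop("CV records must share the same splits (seeds differ)")
  d <- testFoldAuc(resultA) - testFoldAuc(resultB)
  pbar <- rowMeans(d)
  s2 <- (d[, 1] - pbar)^2 + (d[, 2] - pbar)^2
  denom <- sqrt(mean(s2))
  if (denom == 0)
    stop("degenerate 5x2cv statistic: zero variance across replicates")
  t <- d[1, 1] / denom
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df = 5),
    greater = stats::pt(t, df = 5, lower.tail = FALSE),
    less = stats::pt(t, df = 5))
  list(t = unname(t), df = 5L, p = unname(p))
}

#' Mann-Whitney U test with midrank ties
#'
#' Rank-sum U statistic for sample a versus sample b. For combined sizes
#' up to 12 the p-value is computed by exact enumeration of all
#' `choose(na + nb, na)` group assignments of the pooled values (valid
#' under ties); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return list with `U` (for sample a), `p`, and the `method` used
#'   ("exact" or "normal").
#' @export
mannWhitneyU <- function(a, b,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (na + nb <= 12L) {
    idx <- utils::combn(na + nb, na)
    Us <- apply(idx, 2L, function(ii) sum(r[ii])) - na * (na + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
      greater = mean(Us >= U - 1e-9),
      less = mean(Us <= U + 1e-9))
    return(list(U = unname(U), p = p, method = "exact"))
  }
  N <- na + nb
  ties <- table(pooled)
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {  # all values tied
    p <- if (alternative == "two.sided") 1 else 1
    return(list(U = unname(U), p = p, method = "normal"))
  }
  cc <- 0.5
  z <- switch(alternative,
    two.sided = (abs(U - mu) - cc) / sqrt(sigma2),
    greater = (U - mu - cc) / sqrt(sigma2),
    less = (mu - U - cc) / sqrt(sigma2))
  z <- max(z, 0)
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-z)
       else stats::pnorm(-z)
  list(U = unname(U), p = min(p, 1), method = "normal")
}

#' Pairwise method-comparison matrix
#'
#' Upper triangle: one-sided Mann-Whitney p-values over each method pair's
#' 20 AUC values; entry (r, c) tests the column method against the row
#' method, so a small p-value flags the column method's AUC as
#' significantly lower than the row method's (a large value means the
#' column method is at least as good). Lower triangle: one-sided
#' Dietterich 5x2cv t-test p-values with the same orientation -- entry
#' (r, c) is large when the row method's AUC exceeds the column method's.
#' Degenerate comparisons (zero-variance t statistic) are reported as NA.
#'
#' @param results named list of [CVResult-class] on matched splits.
#' @return list with `methods`, the p-value `matrix` (diagonal NA), and a
#'   logical `degenerate` matrix marking undefined t statistics.
#' @export
comparisonMatrix <- function(results) {
  stopifnot(length(results) >= 2)
  methods <- vapply(results, function(r) r@method, character(1))
  k <- length(results)
  M <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  deg <- matrix(FALSE, k, k, dimnames = list(methods, methods))
  for (r in seq_len(k)) for (c_ in seq_len(k)) {
    if (r == c_) next
    if (c_ > r) {
      # Mann-Whitney: alternative "column < row"
      M[r, c_] <- mannWhitneyU(as.vector(results[[c_]]@auc),
                               as.vector(results[[r]]@auc),
                               alternative = "less")$p
    } else {
      res <- tryCatch(
        dietterichT(results[[r]], results[[c_]], alternative = "less"),
        error = function(e) NULL)
      if (is.null(res)) deg[r, c_] <- TRUE else M[r, c_] <- res$p
    }
  }
  list(methods = methods, matrix = M, degenerate = deg)
}
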