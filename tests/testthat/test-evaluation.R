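test_that("AUC matches brute-force pair counting and the U statistic", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")

  s <- c(0.1, 0.4, 0.35, 0.8)
  l <- c(0, 0, 1, 1)
  expect_equal(rocAuc(s, l), oraclePairAuc(s, l))
  set.seed(14)
  for (i in 1:10) {
    s <- round(runif(30), 1)                 # coarse grid forces ties
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(rocAuc(s, l), oraclePairAuc(s, l), tolerance = 1e-12)
    # cross-module identity: AUC = U / (n1 * n0) with U for the positives
    u <- mannWhitneyU(s[l == 1], s[l == 0])$U
    expect_equal(rocAuc(s, l), u / (sum(l) * sum(1 - l)), tolerance = 1e-12)
  }
})

test_that("leave-one-out counts held-out hits fold by fold", {
  mem <- randomMemory(10, seed = 23)
  oracleTrainer <- function(tr) {
    function(q) caseLabels(q)                # cheats: reads the true label
  }
  expect_equal(leaveOneOut(mem, oracleTrainer)$accuracy, 1)

  # majority trainer on a 6-vs-4 memory: majority holdouts right (6),
  # minority wrong (4) -> accuracy 0.6, by enumeration of all 10 folds
  df <- data.frame(A = rep(c("no", "yes"), 5),
                   outcome = rep(c("failure", "success"), c(6, 4)))
  mem64 <- caseMemory(df, binarySchema("A"))
  majorityTrainer <- function(tr) {
    p <- mean(caseLabels(tr))
    function(q) rep(round(p), nCases(q))
  }
  res <- leaveOneOut(mem64, majorityTrainer)
  expect_equal(res$correct, 6L)
  expect_equal(res$accuracy, 0.6)

  # result invariant to case order
  set.seed(3)
  perm <- sample(10)
  expect_equal(leaveOneOut(subsetCases(mem64, perm), majorityTrainer)$accuracy,
               0.6)
  expect_error(leaveOneOut(mem64, function(tr) stop("boom")), "fold 1")
})

test_that("5x2 cross-validation partitions, stratifies and reproduces", {
  mem <- randomMemory(40, seed = 29)
  noiseTrainer <- function(tr) function(q) runif(nCases(q))
  res <- fiveByTwoCV(mem, list(noise = noiseTrainer), seed = 17)$noise
  expect_s4_class(res, "CVResult")
  expect_equal(dim(res@auc), c(5L, 2L, 2L))
  expect_equal(sum(!is.na(res@auc)), 20L)
  expect_true(all(res@auc >= 0 & res@auc <= 1))

  res2 <- fiveByTwoCV(mem, list(noise = noiseTrainer), seed = 17)$noise
  expect_identical(res@auc, res2@auc)        # same seed, same record

  tab <- cvTable(list(res))
  expect_equal(ncol(tab), 22L)               # method + 20 AUCs + test mean
  expect_equal(tab$avg_test, mean(testFoldAuc(res)))
})

test_that("the 5x2cv t statistic follows the hand formula", {
  # constant differences 0.2 / 0.0 across replicates: s_i^2 = 0.02,
  # t = 0.2 / sqrt(0.02)
  base <- array(0.7, c(5, 2, 2),
                dimnames = list(paste0("R", 1:5), c("A", "B"), c("S1", "S2")))
  shifted <- base
  shifted[, "A", "S2"] <- base[, "A", "S2"] + 0.2   # fold-1 test AUC higher
  a <- new("CVResult", method = "a", auc = shifted, seed = 1)
  b <- new("CVResult", method = "b", auc = base, seed = 1)
  res <- dietterichT(a, b)
  expect_equal(res$t, 0.2 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(res$df, 5L)
  expect_equal(res$p, 2 * stats::pt(-0.2 / sqrt(0.02), 5), tolerance = 1e-12)

  # scale invariance of the ratio
  scaled <- base
  scaled[, "A", "S2"] <- base[, "A", "S2"] + 0.05
  a2 <- new("CVResult", method = "a2", auc = scaled, seed = 1)
  expect_equal(dietterichT(a2, b)$t, res$t, tolerance = 1e-12)

  # identical records: zero variance is an error, not NaN
  expect_error(dietterichT(b, b), "zero variance")
  bb <- b; bb@seed <- 2
  expect_error(dietterichT(a, bb), "seeds differ")
})

test_that("Mann-Whitney p-values agree with exact enumeration and wilcox.test", {
  # complete separation
  sep <- mannWhitneyU(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$U, 9)                     # n_a * n_b
  expect_equal(sep$p, 2 / choose(6, 3), tolerance = 1e-12)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$U, 0)

  # identical samples: no evidence
  expect_gte(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 0.99)

  # small-sample branch matches wilcox.test exact p (tie-free data)
  set.seed(37)
  for (i in 1:5) {
    a <- runif(5); b <- runif(6)
    mine <- mannWhitneyU(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # large-sample branch matches wilcox.test normal approximation with ties
  for (i in 1:5) {
    a <- sample(seq(0, 1, 0.1), 15, TRUE)
    b <- sample(seq(0, 1, 0.1), 18, TRUE)
    mine <- mannWhitneyU(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$method, "normal")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the comparison matrix carries both tests in the right orientation", {
  # method `hi` dominates `lo` on every one of the 20 AUCs
  mkRes <- function(vals, id) {
    new("CVResult", method = id,
        auc = array(vals, c(5, 2, 2),
                    dimnames = list(paste0("R", 1:5), c("A", "B"),
                                    c("S1", "S2"))),
        seed = 1)
  }
  set.seed(41)
  hi <- mkRes(runif(20, 0.8, 0.95), "hi")
  lo <- mkRes(runif(20, 0.5, 0.7), "lo")
  cmp <- comparisonMatrix(list(hi = hi, lo = lo))
  expect_true(all(is.na(diag(cmp$matrix))))
  # upper triangle, row hi / col lo: column dominated -> small p
  expect_lt(cmp$matrix["hi", "lo"], 0.05)
  # lower triangle, row lo / col hi: row dominated -> small p
  expect_lt(cmp$matrix["lo", "hi"], 0.05)

  # two identical records: Mann-Whitney non-significant, t degenerate
  cmp2 <- comparisonMatrix(list(a = mkRes(rep(0.8, 20), "a"),
                                b = mkRes(rep(0.8, 20), "b")))
  expect_gt(cmp2$matrix["a", "b"], 0.4)
  expect_true(cmp2$degenerate["b", "a"])
})
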