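test_that("contingency tables count cases and prune empty levels", {
  sch <- binarySchema("A")
  mem <- caseMemory(data.frame(A = c("no", "no", "yes", "yes"),
                               outcome = c("success", "failure",
                                           "success", "failure")), sch)
  tab <- contingencyTable(mem, "A")
  expect_equal(unname(tab), matrix(1L, 2, 2))
  expect_equal(sum(tab), nCases(mem))

  # declared-but-unobserved level is pruned with a warning
  sch3 <- list(list(name = "A", categories = c("low", "mid", "high"),
                    role = "input"),
               list(name = "outcome", categories = c("success", "failure"),
                    role = "target"))
  mem3 <- caseMemory(data.frame(A = c("low", "high", "low", "high"),
                                outcome = c("success", "failure",
                                            "failure", "success")), sch3)
  expect_warning(tab3 <- contingencyTable(mem3, "A"), "pruned")
  expect_equal(rownames(tab3), c("low", "high"))
  expect_error(contingencyTable(mem, "outcome"), "differ")
})

test_that("chi-square statistics match hand computation, with and without Yates", {
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  plain <- chiSquareTest(tab, "none")
  # n(ad - bc)^2 / (r1 r2 c1 c2) = 80 * 800^2 / 40^4 = 20
  expect_equal(plain$statistic, 20, tolerance = 1e-12)
  expect_equal(plain$df, 1)
  yates <- chiSquareTest(tab, "yates")
  # 80 * (|800| - 40)^2 / 40^4 = 18.05
  expect_equal(yates$statistic, 18.05, tolerance = 1e-12)

  # proportional rows: exact independence
  ind <- chiSquareTest(matrix(c(20, 10, 40, 20), 2, byrow = TRUE), "none")
  expect_equal(ind$statistic, 0, tolerance = 1e-12)
  expect_equal(ind$p, 1, tolerance = 1e-9)

  expect_error(chiSquareTest(matrix(1:3, 1)), "degenerate")
  expect_error(chiSquareTest(matrix(1:6, 2), "yates"), "2x2")
})

test_that("Monte-Carlo p-values are seeded multiples of 1/(B+1) with the right floor", {
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  B <- 500
  p1 <- chiSquareMonteCarlo(tab, B, seed = 11)
  expect_identical(p1, chiSquareMonteCarlo(tab, B, seed = 11))
  expect_equal(p1 * (B + 1), round(p1 * (B + 1)), tolerance = 1e-9)
  expect_gte(p1, 1 / (B + 1))

  # zero statistic: every simulated table ties or exceeds -> p = 1
  flat <- matrix(c(20, 20, 20, 20), 2)
  expect_equal(chiSquareMonteCarlo(flat, 200, seed = 3), 1)

  # asymptotic consistency at large counts
  big <- matrix(c(60, 20, 20, 60), 2, byrow = TRUE)
  pAsym <- chiSquareTest(big, "none")$p
  pMC <- chiSquareMonteCarlo(big, 2000, seed = 5)
  se <- sqrt(pAsym * (1 - pAsym) / 2000)
  expect_lt(abs(pMC - pAsym), 3 * se + 1 / 2001)
})

test_that("Fisher's exact test enumerates the 2x2 null exactly", {
  # [[3,1],[1,3]]: two-sided p = 34/70 by hypergeometric enumeration
  expect_equal(fisherExact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  # all-zero row prunes to a degenerate table -> p = 1
  degenerate <- matrix(c(0, 0, 5, 3), 2, byrow = TRUE)
  expect_equal(fisherExact(degenerate), 1)
  # r x c branch is seeded Monte Carlo
  tab3 <- matrix(c(8, 2, 1, 3, 4, 6), 3, byrow = TRUE)
  p1 <- fisherExact(tab3, mcReplicates = 1000, seed = 9)
  expect_identical(p1, fisherExact(tab3, mcReplicates = 1000, seed = 9))
  expect_equal(p1 * 1001, round(p1 * 1001), tolerance = 1e-9)
})

test_that("battery p-values are invariant to case order", {
  mem <- randomMemory(80, seed = 55)
  rep1 <- relevantVariables(mem, seed = 2)
  set.seed(77)
  rep2 <- relevantVariables(subsetCases(mem, sample(nCases(mem))), seed = 2)
  expect_equal(rep1$p_yates, rep2$p_yates)
  expect_equal(rep1$p_monte_carlo, rep2$p_monte_carlo)
  expect_equal(rep1$p_fisher, rep2$p_fisher)
})

test_that("the relevance report flags planted signal and spares noise", {
  # one variable deterministically equal to the target, others independent
  set.seed(61)
  n <- 500
  o <- sample(c("success", "failure"), n, TRUE)
  df <- data.frame(A = ifelse(o == "failure", "yes", "no"),
                   B = sample(c("no", "yes"), n, TRUE),
                   C = sample(paste0("c", 1:3), n, TRUE),
                   outcome = o)
  sch <- list(list(name = "A", categories = c("no", "yes"), role = "input"),
              list(name = "B", categories = c("no", "yes"), role = "input"),
              list(name = "C", categories = paste0("c", 1:3), role = "input"),
              list(name = "outcome", categories = c("success", "failure"),
                   role = "target"))
  mem <- caseMemory(df, sch)
  B <- 2000
  rep <- relevantVariables(mem, mcReplicates = B, seed = 12)
  expect_equal(nrow(rep), 3L)                     # one row per input variable
  expect_equal(rep$variable, c("A", "B", "C"))
  a <- rep[rep$variable == "A", ]
  expect_true(a$selected)
  expect_equal(a$p_monte_carlo, 1 / (B + 1))     # attainable floor
  expect_equal(a$p_fisher, stats::fisher.test(table(df$A, df$outcome))$p.value)
  expect_false(rep[rep$variable == "B", "selected"])
  expect_false(rep[rep$variable == "C", "selected"])

  # "all" mode is at least as strict as "any"
  repAll <- relevantVariables(mem, mcReplicates = B, seed = 12, mode = "all")
  expect_true(all(repAll$selected <= rep$selected))
})

test_that("a constant variable yields uninformative unit p-values", {
  sch <- binarySchema(c("A", "K"))
  df <- data.frame(A = rep(c("no", "yes"), 10),
                   K = rep("yes", 20),
                   outcome = rep(c("success", "failure"), 10))
  mem <- caseMemory(df, sch)
  rep <- suppressWarnings(relevantVariables(mem, seed = 1))
  k <- rep[rep$variable == "K", ]
  expect_equal(unlist(k[, c("p_yates", "p_monte_carlo", "p_fisher")]),
               c(p_yates = 1, p_monte_carlo = 1, p_fisher = 1))
  expect_false(k$selected)
})
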