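test_that("node quality matches the Bayesian-Dirichlet closed form", {
  sch <- binarySchema("A")
  df <- data.frame(A = c("no", "no", "yes", "yes"),
                   outcome = c("success", "failure", "success", "failure"))
  mem <- caseMemory(df, sch)
  # counts (2,2), no parents: log[1! * 2! * 2! / 5!] = log(1/30)
  expect_equal(scoreNode(mem, "A")$value, log(1 / 30), tolerance = 1e-12)
  expect_error(scoreNode(mem, "A", "A"), "itself")
})

test_that("node scores are invariant to row order and reward true parents", {
  mem <- randomMemory(200, seed = 11)
  s1 <- scoreNode(mem, "B", c("A", "C"))$value
  set.seed(42)
  shuffled <- subsetCases(mem, sample(nCases(mem)))
  expect_equal(scoreNode(shuffled, "B", c("A", "C"))$value, s1)

  # a node that copies its parent scores higher with that parent
  set.seed(5)
  a <- sample(c("no", "yes"), 500, TRUE)
  df <- data.frame(A = a, B = a,
                   outcome = sample(c("success", "failure"), 500, TRUE))
  sch <- binarySchema(c("A", "B"))
  memCopy <- caseMemory(df, sch)
  expect_gt(scoreNode(memCopy, "B", "A")$value,
            scoreNode(memCopy, "B")$value)
})

test_that("the structure score decomposes over nodes", {
  mem <- randomMemory(100, arities = c(A = 2, B = 3, C = 2, D = 4), seed = 2)
  parents <- list(A = character(0), B = "A", C = c("A", "B"),
                  D = "outcome", outcome = character(0))
  total <- structureScore(mem, parents)
  byNode <- sum(vapply(names(parents), function(v)
    scoreNode(mem, v, parents[[v]])$value, numeric(1)))
  expect_equal(total, byNode, tolerance = 1e-12)
})

test_that("tabu search attains the exhaustive optimum on 3-node problems", {
  # planted chain A -> B -> outcome with strong CPTs
  set.seed(21)
  n <- 1000
  a <- sample(c("no", "yes"), n, TRUE)
  b <- ifelse(runif(n) < 0.85, a, sample(c("no", "yes"), n, TRUE))
  o <- ifelse(runif(n) < 0.85, ifelse(b == "yes", "failure", "success"),
              sample(c("success", "failure"), n, TRUE))
  mem <- caseMemory(data.frame(A = a, B = b, outcome = o),
                    binarySchema(c("A", "B")))
  found <- tabuSearchStructure(mem, tabuConfig(seed = 1))
  bestExhaustive <- max(vapply(oracleAllDags(variableNames(mem)),
                               function(p) structureScore(mem, p),
                               numeric(1)))
  expect_equal(structureScore(mem, found), bestExhaustive, tolerance = 1e-9)

  # the same optimality holds on unstructured data
  memNull <- randomMemory(300, arities = c(A = 2, B = 3), seed = 33)
  foundNull <- tabuSearchStructure(memNull, tabuConfig(seed = 1))
  bestNull <- max(vapply(oracleAllDags(variableNames(memNull)),
                         function(p) structureScore(memNull, p), numeric(1)))
  expect_equal(structureScore(memNull, foundNull), bestNull, tolerance = 1e-9)
})

test_that("tabu search returns the empty graph on independent variables", {
  # 4 mutually independent variables; the oracle first confirms that the
  # empty graph is score-optimal among all 543 4-node DAGs on this sample
  mem <- randomMemory(1000, arities = c(A = 2, B = 2, C = 2), seed = 9)
  allScores <- vapply(oracleAllDags(variableNames(mem)),
                      function(p) structureScore(mem, p), numeric(1))
  empty <- stats::setNames(lapply(variableNames(mem), function(v) character(0)),
                           variableNames(mem))
  expect_equal(max(allScores), structureScore(mem, empty), tolerance = 1e-9)
  found <- tabuSearchStructure(mem, tabuConfig(seed = 1))
  expect_equal(sum(lengths(found)), 0L)
  # and never scores below the empty graph on arbitrary data
  for (s in 1:5) {
    m2 <- randomMemory(60, arities = c(A = 2, B = 3, C = 2), seed = 100 + s)
    found2 <- tabuSearchStructure(m2, tabuConfig(seed = 1))
    empty <- stats::setNames(lapply(variableNames(m2),
                                    function(v) character(0)),
                             variableNames(m2))
    expect_gte(structureScore(m2, found2), structureScore(m2, empty) - 1e-9)
  }
})

test_that("independence-test method selection follows the 80% expected-count rule", {
  sch <- binarySchema(c("A", "B"))
  # balanced 2x2 with all expected counts 20: chi-square branch, stat 20
  df <- data.frame(
    A = rep(c("no", "yes"), c(40, 40)),
    B = rep(c("no", "yes", "no", "yes"), c(30, 10, 10, 30)),
    outcome = rep(c("success", "failure"), 40))
  mem <- caseMemory(df, sch)
  res <- ciTest(mem, "A", "B")
  expect_equal(res$method, "chi_square")
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # n = 12: most expected counts < 5 -> Fisher branch
  df2 <- data.frame(
    A = rep(c("no", "yes"), c(6, 6)),
    B = rep(c("no", "yes", "no", "yes"), c(4, 2, 2, 4)),
    outcome = rep(c("success", "failure"), 6))
  res2 <- ciTest(caseMemory(df2, sch), "A", "B")
  expect_equal(res2$method, "fisher")

  # identical rows: exact independence, statistic 0, p = 1
  df3 <- data.frame(
    A = rep(c("no", "yes"), c(40, 40)),
    B = rep(c("no", "yes"), 40),
    outcome = rep(c("success", "failure"), 40))
  res3 <- ciTest(caseMemory(df3, sch), "A", "B")
  expect_equal(res3$statistic, 0, tolerance = 1e-12)
  expect_equal(res3$p, 1, tolerance = 1e-9)
})

test_that("conditional tests stratify and stay deterministic under seed", {
  set.seed(13)
  n <- 300
  c_ <- sample(c("no", "yes"), n, TRUE)
  a <- ifelse(runif(n) < 0.8, c_, sample(c("no", "yes"), n, TRUE))
  b <- ifelse(runif(n) < 0.8, c_, sample(c("no", "yes"), n, TRUE))
  mem <- caseMemory(data.frame(A = a, B = b, C = c_,
                               outcome = sample(c("success", "failure"), n, TRUE)),
                    binarySchema(c("A", "B", "C")))
  # A and B are dependent marginally but independent given C
  marg <- ciTest(mem, "A", "B")
  cond <- ciTest(mem, "A", "B", "C", seed = 7)
  expect_lt(marg$p, 0.01)
  expect_gt(cond$p, 0.01)
  expect_identical(cond, ciTest(mem, "A", "B", "C", seed = 7))
})

test_that("constraint-based search recovers colliders and prunes independence", {
  # AND-gate collider: C depends on each parent marginally, A and B are
  # independent until conditioned on C
  set.seed(31)
  n <- 2000
  a <- sample(c("no", "yes"), n, TRUE)
  b <- sample(c("no", "yes"), n, TRUE)
  coll <- ifelse(a == "yes" & b == "yes", "yes", "no")
  coll <- ifelse(runif(n) < 0.85, coll, sample(c("no", "yes"), n, TRUE))
  mem <- caseMemory(data.frame(A = a, B = b, C = coll,
                               outcome = sample(c("success", "failure"), n, TRUE)),
                    binarySchema(c("A", "B", "C")))
  st <- ciSearchStructure(mem, ciConfig(seed = 3))
  expect_setequal(sort(st$C), c("A", "B"))      # collider orientation
  expect_length(st$A, 0)
  expect_length(st$B, 0)

  # independent variables -> empty structure
  memInd <- randomMemory(2000, arities = c(A = 2, B = 3), seed = 17)
  stInd <- ciSearchStructure(memInd, ciConfig(seed = 3))
  expect_equal(sum(lengths(stInd)), 0L)
})

test_that("CPT fitting applies Laplace smoothing and handles unseen strata", {
  sch <- binarySchema("A")
  mem <- caseMemory(data.frame(A = c("no", "no", "no", "yes"),
                               outcome = c("success", "success", "failure",
                                           "failure")),
                    sch)
  noParents <- list(A = character(0), outcome = character(0))
  m1 <- fitCPTs(mem, noParents, smoothing = 1)
  expect_equal(unname(m1@cpts$A[, 1]), c(4 / 6, 2 / 6))
  m0 <- fitCPTs(mem, noParents, smoothing = 0)
  expect_equal(unname(m0@cpts$A[, 1]), c(3 / 4, 1 / 4))

  # parent configuration never observed: uniform column under smoothing
  withPa <- list(A = character(0), outcome = "A")
  mem2 <- caseMemory(data.frame(A = c("no", "no"),
                                outcome = c("success", "failure")), sch)
  m2 <- fitCPTs(mem2, withPa, smoothing = 1)
  expect_equal(unname(m2@cpts$outcome[, 2]), c(0.5, 0.5))
  # columns always sum to 1 (validity enforces it too)
  for (v in names(m2@cpts))
    expect_equal(unname(colSums(m2@cpts[[v]])), rep(1, ncol(m2@cpts[[v]])))
})

test_that("posterior inference equals full-joint enumeration", {
  # property over random small networks (binary/ternary nodes)
  set.seed(99)
  for (s in 1:20) {
    nv <- sample(2:5, 1)
    arities <- stats::setNames(sample(2:3, nv, TRUE),
                               paste0(LETTERS[seq_len(nv)]))
    cfg <- syntheticConfig(nCases = 40, nVariables = nv,
                           arities = arities,
                           nNoiseVariables = sample(0:(nv - 1), 1),
                           maxParents = 2, effectStrength = 0.2,
                           targetPrevalence = 0.5, seed = 500 + s)
    gt <- generateGroundTruth(cfg)
    mem <- sampleCases(gt, 40, seed = 600 + s)
    st <- stats::setNames(lapply(gt@nodes, function(v) gt@parents[[v]]),
                          gt@nodes)
    model <- fitCPTs(mem, st, smoothing = 1)
    post <- predictPosteriors(model, mem)
    for (i in c(1L, 7L, 23L)) {
      expect_equal(post[i], oracleJointPosterior(model, mem, i),
                   tolerance = 1e-10)
    }
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("a target with no neighbours gets its smoothed prior as posterior", {
  mem <- randomMemory(50, seed = 19)
  empty <- stats::setNames(lapply(variableNames(mem), function(v) character(0)),
                           variableNames(mem))
  model <- fitCPTs(mem, empty, smoothing = 1)
  npos <- sum(caseLabels(mem))
  prior <- (npos + 1) / (nCases(mem) + 2)
  expect_equal(unique(round(predictPosteriors(model, mem), 12)),
               round(prior, 12))
})

test_that("tabu search recovers most skeleton edges at large n", {
  hits <- numeric(5)
  for (s in 1:5) {
    cfg <- syntheticConfig(nCases = 5000, nVariables = 5,
                           nNoiseVariables = 0, maxParents = 2,
                           effectStrength = 0.25, seed = 700 + s)
    gt <- generateGroundTruth(cfg)
    mem <- sampleCases(gt, 5000, seed = 800 + s)
    st <- tabuSearchStructure(mem, tabuConfig(seed = 1))
    true <- skeletonOf(gt@parents)
    hits[s] <- mean(true %in% skeletonOf(st))
  }
  expect_gte(mean(hits), 0.8)
})
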