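# Independent oracles used to freeze expected values. Each takes a path
# through the problem that does not share code with the implementation it
# checks: exhaustive enumeration, brute-force pair counting, full-joint
# summation, and generic numeric optimisation.

# All DAGs on a small node set, as parents lists (25 DAGs for 3 nodes).
oracleAllDags <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  out <- list()
  states <- expand.grid(rep(list(0:2), nrow(pairs)))  # 0 none, 1 a->b, 2 b->a
  for (i in seq_len(nrow(states))) {
    parents <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
    for (j in seq_len(nrow(pairs))) {
      s <- states[i, j]
      if (s == 1) parents[[pairs[j, 2]]] <- c(parents[[pairs[j, 2]]], pairs[j, 1])
      if (s == 2) parents[[pairs[j, 1]]] <- c(parents[[pairs[j, 1]]], pairs[j, 2])
    }
    if (length(retreatCBR:::dagTopoOrder(parents)) == length(nodes))
      out[[length(out) + 1L]] <- parents
  }
  out
}

# Posterior of the positive target class by brute-force summation of the
# full joint over ALL variables (not just the Markov blanket).
oracleJointPosterior <- function(model, memory, row) {
  df <- caseData(memory)
  target <- targetVariable(memory)
  arity <- vapply(model@levels, length, integer(1))
  jointOf <- function(codes) {
    lp <- 0
    for (v in model@nodes) {
      cpt <- model@cpts[[v]]
      pa <- attr(cpt, "parents")
      idx <- 1L; stride <- 1L
      for (p in pa) {
        idx <- idx + (codes[[p]] - 1L) * stride
        stride <- stride * arity[[p]]
      }
      lp <- lp + log(cpt[codes[[v]], idx])
    }
    exp(lp)
  }
  codes <- lapply(model@nodes, function(v)
    match(as.character(df[[v]][row]), model@levels[[v]]))
  names(codes) <- model@nodes
  pr <- numeric(arity[[target]])
  for (t in seq_len(arity[[target]])) {
    codes[[target]] <- t
    pr[t] <- jointOf(codes)
  }
  posIdx <- match(targetPositive(memory), model@levels[[target]])
  pr[posIdx] / sum(pr)
}

# Constrained minimiser of the asymmetric mixture loss by generic numeric
# optimisation: parameterise alpha = (free..., 1 - sum(free)) and run BFGS
# from several starts.
oracleMixtureSolve <- function(x, y, k) {
  x <- rbind(x)
  m <- nrow(x)
  obj <- function(free) {
    a <- c(free, 1 - sum(free))
    r <- drop(crossprod(x, a)) - y
    sum((1 + k * y) * r^2)
  }
  if (m == 1L) return(list(alpha = 1, objective = obj(numeric(0))))
  starts <- list(rep(1 / m, m - 1L), rep(0, m - 1L), rep(1, m - 1L))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$objective)
      best <- list(alpha = c(fit$par, 1 - sum(fit$par)),
                   objective = fit$value)
  }
  best
}

# AUC by exhaustive positive/negative pair counting (ties count 1/2).
oraclePairAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random seeded mixture instances shared by oracle-equivalence tests
randomMixtureInstance <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1)
  n <- sample(5:50, 1)
  x <- matrix(stats::runif(m * n), m, n)
  y <- stats::rbinom(n, 1, 0.5)
  if (all(y == 0)) y[1] <- 1
  if (all(y == 1)) y[1] <- 0
  list(x = x, y = y)
}
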