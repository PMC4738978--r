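# Discrete Bayesian-network learning: K2-style Bayesian-Dirichlet scoring,
# score-based tabu search, conditional-independence (constraint-based)
# search, CPT estimation and exact posterior inference for the target.

#' Tabu-search configuration
#'
#' @param tabuListLength number of most recent moves kept tabu.
#' @param maxIterations number of consecutive non-improving moves after
#'   which the search stops.
#' @param maxParents cap on parent-set size; with a clinic-scale memory
#'   (~200 cases) parent sets beyond 3 leave CPT strata too sparse to
#'   estimate.
#' @param seed RNG seed (tabu search itself is deterministic; the seed is
#'   recorded for provenance and used for any tie randomisation downstream).
#' @return A validated list of class `tabuConfig`.
#' @export
tabuConfig <- function(tabuListLength = 10L, maxIterations = 100L,
                       maxParents = 3L, seed = 1L) {
  stopifnot(tabuListLength >= 1, maxIterations >= 1, maxParents >= 1)
  structure(list(tabuListLength = as.integer(tabuListLength),
                 maxIterations = as.integer(maxIterations),
                 maxParents = as.integer(maxParents),
                 seed = as.integer(seed)),
            class = "tabuConfig")
}

#' Conditional-independence search configuration
#'
#' @param alpha significance level of the independence tests in (0,1);
#'   an edge survives only if no tested conditioning set yields p >= alpha.
#' @param maxConditioningSize largest conditioning-set size tried. Default
#'   1: with ~200 cases and up to 5-category variables, strata defined by
#'   two or more conditioning variables are too sparse for valid
#'   contingency tests.
#' @param mcReplicates Monte-Carlo replicates for the stratified
#'   small-count branch of [ciTest()].
#' @param maxParents cap on parent-set size after orientation; nodes over
#'   the cap keep the parents with the strongest marginal association
#'   (smallest unconditional test p-value). Keeps CPTs estimable from a
#'   clinic-scale memory.
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return A validated list of class `ciConfig`.
#' @export
ciConfig <- function(alpha = 0.05, maxConditioningSize = 1L,
                     mcReplicates = 400L, maxParents = 3L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, maxConditioningSize >= 0,
            mcReplicates >= 1, maxParents >= 1)
  structure(list(alpha = alpha,
                 maxConditioningSize = as.integer(maxConditioningSize),
                 mcReplicates = as.integer(mcReplicates),
                 maxParents = as.integer(maxParents),
                 seed = as.integer(seed)),
            class = "ciConfig")
}

# ---- scoring ---------------------------------------------------------------

scoreNodeCodes <- function(codes, arity, node, parents) {
  y <- codes[, node]
  r <- arity[[node]]
  n <- length(y)
  if (!length(parents)) {
    Nk <- tabulate(y, r)
    return(lgamma(r) - lgamma(n + r) + sum(lgamma(Nk + 1)))
  }
  cfg <- configIndex(codes, parents, arity)
  q <- prod(arity[parents])
  cnt <- tabulate((cfg - 1L) * r + y, r * q)
  dim(cnt) <- c(r, q)
  Nj <- colSums(cnt)
  sum(lgamma(r) - lgamma(Nj + r)) + sum(lgamma(cnt + 1))
}

#' Score one node given a candidate parent set
#'
#' The node-quality function is the K2-style Bayesian-Dirichlet log
#' marginal likelihood with a uniform (all-ones) Dirichlet prior:
#' `sum_j [ log (r-1)! - log (N_j + r - 1)! + sum_k log N_jk! ]`, where `r`
#' is the node's category count, `j` ranges over parent configurations,
#' `N_jk` counts cases with node category `k` under configuration `j`, and
#' `N_j = sum_k N_jk`. It is decomposable, so a structure's score is the
#' sum of its node scores, and it is invariant to the row order of the
#' memory.
#'
#' @param memory a [CaseMemory-class].
#' @param node node name.
#' @param parents character vector of parent names (may be empty).
#' @return list with `node`, `parents`, and the log-score `value`.
#' @export
scoreNode <- function(memory, node, parents = character(0)) {
  if (node %in% parents) stop("parent set must not contain the node itself")
  stopifnot(nCases(memory) >= 1,
            all(c(node, parents) %in% variableNames(memory)))
  mc <- memoryCodes(memory)
  list(node = node, parents = parents,
       value = scoreNodeCodes(mc$codes, mc$arity, node, parents))
}

#' Total decomposable score of a structure
#'
#' @param memory a [CaseMemory-class].
#' @param parents named list mapping each node to its parents.
#' @return Sum of the per-node K2 log scores.
#' @export
structureScore <- function(memory, parents) {
  mc <- memoryCodes(memory)
  sum(vapply(names(parents),
             function(v) scoreNodeCodes(mc$codes, mc$arity, v, parents[[v]]),
             numeric(1)))
}

# ---- tabu search -----------------------------------------------------------

#' Learn a DAG by score-based tabu search
#'
#' Local search over single-edge moves (add / delete / reverse) under the
#' decomposable K2 score. Each step applies the best candidate move that is
#' not tabu; a move undoing one of the `tabuListLength` most recent moves
#' is forbidden unless it improves on the best structure found so far
#' (aspiration). The search stops after `maxIterations` consecutive
#' non-improving steps and returns the parent sets of the best structure
#' visited, which is never worse than the empty graph it starts from.
#'
#' @param memory a [CaseMemory-class] with >= 2 variables and >= 1 case.
#' @param config a [tabuConfig()].
#' @return Named list of parent sets (one entry per variable), acyclic,
#'   parent-set sizes capped at `config$maxParents`.
#' @export
tabuSearchStructure <- function(memory, config = tabuConfig()) {
  vars <- variableNames(memory)
  p <- length(vars)
  stopifnot(p >= 2, nCases(memory) >= 1)
  mc <- memoryCodes(memory)
  codes <- mc$codes; arity <- mc$arity

  cache <- new.env(parent = emptyenv())
  nodeScoreIdx <- function(v, pa) {           # v, pa are integer indices
    key <- paste0(v, "|", paste(sort.int(pa), collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    s <- scoreNodeCodes(codes, arity, v, pa)
    cache[[key]] <- s
    s
  }

  # state: adjacency (adj[u, v] TRUE for edge u -> v), parent index lists,
  # per-node scores, and the transitive closure D (D[u, v]: path u ~> v)
  adj <- matrix(FALSE, p, p)
  parentsIdx <- lapply(seq_len(p), function(v) integer(0))
  scores <- vapply(seq_len(p), function(v) nodeScoreIdx(v, integer(0)),
                   numeric(1))
  total <- sum(scores)
  best <- list(parents = parentsIdx, total = total)
  tabu <- character(0)
  closure <- function(adj) {
    D <- adj
    repeat {
      D2 <- D | (D %*% D > 0)
      if (identical(D2, D)) return(D)
      D <- D2
    }
  }
  D <- closure(adj)

  moveKey <- function(type, u, v) paste(type, u, v, sep = "|")
  inverseKey <- function(type, u, v) switch(type,
    add = moveKey("delete", u, v),
    delete = moveKey("add", u, v),
    reverse = moveKey("reverse", v, u))
  nParents <- lengths(parentsIdx)

  nonImproving <- 0L
  repeat {
    # candidate moves as (type, u, v, delta); deltas from the score cache
    bestMove <- NULL; bestDelta <- -Inf
    consider <- function(type, u, v, delta) {
      # tabu unless aspiration: the move would beat the best total found
      if ((moveKey(type, u, v) %in% tabu) &&
          !(total + delta > best$total + 1e-12)) return()
      if (is.null(bestMove) || delta > bestDelta + 1e-12) {
        bestMove <<- list(type = type, u = u, v = v, delta = delta)
        bestDelta <<- delta
      }
    }
    for (v in seq_len(p)) {
      pa <- parentsIdx[[v]]
      for (u in pa) {
        newPa <- pa[pa != u]
        dDel <- nodeScoreIdx(v, newPa) - scores[v]
        consider("delete", u, v, dDel)
        # reverse u -> v: cycle iff u reaches v via some other child
        if (nParents[u] < config$maxParents) {
          others <- which(adj[u, ]); others <- others[others != v]
          if (!any(D[others, v])) {
            dRev <- dDel + nodeScoreIdx(u, c(parentsIdx[[u]], v)) - scores[u]
            consider("reverse", u, v, dRev)
          }
        }
      }
      if (nParents[v] < config$maxParents) {
        candAdd <- which(!adj[, v] & !adj[v, ] & !D[v, ])  # no edge, no cycle
        candAdd <- candAdd[candAdd != v]
        for (u in candAdd)
          consider("add", u, v, nodeScoreIdx(v, c(pa, u)) - scores[v])
      }
    }
    if (is.null(bestMove)) break

    u <- bestMove$u; v <- bestMove$v
    switch(bestMove$type,
      add = { parentsIdx[[v]] <- c(parentsIdx[[v]], u); adj[u, v] <- TRUE },
      delete = { parentsIdx[[v]] <- setdiff(parentsIdx[[v]], u)
                 adj[u, v] <- FALSE },
      reverse = {
        parentsIdx[[v]] <- setdiff(parentsIdx[[v]], u)
        parentsIdx[[u]] <- c(parentsIdx[[u]], v)
        adj[u, v] <- FALSE; adj[v, u] <- TRUE
      })
    nParents <- lengths(parentsIdx)
    scores[v] <- nodeScoreIdx(v, parentsIdx[[v]])
    if (bestMove$type == "reverse")
      scores[u] <- nodeScoreIdx(u, parentsIdx[[u]])
    total <- sum(scores)
    D <- closure(adj)
    tabu <- c(inverseKey(bestMove$type, u, v), tabu)
    if (length(tabu) > config$tabuListLength)
      tabu <- tabu[seq_len(config$tabuListLength)]

    if (total > best$total + 1e-12) {
      best <- list(parents = parentsIdx, total = total)
      nonImproving <- 0L
    } else {
      nonImproving <- nonImproving + 1L
      if (nonImproving >= config$maxIterations) break
    }
  }
  stats::setNames(lapply(best$parents, function(pa) vars[pa]), vars)
}

# ---- conditional-independence testing and search ---------------------------

#' Conditional-independence test between two categorical variables
#'
#' Builds the contingency table of `a` versus `b`, stratified by every
#' observed configuration of the conditioning variables. The method is a
#' pure function of the expected-count matrix: when at least 80% of the
#' expected cell counts (pooled over strata) exceed 5, a Pearson chi-square
#' test is used (per-stratum statistics and degrees of freedom are summed);
#' otherwise an exact-style small-sample branch fires -- Fisher's exact
#' test for an unconditional table, or a seeded Monte-Carlo test of the
#' summed chi-square statistic under the stratified fixed-margins null.
#'
#' @param memory a [CaseMemory-class].
#' @param a,b distinct variable names, neither in `given`.
#' @param given character vector of conditioning variable names.
#' @param mcReplicates Monte-Carlo replicates for the small-count branch.
#' @param seed optional seed for the Monte-Carlo draws; `NULL` uses the
#'   current RNG stream.
#' @return list with `method` ("chi_square" or "fisher"), `statistic`
#'   (summed Pearson statistic; NA for the unconditional exact branch),
#'   `df`, and `p`.
#' @export
ciTest <- function(memory, a, b, given = character(0),
                   mcReplicates = 400L, seed = NULL) {
  stopifnot(a != b, !(a %in% given), !(b %in% given))
  df <- caseData(memory)
  strata <- if (length(given)) interaction(df[given], drop = TRUE)
            else factor(rep.int(1L, nrow(df)))
  tables <- list()
  for (s in levels(strata)) {
    idx <- strata == s
    if (!any(idx)) next
    tab <- table(droplevels(df[[a]][idx]), droplevels(df[[b]][idx]))
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      warning("stratum '", s, "' degenerate for ", a, " vs ", b, "; skipped")
      next
    }
    tables[[length(tables) + 1L]] <- tab
  }
  if (!length(tables)) stop("all strata empty or degenerate for ", a, " vs ", b)

  expected <- unlist(lapply(tables, function(tab)
    outer(rowSums(tab), colSums(tab)) / sum(tab)))
  useChi <- mean(expected > 5) >= 0.8

  pearson <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  statObs <- sum(vapply(tables, pearson, numeric(1)))
  dfTot <- sum(vapply(tables, function(tab)
    (nrow(tab) - 1L) * (ncol(tab) - 1L), numeric(1)))

  if (useChi) {
    return(list(method = "chi_square", statistic = statObs, df = dfTot,
                p = stats::pchisq(statObs, dfTot, lower.tail = FALSE)))
  }
  if (!length(given) && length(tables) == 1L) {
    tab <- tables[[1L]]
    p <- if (nrow(tab) == 2L && ncol(tab) == 2L)
      stats::fisher.test(tab)$p.value
    else {
      if (!is.null(seed)) set.seed(seed)
      stats::fisher.test(tab, simulate.p.value = TRUE, B = mcReplicates)$p.value
    }
    return(list(method = "fisher", statistic = statObs, df = dfTot, p = p))
  }
  # stratified small-count branch: Monte-Carlo on the summed statistic
  # under the fixed-margins null within each stratum
  if (!is.null(seed)) set.seed(seed)
  sims <- numeric(mcReplicates)
  for (tab in tables) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    draws <- stats::r2dtable(mcReplicates, rowSums(tab), colSums(tab))
    sims <- sims + vapply(draws, function(s) sum((s - E)^2 / E), numeric(1))
  }
  p <- (sum(sims >= statObs - 1e-12) + 1) / (mcReplicates + 1)
  list(method = "fisher", statistic = statObs, df = dfTot, p = p)
}

#' Learn a DAG by conditional-independence search
#'
#' Constraint-based structure search. Phase 1 starts from the complete
#' undirected graph and removes the edge a--b whenever some conditioning
#' set (drawn from the current neighbourhoods, sizes 0 to
#' `maxConditioningSize`) makes [ciTest()] report independence
#' (p >= alpha), recording the separating set. Phase 2 orients edges:
#' v-structures a -> c <- b are detected where a and b are non-adjacent and
#' c is outside their separating set; Meek-style propagation follows, and
#' any still-undirected edge is oriented from the lexicographically smaller
#' variable unless that would close a cycle. All tie-breaks are
#' deterministic in variable order.
#'
#' @param memory a [CaseMemory-class] with >= 2 variables.
#' @param config a [ciConfig()].
#' @return Named list of parent sets; acyclic.
#' @export
ciSearchStructure <- function(memory, config = ciConfig()) {
  vars <- sort(variableNames(memory))
  if (length(variableNames(memory)) < 2L)
    return(stats::setNames(lapply(variableNames(memory),
                                  function(v) character(0)),
                           variableNames(memory)))
  set.seed(config$seed)
  p <- length(vars)
  adj <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  adj[upper.tri(adj)] <- TRUE
  adj <- adj | t(adj)
  sepsets <- new.env(parent = emptyenv())
  sepKey <- function(a, b) paste(sort(c(a, b)), collapse = "|")

  for (csize in 0:config$maxConditioningSize) {
    for (a in vars) for (b in vars) {
      if (a >= b || !adj[a, b]) next
      neigh <- union(vars[adj[a, ]], vars[adj[b, ]])
      neigh <- setdiff(neigh, c(a, b))
      condSets <- if (csize == 0L) list(character(0))
                  else if (length(neigh) >= csize)
                    utils::combn(sort(neigh), csize, simplify = FALSE)
                  else list()
      for (S in condSets) {
        # a test degenerate in every stratum (e.g. a constant variable)
        # carries no evidence of dependence: treat as independent
        res <- tryCatch(
          suppressWarnings(
            ciTest(memory, a, b, S, mcReplicates = config$mcReplicates)),
          error = function(e) list(p = 1))
        if (res$p >= config$alpha) {
          adj[a, b] <- adj[b, a] <- FALSE
          sepsets[[sepKey(a, b)]] <- S
          break
        }
      }
    }
  }

  # orientation: dir[u, v] = TRUE means u -> v
  dir <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  # v-structures
  for (c_ in vars) for (a in vars) for (b in vars) {
    if (a >= b || a == c_ || b == c_) next
    if (adj[a, c_] && adj[b, c_] && !adj[a, b]) {
      S <- sepsets[[sepKey(a, b)]] %||% character(0)
      if (!(c_ %in% S)) {
        if (!dir[c_, a]) dir[a, c_] <- TRUE
        if (!dir[c_, b]) dir[b, c_] <- TRUE
      }
    }
  }
  undirected <- function(u, v) adj[u, v] && !dir[u, v] && !dir[v, u]
  # Meek propagation (rules 1 and 2), deterministic sweep to fixpoint
  repeat {
    changed <- FALSE
    for (u in vars) for (v in vars) {
      if (u == v || !undirected(u, v)) next
      # rule 1: w -> u, u -- v, w and v non-adjacent  =>  u -> v
      for (w in vars[dir[, u]]) {
        if (w != v && !adj[w, v]) { dir[u, v] <- TRUE; changed <- TRUE; break }
      }
      if (dir[u, v]) next
      # rule 2: u -> w -> v and u -- v  =>  u -> v
      for (w in vars[dir[u, ]]) {
        if (dir[w, v]) { dir[u, v] <- TRUE; changed <- TRUE; break }
      }
    }
    if (!changed) break
  }
  # remaining undirected edges: lexicographic orientation, cycle-safe
  parentsOf <- function() {
    stats::setNames(lapply(vars, function(v) vars[dir[, v]]), vars)
  }
  for (u in vars) for (v in vars) {
    if (u >= v || !undirected(u, v)) next
    if (!wouldCycle(parentsOf(), u, v)) dir[u, v] <- TRUE
    else dir[v, u] <- TRUE
  }
  # conflicting v-structures can leave directed cycles; rebuild the DAG by
  # cycle-safe insertion in deterministic edge order (reverse, else drop)
  final <- stats::setNames(lapply(vars, function(v) character(0)), vars)
  for (u in vars) for (v in vars) {
    if (!dir[u, v]) next
    if (!wouldCycle(final, u, v)) final[[v]] <- c(final[[v]], u)
    else if (!dir[v, u] && !wouldCycle(final, v, u))
      final[[u]] <- c(final[[u]], v)
  }
  out <- final
  # cap parent sets: keep the parents with the strongest marginal
  # association (deterministic; ties by variable order)
  for (v in vars) {
    pa <- out[[v]]
    if (length(pa) > config$maxParents) {
      pv <- vapply(pa, function(u) tryCatch(
        suppressWarnings(
          ciTest(memory, u, v, mcReplicates = config$mcReplicates))$p,
        error = function(e) 1), numeric(1))
      out[[v]] <- pa[order(pv, pa)][seq_len(config$maxParents)]
    }
  }
  # restore the memory's column order
  out[variableNames(memory)]
}

# ---- CPT fitting and inference ---------------------------------------------

#' Fit conditional probability tables for a given structure
#'
#' Each CPT entry is the Laplace-smoothed frequency
#' `(count + smoothing) / (stratum total + smoothing * arity)`; with
#' `smoothing = 0` this is the maximum-likelihood estimate and unseen
#' parent configurations fall back to a uniform column.
#'
#' @param memory a [CaseMemory-class].
#' @param parents named list of parent sets (from a structure search).
#' @param smoothing non-negative pseudo-count; default 1 avoids zero
#'   posteriors inside the mixture.
#' @param method label recorded on the model.
#' @return A [BayesNetModel-class].
#' @export
fitCPTs <- function(memory, parents, smoothing = 1, method = "custom") {
  stopifnot(smoothing >= 0, all(names(parents) %in% variableNames(memory)))
  mc <- memoryCodes(memory)
  cpts <- list()
  for (v in names(parents)) {
    pa <- parents[[v]]
    r <- mc$arity[[v]]
    q <- if (length(pa)) prod(mc$arity[pa]) else 1L
    cfg <- configIndex(mc$codes, pa, mc$arity)
    cnt <- tabulate((cfg - 1L) * r + mc$codes[, v], r * q)
    dim(cnt) <- c(r, q)
    tot <- rep(colSums(cnt), each = r)
    prob <- (cnt + smoothing) / (tot + smoothing * r)
    zero <- tot + smoothing * r == 0
    prob[zero] <- 1 / r
    dim(prob) <- c(r, q)
    rownames(prob) <- mc$levels[[v]]
    attr(prob, "parents") <- pa
    cpts[[v]] <- prob
  }
  new("BayesNetModel", nodes = names(parents), parents = parents,
      levels = mc$levels[names(parents)], cpts = cpts,
      smoothing = smoothing, method = method)
}

setMethod("show", "BayesNetModel", function(object) {
  nEdges <- sum(vapply(object@parents, length, integer(1)))
  cat("BayesNetModel (", object@method, " search): ",
      length(object@nodes), " nodes, ", nEdges, " edges\n", sep = "")
  cat("  smoothing:", object@smoothing,
      if (length(object@cpts)) "(CPTs fitted)" else "(structure only)", "\n")
})

# children of `node` in a parents-list structure
childrenOf <- function(parents, node) {
  names(parents)[vapply(parents, function(pa) node %in% pa, logical(1))]
}

#' Posterior probability of the positive target class
#'
#' Exact inference by enumeration over the target variable only: with all
#' input variables observed, the posterior depends on the target's Markov
#' blanket, so `P(target = t | evidence)` is proportional to the product of
#' the target's own CPT entry and the CPT entries of its children, each
#' evaluated with the target set to `t`.
#'
#' `predictPosteriors` is the vectorised form over all cases of a memory.
#'
#' @param model a fitted [BayesNetModel-class].
#' @param memory a [CaseMemory-class] supplying values for every input
#'   variable (the target column is ignored as evidence).
#' @param targetVar,positiveLevel target variable and positive category;
#'   default from the memory.
#' @return `predictPosteriors`: numeric vector in \[0,1\], one per case.
#' @export
predictPosteriors <- function(model, memory,
                              targetVar = targetVariable(memory),
                              positiveLevel = targetPositive(memory)) {
  if (!length(model@cpts)) stop("model has no fitted CPTs")
  df <- caseData(memory)
  for (v in model@nodes) {
    if (is.null(df[[v]])) stop("evidence lacks variable ", v)
    if (!identical(levels(df[[v]]), model@levels[[v]]))
      stop("category levels of '", v, "' do not match the model schema")
  }
  codes <- vapply(df[model@nodes], as.integer, integer(nrow(df)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(df),
                                           dimnames = list(NULL, model@nodes))
  arity <- vapply(model@levels, length, integer(1))
  rT <- arity[[targetVar]]
  posIdx <- match(positiveLevel, model@levels[[targetVar]])
  if (is.na(posIdx)) stop("positive level absent from the model's target categories")
  kids <- childrenOf(model@parents, targetVar)
  n <- nrow(codes)

  logLik <- matrix(0, n, rT)
  for (t in seq_len(rT)) {
    codesT <- codes
    codesT[, targetVar] <- t
    cptT <- model@cpts[[targetVar]]
    cfg <- configIndex(codesT, attr(cptT, "parents"), arity)
    ll <- log(cptT[cbind(t, cfg)])
    for (ch in kids) {
      cptC <- model@cpts[[ch]]
      cfgC <- configIndex(codesT, attr(cptC, "parents"), arity)
      ll <- ll + log(cptC[cbind(codesT[, ch], cfgC)])
    }
    logLik[, t] <- ll
  }
  m <- apply(logLik, 1L, max)
  w <- exp(logLik - m)
  w[, posIdx] / rowSums(w)
}

#' @rdname predictPosteriors
#' @param case a single-row memory (or a one-case subset).
#' @export
predictPosterior <- function(model, case,
                             targetVar = targetVariable(case),
                             positiveLevel = targetPositive(case)) {
  predictPosteriors(model, case, targetVar, positiveLevel)[1L]
}
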