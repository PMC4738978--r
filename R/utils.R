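# Internal graph and coding helpers shared across modules.

# Topological order of a parents-list DAG; character(0) if cyclic.
dagTopoOrder <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0L]
  remaining <- setdiff(nodes, avail)
  while (length(avail)) {
    avail <- sort(avail)   # deterministic
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    for (w in remaining) {
      if (v %in% parents[[w]] &&
          all(parents[[w]] %in% order)) {
        avail <- c(avail, w)
      }
    }
    remaining <- setdiff(remaining, avail)
  }
  if (length(order) == length(nodes)) order else character(0)
}

# TRUE if adding edge from -> to creates a directed cycle, i.e. `from` is
# reachable from `to` along existing edges.
wouldCycle <- function(parents, from, to) {
  # walk children: edge u -> v means u %in% parents[[v]]
  stack <- to
  seen <- character(0)
  nodes <- names(parents)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == from) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    kids <- nodes[vapply(nodes, function(w) v %in% parents[[w]], logical(1))]
    stack <- c(stack, kids)
  }
  FALSE
}

# Integer coding of a factor data.frame: n x p matrix of level codes plus
# arities, used by the scoring and sampling hot paths.
memoryCodes <- function(memory) {
  df <- caseData(memory)
  codes <- vapply(df, as.integer, integer(nrow(df)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(df))
  colnames(codes) <- names(df)
  list(codes = codes,
       arity = vapply(df, nlevels, integer(1)),
       levels = lapply(df, levels))
}

# Linear parent-configuration index (first parent fastest), 1-based.
configIndex <- function(codes, parents, arity) {
  if (!length(parents)) return(rep.int(1L, nrow(codes)))
  idx <- rep.int(0L, nrow(codes))
  stride <- 1L
  for (p in parents) {
    idx <- idx + (codes[, p] - 1L) * stride
    stride <- stride * arity[[p]]
  }
  idx + 1L
}

# Derive a stream of sub-seeds (< 2^31) from one master seed, so that
# independent stages draw from independent, reproducible streams.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
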