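# Shared fixtures: small schemas and memories built in code.

binarySchema <- function(vars = c("A", "B"), target = "outcome") {
  c(lapply(vars, function(v)
      list(name = v, categories = c("no", "yes"), role = "input")),
    list(list(name = target, categories = c("success", "failure"),
              role = "target")))
}

# memory from explicit character columns (last column = target by schema)
memFromColumns <- function(..., schema) {
  df <- data.frame(..., check.names = FALSE, stringsAsFactors = FALSE)
  caseMemory(df, schema)
}

# random memory: independent uniform categorical columns
randomMemory <- function(n, arities = c(A = 2, B = 3, C = 2), seed = 1) {
  set.seed(seed)
  vars <- names(arities)
  schema <- c(lapply(vars, function(v) {
    r <- arities[[v]]
    list(name = v,
         categories = if (r == 2) c("no", "yes") else paste0("c", seq_len(r)),
         role = "input")
  }), list(list(name = "outcome", categories = c("success", "failure"),
                role = "target")))
  cols <- lapply(vars, function(v) {
    cats <- if (arities[[v]] == 2) c("no", "yes") else paste0("c", seq_len(arities[[v]]))
    sample(cats, n, replace = TRUE)
  })
  names(cols) <- vars
  cols$outcome <- sample(c("success", "failure"), n, replace = TRUE)
  caseMemory(as.data.frame(cols, check.names = FALSE), schema)
}

# skeleton (undirected edge set) of a parents list, as sorted "a~b" keys
skeletonOf <- function(parents) {
  sort(unique(unlist(lapply(names(parents), function(v)
    lapply(parents[[v]], function(u) paste(sort(c(u, v)), collapse = "~"))))))
}
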