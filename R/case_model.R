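# The CBR case memory: schema-validated categorical cases, CSV/YAML I/O,
# and the retrieve / retain stages of the CBR cycle.

#' Construct a case memory from a data frame and a schema
#'
#' @param data data.frame of raw (character or factor) values, one row per
#'   case. Row names, or a `case_id` column, give the case ids.
#' @param schema list of variable descriptors, each a list with elements
#'   `name`, `categories` (>= 2 unique labels) and `role` (`"input"` or
#'   `"target"`). Exactly one variable must have role `"target"` with two
#'   categories.
#' @param targetPositive target category coded as the positive (failure)
#'   class; defaults to the last declared target category.
#' @param retreatmentVar name of the binary variable flagging retreatment
#'   cases (its last category means "is a retreatment"), or `NULL` when all
#'   cases are retreatments.
#' @return A validated [CaseMemory-class].
#' @export
caseMemory <- function(data, schema, targetPositive = NULL,
                       retreatmentVar = NULL) {
  vnames <- vapply(schema, `[[`, character(1), "name")
  roles <- vapply(schema, `[[`, character(1), "role")
  if (anyDuplicated(vnames))
    stop("schema declares duplicate variable names")
  if (sum(roles == "target") != 1L)
    stop("schema must declare exactly one target variable")
  if (!all(roles %in% c("input", "target")))
    stop("variable roles must be 'input' or 'target'")
  if ("case_id" %in% names(data)) {
    rownames(data) <- as.character(data$case_id)
    data$case_id <- NULL
  }
  missingCols <- setdiff(vnames, names(data))
  if (length(missingCols))
    stop("schema error: case table lacks column(s) ",
         paste(missingCols, collapse = ", "))
  extra <- setdiff(names(data), vnames)
  if (length(extra))
    stop("schema error: case table has undeclared column(s) ",
         paste(extra, collapse = ", "))
  data <- data[vnames]
  for (sp in schema) {
    cats <- as.character(sp$categories)
    if (anyDuplicated(cats)) stop("duplicate categories for ", sp$name)
    raw <- as.character(data[[sp$name]])
    badIdx <- which(!is.na(raw) & !(raw %in% cats))
    if (length(badIdx))
      stop(sprintf(
        "validation error: variable '%s', row %d: value '%s' is not a declared category",
        sp$name, badIdx[1L], raw[badIdx[1L]]))
    if (anyNA(raw))
      stop(sprintf("validation error: variable '%s', row %d: missing value",
                   sp$name, which(is.na(raw))[1L]))
    data[[sp$name]] <- factor(raw, levels = cats)
  }
  if (is.null(rownames(data)) || identical(rownames(data), as.character(seq_len(nrow(data)))))
    rownames(data) <- paste0("case", seq_len(nrow(data)))
  target <- vnames[roles == "target"]
  tcats <- as.character(schema[[which(roles == "target")]]$categories)
  if (length(tcats) != 2L) stop("target variable must have exactly 2 categories")
  if (is.null(targetPositive)) targetPositive <- tcats[2L]
  new("CaseMemory", cases = data, target = target,
      targetPositive = targetPositive,
      retreatmentVar = as.character(retreatmentVar %||% character(0)))
}

#' Load a case table and schema from disk
#'
#' The case table is a UTF-8 CSV with a header row of variable names (an
#' optional `case_id` column supplies case ids); the schema is a YAML (or
#' JSON) document with a `variables` list of `{name, categories, role}`
#' entries and optional top-level `target_positive` and
#' `retreatment_variable` fields.
#'
#' @param tablePath path to the CSV case table.
#' @param schemaPath path to the YAML/JSON schema.
#' @return A validated [CaseMemory-class]; row order is preserved.
#' @export
loadCaseTable <- function(tablePath, schemaPath) {
  sch <- readSchemaFile(schemaPath)
  df <- utils::read.csv(tablePath, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  caseMemory(df, sch$variables,
             targetPositive = sch$target_positive,
             retreatmentVar = sch$retreatment_variable)
}

readSchemaFile <- function(path) {
  sch <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  if (is.null(sch$variables)) stop("schema error: no 'variables' list in ", path)
  sch
}

#' Write a case memory back to a CSV table and YAML schema
#'
#' Inverse of [loadCaseTable()]: writing then loading reproduces the memory
#' exactly.
#'
#' @param memory a [CaseMemory-class].
#' @param tablePath,schemaPath output paths.
#' @export
writeCaseTable <- function(memory, tablePath, schemaPath) {
  df <- caseData(memory)
  out <- data.frame(case_id = rownames(df),
                    lapply(df, as.character),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, tablePath, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  yaml::write_yaml(list(
    variables = memorySchema(memory),
    target_positive = memory@targetPositive,
    retreatment_variable = if (length(memory@retreatmentVar))
      memory@retreatmentVar else NULL
  ), schemaPath)
  invisible(c(table = tablePath, schema = schemaPath))
}

#' @rdname accessors
#' @export
caseData <- function(memory) memory@cases

#' Accessors for case memories
#'
#' `caseData` returns the factor data.frame; `nCases` the number of cases;
#' `variableNames` all variable names; `inputVariables` the non-target
#' names; `targetVariable` / `targetPositive` the target column and its
#' positive class; `memorySchema` the schema as a list of
#' `{name, categories, role}` descriptors; `caseLabels` the 0/1 coding of
#' the target (1 = positive class).
#'
#' @param memory a [CaseMemory-class].
#' @name accessors
#' @export
nCases <- function(memory) nrow(memory@cases)

#' @rdname accessors
#' @export
variableNames <- function(memory) names(memory@cases)

#' @rdname accessors
#' @export
inputVariables <- function(memory) setdiff(names(memory@cases), memory@target)

#' @rdname accessors
#' @export
targetVariable <- function(memory) memory@target

#' @rdname accessors
#' @export
targetPositive <- function(memory) memory@targetPositive

#' @rdname accessors
#' @export
caseLabels <- function(memory) {
  as.integer(memory@cases[[memory@target]] == memory@targetPositive)
}

#' @rdname accessors
#' @export
memorySchema <- function(memory) {
  df <- memory@cases
  lapply(names(df), function(v) list(
    name = v, categories = levels(df[[v]]),
    role = if (v == memory@target) "target" else "input"))
}

setMethod("show", "CaseMemory", function(object) {
  df <- object@cases
  cat("CaseMemory with", nrow(df), "cases and", ncol(df), "variables\n")
  cat("  target:", object@target, "(positive class:",
      object@targetPositive, ")\n")
  npos <- sum(df[[object@target]] == object@targetPositive)
  cat("  class balance:", npos, "positive /", nrow(df) - npos, "negative\n")
  if (length(object@retreatmentVar))
    cat("  retreatment flag variable:", object@retreatmentVar, "\n")
})

#' Retrieve stage: select the retreatment cases
#'
#' Filters the memory to the cases flagged as retreatments (the last
#' category of the memory's retreatment-flag variable), dropping cases that
#' involve only an initial treatment. All retrieved cases are passed onward
#' to model building. When the memory declares no retreatment variable the
#' memory is returned unchanged.
#'
#' @param memory a [CaseMemory-class].
#' @return The sub-memory of retreatment cases, order preserved (possibly
#'   empty).
#' @export
retrieveRetreatmentCases <- function(memory) {
  if (!length(memory@retreatmentVar)) return(memory)
  col <- memory@cases[[memory@retreatmentVar]]
  keep <- col == levels(col)[nlevels(col)]
  out <- memory
  out@cases <- memory@cases[keep, , drop = FALSE]
  out
}

#' Retain stage: add a solved case to the memory
#'
#' @param memory a [CaseMemory-class].
#' @param case named list (or one-row data.frame) of category labels for
#'   every input variable; may omit the target.
#' @param verifiedLabel the expert-verified target category.
#' @param caseId id of the new case; must not collide with an existing id.
#' @return A new memory with the case appended; the input memory is
#'   unchanged.
#' @export
retainCase <- function(memory, case, verifiedLabel, caseId) {
  df <- memory@cases
  if (caseId %in% rownames(df))
    stop("duplicate case_id: ", caseId)
  case <- as.list(case)
  case[[memory@target]] <- verifiedLabel
  row <- df[0, , drop = FALSE]
  for (v in names(df)) {
    val <- as.character(case[[v]] %||% NA_character_)
    if (is.na(val) || !(val %in% levels(df[[v]])))
      stop(sprintf("case does not validate: variable '%s', value '%s'",
                   v, val))
    row[1L, v] <- val
  }
  rownames(row) <- caseId
  out <- memory
  out@cases <- rbind(df, row)
  validObject(out)
  out
}

#' Recode a categorical variable into coarser categories
#'
#' Variables with many raw levels are recoded so the final variables carry
#' around 3-4 categories, mirroring the preprocessing of the clinical case
#' table.
#'
#' @param values vector of raw labels.
#' @param mapping named character vector, `names(mapping)` = raw labels,
#'   values = coarse categories; must cover every observed raw label.
#' @return Character vector of coarse categories, same length as `values`.
#' @export
recodeVariable <- function(values, mapping) {
  values <- as.character(values)
  unmapped <- setdiff(unique(values), names(mapping))
  if (length(unmapped))
    stop("recode error: unmapped raw label(s): ",
         paste(unmapped, collapse = ", "))
  unname(mapping[values])
}

#' Subset a case memory by row index
#'
#' @param memory a [CaseMemory-class].
#' @param i integer or logical index into the cases.
#' @return The sub-memory, schema unchanged.
#' @export
subsetCases <- function(memory, i) {
  out <- memory
  out@cases <- memory@cases[i, , drop = FALSE]
  out
}
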