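#' Declare a feature schema entry
#'
#' A dataset schema is a list of `feature_schema` objects, one per feature
#' column, declaring whether the feature is categorical (with an explicit,
#' ordered level set) or continuous. The schema is the contract every other
#' component relies on: conditional probability tables are indexed by the
#' declared levels, and the structure-learning legality rules (a categorical
#' node may not have a continuous parent) are read off the schema.
#'
#' @param name Column name.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels Character vector of category labels, required (non-empty,
#'   unique) for categorical features and disallowed for continuous ones.
#' @return An object of class `"feature_schema"`.
#' @export
#' @examples
#' feature_schema("safety", "categorical", c("low", "med", "high"))
#' feature_schema("age", "continuous")
feature_schema <- function(name, kind = c("categorical", "continuous"),
                           levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0L)
      stop("categorical feature '", name, "' needs a non-empty level set")
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop("duplicate levels for feature '", name, "'")
  } else if (!is.null(levels)) {
    stop("continuous feature '", name, "' must not declare levels")
  }
  structure(list(name = name, kind = kind, levels = levels),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  if (x$kind == "categorical") {
    cat(sprintf("<feature %s: categorical {%s}>\n", x$name,
                paste(x$levels, collapse = ", ")))
  } else {
    cat(sprintf("<feature %s: continuous>\n", x$name))
  }
  invisible(x)
}

# Name reserved for the level absorbing categorical missing values.
MISSING_LEVEL <- "__missing__"

schema_names <- function(schema) vapply(schema, `[[`, "", "name")
schema_kinds <- function(schema) vapply(schema, `[[`, "", "kind")

#' Assemble a schema-typed dataset table
#'
#' Wraps a data frame as a `dataset_table`: categorical columns become
#' factors over their declared levels, continuous columns numeric, and the
#' class column a factor. Invariants are enforced: every categorical value
#' must be a declared level, every continuous value finite, and no missing
#' values may remain.
#'
#' @param df Data frame with one column per schema feature plus the class
#'   column.
#' @param schema List of [feature_schema()] objects.
#' @param class_name Name of the class column.
#' @param provenance `"original"`, `"synthetic"` or `"enlarged"`.
#' @param strict If `TRUE` (default) an undeclared categorical value is an
#'   error; silent level growth would corrupt CPT domains downstream.
#' @return A data frame of class `"dataset_table"` carrying `schema`,
#'   `class_name` and `provenance` attributes.
#' @export
dataset_table <- function(df, schema, class_name,
                          provenance = c("original", "synthetic", "enlarged"),
                          strict = TRUE) {
  provenance <- match.arg(provenance)
  fn <- schema_names(schema)
  missing_cols <- setdiff(c(fn, class_name), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, c(fn, class_name), drop = FALSE]
  for (fs in schema) {
    v <- df[[fs$name]]
    if (fs$kind == "categorical") {
      v <- as.character(v)
      bad <- setdiff(unique(v), fs$levels)
      if (length(bad)) {
        if (strict)
          stop("feature '", fs$name, "' has undeclared value(s): ",
               paste(bad, collapse = ", "))
        fs$levels <- c(fs$levels, bad)
      }
      df[[fs$name]] <- factor(v, levels = fs$levels)
    } else {
      v <- as.numeric(v)
      if (anyNA(v) || any(!is.finite(v)))
        stop("feature '", fs$name, "' has missing or non-finite values")
      df[[fs$name]] <- v
    }
  }
  if (anyNA(df)) stop("missing values remain after typing")
  df[[class_name]] <- factor(as.character(df[[class_name]]))
  structure(df,
            schema = schema, class_name = class_name,
            provenance = provenance,
            class = c("dataset_table", "data.frame"))
}

#' @export
print.dataset_table <- function(x, ...) {
  cn <- attr(x, "class_name")
  cat(sprintf("dataset_table: %d rows, %d features + class '%s' (%s)\n",
              nrow(x), length(attr(x, "schema")), cn, attr(x, "provenance")))
  tab <- table(x[[cn]])
  cat("  class counts:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Strip the class column from a dataset table
#'
#' @param table A `dataset_table`.
#' @return A plain data frame of the feature columns only.
#' @export
feature_frame <- function(table) {
  df <- as.data.frame(table)
  df[[attr(table, "class_name")]] <- NULL
  attr(df, "schema") <- attr(table, "schema")
  df
}

#' Load a CSV data set under a declared schema
#'
#' Applies the preprocessing policy for missing values: a missing value in a
#' categorical feature is consigned to a dedicated new level
#' (`"__missing__"`, appended to that feature's level set), while a row with
#' a missing continuous value is dropped entirely.
#'
#' @param path CSV file with a header row.
#' @param schema List of [feature_schema()] objects.
#' @param class_name Name of the class column in the file.
#' @param missing_token Text encoding a missing cell (in addition to empty
#'   cells), e.g. `"?"`. Use `NA` for "empty cells only".
#' @param strict Passed to [dataset_table()].
#' @return A `dataset_table`.
#' @export
load_dataset <- function(path, schema, class_name, missing_token = NA,
                         strict = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  fn <- schema_names(schema)
  missing_cols <- setdiff(c(fn, class_name), names(raw))
  if (length(missing_cols))
    stop("file lacks column(s): ", paste(missing_cols, collapse = ", "))
  is_missing <- function(v) {
    m <- is.na(v) | v == ""
    if (!is.na(missing_token)) m <- m | v == missing_token
    m
  }
  # categorical: missing -> dedicated level; continuous: drop the row
  drop <- rep(FALSE, nrow(raw))
  schema2 <- schema
  for (i in seq_along(schema)) {
    fs <- schema[[i]]
    v <- raw[[fs$name]]
    m <- is_missing(v)
    if (fs$kind == "categorical") {
      if (any(m)) {
        if (MISSING_LEVEL %in% fs$levels)
          stop("level collision: '", MISSING_LEVEL,
               "' already declared for '", fs$name, "'")
        schema2[[i]]$levels <- c(fs$levels, MISSING_LEVEL)
        v[m] <- MISSING_LEVEL
        raw[[fs$name]] <- v
      }
    } else {
      drop <- drop | m
    }
  }
  raw <- raw[!drop, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no rows remain after dropping missing values")
  dataset_table(raw, schema2, class_name, provenance = "original",
                strict = strict)
}

#' Merge class labels down to a binary class
#'
#' @param table A `dataset_table`.
#' @param merge_map Named character vector mapping every observed class
#'   label to `"+"` or `"-"`; both output labels must be used.
#' @return The table with a binary class column; row order preserved. The
#'   original labels are kept in the `label_map` attribute.
#' @export
#' @examples
#' \dontrun{
#' binarize_class(tbl, c(good = "+", vgood = "+", acc = "-", unacc = "-"))
#' }
binarize_class <- function(table, merge_map) {
  cn <- attr(table, "class_name")
  obs <- unique(as.character(table[[cn]]))
  unmapped <- setdiff(obs, names(merge_map))
  if (length(unmapped))
    stop("unmapped class label(s): ", paste(unmapped, collapse = ", "))
  if (!all(merge_map %in% c("+", "-")))
    stop("merge_map values must be '+' or '-'")
  new <- unname(merge_map[as.character(table[[cn]])])
  if (length(unique(new)) < 2L)
    stop("merge_map collapses the class to a single label")
  out <- table
  out[[cn]] <- factor(new, levels = c("+", "-"))
  attr(out, "label_map") <- merge_map
  out
}

#' Class balance of a binary table
#'
#' @param table A binary-class `dataset_table`.
#' @param minority_label The label of the minority ("positive") class.
#' @return An object of class `"class_balance"`: counts `M`, `m_plus`,
#'   `m_minus` and proportions `p_plus`, `p_minus`.
#' @export
#' @examples
#' balance_counts(134, 1594)  # 7.75% minority
class_balance <- function(table, minority_label = "+") {
  cn <- attr(table, "class_name")
  labs <- as.character(table[[cn]])
  if (!minority_label %in% labs)
    stop("minority label '", minority_label, "' absent from the table")
  m_plus <- sum(labs == minority_label)
  m_minus <- sum(labs != minority_label)
  balance_counts(m_plus, m_minus)
}

#' Class balance from raw counts
#'
#' @param m_plus Minority count.
#' @param m_minus Majority count.
#' @return A `"class_balance"` object.
#' @export
balance_counts <- function(m_plus, m_minus) {
  if (m_plus <= 0L) stop("minority class is empty")
  if (m_plus >= m_minus)
    stop("'minority' class is not the minority (", m_plus, " >= ", m_minus,
         ")")
  M <- m_plus + m_minus
  structure(list(M = M, m_plus = m_plus, m_minus = m_minus,
                 p_plus = m_plus / M, p_minus = m_minus / M),
            class = "class_balance")
}

#' @export
print.class_balance <- function(x, ...) {
  cat(sprintf("class balance: %d instances, minority %d (%.2f%%)\n",
              x$M, x$m_plus, 100 * x$p_plus))
  invisible(x)
}

#' Write a dataset table to CSV (with a JSON sidecar)
#'
#' Continuous values are written with 17 significant digits so that
#' `load_dataset(write_dataset(x))` round-trips bit-exactly. A sidecar
#' `<path>.json` records the schema, class column and provenance.
#'
#' @param table A `dataset_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path) {
  df <- as.data.frame(table)
  schema <- attr(table, "schema")
  for (fs in schema) {
    if (fs$kind == "categorical") {
      df[[fs$name]] <- as.character(df[[fs$name]])
    } else {
      df[[fs$name]] <- vapply(df[[fs$name]],
                              function(z) format(z, digits = 17,
                                                 scientific = FALSE),
                              "")
    }
  }
  cn <- attr(table, "class_name")
  df[[cn]] <- as.character(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  side <- list(
    class_name = cn,
    provenance = attr(table, "provenance"),
    schema = lapply(schema, function(fs)
      list(name = fs$name, kind = fs$kind, levels = fs$levels))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a schema sidecar written by [write_dataset()]
#'
#' @param path Path to the `.json` sidecar.
#' @return A list with `schema`, `class_name` and `provenance`.
#' @export
read_schema_sidecar <- function(path) {
  side <- jsonlite::read_json(path)
  schema <- lapply(side$schema, function(s)
    feature_schema(s$name, s$kind,
                   if (s$kind == "categorical") unlist(s$levels)))
  list(schema = schema, class_name = side$class_name,
       provenance = side$provenance)
}
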