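#' Construct a tabular dataset
#'
#' The shared data container for the package: a numeric feature matrix, a
#' binary label vector and a per-column schema saying which columns are
#' continuous (and among those, which participate in supervised
#' discretization) and which are categorical.
#'
#' @param X numeric matrix (or data frame coercible to one), rows = samples.
#' @param y binary labels, every element 0 or 1. Both classes need not be
#'   present, but fitting operations require both.
#' @param schema data frame with columns `name`, `kind`
#'   (`"continuous"`/`"categorical"`) and `discretize` (logical). Defaults to
#'   all-continuous, all flagged for discretization.
#' @return an object of class `tabular_dataset` with elements `X`, `y`,
#'   `schema`.
#' @export
tabular_dataset <- function(X, y, schema = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    validation_error("X must be a numeric matrix")
  y <- as.integer(y)
  if (nrow(X) != length(y))
    validation_error("row count of X must equal length of y")
  if (length(y) && !all(y %in% c(0L, 1L)))
    validation_error("labels must all be 0 or 1")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(schema)) {
    schema <- data.frame(
      name = colnames(X),
      kind = rep("continuous", ncol(X)),
      discretize = rep(TRUE, ncol(X)),
      stringsAsFactors = FALSE
    )
  }
  validate_schema(schema, colnames(X))
  structure(list(X = X, y = y, schema = schema), class = "tabular_dataset")
}

validate_schema <- function(schema, colnames_x) {
  req <- c("name", "kind", "discretize")
  if (!all(req %in% names(schema)))
    validation_error("schema needs columns name, kind, discretize")
  if (anyDuplicated(schema$name))
    validation_error("schema feature names must be unique")
  if (!all(schema$kind %in% c("continuous", "categorical")))
    validation_error("schema kind must be 'continuous' or 'categorical'")
  bad <- schema$discretize & schema$kind != "continuous"
  if (any(bad))
    validation_error(sprintf(
      "only continuous columns may be flagged for discretization: %s",
      paste(schema$name[bad], collapse = ", ")))
  if (!setequal(schema$name, colnames_x) ||
      !identical(schema$name, colnames_x))
    validation_error("schema names must match dataset columns in order")
  invisible(schema)
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cs <- class_summary(x)
  cat(sprintf(
    "<tabular_dataset> %d rows, %d features (%d flagged for discretization)\n",
    nrow(x$X), ncol(x$X), sum(x$schema$discretize)))
  cat(sprintf("  negatives: %d, positives: %d, prevalence: %s\n",
              cs$n_neg, cs$n_pos,
              if (is.na(cs$pos_prevalence)) "undefined"
              else format(cs$pos_prevalence, digits = 4)))
  invisible(x)
}

n_rows <- function(ds) nrow(ds$X)

subset_rows <- function(ds, idx) {
  tabular_dataset(ds$X[idx, , drop = FALSE], ds$y[idx], ds$schema)
}

#' Load a delimited table as a tabular dataset
#'
#' Reads a delimited text file (comma by default, tab auto-detected) with a
#' mandatory header row, separates the label column, coerces labels to
#' \{0,1\} and types the remaining columns. Missing values are rejected with
#' an error rather than silently imputed.
#'
#' @param path file path.
#' @param label_column name of the label column.
#' @param positive_label optional raw token to map to 1 (everything else maps
#'   to 0); by default the column must already contain 0/1.
#' @param schema_overrides optional named character vector or list mapping
#'   column name to kind (`"continuous"`/`"categorical"`); categorical columns
#'   are never flagged for discretization.
#' @param schema_path optional path to a JSON schema sidecar (as written by
#'   [write_table()]) mapping column name to `{kind, discretize}`.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return a [tabular_dataset()].
#' @export
load_table <- function(path, label_column = "label", positive_label = NULL,
                       schema_overrides = NULL, schema_path = NULL,
                       sep = NULL) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!label_column %in% names(df))
    validation_error(sprintf("label column '%s' not found", label_column))
  raw_y <- df[[label_column]]
  if (!is.null(positive_label)) {
    y <- as.integer(as.character(raw_y) == as.character(positive_label))
  } else {
    y <- suppressWarnings(as.integer(raw_y))
    if (anyNA(y) || !all(y %in% c(0L, 1L)))
      validation_error(
        "label column must contain 0/1 tokens (or supply positive_label)")
  }
  feat <- df[setdiff(names(df), label_column)]
  if (ncol(feat) == 0L) validation_error("no feature columns in file")

  sidecar <- NULL
  if (!is.null(schema_path)) {
    sidecar <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  }
  kind <- vapply(names(feat), function(nm) {
    if (!is.null(schema_overrides) && nm %in% names(schema_overrides))
      return(as.character(schema_overrides[[nm]]))
    if (!is.null(sidecar) && nm %in% names(sidecar))
      return(as.character(sidecar[[nm]]$kind))
    if (is.numeric(feat[[nm]])) "continuous" else "categorical"
  }, character(1))
  disc <- vapply(names(feat), function(nm) {
    if (!is.null(sidecar) && nm %in% names(sidecar) &&
        !is.null(sidecar[[nm]]$discretize))
      return(isTRUE(sidecar[[nm]]$discretize))
    kind[[nm]] == "continuous"
  }, logical(1))

  Xc <- lapply(names(feat), function(nm) {
    v <- feat[[nm]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) & !anyNA(v)) {
        bad <- which(is.na(v2))[1]
        validation_error(sprintf(
          "non-numeric value in column '%s' at data row %d", nm, bad))
      }
      v <- v2
    }
    if (anyNA(v))
      validation_error(sprintf(
        "missing value in column '%s' at data row %d; missing values are rejected",
        nm, which(is.na(v))[1]))
    v
  })
  X <- do.call(cbind, Xc)
  colnames(X) <- names(feat)
  if (anyNA(y)) validation_error("missing value in label column")
  schema <- data.frame(name = names(feat), kind = unname(kind),
                       discretize = unname(disc), stringsAsFactors = FALSE)
  tabular_dataset(X, y, schema)
}

#' Write a tabular dataset as delimited text (plus schema sidecar)
#'
#' @param ds a [tabular_dataset()].
#' @param path output file path (comma-separated, header row).
#' @param label_column name for the label column.
#' @param schema_path optional path for a JSON schema sidecar; default
#'   `paste0(path, ".schema.json")`; `NA` suppresses the sidecar.
#' @return `path`, invisibly.
#' @export
write_table <- function(ds, path, label_column = "label",
                        schema_path = paste0(path, ".schema.json")) {
  df <- as.data.frame(ds$X)
  df[[label_column]] <- ds$y
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.na(schema_path) && !is.null(schema_path)) {
    side <- lapply(seq_len(nrow(ds$schema)), function(i)
      list(kind = ds$schema$kind[i], discretize = ds$schema$discretize[i]))
    names(side) <- ds$schema$name
    jsonlite::write_json(side, schema_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Class counts and prevalence
#'
#' @param ds a [tabular_dataset()].
#' @return list with `n_neg`, `n_pos` and `pos_prevalence` (`NA` for an empty
#'   dataset).
#' @export
class_summary <- function(ds) {
  n_pos <- sum(ds$y == 1L)
  n_neg <- sum(ds$y == 0L)
  n <- n_pos + n_neg
  list(n_neg = n_neg, n_pos = n_pos,
       pos_prevalence = if (n == 0) NA_real_ else n_pos / n)
}

#' Stratified train/test split
#'
#' Splits a dataset into disjoint train and test subsets preserving the class
#' proportions. Within each class the train allocation is
#' `round(train_fraction * class_count)` up to a deterministic +-1 remainder
#' rule: base allocations are floors, and leftover slots go to the classes
#' with the largest fractional parts (ties broken by class index, negatives
#' first).
#'
#' @param ds a [tabular_dataset()]; both classes must be present.
#' @param train_fraction proportion in (0, 1].
#' @param seed integer seed; the split is a pure function of (data, fraction,
#'   seed).
#' @return list of class `split_result` with `train`, `test` (both
#'   [tabular_dataset()]), `train_idx`, `test_idx`, `seed`, `train_fraction`.
#' @export
stratified_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction <= 1))
    validation_error("train_fraction must be in (0, 1]")
  cs <- class_summary(ds)
  if (cs$n_pos == 0L || cs$n_neg == 0L)
    fadel_error("both classes must be present for a stratified split",
                "fadel_stratification_error")
  classes <- c(0L, 1L)
  counts <- c(cs$n_neg, cs$n_pos)
  exact <- train_fraction * counts
  base <- floor(exact)
  total_train <- round(train_fraction * n_rows(ds))
  remainder <- total_train - sum(base)
  frac <- exact - base
  take <- base
  if (remainder > 0) {
    ord <- order(-frac, seq_along(classes))
    take[ord[seq_len(remainder)]] <- take[ord[seq_len(remainder)]] + 1L
  } else if (remainder < 0) {
    ord <- order(frac, seq_along(classes))
    k <- -remainder
    take[ord[seq_len(k)]] <- take[ord[seq_len(k)]] - 1L
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (ci in seq_along(classes)) {
    rows <- which(ds$y == classes[ci])
    perm <- if (length(rows) == 1L) rows else sample(rows)
    train_idx <- c(train_idx, perm[seq_len(min(take[ci], length(rows)))])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_rows(ds)), train_idx)
  structure(list(
    train = subset_rows(ds, train_idx),
    test = subset_rows(ds, test_idx),
    train_idx = train_idx, test_idx = test_idx,
    seed = as.integer(seed), train_fraction = train_fraction
  ), class = "split_result")
}

# Stratified fold assignment for out-of-fold stacking: returns an integer
# vector of fold ids 1..k. Requires >= k members per class so every fold
# holds both classes.
stratified_folds <- function(y, k, seed) {
  if (k < 2L) validation_error("k must be >= 2")
  folds <- integer(length(y))
  set.seed(seed)
  for (cls in c(0L, 1L)) {
    rows <- which(y == cls)
    if (length(rows) < k)
      fadel_error(sprintf(
        "class %d has %d members; %d folds need at least %d",
        cls, length(rows), k, k), "fadel_stratification_error")
    perm <- sample(rows)
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}
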