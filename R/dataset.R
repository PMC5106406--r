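#' Record-by-dimension dataset with per-dimension metadata
#'
#' `ss_dataset` is the central data container of subspacer: a table of
#' `n_records` rows by `n_dims` columns, per-dimension metadata (kind,
#' observed range, category levels) and an optional class label per record.
#' Labels are deliberately kept outside the value table: they are never
#' encoded, normalized or clustered, and exist only for splitting and
#' evaluation.
#'
#' @param values A tibble of dimension values (numeric or character columns;
#'   `NA` marks a missing value).
#' @param dim_meta A tibble with columns `name`, `kind`
#'   (`"numeric"`, `"binary"` or `"categorical"`), `observed_min`,
#'   `observed_max` and a list-column `levels` (category codes in declared
#'   order; `character(0)` for numeric dimensions).
#' @param record_ids Character vector of unique record identifiers.
#' @param labels Optional character vector of class labels, one per record.
#' @return An object of class `ss_dataset`.
#' @export
new_dataset <- function(values, dim_meta, record_ids, labels = NULL) {
  values <- as_tibble(values)
  dim_meta <- as_tibble(dim_meta)
  stopifnot(
    nrow(dim_meta) == ncol(values),
    identical(dim_meta$name, names(values)),
    length(record_ids) == nrow(values)
  )
  record_ids <- as.character(record_ids)
  if (anyDuplicated(record_ids)) abort("record_ids must be unique")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      abort("labels must have exactly one entry per record")
    }
    names(labels) <- record_ids
  }
  bad <- with(dim_meta, !is.na(observed_min) & !is.na(observed_max) &
                observed_min > observed_max)
  if (any(bad)) abort("dim_meta: observed_min > observed_max")
  structure(
    list(values = values, dim_meta = dim_meta,
         record_ids = record_ids, labels = labels),
    class = "ss_dataset"
  )
}

#' @export
print.ss_dataset <- function(x, ...) {
  cat(sprintf("<ss_dataset> %d records x %d dimensions\n",
              n_records(x), n_dims(x)))
  kinds <- table(x$dim_meta$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    lt <- table(x$labels)
    cat("  labels:", paste(names(lt), lt, sep = ":", collapse = ", "), "\n")
  }
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' Dataset dimensions
#'
#' @param ds An [new_dataset()] object.
#' @return `n_records()` and `n_dims()` return counts; `dim_names()` the
#'   dimension names in table order.
#' @export
n_records <- function(ds) nrow(ds$values)

#' @rdname n_records
#' @export
n_dims <- function(ds) ncol(ds$values)

#' @rdname n_records
#' @export
dim_names <- function(ds) ds$dim_meta$name

#' Numeric value matrix of a preprocessed dataset
#'
#' @param ds A fully numeric, missing-free [new_dataset()] object.
#' @return A numeric matrix with record ids as row names and dimension names
#'   as column names.
#' @export
values_matrix <- function(ds) {
  check_numeric_dataset(ds, "values_matrix()")
  m <- as.matrix(ds$values)
  rownames(m) <- ds$record_ids
  m
}

infer_kind <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0) return(list(kind = "numeric", levels = character(0)))
  suppressWarnings(num <- as.numeric(obs))
  if (!anyNA(num)) return(list(kind = "numeric", levels = character(0)))
  lev <- sort(unique(as.character(obs)))
  kind <- if (length(lev) == 2) "binary" else "categorical"
  list(kind = kind, levels = lev)
}

make_dim_meta <- function(values, kinds = NULL, levels = NULL) {
  metas <- imap(values, function(col, nm) {
    info <- infer_kind(col)
    if (!is.null(kinds) && !is.na(kinds[[nm]])) {
      info$kind <- kinds[[nm]]
      info$levels <- levels[[nm]]
    }
    obs <- col[!is.na(col)]
    rng <- if (info$kind == "numeric" && length(obs) > 0) {
      range(as.numeric(obs))
    } else c(NA_real_, NA_real_)
    tibble(name = nm, kind = info$kind,
           observed_min = rng[1], observed_max = rng[2],
           levels = list(info$levels))
  })
  bind_rows(metas)
}

coerce_column <- function(col, kind) {
  if (kind == "numeric") suppressWarnings(as.numeric(col)) else as.character(col)
}

#' Build a dataset from a plain data frame
#'
#' Dimension kinds are inferred per column: numeric when every non-missing
#' value parses as a number, binary when there are exactly two distinct
#' non-missing values, categorical otherwise.  Empty strings and the token
#' `"?"` (the WEKA missing-value convention) are treated as missing.
#'
#' @param df A data frame; one row per record.
#' @param label_column Optional name of the class-label column; it is removed
#'   from the value table and stored separately.
#' @param id_column Optional name of a record-identifier column; defaults to
#'   the 0-based row index.
#' @param missing_tokens Character values read as missing markers.
#' @return An `ss_dataset`.
#' @export
as_dataset <- function(df, label_column = NULL, id_column = NULL,
                       missing_tokens = c("", "?")) {
  df <- as_tibble(df)
  if (anyDuplicated(names(df))) abort("duplicate column names in input")
  for (tok in missing_tokens) {
    df <- mutate(df, dplyr::across(dplyr::where(is.character),
                                   ~ replace(.x, .x == tok, NA)))
  }
  record_ids <- if (!is.null(id_column)) {
    if (!id_column %in% names(df)) abort(paste0("id column not found: ", id_column))
    ids <- as.character(df[[id_column]])
    df <- select(df, -dplyr::all_of(id_column))
    ids
  } else {
    as.character(seq_len(nrow(df)) - 1L)
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      abort(paste0("label column not found: ", label_column))
    }
    labels <- as.character(df[[label_column]])
    df <- select(df, -dplyr::all_of(label_column))
  }
  meta <- make_dim_meta(df)
  vals <- as_tibble(map2(df, meta$kind, coerce_column))
  new_dataset(vals, meta, record_ids, labels)
}

#' Read a dataset from CSV or ARFF
#'
#' CSV files are comma-separated with a header row of dimension names.  ARFF
#' files follow the WEKA dialect (`@relation` / `@attribute` / `@data`,
#' nominal domains in braces, `?` for missing); attribute declarations drive
#' the dimension kinds, with two-level nominal attributes recorded as binary.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"arff"`, or `"auto"` (by file extension).
#' @inheritParams as_dataset
#' @return An `ss_dataset`.
#' @export
read_dataset <- function(path, format = c("auto", "csv", "arff"),
                         label_column = NULL, id_column = NULL,
                         missing_tokens = c("", "?")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          na = character(0), show_col_types = FALSE)
    return(as_dataset(df, label_column, id_column, missing_tokens))
  }
  df <- foreign::read.arff(path)
  if (anyDuplicated(names(df))) abort("duplicate column names in input")
  declared <- arff_declared_levels(path)
  kinds <- map_chr(df, function(col) {
    if (is.factor(col)) {
      if (nlevels(col) == 2) "binary" else "categorical"
    } else "numeric"
  })
  # read.arff sorts nominal levels; restore the declared header order
  lvls <- imap(df, function(col, nm) {
    if (!is.factor(col)) return(character(0))
    decl <- declared[[nm]]
    if (!is.null(decl) && setequal(decl, levels(col))) decl else levels(col)
  })
  df <- mutate(as_tibble(df), dplyr::across(dplyr::where(is.factor), as.character))
  record_ids <- if (!is.null(id_column)) {
    ids <- as.character(df[[id_column]])
    df <- select(df, -dplyr::all_of(id_column))
    kinds <- kinds[names(df)]; lvls <- lvls[names(df)]
    ids
  } else as.character(seq_len(nrow(df)) - 1L)
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      abort(paste0("label column not found: ", label_column))
    }
    labels <- as.character(df[[label_column]])
    df <- select(df, -dplyr::all_of(label_column))
    kinds <- kinds[names(df)]; lvls <- lvls[names(df)]
  }
  meta <- make_dim_meta(df, kinds = kinds, levels = lvls)
  vals <- as_tibble(map2(df, meta$kind, coerce_column))
  new_dataset(vals, meta, record_ids, labels)
}

# nominal level order as declared in the @attribute header lines
arff_declared_levels <- function(path) {
  header <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0 || grepl("^\\s*@data", line, ignore.case = TRUE)) break
    header <- c(header, line)
  }
  attr_lines <- grep("^\\s*@attribute", header, ignore.case = TRUE,
                     value = TRUE)
  out <- list()
  for (line in attr_lines) {
    m <- regmatches(line, regexec(
      "^\\s*@attribute\\s+('[^']+'|\"[^\"]+\"|\\S+)\\s+\\{([^}]*)\\}",
      line, ignore.case = TRUE))[[1]]
    if (length(m) == 3) {
      nm <- gsub("^['\"]|['\"]$", "", m[2])
      out[[nm]] <- trimws(strsplit(m[3], ",")[[1]])
    }
  }
  out
}

#' Write a dataset as CSV
#'
#' The label column, when present, is appended as the last column under the
#' given name.
#'
#' @param ds An `ss_dataset`.
#' @param path Output path.
#' @param label_column Name for the label column.
#' @param id_column Name for the record-id column; `NULL` omits it.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, label_column = "class",
                          id_column = "record_id") {
  out <- ds$values
  if (!is.null(ds$labels)) out[[label_column]] <- unname(ds$labels)
  if (!is.null(id_column)) {
    out <- dplyr::bind_cols(tibble(!!id_column := ds$record_ids), out)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
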