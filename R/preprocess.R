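#' Preprocessing audit report
#'
#' Each preprocessing step ([drop_incomplete_records()], [encode_nominal()],
#' [normalize_minmax()]) attaches a cumulative report to the dataset it
#' returns, so a piped chain keeps a full audit trail of what was dropped,
#' recoded and rescaled.
#'
#' @param ds A dataset returned by a preprocessing step.
#' @return A list of class `ss_preprocess_report` with elements
#'   `n_dropped_records`, `dropped_ids`, `encoded_dims` (named list of
#'   level-to-code mappings), `normalized_dims` (tibble of name/min/max) and
#'   `constant_dims`.
#' @export
preprocess_report <- function(ds) {
  rep <- attr(ds, "preprocess_report")
  if (is.null(rep)) rep <- empty_report()
  rep
}

empty_report <- function() {
  structure(
    list(n_dropped_records = 0L, dropped_ids = character(0),
         encoded_dims = list(),
         normalized_dims = tibble(name = character(0), min = double(0),
                                  max = double(0)),
         constant_dims = character(0)),
    class = "ss_preprocess_report"
  )
}

merge_report <- function(ds, new) {
  rep <- preprocess_report(ds)
  rep$n_dropped_records <- rep$n_dropped_records + (new$n_dropped_records %||% 0L)
  rep$dropped_ids <- c(rep$dropped_ids, new$dropped_ids)
  rep$encoded_dims <- c(rep$encoded_dims, new$encoded_dims)
  if (!is.null(new$normalized_dims)) {
    rep$normalized_dims <- bind_rows(rep$normalized_dims, new$normalized_dims)
  }
  rep$constant_dims <- union(rep$constant_dims, new$constant_dims)
  rep
}

#' @export
print.ss_preprocess_report <- function(x, ...) {
  cat("<preprocess report>\n")
  cat("  dropped records:", x$n_dropped_records, "\n")
  cat("  encoded dims:   ", length(x$encoded_dims), "\n")
  cat("  normalized dims:", nrow(x$normalized_dims), "\n")
  if (length(x$constant_dims)) {
    cat("  constant dims:  ", paste(x$constant_dims, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Remove records with any missing value
#'
#' Complete-case filtering: a record is kept only if every dimension value is
#' present.  Record order is preserved and labels are filtered consistently.
#'
#' @param ds An `ss_dataset`.
#' @return The filtered dataset, with the dropped ids recorded in its
#'   [preprocess_report()].
#' @export
drop_incomplete_records <- function(ds) {
  stopifnot(inherits(ds, "ss_dataset"))
  complete <- !apply(is.na(ds$values), 1, any)
  if (!any(complete)) {
    abort("every record has a missing value; nothing would remain")
  }
  out <- new_dataset(ds$values[complete, , drop = FALSE], ds$dim_meta,
                     ds$record_ids[complete],
                     if (!is.null(ds$labels)) ds$labels[complete])
  rep <- merge_report(ds, list(
    n_dropped_records = sum(!complete),
    dropped_ids = ds$record_ids[!complete]
  ))
  attr(out, "preprocess_report") <- rep
  out
}

#' Encode nominal dimensions as integer codes
#'
#' Binary dimensions map their two levels to 0 and 1 in declared level order
#' (first level becomes 0).  Categorical dimensions with k > 2 levels map to
#' the integer codes 0..k-1, again in declared order, keeping one column per
#' dimension.  Numeric dimensions are untouched.  The level-to-code mappings
#' are recorded in the [preprocess_report()].
#'
#' @param ds An `ss_dataset`.
#' @return The dataset with every dimension numeric.
#' @export
encode_nominal <- function(ds) {
  stopifnot(inherits(ds, "ss_dataset"))
  meta <- ds$dim_meta
  vals <- ds$values
  mappings <- list()
  for (i in seq_len(nrow(meta))) {
    if (meta$kind[i] == "numeric") next
    lev <- meta$levels[[i]]
    col <- as.character(vals[[i]])
    extra <- setdiff(unique(col[!is.na(col)]), lev)
    if (length(extra)) {
      abort(paste0("dimension ", meta$name[i],
                   " has values outside its declared levels: ",
                   paste(extra, collapse = ", ")))
    }
    codes <- setNames(seq_along(lev) - 1L, lev)
    vals[[i]] <- as.numeric(codes[col])
    mappings[[meta$name[i]]] <- codes
    obs <- vals[[i]][!is.na(vals[[i]])]
    if (length(obs)) {
      meta$observed_min[i] <- min(obs)
      meta$observed_max[i] <- max(obs)
    }
  }
  out <- new_dataset(vals, meta, ds$record_ids, unname(ds$labels))
  attr(out, "preprocess_report") <- merge_report(ds, list(encoded_dims = mappings))
  out
}

#' Min-max normalization to the unit interval
#'
#' Each dimension is rescaled linearly by `(v - min) / (max - min)` using its
#' own observed minimum and maximum, so that every value falls in \[0, 1\]
#' and all dimensions carry equal weight downstream.  A constant dimension
#' (min equal to max) would divide by zero; it is mapped to 0 with a warning
#' and listed under `constant_dims` in the report.  The transform is
#' idempotent: data already spanning \[0, 1\] is unchanged.
#'
#' @param ds A fully numeric `ss_dataset` without missing values (run
#'   [drop_incomplete_records()] and [encode_nominal()] first).
#' @return The normalized dataset.
#' @export
normalize_minmax <- function(ds) {
  check_numeric_dataset(ds, "normalize_minmax()")
  meta <- ds$dim_meta
  vals <- ds$values
  norm_rows <- list()
  constant <- character(0)
  for (i in seq_len(nrow(meta))) {
    col <- vals[[i]]
    lo <- min(col); hi <- max(col)
    if (hi == lo) {
      vals[[i]] <- rep(0, length(col))
      constant <- c(constant, meta$name[i])
    } else {
      vals[[i]] <- (col - lo) / (hi - lo)
    }
    norm_rows[[i]] <- tibble(name = meta$name[i], min = lo, max = hi)
    meta$observed_min[i] <- min(vals[[i]])
    meta$observed_max[i] <- max(vals[[i]])
  }
  if (length(constant)) {
    warn(paste0("constant dimensions mapped to 0: ",
                paste(constant, collapse = ", ")))
  }
  out <- new_dataset(vals, meta, ds$record_ids, unname(ds$labels))
  attr(out, "preprocess_report") <- merge_report(ds, list(
    normalized_dims = bind_rows(norm_rows), constant_dims = constant
  ))
  out
}

#' Full preprocessing chain
#'
#' Convenience wrapper running [drop_incomplete_records()],
#' [encode_nominal()] and [normalize_minmax()] in that order.
#'
#' @param ds An `ss_dataset`.
#' @return A fully numeric dataset in \[0, 1\] with a cumulative
#'   [preprocess_report()].
#' @export
preprocess <- function(ds) {
  ds |> drop_incomplete_records() |> encode_nominal() |> normalize_minmax()
}

#' Split a labeled dataset by class label
#'
#' @param ds An `ss_dataset` with labels.
#' @return A named list of datasets, one per distinct label (in sorted label
#'   order); record order within each subset is preserved and `dim_meta` is
#'   shared.
#' @export
split_by_label <- function(ds) {
  stopifnot(inherits(ds, "ss_dataset"))
  if (is.null(ds$labels)) abort("dataset has no labels to split by")
  out <- list()
  for (lab in sort(unique(unname(ds$labels)))) {
    keep <- unname(ds$labels) == lab
    out[[lab]] <- new_dataset(ds$values[keep, , drop = FALSE], ds$dim_meta,
                              ds$record_ids[keep], unname(ds$labels)[keep])
  }
  out
}

#' Drop a set of dimensions from a dataset
#'
#' Used by the refinement step of the analysis workflow: dimensions found to
#' dominate every class's subspaces are removed before re-clustering, so
#' that more class-specific local structure can surface.
#'
#' @param ds An `ss_dataset`.
#' @param dims Character vector of dimension names to remove; must be a
#'   proper subset of the dataset's dimensions.
#' @return The dataset without those columns; records, labels and the
#'   remaining metadata are unchanged.
#' @export
remove_dimensions <- function(ds, dims) {
  stopifnot(inherits(ds, "ss_dataset"))
  dims <- unique(as.character(dims))
  unknown <- setdiff(dims, dim_names(ds))
  if (length(unknown)) {
    abort(paste0("unknown dimensions: ", paste(unknown, collapse = ", ")))
  }
  keep <- setdiff(dim_names(ds), dims)
  if (length(keep) == 0) abort("cannot remove every dimension")
  new_dataset(ds$values[, keep, drop = FALSE],
              ds$dim_meta[match(keep, ds$dim_meta$name), , drop = FALSE],
              ds$record_ids, unname(ds$labels))
}
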