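#' Subspace-cluster collections
#'
#' A subspace cluster pairs a set of member record ids with the set of
#' dimensions in which those members are mutually similar.  A collection is
#' an ordered tibble of such clusters -- typically pooled from many
#' clustering runs -- with one row per cluster, list-columns `members` and
#' `dimensions`, and provenance columns (`run_id`, `C`, `D`, `seed`,
#' `source`).
#'
#' @param members List of character vectors of record ids (one per cluster).
#' @param dimensions List of character vectors of dimension names.
#' @param run_id,C,D,seed,source Provenance, recycled to the number of
#'   clusters.  `source` is `"internal"` for clusters produced by this
#'   package and `"imported"` for results read from external files.
#' @param dataset_ref Identifier of the dataset the clusters are bound to.
#' @return A tibble of class `ss_clusters`.
#' @export
cluster_collection <- function(members, dimensions, run_id = NA_character_,
                               C = NA_integer_, D = NA_integer_,
                               seed = NA_integer_, source = "internal",
                               dataset_ref = NA_character_) {
  stopifnot(is.list(members), is.list(dimensions),
            length(members) == length(dimensions))
  k <- length(members)
  if (any(lengths(members) == 0)) abort("clusters must have at least one member")
  if (any(lengths(dimensions) == 0)) {
    abort("clusters must have at least one dimension")
  }
  out <- tibble(
    cluster_id = paste0("c", seq_len(k)),
    members = map(members, as.character),
    dimensions = map(dimensions, as.character),
    run_id = rep_len(as.character(run_id), k),
    C = rep_len(as.integer(C), k),
    D = rep_len(as.integer(D), k),
    seed = rep_len(as.integer(seed), k),
    source = rep_len(as.character(source), k)
  )
  attr(out, "dataset_ref") <- dataset_ref
  class(out) <- c("ss_clusters", class(out))
  out
}

restore_clusters <- function(tbl, template) {
  attr(tbl, "dataset_ref") <- attr(template, "dataset_ref")
  if (!inherits(tbl, "ss_clusters")) class(tbl) <- c("ss_clusters", class(tbl))
  tbl
}

#' Check a collection against the dataset it is bound to
#'
#' @param coll An [cluster_collection()].
#' @param ds The bound `ss_dataset`.
#' @return `coll`, invisibly; errors if any member or dimension id is not in
#'   the dataset's universe.
#' @export
validate_clusters <- function(coll, ds) {
  bad_m <- setdiff(unique(unlist(coll$members)), ds$record_ids)
  if (length(bad_m)) {
    abort(paste0("unknown record ids in collection: ",
                 paste(head(bad_m, 5), collapse = ", ")))
  }
  bad_d <- setdiff(unique(unlist(coll$dimensions)), dim_names(ds))
  if (length(bad_d)) {
    abort(paste0("unknown dimensions in collection: ",
                 paste(head(bad_d, 5), collapse = ", ")))
  }
  invisible(coll)
}

#' Set dissimilarities between id sets
#'
#' All three measures are dissimilarities in \[0, 1\]:
#' `jaccard = 1 - |A∩B| / |A∪B|`, `dice = 1 - 2|A∩B| / (|A| + |B|)`, and
#' `overlap = 1 - |A∩B| / min(|A|, |B|)`.  By convention
#' `d(∅, ∅) = 0` and `d(∅, X) = 1` for non-empty `X`, which keeps pairwise
#' matrices total where the ratio would be 0/0.
#'
#' @param A,B Vectors treated as sets (duplicates ignored).
#' @param measure `"jaccard"`, `"dice"` or `"overlap"`.
#' @return A dissimilarity in \[0, 1\], symmetric in `A` and `B`.
#' @export
set_distance <- function(A, B, measure = c("jaccard", "dice", "overlap")) {
  measure <- arg_match(measure)
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 && length(B) == 0) return(0)
  if (length(A) == 0 || length(B) == 0) return(1)
  inter <- length(intersect(A, B))
  sim <- switch(measure,
    jaccard = inter / length(union(A, B)),
    dice = 2 * inter / (length(A) + length(B)),
    overlap = inter / min(length(A), length(B))
  )
  1 - sim
}

#' Pairwise dissimilarity matrix over a collection
#'
#' Computes the chosen set dissimilarity between every pair of clusters,
#' applied to either their dimension sets (how alike the subspaces are) or
#' their member sets (how alike the patient groups are).
#'
#' @param coll An [cluster_collection()] with at least two clusters.
#' @inheritParams set_distance
#' @param basis `"dimensions"` or `"members"`.
#' @return A symmetric `k x k` matrix of class `ss_distmat` with zero
#'   diagonal, cluster ids as dimnames, and `measure` / `basis` attributes.
#' @export
pairwise_distances <- function(coll, measure = c("jaccard", "dice", "overlap"),
                               basis = c("dimensions", "members")) {
  measure <- arg_match(measure)
  basis <- arg_match(basis)
  k <- nrow(coll)
  if (k < 2) abort("need at least 2 clusters for pairwise distances")
  sets <- map(coll[[basis]], unique)
  m <- matrix(0, k, k, dimnames = list(coll$cluster_id, coll$cluster_id))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- set_distance(sets[[i]], sets[[j]], measure)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  structure(m, measure = measure, basis = basis,
            cluster_order = coll$cluster_id, class = c("ss_distmat", "matrix"))
}

#' Filter specifications for cluster collections
#'
#' A flat filter: a list of clauses combined with a single AND or OR.  For
#' nested logic, apply several specs in sequence.  Clause constructors:
#' `dim_count_range()` and `member_count_range()` bound the subspace or
#' cluster size, `must_include_dims()` keeps clusters whose subspace
#' contains every named dimension, `must_exclude_dims()` those containing
#' none of them.
#'
#' @param ... Clauses built with the constructors below.
#' @param combine `"AND"` or `"OR"`.
#' @return An object of class `ss_filter_spec`.
#' @export
filter_spec <- function(..., combine = c("AND", "OR")) {
  combine <- arg_match(combine)
  clauses <- list(...)
  ok <- map_lgl(clauses, ~ inherits(.x, "ss_filter_clause"))
  if (length(clauses) && !all(ok)) abort("clauses must be built with the clause constructors")
  structure(list(clauses = clauses, combine = combine),
            class = "ss_filter_spec")
}

new_clause <- function(kind, payload) {
  structure(list(kind = kind, payload = payload), class = "ss_filter_clause")
}

#' @rdname filter_spec
#' @param lo,hi Inclusive bounds.
#' @export
dim_count_range <- function(lo, hi) {
  if (lo > hi) abort("range must have lo <= hi")
  new_clause("dim_count_range", c(lo = lo, hi = hi))
}

#' @rdname filter_spec
#' @export
member_count_range <- function(lo, hi) {
  if (lo > hi) abort("range must have lo <= hi")
  new_clause("member_count_range", c(lo = lo, hi = hi))
}

#' @rdname filter_spec
#' @param dims Character vector of dimension names.
#' @export
must_include_dims <- function(dims) new_clause("must_include_dims", as.character(dims))

#' @rdname filter_spec
#' @export
must_exclude_dims <- function(dims) new_clause("must_exclude_dims", as.character(dims))

clause_matches <- function(clause, members, dimensions) {
  switch(clause$kind,
    dim_count_range = {
      n <- length(dimensions)
      n >= clause$payload[["lo"]] && n <= clause$payload[["hi"]]
    },
    member_count_range = {
      n <- length(members)
      n >= clause$payload[["lo"]] && n <= clause$payload[["hi"]]
    },
    must_include_dims = all(clause$payload %in% dimensions),
    must_exclude_dims = !any(clause$payload %in% dimensions),
    abort(paste0("unknown clause kind: ", clause$kind))
  )
}

#' Apply a filter spec to a collection
#'
#' An empty clause list keeps every cluster.  The logical keep-mask, aligned
#' with the input order, is attached as the `"kept"` attribute so callers
#' can render filtered-out clusters greyed rather than dropped.
#'
#' @param coll An [cluster_collection()].
#' @param spec An [filter_spec()].
#' @return The filtered collection with attribute `kept` (logical mask over
#'   the input clusters).
#' @export
apply_filter <- function(coll, spec) {
  stopifnot(inherits(spec, "ss_filter_spec"))
  if (length(spec$clauses) == 0) {
    keep <- rep(TRUE, nrow(coll))
  } else {
    hit <- map(spec$clauses, function(cl) {
      map_lgl(seq_len(nrow(coll)), function(i) {
        clause_matches(cl, coll$members[[i]], coll$dimensions[[i]])
      })
    })
    hits <- do.call(cbind, hit)
    keep <- if (spec$combine == "AND") apply(hits, 1, all) else apply(hits, 1, any)
  }
  out <- restore_clusters(coll[keep, , drop = FALSE], coll)
  attr(out, "kept") <- keep
  out
}

#' Dimension occurrence counts across a collection
#'
#' How many clusters' subspaces contain each dimension -- the quantity
#' behind the dimension-distribution barchart and the aggregation-table
#' column order.
#'
#' @param coll An [cluster_collection()].
#' @param all_dims Optional character vector of the full dimension universe;
#'   dimensions absent from every cluster are then reported with count 0.
#' @return A tibble with columns `dimension` and `count`, sorted by
#'   decreasing count with ties broken by name.
#' @export
dimension_occurrence <- function(coll, all_dims = NULL) {
  counts <- table(unlist(map(coll$dimensions, unique)))
  out <- tibble(dimension = names(counts), count = as.integer(counts))
  if (!is.null(all_dims)) {
    missing <- setdiff(all_dims, out$dimension)
    out <- bind_rows(out, tibble(dimension = missing,
                                 count = integer(length(missing))))
  }
  arrange(out, desc(count), dimension)
}

#' Read and write cluster collections
#'
#' The native format is JSON:
#' `{dataset_ref, clusters: [{cluster_id, members, dimensions, provenance}]}`.
#' `read_results()` also accepts a plain-text dialect compatible with
#' subspace-clustering toolkits built on WEKA, with one cluster per line: a
#' bracketed 0/1 dimension mask followed by whitespace-separated 0-based
#' record indices, e.g. `[1 0 1] 0 2 5`.  Clusters imported from that
#' dialect are tagged `source = "imported"`.
#'
#' @param path File path.
#' @param coll An [cluster_collection()].
#' @param format `"json"` or `"opensubspace"` (`"auto"` sniffs the first
#'   character).
#' @param dim_names,record_ids Universe used to decode the text dialect's
#'   positional indices (required for `"opensubspace"`).
#' @return `read_results()` returns an `ss_clusters`; `write_results()`
#'   returns `path` invisibly.  Writing then reading (or the reverse) is the
#'   identity on the native format.
#' @export
write_results <- function(coll, path) {
  obj <- list(
    dataset_ref = attr(coll, "dataset_ref"),
    clusters = map(seq_len(nrow(coll)), function(i) {
      list(cluster_id = coll$cluster_id[i],
           members = coll$members[[i]],
           dimensions = coll$dimensions[[i]],
           provenance = list(run_id = coll$run_id[i], C = coll$C[i],
                             D = coll$D[i], seed = coll$seed[i],
                             source = coll$source[i]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("auto", "json", "opensubspace"),
                         dim_names = NULL, record_ids = NULL) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    first <- substr(trimws(readLines(path, n = 1, warn = FALSE)), 1, 1)
    format <- if (identical(first, "{")) "json" else "opensubspace"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    cl <- obj$clusters
    if (length(cl) == 0) abort("results file contains no clusters")
    out <- cluster_collection(
      members = map(cl, ~ as.character(unlist(.x$members))),
      dimensions = map(cl, ~ as.character(unlist(.x$dimensions))),
      run_id = map_chr(cl, ~ .x$provenance$run_id %||% NA_character_),
      C = map_int(cl, ~ as.integer(.x$provenance$C %||% NA)),
      D = map_int(cl, ~ as.integer(.x$provenance$D %||% NA)),
      seed = map_int(cl, ~ as.integer(.x$provenance$seed %||% NA)),
      source = map_chr(cl, ~ .x$provenance$source %||% "imported"),
      dataset_ref = obj$dataset_ref %||% NA_character_
    )
    out$cluster_id <- map_chr(cl, ~ .x$cluster_id %||% NA_character_)
    return(out)
  }
  if (is.null(dim_names) || is.null(record_ids)) {
    abort("dim_names and record_ids are required to import the text dialect")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("results file contains no clusters")
  parsed <- imap(lines, function(line, lineno) {
    m <- regmatches(line, regexec("^\\s*\\[([^]]*)\\]\\s*(.*)$", line))[[1]]
    if (length(m) != 3) {
      abort(paste0("line ", lineno, ": expected '[mask] indices'"))
    }
    mask <- suppressWarnings(as.integer(strsplit(trimws(m[2]), "\\s+")[[1]]))
    if (anyNA(mask) || !all(mask %in% c(0L, 1L))) {
      abort(paste0("line ", lineno, ": mask must be 0/1 values"))
    }
    if (length(mask) != length(dim_names)) {
      abort(paste0("line ", lineno, ": mask length ", length(mask),
                   " != number of dimensions ", length(dim_names)))
    }
    idx <- suppressWarnings(as.integer(strsplit(trimws(m[3]), "\\s+")[[1]]))
    if (length(idx) == 0 || anyNA(idx)) {
      abort(paste0("line ", lineno, ": missing or non-integer record indices"))
    }
    if (any(idx < 0 | idx >= length(record_ids))) {
      abort(paste0("line ", lineno, ": record index out of range"))
    }
    list(dims = dim_names[mask == 1L], members = record_ids[idx + 1L])
  })
  cluster_collection(
    members = map(parsed, "members"),
    dimensions = map(parsed, "dims"),
    source = "imported"
  )
}

#' Export a distance matrix as CSV with cluster labels
#'
#' @param dm An `ss_distmat` from [pairwise_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path) {
  out <- as_tibble(unclass(dm))
  out <- dplyr::bind_cols(tibble(cluster_id = rownames(dm)), out)
  readr::write_csv(out, path)
  invisible(path)
}
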