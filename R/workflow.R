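#' Detect globally dominant dimensions across class-wise clusterings
#'
#' A dimension that turns up in most subspaces of *every* class reflects
#' global similarity between records rather than anything class-specific;
#' such dimensions crowd out local structure and are candidates for removal
#' before re-clustering.  Formally, a dimension is dominant iff within each
#' label's pooled collection it occurs in at least a fraction `tau` of that
#' label's clusters.  The rule is monotone in `tau`: raising the threshold
#' can only shrink the result.
#'
#' @param collections A named list with one [cluster_collection()] (or list
#'   of `proclus_result`) per class label; must be non-empty, and every
#'   collection must contain at least one cluster.
#' @param tau Occurrence threshold in (0, 1\]; default 0.5.
#' @return A sorted character vector of dominant dimension names (possibly
#'   empty).
#' @export
detect_dominant_dimensions <- function(collections, tau = 0.5) {
  if (length(collections) == 0) abort("need at least one collection per label")
  if (tau <= 0 || tau > 1) abort("tau must be in (0, 1]")
  per_label <- map(collections, function(coll) {
    if (is.list(coll) && !inherits(coll, "ss_clusters")) {
      coll <- pool_results(coll)
    }
    if (nrow(coll) == 0) abort("empty collection for one label")
    occ <- dimension_occurrence(coll)
    occ$dimension[occ$count / nrow(coll) >= tau]
  })
  sort(Reduce(intersect, per_label))
}

#' Lowest-variance dimensions of a whole dataset
#'
#' The single-cluster analogue of per-medoid subspace selection: treating
#' all records of a (sub)dataset as one cluster, the `D` dimensions with the
#' smallest variance are the ones in which the records are globally most
#' similar.  Useful for characterizing a class subset as a whole, where a
#' partition into several clusters is not meaningful.
#'
#' @param ds A fully numeric, missing-free `ss_dataset`.
#' @param D Number of dimensions to return.
#' @return Character vector of `D` dimension names, ordered by increasing
#'   variance (ties by column position).
#' @export
single_cluster_dims <- function(ds, D) {
  X <- values_matrix(ds)
  if (D > ncol(X)) abort("D exceeds the number of dimensions")
  v <- apply(X, 2, var)
  colnames(X)[order(v, seq_along(v))[seq_len(D)]]
}

#' Workflow configuration
#'
#' @param do_split Split by class label first (skipped with a log note when
#'   labels are absent).
#' @param C_values,D_values,seeds Sweep grid passed to [run_sweep()].
#' @param refine Run the dominant-dimension refinement: detect (or take
#'   `manual_dims`), remove, re-sweep on the remaining dimensions.
#' @param tau Dominance threshold for [detect_dominant_dimensions()].
#' @param manual_dims Optional expert-chosen dimensions to remove instead of
#'   the detected set (the human-in-the-loop path).
#' @param filters A list of [filter_spec()]s applied in sequence to each
#'   pooled collection.
#' @param proclus_args Further arguments passed on to [proclus()].
#' @return A list of class `ss_workflow_config`.
#' @export
workflow_config <- function(do_split = TRUE, C_values = 2:4, D_values = 3:6,
                            seeds = 1L, refine = TRUE, tau = 0.5,
                            manual_dims = NULL, filters = list(),
                            proclus_args = list()) {
  if (tau <= 0 || tau > 1) abort("tau must be in (0, 1]")
  structure(
    list(do_split = do_split, C_values = C_values, D_values = D_values,
         seeds = as.integer(seeds), refine = refine, tau = tau,
         manual_dims = manual_dims, filters = filters,
         proclus_args = proclus_args),
    class = "ss_workflow_config"
  )
}

#' Run the class-split / refine / re-cluster workflow
#'
#' The three-step procedure for relating records, dimensions and class
#' labels: (1) split the records by class label, so each class is clustered
#' on its own; (2) optionally detect dimensions that dominate every class's
#' subspaces and remove them; (3) cluster the remaining dimensions with a
#' parameter sweep, pooling clusters across settings.  Both the
#' pre-refinement and (when enabled) post-refinement pooled collections are
#' evaluated and returned; the post-refinement collections are asserted to
#' contain none of the removed dimensions.
#'
#' @param ds A preprocessed (numeric, missing-free) `ss_dataset`; labels are
#'   required when `do_split` is `TRUE`.
#' @param config An [workflow_config()].
#' @param out_dir Optional directory; when given, evaluation CSVs, pooled
#'   collections (JSON), embeddings (CSV) and a JSON manifest are written.
#' @return An `ss_workflow_report`: list with `pre` and `post` (named lists
#'   of pooled collections per label), `dominant_dims`, `evaluations`
#'   (tibble with `phase` and `label` columns), `embeddings`, `log`, and
#'   `config`.
#' @export
run_workflow <- function(ds, config = workflow_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ss_workflow_config"))
  check_numeric_dataset(ds, "run_workflow()")
  log <- character(0)
  if (config$do_split && !is.null(ds$labels)) {
    subsets <- split_by_label(ds)
  } else {
    if (config$do_split) {
      log <- c(log, "no class labels present; class-split step skipped")
    } else {
      log <- c(log, "class-split step disabled by configuration")
    }
    subsets <- list(all = ds)
  }

  sweep_and_pool <- function(sub, label) {
    res <- do.call(run_sweep, c(
      list(ds = sub, C_values = config$C_values[config$C_values <= n_records(sub)],
           D_values = config$D_values[config$D_values <= n_dims(sub)],
           seeds = config$seeds),
      config$proclus_args))
    pool_results(res, dataset_ref = label)
  }

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("workflow stage '", label, "' failed: ",
                   conditionMessage(e)))
    })
  }

  pre <- imap(subsets, function(sub, lab) {
    stage(paste0("cluster[", lab, "]"), sweep_and_pool(sub, lab))
  })

  dominant <- character(0)
  post <- NULL
  if (config$refine) {
    dominant <- stage("detect_dominant_dimensions", {
      if (!is.null(config$manual_dims)) {
        config$manual_dims
      } else {
        detect_dominant_dimensions(pre, tau = config$tau)
      }
    })
    if (length(dominant) == 0) {
      log <- c(log, "refinement enabled but no dominant dimensions found")
    } else if (length(dominant) >= n_dims(ds)) {
      log <- c(log, "refinement skipped: dominant set covers every dimension")
      dominant <- character(0)
    } else {
      post <- imap(subsets, function(sub, lab) {
        stage(paste0("recluster[", lab, "]"),
              sweep_and_pool(remove_dimensions(sub, dominant), lab))
      })
      for (coll in post) {      # hard invariant: removed dims never reappear
        stopifnot(!any(dominant %in% unlist(coll$dimensions)))
      }
    }
  }

  apply_filters <- function(colls) {
    if (length(config$filters) == 0 || is.null(colls)) return(colls)
    map(colls, function(coll) {
      for (spec in config$filters) coll <- apply_filter(coll, spec)
      coll
    })
  }
  pre_f <- apply_filters(pre)
  post_f <- apply_filters(post)

  eval_phase <- function(colls, phase) {
    if (is.null(colls)) return(NULL)
    bind_rows(imap(colls, function(coll, lab) {
      if (nrow(coll) == 0) return(NULL)
      # label scores use the full dataset's label universe: a within-class
      # subset is single-labeled, so K must come from the parent dataset
      mutate(evaluate_clusters(coll, subsets[[lab]], labels = ds$labels),
             phase = phase, label = lab, .before = 1)
    }))
  }
  evaluations <- bind_rows(eval_phase(pre_f, "pre"), eval_phase(post_f, "post"))

  embed_phase <- function(colls, phase) {
    if (is.null(colls)) return(list())
    out <- list()
    for (lab in names(colls)) {
      if (nrow(colls[[lab]]) >= 2) {
        dm <- pairwise_distances(colls[[lab]], "jaccard", "dimensions")
        out[[paste(phase, lab, sep = "_")]] <- mds_embed(dm)
      }
    }
    out
  }
  embeddings <- c(embed_phase(pre_f, "pre"), embed_phase(post_f, "post"))

  report <- structure(
    list(pre = pre_f, post = post_f, dominant_dims = dominant,
         evaluations = evaluations, embeddings = embeddings, log = log,
         config = config),
    class = "ss_workflow_report"
  )
  if (!is.null(out_dir)) write_workflow_report(report, out_dir)
  report
}

#' @export
print.ss_workflow_report <- function(x, ...) {
  cat("<workflow report>\n")
  for (lab in names(x$pre)) {
    cat(sprintf("  pre[%s]: %d clusters\n", lab, nrow(x$pre[[lab]])))
  }
  if (length(x$dominant_dims)) {
    cat("  dominant dims:", paste(x$dominant_dims, collapse = ", "), "\n")
  }
  for (lab in names(x$post %||% list())) {
    cat(sprintf("  post[%s]: %d clusters\n", lab, nrow(x$post[[lab]])))
  }
  for (line in x$log) cat("  note:", line, "\n")
  invisible(x)
}

#' Write all workflow artifacts to a directory
#'
#' @param report An `ss_workflow_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_workflow_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  save_collection <- function(coll, name) {
    p <- file.path(out_dir, paste0(name, ".json"))
    write_results(coll, p)
    artifacts[[name]] <<- basename(p)
  }
  for (lab in names(report$pre)) {
    save_collection(report$pre[[lab]], paste0("clusters_pre_", lab))
  }
  for (lab in names(report$post %||% list())) {
    save_collection(report$post[[lab]], paste0("clusters_post_", lab))
  }
  if (!is.null(report$evaluations) && nrow(report$evaluations) > 0) {
    readr::write_csv(report$evaluations, file.path(out_dir, "evaluation.csv"))
    artifacts[["evaluation"]] <- "evaluation.csv"
  }
  for (nm in names(report$embeddings)) {
    f <- paste0("embedding_", nm, ".csv")
    write_embedding(report$embeddings[[nm]], file.path(out_dir, f))
    artifacts[[paste0("embedding_", nm)]] <- f
  }
  manifest <- list(
    dominant_dims = report$dominant_dims,
    config = report$config[c("do_split", "C_values", "D_values", "seeds",
                             "refine", "tau")],
    log = report$log,
    artifacts = artifacts,
    version = as.character(packageVersion("subspacer"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "workflow_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
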