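#' Specification for a synthetic planted-subspace dataset
#'
#' The generator plants Gaussian clusters inside disjoint subspaces on a
#' Uniform(0, 1) background: members of a planted cluster are drawn
#' `Normal(mean, sigma_in)` (clipped to \[0, 1\]) on that cluster's subspace
#' dimensions and uniformly everywhere else, which is exactly the
#' low-variance-per-dimension structure a projected-clustering algorithm is
#' built to detect.  Optional extras emulate features of real clinical
#' tables: globally dominant dimensions on which *every* record is
#' concentrated, nominal 0/1 dimensions generated as yes/no strings (so the
#' encoding step is exercised), fully-background noise records with
#' coin-flip labels, and missing values injected after the ground truth is
#' fixed.
#'
#' @param n_records,n_dims Table shape (noise records included in
#'   `n_records`).
#' @param clusters List of planted clusters, each a list with `size`,
#'   `subspace_size`, `label`, optional `mean_profile` (per-subspace-dim
#'   means in \[0, 1\]; defaults to an alternating 0.15 / 0.85 pattern
#'   rotated per cluster, which keeps planted clusters well separated) and
#'   optional `sigma_in` (default 0.05).
#' @param n_global_dims Number of globally dominant dimensions: every record
#'   is drawn `Normal(global_mean, sigma)` except for a small
#'   `global_outlier_rate` fraction drawn from the Uniform(0, 1) background.
#'   The outliers anchor the observed range, so the bulk stays concentrated
#'   even after per-dimension min-max normalization -- the pattern of a
#'   clinical marker on which almost all patients agree.
#' @param global_mean Mean of the global dimensions.
#' @param global_outlier_rate Fraction of records drawn from the background
#'   on each global dimension (default 0.05).
#' @param n_noise_records Records drawn entirely from the background.
#' @param n_categorical_dims Background dimensions replaced by nominal
#'   yes/no columns (Bernoulli with a cluster-specific rate).
#' @param missing_rate Fraction of cells set to missing, uniformly at
#'   random, after ground truth is recorded.
#' @param seed Integer seed; the same spec and seed always generate
#'   byte-identical output.
#' @return A list of class `ss_synth_spec`.
#' @export
synth_spec <- function(n_records, n_dims, clusters, n_global_dims = 0,
                       global_mean = 0.5, global_outlier_rate = 0.05,
                       n_noise_records = 0, n_categorical_dims = 0,
                       missing_rate = 0, seed = 1) {
  sizes <- map_int(clusters, ~ as.integer(.x$size))
  sub_sizes <- map_int(clusters, ~ as.integer(.x$subspace_size))
  if (sum(sizes) + n_noise_records != n_records) {
    abort("cluster sizes plus noise records must sum to n_records")
  }
  if (any(sub_sizes < 1)) abort("subspace sizes must be >= 1")
  if (sum(sub_sizes) + n_global_dims > n_dims) {
    abort("disjoint planted subspaces plus global dims exceed n_dims")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  structure(
    list(n_records = as.integer(n_records), n_dims = as.integer(n_dims),
         clusters = clusters, n_global_dims = as.integer(n_global_dims),
         global_mean = global_mean, global_outlier_rate = global_outlier_rate,
         n_noise_records = as.integer(n_noise_records),
         n_categorical_dims = as.integer(n_categorical_dims),
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "ss_synth_spec"
  )
}

default_profile <- function(subspace_size, cluster_index) {
  base <- rep(c(0.15, 0.85), length.out = subspace_size + cluster_index - 1)
  base[cluster_index:(cluster_index + subspace_size - 1)]
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a dataset with planted subspace clusters
#'
#' @param spec An [synth_spec()].
#' @return A list with elements `dataset` (an `ss_dataset` with labels) and
#'   `truth`, an `ss_ground_truth` list recording `membership` (named
#'   per-record cluster id, `"noise"` for background records), `subspaces`
#'   (named list of planted dimension sets), `global_dims` and `labels`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "ss_synth_spec"))
  withr::with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  n <- spec$n_records; d <- spec$n_dims
  dims <- sprintf("dim%02d", seq_len(d))
  record_ids <- sprintf("r%03d", seq_len(n))
  k <- length(spec$clusters)

  global_dims <- if (spec$n_global_dims > 0) dims[seq_len(spec$n_global_dims)] else character(0)
  cursor <- spec$n_global_dims
  subspaces <- list()
  for (i in seq_len(k)) {
    s <- spec$clusters[[i]]$subspace_size
    subspaces[[paste0("t", i)]] <- dims[(cursor + 1):(cursor + s)]
    cursor <- cursor + s
  }

  # background everywhere, then overwrite planted structure
  m <- matrix(runif(n * d), n, d, dimnames = list(record_ids, dims))

  membership <- setNames(rep("noise", n), record_ids)
  labels <- setNames(rep(NA_character_, n), record_ids)
  row0 <- 0L
  for (i in seq_len(k)) {
    cl <- spec$clusters[[i]]
    rows <- (row0 + 1):(row0 + cl$size)
    row0 <- row0 + cl$size
    sigma <- cl$sigma_in %||% 0.05
    profile <- cl$mean_profile %||% default_profile(cl$subspace_size, i)
    stopifnot(length(profile) == cl$subspace_size)
    sub <- subspaces[[paste0("t", i)]]
    for (j in seq_along(sub)) {
      m[rows, sub[j]] <- clip01(rnorm(length(rows), profile[j], sigma))
    }
    membership[rows] <- paste0("t", i)
    labels[rows] <- cl$label
  }
  if (spec$n_noise_records > 0) {
    noise_rows <- (n - spec$n_noise_records + 1):n
    lab_pool <- unique(map_chr(spec$clusters, "label"))
    labels[noise_rows] <- sample(lab_pool, length(noise_rows), replace = TRUE)
  }
  sigma_g <- min(map_dbl(spec$clusters, ~ .x$sigma_in %||% 0.05))
  for (g in global_dims) {
    v <- clip01(rnorm(n, spec$global_mean, sigma_g))
    spread <- runif(n) < spec$global_outlier_rate
    v[spread] <- runif(sum(spread))
    m[, g] <- v
  }

  truth <- structure(
    list(membership = membership, subspaces = subspaces,
         global_dims = global_dims, labels = labels),
    class = "ss_ground_truth"
  )

  vals <- as_tibble(as.data.frame(m))
  meta <- make_dim_meta(vals)

  # nominal columns: thresholded background dims become yes/no strings with a
  # cluster-specific rate, exercising the encoding step downstream
  if (spec$n_categorical_dims > 0) {
    planted <- c(global_dims, unlist(subspaces))
    free <- setdiff(dims, planted)
    if (length(free) < spec$n_categorical_dims) {
      abort("not enough background dimensions for n_categorical_dims")
    }
    cat_dims <- free[seq_len(spec$n_categorical_dims)]
    rates <- setNames(runif(k, 0.2, 0.8), paste0("t", i = seq_len(k)))
    for (cd in cat_dims) {
      q <- ifelse(membership == "noise", 0.5, rates[membership])
      vals[[cd]] <- ifelse(runif(n) < q, "yes", "no")
    }
    meta <- make_dim_meta(vals)
  }

  if (spec$missing_rate > 0) {
    holes <- which(runif(n * d) < spec$missing_rate)
    for (h in holes) {
      r <- ((h - 1) %% n) + 1
      cidx <- ((h - 1) %/% n) + 1
      vals[r, cidx] <- NA
    }
    meta <- make_dim_meta(vals)
  }

  ds <- new_dataset(vals, meta, record_ids, unname(labels))
  list(dataset = ds, truth = truth)
}

#' Ready-made spec shaped like a small two-class clinical cohort
#'
#' Mirrors the shape of the kind of vaccination-outcome table this package
#' targets: 71 records in two outcome classes of 29 (`pos`) and 42 (`neg`),
#' 61 mixed binary/numeric dimensions, a block of 11 globally dominant
#' dimensions, and one planted class-specific subspace per class.  Values
#' are synthetic throughout -- only the shape is modeled on real cohorts.
#'
#' @param seed Integer seed.
#' @return An [synth_spec()].
#' @export
demo_cohort_spec <- function(seed = 1) {
  synth_spec(
    n_records = 71, n_dims = 61,
    clusters = list(
      list(size = 29, subspace_size = 5, label = "pos"),
      list(size = 42, subspace_size = 5, label = "neg")
    ),
    n_global_dims = 11,
    n_categorical_dims = 10,
    seed = seed
  )
}

#' @export
print.ss_synth_spec <- function(x, ...) {
  cat(sprintf("<synth spec> %d records x %d dims, %d planted clusters",
              x$n_records, x$n_dims, length(x$clusters)))
  if (x$n_global_dims > 0) cat(",", x$n_global_dims, "global dims")
  if (x$n_noise_records > 0) cat(",", x$n_noise_records, "noise records")
  cat(", seed", x$seed, "\n")
  invisible(x)
}

#' Write a synthetic ground truth as JSON
#'
#' @param truth An `ss_ground_truth` from [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(membership = as.list(truth$membership),
         subspaces = truth$subspaces,
         global_dims = truth$global_dims,
         labels = as.list(truth$labels)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
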