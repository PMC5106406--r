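#' Manhattan segmental distance
#'
#' The per-dimension-averaged city-block distance PROCLUS uses inside a
#' cluster's subspace: `(1/|dims|) * sum over d in dims of |x_d - y_d|`.
#' Averaging (rather than summing) makes distances comparable across
#' subspaces of different dimensionality.
#'
#' @param x,y Numeric vectors defined on all of `dims` (named, or indexed by
#'   position).
#' @param dims Dimension names or indices to restrict to; must be non-empty.
#' @return A non-negative number.
#' @export
manhattan_segmental_distance <- function(x, y, dims) {
  if (length(dims) == 0) abort("dims must be non-empty")
  mean(abs(x[dims] - y[dims]))
}

# distance from every row of X to point m, restricted to dims (vectorized)
msd_to_point <- function(X, m, dims) {
  sub <- X[, dims, drop = FALSE]
  rowMeans(abs(sweep(sub, 2, m[dims])))
}

#' Greedy farthest-first medoid candidates
#'
#' Picks `count` well-scattered records: the first uniformly at random
#' (seeded), each next one the record maximizing its minimum full-space
#' segmental distance to those already chosen.  Ties break to the lowest
#' record index, so the result is deterministic given the seed.
#'
#' @param ds A fully numeric, missing-free `ss_dataset`.
#' @param count Number of candidates, at most `n_records(ds)`.
#' @param seed Integer seed for the initial draw.
#' @return An ordered character vector of record ids.
#' @export
greedy_medoid_candidates <- function(ds, count, seed = 1) {
  X <- values_matrix(ds)
  if (count > nrow(X)) abort("count exceeds the number of records")
  idx <- withr::with_seed(seed, greedy_farthest_first(X, count))
  rownames(X)[idx]
}

greedy_farthest_first <- function(X, count, pool = seq_len(nrow(X))) {
  chosen <- pool[sample.int(length(pool), 1)]
  if (count == 1) return(chosen)
  alldims <- seq_len(ncol(X))
  mind <- msd_to_point(X[pool, , drop = FALSE], X[chosen, ], alldims)
  for (i in 2:count) {
    nxt <- pool[which.max(mind)]      # which.max takes the first (lowest) index
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, msd_to_point(X[pool, , drop = FALSE], X[nxt, ], alldims))
    mind[pool %in% chosen] <- -Inf
  }
  chosen
}

#' Per-medoid subspace selection
#'
#' For each medoid, its locality is the set of records within the full-space
#' segmental distance to the nearest other medoid; an empty locality falls
#' back to the `ceiling(n/C)` nearest records.  The mean absolute deviation
#' `X[i, j]` of the locality from the medoid is computed per dimension,
#' standardized to Z-scores within each medoid, and the `C * D` globally
#' smallest Z values are taken greedily subject to at least two dimensions
#' per medoid.  When a medoid's deviations are all equal (zero spread), its
#' dimensions rank by smallest raw deviation instead.  All ties break to the
#' lowest index.
#'
#' @param ds A fully numeric, missing-free `ss_dataset`.
#' @param medoids Character vector of at least two medoid record ids.
#' @param D Average subspace dimensionality (so `C * D` dimension slots are
#'   distributed, `C = length(medoids)`).
#' @return A named list of dimension-name sets, one per medoid, whose sizes
#'   sum to `C * D`.
#' @export
find_dimensions <- function(ds, medoids, D) {
  X <- values_matrix(ds)
  midx <- match(medoids, rownames(X))
  if (anyNA(midx)) abort("unknown medoid record id")
  sets <- find_dimensions_impl(X, midx, D)
  lapply(sets, function(j) colnames(X)[j])
}

find_dimensions_impl <- function(X, midx, D) {
  C <- length(midx)
  if (C < 2) abort("need at least 2 medoids (locality radius is the distance to the nearest other medoid)")
  if (D < 2) abort("average dimensionality D must be at least 2")
  n <- nrow(X); d <- ncol(X)
  alldims <- seq_len(d)
  # locality radius: full-space distance to nearest other medoid
  Z <- matrix(NA_real_, C, d)
  Xdev <- matrix(NA_real_, C, d)
  for (i in seq_len(C)) {
    dist_to_others <- vapply(midx[-i], function(m) {
      manhattan_segmental_distance(X[midx[i], ], X[m, ], alldims)
    }, numeric(1))
    delta <- min(dist_to_others)
    dall <- msd_to_point(X, X[midx[i], ], alldims)
    loc <- which(dall < delta)
    if (length(loc) <= 1) {                       # degenerate: take nearest n/C
      loc <- order(dall)[seq_len(min(n, ceiling(n / C)))]
    }
    dev <- colMeans(abs(sweep(X[loc, , drop = FALSE], 2, X[midx[i], ])))
    Xdev[i, ] <- dev
    s <- sd(dev)
    Z[i, ] <- if (is.na(s) || s == 0) rep(0, d) else (dev - mean(dev)) / s
  }
  # greedy pick: two smallest per medoid first, then the global remainder
  ord_key <- function(i) order(Z[i, ], Xdev[i, ], seq_len(d))
  picked <- vector("list", C)
  taken <- matrix(FALSE, C, d)
  for (i in seq_len(C)) {
    first2 <- ord_key(i)[1:2]
    picked[[i]] <- first2
    taken[i, first2] <- TRUE
  }
  remaining <- D * C - 2 * C
  if (remaining > 0) {
    cand <- expand.grid(medoid = seq_len(C), dim = seq_len(d))
    cand <- cand[!taken[cbind(cand$medoid, cand$dim)], ]
    key_z <- Z[cbind(cand$medoid, cand$dim)]
    key_x <- Xdev[cbind(cand$medoid, cand$dim)]
    cand <- cand[order(key_z, key_x, cand$medoid, cand$dim), ]
    take <- cand[seq_len(remaining), ]
    for (r in seq_len(nrow(take))) {
      i <- take$medoid[r]
      picked[[i]] <- c(picked[[i]], take$dim[r])
    }
  }
  lapply(picked, sort)
}

# assign every record to the medoid minimizing the segmental distance under
# that medoid's dimension set; ties to the lowest medoid index
assign_records <- function(X, midx, dimsets) {
  D <- vapply(seq_along(midx), function(i) {
    msd_to_point(X, X[midx[i], ], dimsets[[i]])
  }, numeric(nrow(X)))
  list(cluster = max.col(-D, ties.method = "first"), dist = D)
}

# objective: cluster-size-weighted mean segmental distance of members to
# their cluster centroid, each cluster under its own dimension set
evaluate_assignment <- function(X, assign, dimsets) {
  n <- nrow(X)
  total <- 0
  for (i in seq_along(dimsets)) {
    rows <- which(assign == i)
    if (length(rows) == 0) next
    sub <- X[rows, dimsets[[i]], drop = FALSE]
    centroid <- colMeans(sub)
    w <- mean(rowMeans(abs(sweep(sub, 2, centroid))))
    total <- total + length(rows) * w
  }
  total / n
}

#' PROCLUS projected clustering
#'
#' Partitions a fully numeric dataset into `C` clusters, each with its own
#' relevant dimension set of average size `D`, following the classic
#' medoid-based projected-clustering scheme: a random sample of
#' `min(n, sample_factor * C)` records is thinned to a greedy farthest-first
#' pool of `min(sample, greedy_factor * C)` candidate medoids; the iterative
#' phase repeatedly selects per-medoid dimension sets ([find_dimensions()]),
#' assigns every record to its nearest medoid under that medoid's subspace,
#' scores the configuration, and swaps "bad" medoids (the smallest cluster,
#' plus any below `min_deviation * n / C` members) for unused pool
#' candidates, keeping the best configuration seen; it stops after
#' `max_iterations` swaps without improvement.  A refinement pass recomputes
#' dimension sets from the final clusters (rather than localities) and
#' reassigns once; with `handle_outliers`, a record becomes an outlier when
#' its distance to its nearest medoid exceeds that medoid's sphere of
#' influence (its smallest distance to another medoid under its own
#' dimension set).
#'
#' @param ds A fully numeric, missing-free `ss_dataset`.
#' @param C Target number of clusters (at least 1; at most `n_records`).
#' @param D Average subspace dimensionality per cluster (at least 2, so
#'   every cluster can receive its mandatory two dimensions).
#' @param sample_factor,greedy_factor Sampling multipliers for the candidate
#'   pool (defaults 30 and 3).
#' @param max_iterations Stop after this many consecutive non-improving
#'   medoid swaps (default 30).
#' @param min_deviation Fraction of the expected cluster size `n / C` below
#'   which a cluster's medoid is declared bad (default 0.1).
#' @param handle_outliers Mark records outside every medoid's sphere of
#'   influence as outliers instead of forcing them into a cluster.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   results.
#' @return An object of class `proclus_result`: a list with `clusters` (an
#'   [cluster_collection()]), `outliers` (character record ids), `objective`,
#'   `iterations` and `params`.
#' @export
proclus <- function(ds, C, D, sample_factor = 30, greedy_factor = 3,
                    max_iterations = 30, min_deviation = 0.1,
                    handle_outliers = TRUE, seed = 1) {
  X <- values_matrix(ds)
  n <- nrow(X)
  C <- as.integer(C); D <- as.integer(D)
  if (C < 1) abort("C must be at least 1")
  if (C > n) abort("C cannot exceed the number of records")
  if (C * D < 2 * C) abort("C * D must be at least 2 * C (every cluster needs >= 2 dimensions)")
  params <- list(C = C, D = D, sample_factor = sample_factor,
                 greedy_factor = greedy_factor,
                 max_iterations = max_iterations,
                 min_deviation = min_deviation,
                 handle_outliers = handle_outliers, seed = as.integer(seed))
  res <- withr::with_seed(seed, proclus_impl(X, params))
  coll <- cluster_collection(
    members = res$members, dimensions = res$dimensions,
    run_id = sprintf("C%d_D%d_s%d", C, D, seed),
    C = C, D = D, seed = seed, source = "internal"
  )
  structure(
    list(clusters = coll, outliers = res$outliers, objective = res$objective,
         iterations = res$iterations, params = params),
    class = "proclus_result"
  )
}

proclus_impl <- function(X, p) {
  n <- nrow(X)
  C <- p$C
  sample_idx <- sort(sample.int(n, min(n, p$sample_factor * C)))
  pool_size <- min(length(sample_idx), p$greedy_factor * C)
  pool <- greedy_farthest_first(X, pool_size, pool = sample_idx)
  current <- sort(sample(pool, C))

  best <- list(objective = Inf, medoids = current, dims = NULL, assign = NULL)
  stale <- 0L; iter <- 0L
  while (stale < p$max_iterations && iter < 10L * p$max_iterations) {
    iter <- iter + 1L
    dimsets <- find_dimensions_impl(X, current, p$D)
    asg <- assign_records(X, current, dimsets)
    obj <- evaluate_assignment(X, asg$cluster, dimsets)
    if (obj < best$objective) {
      best <- list(objective = obj, medoids = current, dims = dimsets,
                   assign = asg$cluster)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    # swap bad medoids of the best configuration for unused pool candidates
    sizes <- tabulate(best$assign, nbins = C)
    bad <- union(which.min(sizes), which(sizes < n / C * p$min_deviation))
    unused <- setdiff(pool, best$medoids)
    if (length(unused) == 0 || length(bad) == 0) break
    bad <- bad[seq_len(min(length(bad), length(unused)))]
    replacement <- sample(unused, length(bad))
    current <- best$medoids
    current[bad] <- replacement
    current <- sort(current)
  }

  # refinement: dimension sets from the final clusters, one reassignment
  medoids <- best$medoids
  dimsets <- refine_dimensions(X, medoids, best$assign, p$D)
  asg <- assign_records(X, medoids, dimsets)
  cluster_of <- asg$cluster

  outliers <- integer(0)
  if (p$handle_outliers && C >= 2) {
    sphere <- vapply(seq_len(C), function(i) {
      min(vapply(seq_len(C)[-i], function(j) {
        manhattan_segmental_distance(X[medoids[i], ], X[medoids[j], ],
                                     dimsets[[i]])
      }, numeric(1)))
    }, numeric(1))
    nearest_dist <- asg$dist[cbind(seq_len(n), cluster_of)]
    outliers <- which(nearest_dist > sphere[cluster_of])
    cluster_of[outliers] <- NA_integer_
  }

  keep <- which(tabulate(cluster_of[!is.na(cluster_of)], nbins = C) > 0)
  list(
    members = lapply(keep, function(i) rownames(X)[which(cluster_of == i)]),
    dimensions = lapply(keep, function(i) colnames(X)[dimsets[[i]]]),
    outliers = rownames(X)[outliers],
    objective = evaluate_assignment(X, cluster_of, dimsets),
    iterations = iter
  )
}

# dimension selection for the refinement phase: deviations measured over the
# actual cluster members instead of medoid localities
refine_dimensions <- function(X, midx, assign, D) {
  C <- length(midx)
  d <- ncol(X)
  Z <- matrix(NA_real_, C, d)
  Xdev <- matrix(NA_real_, C, d)
  for (i in seq_len(C)) {
    rows <- which(assign == i)
    if (length(rows) <= 1) rows <- unique(c(rows, midx[i]))
    dev <- colMeans(abs(sweep(X[rows, , drop = FALSE], 2, X[midx[i], ])))
    Xdev[i, ] <- dev
    s <- sd(dev)
    Z[i, ] <- if (is.na(s) || s == 0) rep(0, d) else (dev - mean(dev)) / s
  }
  picked <- vector("list", C)
  taken <- matrix(FALSE, C, d)
  for (i in seq_len(C)) {
    first2 <- order(Z[i, ], Xdev[i, ], seq_len(d))[1:2]
    picked[[i]] <- first2
    taken[i, first2] <- TRUE
  }
  remaining <- D * C - 2 * C
  if (remaining > 0) {
    cand <- expand.grid(medoid = seq_len(C), dim = seq_len(d))
    cand <- cand[!taken[cbind(cand$medoid, cand$dim)], ]
    key_z <- Z[cbind(cand$medoid, cand$dim)]
    key_x <- Xdev[cbind(cand$medoid, cand$dim)]
    cand <- cand[order(key_z, key_x, cand$medoid, cand$dim), ]
    take <- cand[seq_len(remaining), ]
    for (r in seq_len(nrow(take))) {
      i <- take$medoid[r]
      picked[[i]] <- c(picked[[i]], take$dim[r])
    }
  }
  lapply(picked, sort)
}

#' @export
print.proclus_result <- function(x, ...) {
  cat(sprintf("<proclus result> C=%d D=%d seed=%d: %d clusters, %d outliers, objective %.4f\n",
              x$params$C, x$params$D, x$params$seed, nrow(x$clusters),
              length(x$outliers), x$objective))
  invisible(x)
}

#' @export
tidy.proclus_result <- function(x, ...) {
  mutate(as_tibble(x$clusters),
         n_members = lengths(.data$members),
         n_dims = lengths(.data$dimensions))
}

#' @export
glance.proclus_result <- function(x, ...) {
  tibble(C = x$params$C, D = x$params$D, seed = x$params$seed,
         n_clusters = nrow(x$clusters), n_outliers = length(x$outliers),
         objective = x$objective, iterations = x$iterations)
}

#' Parameter sweep over cluster counts and dimensionalities
#'
#' Runs [proclus()] for every `(C, D, seed)` triple in Cartesian-product
#' order (`C` outer, `D` middle, `seed` inner).  Pairs with `D < 2` are
#' skipped with a warning.  Pooling the clusters of all runs into one
#' collection (see [pool_results()]) is how a large space of parameter
#' settings is explored jointly instead of run by run.
#'
#' @param ds A fully numeric, missing-free `ss_dataset`.
#' @param C_values,D_values Integer vectors of parameter values (non-empty).
#' @param seeds Integer vector of seeds (non-empty).
#' @param ... Further arguments passed to [proclus()].
#' @return A list of `proclus_result`, one per valid triple.
#' @export
run_sweep <- function(ds, C_values, D_values, seeds = 1L, ...) {
  if (length(C_values) == 0 || length(D_values) == 0 || length(seeds) == 0) {
    abort("C_values, D_values and seeds must be non-empty")
  }
  bad_D <- D_values[D_values < 2]
  if (length(bad_D)) {
    warn(paste0("skipping invalid D values (< 2): ",
                paste(unique(bad_D), collapse = ", ")))
    D_values <- D_values[D_values >= 2]
  }
  out <- list()
  for (C in C_values) for (D in D_values) for (s in seeds) {
    out[[length(out) + 1]] <- proclus(ds, C = C, D = D, seed = s, ...)
  }
  out
}

#' Pool clusters from many runs into one collection
#'
#' @param results A list of `proclus_result` (e.g. from [run_sweep()]).
#' @param dataset_ref Optional dataset identifier for the pooled collection.
#' @return An [cluster_collection()] with all clusters in run order,
#'   re-keyed with unique cluster ids.
#' @export
pool_results <- function(results, dataset_ref = NA_character_) {
  if (inherits(results, "proclus_result")) results <- list(results)
  colls <- map(results, "clusters")
  out <- bind_rows(colls)
  out$cluster_id <- paste0("c", seq_len(nrow(out)))
  attr(out, "dataset_ref") <- dataset_ref
  class(out) <- c("ss_clusters", class(out))
  out
}
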