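#' Two-dimensional MDS embedding of a cluster dissimilarity matrix
#'
#' The overview plot of a pooled collection: each cluster becomes a point,
#' and inter-point distances approximate the chosen set dissimilarity.
#' `method = "classical"` is Torgerson double-centering with the top two
#' eigenpairs and a canonical orientation (axes ordered by eigenvalue, each
#' axis's sign fixed so its lowest-index non-zero coordinate is positive),
#' hence fully deterministic.  `method = "smacof"` is iterative stress
#' majorization from a seeded random start, which can fit non-Euclidean
#' matrices more faithfully.  Kruskal stress-1 is reported either way.
#'
#' @param dm An `ss_distmat` from [pairwise_distances()] (symmetric,
#'   zero-diagonal, entries in \[0, 1\]), `k >= 2`.
#' @param method `"classical"` or `"smacof"`.
#' @param seed Integer seed (used by `"smacof"` only).
#' @param max_iter,tol Iteration controls for `"smacof"`.
#' @return An `ss_embedding`: a tibble with columns `cluster_id`, `x`, `y`
#'   (one row per cluster, in collection order) and attributes `stress`,
#'   `method`, plus the matrix's `measure` / `basis` provenance.
#' @export
mds_embed <- function(dm, method = c("classical", "smacof"), seed = 1,
                      max_iter = 500, tol = 1e-10) {
  method <- arg_match(method)
  m <- unclass(dm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix must be symmetric")
  if (min(m) < 0 || max(m) > 1 + 1e-12) abort("distances must lie in [0, 1]")
  k <- nrow(m)
  if (k < 2) abort("need at least 2 clusters to embed")
  coords <- if (method == "classical") {
    classical_mds(m)
  } else {
    withr::with_seed(seed, smacof_mds(m, max_iter, tol))
  }
  fitted <- as.matrix(dist(coords))
  denom <- sum(m^2)
  stress <- if (denom > 0) sqrt(sum((fitted - m)^2) / denom) else 0
  ids <- rownames(m) %||% paste0("c", seq_len(k))
  out <- tibble(cluster_id = ids, x = coords[, 1], y = coords[, 2])
  attr(out, "stress") <- stress
  attr(out, "method") <- method
  attr(out, "measure") <- attr(dm, "measure")
  attr(out, "basis") <- attr(dm, "basis")
  class(out) <- c("ss_embedding", class(out))
  out
}

classical_mds <- function(m) {
  k <- nrow(m)
  J <- diag(k) - matrix(1 / k, k, k)
  B <- -0.5 * J %*% (m^2) %*% J
  e <- eigen(B, symmetric = TRUE)           # eigenvalues in decreasing order
  lam <- pmax(e$values[1:2], 0)
  coords <- e$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(lam), 2)
  for (a in 1:2) {                          # canonical sign per axis
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1], a] < 0) coords[, a] <- -coords[, a]
  }
  coords
}

smacof_mds <- function(m, max_iter, tol) {
  k <- nrow(m)
  X <- matrix(runif(k * 2, -0.5, 0.5), k, 2)
  d <- as.matrix(dist(X))
  sigma_old <- sum((m - d)^2) / 2
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, m / d, 0)
    Bm <- -ratio
    diag(Bm) <- 0
    diag(Bm) <- -rowSums(Bm)
    X <- Bm %*% X / k                      # Guttman transform
    d <- as.matrix(dist(X))
    sigma <- sum((m - d)^2) / 2
    if (abs(sigma_old - sigma) < tol) break
    sigma_old <- sigma
  }
  sweep(X, 2, colMeans(X))
}

#' Small multiples: one embedding per measure/basis configuration
#'
#' @param coll An [cluster_collection()] with at least two clusters.
#' @param configs A list of `list(measure =, basis =)` pairs.
#' @param ... Passed to [mds_embed()].
#' @return A list of `ss_embedding`, sharing the collection's row order.
#' @export
small_multiples <- function(coll, configs, ...) {
  map(configs, function(cfg) {
    mds_embed(pairwise_distances(coll, cfg$measure, cfg$basis), ...)
  })
}

#' Per-cluster color values for overview plots
#'
#' Computes the scalar that drives cluster coloring in the MDS overview.
#' Modes: `"n_dims"` and `"n_members"` are the literal set sizes;
#' `"compactness"` is [compactness()]; `"dimension:<name>"` is the cluster
#' mean of one dimension; `"purity"` is the signed majority score
#' `s = +/-(2 * p_majority - 1)`, positive when the majority label is the
#' alphabetically first class, mapped onto a diverging blue/brown scale
#' whose bright midpoint is an even mixture.
#'
#' @param coll An [cluster_collection()].
#' @param ds The bound `ss_dataset` (needed for compactness and dimension
#'   modes).
#' @param labels Named per-record labels (needed for purity mode); defaults
#'   to the dataset's labels.
#' @param mode One of `"n_dims"`, `"n_members"`, `"compactness"`,
#'   `"purity"`, or `"dimension:<name>"`.
#' @return A tibble with `cluster_id` and `value`, with a `scale` attribute
#'   describing the palette (diverging blue/brown for purity, sequential
#'   otherwise).
#' @export
color_values <- function(coll, ds = NULL, labels = ds$labels,
                         mode = "n_dims") {
  scale <- list(palette = "sequential", low = "#f7fbff", high = "#08306b")
  if (mode == "n_dims") {
    val <- lengths(coll$dimensions)
  } else if (mode == "n_members") {
    val <- lengths(coll$members)
  } else if (mode == "compactness") {
    if (is.null(ds)) abort("compactness mode needs the dataset")
    val <- map_dbl(seq_len(nrow(coll)), function(i) {
      compactness(ds, coll$members[[i]], coll$dimensions[[i]])
    })
  } else if (mode == "purity") {
    if (is.null(labels)) abort("purity mode needs labels")
    first_class <- sort(unique(unname(labels)))[1]
    val <- map_dbl(coll$members, function(mem) {
      mp <- majority_purity(mem, labels)
      s <- 2 * mp$purity - 1
      if (identical(mp$majority, first_class)) s else -s
    })
    scale <- list(palette = "diverging", low = "#8c510a", mid = "#f5f5f5",
                  high = "#2166ac", midpoint = 0)
  } else if (grepl("^dimension:", mode)) {
    dim <- sub("^dimension:", "", mode)
    if (is.null(ds)) abort("dimension mode needs the dataset")
    if (!dim %in% dim_names(ds)) abort(paste0("unknown dimension: ", dim))
    X <- values_matrix(ds)
    val <- map_dbl(coll$members, ~ mean(X[.x, dim]))
  } else {
    abort(paste0("unknown color mode: ", mode))
  }
  out <- tibble(cluster_id = coll$cluster_id, value = as.numeric(val))
  attr(out, "scale") <- scale
  attr(out, "mode") <- mode
  out
}

#' Seriation of a distance matrix for heatmap display
#'
#' `order = "hclust"` computes the leaf order of average-linkage
#' hierarchical clustering on the dissimilarities (deterministic; ties in
#' the merge sequence resolve by index), so similar clusters sit next to
#' each other and block structure becomes visible.  `order = "none"` keeps
#' the input order.
#'
#' @param dm An `ss_distmat`.
#' @param order `"hclust"` or `"none"`.
#' @return A list with `order` (a permutation of `1:k`) and `matrix` (the
#'   reordered matrix, still symmetric).
#' @export
heatmap_order <- function(dm, order = c("hclust", "none")) {
  order <- arg_match(order)
  m <- unclass(dm)
  perm <- if (order == "none" || nrow(m) < 3) {
    seq_len(nrow(m))
  } else {
    hclust(stats::as.dist(m), method = "average")$order
  }
  list(order = perm, matrix = m[perm, perm, drop = FALSE])
}

#' Aggregation table: per-cluster value distributions by dimension
#'
#' A cluster-by-dimension grid summarizing the member values of each cluster
#' in each dimension, next to the global distribution over all records.
#' Columns are ordered by how many of the collection's subspaces contain the
#' dimension (descending, name tie-break), with subspace membership flagged
#' per cell.  Numeric dimensions are summarized as a "barcode" of counts
#' over `n_bins` equal-width bins on \[0, 1\] (so the data must be
#' normalized); binary/categorical dimensions as a histogram of counts per
#' level code.
#'
#' @param coll An [cluster_collection()].
#' @param ds The bound, preprocessed `ss_dataset`.
#' @param n_bins Number of barcode bins for numeric dimensions.
#' @return An `ss_aggtable`: a list with `cells` (tibble: `cluster_id`,
#'   `dimension`, `in_subspace`, list-column `counts`), `dim_order`,
#'   `global` (tibble: `dimension`, `counts`) and `n_bins`.  Every cell's
#'   counts sum to the cluster size; global counts sum to `n_records`.
#' @export
aggregation_table <- function(coll, ds, n_bins = 20) {
  check_numeric_dataset(ds, "aggregation_table()")
  validate_clusters(coll, ds)
  X <- values_matrix(ds)
  if (min(X) < 0 || max(X) > 1) {
    abort("aggregation_table() expects normalized values in [0, 1]")
  }
  occ <- dimension_occurrence(coll, all_dims = dim_names(ds))
  dim_order <- occ$dimension
  summarise_values <- function(v, kind, levels) {
    if (kind == "numeric") {
      breaks <- seq(0, 1, length.out = n_bins + 1)
      counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                              n_bins), nbins = n_bins)
      setNames(as.integer(counts),
               sprintf("bin%02d", seq_len(n_bins)))
    } else {
      codes <- seq_along(levels) - 1L
      counts <- vapply(codes, function(cd) sum(v == cd), integer(1))
      setNames(counts, levels)
    }
  }
  meta <- ds$dim_meta
  global <- map(dim_order, function(dn) {
    i <- match(dn, meta$name)
    summarise_values(X[, dn], meta$kind[i], meta$levels[[i]])
  })
  cells <- list()
  for (ci in seq_len(nrow(coll))) {
    mem <- coll$members[[ci]]
    sub_dims <- coll$dimensions[[ci]]
    for (dn in dim_order) {
      i <- match(dn, meta$name)
      cells[[length(cells) + 1]] <- tibble(
        cluster_id = coll$cluster_id[ci], dimension = dn,
        in_subspace = dn %in% sub_dims,
        counts = list(summarise_values(X[mem, dn], meta$kind[i],
                                       meta$levels[[i]]))
      )
    }
  }
  structure(
    list(cells = bind_rows(cells), dim_order = dim_order,
         global = tibble(dimension = dim_order, counts = global),
         n_bins = n_bins),
    class = "ss_aggtable"
  )
}

#' @export
print.ss_aggtable <- function(x, ...) {
  cat(sprintf("<aggregation table> %d clusters x %d dimensions (%d-bin barcodes)\n",
              length(unique(x$cells$cluster_id)), length(x$dim_order), x$n_bins))
  invisible(x)
}

#' Table-lens report of one cluster's records
#'
#' One row per member with the raw dimension values, optionally stably
#' sorted by one dimension, plus a parallel flag table driving cell
#' coloring.  In `"quartiles"` mode each numeric value is flagged `low`
#' (below the first quartile), `high` (above the third), `outlier_low` /
#' `outlier_high` (beyond 1.5 IQR, Tukey's rule) or `mid`; quartiles use
#' linear-interpolation quantiles.  In `"categories"` mode the flag is the
#' level itself, one color per level present.
#'
#' @param members Character vector of member record ids (non-empty).
#' @param ds The bound `ss_dataset`.
#' @param sort_dim Optional dimension name to sort rows by (stable sort).
#' @param color `"quartiles"` or `"categories"`.
#' @return An `ss_tablelens`: list with `data` (tibble, first column
#'   `record_id`) and `flags` (same shape, character codes).
#' @export
table_lens <- function(members, ds, sort_dim = NULL,
                       color = c("quartiles", "categories")) {
  color <- arg_match(color)
  if (length(members) == 0) abort("cluster has no members")
  if (!is.null(sort_dim) && !sort_dim %in% dim_names(ds)) {
    abort(paste0("unknown sort dimension: ", sort_dim))
  }
  rows <- match(members, ds$record_ids)
  if (anyNA(rows)) abort("unknown record ids")
  data <- ds$values[rows, , drop = FALSE]
  ids <- ds$record_ids[rows]
  if (!is.null(sort_dim)) {
    ord <- order(data[[sort_dim]])          # order() is a stable sort
    data <- data[ord, , drop = FALSE]
    ids <- ids[ord]
  }
  flag_column <- function(v, kind) {
    if (color == "categories" || kind != "numeric") return(as.character(v))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    dplyr::case_when(
      v < q[1] - 1.5 * iqr ~ "outlier_low",
      v > q[2] + 1.5 * iqr ~ "outlier_high",
      v < q[1] ~ "low",
      v > q[2] ~ "high",
      TRUE ~ "mid"
    )
  }
  flags <- as_tibble(map2(data, ds$dim_meta$kind, flag_column))
  structure(
    list(data = dplyr::bind_cols(tibble(record_id = ids), data),
         flags = dplyr::bind_cols(tibble(record_id = ids), flags),
         sort_dim = sort_dim, color = color),
    class = "ss_tablelens"
  )
}

#' @export
print.ss_tablelens <- function(x, ...) {
  cat(sprintf("<table lens> %d records x %d dimensions, %s coloring\n",
              nrow(x$data), ncol(x$data) - 1, x$color))
  invisible(x)
}

#' Write a table-lens report to disk
#'
#' Emits `<path>` as CSV of raw values and `<path base>_flags.csv` with the
#' color codes, so the rendered report can be rebuilt without re-running.
#'
#' @param tl An `ss_tablelens`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_lens <- function(tl, path) {
  readr::write_csv(tl$data, path)
  readr::write_csv(tl$flags, sub("\\.csv$", "_flags.csv", path))
  invisible(path)
}

#' Glyph spike data for cluster dots
#'
#' For each cluster, every dimension of its subspace becomes a spike around
#' the border of its dot: the angle encodes the dimension's position in the
#' dataset's column order (`2 * pi * (index - 1) / n_dims`), the color index
#' cycles through a fixed 10-color palette (`(index - 1) mod 10`, so every
#' 10th dimension shares a color), and the length encodes importance.
#' `importance = "inverse_spread"` maps length to
#' `1 - sd_within_cluster / sd_global`, clipped to \[0.2, 1\] (long spikes =
#' dimensions where the cluster is much tighter than the data as a whole;
#' 0.2 when the global spread is zero); `"constant"` gives unit length.
#' This machine-readable sidecar is what figures are drawn from and what
#' tests inspect -- no rendered image is ever parsed.
#'
#' @param coll An [cluster_collection()].
#' @param ds The bound `ss_dataset`.
#' @param importance `"inverse_spread"` or `"constant"`.
#' @return A tibble with columns `cluster_id`, `dimension`, `dim_index`
#'   (1-based dataset column position), `angle`, `color_index` (0-9) and
#'   `length`.
#' @export
glyph_data <- function(coll, ds, importance = c("inverse_spread", "constant")) {
  importance <- arg_match(importance)
  validate_clusters(coll, ds)
  X <- values_matrix(ds)
  nd <- n_dims(ds)
  global_sd <- apply(X, 2, sd)
  rows <- list()
  for (i in seq_len(nrow(coll))) {
    dims <- coll$dimensions[[i]]
    idx <- match(dims, dim_names(ds))
    len <- if (importance == "constant") {
      rep(1, length(dims))
    } else {
      gsd <- global_sd[dims]
      csd <- apply(X[coll$members[[i]], dims, drop = FALSE], 2, sd)
      ifelse(gsd > 0, pmin(1, pmax(0.2, 1 - csd / gsd)), 0.2)
    }
    rows[[i]] <- tibble(
      cluster_id = coll$cluster_id[i], dimension = dims, dim_index = idx,
      angle = 2 * pi * (idx - 1) / nd,
      color_index = (idx - 1L) %% 10L,
      length = as.numeric(len)
    )
  }
  bind_rows(rows)
}

#' Glyph figure: embedded clusters with dimension spikes
#'
#' Draws each cluster at its embedding position with its subspace spikes
#' (see [glyph_data()]).  When `path` is given, writes the figure plus a
#' `<path>.csv` sidecar of the spike data.
#'
#' @param coll An [cluster_collection()].
#' @param ds The bound `ss_dataset`.
#' @param embedding An `ss_embedding` with one row per cluster.
#' @param importance Passed to [glyph_data()].
#' @param path Optional figure path (`.png` or `.svg` by extension).
#' @param spike_scale Spike length in embedding units.
#' @return The ggplot object, invisibly when writing to `path`.
#' @export
glyph_figure <- function(coll, ds, embedding,
                         importance = c("inverse_spread", "constant"),
                         path = NULL, spike_scale = 0.05) {
  if (nrow(embedding) != nrow(coll)) {
    abort("embedding must have one row per cluster")
  }
  spikes <- glyph_data(coll, ds, importance)
  spikes <- left_join(spikes,
                      select(as_tibble(embedding), "cluster_id", "x", "y"),
                      by = "cluster_id")
  spikes <- mutate(spikes,
    xend = .data$x + spike_scale * .data$length * cos(.data$angle),
    yend = .data$y + spike_scale * .data$length * sin(.data$angle))
  pal <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
           "#e6ab02", "#a6761d", "#666666", "#1f78b4", "#b2df8a")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = spikes,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend,
                   colour = factor(.data$color_index, levels = 0:9))) +
    ggplot2::geom_point(data = as_tibble(embedding),
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE,
                                 name = "dim index mod 10") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2")
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 6, dpi = 150)
    readr::write_csv(select(spikes, -"x", -"y", -"xend", -"yend"),
                     paste0(path, ".csv"))
    return(invisible(p))
  }
  p
}

#' @export
autoplot.ss_embedding <- function(object, colour = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(colour)) df$colour <- colour$value[match(df$cluster_id,
                                                        colour$cluster_id)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "MDS 1", y = "MDS 2",
      title = sprintf("%s on %s (stress %.3f)", attr(object, "measure"),
                      attr(object, "basis"), attr(object, "stress")))
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 2)
  }
}

#' Heatmap plot of a (reordered) distance matrix
#'
#' Darker cells are more dissimilar cluster pairs.
#'
#' @param dm An `ss_distmat`.
#' @param order Passed to [heatmap_order()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(dm, order = "hclust") {
  ho <- heatmap_order(dm, order)
  m <- ho$matrix
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  df$row_id <- factor(rownames(m)[df$row], levels = rev(rownames(m)))
  df$col_id <- factor(colnames(m)[df$col], levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_id, y = .data$row_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#f7f7f7", high = "#252525",
                                 limits = c(0, 1), name = "dissimilarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write an embedding as CSV
#'
#' @param embedding An `ss_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  readr::write_csv(as_tibble(embedding), path)
  invisible(path)
}
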