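planted_points_dm <- function(k = 50, seed = 14) {
  pts <- withr::with_seed(seed, matrix(runif(k * 2, 0, 0.5), k, 2))
  dm <- as.matrix(dist(pts, method = "euclidean"))
  dm <- dm / max(dm) * 0.99                 # keep inside [0, 1]
  rownames(dm) <- colnames(dm) <- paste0("c", seq_len(k))
  list(points = pts, dm = dm)
}

procrustes_rmse <- function(X, Y) {
  # align Y onto X by translation + rotation/reflection + scale
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(Yc^2)
  sqrt(mean((Xc - scl * Yc %*% R)^2))
}

test_that("classical MDS reconstructs planted 2-D configurations", {
  pp <- planted_points_dm()
  emb <- mds_embed(pp$dm, method = "classical")
  expect_equal(nrow(emb), 50)
  expect_equal(emb$cluster_id, rownames(pp$dm))
  scaled_pts <- pp$points / max(as.matrix(dist(pp$points))) * 0.99
  expect_lt(procrustes_rmse(scaled_pts, cbind(emb$x, emb$y)), 1e-6)
  expect_lt(attr(emb, "stress"), 1e-6)

  # independent oracle: inter-point distances match stats::cmdscale's fit
  cm <- cmdscale(pp$dm, k = 2)
  expect_equal(as.matrix(dist(cbind(emb$x, emb$y))), as.matrix(dist(cm)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two points embed at exactly their stated distance", {
  dm <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  emb <- mds_embed(dm, method = "classical")
  expect_equal(dist(cbind(emb$x, emb$y))[1], 0.6, tolerance = 1e-12)
})

test_that("degenerate and invalid matrices are handled", {
  zero <- matrix(0, 4, 4)
  emb <- mds_embed(zero, method = "classical")
  expect_equal(emb$x, rep(0, 4))
  expect_equal(emb$y, rep(0, 4))

  asym <- matrix(c(0, 0.2, 0.4, 0), 2, 2)
  expect_error(mds_embed(asym), "symmetric")
  expect_error(mds_embed(matrix(0, 1, 1)), "at least 2")
})

test_that("smacof embedding is seeded and lowers stress on hard matrices", {
  pp <- planted_points_dm(k = 20, seed = 3)
  e1 <- mds_embed(pp$dm, method = "smacof", seed = 5)
  e2 <- mds_embed(pp$dm, method = "smacof", seed = 5)
  expect_identical(e1$x, e2$x)
  expect_lt(attr(e1, "stress"), 0.05)
})

test_that("small multiples share order and react to the basis", {
  # dimension overlap differs from member overlap by construction
  coll <- cluster_collection(
    members = list(c("r1", "r2"), c("r1", "r2"), c("r5", "r6")),
    dimensions = list(c("d1", "d2"), c("d3", "d4"), c("d3", "d4"))
  )
  embs <- small_multiples(coll, list(
    list(measure = "jaccard", basis = "dimensions"),
    list(measure = "jaccard", basis = "members"),
    list(measure = "jaccard", basis = "dimensions")
  ))
  expect_length(embs, 3)
  expect_equal(embs[[1]]$cluster_id, embs[[2]]$cluster_id)
  expect_identical(embs[[1]]$x, embs[[3]]$x)        # duplicate config
  d_dim <- dist(cbind(embs[[1]]$x, embs[[1]]$y))
  d_mem <- dist(cbind(embs[[2]]$x, embs[[2]]$y))
  expect_false(isTRUE(all.equal(as.vector(d_dim), as.vector(d_mem))))
})

test_that("color values cover every mode with the documented conventions", {
  gen <- generate_dataset(global_dims_spec(seed = 4))
  ds <- preprocess(gen$dataset)
  ids <- ds$record_ids
  pos_ids <- ids[unname(ds$labels) == "pos"]
  neg_ids <- ids[unname(ds$labels) == "neg"]
  coll <- cluster_collection(
    members = list(pos_ids[1:10], c(pos_ids[1:5], neg_ids[1:5]), neg_ids[1:8]),
    dimensions = list(dim_names(ds)[1:3], dim_names(ds)[2:5],
                      dim_names(ds)[1:2])
  )
  expect_equal(color_values(coll, mode = "n_dims")$value, c(3, 4, 2))
  expect_equal(color_values(coll, mode = "n_members")$value, c(10, 10, 8))

  pur <- color_values(coll, ds, mode = "purity")
  expect_equal(pur$value, c(-1, 0, 1))   # pure pos, even, pure neg ("neg" sorts first)
  expect_equal(attr(pur, "scale")$palette, "diverging")

  cmp <- color_values(coll, ds, mode = "compactness")
  expect_equal(cmp$value[1], compactness(ds, pos_ids[1:10], dim_names(ds)[1:3]))

  dimmode <- color_values(coll, ds, mode = paste0("dimension:", dim_names(ds)[1]))
  X <- values_matrix(ds)
  expect_equal(dimmode$value[3], mean(X[neg_ids[1:8], dim_names(ds)[1]]))
  expect_error(color_values(coll, ds, mode = "dimension:nope"), "unknown dimension")
  expect_error(color_values(coll, ds, mode = "sparkle"), "unknown color mode")
})

test_that("heatmap seriation permutes without losing entries", {
  coll <- random_collection(10, paste0("r", 1:30), paste0("d", 1:10), seed = 6)
  # plant an identical pair: rows 3 and 7 get the same sets
  coll$members[[7]] <- coll$members[[3]]
  coll$dimensions[[7]] <- coll$dimensions[[3]]
  dm <- pairwise_distances(coll, "jaccard", "dimensions")

  none <- heatmap_order(dm, "none")
  expect_equal(none$order, 1:10)

  ho <- heatmap_order(dm, "hclust")
  expect_setequal(ho$order, 1:10)
  expect_true(isSymmetric(ho$matrix))
  # identical clusters merge first, so they sit adjacent in leaf order
  expect_equal(abs(diff(match(c(3, 7), ho$order))), 1)
  # entries preserved under the permutation
  expect_equal(ho$matrix, unclass(dm)[ho$order, ho$order])
})

test_that("aggregation-table counts conserve cluster sizes and records", {
  gen <- generate_dataset(synth_spec(
    n_records = 40, n_dims = 8,
    clusters = list(list(size = 40, subspace_size = 3, label = "a")),
    n_categorical_dims = 2, seed = 31
  ))
  ds <- preprocess(gen$dataset)
  coll <- random_collection(4, ds$record_ids, dim_names(ds), seed = 2)
  at <- aggregation_table(coll, ds)
  sizes <- setNames(lengths(coll$members), coll$cluster_id)
  for (i in seq_len(nrow(at$cells))) {
    expect_equal(sum(at$cells$counts[[i]]),
                 unname(sizes[at$cells$cluster_id[i]]))
  }
  expect_true(all(vapply(at$global$counts, sum, 1) == n_records(ds)))
  # in_subspace flags mirror the cluster dimension sets
  for (i in seq_len(nrow(at$cells))) {
    ci <- match(at$cells$cluster_id[i], coll$cluster_id)
    expect_equal(at$cells$in_subspace[i],
                 at$cells$dimension[i] %in% coll$dimensions[[ci]])
  }
})

test_that("aggregation-table columns sort by occurrence then name", {
  ds <- as_dataset(tibble::tibble(a = c(0, 1), b = c(0, 1), c = c(0, 1)))
  coll <- cluster_collection(
    members = list(c("0", "1"), "0", "1"),
    dimensions = list(c("b", "c"), c("b"), c("b", "a"))
  )
  at <- aggregation_table(coll, ds)
  expect_equal(at$dim_order, c("b", "a", "c"))      # 3, 1, 1 with name ties
  # a cluster holding every record reproduces the global summary
  full_row <- dplyr::filter(at$cells, .data$cluster_id == "c1",
                            .data$dimension == "a")
  expect_equal(full_row$counts[[1]],
               at$global$counts[[match("a", at$global$dimension)]])
})

test_that("table lens flags quartiles and Tukey outliers by the stated rules", {
  ds <- as_dataset(tibble::tibble(v = c(1, 2, 3, 4, 5, 6, 7, 8)))
  tl <- table_lens(ds$record_ids, ds, color = "quartiles")
  # for 1..8: Q1 = 2.75, Q3 = 6.25 under linear-interpolation quantiles
  expect_equal(tl$flags$v, c("low", "low", rep("mid", 4), "high", "high"))

  out <- as_dataset(tibble::tibble(v = c(rep(5, 9), 100)))
  tlo <- table_lens(out$record_ids, out, color = "quartiles")
  expect_equal(tlo$flags$v[10], "outlier_high")

  catds <- as_dataset(tibble::tibble(g = c("x", "y", "x", "z")))
  tlc <- table_lens(catds$record_ids, catds, color = "categories")
  expect_equal(sort(unique(tlc$flags$g)), c("x", "y", "z"))

  sorted <- table_lens(ds$record_ids, ds, sort_dim = "v")
  expect_equal(sorted$data$v, sort(ds$values$v))
  expect_setequal(sorted$data$record_id, ds$record_ids)  # rows only permuted
  expect_error(table_lens(ds$record_ids, ds, sort_dim = "nope"),
               "unknown sort dimension")
})

test_that("glyph sidecar obeys the angle, mod-10 color and spread rules", {
  gen <- generate_dataset(recovery_spec(seed = 23))
  ds <- preprocess(gen$dataset)
  ids <- names(gen$truth$membership)[gen$truth$membership == "t1"]
  # dim01 is in t1's planted subspace; dim11 and dim21 are background for t1
  dims <- dim_names(ds)[c(1, 11, 21)]
  coll <- cluster_collection(members = list(ids), dimensions = list(dims))

  gd <- glyph_data(coll, ds, importance = "constant")
  expect_equal(gd$angle, 2 * pi * (gd$dim_index - 1) / n_dims(ds))
  # dims 1, 11, 21 share palette slot 0
  expect_equal(gd$color_index, rep(0L, 3))
  expect_equal(gd$length, rep(1, 3))

  giv <- glyph_data(coll, ds, importance = "inverse_spread")
  expect_true(all(giv$length >= 0.2 & giv$length <= 1))
  # the planted subspace dim is far tighter than a background dim
  planted_len <- giv$length[giv$dimension == dim_names(ds)[1]]
  bg_len <- giv$length[giv$dimension == dim_names(ds)[21]]
  expect_gt(planted_len, bg_len)
})

test_that("view computations are pure functions of their inputs", {
  coll <- random_collection(6, paste0("r", 1:20), paste0("d", 1:8), seed = 9)
  dm <- pairwise_distances(coll, "dice", "members")
  expect_identical(mds_embed(dm), mds_embed(dm))
  expect_identical(heatmap_order(dm), heatmap_order(dm))
})

test_that("figure exports write a machine-readable sidecar", {
  gen <- generate_dataset(synth_spec(
    n_records = 30, n_dims = 6,
    clusters = list(list(size = 30, subspace_size = 2, label = "a")),
    seed = 16
  ))
  ds <- preprocess(gen$dataset)
  coll <- random_collection(3, ds$record_ids, dim_names(ds), seed = 4)
  emb <- mds_embed(pairwise_distances(coll, "jaccard", "dimensions"))
  path <- withr::local_tempfile(fileext = ".png")
  p <- glyph_figure(coll, ds, emb, path = path)
  expect_s3_class(p, "ggplot")
  expect_true(file.exists(path))
  sidecar <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  expect_equal(sort(unique(sidecar$cluster_id)), sort(coll$cluster_id))
  expect_true(all(sidecar$color_index %in% 0:9))
  expect_error(glyph_figure(coll, ds, emb[1:2, ]), "one row per cluster")
})
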