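test_that("manhattan segmental distance averages absolute differences", {
  x <- c(a = 0, b = 0, c = 0)
  y <- c(a = 1, b = 1, c = 1)
  expect_equal(manhattan_segmental_distance(x, y, c("a", "b", "c")), 1)
  x2 <- c(1, 5, 9); y2 <- c(2, 3, 9)
  expect_equal(manhattan_segmental_distance(x2, y2, 2), 2)
  expect_equal(manhattan_segmental_distance(x2, x2, 1:3), 0)
  expect_error(manhattan_segmental_distance(x2, y2, integer(0)), "non-empty")
})

test_that("greedy candidates start random and then take the farthest point", {
  ds <- as_dataset(tibble::tibble(x = c(0, 1, 10)))
  # whichever point starts, with count=2 the second pick maximizes the
  # minimum distance; from 0 or 1 that is the point at 10
  for (seed in 1:10) {
    picks <- greedy_medoid_candidates(ds, 2, seed = seed)
    if (picks[1] %in% c("0", "1")) expect_equal(picks[2], "2")
  }
  # exhaustion yields a permutation; same seed twice is identical
  all3 <- greedy_medoid_candidates(ds, 3, seed = 4)
  expect_setequal(all3, c("0", "1", "2"))
  expect_identical(greedy_medoid_candidates(ds, 3, seed = 4), all3)
  expect_error(greedy_medoid_candidates(ds, 4, seed = 1), "exceeds")
})

test_that("dimension selection finds the low-variance dims of a locality", {
  # medoid 1's neighbourhood is tightly concentrated in dims d1, d2 and
  # uniform elsewhere; medoid 2's blob is far away
  withr::with_seed(21, {
    blob1 <- tibble::tibble(
      d1 = 0.5 + rnorm(20, 0, 0.01), d2 = 0.3 + rnorm(20, 0, 0.01),
      d3 = runif(20), d4 = runif(20), d5 = runif(20), d6 = runif(20)
    )
    blob2 <- tibble::tibble(
      d1 = 5 + runif(20), d2 = 5 + runif(20), d3 = 5 + rnorm(20, 0, 0.01),
      d4 = 5 + rnorm(20, 0, 0.01), d5 = 5 + runif(20), d6 = 5 + runif(20)
    )
  })
  ds <- as_dataset(dplyr::bind_rows(blob1, blob2))
  sets <- find_dimensions(ds, medoids = c("0", "20"), D = 3)
  expect_length(sets, 2)
  expect_true(all(c("d1", "d2") %in% sets[[1]]))
  expect_true(all(c("d3", "d4") %in% sets[[2]]))
  # budget: sizes sum to C*D with at least 2 per medoid
  expect_equal(sum(lengths(sets)), 2 * 3)
  expect_true(all(lengths(sets) >= 2))
  expect_error(find_dimensions(ds, medoids = "0", D = 3), "at least 2 medoids")
})

test_that("selected dimension deviations match a brute-force Z computation", {
  withr::with_seed(33, {
    df <- tibble::tibble(
      a = rnorm(30, 0.5, 0.02), b = runif(30), c = runif(30), d = runif(30)
    )
  })
  ds <- as_dataset(df)
  X <- values_matrix(ds)
  sets <- find_dimensions(ds, medoids = c("0", "15"), D = 2)
  # oracle: for each medoid, the 2 dims with smallest Z over its locality
  brute_set <- function(mi, other) {
    delta <- mean(abs(X[mi, ] - X[other, ]))
    dall <- rowMeans(abs(sweep(X, 2, X[mi, ])))
    loc <- which(dall < delta)
    if (length(loc) <= 1) loc <- order(dall)[1:15]
    dev <- colMeans(abs(sweep(X[loc, , drop = FALSE], 2, X[mi, ])))
    z <- (dev - mean(dev)) / sd(dev)
    colnames(X)[order(z)[1:2]]
  }
  expect_setequal(sets[[1]], brute_set(1, 16))
  expect_setequal(sets[[2]], brute_set(16, 1))
})

test_that("proclus returns a partition respecting the dimension budget", {
  for (seed in 1:25) {
    spec <- synth_spec(
      n_records = 60, n_dims = 10,
      clusters = list(list(size = 30, subspace_size = 3, label = "a"),
                      list(size = 30, subspace_size = 3, label = "b")),
      seed = seed
    )
    ds <- preprocess(generate_dataset(spec)$dataset)
    res <- proclus(ds, C = 2, D = 3, seed = seed)
    members <- unlist(res$clusters$members)
    expect_false(anyDuplicated(members) > 0)                 # disjoint
    expect_setequal(c(members, res$outliers), ds$record_ids) # exhaustive
    expect_true(all(lengths(res$clusters$dimensions) >= 2))
    if (nrow(res$clusters) == 2) {
      expect_equal(sum(lengths(res$clusters$dimensions)), 2 * 3)
    }
  }
})

test_that("identical dataset, parameters and seed give bit-identical results", {
  ds <- preprocess(generate_dataset(recovery_spec(seed = 17))$dataset)
  r1 <- proclus(ds, C = 3, D = 5, seed = 23)
  r2 <- proclus(ds, C = 3, D = 5, seed = 23)
  expect_identical(r1$clusters$members, r2$clusters$members)
  expect_identical(r1$clusters$dimensions, r2$clusters$dimensions)
  expect_identical(r1$objective, r2$objective)
  r3 <- proclus(ds, C = 3, D = 5, seed = 24)
  expect_false(identical(r1$clusters$members, r3$clusters$members))
})

test_that("parameter constraints are rejected up front", {
  ds <- preprocess(generate_dataset(recovery_spec(seed = 1))$dataset)
  expect_error(proclus(ds, C = 3, D = 1, seed = 1), "2 \\* C")
  expect_error(proclus(ds, C = 301, D = 5, seed = 1), "exceed")
  raw <- generate_dataset(demo_cohort_spec(seed = 1))$dataset
  expect_error(proclus(raw, C = 2, D = 3, seed = 1), "numeric")
})

test_that("tidy and glance summarize a clustering result", {
  ds <- preprocess(generate_dataset(recovery_spec(seed = 2))$dataset)
  res <- proclus(ds, C = 3, D = 5, seed = 5)
  td <- tidy(res)
  expect_true(all(c("cluster_id", "n_members", "n_dims") %in% names(td)))
  expect_equal(sum(td$n_members), 300 - length(res$outliers))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$C, 3L)
  expect_gte(gl$objective, 0)
})

test_that("sweeps enumerate the parameter grid in product order", {
  spec <- synth_spec(
    n_records = 40, n_dims = 8,
    clusters = list(list(size = 40, subspace_size = 3, label = "a")),
    seed = 6
  )
  ds <- preprocess(generate_dataset(spec)$dataset)
  res <- run_sweep(ds, C_values = 2:3, D_values = 3:4, seeds = c(1, 2))
  expect_length(res, 2 * 2 * 2)
  grid <- t(vapply(res, function(r) {
    c(r$params$C, r$params$D, r$params$seed)
  }, integer(3)))
  expect_equal(grid[, 1], rep(2:3, each = 4))       # C outer
  expect_equal(grid[, 2], rep(rep(3:4, each = 2), 2))
  expect_equal(grid[, 3], rep(c(1L, 2L), 4))        # seed inner

  single <- run_sweep(ds, 2, 3, seeds = 7)
  direct <- proclus(ds, C = 2, D = 3, seed = 7)
  expect_identical(single[[1]]$clusters$members, direct$clusters$members)

  expect_warning(skipped <- run_sweep(ds, 2, c(1, 3), seeds = 1), "skipping")
  expect_length(skipped, 1)
  expect_error(run_sweep(ds, integer(0), 3, 1), "non-empty")
})

test_that("pooling binds clusters across runs with fresh unique ids", {
  spec <- synth_spec(
    n_records = 40, n_dims = 8,
    clusters = list(list(size = 40, subspace_size = 3, label = "a")),
    seed = 3
  )
  ds <- preprocess(generate_dataset(spec)$dataset)
  res <- run_sweep(ds, 2:3, 3, seeds = 1)
  pool <- pool_results(res, dataset_ref = "sweep")
  expect_s3_class(pool, "ss_clusters")
  expect_equal(nrow(pool), sum(vapply(res, function(r) nrow(r$clusters), 1L)))
  expect_false(anyDuplicated(pool$cluster_id) > 0)
  expect_equal(attr(pool, "dataset_ref"), "sweep")
})
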