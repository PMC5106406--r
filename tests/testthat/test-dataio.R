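test_that("CSV reading infers shapes, kinds and missing markers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("height,weight", "1.2,50", "1.5,60", "1.8,70"), path)
  ds <- read_dataset(path)
  expect_equal(n_records(ds), 3)
  expect_equal(n_dims(ds), 2)
  expect_equal(ds$dim_meta$kind, c("numeric", "numeric"))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,sex,outcome", "1,?,pos", "2,m,neg", "3,f,pos"), path2)
  ds2 <- read_dataset(path2, label_column = "outcome")
  expect_true(is.na(ds2$values$sex[1]))
  expect_equal(ds2$dim_meta$kind, c("numeric", "binary"))
  expect_equal(unname(ds2$labels), c("pos", "neg", "pos"))
  expect_false("outcome" %in% dim_names(ds2))

  expect_error(read_dataset(path2, label_column = "nope"), "label column")
  expect_error(read_dataset("/nonexistent/file.csv"), "not found")
})

test_that("ARFF attribute declarations drive dimension kinds", {
  path <- withr::local_tempfile(fileext = ".arff")
  writeLines(c(
    "@relation demo",
    "@attribute age numeric",
    "@attribute sex {m,f}",
    "@attribute grade {low,mid,high}",
    "@data",
    "50,m,low",
    "61,f,high",
    "55,?,mid"
  ), path)
  ds <- read_dataset(path)
  expect_equal(ds$dim_meta$kind, c("numeric", "binary", "categorical"))
  expect_equal(ds$dim_meta$levels[[2]], c("m", "f"))
  expect_equal(ds$dim_meta$levels[[3]], c("low", "mid", "high"))
  expect_true(is.na(ds$values$sex[3]))
})

test_that("incomplete-record removal keeps exactly the complete records", {
  df <- tibble::tibble(
    a = c(1, NA, 3, 4, 5),
    b = c("x", "y", NA, "y", "x")
  )
  ds <- as_dataset(df, label_column = NULL)
  out <- drop_incomplete_records(ds)
  expect_equal(out$record_ids, c("0", "3", "4"))
  rep <- preprocess_report(out)
  expect_equal(rep$n_dropped_records, 2L)
  expect_setequal(rep$dropped_ids, c("1", "2"))

  clean <- as_dataset(tibble::tibble(a = 1:3))
  out2 <- drop_incomplete_records(clean)
  expect_equal(out2$values, clean$values)
  expect_equal(preprocess_report(out2)$n_dropped_records, 0L)

  allmiss <- as_dataset(tibble::tibble(a = c(NA, 1), b = c(1, NA)))
  expect_error(drop_incomplete_records(allmiss), "nothing would remain")
})

test_that("nominal encoding maps levels to integer codes in declared order", {
  df <- tibble::tibble(
    flag = c("no", "yes", "no"),
    grade = c("a", "c", "b"),
    num = c(1.5, 2.5, 3.5)
  )
  ds <- encode_nominal(as_dataset(df))
  expect_equal(ds$values$flag, c(0, 1, 0))          # first level -> 0
  expect_equal(ds$values$grade, c(0, 2, 1))         # codes 0..k-1
  expect_equal(ds$values$num, df$num)               # numeric untouched
  rep <- preprocess_report(ds)
  expect_equal(rep$encoded_dims$flag, c(no = 0L, yes = 1L))
  expect_equal(rep$encoded_dims$grade, c(a = 0L, b = 1L, c = 2L))

  allnum <- as_dataset(tibble::tibble(x = 1:3, y = 4:6))
  expect_equal(encode_nominal(allnum)$values, allnum$values)
})

test_that("min-max normalization matches the linear rescaling formula", {
  ds <- as_dataset(tibble::tibble(x = c(2, 4, 6)))
  out <- normalize_minmax(ds)
  expect_equal(out$values$x, c(0, 0.5, 1))

  const <- as_dataset(tibble::tibble(x = c(3, 3, 3), y = c(0, 1, 2)))
  expect_warning(out2 <- normalize_minmax(const), "constant")
  expect_equal(out2$values$x, c(0, 0, 0))
  expect_equal(preprocess_report(out2)$constant_dims, "x")

  # idempotence on already-normalized data
  twice <- suppressWarnings(normalize_minmax(out))
  expect_equal(twice$values, out$values)

  miss <- as_dataset(tibble::tibble(x = c(1, NA)))
  expect_error(normalize_minmax(miss), "drop_incomplete_records")
})

test_that("split_by_label partitions records and shares dim_meta", {
  ds <- as_dataset(
    tibble::tibble(x = 1:5, lab = c("pos", "pos", "neg", "neg", "neg")),
    label_column = "lab"
  )
  parts <- split_by_label(ds)
  expect_named(parts, c("neg", "pos"))
  expect_equal(n_records(parts$pos), 2)
  expect_equal(n_records(parts$neg), 3)
  expect_identical(parts$pos$dim_meta, ds$dim_meta)
  expect_setequal(c(parts$pos$record_ids, parts$neg$record_ids), ds$record_ids)

  single <- as_dataset(tibble::tibble(x = 1:2, lab = c("a", "a")),
                       label_column = "lab")
  expect_equal(n_records(split_by_label(single)$a), 2)

  nolab <- as_dataset(tibble::tibble(x = 1:2))
  expect_error(split_by_label(nolab), "no labels")
})

test_that("drop -> encode -> normalize yields numeric [0,1] tables on random data", {
  for (seed in 1:100) {
    spec <- synth_spec(
      n_records = 30, n_dims = 8,
      clusters = list(list(size = 30, subspace_size = 2, label = "a")),
      n_categorical_dims = 2, missing_rate = 0.03, seed = seed
    )
    ds <- generate_dataset(spec)$dataset
    out <- suppressWarnings(preprocess(ds))
    m <- values_matrix(out)
    expect_false(anyNA(m))
    expect_gte(min(m), 0)
    expect_lte(max(m), 1)

    if (!is.null(out$labels)) {
      parts <- split_by_label(out)
      expect_equal(sum(vapply(parts, n_records, integer(1))), n_records(out))
      ids <- unlist(lapply(parts, function(p) p$record_ids))
      expect_false(anyDuplicated(ids) > 0)  # disjoint subsets
    }
  }
})

test_that("record ids come from the id column when one is given", {
  df <- tibble::tibble(id = c("p1", "p2"), x = c(1, 2))
  ds <- as_dataset(df, id_column = "id")
  expect_equal(ds$record_ids, c("p1", "p2"))
  expect_equal(n_dims(ds), 1)
})

test_that("dataset round-trips through write_dataset/read_dataset", {
  spec <- synth_spec(
    n_records = 20, n_dims = 6,
    clusters = list(list(size = 20, subspace_size = 2, label = "z")),
    seed = 4
  )
  ds <- preprocess(generate_dataset(spec)$dataset)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path, label_column = "class", id_column = "record_id")
  expect_equal(back$record_ids, ds$record_ids)
  expect_equal(unname(back$labels), unname(ds$labels))
  expect_equal(as.matrix(back$values), as.matrix(ds$values), tolerance = 1e-12)
})
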