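# Shared fixture builders; everything is generated in code at test time.

# the recovery benchmark: 3 well-separated clusters of 100 planted in
# disjoint 5-dim subspaces of a 25-dim uniform background
recovery_spec <- function(seed = 1) {
  synth_spec(
    n_records = 300, n_dims = 25,
    clusters = list(
      list(size = 100, subspace_size = 5, label = "a", sigma_in = 0.05),
      list(size = 100, subspace_size = 5, label = "b", sigma_in = 0.05),
      list(size = 100, subspace_size = 5, label = "c", sigma_in = 0.05)
    ),
    seed = seed
  )
}

# two labeled classes with one planted subspace each plus a dominant block
global_dims_spec <- function(seed = 1, n_global_dims = 6) {
  synth_spec(
    n_records = 160, n_dims = 24,
    clusters = list(
      list(size = 70, subspace_size = 4, label = "pos"),
      list(size = 90, subspace_size = 4, label = "neg")
    ),
    n_global_dims = n_global_dims,
    seed = seed
  )
}

workflow_test_config <- function(...) {
  workflow_config(C_values = 2:3, D_values = c(6, 8, 10, 12), seeds = 1, ...)
}

# a small numeric dataset straight from a tibble
tiny_dataset <- function(df, ...) as_dataset(df, ...)

# random cluster collection over a synthetic universe of record/dim names
random_collection <- function(k, record_ids, dims, seed = 1) {
  withr::with_seed(seed, {
    cluster_collection(
      members = lapply(seq_len(k), function(i) {
        sample(record_ids, sample(2:max(3, length(record_ids) %/% 2), 1))
      }),
      dimensions = lapply(seq_len(k), function(i) {
        sample(dims, sample(2:max(3, length(dims) - 1), 1))
      })
    )
  })
}

# brute-force set dissimilarities used as test oracles (independent of the
# implementation's set_distance)
brute_jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) && !length(B)) return(0)
  if (!length(A) || !length(B)) return(1)
  1 - sum(A %in% B) / length(unique(c(A, B)))
}
brute_dice <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) && !length(B)) return(0)
  if (!length(A) || !length(B)) return(1)
  1 - 2 * sum(A %in% B) / (length(A) + length(B))
}
brute_overlap <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) && !length(B)) return(0)
  if (!length(A) || !length(B)) return(1)
  1 - sum(A %in% B) / min(length(A), length(B))
}
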