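#' Entropy purity of a cluster with respect to class labels
#'
#' Normalized Shannon entropy of the label proportions inside the cluster:
#' `H = -sum(p_c * log(p_c)) / log(K)` with `K` the number of distinct
#' labels in the full dataset and `0 * log 0 = 0`.  0 means a pure cluster,
#' 1 a uniform mixture; normalizing by `log(K)` keeps the score comparable
#' across datasets.
#'
#' @param members Character vector of member record ids.
#' @param labels Named character vector of class labels for every record
#'   (names are record ids); at least two distinct labels must exist.
#' @return A number in \[0, 1\].
#' @export
entropy_score <- function(members, labels) {
  p <- member_label_props(members, labels)
  K <- length(unique(unname(labels)))
  if (K < 2) abort("need at least 2 distinct labels in the dataset")
  H <- -sum(ifelse(p > 0, p * log2(p), 0))
  H / log2(K)
}

member_label_props <- function(members, labels) {
  lab <- labels[members]
  if (anyNA(lab) || length(lab) != length(members)) {
    abort("every cluster member must have a label")
  }
  as.vector(table(lab)) / length(lab)
}

#' Majority-class purity of a cluster
#'
#' @inheritParams entropy_score
#' @return A list with `purity` (the largest label proportion, in (0, 1\])
#'   and `majority` (that label; ties break to the alphabetically first).
#' @export
majority_purity <- function(members, labels) {
  lab <- labels[members]
  if (anyNA(lab) || length(lab) != length(members)) {
    abort("every cluster member must have a label")
  }
  tab <- table(lab)
  tab <- tab[order(-tab, names(tab))]
  list(purity = as.numeric(tab[1]) / length(lab), majority = names(tab)[1])
}

#' Within-subspace compactness of a cluster
#'
#' Mean Manhattan segmental distance of the members to their member-wise
#' mean vector, restricted to the cluster's own dimension set -- the
#' subspace in which the members are supposed to be similar.  0 iff all
#' members coincide on those dimensions; scales linearly with spread.
#'
#' @param ds A fully numeric, missing-free `ss_dataset`.
#' @param members Character vector of member record ids (non-empty).
#' @param dimensions Character vector of the cluster's dimensions.
#' @return A non-negative number.
#' @export
compactness <- function(ds, members, dimensions) {
  if (length(members) == 0) abort("cluster has no members")
  X <- values_matrix(ds)
  sub <- X[members, dimensions, drop = FALSE]
  centroid <- colMeans(sub)
  mean(rowMeans(abs(sweep(sub, 2, centroid))))
}

#' Per-cluster evaluation table
#'
#' One row per cluster with size, subspace size, entropy, majority purity
#' and label, and compactness -- the table behind purity scatter plots and
#' the evaluation CSV export.
#'
#' @param coll An [cluster_collection()].
#' @param ds The bound `ss_dataset`.
#' @param labels Named character labels per record; defaults to the
#'   dataset's own labels.  When absent, the label-based columns are `NA`.
#' @return A tibble with columns `cluster_id`, `n_members`, `n_dims`,
#'   `entropy`, `purity`, `majority`, `compactness`.
#' @export
evaluate_clusters <- function(coll, ds, labels = ds$labels) {
  validate_clusters(coll, ds)
  rows <- map(seq_len(nrow(coll)), function(i) {
    mem <- coll$members[[i]]
    dims <- coll$dimensions[[i]]
    if (is.null(labels)) {
      ent <- NA_real_; pur <- NA_real_; maj <- NA_character_
    } else {
      ent <- entropy_score(mem, labels)
      mp <- majority_purity(mem, labels)
      pur <- mp$purity; maj <- mp$majority
    }
    tibble(cluster_id = coll$cluster_id[i],
           n_members = length(mem), n_dims = length(dims),
           entropy = ent, purity = pur, majority = maj,
           compactness = compactness(ds, mem, dims))
  })
  bind_rows(rows)
}

pair_f1 <- function(found, truth) {
  inter <- length(intersect(found, truth))
  if (inter == 0) return(0)
  prec <- inter / length(found)
  rec <- inter / length(truth)
  2 * prec * rec / (prec + rec)
}

#' Recovery of a clustering against planted ground truth
#'
#' Found clusters are matched one-to-one to planted clusters greedily by
#' pairwise member F1 (largest first; ties break to the lowest found index,
#' then the lowest true index).  `member_f1` is the mean F1 over
#' `max(n_found, n_true)` slots, so unmatched clusters on either side count
#' as 0; `subspace_jaccard_sim` is the mean Jaccard *similarity*
#' (`1 - `[set_distance()]) between the matched dimension sets; and
#' `mean_entropy` is the cluster-size-weighted mean [entropy_score()] of the
#' found clusters against the ground-truth labels.  All three are invariant
#' to relabeling or reordering the found clusters.
#'
#' @param result A `proclus_result` or an [cluster_collection()].
#' @param truth An `ss_ground_truth` from [generate_dataset()] (record
#'   universes must agree).
#' @return A one-row tibble with `member_f1`, `subspace_jaccard_sim` and
#'   `mean_entropy`.
#' @export
match_to_ground_truth <- function(result, truth) {
  coll <- if (inherits(result, "proclus_result")) result$clusters else result
  found_members <- coll$members
  found_dims <- coll$dimensions
  universe <- names(truth$membership)
  unknown <- setdiff(unique(unlist(found_members)), universe)
  if (length(unknown)) abort("found clusters reference records outside the ground-truth universe")

  true_ids <- names(truth$subspaces)
  true_members <- map(true_ids, function(t) universe[truth$membership == t])
  nf <- length(found_members); nt <- length(true_members)

  f1 <- matrix(0, nf, nt)
  for (i in seq_len(nf)) for (j in seq_len(nt)) {
    f1[i, j] <- pair_f1(found_members[[i]], true_members[[j]])
  }
  matched_f1 <- numeric(0)
  matched_jac <- numeric(0)
  free_f <- seq_len(nf); free_t <- seq_len(nt)
  while (length(free_f) > 0 && length(free_t) > 0) {
    sub <- f1[free_f, free_t, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    fi <- free_f[best[1]]; tj <- free_t[best[2]]
    matched_f1 <- c(matched_f1, f1[fi, tj])
    matched_jac <- c(matched_jac,
                     1 - set_distance(found_dims[[fi]],
                                      truth$subspaces[[tj]], "jaccard"))
    free_f <- setdiff(free_f, fi); free_t <- setdiff(free_t, tj)
  }
  slots <- max(nf, nt)
  labels <- truth$labels
  sizes <- lengths(found_members)
  ent <- map_dbl(found_members, entropy_score, labels = labels)
  tibble(
    member_f1 = sum(matched_f1) / slots,
    subspace_jaccard_sim = if (length(matched_jac)) mean(matched_jac) else 0,
    mean_entropy = sum(sizes * ent) / sum(sizes)
  )
}
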