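# Matching of temporal-synergy activation profiles across movement
# strategies: constrained k-means++ clustering with a correlation validity
# check and a one-profile-per-strategy constraint.

#' Cluster activation profiles across strategies with k-means++
#'
#' K-means (k-means++ seeding, Euclidean metric on the 101-sample profiles,
#' best of `restarts` runs by within-cluster sum of squares) followed by the
#' two validity checks: every profile must correlate (Pearson) at least
#' `cor_threshold` with its cluster centroid, and no cluster may contain
#' more than one profile from the same strategy. Singleton clusters are
#' valid by construction (correlation with their own centroid is 1).
#'
#' @param profiles matrix with one unit-maximum 101-sample profile per row.
#' @param strategies character vector of strategy labels, one per profile.
#' @param k number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed integer seed.
#' @param restarts,iter_max clustering protocol (study defaults 50 and 1000).
#' @param cor_threshold centroid-correlation validity threshold.
#' @return Object of class `cluster_solution`: `k`, `assignments`,
#'   `centroids` (k x 101), `correlations`, `valid`, `valid_correlation`,
#'   `valid_strategy`, `strategies`, `singletons` (logical per cluster).
#' @export
cluster_profiles <- function(profiles, strategies, k, seed = 1,
                             restarts = 50, iter_max = 1000,
                             cor_threshold = 0.9) {
  profiles <- as.matrix(profiles)
  p <- nrow(profiles)
  if (length(strategies) != p)
    stop("need one strategy label per profile")
  if (k < 1 || k > p) stop("k must lie in [1, ", p, "], got ", k)
  fit <- with_seed(split_seed(seed, "kmeans"), {
    if (k == p) {
      # all-singleton partition: exact and always attainable
      list(cluster = seq_len(p), centers = profiles, tot_withinss = 0)
    } else {
      best <- NULL
      for (r in seq_len(restarts)) {
        cand <- kmeans_lloyd(profiles, k, iter_max = iter_max)
        if (is.null(best) || cand$tot_withinss < best$tot_withinss) best <- cand
      }
      best
    }
  })
  correlations <- vapply(seq_len(p), function(i) {
    centroid <- fit$centers[fit$cluster[i], ]
    if (sum(fit$cluster == fit$cluster[i]) == 1) return(1)
    if (sd(centroid) == 0 || sd(profiles[i, ]) == 0) return(0)
    cor(profiles[i, ], centroid)
  }, 1)
  sizes <- tabulate(fit$cluster, nbins = k)
  dup_strategy <- any(vapply(seq_len(k), function(j)
    anyDuplicated(strategies[fit$cluster == j]) > 0, TRUE))
  valid_correlation <- all(correlations >= cor_threshold)
  valid_strategy <- !dup_strategy
  structure(list(k = k, assignments = fit$cluster, centroids = fit$centers,
                 correlations = correlations,
                 valid = valid_correlation && valid_strategy,
                 valid_correlation = valid_correlation,
                 valid_strategy = valid_strategy,
                 strategies = strategies,
                 singletons = sizes == 1,
                 tot_withinss = fit$tot_withinss),
            class = "cluster_solution")
}

#' Find the minimum number of clusters satisfying both matching constraints
#'
#' Increases `k` from one until the solution is valid (all centroid
#' correlations at least `cor_threshold` and at most one profile per
#' strategy per cluster). Clusters containing a single profile are
#' strategy-specific synergies. The all-singleton partition at
#' `k = nrow(profiles)` is always valid, so the search cannot fail.
#'
#' @inheritParams cluster_profiles
#' @return A valid `cluster_solution` with additional element
#'   `strategy_specific` (data frame of singleton clusters and the strategy
#'   each is attributed to).
#' @export
find_min_valid_k <- function(profiles, strategies, seed = 1,
                             restarts = 50, iter_max = 1000,
                             cor_threshold = 0.9) {
  profiles <- as.matrix(profiles)
  for (k in seq_len(nrow(profiles))) {
    sol <- cluster_profiles(profiles, strategies, k, seed = seed,
                            restarts = restarts, iter_max = iter_max,
                            cor_threshold = cor_threshold)
    if (sol$valid) {
      singles <- which(sol$singletons)
      sol$strategy_specific <- data.frame(
        cluster = singles,
        strategy = vapply(singles, function(j)
          strategies[sol$assignments == j][1], ""),
        stringsAsFactors = FALSE)
      return(sol)
    }
  }
  stop("unreachable: the all-singleton partition is always valid")
}

# Fractional position of the ascending half-maximum crossing of a profile
# (used as the chronological tie-break); Inf if no ascending crossing.
ascending_halfmax <- function(y) {
  pk <- find_main_peak(y)
  half <- pk$value / 2
  i <- pk$index + 1  # 1-based sample index of the peak
  while (i > 1 && y[i - 1] > half) i <- i - 1
  if (i == 1) return(-Inf)
  (i - 2) + (half - y[i - 1]) / (y[i] - y[i - 1])
}

#' Order clusters chronologically by centroid peak time
#'
#' Sorts clusters by the main-peak index of their centroid; ties are broken
#' by the earlier ascending half-maximum crossing. Cluster ids in the
#' returned solution are relabeled `1..k` in chronological order.
#'
#' @param solution a `cluster_solution`.
#' @return The solution with clusters renumbered chronologically and an
#'   added `order` element (old cluster ids in chronological order).
#' @export
order_clusters_chronologically <- function(solution) {
  k <- solution$k
  peaks <- apply(solution$centroids, 1, function(y) find_main_peak(y)$index)
  ties <- apply(solution$centroids, 1, ascending_halfmax)
  ord <- order(peaks, ties)
  relabel <- match(seq_len(k), ord)
  solution$centroids <- solution$centroids[ord, , drop = FALSE]
  solution$assignments <- relabel[solution$assignments]
  solution$singletons <- solution$singletons[ord]
  if (!is.null(solution$strategy_specific)) {
    solution$strategy_specific$cluster <-
      relabel[solution$strategy_specific$cluster]
  }
  solution$order <- ord
  solution
}

# Canonical signature of a partition: clusters as sorted member index sets,
# sorted lexicographically (label-invariant).
partition_signature <- function(assignments) {
  groups <- split(seq_along(assignments), assignments)
  sig <- vapply(groups, function(g) paste(sort(g), collapse = ","), "")
  paste(sort(sig), collapse = "|")
}

#' Assess robustness of the matching over repeated clustering runs
#'
#' Repeats [find_min_valid_k()] with independent seeds and reports the
#' fraction of run pairs whose partitions are identical (after
#' label-invariant canonicalization). A warning is issued when agreement is
#' below 1.
#'
#' @inheritParams cluster_profiles
#' @param repeats number of repetitions (study default 10).
#' @return List with `agreement` (fraction of identical run pairs in
#'   `[0, 1]`), `k_values`, `signatures`.
#' @export
robustness_check <- function(profiles, strategies, repeats = 10, seed = 1,
                             restarts = 50, iter_max = 1000,
                             cor_threshold = 0.9) {
  sols <- lapply(seq_len(repeats), function(r)
    find_min_valid_k(profiles, strategies,
                     seed = split_seed(seed, paste0("repeat/", r)),
                     restarts = restarts, iter_max = iter_max,
                     cor_threshold = cor_threshold))
  sigs <- vapply(sols, function(s) partition_signature(s$assignments), "")
  pairs <- utils::combn(repeats, 2)
  agree <- mean(sigs[pairs[1, ]] == sigs[pairs[2, ]])
  if (agree < 1)
    warning("cluster assignments varied across repetitions (agreement ",
            round(agree, 3), ")")
  list(agreement = agree,
       k_values = vapply(sols, `[[`, 1, "k"),
       signatures = sigs)
}
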