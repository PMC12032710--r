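# Synergy extraction: NMF with multiplicative updates, cross-validated
# model-order selection (R^2-knee and global/local criteria), and
# compactness accounting for the temporal vs. spatial model comparison.

#' Assemble the NMF input matrix for one strategy dataset
#'
#' Concatenates all trials of one movement-by-floor-by-strategy group into
#' the two NMF arrangements: the temporal matrix (101 x 30*tr; trials side
#' by side, muscles within trial) whose trial-independent factors are
#' activation profiles, and the spatial matrix (30 x 101*tr; trials side by
#' side, time samples within trial) whose trial-independent factors are
#' muscle-weighting vectors. Column-block order follows trial order, so the
#' matrices reshape losslessly back to the trial list.
#'
#' @param trials list of 101 x 30 envelope matrices (or `processed_trial`
#'   objects) sharing one strategy label.
#' @param label strategy label carried along for bookkeeping.
#' @param meta optional data frame of per-trial metadata (one row per trial).
#' @return Object of class `strategy_dataset` with `temporal_matrix`,
#'   `spatial_matrix`, `trials`, `n_trials`, `label`, `meta`.
#' @export
build_strategy_dataset <- function(trials, label = "", meta = NULL) {
  mats <- lapply(trials, function(tr)
    if (inherits(tr, "processed_trial") || is.list(tr)) tr$envelope else tr)
  ok <- vapply(mats, function(m) all(dim(m) == c(101, 30)), TRUE)
  if (!all(ok)) stop("all trials must be 101 x 30 envelope matrices")
  temporal <- do.call(cbind, mats)                    # 101 x 30*tr
  spatial <- do.call(cbind, lapply(mats, t))          # 30 x 101*tr
  structure(list(temporal_matrix = temporal, spatial_matrix = spatial,
                 trials = mats, n_trials = length(mats),
                 label = label, meta = meta),
            class = "strategy_dataset")
}

#' Split a strategy dataset back into its trial matrices
#' @param dataset a `strategy_dataset`.
#' @param kind which arrangement to unstack.
#' @return List of 101 x 30 matrices.
#' @export
unstack_trials <- function(dataset, kind = c("temporal", "spatial")) {
  kind <- match.arg(kind)
  tr <- dataset$n_trials
  if (kind == "temporal") {
    lapply(seq_len(tr), function(s)
      dataset$temporal_matrix[, ((s - 1) * 30 + 1):(s * 30), drop = FALSE])
  } else {
    lapply(seq_len(tr), function(s)
      t(dataset$spatial_matrix[, ((s - 1) * 101 + 1):(s * 101), drop = FALSE]))
  }
}

# One multiplicative-update NMF run (Frobenius loss, Lee-Seung updates).
# Returns W (m x n), H (n x p), the objective trace, and iterations used.
nmf_run <- function(V, n, max_iter, tol = 1e-6, tol_window = 10) {
  eps <- .Machine$double.eps
  m <- nrow(V); p <- ncol(V)
  scale0 <- sqrt(mean(V) / n)
  W <- matrix(runif(m * n), m, n) * scale0
  H <- matrix(runif(n * p), n, p) * scale0
  obj <- numeric(max_iter)
  WH <- W %*% H
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, WH) + eps)
    WH <- W %*% H
    W <- W * (V %*% t(H)) / (WH %*% t(H) + eps)
    WH <- W %*% H
    obj[it] <- sum((V - WH)^2)
    if (it > tol_window) {
      rel <- (obj[it - tol_window] - obj[it]) / max(obj[it - tol_window], eps)
      if (rel < tol) { obj <- obj[seq_len(it)]; break }
    }
  }
  list(W = W, H = H, objective = obj[length(obj)], trace = obj)
}

#' Extract synergies by non-negative matrix factorization
#'
#' Multiplicative-update NMF minimizing squared reconstruction error,
#' restarted from `restarts` random nonnegative initializations (each capped
#' at `max_iter` iterations, with early stopping once the relative objective
#' decrease falls below `tol` over 10 iterations); the restart with the
#' lowest objective is kept. Trial-independent factors are renormalized to
#' unit maximum with the scale folded into the trial-dependent counterpart,
#' which leaves the reconstruction unchanged.
#'
#' @param x a nonnegative matrix, or a `strategy_dataset`.
#' @param n number of synergies, `1 <= n <= min(dim)`.
#' @param kind `"temporal"` (factors of a 101 x 30*tr matrix: profiles are
#'   trial-independent) or `"spatial"` (30 x 101*tr: weighting vectors are
#'   trial-independent).
#' @param restarts,max_iter NMF protocol settings (study defaults 50 and
#'   3000).
#' @param seed integer seed; each restart draws its initialization from a
#'   sub-stream.
#' @param tol early-stopping relative tolerance.
#' @return Object of class `synergy_model`: `kind`, `n`, `trial_independent`
#'   (101 x n profiles or 30 x n weighting vectors, unit maximum),
#'   `trial_dependent` (list per trial: n x 30 weightings or n x 101
#'   profiles; `NULL` block structure if `x` was a bare matrix, in which
#'   case `H` holds the full factor), `H`, `r2_train`, `objective`,
#'   `objective_trace`.
#' @export
nmf_extract <- function(x, n, kind = c("temporal", "spatial"),
                        restarts = 50, max_iter = 3000, seed = 1,
                        tol = 1e-6) {
  kind <- match.arg(kind)
  n_trials <- NULL
  if (inherits(x, "strategy_dataset")) {
    n_trials <- x$n_trials
    V <- if (kind == "temporal") x$temporal_matrix else x$spatial_matrix
  } else {
    V <- x
  }
  if (any(V < 0)) stop("NMF input must be nonnegative")
  if (all(V == 0)) stop("NMF input is all zero; nothing to decompose")
  if (n < 1 || n > min(dim(V)))
    stop("n must lie in [1, ", min(dim(V)), "], got ", n)
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- with_seed(split_seed(seed, paste0("nmf/", r)),
                     nmf_run(V, n, max_iter, tol = tol))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  # unit-max convention on the trial-independent factor (columns of W)
  scales <- apply(best$W, 2, max)
  scales[scales == 0] <- 1
  W <- sweep(best$W, 2, scales, "/")
  H <- sweep(best$H, 1, scales, "*")
  sst <- sum((V - rowMeans(V))^2)
  r2 <- 1 - best$objective / sst
  trial_dependent <- NULL
  if (!is.null(n_trials)) {
    block <- if (kind == "temporal") 30 else 101
    trial_dependent <- lapply(seq_len(n_trials), function(s)
      H[, ((s - 1) * block + 1):(s * block), drop = FALSE])
  }
  structure(list(kind = kind, n = n, trial_independent = W,
                 trial_dependent = trial_dependent, H = H,
                 r2_train = r2, objective = best$objective,
                 objective_trace = best$trace),
            class = "synergy_model")
}

#' Fit fixed trial-independent factors to held-out trials
#'
#' With the trial-independent factors frozen, solves a nonnegative least
#' squares problem per column of the held-out data for the trial-dependent
#' factors, and reports the reconstruction quality over the held-out set.
#'
#' @param fixed trial-independent factor matrix (101 x n profiles for the
#'   temporal model, 30 x n weighting vectors for the spatial model).
#' @param new_trials list of 101 x 30 trial matrices.
#' @param kind model kind.
#' @return List with `trial_dependent` (per trial), `r2` (R^2 over the
#'   concatenated held-out set), `reconstruction`.
#' @export
fit_fixed_factors <- function(fixed, new_trials,
                              kind = c("temporal", "spatial")) {
  kind <- match.arg(kind)
  expected_rows <- if (kind == "temporal") 101 else 30
  if (nrow(fixed) != expected_rows)
    stop("fixed factors must have ", expected_rows, " rows for the ",
         kind, " model")
  V <- if (kind == "temporal") do.call(cbind, new_trials)
       else do.call(cbind, lapply(new_trials, t))
  H <- apply(V, 2, function(col) pracma::lsqnonneg(fixed, col)$x)
  H <- matrix(H, nrow = ncol(fixed))
  recon <- fixed %*% H
  r2 <- compute_r_squared(V, recon)
  block <- if (kind == "temporal") 30 else 101
  trial_dependent <- lapply(seq_along(new_trials), function(s)
    H[, ((s - 1) * block + 1):(s * block), drop = FALSE])
  list(trial_dependent = trial_dependent, r2 = r2, reconstruction = recon)
}

#' Multivariate R-squared of a reconstruction
#'
#' `R^2 = 1 - SSE/SST` with SSE the sum of squared residuals and SST the sum
#' of squared deviations from the mean vector. By default the mean vector is
#' the per-row mean across columns (multivariate convention: each time
#' sample / muscle keeps its own mean); `center = "grand"` uses the grand
#' mean instead.
#'
#' @param data,reconstruction matrices of identical shape.
#' @param center `"row"` (default) or `"grand"`.
#' @return A scalar in `(-Inf, 1]`.
#' @export
compute_r_squared <- function(data, reconstruction, center = c("row", "grand")) {
  center <- match.arg(center)
  if (!all(dim(data) == dim(reconstruction)))
    stop("data and reconstruction must have the same shape")
  sse <- sum((data - reconstruction)^2)
  mu <- if (center == "row") rowMeans(data) else mean(data)
  sst <- sum((data - mu)^2)
  if (sst == 0) stop("SST is zero; R^2 is undefined for constant data")
  1 - sse / sst
}

#' Cross-validated R-squared curve over candidate synergy numbers
#'
#' Five-fold cross-validation over whole trials (80:20 train/test split,
#' stratified by support condition when metadata is available): for every
#' fold and candidate `n`, synergies are extracted from the training trials,
#' the trial-independent factors are fixed and fitted to the test trials,
#' and the held-out R^2 is recorded.
#'
#' @param dataset a `strategy_dataset` (needs `>= folds` trials).
#' @param kind model kind.
#' @param n_range candidate synergy numbers (study default `1:30`).
#' @param folds number of folds.
#' @param restarts,max_iter NMF settings per extraction.
#' @param seed integer seed (fold assignment and NMF restarts).
#' @return Object of class `cv_curve`: `kind`, `n_values`, `r2_cv` (folds x
#'   n matrix), `r2_mean`, `r2_sd`, `fold_assignment`.
#' @export
cross_validated_curve <- function(dataset, kind = c("temporal", "spatial"),
                                  n_range = 1:30, folds = 5,
                                  restarts = 50, max_iter = 3000, seed = 1) {
  kind <- match.arg(kind)
  tr <- dataset$n_trials
  if (tr < folds)
    stop("dataset '", dataset$label, "' has ", tr,
         " trials; at least ", folds, " are required for ", folds, "-fold CV")
  support <- if (!is.null(dataset$meta$support)) dataset$meta$support
             else rep("all", tr)
  fold_of <- integer(tr)
  with_seed(split_seed(seed, "folds"), {
    for (lv in unique(support)) {
      idx <- sample(which(support == lv))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  r2 <- matrix(NA_real_, folds, length(n_range),
               dimnames = list(NULL, n_range))
  for (f in seq_len(folds)) {
    train <- dataset$trials[fold_of != f]
    test <- dataset$trials[fold_of == f]
    if (length(test) == 0 || length(train) == 0) next
    train_ds <- build_strategy_dataset(train, label = dataset$label)
    for (j in seq_along(n_range)) {
      model <- nmf_extract(train_ds, n_range[j], kind = kind,
                           restarts = restarts, max_iter = max_iter,
                           seed = split_seed(seed, paste("fold", f, n_range[j])))
      fit <- fit_fixed_factors(model$trial_independent, test, kind = kind)
      r2[f, j] <- fit$r2
    }
  }
  structure(list(kind = kind, n_values = n_range, r2_cv = r2,
                 r2_mean = colMeans(r2, na.rm = TRUE),
                 r2_sd = apply(r2, 2, sd, na.rm = TRUE),
                 fold_assignment = fold_of),
            class = "cv_curve")
}

#' Select the number of synergies at the R-squared knee
#'
#' Fits a series of least-squares lines to the R^2 curve over the intervals
#' `[N_k, N_max]` for `k = 1, 2, ...`, iteratively removing the smallest
#' candidate, and selects the first left endpoint whose regression mean
#' squared residual falls below `mse_threshold` -- the point after which the
#' curve is approximately straight.
#'
#' @param curve a `cv_curve`, or a numeric vector of mean R^2 values.
#' @param mse_threshold MSE threshold (study value `1e-4`).
#' @return List with `n_knee` and `knee_mse_trace` (MSE per left endpoint).
#' @export
select_n_knee <- function(curve, mse_threshold = 1e-4) {
  r2 <- if (inherits(curve, "cv_curve")) curve$r2_mean else curve
  nv <- if (inherits(curve, "cv_curve")) curve$n_values else seq_along(r2)
  N <- length(r2)
  if (N < 2) stop("R^2 curve must cover at least 2 candidate numbers")
  mse <- rep(NA_real_, N - 1)
  for (k in seq_len(N - 1)) {
    xs <- nv[k:N]; ys <- r2[k:N]
    fit <- lm(ys ~ xs)
    mse[k] <- mean(residuals(fit)^2)
    if (mse[k] < mse_threshold) {
      return(list(n_knee = nv[k], knee_mse_trace = mse[seq_len(k)]))
    }
  }
  stop("no left endpoint reaches MSE < ", mse_threshold,
       "; minimum MSE was ", format(min(mse, na.rm = TRUE)))
}

#' Select the number of synergies by the global/local criterion
#'
#' The smallest `n` whose mean R^2 reaches at least `global` (default 0.9)
#' while the local increment `R^2(n) - R^2(n-1)` stays below `local`
#' (default 0.05); `R^2(0)` is defined as 0.
#'
#' @param curve a `cv_curve` or numeric vector of mean R^2 values.
#' @param global,local criterion thresholds.
#' @return List with `n_star` and `criteria_trace` (per-n logical table).
#' @export
select_n_star <- function(curve, global = 0.9, local = 0.05) {
  r2 <- if (inherits(curve, "cv_curve")) curve$r2_mean else curve
  nv <- if (inherits(curve, "cv_curve")) curve$n_values else seq_along(r2)
  prev <- c(0, r2[-length(r2)])
  ok_global <- r2 >= global
  ok_local <- (r2 - prev) < local
  hit <- which(ok_global & ok_local)
  trace <- data.frame(n = nv, r2 = r2, global_ok = ok_global,
                      local_ok = ok_local)
  if (length(hit) == 0)
    stop("no candidate n satisfies both the global (R^2 >= ", global,
         ") and local (increment < ", local, ") criteria")
  list(n_star = nv[hit[1]], criteria_trace = trace)
}

#' Parameter counts of the temporal and spatial representations
#'
#' For a dataset represented with `n_temporal` temporal and `n_spatial`
#' spatial synergies over `T` time samples and `M` muscles, the temporal
#' model stores `T * n_temporal` trial-independent values (profiles) and
#' `n_temporal * M` trial-dependent values per trial (weightings); the
#' spatial model stores `n_spatial * M` trial-independent and
#' `T * n_spatial` trial-dependent values.
#'
#' @param n_temporal,n_spatial selected synergy numbers (>= 1).
#' @param T,M time samples and muscles.
#' @return A one-row data frame with the four counts and the two sums.
#' @export
#' @examples
#' compactness_summary(7, 15)  # temporal sum 917, spatial sum 1965
compactness_summary <- function(n_temporal, n_spatial, T = 101, M = 30) {
  stopifnot(n_temporal >= 1, n_spatial >= 1)
  ti_t <- T * n_temporal
  td_t <- n_temporal * M
  ti_s <- n_spatial * M
  td_s <- T * n_spatial
  data.frame(n_temporal = n_temporal, n_spatial = n_spatial,
             trial_independent_temporal = ti_t,
             trial_dependent_temporal = td_t,
             trial_independent_spatial = ti_s,
             trial_dependent_spatial = td_s,
             sum_temporal = ti_t + td_t,
             sum_spatial = ti_s + td_s)
}

#' Mean and SD of the spatial-minus-temporal synergy-count difference
#'
#' @param n_temporal,n_spatial vectors of selected synergy numbers over
#'   datasets (same length, >= 2).
#' @return List with `differences`, `mean`, `sd` (sample SD).
#' @export
#' @examples
#' compare_model_counts(c(7, 6), c(15, 12))
compare_model_counts <- function(n_temporal, n_spatial) {
  stopifnot(length(n_temporal) == length(n_spatial), length(n_temporal) >= 2)
  d <- n_spatial - n_temporal
  list(differences = d, mean = mean(d), sd = sd(d))
}
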