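# Shared helpers: channel metadata, seed splitting, profile construction.

#' Muscle channel table
#'
#' The fixed 30-channel layout used throughout the package: 14 bilaterally
#' recorded muscles (left/right pairs, in the order pectoralis major,
#' latissimus dorsi, trapezius, deltoideus, biceps brachii, triceps brachii,
#' gluteus medius, tensor fasciae latae, rectus femoris, vastus medialis,
#' biceps femoris, tibialis anterior, peroneus longus, gastrocnemius)
#' followed by the two single trunk channels erector spinae (ES) and rectus
#' abdominis (RA). Each channel carries a functional group label used by the
#' synthetic generator's support effects: `upper_body` (arm/shoulder
#' muscles), `lower_limb` (hip/leg muscles) or `trunk` (ES, RA).
#'
#' @return A data frame with columns `channel`, `code` (e.g. `"Pec_L"`),
#'   `muscle` (e.g. `"Pec"`), `side` (`"L"`, `"R"` or `NA`) and `group`.
#' @export
#' @examples
#' head(muscle_channel_table())
muscle_channel_table <- function() {
  bilateral <- c("Pec", "Lat", "Tra", "Del", "Bic", "Tri",
                 "GM", "TF", "RF", "VM", "BF", "TA", "PL", "GA")
  group <- c(rep("upper_body", 6), rep("lower_limb", 8))
  df <- data.frame(
    muscle = c(rep(bilateral, each = 2), "ES", "RA"),
    side   = c(rep(c("L", "R"), 14), NA, NA),
    group  = c(rep(group, each = 2), "trunk", "trunk"),
    stringsAsFactors = FALSE
  )
  df$code <- ifelse(is.na(df$side), df$muscle, paste(df$muscle, df$side, sep = "_"))
  df$channel <- seq_len(nrow(df))
  df[, c("channel", "code", "muscle", "side", "group")]
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' All randomness in the package flows from a single integer seed; stages and
#' per-trial draws obtain their own stream by hashing the master seed with a
#' short key (e.g. `"trial/P03/7"`). The hash is a 31-bit multiplicative
#' scheme, so derived seeds always fit a 32-bit integer.
#'
#' @param seed integer master seed.
#' @param key character scalar naming the consumer.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(key)) {
    h <- (h * 131 + c) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Unit-maximum truncated-Gaussian activation profile
#'
#' Bell-shaped activation profile on the 101-point time-normalized grid
#' (0--100% of movement duration), truncated at the grid boundaries and
#' scaled to unit maximum.
#'
#' @param peak peak time in % of the movement cycle, in `[0, 100]`.
#' @param width Gaussian width parameter (sigma) in % of the cycle, > 0.
#' @param grid sample positions, default `0:100`.
#' @return Numeric vector of `length(grid)` with maximum 1.
#' @export
#' @examples
#' p <- bump_profile(50, 5)
#' which.max(p) - 1  # 50
bump_profile <- function(peak, width, grid = 0:100) {
  if (width <= 0) stop("profile width must be > 0, got ", width)
  if (peak < 0 || peak > 100) stop("profile peak must lie in [0, 100], got ", peak)
  y <- exp(-0.5 * ((grid - peak) / width)^2)
  y / max(y)
}

# Smoothstep ramp: 0 below x0, 1 above x1, C1-smooth cubic in between.
smoothstep <- function(t, x0, x1) {
  u <- pmin(pmax((t - x0) / (x1 - x0), 0), 1)
  u * u * (3 - 2 * u)
}

# Internal k-means++ initialization: rows of x are points.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx <- sample.int(n, 1)
      } else {
        idx <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

# Lloyd's algorithm with k-means++ seeding; empty clusters are refilled with
# the point farthest from its centroid. Returns assignments, centers, wss.
kmeans_lloyd <- function(x, k, iter_max = 1000) {
  n <- nrow(x)
  centers <- kmeanspp_init(x, k)
  assign_pts <- function(centers) {
    d <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_pts(centers)
  for (it in seq_len(iter_max)) {
    for (j in seq_len(k)) {
      members <- which(cl == j)
      if (length(members) == 0) {
        # refill empty cluster with the worst-fit point
        dists <- rowSums((x - centers[cl, , drop = FALSE])^2)
        far <- which.max(dists)
        centers[j, ] <- x[far, ]
        cl[far] <- j
      } else {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    cl_new <- assign_pts(centers)
    if (all(cl_new == cl)) break
    cl <- cl_new
  }
  wss <- sum((x - centers[cl, , drop = FALSE])^2)
  list(cluster = cl, centers = centers, tot_withinss = wss)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
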