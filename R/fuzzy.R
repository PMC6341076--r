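# Time-course fuzzy c-means: feature standardization over stage means,
# low-signal pre-filtering, the Bezdek alternating-update algorithm with a
# permutation-invariant seeded k-means++ initialization, and membership
# thresholding.

#' Stage means of a sample-level matrix
#'
#' @param values matrix, features x samples.
#' @param design a [StageDesign-class]; every stage must have >= 1 sample
#'   among the columns.
#' @return matrix, features x stages, in design stage order.
#' @export
stageMeans <- function(values, design) {
  st <- stageOf(design, colnames(values))
  out <- vapply(stages(design), function(s) {
    cols <- which(st == s)
    if (length(cols) == 0L) stopf("stage '%s' has no samples in the matrix", s)
    rowMeans(values[, cols, drop = FALSE])
  }, numeric(nrow(values)))
  matrix(out, nrow = nrow(values),
         dimnames = list(rownames(values), stages(design)))
}

#' Remove features with no signal at any stage
#'
#' Drops features whose stage mean is <= `threshold` at ALL stages (on the
#' package's non-negative log2 scale the default threshold 0 removes
#' features never detected above background).
#'
#' @param values normalized matrix, features x samples.
#' @param design a [StageDesign-class].
#' @param threshold expressed threshold (default 0).
#' @return the retained rows of `values`.
#' @export
prefilterFeatures <- function(values, design, threshold = 0) {
  sm <- stageMeans(values, design)
  keep <- apply(sm, 1, function(p) any(p > threshold))
  values[keep, , drop = FALSE]
}

#' Standardize stage profiles
#'
#' Collapses replicates to stage means, then z-scores each feature across
#' stages (mean 0, SD 1, population SD convention). Zero-variance features
#' cannot be standardized: they are dropped with a message (their ids kept
#' in attribute `dropped`) or raise an error with `drop_constant = FALSE`.
#'
#' @param values normalized matrix, features x samples.
#' @param design a [StageDesign-class].
#' @param drop_constant drop zero-variance features (default TRUE).
#' @return features x stages matrix of z-scored stage profiles.
#' @export
standardizeProfiles <- function(values, design, drop_constant = TRUE) {
  sm <- stageMeans(values, design)
  sds <- apply(sm, 1, sd_pop)
  const <- sds == 0
  if (any(const)) {
    if (!drop_constant)
      stopf("%d zero-variance feature(s); pre-filter first", sum(const))
    message(sum(const), " zero-variance feature(s) dropped before z-scoring")
  }
  z <- (sm[!const, , drop = FALSE] -
          rowMeans(sm[!const, , drop = FALSE])) / sds[!const]
  attr(z, "dropped") <- rownames(sm)[const]
  z
}

# Squared Euclidean distances between rows of X and rows of centers.
sq_dist <- function(X, centers) {
  d <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  pmax(d, 0)
}

# Membership update: u_ik proportional to (1/d_ik^2)^(1/(m-1)); rows with an
# exact-zero distance put all membership on the zero-distance center(s).
fcm_membership <- function(d2, m) {
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit))
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  if (any(!hit)) {
    w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
    u[!hit, ] <- w / rowSums(w)
  }
  u
}

# Permutation-invariant seeded k-means++: candidates are ranked in a
# canonical (lexicographic row) order and selected by inverse-CDF sampling,
# so the same seed picks the same points whatever the input row order.
kmeanspp_init <- function(X, c, seed) {
  canon <- do.call(order, as.data.frame(X))
  with_seed(seed, {
    pick_by_cdf <- function(prob) {
      p <- prob[canon]
      canon[which(cumsum(p / sum(p)) >= runif(1))[1]]
    }
    idx <- pick_by_cdf(rep(1, nrow(X)))
    for (k in seq_len(c - 1L)) {
      d2 <- apply(sq_dist(X, X[idx, , drop = FALSE]), 1, min)
      if (all(d2 == 0)) { idx <- c(idx, idx[1]); next }
      idx <- c(idx, pick_by_cdf(d2))
    }
    X[idx, , drop = FALSE]
  })
}

#' Fuzzy c-means clustering of standardized stage profiles
#'
#' Bezdek's alternating updates: memberships from current centers
#' (`u_ik` proportional to `(1/d_ik^2)^(1/(m-1))`, full membership on an
#' exact-zero-distance center), then centers as `u^m`-weighted means.
#' Stops when the largest center coordinate shift falls below `tol`.
#' The alternation is restarted from `nstart` independent seeded
#' initializations and the solution with the lowest final objective is
#' kept (the usual guard against poor local optima). Cluster labels are
#' re-ordered by the stage index at which each center peaks, so numbering
#' is reproducible across runs.
#'
#' @param X standardized matrix (features x stages), no missing values.
#' @param c number of centers (default 6, the time-course cluster count).
#' @param m fuzzifier > 1 (default 1.25).
#' @param tol convergence tolerance on the center shift (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param seed integer seed for the center initializations.
#' @param nstart number of restarts (default 5).
#' @return a [FuzzyClustering-class] object.
#' @export
fuzzyCMeans <- function(X, c = 6L, m = 1.25, tol = 1e-6, max_iter = 300L,
                        seed = 1L, nstart = 5L) {
  X <- as.matrix(X)
  if (c < 2L) stopf("'c' must be >= 2")
  if (m <= 1) stopf("fuzzifier 'm' must be > 1")
  if (nrow(X) <= c) stopf("need more features than centers")
  if (anyNA(X)) stopf("X must not contain missing values")
  if (nstart < 1L) stopf("'nstart' must be >= 1")
  one_run <- function(init_seed) {
    centers <- kmeanspp_init(X, c, init_seed)
    trace <- numeric(0)
    u <- NULL
    for (it in seq_len(max_iter)) {
      d2 <- sq_dist(X, centers)
      u <- fcm_membership(d2, m)
      um <- u^m
      trace <- c(trace, sum(um * d2))
      new_centers <- (t(um) %*% X) / colSums(um)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    list(centers = centers, u = u, trace = trace)
  }
  runs <- lapply(seq_len(nstart), function(r)
    one_run(sub_seed(seed, paste0("init", r))))
  best <- runs[[which.min(vapply(runs, function(r)
    tail(r$trace, 1), numeric(1)))]]
  centers <- best$centers
  u <- best$u
  trace <- best$trace
  # reproducible label order: by the stage where each center peaks
  peak_stage <- apply(centers, 1, which.max)
  ord <- order(peak_stage, apply(centers, 1, which.min))
  centers <- centers[ord, , drop = FALSE]
  u <- u[, ord, drop = FALSE]
  rownames(centers) <- paste0("C", seq_len(c))
  dimnames(u) <- list(rownames(X), rownames(centers))
  new("FuzzyClustering", centers = centers, membership = u, m = m,
      threshold = NA_real_,
      assignments = setNames(rep(NA_integer_, nrow(u)), rownames(u)),
      objective = trace)
}

#' Threshold memberships into hard assignments
#'
#' Features take their argmax cluster when the maximum membership reaches
#' `threshold`, and stay unassigned (NA) otherwise.
#'
#' @param clustering a [FuzzyClustering-class].
#' @param threshold membership threshold in (0, 1] (default 0.3).
#' @return the clustering with its `assignments` slot filled.
#' @export
assignClusters <- function(clustering, threshold = 0.3) {
  if (threshold <= 0 || threshold > 1)
    stopf("'threshold' must lie in (0, 1]")
  u <- membership(clustering)
  mx <- apply(u, 1, max)
  a <- ifelse(mx >= threshold, apply(u, 1, which.max), NA_integer_)
  clustering@assignments <- setNames(as.integer(a), rownames(u))
  clustering@threshold <- threshold
  clustering
}
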