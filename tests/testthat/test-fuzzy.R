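# Standardization, pre-filtering, the fuzzy c-means engine and membership
# thresholding.

make_norm <- function(stage_values, design, n_rep = 2L) {
  # expand per-stage values into identical replicates
  m <- stage_values[, rep(seq_len(ncol(stage_values)), each = n_rep),
                    drop = FALSE]
  colnames(m) <- samples(design)
  m
}

test_that("standardizeProfiles z-scores stage means with population SD", {
  d <- StageDesign(stages = c("s1", "s2", "s3"), replicates = 2L)
  sv <- matrix(c(1, 2, 3), 1, 3, dimnames = list("f1", NULL))
  z <- standardizeProfiles(make_norm(sv, d), d)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # replicates (2, 4) at a stage average to 3
  m <- matrix(c(2, 4, 1, 1, 5, 5), 1, 6,
              dimnames = list("f1", samples(d)))
  expect_equal(unname(stageMeans(m, d)[1, ]), c(3, 1, 5))
  # constant profiles are dropped with a message, or error on request
  m2 <- rbind(f1 = c(1, 1, 2, 2, 3, 3), f2 = rep(1, 6))
  colnames(m2) <- samples(d)
  expect_message(z <- standardizeProfiles(m2, d), "zero-variance")
  expect_identical(rownames(z), "f1")
  expect_identical(attr(z, "dropped"), "f2")
  expect_error(standardizeProfiles(m2, d, drop_constant = FALSE),
               "zero-variance")
})

test_that("prefilterFeatures drops features silent at every stage", {
  d <- StageDesign(stages = c("s1", "s2"), replicates = 2L)
  m <- rbind(allzero = c(0, 0, 0, 0),
             onestage = c(0, 0, 1, 0.5),
             boundary = c(0, 0, 0, 0))
  colnames(m) <- samples(d)
  kept <- prefilterFeatures(m, d)
  expect_identical(rownames(kept), "onestage")
  # any epsilon above the threshold retains
  m["boundary", 3] <- 1e-9
  expect_true("boundary" %in% rownames(prefilterFeatures(m, d)))
})

test_that("fuzzy c-means separates two planted groups and respects zeros", {
  withr::with_seed(51, {
    p1 <- c(1, 0, 0, 0, 0, 0); p2 <- c(0, 0, 0, 0, 0, 1)
    X <- rbind(matrix(rep(p1, 40), 40, byrow = TRUE),
               matrix(rep(p2, 40), 40, byrow = TRUE)) +
      matrix(rnorm(480, sd = 0.1), 80)
  })
  rownames(X) <- paste0("f", 1:80)
  fc <- fuzzyCMeans(X, c = 2, m = 1.25, seed = 5)
  u <- membership(fc)
  expect_true(all(abs(rowSums(u) - 1) < 1e-9))
  own <- c(rep(1, 40), rep(2, 40))
  grp1 <- which.max(u[1, ])       # label of the first planted group
  own_m <- ifelse(own == 1, u[, grp1], u[, 3 - grp1])
  expect_true(all(own_m > 0.9))
  # identical points collapse onto their center with membership exactly 1
  Y <- rbind(matrix(rep(c(1, 0, 0), 10), 10, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 10), 10, byrow = TRUE))
  rownames(Y) <- paste0("g", 1:20)
  fy <- fuzzyCMeans(Y, c = 2, m = 2, seed = 1)
  expect_true(all(apply(membership(fy), 1, max) == 1))
  expect_error(fuzzyCMeans(X, c = 1), "c")
  expect_error(fuzzyCMeans(X, m = 1), "m")
})

test_that("near-crisp fuzzifier reproduces hard k-means labels", {
  withr::with_seed(53, {
    p1 <- c(2, 0, 0, 0); p2 <- c(0, 0, 0, 2); p3 <- c(0, 2, 2, 0)
    X <- rbind(matrix(rep(p1, 30), 30, byrow = TRUE),
               matrix(rep(p2, 30), 30, byrow = TRUE),
               matrix(rep(p3, 30), 30, byrow = TRUE)) +
      matrix(rnorm(360, sd = 0.15), 90)
    rownames(X) <- paste0("f", 1:90)
    km <- kmeans(X, centers = 3, nstart = 10)
  })
  fc <- assignClusters(fuzzyCMeans(X, c = 3, m = 1.05, seed = 2), 0.3)
  a <- clusterAssignments(fc)
  expect_false(anyNA(a))
  expect_equal(best_label_agreement(a, km$cluster, 3), 1)
})

test_that("objective trace is non-increasing on random data", {
  withr::with_seed(59, {
    for (i in 1:50) {
      X <- matrix(rnorm(40 * 6), 40)
      rownames(X) <- paste0("f", 1:40)
      fc <- fuzzyCMeans(X, c = 3, m = 1.5, seed = i)
      expect_true(all(diff(objectiveTrace(fc)) <= 1e-9))
    }
  })
})

test_that("permuting input features permutes outputs identically", {
  sim <- simulateWaveProfiles(n_per_wave = 20, n_waves = 3, n_stages = 6,
                              seed = 61)
  X <- sim$X
  fc1 <- assignClusters(fuzzyCMeans(X, c = 3, seed = 9), 0.3)
  perm <- rev(seq_len(nrow(X)))
  fc2 <- assignClusters(fuzzyCMeans(X[perm, ], c = 3, seed = 9), 0.3)
  expect_identical(clusterAssignments(fc2),
                   clusterAssignments(fc1)[perm])
  expect_equal(clusterCenters(fc2), clusterCenters(fc1), tolerance = 1e-8)
})

test_that("fuzzy memberships agree with an independent c-means reference", {
  skip_if_not_installed("e1071")
  sim <- simulateWaveProfiles(n_per_wave = 30, n_waves = 4, n_stages = 8,
                              noise_sd = 0.1, seed = 67)
  fc <- fuzzyCMeans(sim$X, c = 4, m = 1.5, seed = 3)
  ref <- withr::with_seed(3, e1071::cmeans(sim$X, centers = 4, m = 1.5))
  ours <- apply(membership(fc), 1, which.max)
  theirs <- ref$cluster
  expect_gte(best_label_agreement(ours, theirs, 4), 0.98)
})

test_that("assignClusters thresholds the argmax membership", {
  u <- rbind(f1 = c(0.6, 0.4), f2 = c(0.29, 0.71), f3 = c(0.5, 0.5))
  fc <- new("FuzzyClustering", centers = matrix(0, 2, 3),
            membership = u, m = 1.25, threshold = NA_real_,
            assignments = setNames(rep(NA_integer_, 3), rownames(u)),
            objective = 1)
  a <- clusterAssignments(assignClusters(fc, 0.3))
  expect_identical(unname(a), c(1L, 2L, 1L))
  # max below threshold is unassigned
  u2 <- rbind(f1 = c(0.29, 0.28, 0.43) / sum(c(0.29, 0.28, 0.43)))
  fc2 <- new("FuzzyClustering", centers = matrix(0, 3, 3),
             membership = rbind(f1 = c(0.29, 0.28, 0.43)), m = 1.25,
             threshold = NA_real_,
             assignments = c(f1 = NA_integer_), objective = 1)
  expect_identical(unname(clusterAssignments(assignClusters(fc2, 0.44))),
                   NA_integer_)
  # threshold 1 keeps only exact-1 memberships
  fc3 <- new("FuzzyClustering", centers = matrix(0, 2, 3),
             membership = rbind(f1 = c(1, 0), f2 = c(0.6, 0.4)), m = 1.25,
             threshold = NA_real_,
             assignments = c(f1 = NA_integer_, f2 = NA_integer_),
             objective = 1)
  expect_identical(unname(clusterAssignments(assignClusters(fc3, 1))),
                   c(1L, NA_integer_))
  expect_error(assignClusters(fc, 0), "threshold")
  expect_error(assignClusters(fc, 1.1), "threshold")
})
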