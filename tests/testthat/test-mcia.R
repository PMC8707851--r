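# independent preprocessing replica for the oracles: center columns,
# unit column sd, total inertia 1
ppCenterScale <- function(X) {
  Z <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  sds <- apply(Z, 2, stats::sd); sds[sds == 0] <- 1
  Z <- sweep(Z, 2, sds, "/")
  Z / sqrt(sum(Z^2) / nrow(Z))
}

test_that("K identical tables give symmetric pseudo-eigenvalues and RV 1", {
  set.seed(1)
  X <- matrix(stats::rnorm(40), 8)
  m <- mciaFit(list(a = X, b = X, c = X), nAxes = 2,
               preprocess = "centerScale")
  expect_true(all(abs(rvMatrix(m) - 1) < 1e-8))
  pe <- pseudoEigenvalues(m)
  expect_lt(max(abs(sweep(pe, 2, colMeans(pe)))), 1e-8)
})

test_that("K = 1 reduces to PCA of the preprocessed table", {
  set.seed(2)
  X <- matrix(stats::rnorm(60), 10)
  m <- mciaFit(list(x = X), nAxes = 4, preprocess = "centerScale")
  Z <- ppCenterScale(X)
  pca <- sort(eigen(crossprod(Z) / nrow(Z), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(eigenvalues(m), pca[1:4], tolerance = 1e-8)
})

test_that("the first axis matches grid-search covariance maximization", {
  set.seed(3)
  X <- matrix(stats::rnorm(8), 4); Y <- matrix(stats::rnorm(8), 4)
  m <- mciaFit(list(x = X, y = Y), nAxes = 1, preprocess = "centerScale")
  Zx <- ppCenterScale(X); Zy <- ppCenterScale(Y)
  n <- 4
  best <- 0
  for (t1 in seq(0, 179, by = 1)) for (t2 in seq(0, 179, by = 1)) {
    u1 <- c(cos(t1 * pi / 180), sin(t1 * pi / 180))
    u2 <- c(cos(t2 * pi / 180), sin(t2 * pi / 180))
    y1 <- Zx %*% u1; y2 <- Zy %*% u2
    # max over the unit-variance reference score of summed cov^2
    val <- max(eigen(tcrossprod(y1) + tcrossprod(y2),
                     symmetric = TRUE, only.values = TRUE)$values) / n
    if (val > best) best <- val
  }
  expect_equal(eigenvalues(m)[1], best, tolerance = 1e-3)
})

test_that("RV has its closed-form special cases", {
  set.seed(4)
  X <- matrix(stats::rnorm(30), 10)
  expect_equal(rvCoefficient(X, X), 1)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(rvCoefficient(matrix(x), matrix(y)),
               stats::cor(x, y)^2)
  # constructed orthogonality: XX^T and YY^T with disjoint sample support
  A <- rbind(diag(2) - 1 / 2, matrix(0, 2, 2))
  B <- rbind(matrix(0, 2, 2), diag(2) - 1 / 2)
  expect_equal(rvCoefficient(A, B), 0, tolerance = 1e-12)
  expect_error(rvCoefficient(matrix(0, 4, 2), X[1:4, ]), "zero-inertia")
})

test_that("global scores are uncorrelated and eigenvalues permutation-invariant", {
  set.seed(5)
  tables <- list(a = matrix(stats::runif(48), 8),
                 b = matrix(stats::runif(40), 8))
  m <- mciaFit(tables, nAxes = 3)
  cv <- stats::cov(globalScores(m))
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  perm <- tables
  perm$a <- perm$a[, sample(ncol(perm$a))]
  m2 <- mciaFit(perm, nAxes = 3)
  expect_equal(eigenvalues(m2), eigenvalues(m), tolerance = 1e-10)
})

test_that("mismatched samples and excessive axes are rejected", {
  expect_error(mciaFit(list(matrix(1:6, 3), matrix(1:8, 4))),
               "sample set")
  set.seed(6)
  expect_error(mciaFit(list(matrix(stats::runif(8), 4)), nAxes = 4),
               "rank")
})

# per-method sample x top-genus tables, the layout the RV and MCIA
# comparisons operate on
methodTables <- function(tr, seed, depth = 1e5, topN = 50) {
  biases <- defaultBiasModels(genusInfo(tr), depth = depth)
  profs <- lapply(biases, function(b)
    observationProfiles(observeWithClassifier(tr, b, seed = seed)))
  h <- harmonizeProfiles(unlist(profs, use.names = FALSE))
  keep <- sort(unique(unlist(lapply(profs, topGenera, n = topN))))
  keep <- intersect(colnames(h$matrix), keep)
  tables <- lapply(names(biases), function(m) {
    sub <- h$matrix[h$info$method == m, keep, drop = FALSE]
    rownames(sub) <- h$info$sample[h$info$method == m]
    sub[truthDesign(tr)$sample, , drop = FALSE]
  })
  stats::setNames(tables, names(biases))
}

test_that("metagenome methods agree more than amplicon on synthetic data", {
  metag <- c("Kaiju", "KaijuMAR", "Kraken2", "Bracken")
  minMeta <- maxAmp <- numeric(0)
  for (sd in 1:10) {
    tr <- generateTruth(seed = sd)
    rv <- rvMatrix(mciaFit(methodTables(tr, seed = sd), nAxes = 1))
    minMeta <- c(minMeta, min(rv[metag, metag][upper.tri(diag(4))]))
    maxAmp <- c(maxAmp, max(rv["Amplicon", metag]))
  }
  expect_gt(mean(minMeta), mean(maxAmp))
})

test_that("the first axis separates biostimulated samples", {
  tr <- generateTruth(seed = 10)
  mc <- mciaFit(methodTables(tr, seed = 10), nAxes = 2)
  ax1 <- globalScores(mc)[, 1]
  swob <- grepl("^SWOB", truthDesign(tr)$sample)
  # silhouette of the SWOB group on axis 1
  sil <- vapply(which(swob), function(i) {
    a <- mean(abs(ax1[i] - ax1[swob][-match(i, which(swob))]))
    b <- mean(abs(ax1[i] - ax1[!swob]))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})
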