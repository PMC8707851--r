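# Multiple co-inertia analysis (MCoA) of K sample-matched tables.
#
# Axis f maximizes the sum over tables of squared covariances between a
# table score X_k u_k (unit-norm u_k) and a common unit-variance
# reference score v, subject to orthogonality with previous axes. The
# solution is the leading eigenvector of the pooled cross-product
# operator sum_k X_k X_k^T; per-table squared covariances are the
# pseudo-eigenvalues and sum to the axis eigenvalue.

.preprocessNsc <- function(X) {
  X <- as.matrix(X)
  if (min(X) < 0) X <- X - min(X)
  tot <- sum(X)
  if (tot <= 0) .stopf("zero-inertia table")
  F <- X / tot
  rs <- rowSums(F)
  if (any(rs <= 0)) .stopf("table has an empty sample row")
  R <- sweep(F, 1, rs, "/")              # row profiles
  Z <- sweep(R, 2, colSums(F), "-")      # non-symmetric CA centering
  sweep(Z, 2, colMeans(Z), "-")          # exact column centering
}

.preprocessCenterScale <- function(X) {
  X <- as.matrix(X)
  Z <- scale(X, center = TRUE, scale = FALSE)
  sds <- apply(Z, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(Z, 2, sds, "/")
}

.scaleInertia <- function(Z) {
  n <- nrow(Z)
  inertia <- sum(Z^2) / n
  if (inertia <= 0) .stopf("zero-inertia table")
  Z / sqrt(inertia)
}

#' RV coefficient between two sample-matched tables
#'
#' The multivariate generalization of the squared Pearson correlation:
#' \deqn{RV = \frac{tr(XX^T YY^T)}{\sqrt{tr((XX^T)^2)\, tr((YY^T)^2)}}}
#' computed after column centering; values lie in [0, 1].
#'
#' @param X,Y matrices with the same number of rows (samples).
#' @return RV coefficient.
#' @export
rvCoefficient <- function(X, Y) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  if (nrow(X) != nrow(Y)) .stopf("tables must share the sample count")
  sx <- tcrossprod(X); sy <- tcrossprod(Y)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den <= 0) .stopf("zero-inertia table")
  sum(sx * sy) / den
}

#' Fit a multiple co-inertia analysis
#'
#' Tables are preprocessed (default: non-symmetric correspondence
#' weighting — relative frequencies, row profiles centered by the column
#' marginal — or plain center-and-scale), scaled to total inertia 1, and
#' ordinated jointly. Successive axes are obtained by projecting the
#' global score direction out of every table (deflation), which makes
#' global scores of distinct axes exactly uncorrelated and reduces to
#' PCA when K = 1.
#'
#' @param tables named list of K sample x variable matrices sharing row
#'   order (sample names, when present, must agree).
#' @param nAxes number of axes to retain.
#' @param preprocess \code{"nsc"} or \code{"centerScale"}.
#' @return an \linkS4class{MCIAResult}.
#' @export
mciaFit <- function(tables, nAxes = 2, preprocess = c("nsc", "centerScale")) {
  preprocess <- match.arg(preprocess)
  if (!is.list(tables) || length(tables) < 1) .stopf("need K >= 1 tables")
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  n <- nrow(as.matrix(tables[[1]]))
  rn <- rownames(as.matrix(tables[[1]]))
  for (k in seq_along(tables)) {
    Xk <- as.matrix(tables[[k]])
    if (nrow(Xk) != n) .stopf("tables must share the sample set")
    if (!is.null(rn) && !is.null(rownames(Xk)) &&
        !identical(rownames(Xk), rn))
      .stopf("tables must share the sample order")
    if (any(!is.finite(Xk))) .stopf("non-finite entries in table %d", k)
  }
  pp <- switch(preprocess, nsc = .preprocessNsc,
               centerScale = .preprocessCenterScale)
  Z <- lapply(tables, function(X) .scaleInertia(pp(X)))

  M0 <- Reduce(`+`, lapply(Z, tcrossprod))
  fullSpec <- pmax(eigen(M0, symmetric = TRUE, only.values = TRUE)$values, 0) / n
  rank <- sum(fullSpec > max(fullSpec) * 1e-10)
  if (nAxes > rank) .stopf("nAxes (%d) exceeds the rank (%d)", nAxes, rank)

  W <- Z
  K <- length(Z)
  ev <- numeric(nAxes)
  pseudo <- matrix(0, K, nAxes,
                   dimnames = list(names(tables), paste0("axis", seq_len(nAxes))))
  gScores <- matrix(0, n, nAxes,
                    dimnames = list(rn, paste0("axis", seq_len(nAxes))))
  tScores <- lapply(Z, function(z)
    matrix(0, n, nAxes, dimnames = list(rn, paste0("axis", seq_len(nAxes)))))
  loads <- lapply(Z, function(z)
    matrix(0, ncol(z), nAxes,
           dimnames = list(colnames(z), paste0("axis", seq_len(nAxes)))))
  for (f in seq_len(nAxes)) {
    M <- Reduce(`+`, lapply(W, tcrossprod))
    es <- eigen(M, symmetric = TRUE)
    vtil <- es$vectors[, 1]
    if (vtil[which.max(abs(vtil))] < 0) vtil <- -vtil
    ev[f] <- max(es$values[1], 0) / n
    for (k in seq_len(K)) {
      w <- drop(crossprod(W[[k]], vtil))
      nw <- sqrt(sum(w^2))
      pseudo[k, f] <- nw^2 / n
      u <- if (nw > 0) w / nw else w
      loads[[k]][, f] <- u
      tScores[[k]][, f] <- drop(W[[k]] %*% u)
    }
    gScores[, f] <- sqrt(n) * vtil * sqrt(ev[f])
    W <- lapply(W, function(w) w - vtil %*% crossprod(vtil, w))
  }

  rv <- matrix(1, K, K, dimnames = list(names(tables), names(tables)))
  if (K > 1)
    for (i in 1:(K - 1)) for (j in (i + 1):K)
      rv[i, j] <- rv[j, i] <- min(1, max(0, rvCoefficient(Z[[i]], Z[[j]])))

  new("MCIAResult", eigenvalues = ev, fullSpectrum = fullSpec,
      pseudoEigenvalues = pseudo,
      varianceProportions = ev / sum(fullSpec), globalScores = gScores,
      tableScores = tScores, loadings = loads, rv = rv,
      tableNames = names(tables))
}
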