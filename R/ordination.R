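ordination_result <- function(points, method, eigenvalues = NULL,
                              prop_explained = NULL, stress = NA_real_,
                              negative_eigenvalues = numeric(0),
                              loadings = NULL, converged = NA) {
  structure(list(points = points, method = method,
                 eigenvalues = eigenvalues,
                 prop_explained = prop_explained, stress = stress,
                 negative_eigenvalues = negative_eigenvalues,
                 loadings = loadings, converged = converged),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", x$method,
              nrow(x$points), ncol(x$points)))
  if (!is.null(x$prop_explained)) {
    cat("proportion explained:",
        paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 4L)),
              collapse = ", "), "\n")
  }
  if (!is.na(x$stress)) cat(sprintf("stress: %.4f\n", x$stress))
  invisible(x)
}

#' Principal coordinate analysis (metric MDS)
#'
#' Classical scaling of a dissimilarity matrix: the matrix `-d^2/2` is
#' double-centred (Gower), eigendecomposed, and coordinates are the
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' The proportion explained by each axis is its eigenvalue over the sum of
#' positive eigenvalues. Negative eigenvalues (possible for semi-metric
#' dissimilarities such as Bray-Curtis) are reported but excluded from the
#' coordinates; no Lingoes/Cailliez correction is applied.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @return an `ordination_result` with `points`, `eigenvalues` (positive),
#'   `prop_explained` and `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  lambda <- e$values[pos]
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda),
                                                 nrow = sum(pos))
  dimnames(pts) <- list(rownames(D), paste0("PCo", seq_len(sum(pos))))
  ordination_result(pts, "PCoA", eigenvalues = lambda,
                    prop_explained = lambda / sum(lambda),
                    negative_eigenvalues = e$values[e$values < -tol])
}

# pool-adjacent-violators fit of y (ordered) -- non-decreasing solution
pava <- function(y) {
  n <- length(y)
  fit <- y
  w <- rep(1, n)
  i <- 1L
  vals <- numeric(n); wts <- numeric(n); len <- integer(n); nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    vals[nb] <- y[i]; wts[nb] <- 1; len[nb] <- 1L
    while (nb > 1L && vals[nb - 1L] > vals[nb]) {
      tw <- wts[nb - 1L] + wts[nb]
      vals[nb - 1L] <- (vals[nb - 1L] * wts[nb - 1L] +
                          vals[nb] * wts[nb]) / tw
      wts[nb - 1L] <- tw
      len[nb - 1L] <- len[nb - 1L] + len[nb]
      nb <- nb - 1L
    }
  }
  rep.int(vals[seq_len(nb)], len[seq_len(nb)])
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 by iterative majorisation (Guttman
#' transform) alternated with monotone regression of configuration
#' distances on the input dissimilarities (pool-adjacent-violators;
#' primary/"weak" tie treatment: tied dissimilarities are ordered by the
#' current configuration distances and need not receive equal
#' disparities). The best of `n_starts` starts is returned: the first
#' start is the PCoA configuration, the rest are random.
#'
#' @param d dissimilarity matrix or [stats::dist].
#' @param k embedding dimension (default 2).
#' @param n_starts number of starts (>= 1).
#' @param seed integer seed for the random starts.
#' @param max_iter,tol iteration cap and relative stress-change tolerance.
#' @return `ordination_result` with `points` (centred, principal-axis
#'   rotated), `stress` (Kruskal stress-1 of the best start) and
#'   `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1L, max_iter = 300,
                 tol = 1e-7) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n <= k + 1L) stop("NMDS needs more than k + 1 samples")
  pair <- which(upper.tri(D))
  diss <- D[pair]
  set.seed(seed)
  run_one <- function(X) {
    stress <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dc <- as.matrix(stats::dist(X))
      dvec <- dc[pair]
      ord <- order(diss, dvec)  # primary tie treatment
      disp <- numeric(length(dvec))
      disp[ord] <- pava(dvec[ord])
      denom <- sum(dvec^2)
      new_stress <- if (denom > 0) sqrt(sum((dvec - disp)^2) / denom) else 0
      if (is.finite(stress) &&
          abs(stress - new_stress) < tol * max(stress, 1e-12)) {
        stress <- new_stress
        converged <- TRUE
        break
      }
      stress <- new_stress
      # Guttman transform with disparities as targets
      Dhat <- matrix(0, n, n)
      Dhat[pair] <- disp
      Dhat <- Dhat + t(Dhat)
      ratio <- ifelse(dc > 0, Dhat / dc, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    list(X = X, stress = stress, converged = converged)
  }
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    X0 <- if (s == 1L) {
      p <- pcoa(stats::as.dist(D))$points
      if (ncol(p) >= k) p[, seq_len(k), drop = FALSE] else
        cbind(p, matrix(stats::rnorm(n * (k - ncol(p)), sd = 1e-3), n))
    } else {
      matrix(stats::rnorm(n * k), n, k)
    }
    res <- run_one(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  X <- X %*% svd(X)$v  # principal-axis rotation
  dimnames(X) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  ordination_result(X, "NMDS", stress = best$stress,
                    converged = best$converged)
}

#' Principal component analysis of soil properties
#'
#' Column-standardised (when `scale = TRUE`) PCA, as used to ordinate soil
#' physicochemical profiles across stands.
#'
#' @param x numeric matrix or data.frame, samples x variables, no missing
#'   values.
#' @param scale standardise columns to unit variance.
#' @return `ordination_result` with scores in `points`, `eigenvalues`
#'   (variances of the components), `prop_explained` and variable
#'   `loadings`.
#' @export
pca <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("PCA needs at least 2 variables")
  if (anyNA(x)) stop("PCA input contains missing values")
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance column(s) with scale = TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- fit$sdev^2
  ordination_result(fit$x, "PCA", eigenvalues = ev,
                    prop_explained = ev / sum(ev),
                    loadings = fit$rotation)
}
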