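standardize_explanatory <- function(x, no_scale = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance explanatory variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  do_scale <- !(colnames(x) %in% no_scale)
  x <- sweep(x, 2L, colMeans(x))
  x[, do_scale] <- sweep(x[, do_scale, drop = FALSE], 2L,
                         sds[do_scale], "/")
  x
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a dissimilarity matrix on explanatory
#' variables: the principal coordinates with positive eigenvalues form
#' the response matrix Y, Y is regressed on the (centred, standardised)
#' explanatory matrix by least squares, and the constrained proportion is
#' `trace(Yhat' Yhat) / trace(Y' Y)`. The pseudo-F statistic
#' `(trace_constrained/q) / (trace_residual/(n-q-1))` is tested by
#' permuting the rows of the explanatory matrix. Negative-eigenvalue
#' principal coordinates are dropped (no correction), keeping the
#' constrained proportion interpretable.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param x explanatory variables (numeric data.frame or matrix, samples
#'   in rows, full column rank after standardisation).
#' @param n_permutations permutations for the pseudo-F test.
#' @param seed integer seed.
#' @param no_scale character vector of columns centred but not scaled to
#'   unit variance (conventionally `"pH"`, which is already on a fixed
#'   scale).
#' @return object of class `dbrda_result`: `constrained_proportion`,
#'   `constrained_eigenvalues`, `unconstrained_eigenvalues`, `pseudo_F`,
#'   `p_value`, `site_scores` (on constrained axes).
#' @export
dbrda <- function(d, x, n_permutations = 999, seed = 1L, no_scale = NULL) {
  X <- standardize_explanatory(x, no_scale)
  n <- nrow(X)
  ord <- pcoa(d)
  Y <- ord$points
  if (nrow(Y) != n) stop("explanatory rows must match samples")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient explanatory matrix; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  q <- ncol(X)
  if (n <= q + 1L) stop("need more samples than explanatory variables")
  tt <- sum(Y^2)
  fit_trace <- function(Xp) sum(qr.fitted(qr(Xp), Y)^2)
  tc <- fit_trace(X)
  f_obs <- (tc / q) / ((tt - tc) / (n - q - 1L))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    tcp <- fit_trace(X[sample.int(n), , drop = FALSE])
    fp <- (tcp / q) / ((tt - tcp) / (n - q - 1L))
    if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  Yhat <- qr.fitted(qr_x, Y)
  ec <- eigen(crossprod(Yhat), symmetric = TRUE)
  keep <- ec$values > max(ec$values, 0) * 1e-9
  eu <- eigen(crossprod(Y - Yhat), symmetric = TRUE)$values
  scores <- Yhat %*% ec$vectors[, keep, drop = FALSE]
  colnames(scores) <- paste0("dbRDA", seq_len(sum(keep)))
  rownames(scores) <- rownames(Y)
  structure(list(constrained_proportion = tc / tt,
                 constrained_eigenvalues = ec$values[keep],
                 unconstrained_eigenvalues = eu[eu > 1e-12],
                 pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 site_scores = scores, variables = colnames(X)),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "db-RDA: constrained proportion = %.3f, pseudo-F = %.4g, p = %.4g\n",
    x$constrained_proportion, x$pseudo_F, x$p_value))
  invisible(x)
}

#' Permutation forward selection of explanatory variables
#'
#' Builds a db-RDA model by forward selection: at each step the candidate
#' whose marginal addition has the smallest permutation p-value (ties
#' broken by larger partial pseudo-F) is added, stopping when no
#' candidate reaches `alpha`. To control the selection-wide false
#' positive rate, a global permutation test of the full candidate set is
#' run first (double-stopping rule); if the global model is not
#' significant at `alpha` the selection is empty.
#'
#' @param d dissimilarity matrix.
#' @param candidates data.frame of candidate explanatory variables.
#' @param alpha entry threshold (default 0.05).
#' @param n_permutations permutations per test (default 499).
#' @param seed integer seed.
#' @param no_scale columns not scaled to unit variance (e.g. `"pH"`).
#' @param global_test apply the global pre-test (default `TRUE`).
#' @return object of class `forward_selection`: `selected` (in order),
#'   `step_p`, `step_F`, `global_p`.
#' @export
forward_select <- function(d, candidates, alpha = 0.05,
                           n_permutations = 499, seed = 1L,
                           no_scale = NULL, global_test = TRUE) {
  X <- standardize_explanatory(candidates, no_scale)
  n <- nrow(X)
  Y <- pcoa(d)$points
  tt <- sum(Y^2)
  set.seed(seed)
  global_p <- NA_real_
  if (global_test) {
    Xg <- X
    qg <- qr(Xg)$rank
    trace_of <- function(M) sum(qr.fitted(qr(M), Y)^2)
    tc <- trace_of(Xg)
    f_obs <- (tc / qg) / ((tt - tc) / (n - qg - 1L))
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      tcp <- trace_of(Xg[sample.int(n), , drop = FALSE])
      fp <- (tcp / qg) / ((tt - tcp) / (n - qg - 1L))
      if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    global_p <- (1 + exceed) / (1 + n_permutations)
    if (global_p >= alpha) {
      return(structure(list(selected = character(0),
                            step_p = numeric(0), step_F = numeric(0),
                            global_p = global_p),
                       class = "forward_selection"))
    }
  }
  selected <- character(0)
  step_p <- numeric(0)
  step_F <- numeric(0)
  remaining <- colnames(X)
  trace_sel <- 0
  while (length(remaining)) {
    best <- NULL
    for (v in remaining) {
      Xv <- X[, c(selected, v), drop = FALSE]
      qv <- qr(Xv)$rank
      tc_full <- sum(qr.fitted(qr(Xv), Y)^2)
      df_res <- n - qv - 1L
      partial_f <- function(tc) (tc - trace_sel) /
        ((tt - tc) / df_res)
      f_obs <- partial_f(tc_full)
      exceed <- 0L
      for (b in seq_len(n_permutations)) {
        Xp <- Xv
        Xp[, v] <- Xp[sample.int(n), v]
        fp <- partial_f(sum(qr.fitted(qr(Xp), Y)^2))
        if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (1 + n_permutations)
      if (is.null(best) || p < best$p ||
          (p == best$p && f_obs > best$f)) {
        best <- list(v = v, p = p, f = f_obs, tc = tc_full)
      }
    }
    if (best$p >= alpha) break
    selected <- c(selected, best$v)
    step_p <- c(step_p, best$p)
    step_F <- c(step_F, best$f)
    trace_sel <- best$tc
    remaining <- setdiff(remaining, best$v)
  }
  structure(list(selected = selected, step_p = step_p, step_F = step_F,
                 global_p = global_p),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  if (!length(x$selected)) {
    cat("forward selection: no variable selected")
    if (!is.na(x$global_p)) cat(sprintf(" (global p = %.3g)", x$global_p))
    cat("\n")
  } else {
    cat("forward selection order:\n")
    for (i in seq_along(x$selected)) {
      cat(sprintf("  %d. %s (p = %.4g, partial F = %.3g)\n", i,
                  x$selected[i], x$step_p[i], x$step_F[i]))
    }
  }
  invisible(x)
}
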