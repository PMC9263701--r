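#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1,
#' input order preserved (delegates to [stats::p.adjust()] after
#' validating the input range).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson or Spearman correlation with p-value
#'
#' Spearman's rho is Pearson's correlation of average ranks; its p-value
#' is computed by exhaustive permutation of one variable's ranks when
#' n <= 9 (two-sided: proportion of permutations with |rho| at least as
#' large) and by the t approximation with n - 2 degrees of freedom
#' otherwise. Pearson p-values always use the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 4, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y")
  }
  if (method == "spearman") {
    rx <- rank(x)
    ry <- rank(y)
    r <- stats::cor(rx, ry)
    if (n <= 9L) {
      pm <- all_perms(n)
      r_all <- as.vector(stats::cor(rx, t(matrix(ry[pm], nrow(pm), n))))
      p <- mean(abs(r_all) >= abs(r) - 1e-12)
    } else {
      p <- t_cor_p(r, n)
    }
  } else {
    r <- stats::cor(x, y)
    p <- t_cor_p(r, n)
  }
  list(estimate = r, p_value = p, method = method, n = n)
}

t_cor_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Runs a one-way analysis of variance followed by Tukey's honestly
#' significant difference test at level `alpha`, and summarises the
#' pairwise results as a compact letter display (groups sharing a letter
#' do not differ significantly). Accepts either raw values + group
#' labels, or per-group summary statistics (mean, sd, n), from which the
#' pooled mean square error is reconstructed — useful for re-analysing
#' published tables that print mean +/- sd.
#'
#' @param values numeric vector of raw observations (with `groups`), or
#'   `NULL` when summaries are supplied.
#' @param groups group labels for `values`.
#' @param means,sds,ns per-group summaries (named vectors, n >= 2 each);
#'   used when `values` is `NULL`.
#' @param alpha significance level (default 0.05).
#' @return object of class `tukey_letters`: `letters` (named character,
#'   ordered by decreasing mean), `p_matrix` (Tukey adjusted pairwise
#'   p-values), `anova_F`, `anova_p`, `alpha`.
#' @export
anova_tukey <- function(values = NULL, groups = NULL, means = NULL,
                        sds = NULL, ns = NULL, alpha = 0.05) {
  if (!is.null(values)) {
    groups <- as.factor(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
    means <- tapply(values, groups, mean)
    sds <- tapply(values, groups, stats::sd)
    ns <- as.vector(table(groups))
    names(ns) <- levels(groups)
  } else {
    if (is.null(means) || is.null(sds) || is.null(ns)) {
      stop("supply either raw values + groups or means + sds + ns")
    }
    if (any(ns < 2L)) stop("summary input needs n >= 2 per group")
    if (is.null(names(means))) {
      names(means) <- paste0("g", seq_along(means))
    }
    names(sds) <- names(ns) <- names(means)
  }
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  N <- sum(ns)
  df_err <- N - k
  mse <- sum((ns - 1) * sds^2) / df_err
  grand <- sum(ns * means) / N
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  if (mse > 0) {
    f <- msb / mse
    anova_p <- stats::pf(f, k - 1, df_err, lower.tail = FALSE)
  } else {
    f <- if (msb > 0) Inf else NaN
    anova_p <- if (msb > 0) 0 else 1
  }
  pm <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      if (se == 0) {
        p <- if (means[i] == means[j]) 1 else 0
      } else {
        q <- abs(means[i] - means[j]) / se
        p <- stats::ptukey(q, nmeans = k, df = df_err,
                           lower.tail = FALSE)
      }
      pm[i, j] <- pm[j, i] <- p
    }
  }
  ord <- order(means, decreasing = TRUE)
  letters_out <- cld_insert_absorb(pm[ord, ord, drop = FALSE] < alpha)
  structure(list(letters = letters_out, p_matrix = pm, anova_F = f,
                 anova_p = anova_p, alpha = alpha,
                 means = means[ord]),
            class = "tukey_letters")
}

# compact letter display by insert-and-absorb over a logical matrix of
# significant pairs (rows/cols assumed ordered by decreasing mean)
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (cc in cols) {
        if (i %in% cc && j %in% cc) {
          new_cols <- c(new_cols, list(setdiff(cc, i)),
                        list(setdiff(cc, j)))
        } else {
          new_cols <- c(new_cols, list(cc))
        }
      }
      # absorb: drop empties, duplicates, and proper subsets
      new_cols <- unique(lapply(new_cols, sort))
      new_cols <- new_cols[lengths(new_cols) > 0L]
      keep <- vapply(seq_along(new_cols), function(a) {
        !any(vapply(seq_along(new_cols), function(b) {
          b != a && length(new_cols[[a]]) < length(new_cols[[b]]) &&
            all(new_cols[[a]] %in% new_cols[[b]])
        }, logical(1L)))
      }, logical(1L))
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, integer(1L)))]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc,
                               logical(1L)))], collapse = "")
  }, character(1L))
  names(out) <- rownames(sig)
  out
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g; Tukey HSD at alpha = %g\n",
              x$anova_F, x$anova_p, x$alpha))
  df <- data.frame(mean = x$means, letters = x$letters[names(x$means)])
  print(df)
  invisible(x)
}

#' Significance stars for p-values
#' @param p numeric vector.
#' @return character vector: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#'   `""` otherwise.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}
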