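# all permutations of 1..n as an n! x n matrix (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities between and within
#' groups: `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g
#' sum_{i<j in g} d_ij^2 / n_g`, `SS_between = SS_total - SS_within`, and
#' tests `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))` by free
#' permutation of the group labels. With `n_permutations = "exact"` all
#' label assignments are enumerated (small n only) and the p-value is the
#' exact proportion of assignments with F at least as large as observed;
#' otherwise p = (1 + exceedances) / (1 + n_permutations), which cannot
#' be 0.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param labels group labels, one per sample; >= 2 groups with >= 2
#'   samples each.
#' @param n_permutations number of random permutations (default 999) or
#'   `"exact"`.
#' @param seed integer seed for the permutation draw.
#' @return object of class `permanova_result`: `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1L) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels must match the number of samples")
  sizes <- table(labels)
  a <- length(sizes)
  if (a < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  d2 <- D^2
  ss_total <- sum(d2) / (2 * n)
  if (ss_total == 0) stop("constant (all-zero) distance matrix: F undefined")
  lab_int <- as.integer(labels)
  n_g <- tabulate(lab_int, a)
  stat <- function(lab) {
    G <- matrix(0, n, a)
    G[cbind(seq_len(n), lab)] <- 1
    ss_within <- sum(colSums((d2 %*% G) * G) / (2 * n_g))
    ss_between <- ss_total - ss_within
    c(f = (ss_between / (a - 1L)) / (ss_within / (n - a)),
      r2 = ss_between / ss_total)
  }
  obs <- stat(lab_int)
  if (identical(n_permutations, "exact")) {
    if (n > 9L) stop("exact enumeration limited to n <= 9")
    pm <- all_perms(n)
    f_all <- apply(pm, 1L, function(p) stat(lab_int[p])[["f"]])
    p_value <- mean(f_all >= obs[["f"]] - 1e-12)
    n_perm_used <- nrow(pm)
  } else {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      fp <- stat(lab_int[sample.int(n)])[["f"]]
      if (fp >= obs[["f"]] - 1e-12) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (1 + n_permutations)
    n_perm_used <- as.integer(n_permutations)
  }
  structure(list(pseudo_F = obs[["f"]], R2 = obs[["r2"]],
                 p_value = p_value, n_permutations = n_perm_used,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}
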