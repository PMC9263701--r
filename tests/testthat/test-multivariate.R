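test_that("PERMANOVA separates a degenerate two-cluster design completely", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  rownames(D) <- colnames(D) <- paste0("s", 1:4)
  res <- permanova(as.dist(D), c("A", "A", "B", "B"),
                   n_permutations = "exact")
  expect_equal(res$R2, 1)
  expect_equal(res$pseudo_F, Inf)
  # minimum attainable p under exhaustive enumeration: only the two
  # cluster-respecting label assignments reach this F
  expect_equal(res$p_value, 1 / 3)
})

test_that("exact PERMANOVA p and F match the exhaustive oracle", {
  set.seed(51)
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(pts))
    rownames(D) <- colnames(D) <- paste0("s", 1:n)
    labels <- sample(rep(c("A", "B"), length.out = n))
    if (min(table(labels)) < 2) next
    res <- permanova(as.dist(D), labels, n_permutations = "exact")
    ora <- oracle_permanova_exact(D, labels)
    expect_equal(res$pseudo_F, ora$f, tolerance = 1e-10)
    expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  }
})

test_that("PERMANOVA agrees with the independent vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(52)
  m <- matrix(rpois(12 * 20, 15), 12, 20,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:20)))
  d <- bray_curtis(m)
  lab <- rep(c("A", "B", "C"), each = 4)
  res <- permanova(d, lab, n_permutations = 199, seed = 1)
  ref <- vegan::adonis2(d ~ lab, permutations = 199)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA R2 is invariant to relabeling and sample order", {
  set.seed(53)
  m <- matrix(rpois(10 * 15, 10), 10, 15,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:15)))
  d <- bray_curtis(m)
  lab <- rep(c("A", "B"), each = 5)
  r1 <- permanova(d, lab, n_permutations = 49, seed = 1)$R2
  r2 <- permanova(d, ifelse(lab == "A", "zebra", "ant"),
                  n_permutations = 49, seed = 1)$R2
  perm <- sample(10)
  d2 <- as.dist(as.matrix(d)[perm, perm])
  r3 <- permanova(d2, lab[perm], n_permutations = 49, seed = 1)$R2
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("PERMANOVA rejects invalid designs", {
  D <- as.dist(matrix(1, 4, 4) - diag(4))
  expect_error(permanova(D, c("A", "A", "A", "B")), "size 1")
  expect_error(permanova(D, c("A", "A", "A", "A")), "2 groups")
  expect_error(permanova(as.dist(matrix(0, 4, 4)),
                         c("A", "A", "B", "B")), "undefined")
})

test_that("db-RDA explains exactly the axis it is fed", {
  set.seed(61)
  m <- matrix(rpois(12 * 18, 12), 12, 18,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:18)))
  d <- bray_curtis(m)
  ord <- pcoa(d)
  x <- data.frame(ax1 = ord$points[, 1])
  res <- dbrda(d, x, n_permutations = 99, seed = 1)
  expect_equal(res$constrained_proportion, ord$prop_explained[1],
               tolerance = 1e-9)
  # the full axis set explains everything
  full <- as.data.frame(ord$points)
  res_full <- dbrda(d, full, n_permutations = 9, seed = 1)
  expect_equal(res_full$constrained_proportion, 1, tolerance = 1e-9)
})

test_that("db-RDA input contracts: variance, rank, alignment", {
  set.seed(62)
  m <- matrix(rpois(10 * 12, 10), 10, 12,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:12)))
  d <- bray_curtis(m)
  expect_error(dbrda(d, data.frame(flat = rep(2, 10))), "zero-variance")
  z <- rnorm(10)
  expect_error(dbrda(d, data.frame(a = z, b = 2 * z)), "collinear")
})

test_that("db-RDA constrained proportion matches vegan on Euclidean input", {
  skip_if_not_installed("vegan")
  set.seed(63)
  pts <- matrix(rnorm(12 * 4), 12, 4)
  rownames(pts) <- paste0("s", 1:12)
  d <- dist(pts)
  x <- data.frame(v1 = rnorm(12), v2 = rnorm(12))
  mine <- dbrda(d, x, n_permutations = 9, seed = 1)
  ref <- vegan::dbrda(d ~ v1 + v2, data = as.data.frame(scale(x)))
  ref_prop <- ref$CCA$tot.chi / ref$tot.chi
  expect_equal(mine$constrained_proportion, ref_prop, tolerance = 1e-8)
})

test_that("forward selection finds a planted driver before noise", {
  set.seed(71)
  grad <- seq(-1.5, 1.5, length.out = 14)
  m <- matrix(rpois(14 * 25, exp(2 + outer(grad, rnorm(25)))), 14, 25,
              dimnames = list(paste0("s", 1:14), paste0("t", 1:25)))
  d <- bray_curtis(m)
  cand <- data.frame(driver = grad,
                     n1 = rnorm(14), n2 = rnorm(14), n3 = rnorm(14),
                     n4 = rnorm(14), n5 = rnorm(14))
  sel <- forward_select(d, cand, n_permutations = 199, seed = 2)
  expect_gt(length(sel$selected), 0)
  expect_equal(sel$selected[1], "driver")
})

test_that("a duplicated informative variable is selected only once", {
  set.seed(72)
  grad <- seq(-1.5, 1.5, length.out = 12)
  m <- matrix(rpois(12 * 20, exp(2 + outer(grad, rnorm(20)))), 12, 20,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:20)))
  d <- bray_curtis(m)
  cand <- data.frame(a = grad, b = grad)
  sel <- forward_select(d, cand, n_permutations = 199, seed = 3)
  expect_equal(length(sel$selected), 1)
})

test_that("Tukey letters separate clearly different groups and merge equal ones", {
  # identical groups share a letter
  res <- anova_tukey(means = c(g1 = 5, g2 = 5, g3 = 5),
                     sds = c(0.5, 0.5, 0.5), ns = c(3, 3, 3))
  expect_true(all(res$letters == "a"))
  # huge separation, tiny variance
  res2 <- anova_tukey(means = c(lo = 1, hi = 100),
                      sds = c(0.01, 0.01), ns = c(3, 3))
  expect_equal(length(unique(res2$letters)), 2)
  # raw-value interface agrees with the summary interface
  set.seed(81)
  vals <- c(rnorm(5, 0), rnorm(5, 4), rnorm(5, 4.2))
  grp <- rep(c("a", "b", "c"), each = 5)
  r_raw <- anova_tukey(values = vals, groups = grp)
  r_sum <- anova_tukey(means = tapply(vals, grp, mean),
                       sds = tapply(vals, grp, sd), ns = c(5, 5, 5))
  expect_equal(unname(r_raw$p_matrix), unname(r_sum$p_matrix),
               tolerance = 1e-9)
})

test_that("Tukey pairwise p-values match the base TukeyHSD reference", {
  set.seed(82)
  vals <- c(rnorm(6, 0), rnorm(6, 1.5), rnorm(6, 1.7))
  grp <- factor(rep(c("a", "b", "c"), each = 6))
  mine <- anova_tukey(values = vals, groups = grp)
  ref <- TukeyHSD(aov(vals ~ grp))$grp
  expect_equal(mine$p_matrix["b", "a"], ref["b-a", "p adj"],
               tolerance = 1e-8)
  expect_equal(mine$p_matrix["c", "b"], ref["c-b", "p adj"],
               tolerance = 1e-8)
})

test_that("compact letters satisfy the sharing-significance equivalence", {
  set.seed(83)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    means <- rnorm(k, sd = 2)
    names(means) <- paste0("g", seq_len(k))
    res <- anova_tukey(means = means, sds = rep(0.8, k),
                       ns = rep(4, k))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        share <- any(strsplit(res$letters[[names(means)[i]]], "")[[1]]
                     %in% strsplit(res$letters[[names(means)[j]]],
                                   "")[[1]])
        sig <- res$p_matrix[names(means)[i], names(means)[j]] <
          res$alpha
        expect_equal(share, !sig)
      }
    }
  }
})

test_that("correlation utilities match closed forms and the exact null", {
  x <- 1:8
  expect_equal(correlate(x, exp(x), method = "spearman")$estimate, 1)
  expect_equal(correlate(x, -x, method = "pearson")$estimate, -1)
  expect_error(correlate(1:5, rep(2, 5)), "zero variance")
  expect_error(correlate(1:3, 1:3), "at least 4")
  # n = 5 Spearman p equals the 120-permutation enumeration
  set.seed(91)
  for (rep in 1:5) {
    x <- rnorm(5)
    y <- rnorm(5)
    got <- correlate(x, y, method = "spearman")
    rx <- rank(x)
    ry <- rank(y)
    pm <- permutations_of(5)
    r_all <- apply(pm, 1, function(p) cor(rx, ry[p]))
    p_exact <- mean(abs(r_all) >= abs(got$estimate) - 1e-12)
    expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  }
  # larger n: t approximation agrees with cor.test
  set.seed(92)
  x <- rnorm(20)
  y <- x + rnorm(20)
  got <- correlate(x, y, method = "pearson")
  ref <- cor.test(x, y)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(93)
  for (rep in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone: ordering of adjusted follows ordering of raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})
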