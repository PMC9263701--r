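# independent brute-force oracles, deliberately naive ---------------------

# elementwise Bray-Curtis, no vectorisation shared with the implementation
oracle_bray <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  unname(num / den)
}

# all-pairs shortest path lengths by Floyd-Warshall on the adjacency
oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  a <- matrix(Inf, n, n)
  diag(a) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    a[el[e, 1], el[e, 2]] <- 1
    a[el[e, 2], el[e, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (a[i, k] + a[k, j] < a[i, j]) a[i, j] <- a[i, k] + a[k, j]
      }
    }
  }
  a
}

oracle_apl <- function(g) {
  d <- oracle_distances(g)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) 0 else mean(v)
}

oracle_diameter <- function(g) {
  d <- oracle_distances(g)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) 0 else max(v)
}

# mean local clustering, 0 for degree < 2, by direct triangle counting
oracle_clustering <- function(g) {
  n <- igraph::vcount(g)
  a <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    a[el[e, 1], el[e, 2]] <- 1
    a[el[e, 2], el[e, 1]] <- 1
  }
  local <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) links <- links + a[nb[i], nb[j]]
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

# exhaustive betweenness: enumerate every shortest path between every
# ordered pair by depth-first search over simple paths
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  d <- oracle_distances(g)
  a <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    a[el[e, 1], el[e, 2]] <- 1
    a[el[e, 2], el[e, 1]] <- 1
  }
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        if (length(path) - 1 == d[s, t]) out[[length(out) + 1]] <<- path
        return(invisible())
      }
      if (length(path) - 1 >= d[s, t]) return(invisible())
      for (w in which(a[v, ] == 1)) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    out
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      ps <- paths_between(s, t)
      if (!length(ps)) next
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        for (v in inner) b[v] <- b[v] + 1 / length(ps)
      }
    }
  }
  b
}

oracle_centralization_betweenness <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 2) return(0)
  b <- oracle_betweenness(g) / ((n - 1) * (n - 2) / 2)
  sum(max(b) - b) / (n - 1)
}

# modularity of a partition straight from its definition
oracle_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  q <- 0
  for (cc in unique(membership)) {
    inside <- sum(membership[el[, 1]] == cc & membership[el[, 2]] == cc)
    deg_sum <- sum(igraph::degree(g)[membership == cc])
    q <- q + inside / m - (deg_sum / (2 * m))^2
  }
  q
}

# exhaustive one-way PERMANOVA: every permutation of the label vector,
# sums of squares computed pair by pair
oracle_permanova_exact <- function(D, labels) {
  n <- nrow(D)
  f_of <- function(lab) {
    groups <- unique(lab)
    sst <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (gg in groups) {
      idx <- which(lab == gg)
      s <- 0
      if (length(idx) > 1) {
        for (i in 1:(length(idx) - 1)) {
          for (j in (i + 1):length(idx)) {
            s <- s + D[idx[i], idx[j]]^2
          }
        }
      }
      ssw <- ssw + s / length(idx)
    }
    a <- length(groups)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(labels)
  perm_rows <- permutations_of(n)
  f_all <- apply(perm_rows, 1, function(p) f_of(labels[p]))
  list(f = f_obs, p = mean(f_all >= f_obs - 1e-12))
}

# recursive permutation generator, independent of the package's
permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(ifelse(sub >= i, sub + 1, sub), nrow(sub)))
  }))
}

# step-up BH straight from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
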