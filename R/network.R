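#' Family-family correlation matrices for one age group
#'
#' Computes the all-pairs Spearman (or Pearson) correlation matrix over
#' family-level abundances within a group of samples, together with raw
#' p-values from the t approximation with n - 2 degrees of freedom.
#' Families with zero variance across the group's samples carry no
#' correlation information and are excluded up front with a message.
#'
#' @param x samples x families abundance matrix for one age group
#'   (rarefied counts or relative abundances).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `rho` and `p` (symmetric matrices over retained
#'   families; unit diagonal in `rho`, `NA` diagonal in `p`), `n_samples`
#'   and `excluded` (names of dropped families).
#' @export
family_correlations <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- unclass(as.matrix(x))
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 samples per group for correlations")
  sds <- apply(m, 2L, stats::sd)
  excluded <- colnames(m)[sds == 0]
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " zero-variance famil(ies): ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ..." else "")
    m <- m[, sds > 0, drop = FALSE]
  }
  if (method == "spearman") m <- apply(m, 2L, rank)
  rho <- stats::cor(m)
  rho <- pmin(pmax(rho, -1), 1)
  tt <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- NA_real_
  diag(rho) <- 1
  list(rho = rho, p = p, n_samples = n, excluded = excluded)
}

#' Build a thresholded co-occurrence network
#'
#' Turns correlation and p-value matrices into a signed co-occurrence
#' graph: p-values on the upper triangle are Benjamini-Hochberg adjusted
#' (unless `use_fdr = FALSE`), and an edge is kept iff `|rho| >
#' r_threshold` and the (adjusted) p is below `p_threshold`. Edge sign is
#' the sign of rho. Node attributes `family`, `phylum` and `abundance`
#' (mean relative abundance) are attached when taxonomy/abundances are
#' given; isolated nodes are dropped by default.
#'
#' @param rho,p symmetric matrices as returned by
#'   [family_correlations()].
#' @param r_threshold minimum `|rho|` (default 0.8, must be < 1).
#' @param p_threshold maximum (adjusted) p (default 0.01).
#' @param use_fdr adjust p-values with Benjamini-Hochberg before
#'   thresholding (default `TRUE`).
#' @param taxonomy optional [taxonomy_table()] keyed by family name,
#'   used to attach a `phylum` vertex attribute.
#' @param abundances optional named vector of mean relative abundances.
#' @param keep_isolated keep nodes without any edge (default `FALSE`).
#' @param group optional group label stored as a graph attribute.
#' @return an undirected igraph graph with edge attributes `rho`,
#'   `p_raw`, `p_adj`, `sign` and the node attributes described above.
#' @export
build_network <- function(rho, p, r_threshold = 0.8, p_threshold = 0.01,
                          use_fdr = TRUE, taxonomy = NULL,
                          abundances = NULL, keep_isolated = FALSE,
                          group = NA_character_) {
  if (!identical(dim(rho), dim(p)) ||
      !identical(rownames(rho), rownames(p))) {
    stop("rho and p matrices must share dimensions and indices")
  }
  if (r_threshold < 0 || r_threshold >= 1) {
    stop("r_threshold must lie in [0, 1)")
  }
  fam <- rownames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  p_raw <- p[ut]
  p_adj <- if (use_fdr) bh_adjust(p_raw) else p_raw
  keep <- abs(rho[ut]) > r_threshold & p_adj < p_threshold
  edges <- data.frame(
    from = fam[ut[keep, 1L]], to = fam[ut[keep, 2L]],
    rho = rho[ut][keep], p_raw = p_raw[keep], p_adj = p_adj[keep],
    sign = ifelse(rho[ut][keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  vertices <- data.frame(name = fam, family = fam,
                         stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    vertices$phylum <- taxonomy$phylum[match(fam, taxonomy$family)]
    vertices$phylum[is.na(vertices$phylum)] <- "unclassified"
  }
  if (!is.null(abundances)) {
    vertices$abundance <- as.numeric(abundances[fam])
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "group", group)
  if (!keep_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g
}

#' Per-sample subnetwork of a group co-occurrence network
#'
#' Induces the subgraph of a group-level network on the families present
#' (abundance > 0) in one sample, restricting edges accordingly.
#'
#' @param network igraph graph from [build_network()].
#' @param sample_abundances named numeric vector of family abundances
#'   for one sample (names matched against node names).
#' @return the induced igraph subgraph.
#' @export
extract_subnetwork <- function(network, sample_abundances) {
  present <- names(sample_abundances)[sample_abundances > 0]
  keep <- intersect(igraph::V(network)$name, present)
  igraph::induced_subgraph(network, keep)
}

#' Topological parameter suite of a co-occurrence network
#'
#' Computes the standard descriptors used to characterise microbial
#' co-occurrence networks, treating edges as unweighted and undirected:
#' average path length and diameter over connected pairs only, average
#' degree `2m/n`, graph density `2m/(n(n-1))`, mean local clustering
#' coefficient (0 for nodes of degree < 2), modularity and number of
#' communities from a deterministic greedy modularity-maximising
#' partition, and Freeman betweenness centralization
#' `sum(b_max - b_i)/(n-1)` with node betweenness normalised to \[0, 1\]
#' (a star graph scores exactly 1).
#'
#' @param network an igraph graph with >= 1 node.
#' @return object of class `network_topology`: a named list of the
#'   fields above plus `n_nodes`, `n_edges`, `n_positive_edges`,
#'   `n_negative_edges` and a `degenerate` flag for single-node or
#'   edgeless graphs (path-based metrics reported as 0).
#' @export
topology <- function(network) {
  n <- igraph::vcount(network)
  if (n < 1L) stop("network must have at least 1 node")
  m <- igraph::ecount(network)
  sign_attr <- igraph::edge_attr(network, "sign")
  n_pos <- if (is.null(sign_attr)) m else sum(sign_attr == "positive")
  degenerate <- n < 2L || m == 0L
  if (m > 0L) {
    apl <- igraph::mean_distance(network, directed = FALSE,
                                 unconnected = TRUE)
    diam <- igraph::diameter(network, directed = FALSE,
                             unconnected = TRUE)
  } else {
    apl <- 0
    diam <- 0
  }
  dens <- if (n > 1L) 2 * m / (n * (n - 1)) else 0
  clust <- if (m > 0L) {
    igraph::transitivity(network, type = "localaverage",
                         isolates = "zero")
  } else 0
  if (m > 0L) {
    memb <- igraph::membership(igraph::cluster_fast_greedy(network))
    mod <- igraph::modularity(network, memb)
    n_clust <- length(unique(memb))
  } else {
    mod <- 0
    n_clust <- n
  }
  centr <- if (n > 2L) {
    b <- igraph::betweenness(network, directed = FALSE,
                             normalized = TRUE)
    sum(max(b) - b) / (n - 1)
  } else 0
  structure(list(n_nodes = n, n_edges = m, n_positive_edges = n_pos,
                 n_negative_edges = m - n_pos,
                 average_path_length = apl, diameter = as.numeric(diam),
                 average_degree = 2 * m / n, graph_density = dens,
                 clustering_coefficient = clust, modularity = mod,
                 n_clusters = n_clust,
                 centralization_betweenness = centr,
                 degenerate = degenerate),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("network topology:\n")
  print(unlist(x[setdiff(names(x), "degenerate")]))
  invisible(x)
}

#' Combine topology records into a data frame
#' @param topologies list of `network_topology` objects (optionally
#'   named).
#' @return data.frame, one row per network.
#' @export
topology_frame <- function(topologies) {
  df <- do.call(rbind, lapply(topologies, function(t)
    as.data.frame(t[setdiff(names(t), "degenerate")])))
  if (!is.null(names(topologies))) rownames(df) <- names(topologies)
  df
}

#' Newman modularity of a given partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c` is the number of
#' edges inside community `c` and `d_c` the total degree of its nodes.
#'
#' @param network igraph graph with >= 1 edge.
#' @param partition community membership: named vector or vector aligned
#'   with the node order.
#' @return the modularity score Q.
#' @export
modularity_score <- function(network, partition) {
  m <- igraph::ecount(network)
  if (m == 0L) stop("modularity undefined for an edgeless network")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), nodes)) {
      stop("partition must cover all nodes exactly")
    }
    partition <- partition[nodes]
  } else if (length(partition) != length(nodes)) {
    stop("partition must cover all nodes exactly")
  }
  comm <- as.character(partition)
  el <- igraph::as_edgelist(network, names = TRUE)
  c1 <- comm[match(el[, 1L], nodes)]
  c2 <- comm[match(el[, 2L], nodes)]
  deg <- igraph::degree(network)
  d_c <- tapply(deg, comm, sum)
  q <- 0
  for (cc in unique(comm)) {
    e_c <- sum(c1 == cc & c2 == cc)
    q <- q + e_c / m - (d_c[[cc]] / (2 * m))^2
  }
  unname(q)
}

#' Erdos-Renyi G(n, m) null ensemble of topology suites
#'
#' Draws `n_graphs` random simple graphs uniformly among those with
#' exactly `n_nodes` nodes and `n_edges` edges, computes the full
#' topology suite for each, and summarises the ensemble. Used as the
#' size-matched random baseline for small-world assessment.
#'
#' @param n_nodes,n_edges size of every null graph.
#' @param n_graphs ensemble size (default 10000).
#' @param seed integer seed.
#' @return object of class `er_null_ensemble`: `metrics` (n_graphs x
#'   metric matrix), `mean`, `sd`, `q95` (95th percentiles), `n_nodes`,
#'   `n_edges`.
#' @export
er_null_ensemble <- function(n_nodes, n_edges, n_graphs = 10000,
                             seed = 1L) {
  max_m <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_m) {
    stop("impossible edge count: ", n_edges, " (max ", max_m, ")")
  }
  set.seed(seed)
  cols <- c("average_path_length", "diameter", "graph_density",
            "clustering_coefficient", "modularity", "n_clusters",
            "centralization_betweenness", "average_degree")
  mm <- matrix(NA_real_, n_graphs, length(cols),
               dimnames = list(NULL, cols))
  for (i in seq_len(n_graphs)) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    t <- topology(g)
    mm[i, ] <- unlist(t[cols])
  }
  structure(list(metrics = mm, mean = colMeans(mm),
                 sd = apply(mm, 2L, stats::sd),
                 q95 = apply(mm, 2L, stats::quantile, probs = 0.95),
                 n_nodes = n_nodes, n_edges = n_edges,
                 n_graphs = n_graphs, seed = seed),
            class = "er_null_ensemble")
}

#' @export
print.er_null_ensemble <- function(x, ...) {
  cat(sprintf("ER G(n=%d, m=%d) null ensemble of %d graphs\n",
              x$n_nodes, x$n_edges, x$n_graphs))
  print(round(rbind(mean = x$mean, sd = x$sd, q95 = x$q95), 4))
  invisible(x)
}

#' Small-world assessment against a matched random ensemble
#'
#' Compares a real network's average path length, clustering
#' coefficient, number of clusters and modularity against a size-matched
#' Erdos-Renyi ensemble: reports the ratio real/null-mean, the empirical
#' percentile of the real value in the ensemble, and a
#' `higher_than_null` flag set when the real value exceeds the 95th null
#' percentile. Clustering and modularity above the null with comparable
#' path length is the classic small-world / modular signature.
#'
#' @param topo a `network_topology` (see [topology()]).
#' @param ensemble an [er_null_ensemble()] matched on `n_nodes` and
#'   `n_edges`.
#' @return data.frame with one row per metric: `real`, `null_mean`,
#'   `ratio`, `percentile`, `higher_than_null`.
#' @export
small_world_assessment <- function(topo, ensemble) {
  if (topo$n_nodes != ensemble$n_nodes ||
      topo$n_edges != ensemble$n_edges) {
    stop("ensemble not matched on n_nodes/n_edges")
  }
  metrics <- c("average_path_length", "clustering_coefficient",
               "n_clusters", "modularity")
  out <- lapply(metrics, function(m) {
    real <- topo[[m]]
    null_v <- ensemble$metrics[, m]
    data.frame(metric = m, real = real, null_mean = mean(null_v),
               ratio = if (mean(null_v) != 0) real / mean(null_v)
                       else NA_real_,
               percentile = mean(null_v <= real),
               higher_than_null = real >
                 stats::quantile(null_v, 0.95, names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Phylum-level link summary of a network
#'
#' Counts network links within and between phyla: a symmetric matrix
#' whose diagonal holds within-phylum links and whose upper triangle sums
#' (plus the diagonal) equal the total edge count. Optionally truncated
#' to the `top_k` phyla by total link count, with the remainder merged
#' into `"others"`.
#'
#' @param network igraph graph whose nodes carry a `phylum` attribute
#'   (missing attribute or values mapped to `"unclassified"`).
#' @param top_k keep the `top_k` most linked phyla (default `Inf`).
#' @return symmetric integer matrix phylum x phylum.
#' @export
phylum_link_summary <- function(network, top_k = Inf) {
  ph <- igraph::vertex_attr(network, "phylum")
  if (is.null(ph)) ph <- rep("unclassified", igraph::vcount(network))
  ph[is.na(ph)] <- "unclassified"
  el <- igraph::as_edgelist(network, names = FALSE)
  p1 <- ph[el[, 1L]]
  p2 <- ph[el[, 2L]]
  tally <- function(a, b) {
    phyla <- sort(unique(c(a, b, ph_keep)))
    mat <- matrix(0L, length(phyla), length(phyla),
                  dimnames = list(phyla, phyla))
    for (i in seq_along(a)) {
      mat[a[i], b[i]] <- mat[a[i], b[i]] + 1L
      if (a[i] != b[i]) mat[b[i], a[i]] <- mat[b[i], a[i]] + 1L
    }
    mat
  }
  ph_keep <- sort(unique(ph))
  mat <- tally(p1, p2)
  if (is.finite(top_k) && nrow(mat) > top_k) {
    # rank phyla by total link involvement and merge the rest
    tot <- vapply(rownames(mat),
                  function(x) sum(p1 == x) + sum(p2 == x), numeric(1L))
    keep <- names(sort(tot, decreasing = TRUE))[seq_len(top_k)]
    ph_keep <- keep
    re <- function(v) ifelse(v %in% keep, v, "others")
    mat <- tally(re(p1), re(p2))
  }
  mat
}

#' Correlation of ln-transformed subnetwork topology with stand age
#'
#' For each topological parameter, computes Pearson's correlation of the
#' ln-transformed parameter against stand age across per-sample
#' subnetworks. Samples with non-positive parameter values are dropped
#' for that parameter (the ln transform is undefined there) with a
#' warning; parameters constant across samples are skipped.
#'
#' @param topologies data.frame of per-sample topology parameters (rows
#'   = samples), e.g. from [topology_frame()].
#' @param stand_age numeric vector aligned with the rows.
#' @param params columns to test (default: the four the chronosequence
#'   analysis tracks).
#' @return data.frame with `parameter`, `r`, `p_value`, `n_used`.
#' @export
topology_vs_age <- function(topologies, stand_age,
                            params = c("average_path_length",
                                       "centralization_betweenness",
                                       "n_edges", "n_nodes")) {
  stopifnot(nrow(topologies) == length(stand_age))
  out <- list()
  for (pp in params) {
    v <- topologies[[pp]]
    if (is.null(v)) stop("unknown topology parameter: ", pp)
    ok <- is.finite(v) & v > 0
    if (sum(!ok)) {
      warning(sum(!ok), " sample(s) with non-positive '", pp,
              "' dropped from ln-transformed correlation")
    }
    if (sum(ok) < 4L || stats::sd(v[ok]) == 0 ||
        stats::sd(stand_age[ok]) == 0) {
      warning("parameter '", pp, "' skipped (constant or too few values)")
      next
    }
    ct <- correlate(log(v[ok]), stand_age[ok], method = "pearson")
    out[[pp]] <- data.frame(parameter = pp, r = ct$estimate,
                            p_value = ct$p_value, n_used = ct$n,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman correlations between subnetwork topology and soil properties
#'
#' All-pairs Spearman correlations between per-sample topological
#' parameters and soil physicochemical properties, with significance
#' stars (* p < 0.05, ** p < 0.01, *** p < 0.001). Soil properties other
#' than pH are z-normalised first (a monotone transform, kept for
#' consistency with the reporting convention).
#'
#' @param topologies data.frame of per-sample topology parameters.
#' @param soil data.frame of soil properties, same row order.
#' @param no_scale soil columns left unscaled (default `"pH"`).
#' @return list with matrices `rho`, `p` and `stars` (topology
#'   parameters x soil properties).
#' @export
topology_vs_soil <- function(topologies, soil, no_scale = "pH") {
  stopifnot(nrow(topologies) == nrow(soil))
  if (nrow(soil) < 4L) stop("need at least 4 samples")
  soil <- as.data.frame(soil)
  num <- vapply(soil, is.numeric, logical(1L))
  soil <- soil[num]
  for (cc in setdiff(names(soil), no_scale)) {
    if (stats::sd(soil[[cc]]) > 0) soil[[cc]] <- as.numeric(scale(soil[[cc]]))
  }
  tp <- topologies[vapply(topologies, is.numeric, logical(1L))]
  rho <- matrix(NA_real_, ncol(tp), ncol(soil),
                dimnames = list(names(tp), names(soil)))
  pm <- rho
  for (i in seq_len(ncol(tp))) {
    for (j in seq_len(ncol(soil))) {
      if (stats::sd(tp[[i]]) == 0 || stats::sd(soil[[j]]) == 0) next
      ct <- suppressWarnings(
        correlate(tp[[i]], soil[[j]], method = "spearman"))
      rho[i, j] <- ct$estimate
      pm[i, j] <- ct$p_value
    }
  }
  stars <- matrix(p_stars(pm), nrow(pm), ncol(pm), dimnames = dimnames(pm))
  stars[is.na(pm)] <- ""
  list(rho = rho, p = pm, stars = stars)
}
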