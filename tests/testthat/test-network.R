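make_cor_input <- function(rho_vals, fam = NULL) {
  k <- nrow(rho_vals)
  if (is.null(fam)) fam <- paste0("F", seq_len(k))
  dimnames(rho_vals) <- list(fam, fam)
  rho_vals
}

test_that("family correlations are symmetric and exclude constants", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 5, 5, 5, 5), d = c(9, 1, 4, 7, 2))
  rownames(m) <- paste0("s", 1:5)
  expect_message(fc <- family_correlations(m), "zero-variance")
  expect_false("c" %in% rownames(fc$rho))
  expect_equal(fc$rho["a", "b"], 1)
  expect_identical(fc$rho, t(fc$rho))
  expect_equal(fc$excluded, "c")
  expect_error(family_correlations(m[1:3, ]), "at least 4")
})

test_that("edge rule enforces both thresholds and assigns signs", {
  fam <- c("A", "B", "C")
  rho <- make_cor_input(matrix(c(1, 0.85, -0.9,
                                 0.85, 1, 0.1,
                                 -0.9, 0.1, 1), 3), fam)
  p <- make_cor_input(matrix(c(NA, 0.005, 0.001,
                               0.005, NA, 0.5,
                               0.001, 0.5, NA), 3), fam)
  net <- build_network(rho, p, use_fdr = FALSE)
  ed <- igraph::as_data_frame(net)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_setequal(key, c("A B", "A C"))
  expect_equal(ed$sign[key == "A B"], "positive")
  expect_equal(ed$sign[key == "A C"], "negative")
  # rho over threshold but p too large: no edge
  p2 <- p
  p2["A", "B"] <- p2["B", "A"] <- 0.02
  net2 <- build_network(rho, p2, use_fdr = FALSE)
  ed2 <- igraph::as_data_frame(net2)
  expect_equal(nrow(ed2), 1)
  expect_equal(ed2$rho, -0.9)
  # rho under threshold: no edge regardless of p
  rho3 <- rho
  rho3["A", "B"] <- rho3["B", "A"] <- 0.79
  net3 <- build_network(rho3, p, use_fdr = FALSE)
  expect_equal(igraph::ecount(net3), 1)
})

test_that("BH adjustment happens across the upper triangle", {
  fam <- paste0("F", 1:5)
  rho <- matrix(0.9, 5, 5, dimnames = list(fam, fam))
  diag(rho) <- 1
  p <- matrix(0.009, 5, 5, dimnames = list(fam, fam))
  diag(p) <- NA
  # raw p passes 0.01 but BH over 10 tests of equal p keeps p_adj = p
  net_fdr <- build_network(rho, p, use_fdr = TRUE)
  expect_equal(igraph::ecount(net_fdr), 10)
  p2 <- p
  p2[1, 2] <- p2[2, 1] <- 0.05
  net2 <- build_network(rho, p2, use_fdr = TRUE)
  ed <- igraph::as_data_frame(net2)
  expect_true(all(ed$p_adj >= ed$p_raw))
})

test_that("edge sets shrink monotonically as thresholds tighten", {
  set.seed(101)
  for (rep in 1:10) {
    k <- 8
    fam <- paste0("F", 1:k)
    z <- matrix(rnorm(k * 6), 6, k)
    rho <- cor(z, method = "spearman")
    dimnames(rho) <- list(fam, fam)
    p <- matrix(runif(k * k, 0, 0.05), k, k, dimnames = list(fam, fam))
    p <- (p + t(p)) / 2
    diag(p) <- NA
    edges_of <- function(r_thr, p_thr) {
      g <- build_network(rho, p, r_threshold = r_thr,
                         p_threshold = p_thr, use_fdr = FALSE)
      ed <- igraph::as_data_frame(g)
      paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    }
    base <- edges_of(0.3, 0.04)
    expect_true(all(edges_of(0.5, 0.04) %in% base))
    expect_true(all(edges_of(0.3, 0.01) %in% base))
  }
})

test_that("subnetwork extraction is the induced subgraph on present taxa", {
  fam <- c("A", "B", "C")
  rho <- make_cor_input(matrix(c(1, .9, .9, .9, 1, .9, .9, .9, 1), 3),
                        fam)
  p <- make_cor_input(matrix(1e-6, 3, 3), fam)
  diag(p) <- NA
  tri <- build_network(rho, p, use_fdr = FALSE)
  expect_equal(igraph::ecount(tri), 3)
  all_in <- extract_subnetwork(tri, c(A = 1, B = 2, C = 3))
  expect_equal(igraph::ecount(all_in), 3)
  none_in <- extract_subnetwork(tri, c(A = 0, B = 0, C = 0))
  expect_equal(igraph::vcount(none_in), 0)
  drop_one <- extract_subnetwork(tri, c(A = 1, B = 1, C = 0))
  expect_equal(igraph::vcount(drop_one), 2)
  expect_equal(igraph::ecount(drop_one), 1)
})

test_that("topology matches closed forms on canonical graphs", {
  p4 <- graph_from_pairs(cbind(1:3, 2:4), 4)
  t4 <- topology(p4)
  expect_equal(t4$average_path_length, 10 / 6, tolerance = 1e-12)
  expect_equal(t4$diameter, 3)
  expect_equal(t4$graph_density, 0.5)
  k4 <- graph_from_pairs(t(combn(4, 2)), 4)
  tk <- topology(k4)
  expect_equal(tk$clustering_coefficient, 1)
  expect_equal(tk$graph_density, 1)
  expect_equal(tk$average_path_length, 1)
  star <- graph_from_pairs(cbind(1, 2:5), 5)
  ts <- topology(star)
  expect_equal(ts$centralization_betweenness, 1, tolerance = 1e-12)
  expect_equal(ts$average_degree, 2 * 4 / 5)
  # single node: degenerate flag, path metrics zero
  t1 <- topology(graph_from_pairs(matrix(0, 0, 2), 1))
  expect_true(t1$degenerate)
  expect_equal(t1$average_path_length, 0)
  expect_error(topology(igraph::make_empty_graph(0)), "at least 1")
})

test_that("topology agrees with brute-force oracles on random small graphs", {
  set.seed(111)
  for (rep in 1:200) {
    g <- random_small_graph(7)
    t <- topology(g)
    expect_equal(t$average_path_length, oracle_apl(g),
                 tolerance = 1e-10)
    expect_equal(t$diameter, oracle_diameter(g), tolerance = 1e-10)
    n <- igraph::vcount(g)
    m <- igraph::ecount(g)
    expect_equal(t$graph_density,
                 if (n > 1) 2 * m / (n * (n - 1)) else 0)
    if (m > 0) {
      expect_equal(t$clustering_coefficient, oracle_clustering(g),
                   tolerance = 1e-10)
    }
    expect_equal(t$centralization_betweenness,
                 oracle_centralization_betweenness(g),
                 tolerance = 1e-10)
    expect_equal(t$average_degree, 2 * m / n, tolerance = 1e-12)
  }
})

test_that("modularity score matches the formula and igraph", {
  # two K4 cliques joined by one bridge, clique partition
  pairs <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- graph_from_pairs(pairs, 8)
  part <- rep(c(1, 2), each = 4)
  names(part) <- igraph::V(g)$name
  q <- modularity_score(g, part)
  expect_equal(q, 2 * (6 / 13 - (13 / 26)^2), tolerance = 1e-10)
  expect_equal(q, igraph::modularity(g, part), tolerance = 1e-10)
  # all nodes in one community
  expect_equal(modularity_score(g, rep(1, 8)), 0, tolerance = 1e-12)
  expect_error(modularity_score(graph_from_pairs(matrix(0, 0, 2), 3),
                                rep(1, 3)), "edgeless")
  expect_error(modularity_score(g, part[1:4]), "cover all nodes")
})

test_that("greedy partition dominates the singleton partition", {
  set.seed(112)
  for (rep in 1:100) {
    g <- random_small_graph(7)
    if (igraph::ecount(g) == 0) next
    t <- topology(g)
    singles <- modularity_score(g, seq_len(igraph::vcount(g)))
    expect_gte(t$modularity, singles - 1e-12)
    # the greedy Q matches the direct formula on its own partition
    comm <- igraph::cluster_fast_greedy(g)
    expect_equal(t$modularity,
                 oracle_modularity(g, igraph::membership(comm)),
                 tolerance = 1e-10)
  }
})

test_that("ER G(n,m) ensembles have exact density and reproducible summaries", {
  ens <- er_null_ensemble(20, 30, n_graphs = 50, seed = 9)
  expect_true(all(ens$metrics[, "graph_density"] ==
                    30 / choose(20, 2)))
  ens2 <- er_null_ensemble(20, 30, n_graphs = 50, seed = 9)
  expect_identical(ens$mean, ens2$mean)
  ens3 <- er_null_ensemble(20, 30, n_graphs = 50, seed = 10)
  expect_false(identical(ens$metrics, ens3$metrics))
  expect_error(er_null_ensemble(5, 20), "impossible edge count")
})

test_that("ER mean clustering sits at the connection probability", {
  ens <- er_null_ensemble(50, 200, n_graphs = 400, seed = 2)
  p <- 200 / choose(50, 2)
  se <- ens$sd[["clustering_coefficient"]] / sqrt(400)
  expect_lt(abs(ens$mean[["clustering_coefficient"]] - p), 3 * se)
})

test_that("small-world flags fire for clustered graphs, not null draws", {
  # a null draw scores unremarkably against its own ensemble
  set.seed(13)
  ens <- er_null_ensemble(30, 60, n_graphs = 300, seed = 21)
  flags <- replicate(40, {
    g <- igraph::sample_gnm(30, 60)
    sw <- small_world_assessment(topology(g), ens)
    sw$higher_than_null[sw$metric == "clustering_coefficient"]
  })
  expect_lt(mean(flags), 0.2)
  # a ring lattice has excess clustering at matched size
  lat <- igraph::sample_smallworld(1, 30, 2, p = 0) # ring, 60 edges
  sw <- small_world_assessment(topology(lat), ens)
  expect_true(sw$higher_than_null[sw$metric == "clustering_coefficient"])
  expect_gt(sw$ratio[sw$metric == "clustering_coefficient"], 2)
  # mismatched ensembles are rejected
  expect_error(small_world_assessment(topology(igraph::sample_gnm(10, 5)),
                                      ens), "not matched")
})

test_that("phylum link summary conserves edges and tallies by hand", {
  fam <- paste0("F", 1:5)
  rho <- matrix(0, 5, 5, dimnames = list(fam, fam))
  diag(rho) <- 1
  set_edge <- function(m, i, j, v) {
    m[i, j] <- m[j, i] <- v
    m
  }
  rho <- set_edge(rho, 1, 2, 0.9)   # A-A
  rho <- set_edge(rho, 1, 3, 0.95)  # A-B
  rho <- set_edge(rho, 4, 5, -0.9)  # B-C
  p <- matrix(1e-6, 5, 5, dimnames = list(fam, fam))
  diag(p) <- NA
  tax <- toy_taxonomy(fam, phyla = c("A", "A", "B", "B", "C"))
  tax$family <- fam
  net <- build_network(rho, p, use_fdr = FALSE, taxonomy = tax)
  mat <- phylum_link_summary(net)
  expect_equal(mat["A", "A"], 1)
  expect_equal(mat["A", "B"], 1)
  expect_equal(mat["B", "C"], 1)
  expect_equal(sum(mat[upper.tri(mat)]) + sum(diag(mat)),
               igraph::ecount(net))
  # a single-phylum network concentrates on the diagonal
  tax1 <- toy_taxonomy(fam, phyla = rep("OnlyOne", 5))
  tax1$family <- fam
  net1 <- build_network(rho, p, use_fdr = FALSE, taxonomy = tax1)
  mat1 <- phylum_link_summary(net1)
  expect_equal(unname(mat1["OnlyOne", "OnlyOne"]),
               igraph::ecount(net1))
})

test_that("topology-age correlation recovers exact log-linear signals", {
  ages <- c(3, 10, 21, 43, 50, 90)
  tp <- data.frame(n_edges = exp(ages / 30),
                   average_path_length = runif(6, 1, 2),
                   n_nodes = rep(8, 6),
                   centralization_betweenness = exp(-ages / 50))
  res <- suppressWarnings(
    topology_vs_age(tp, ages,
                    params = c("n_edges",
                               "centralization_betweenness",
                               "n_nodes")))
  expect_equal(res$r[res$parameter == "n_edges"], 1, tolerance = 1e-9)
  expect_equal(res$r[res$parameter == "centralization_betweenness"],
               -1, tolerance = 1e-9)
  # constant parameter is skipped with a warning
  expect_warning(topology_vs_age(tp, ages, params = c("n_nodes")),
                 "skipped")
})

test_that("topology-soil correlations annotate significance correctly", {
  set.seed(121)
  n <- 12
  tp <- data.frame(n_edges = 1:n + rnorm(n, 0, 0.01),
                   diameter = rnorm(n))
  soil <- data.frame(pH = rnorm(n),
                     TOC = 1:n + rnorm(n, 0, 0.01),
                     MBN = rnorm(n))
  res <- topology_vs_soil(tp, soil)
  expect_true(all(abs(res$rho) <= 1, na.rm = TRUE))
  expect_equal(res$rho["n_edges", "TOC"], 1, tolerance = 0.05)
  expect_equal(res$stars["n_edges", "TOC"], "***")
  expect_equal(dim(res$rho), c(2, 3))
  # star rule boundaries
  expect_equal(p_stars(c(0.004, 0.04, 0.2, 0.0004)),
               c("**", "*", "", "***"))
})
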