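#' Configuration for the synthetic chronosequence community generator
#'
#' Defaults emulate the study design the analysis assumes: three sites
#' with ten (site, stand) groups — TRI stands of 10 and 90 years, HZ
#' stands of 13, 50 and 90 years plus an adjacent forest, JL stands of
#' 3, 21 and 43 years plus a forest — sampled in three plots each (30
#' samples), sequencing depths drawn uniformly between 7265 and 9204
#' reads, and 60 bacterial families in 12 phyla dominated by
#' Proteobacteria, Actinobacteria and Acidobacteria. Each age group's
#' family abundances carry planted correlation blocks whose latent
#' correlation tightens with stand age (0.60 forest, 0.75 young, 0.85
#' middle, 0.92 old), mimicking the tightening of associations along the
#' chronosequence; soil TOC and MBN increase linearly with age while the
#' other properties fluctuate around field-realistic magnitudes.
#'
#' @param seed integer master seed.
#' @param stands data.frame with columns `site`, `stand_age`, `land_use`
#'   defining the (site, stand) groups; default is the design above.
#' @param plots_per_stand plots (independent samples) per stand.
#' @param n_families,n_phyla community dimensions.
#' @param dominant_phyla named weights for phylum assignment.
#' @param depth_range integer range of per-sample read depths.
#' @param block_sizes sizes of the planted correlation blocks (shared
#'   family membership across groups).
#' @param block_rho named vector of within-block latent correlations per
#'   age group, each in (-1, 1).
#' @param abundance_meanlog_sd spread of per-family log-normal location
#'   parameters (larger = steeper rank-abundance curve).
#' @param abundance_sdlog within-family log-scale dispersion.
#' @param block_meanlog mean and sd of the log-normal location parameter
#'   for planted-block families. The default gives guild members a
#'   moderately high baseline abundance (roughly 1-3% relative
#'   abundance), reflecting that correlation-based networks can only
#'   resolve associations among taxa whose counts rise above sampling
#'   noise at realistic sequencing depths.
#' @param soil_coef list of soil generator parameters: intercept/slope/sd
#'   for TOC and MBN trends, mean/sd for pH, and (mean, sd) for the
#'   age-independent properties.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(
    seed = 1L,
    stands = default_stand_design(),
    plots_per_stand = 3L,
    n_families = 60L,
    n_phyla = 12L,
    dominant_phyla = c(Proteobacteria = 0.30, Actinobacteria = 0.20,
                       Acidobacteria = 0.15),
    depth_range = c(7265L, 9204L),
    block_sizes = c(12L, 12L),
    block_rho = c(F = 0.60, Y3_20 = 0.75, Y40_50 = 0.85, Y90 = 0.92),
    abundance_meanlog_sd = 1.2,
    abundance_sdlog = 1.2,
    block_meanlog = c(mean = 0.7, sd = 0.5),
    soil_coef = list(
      TOC = c(intercept = 1.0, slope = 0.018, sd = 0.12),
      MBN = c(intercept = 10, slope = 0.35, sd = 3),
      pH = c(mean = 4.1, sd = 0.2),
      TON = c(0.13, 0.03), CN = c(11, 1.2), MBC = c(300, 90),
      AP = c(30, 12), ExchK = c(75, 15), ExchCa = c(500, 180),
      ExchMg = c(35, 10), ExchNa = c(5, 1.5))) {
  cfg <- list(seed = as.integer(seed), stands = stands,
              plots_per_stand = as.integer(plots_per_stand),
              n_families = as.integer(n_families),
              n_phyla = as.integer(n_phyla),
              dominant_phyla = dominant_phyla,
              depth_range = as.integer(depth_range),
              block_sizes = as.integer(block_sizes),
              block_rho = block_rho,
              abundance_meanlog_sd = abundance_meanlog_sd,
              abundance_sdlog = abundance_sdlog,
              block_meanlog = block_meanlog,
              soil_coef = soil_coef)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

default_stand_design <- function() {
  data.frame(
    site = c("TRI", "TRI", "HZ", "HZ", "HZ", "HZ",
             "JL", "JL", "JL", "JL"),
    stand_age = c(10, 90, 13, 50, 90, NA, 3, 21, 43, NA),
    land_use = c("tea", "tea", "tea", "tea", "tea", "forest",
                 "tea", "tea", "tea", "forest"),
    stringsAsFactors = FALSE)
}

validate_simulation_config <- function(cfg) {
  if (sum(cfg$block_sizes) > cfg$n_families) {
    stop("block sizes sum exceeds n_families")
  }
  if (any(abs(cfg$block_rho) >= 1)) stop("block_rho must lie in (-1, 1)")
  if (any(cfg$depth_range <= 0) ||
      cfg$depth_range[1] > cfg$depth_range[2]) {
    stop("depth_range must be positive and increasing")
  }
  miss <- setdiff(age_group_levels(), names(cfg$block_rho))
  if (length(miss)) stop("block_rho missing group(s): ",
                         paste(miss, collapse = ", "))
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#' @param path YAML file path.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stands <- as.data.frame(raw$stands, stringsAsFactors = FALSE)
  raw$stands$stand_age <- suppressWarnings(
    as.numeric(raw$stands$stand_age))
  # block_rho is stored as parallel lists because "F" is not a safe
  # YAML mapping key (it parses as a boolean)
  raw$block_rho <- stats::setNames(unlist(raw$block_rho$rho),
                                   unlist(raw$block_rho$group))
  raw$dominant_phyla <- unlist(raw$dominant_phyla)
  raw$block_meanlog <- unlist(raw$block_meanlog)
  raw$soil_coef <- lapply(raw$soil_coef, unlist)
  do.call(simulation_config, raw)
}

#' @rdname read_simulation_config
#' @param config a [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$stands <- as.list(cfg$stands)
  cfg$block_rho <- list(group = names(config$block_rho),
                        rho = unname(config$block_rho))
  # named atomic vectors must become maps, or YAML drops the names
  cfg$dominant_phyla <- as.list(config$dominant_phyla)
  cfg$block_meanlog <- as.list(config$block_meanlog)
  cfg$soil_coef <- lapply(config$soil_coef, function(v)
    if (is.null(names(v))) as.list(unname(v)) else as.list(v))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

block_membership <- function(cfg) {
  fam <- paste0("Family", sprintf("%02d", seq_len(cfg$n_families)))
  blocks <- list()
  at <- 1L
  for (b in seq_along(cfg$block_sizes)) {
    sz <- cfg$block_sizes[b]
    blocks[[b]] <- fam[at:(at + sz - 1L)]
    at <- at + sz
  }
  blocks
}

block_cor_matrix <- function(cfg, rho) {
  sigma <- diag(cfg$n_families)
  at <- 1L
  for (sz in cfg$block_sizes) {
    idx <- at:(at + sz - 1L)
    sigma[idx, idx] <- rho
    diag(sigma)[idx] <- 1
    at <- at + sz
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("block correlation matrix not positive definite")
  sigma
}

# deterministic substream: each consumer derives its own seed from the
# master seed and a counter, so samples can be generated independently
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 96731) %% 2147483647)
}

#' Simulate a synthetic chronosequence dataset
#'
#' Generates an OTU (family-level) count table, taxonomy, sample
#' metadata with soil chemistry, and a ground-truth record. Per sample,
#' a latent Gaussian vector with the age group's block-correlation
#' matrix is mapped through per-family log-normal marginals (a Gaussian
#' copula) to expected relative abundances, normalised, and counts are
#' drawn Multinomial(depth, proportions). Soil properties follow the
#' configured linear age trends (TOC, MBN) or stationary noise. The
#' truth record stores the planted within-block family pairs per age
#' group and the planted soil slopes.
#'
#' @param config a [simulation_config()].
#' @return list with `otu` ([otu_table()]), `taxonomy`
#'   ([taxonomy_table()]), `samples` ([sample_frame()]) and `truth`.
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)
  fam <- paste0("Family", sprintf("%02d", seq_len(cfg$n_families)))
  # phylum assignment: dominant phyla get fixed weight, rest uniform
  other_n <- cfg$n_phyla - length(cfg$dominant_phyla)
  phyla <- c(names(cfg$dominant_phyla), paste0("Phylum", seq_len(other_n)))
  w <- c(cfg$dominant_phyla,
         stats::setNames(rep((1 - sum(cfg$dominant_phyla)) / other_n,
                             other_n), paste0("Phylum", seq_len(other_n))))
  fam_phylum <- sample(phyla, cfg$n_families, replace = TRUE, prob = w)
  taxonomy <- taxonomy_table(
    fam, kingdom = rep("Bacteria", cfg$n_families), phylum = fam_phylum,
    class = rep("unclassified", cfg$n_families),
    order = rep("unclassified", cfg$n_families), family = fam,
    genus = rep("unclassified", cfg$n_families))
  meanlog <- stats::rnorm(cfg$n_families, 0, cfg$abundance_meanlog_sd)
  in_block <- seq_len(sum(cfg$block_sizes))
  meanlog[in_block] <- stats::rnorm(length(in_block),
                                    cfg$block_meanlog[["mean"]],
                                    cfg$block_meanlog[["sd"]])
  sdlog <- rep(cfg$abundance_sdlog, cfg$n_families)

  st <- cfg$stands
  st$age_group <- as.character(
    assign_age_group(st$stand_age, st$land_use))
  sigma_by_group <- lapply(cfg$block_rho, function(r)
    block_cor_matrix(cfg, r))
  chol_by_group <- lapply(sigma_by_group, chol)

  rows <- list()
  counts <- matrix(0L, 0L, cfg$n_families)
  sample_counter <- 0L
  for (s in seq_len(nrow(st))) {
    for (p in seq_len(cfg$plots_per_stand)) {
      sample_counter <- sample_counter + 1L
      sid <- sprintf("%s_%s_P%d", st$site[s],
                     if (st$land_use[s] == "forest") "F"
                     else paste0("Y", st$stand_age[s]), p)
      set.seed(substream_seed(cfg$seed, sample_counter))
      ch <- chol_by_group[[st$age_group[s]]]
      z <- as.vector(t(ch) %*% stats::rnorm(cfg$n_families))
      u <- stats::pnorm(z)
      a <- stats::qlnorm(u, meanlog = meanlog, sdlog = sdlog)
      prob <- a / sum(a)
      depth <- sample(cfg$depth_range[1]:cfg$depth_range[2], 1L)
      counts <- rbind(counts,
                      as.integer(stats::rmultinom(1L, depth, prob)))
      age <- if (st$land_use[s] == "forest") 0 else st$stand_age[s]
      sc <- cfg$soil_coef
      soil <- c(
        pH = stats::rnorm(1, sc$pH[["mean"]], sc$pH[["sd"]]),
        TOC = sc$TOC[["intercept"]] + sc$TOC[["slope"]] * age +
          stats::rnorm(1, 0, sc$TOC[["sd"]]),
        MBN = sc$MBN[["intercept"]] + sc$MBN[["slope"]] * age +
          stats::rnorm(1, 0, sc$MBN[["sd"]]),
        TON = stats::rnorm(1, sc$TON[1], sc$TON[2]),
        CN = stats::rnorm(1, sc$CN[1], sc$CN[2]),
        MBC = stats::rnorm(1, sc$MBC[1], sc$MBC[2]),
        AP = stats::rnorm(1, sc$AP[1], sc$AP[2]),
        ExchK = stats::rnorm(1, sc$ExchK[1], sc$ExchK[2]),
        ExchCa = stats::rnorm(1, sc$ExchCa[1], sc$ExchCa[2]),
        ExchMg = stats::rnorm(1, sc$ExchMg[1], sc$ExchMg[2]),
        ExchNa = stats::rnorm(1, sc$ExchNa[1], sc$ExchNa[2]))
      soil[-1] <- pmax(soil[-1], 0.01)  # physical non-negativity
      rows[[sample_counter]] <- data.frame(
        sample_id = sid, site = st$site[s], stand_age = age,
        land_use = st$land_use[s], plot = paste0("P", p),
        t(soil), stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, rows)
  rownames(counts) <- md$sample_id
  colnames(counts) <- fam
  samples <- sample_frame(md$sample_id, md$site, md$stand_age,
                          md$land_use, md$plot,
                          soil = md[soil_properties()])
  blocks <- block_membership(cfg)
  truth_edges <- lapply(age_group_levels(), function(g) {
    do.call(rbind, lapply(blocks, function(b) {
      if (length(b) < 2L) return(NULL)
      t(utils::combn(sort(b), 2L))
    }))
  })
  names(truth_edges) <- age_group_levels()
  truth <- list(edges = truth_edges, blocks = blocks,
                block_rho = cfg$block_rho,
                soil_slopes = c(TOC = unname(cfg$soil_coef$TOC[["slope"]]),
                                MBN = unname(cfg$soil_coef$MBN[["slope"]])),
                seed = cfg$seed)
  list(otu = otu_table(counts), taxonomy = taxonomy, samples = samples,
       truth = truth, config = cfg)
}

#' Planted (ground-truth) family pairs for an age group
#'
#' @param truth the `truth` record from [simulate_dataset()].
#' @param age_group one of `F`, `Y3_20`, `Y40_50`, `Y90`.
#' @return data.frame with columns `from`, `to` (sorted unordered
#'   pairs, stable order).
#' @export
truth_edge_set <- function(truth, age_group) {
  if (!age_group %in% names(truth$edges)) {
    stop("unknown age group: ", age_group)
  }
  e <- truth$edges[[age_group]]
  if (is.null(e)) return(data.frame(from = character(0),
                                    to = character(0)))
  df <- data.frame(from = e[, 1L], to = e[, 2L],
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}
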