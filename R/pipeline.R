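#' Run the full chronosequence analysis pipeline
#'
#' Orchestrates every stage of the analysis in order: rarefaction,
#' phylum-level aggregation, richness, Bray-Curtis distances, PCoA and
#' NMDS, PERMANOVA (one factor at a time), db-RDA with permutation
#' forward selection of soil variables, per-age-group co-occurrence
#' networks on family-level relative abundances, per-sample
#' subnetworks, topology suites, Erdos-Renyi null ensembles with
#' small-world assessment, and correlations of subnetwork topology with
#' stand age and soil properties. All artifacts are written under
#' `output_dir` together with a machine-readable manifest recording
#' every parameter, seed and output checksum; any stage failure aborts
#' with the stage name and leaves a `FAILED` marker.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `simulate` (a [simulation_config()] or `TRUE` for defaults) or
#'   `otu_path`/`taxonomy_path`/`metadata_path`/`soil_path`;
#'   `output_dir`; `depth` (rarefaction depth, default 7000);
#'   `r_threshold` (0.8), `p_threshold` (0.01), `use_fdr` (TRUE);
#'   `n_null_graphs` (10000); `n_permutations` (999); `seed` (1);
#'   `age_group_breaks` (c(21, 69)).
#' @return (invisibly) a list with every stage's result plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(depth = 7000, r_threshold = 0.8, p_threshold = 0.01,
         use_fdr = TRUE, n_null_graphs = 10000, n_permutations = 999,
         seed = 1L, age_group_breaks = c(21, 69),
         output_dir = "chronet_output"),
    config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(cfg$output_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log_msg <- function(...) message("[chronet] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failed_marker)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list()

  ## ingest -----------------------------------------------------------
  dat <- stage("ingest", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- if (isTRUE(cfg$simulate)) {
        simulation_config(seed = cfg$seed)
      } else if (inherits(cfg$simulate, "simulation_config")) {
        cfg$simulate
      } else {
        do.call(simulation_config, cfg$simulate)
      }
      simulate_dataset(sim_cfg)
    } else {
      md <- read_sample_frame(cfg$metadata_path, cfg$soil_path,
                              age_group_breaks = cfg$age_group_breaks)
      ot <- read_otu_table(cfg$otu_path, sample_ids = md$sample_id)
      tax <- if (!is.null(ot$taxonomy)) ot$taxonomy
             else read_taxonomy_table(cfg$taxonomy_path)
      list(otu = ot$otu, taxonomy = tax, samples = md, truth = NULL)
    }
  })
  log_msg("ingest: %d samples, %d taxa", nrow(dat$otu), ncol(dat$otu))

  ## rarefaction ------------------------------------------------------
  rare <- stage("rarefy", rarefy(dat$otu, depth = cfg$depth,
                                 seed = cfg$seed))
  samples <- dat$samples[match(rownames(rare), dat$samples$sample_id), ]
  log_msg("rarefy: %d samples retained at depth %d", nrow(rare),
          cfg$depth)

  ## diversity --------------------------------------------------------
  out$richness <- stage("richness", observed_richness(rare))
  out$phylum_table <- stage("aggregate",
    aggregate_by_rank(rare, dat$taxonomy, rank = "phylum", top_k = 10))
  utils::write.table(
    data.frame(sample_id = names(out$richness),
               richness = out$richness),
    file.path(cfg$output_dir, "richness.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  ## ordination -------------------------------------------------------
  bc <- stage("bray_curtis", bray_curtis(rare))
  out$pcoa <- stage("pcoa", pcoa(bc))
  out$nmds <- stage("nmds", nmds(bc, k = 2, n_starts = 10,
                                 seed = cfg$seed))
  utils::write.table(
    data.frame(sample_id = rownames(out$pcoa$points),
               out$pcoa$points[, 1:2]),
    file.path(cfg$output_dir, "pcoa_coordinates.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  log_msg("pcoa: axis 1 %.1f%%, axis 2 %.1f%%",
          100 * out$pcoa$prop_explained[1],
          100 * out$pcoa$prop_explained[2])

  ## permanova (one factor at a time) ---------------------------------
  out$permanova <- stage("permanova", {
    lapply(c(age_group = "age_group", site = "site"), function(f)
      permanova(bc, samples[[f]],
                n_permutations = cfg$n_permutations, seed = cfg$seed))
  })
  log_msg("permanova: age_group R2 = %.3f (p = %.3g), site R2 = %.3f",
          out$permanova$age_group$R2, out$permanova$age_group$p_value,
          out$permanova$site$R2)

  ## db-RDA + forward selection ---------------------------------------
  soil_cols <- intersect(soil_properties(), names(samples))
  out$dbrda <- stage("dbrda", {
    if (!length(soil_cols)) stop("no soil properties available")
    soil <- samples[soil_cols]
    fs <- forward_select(bc, soil, alpha = 0.05,
                         n_permutations = cfg$n_permutations,
                         seed = cfg$seed, no_scale = "pH")
    fit <- if (length(fs$selected)) {
      dbrda(bc, soil[fs$selected],
            n_permutations = cfg$n_permutations, seed = cfg$seed,
            no_scale = "pH")
    } else {
      dbrda(bc, soil, n_permutations = cfg$n_permutations,
            seed = cfg$seed, no_scale = "pH")
    }
    list(selection = fs, fit = fit)
  })
  log_msg("dbrda: %d variable(s) selected, constrained %.1f%%",
          length(out$dbrda$selection$selected),
          100 * out$dbrda$fit$constrained_proportion)

  ## per-group networks -----------------------------------------------
  fam_rel <- stage("family_abundance", {
    ft <- aggregate_by_rank(rare, dat$taxonomy, rank = "family",
                            top_k = Inf, relative = TRUE)
    ft[, colnames(ft) != "unclassified", drop = FALSE]
  })
  out$networks <- stage("networks", {
    nets <- list()
    for (g in levels(samples$age_group)) {
      idx <- which(samples$age_group == g)
      if (length(idx) < 4L) {
        log_msg("networks: skipping group %s (%d samples)", g,
                length(idx))
        next
      }
      fc <- suppressMessages(
        family_correlations(fam_rel[idx, , drop = FALSE]))
      net <- build_network(fc$rho, fc$p, r_threshold = cfg$r_threshold,
                           p_threshold = cfg$p_threshold,
                           use_fdr = cfg$use_fdr,
                           taxonomy = dat$taxonomy,
                           abundances = colMeans(fam_rel[idx, ,
                                                         drop = FALSE]),
                           group = g)
      write_network(net, file.path(cfg$output_dir,
                                   paste0("network_", g, ".graphml")))
      log_msg("networks: %s has %d nodes, %d edges", g,
              igraph::vcount(net), igraph::ecount(net))
      if (igraph::vcount(net) == 0L) {
        log_msg("networks: group %s network is empty; skipped downstream",
                g)
        next
      }
      nets[[g]] <- net
    }
    nets
  })
  out$group_topology <- stage("topology",
    lapply(out$networks, topology))
  out$phylum_links <- stage("phylum_links",
    lapply(out$networks, phylum_link_summary, top_k = 10))

  ## subnetworks ------------------------------------------------------
  out$subnetworks <- stage("subnetworks", {
    subs <- list()
    for (i in seq_len(nrow(samples))) {
      g <- as.character(samples$age_group[i])
      if (is.null(out$networks[[g]])) next
      subs[[samples$sample_id[i]]] <-
        extract_subnetwork(out$networks[[g]], fam_rel[i, ])
    }
    subs
  })
  out$subnetwork_topology <- stage("subnetwork_topology", {
    topology_frame(lapply(out$subnetworks, topology))
  })
  utils::write.table(
    cbind(sample_id = rownames(out$subnetwork_topology),
          out$subnetwork_topology),
    file.path(cfg$output_dir, "subnetwork_topology.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  ## null models + small world ----------------------------------------
  out$small_world <- stage("small_world", {
    lapply(out$group_topology, function(t) {
      if (t$n_nodes < 3L || t$n_edges < 1L) return(NULL)
      ens <- er_null_ensemble(t$n_nodes, t$n_edges,
                              n_graphs = cfg$n_null_graphs,
                              seed = cfg$seed)
      small_world_assessment(t, ens)
    })
  })

  ## topology vs age / soil -------------------------------------------
  sub_ids <- rownames(out$subnetwork_topology)
  sub_meta <- samples[match(sub_ids, samples$sample_id), ]
  out$topology_age <- stage("topology_vs_age", suppressWarnings(
    topology_vs_age(out$subnetwork_topology, sub_meta$stand_age)))
  out$topology_soil <- stage("topology_vs_soil", {
    if (length(soil_cols)) {
      topology_vs_soil(out$subnetwork_topology, sub_meta[soil_cols])
    } else NULL
  })

  ## manifest ---------------------------------------------------------
  results_json <- file.path(cfg$output_dir, "results.json")
  jsonlite::write_json(list(
    richness = as.list(out$richness),
    pcoa_prop_explained = out$pcoa$prop_explained,
    nmds_stress = out$nmds$stress,
    permanova = lapply(out$permanova, unclass),
    dbrda = list(selected = out$dbrda$selection$selected,
                 constrained_proportion =
                   out$dbrda$fit$constrained_proportion,
                 p_value = out$dbrda$fit$p_value),
    group_topology = lapply(out$group_topology, unclass),
    topology_vs_age = out$topology_age),
    results_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- list.files(cfg$output_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    parameters = cfg[c("depth", "r_threshold", "p_threshold",
                       "use_fdr", "n_null_graphs", "n_permutations",
                       "seed", "age_group_breaks")],
    simulated = !is.null(cfg$simulate),
    n_samples = nrow(rare),
    outputs = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
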