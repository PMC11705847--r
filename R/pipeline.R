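#' Build a pipeline run configuration
#'
#' A single global `seed` is split deterministically into per-stage seeds so
#' a run is fully re-creatable from its serialized configuration.
#'
#' @param table_path,tree_path,metadata_path input file paths (any may be
#'   `NULL`; a missing tree skips the assembly stage).
#' @param simulation optional list describing a simulation instead of input
#'   files: `scenario` (`"neutral"`, `"selection"`, `"dispersal_limited"`,
#'   `"modular_network"`) plus that simulator's parameters.
#' @param group_col metadata column used for group comparisons (default
#'   `"niche"`).
#' @param min_rel_abund,drop_singletons filter parameters (see
#'   [filter_otus]).
#' @param normalize `"rarefy"` (default), `"none"` or `"tss"`.
#' @param rarefy_depth target depth (default: minimum sample depth).
#' @param rho_min,p_max network thresholds.
#' @param n_null null-model randomizations (default 999).
#' @param bootstrap_reps NCM bootstrap repetitions (default 1000).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed global integer seed.
#' @param fast if `TRUE`, lowers `n_null` to 199 and `bootstrap_reps` to 200
#'   for quick runs.
#' @return a list of class `run_config`.
#' @export
run_config <- function(table_path = NULL, tree_path = NULL,
                       metadata_path = NULL, simulation = NULL,
                       group_col = "niche",
                       min_rel_abund = 5e-5, drop_singletons = TRUE,
                       normalize = c("rarefy", "none", "tss"),
                       rarefy_depth = NULL,
                       rho_min = 0.6, p_max = 0.01,
                       n_null = 999, bootstrap_reps = 1000, n_perm = 999,
                       seed = 1L, fast = FALSE) {
  normalize <- match.arg(normalize)
  if (fast) {
    n_null <- min(n_null, 199)
    bootstrap_reps <- min(bootstrap_reps, 200)
  }
  cfg <- list(table_path = table_path, tree_path = tree_path,
              metadata_path = metadata_path, simulation = simulation,
              group_col = group_col, min_rel_abund = min_rel_abund,
              drop_singletons = drop_singletons, normalize = normalize,
              rarefy_depth = rarefy_depth, rho_min = rho_min, p_max = p_max,
              n_null = n_null, bootstrap_reps = bootstrap_reps,
              n_perm = n_perm, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

# One knob, many stages: per-stage seeds derived from the global seed.
.stage_seeds <- function(seed) {
  base <- (as.integer(seed) %% 100000L) * 101L
  list(simulate = base + 1L, rarefy = base + 2L, permanova = base + 3L,
       modules = base + 4L, ncm = base + 5L, bnti = base + 6L,
       rc = base + 7L, pnst = base + 8L)
}

.run_simulation <- function(sim, seed) {
  sc <- sim$scenario
  if (sc == "neutral") {
    r <- simulate_neutral(sim$n_taxa, sim$n_samples, sim$depth, sim$Nm_true,
                          seed = seed)
    tree <- simulate_tree(sim$n_taxa, seed = seed)
    md <- data.frame(sample_id = sample_ids(r$table),
                     site = "sim",
                     niche = rep(c("groupA", "groupB"),
                                 length.out = n_samples(r$table)),
                     stringsAsFactors = FALSE)
    list(table = r$table, tree = tree, metadata = md)
  } else if (sc == "selection") {
    tree <- simulate_tree(sim$n_taxa, seed = seed)
    r <- simulate_selection(tree, sim$n_samples, sim$depth, sim$niche_sd,
                            seed = seed)
    r$metadata$niche <- r$metadata$site
    list(table = r$table, tree = tree, metadata = r$metadata)
  } else if (sc == "dispersal_limited") {
    r <- simulate_dispersal_limited(sim$n_taxa, sim$n_blocks,
                                    sim$samples_per_block, sim$depth,
                                    sim$drift_strength, seed = seed)
    r$metadata$niche <- r$metadata$site
    tree <- simulate_tree(sim$n_taxa, seed = seed)
    list(table = r$table, tree = tree, metadata = r$metadata)
  } else if (sc == "modular_network") {
    tab <- simulate_modular_network_data(sim$n_modules, sim$taxa_per_module,
                                         sim$n_samples, sim$rho_within,
                                         seed = seed)
    md <- data.frame(sample_id = sample_ids(tab), site = "sim",
                     niche = "sim", stringsAsFactors = FALSE)
    list(table = tab, tree = NULL, metadata = md)
  } else stop("unknown simulation scenario: ", sc)
}

#' Run the full analysis pipeline
#'
#' Executes filter, normalization, diversity, network, neutral-model and
#' assembly stages in order, writing every module's tabular output, a
#' machine-readable `summary.json` and a human-readable `log.txt` (package
#' version, seeds, parameter echo) into `out_dir`.  The configuration is
#' serialized alongside, so any run is re-creatable from its own artifacts.
#' A configuration without a tree runs everything except the assembly
#' stage, which is skipped with an explicit notice.
#'
#' @param config a [run_config] (or a path to a JSON serialization of one).
#' @param out_dir output directory (created).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    class(config) <- "run_config"
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("phyllonet ", as.character(utils::packageVersion("phyllonet")),
          " pipeline; global seed ", config$seed)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  summary <- list(seed = config$seed)
  stage <- "input"
  res <- tryCatch({
    # ---- input / simulation
    if (!is.null(config$simulation)) {
      sim <- .run_simulation(config$simulation, seeds$simulate)
      table <- sim$table; tree <- sim$tree; metadata <- sim$metadata
      write_otu_table(table, file.path(out_dir, "simulated_otu_table.tsv"))
      write_metadata(metadata, file.path(out_dir, "simulated_metadata.tsv"))
      if (!is.null(tree))
        write_tree(tree, file.path(out_dir, "simulated_tree.nwk"))
      jsonlite::write_json(
        c(config$simulation, list(seed = seeds$simulate)),
        file.path(out_dir, "simulation_params.json"),
        auto_unbox = TRUE, digits = NA)
      logline("simulated scenario '", config$simulation$scenario,
              "' with stage seed ", seeds$simulate)
    } else {
      table <- read_otu_table(config$table_path)
      tree <- if (!is.null(config$tree_path)) read_tree(config$tree_path)
              else NULL
      metadata <- if (!is.null(config$metadata_path))
        read_metadata(config$metadata_path) else NULL
    }
    if (!is.null(metadata)) metadata <- validate_metadata(table, metadata)

    # ---- filter
    stage <- "filter"
    filtered <- filter_otus(table, config$min_rel_abund,
                            config$drop_singletons)
    logline("filter: ", n_taxa(table), " -> ", n_taxa(filtered), " taxa (",
            attr(filtered, "n_singletons_removed"), " singletons, ",
            attr(filtered, "n_rare_removed"), " rare removed)")
    summary$filter <- list(n_taxa_in = n_taxa(table),
                           n_taxa_out = n_taxa(filtered))

    # ---- normalize
    stage <- "normalize"
    if (config$normalize == "rarefy") {
      depth <- if (is.null(config$rarefy_depth))
        min(sample_depths(filtered)) else config$rarefy_depth
      norm <- rarefy(filtered, depth = depth, seed = seeds$rarefy,
                     drop_shallow = TRUE)
      logline("rarefied to depth ", depth)
      summary$normalize <- list(method = "rarefy", depth = depth)
    } else {
      norm <- filtered
      summary$normalize <- list(method = config$normalize)
    }

    groups <- if (!is.null(metadata)) metadata[[config$group_col]] else NULL
    if (!is.null(groups) && length(unique(groups)) < 2) groups <- NULL

    # ---- diversity
    stage <- "diversity"
    alpha <- alpha_diversity(norm)
    utils::write.table(
      data.frame(sample_id = names(alpha), shannon = alpha),
      file.path(out_dir, "alpha_diversity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    dmat <- rclr_aitchison_dist(norm)
    ord <- pcoa(dmat, k = 2)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      file.path(out_dir, "pcoa_coordinates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    summary$diversity <- list(
      shannon_mean = mean(alpha),
      pcoa_var_explained = as.numeric(ord$proportion))
    if (!is.null(groups)) {
      pm <- permanova(dmat, groups, n_perm = config$n_perm,
                      seed = seeds$permanova)
      summary$diversity$permanova <- list(F = pm$F, R2 = pm$R2,
                                          p_value = pm$p_value)
      breadth <- levins_breadth(norm, groups)
      summary$diversity$levins_breadth_group_means <-
        as.list(attr(breadth, "group_means"))
      if (length(unique(groups)) == 2) {
        sim_tab <- simper(norm, groups)
        utils::write.table(sim_tab, file.path(out_dir, "simper.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    logline("diversity stage done")

    # ---- network
    stage <- "network"
    cg <- correlation_graph(norm, rho_min = config$rho_min,
                            p_max = config$p_max)
    if (igraph::ecount(cg$graph) > 0) {
      mods <- detect_modules(cg, seed = seeds$modules)
      zp <- classify_roles(zi_pi(cg, mods))
      topo <- topology(cg, mods)
      export_network(cg, zp, out_dir)
      keystone <- zp$taxon[zp$role != "peripheral"]
      summary$network <- c(topo$network,
                           list(n_keystone = length(keystone),
                                keystone = keystone))
    } else {
      logline("network: no edges at the configured thresholds")
      summary$network <- list(n_nodes = igraph::vcount(cg$graph), n_edges = 0)
    }
    logline("network stage done")

    # ---- neutral model
    stage <- "ncm"
    fit <- ncm_bootstrap(norm, reps = config$bootstrap_reps,
                         seed = seeds$ncm, fit = fit_ncm(norm))
    part <- ncm_partition(fit)
    utils::write.table(cbind(fit$otus, band = as.character(part$labels)),
                       file.path(out_dir, "ncm_otus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$ncm <- list(m = fit$m, Nm = fit$Nm, N = fit$N, R2 = fit$R2,
                        ci_m = as.numeric(fit$ci$m),
                        ci_R2 = as.numeric(fit$ci$R2),
                        band_fractions = as.list(part$fractions))
    logline("ncm stage done: m = ", signif(fit$m, 4),
            ", R2 = ", signif(fit$R2, 4))

    # ---- assembly
    stage <- "assembly"
    if (is.null(tree)) {
      logline("assembly stage skipped: no tree provided")
      summary$assembly <- list(skipped = "no tree")
    } else {
      bn <- bnti(norm, tree, n_null = config$n_null, seed = seeds$bnti)
      rcm <- raup_crick_bray(norm, n_null = config$n_null, seed = seeds$rc)
      asm <- classify_processes(bn, rcm, groups = groups)
      utils::write.table(asm$pairs, file.path(out_dir, "assembly_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$assembly <- list(fractions = as.list(asm$fractions),
                               n_excluded = asm$n_excluded)
      if (!is.null(groups)) {
        summary$assembly$by_group <- lapply(asm$by_group, as.list)
        np <- pnst(norm, tree, groups, n_null = config$n_null,
                   seed = seeds$pnst)
        summary$assembly$pnst <- as.list(np$pnst)
        if (!is.null(np$comparison))
          summary$assembly$pnst_wilcoxon_p <- np$comparison$p_value
      }
      logline("assembly stage done")
    }
    summary
  }, error = function(e) {
    logline("FAILED at stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logline("pipeline complete")
  invisible(res)
}
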