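# End-to-end orchestration for one site and across sites. A master seed
# fans out to fixed per-stage seeds (documented offsets), so any stage can
# be re-run in isolation and reproduce its in-pipeline output.

#' Assemble and validate a full run configuration
#'
#' @param site site label.
#' @param synthetic a [synthetic_config()] to simulate inputs, or `NULL` to
#'   read them from files.
#' @param otu_path,taxonomy_path,survey_path,site_metadata_path input files
#'   (ignored when `synthetic` is given).
#' @param policy a [filter_policy()].
#' @param sparcc a [sparcc_params()] (its seed is overridden by the fan-out).
#' @param r_min,p_max edge thresholds (defaults 0.3 and 0.05).
#' @param n_rewires null-ensemble size (default 100).
#' @param anneal an [anneal_control()].
#' @param plant_transform forwarded to [stack_domains()].
#' @param out_dir output directory (`NULL` = no files written).
#' @param seed master seed; stage seeds are `seed + 1` (simulate),
#'   `seed + 2` (rarefy), `seed + 3` (sparcc), `seed + 4` (nulls),
#'   `seed + 5` (anneal).
#' @return a validated `run_config` list.
#' @export
run_config <- function(site = "site1", synthetic = synthetic_config(),
                       otu_path = NULL, taxonomy_path = NULL,
                       survey_path = NULL, site_metadata_path = NULL,
                       policy = filter_policy(), sparcc = sparcc_params(),
                       r_min = 0.3, p_max = 0.05, n_rewires = 100,
                       anneal = anneal_control(),
                       plant_transform = "none",
                       out_dir = NULL, seed = 1) {
  if (is.null(synthetic) &&
      (is.null(otu_path) || is.null(taxonomy_path) || is.null(survey_path)))
    stop("either a synthetic config or input paths are required")
  stopifnot(r_min > 0, r_min < 1, p_max > 0, p_max <= 1, n_rewires >= 2,
            inherits(policy, "filter_policy"),
            inherits(sparcc, "sparcc_params"),
            inherits(anneal, "anneal_control"))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full single-site pipeline
#'
#' Simulate or read inputs, rarefy, stack domains, estimate SparCC
#' correlations with pseudo p-values, threshold into the bipartite network,
#' compute the topology panel, null-model significance, module detection,
#' Zi-Pi roles and module composition. With `out_dir` set, writes all
#' artifacts (TSV + GraphML/GEXF + resolved config JSON).
#'
#' @param config a [run_config()].
#' @return a `site_run` list: `config`, `stacked`, `corr`, `network`,
#'   `topology`, `nulls`, `partition`, `roles`, `composition`, `truth`
#'   (when synthetic).
#' @export
run_site <- function(config = run_config()) {
  cf <- config
  truth <- NULL
  if (!is.null(cf$synthetic)) {
    sim_cf <- cf$synthetic
    sim_cf$seed <- cf$seed + 1
    sim <- simulate_iden(sim_cf)
    plants <- sim$plants; bacteria <- sim$bacteria; truth <- sim$truth
    depth_ok <- all(colSums(bacteria$counts) >= cf$policy$rarefaction_depth)
    bacteria <- if (depth_ok)
      rarefy(bacteria, cf$policy$rarefaction_depth, seed = cf$seed + 2,
             drop_shallow_samples = cf$policy$drop_shallow_samples)
    else bacteria
  } else {
    site_md <- if (!is.null(cf$site_metadata_path))
      read_site_metadata(cf$site_metadata_path) else NULL
    plants <- read_plant_survey(cf$survey_path, site_md)
    bacteria <- read_otu_table(cf$otu_path, cf$taxonomy_path)
    bacteria <- rarefy(bacteria, cf$policy$rarefaction_depth,
                       seed = cf$seed + 2,
                       drop_shallow_samples = cf$policy$drop_shallow_samples)
  }
  stacked <- stack_domains(plants, bacteria, cf$policy,
                           plant_transform = cf$plant_transform)
  sp <- cf$sparcc
  sp$seed <- cf$seed + 3
  corr <- sparcc(stacked, sp)
  network <- build_network(corr, r_min = cf$r_min, p_max = cf$p_max,
                           site = cf$site)
  topology <- topology_report(network)
  nulls <- null_significance(network, n_rewires = cf$n_rewires,
                             seed = cf$seed + 4)
  partition <- anneal_modules(network, control = cf$anneal,
                              seed = cf$seed + 5)
  roles <- zi_pi(network, partition)
  composition <- module_composition(network, partition,
                                    stacked$lineage)
  run <- structure(list(config = cf, stacked = stacked, corr = corr,
                        network = network, topology = topology,
                        nulls = nulls, partition = partition, roles = roles,
                        composition = composition, truth = truth),
                   class = "site_run")
  if (!is.null(cf$out_dir)) write_site_run(run, cf$out_dir)
  run
}

#' Write all artifacts of a site run
#'
#' @param run a `site_run`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_site_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  export_network(run$network, p("network_edges.tsv"), "edgelist")
  export_network(run$network, p("network.graphml"), "graphml",
                 partition = run$partition, roles = run$roles)
  export_network(run$network, p("network.gexf"), "gexf",
                 partition = run$partition, roles = run$roles)
  write_topology_report(run$topology, p("topology.tsv"))
  write_null_report(run$nulls, p("null_significance.tsv"))
  write_node_roles(run$roles, p("node_roles.tsv"))
  write.table(run$composition$phylum_counts, p("module_phyla.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$composition$plants, p("module_plants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run$config
  cfg$synthetic <- unclass(cfg$synthetic)
  jsonlite::write_json(
    lapply(unclass(cfg), function(x)
      if (inherits(x, c("filter_policy", "sparcc_params", "anneal_control")))
        unclass(x) else x),
    p("resolved_config.json"), auto_unbox = TRUE, null = "null",
    force = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the cross-site comparison over completed site runs
#'
#' @param runs list of >= 2 `site_run` objects.
#' @param out_dir optional output directory for the Venn-region, plant
#'   incidence and phylum composition TSVs.
#' @return list with `collection`, `venn`, `plants`, `phyla`.
#' @export
run_multisite <- function(runs, out_dir = NULL) {
  if (length(runs) < 2) stop("need at least 2 completed site runs")
  networks <- lapply(runs, `[[`, "network")
  names(networks) <- vapply(runs, function(r) r$config$site, character(1))
  lineage <- do.call(c, lapply(runs, function(r) r$stacked$lineage))
  lineage <- lineage[!duplicated(names(lineage))]
  collection <- site_collection(networks, lineage)
  venn <- venn_counts(collection$otu_sets)
  plants <- plant_site_incidence(collection)
  phyla <- site_phylum_composition(collection)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(venn$regions, file.path(out_dir, "venn_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(venn$pairwise, file.path(out_dir, "venn_pairwise.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(venn$unique, file.path(out_dir, "venn_unique.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(plant = rownames(plants$table), plants$table,
                           check.names = FALSE),
                file.path(out_dir, "plant_site_incidence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(site = rownames(phyla$fractions),
                           phyla$fractions, check.names = FALSE),
                file.path(out_dir, "site_phylum_composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(collection = collection, venn = venn, plants = plants, phyla = phyla)
}
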