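# Synthetic paired plant-survey + OTU tables with planted plant-OTU
# association blocks, so every downstream stage has ground truth to recover.

#' Configuration for the synthetic interdomain data generator
#'
#' Defaults emulate one study site: 17 plots, a handful of woody plant
#' species, a few hundred networked OTUs rarefied to 20,000 reads, modular
#' plant-OTU association blocks and one high-degree hub plant.
#'
#' @param n_plots number of plots (samples) per site (default 17).
#' @param n_plants number of plant species (default 8).
#' @param n_otus number of bacterial OTUs (default 150).
#' @param n_modules number of planted modules (default 4; must be <=
#'   `n_plants`).
#' @param hub_plant_index which plant is the high-degree hub (default 1).
#' @param effect_size multiplicative abundance shift of an OTU per standard
#'   deviation of its partner plant's log abundance (default 3; must be > 1
#'   to carry signal, exactly 1 gives the null limit).
#' @param base_lognormal_sigma log-scale SD of latent abundances (default 1).
#' @param sequencing_depth reads per plot in the OTU table (default 20000).
#' @param assoc_fraction fraction of OTUs given a partner plant (default
#'   0.6); the rest are unassociated noise.
#' @param plant_mean_stems mean stem count per plot for a typical plant
#'   (default 20).
#' @param seed integer seed; all generator randomness flows through it.
#'
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_plots = 17, n_plants = 8, n_otus = 150,
                             n_modules = 4, hub_plant_index = 1,
                             effect_size = 3, base_lognormal_sigma = 1,
                             sequencing_depth = 20000,
                             assoc_fraction = 0.6, plant_mean_stems = 20,
                             seed = 1) {
  stopifnot(n_plots >= 2, n_plants >= 2, n_otus >= 2,
            n_modules >= 1, n_modules <= n_plants,
            effect_size >= 1, base_lognormal_sigma > 0,
            sequencing_depth >= 1,
            assoc_fraction > 0, assoc_fraction <= 1,
            hub_plant_index >= 1, hub_plant_index <= n_plants)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate paired plant and OTU tables with planted associations
#'
#' Plants are split round-robin over modules and given independent log-normal
#' latent abundances across plots (observed as Poisson stem counts). Each
#' associated OTU picks one partner plant; its latent abundance is a
#' log-normal baseline multiplied by `effect_size` raised to the partner's
#' standardized log abundance, so partner and OTU covary across plots. The
#' hub plant receives at least three times the median number of partner
#' OTUs. OTU counts are drawn multinomially at `sequencing_depth` per plot.
#'
#' @param config a [synthetic_config()].
#'
#' @return a list with elements `plants` and `bacteria` (both
#'   [sample_matrix()]) and `truth`, a list holding `planted_edges`
#'   (data.frame plant/otu), `module_of` (named vector over plants and
#'   associated OTUs), and `hub_plant`.
#' @export
simulate_iden <- function(config = synthetic_config()) {
  cf <- config
  set.seed(cf$seed)
  plants <- sprintf("plant_%02d", seq_len(cf$n_plants))
  otus <- sprintf("OTU_%04d", seq_len(cf$n_otus))
  plots <- sprintf("plot_%02d", seq_len(cf$n_plots))

  module_of_plant <- setNames(rep(seq_len(cf$n_modules),
                                  length.out = cf$n_plants), plants)

  # latent plant abundances: independent log-normals across plots
  log_lambda <- matrix(rnorm(cf$n_plants * cf$n_plots,
                             mean = log(cf$plant_mean_stems),
                             sd = cf$base_lognormal_sigma),
                       cf$n_plants, cf$n_plots,
                       dimnames = list(plants, plots))
  plant_counts <- matrix(rpois(length(log_lambda), exp(log_lambda)),
                         cf$n_plants, cf$n_plots,
                         dimnames = list(plants, plots))
  # a plot where a species drew zero everywhere is fine; guard all-zero rows
  empty <- rowSums(plant_counts) == 0
  plant_counts[empty, 1L] <- 1

  # partner allocation: hub gets ~30% of associated OTUs, rest spread evenly,
  # which places the hub at >= 3x the median partner count
  n_assoc <- max(cf$n_modules, floor(cf$assoc_fraction * cf$n_otus))
  n_hub <- max(1L, floor(0.3 * n_assoc))
  others <- setdiff(seq_len(cf$n_plants), cf$hub_plant_index)
  partner <- c(rep(cf$hub_plant_index, n_hub),
               rep_len(others, n_assoc - n_hub))

  z <- t(scale(t(log_lambda)))  # standardized log plant abundance per plant
  mu_otu <- rnorm(cf$n_otus, 0, 1)
  latent <- matrix(rlnorm(cf$n_otus * cf$n_plots,
                          meanlog = rep(mu_otu, cf$n_plots),
                          sdlog = cf$base_lognormal_sigma),
                   cf$n_otus, cf$n_plots, dimnames = list(otus, plots))
  for (o in seq_len(n_assoc))
    latent[o, ] <- latent[o, ] * cf$effect_size^z[partner[o], ]

  otu_counts <- matrix(0, cf$n_otus, cf$n_plots,
                       dimnames = list(otus, plots))
  for (s in seq_len(cf$n_plots))
    otu_counts[, s] <- rmultinom(1, cf$sequencing_depth,
                                 latent[, s] / sum(latent[, s]))

  phyla <- sprintf("p__Phylum%02d", rep(seq_len(8), length.out = cf$n_otus))
  lineage <- setNames(paste("k__Bacteria", phyla,
                            sprintf("g__Genus%04d", seq_len(cf$n_otus)),
                            sep = ";"), otus)

  module_of <- c(module_of_plant,
                 setNames(module_of_plant[partner], otus[seq_len(n_assoc)]))
  truth <- list(planted_edges = data.frame(plant = plants[partner],
                                           otu = otus[seq_len(n_assoc)],
                                           stringsAsFactors = FALSE),
                module_of = module_of,
                hub_plant = plants[cf$hub_plant_index])

  list(plants = sample_matrix(plant_counts, "plant"),
       bacteria = sample_matrix(otu_counts, "bacteria", lineage = lineage),
       truth = truth)
}

#' Destroy plant-OTU association by shuffling each OTU row across plots
#'
#' A negative control: every OTU row is independently permuted over plots, so
#' each row's count multiset (and hence its marginal distribution) is kept
#' while all cross-feature association is destroyed.
#'
#' @param x a bacterial [sample_matrix()].
#' @param seed integer seed.
#' @return a [sample_matrix()] of the same shape.
#' @export
shuffle_nulls <- function(x, seed = 1) {
  stopifnot(inherits(x, "sample_matrix"))
  set.seed(seed)
  shuf <- t(apply(x$counts, 1L, sample))
  dimnames(shuf) <- dimnames(x$counts)
  sample_matrix(shuf, domain = x$domain, lineage = x$lineage,
                site_of_sample = x$site_of_sample)
}

#' Write a synthetic site to disk in the package's input dialects
#'
#' @param sim result of [simulate_iden()].
#' @param dir output directory (created if needed).
#' @param site site label used in the file names and site metadata.
#' @return invisibly, the directory.
#' @export
write_synthetic_site <- function(sim, dir, site = "site1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$bacteria, file.path(dir, "otu_table.tsv"),
                    taxonomy_path = file.path(dir, "taxonomy.tsv"),
                    id_column = "otu_id")
  write_plant_survey(sim$plants, file.path(dir, "plant_survey.tsv"))
  write.table(data.frame(plot = colnames(sim$plants$counts), site = site),
              file.path(dir, "site_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$planted_edges, file.path(dir, "truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(node = names(sim$truth$module_of),
                         module = sim$truth$module_of),
              file.path(dir, "truth_modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
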