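# Shared fixtures, all built in code at test time.

# perfectly nested staircase: row i occupied in columns 1..(n - i + 1)
staircase_matrix <- function(n = 4) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) a[i, seq_len(n - i + 1)] <- 1
  a
}

random_incidence <- function(nr, nc, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    a <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) return(a)
  }
}

# n_blocks disjoint complete bipartite blocks with planted labels
block_network <- function(plants_per_block = 2, otus_per_block = 10,
                          n_blocks = 4) {
  p <- plants_per_block * n_blocks
  m <- otus_per_block * n_blocks
  a <- matrix(0, p, m,
              dimnames = list(sprintf("plant_%02d", 1:p),
                              sprintf("OTU_%04d", 1:m)))
  rmod <- rep(seq_len(n_blocks), each = plants_per_block)
  cmod <- rep(seq_len(n_blocks), each = otus_per_block)
  for (b in seq_len(n_blocks)) a[rmod == b, cmod == b] <- 1
  list(a = a, row_modules = rmod, col_modules = cmod,
       truth = setNames(c(rmod, cmod), c(rownames(a), colnames(a))))
}

# small bacterial sample_matrix with distinct lineages
toy_bacteria <- function(n_otus = 6, n_plots = 5, seed = 1, depth = 200) {
  set.seed(seed)
  counts <- matrix(rpois(n_otus * n_plots, depth / n_otus), n_otus, n_plots,
                   dimnames = list(sprintf("OTU_%04d", seq_len(n_otus)),
                                   sprintf("plot_%02d", seq_len(n_plots))))
  lin <- setNames(paste0("k__Bacteria;p__Phylum",
                         rep(1:3, length.out = n_otus), ";g__G", 1:n_otus),
                  rownames(counts))
  sample_matrix(counts, "bacteria", lineage = lin)
}

toy_plants <- function(n_plants = 4, n_plots = 5, seed = 2) {
  set.seed(seed)
  counts <- matrix(rpois(n_plants * n_plots, 10), n_plants, n_plots,
                   dimnames = list(sprintf("plant_%02d", seq_len(n_plants)),
                                   sprintf("plot_%02d", seq_len(n_plots))))
  sample_matrix(counts, "plant")
}

# a fabricated sparcc_result over 2 plants + 3 OTUs with chosen rho/p cells
toy_corr <- function() {
  ids <- c("plant_01", "plant_02", "OTU_0001", "OTU_0002", "OTU_0003")
  rho <- diag(5); dimnames(rho) <- list(ids, ids)
  pv <- matrix(1, 5, 5, dimnames = list(ids, ids))
  set_pair <- function(m, i, j, v) { m[i, j] <- m[j, i] <- v; m }
  rho <- set_pair(rho, "plant_01", "OTU_0001", 0.31)
  pv <- set_pair(pv, "plant_01", "OTU_0001", 0.04)
  rho <- set_pair(rho, "plant_01", "OTU_0002", -0.45)
  pv <- set_pair(pv, "plant_01", "OTU_0002", 0.01)
  rho <- set_pair(rho, "plant_02", "OTU_0003", 0.80)
  pv <- set_pair(pv, "plant_02", "OTU_0003", 0.001)
  # strong but intradomain: must never become an edge
  rho <- set_pair(rho, "OTU_0001", "OTU_0002", 0.90)
  pv <- set_pair(pv, "OTU_0001", "OTU_0002", 0.001)
  # strong rho failing the p filter, and significant rho failing the r filter
  rho <- set_pair(rho, "plant_02", "OTU_0001", 0.70)
  pv <- set_pair(pv, "plant_02", "OTU_0001", 0.20)
  rho <- set_pair(rho, "plant_02", "OTU_0002", 0.10)
  pv <- set_pair(pv, "plant_02", "OTU_0002", 0.001)
  structure(list(rho = rho, pvals = pv, excluded_pairs = NULL,
                 domain = setNames(c("plant", "plant", rep("bacteria", 3)),
                                   ids),
                 params = NULL),
            class = "sparcc_result")
}

fast_sparcc_params <- function(seed = 1)
  sparcc_params(n_inner_draws = 4, n_permutations = 19, seed = seed)
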