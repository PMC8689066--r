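# Barber bipartite modularity, simulated-annealing module detection, and
# Zi-Pi node-role classification (Olesen-style role taxonomy).

#' Barber bipartite modularity of a partition
#'
#' `Q_B = (1/L) * sum_{ij} (A_ij - k_i d_j / L) * delta(g_i, g_j)` over plant
#' rows `i` and OTU columns `j`, with `k`, `d` the degrees and `g` the
#' module labels.
#'
#' @param a binary incidence matrix (plants x OTUs).
#' @param row_modules,col_modules integer module labels for rows and
#'   columns.
#' @return scalar Q.
#' @export
barber_modularity <- function(a, row_modules, col_modules) {
  a <- (as.matrix(a) > 0) * 1
  l <- sum(a)
  if (l == 0) stop("empty network")
  k <- rowSums(a); d <- colSums(a)
  delta <- outer(row_modules, col_modules, "==")
  sum((a - outer(k, d) / l) * delta) / l
}

#' Control parameters for the annealing schedule
#'
#' @param t0 initial temperature (default 1).
#' @param cooling geometric cooling factor per stage (default 0.995).
#' @param c_moves per-stage node reassignments are `c_moves * (P + M)`, plus
#'   `c_moves` merge/split proposals (default 10).
#' @param t_min stop temperature (default 1e-5).
#' @param stale_stages stop after this many consecutive stages with no
#'   accepted move (default 3).
#' @return an `anneal_control` list.
#' @export
anneal_control <- function(t0 = 1, cooling = 0.995, c_moves = 10,
                           t_min = 1e-5, stale_stages = 3) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, c_moves >= 1, t_min > 0)
  structure(as.list(environment()), class = "anneal_control")
}

#' Module detection by simulated annealing on Barber modularity
#'
#' Guimera-Amaral-style search: starts with every node in its own module and
#' applies single-node reassignments plus occasional module merges and
#' random bisection splits, accepting uphill moves always and downhill moves
#' with probability `exp(dQ / T)` under a geometric cooling schedule. The
#' best-ever partition is returned (first-found on ties, deterministic under
#' the seed).
#'
#' @param net an `iden_network` (or a binary incidence matrix).
#' @param control an [anneal_control()].
#' @param seed integer seed.
#' @return an `iden_partition`: `module_of` (named vector over plant then
#'   OTU ids, labels 1..n_modules in order of first appearance), `Q`,
#'   `n_modules`, `trace` (data.frame temperature / best Q per stage),
#'   `seed`.
#' @export
anneal_modules <- function(net, control = anneal_control(), seed = 1) {
  a <- if (inherits(net, "iden_network")) net$incidence else
    (as.matrix(net) > 0) * 1
  if (is.null(rownames(a)))
    rownames(a) <- sprintf("plant_%02d", seq_len(nrow(a)))
  if (is.null(colnames(a)))
    colnames(a) <- sprintf("OTU_%04d", seq_len(ncol(a)))
  set.seed(seed)
  res <- .anneal_cpp(matrix(as.integer(a), nrow(a), ncol(a)),
                     control$t0, control$cooling, control$c_moves,
                     control$t_min, control$stale_stages)
  raw <- c(res$row_modules, res$col_modules)
  labels <- match(raw, unique(raw))  # compact 1..n in first-appearance order
  module_of <- setNames(labels, c(rownames(a), colnames(a)))
  q <- barber_modularity(a, labels[seq_len(nrow(a))],
                         labels[nrow(a) + seq_len(ncol(a))])
  structure(list(module_of = module_of, Q = q,
                 n_modules = length(unique(labels)),
                 trace = data.frame(temperature = res$trace_t,
                                    best_q = res$trace_q),
                 seed = seed),
            class = "iden_partition")
}

#' @export
print.iden_partition <- function(x, ...) {
  cat("iden_partition: ", x$n_modules, " modules, Q = ",
      format(x$Q, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Within-module degree z-score and participation coefficient
#'
#' `Zi = (k_i,own - mean) / sd` of within-module degree, standardized within
#' the node's own module *and* bipartite level (plants against plants, OTUs
#' against OTUs; `sd = 0` gives `Zi = 0`).
#' `Pi = 1 - sum_t (k_i,t / k_i)^2` over modules `t`. Roles follow the
#' (2.5, 0.62) threshold taxonomy via [classify_role()].
#'
#' @param net an `iden_network` (or binary incidence matrix with dimnames).
#' @param partition an `iden_partition` (or named module vector).
#' @param level_normalization standardize Zi within the node's bipartite
#'   level (default TRUE); FALSE pools both levels of a module.
#' @return data.frame: id, domain, degree, module, zi, pi, role.
#' @export
zi_pi <- function(net, partition, level_normalization = TRUE) {
  a <- if (inherits(net, "iden_network")) net$incidence else
    (as.matrix(net) > 0) * 1
  module_of <- if (inherits(partition, "iden_partition"))
    partition$module_of else partition
  ids <- c(rownames(a), colnames(a))
  stopifnot(all(ids %in% names(module_of)))
  gr <- module_of[rownames(a)]; gc <- module_of[colnames(a)]
  mods <- sort(unique(c(gr, gc)))
  # within-module degree of each node into each module (partners live on
  # the opposite level)
  kmod_row <- vapply(mods, function(m)
    rowSums(a[, gc == m, drop = FALSE]), numeric(nrow(a)))
  kmod_col <- vapply(mods, function(m)
    colSums(a[gr == m, , drop = FALSE]), numeric(ncol(a)))
  if (nrow(a) == 1L) kmod_row <- matrix(kmod_row, nrow = 1L)
  if (ncol(a) == 1L) kmod_col <- matrix(kmod_col, nrow = 1L)
  own_row <- kmod_row[cbind(seq_len(nrow(a)), match(gr, mods))]
  own_col <- kmod_col[cbind(seq_len(ncol(a)), match(gc, mods))]
  df <- data.frame(
    id = ids,
    domain = c(rep("plant", nrow(a)), rep("bacteria", ncol(a))),
    degree = c(rowSums(a), colSums(a)),
    module = unname(c(gr, gc)),
    own = c(own_row, own_col),
    stringsAsFactors = FALSE)
  grp <- if (level_normalization) paste(df$module, df$domain) else
    as.character(df$module)
  zi <- numeric(nrow(df))
  for (g in unique(grp)) {
    sel <- grp == g
    mu <- mean(df$own[sel]); s <- sd(df$own[sel])
    zi[sel] <- if (is.na(s) || s == 0) 0 else (df$own[sel] - mu) / s
  }
  kmat <- rbind(kmod_row, kmod_col)
  pi <- 1 - rowSums((kmat / df$degree)^2)
  pi[df$degree == 0] <- 0
  df$zi <- zi
  df$pi <- pi
  df$role <- classify_role(zi, pi)
  df$own <- NULL
  df
}

#' Classify nodes from (Zi, Pi) with the standard role thresholds
#'
#' `Zi > 2.5` and `Pi > 0.62` jointly define: both exceeded, network hub;
#' only Zi, module hub; only Pi, connector; neither, peripheral. The four
#' regions tile the (Zi, Pi) plane exhaustively and exclusively.
#'
#' @param zi,pi numeric vectors (recycled to common length).
#' @param zi_threshold,pi_threshold cutoffs (defaults 2.5 and 0.62).
#' @return character vector of roles.
#' @export
classify_role <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  hi_z <- zi > zi_threshold
  hi_p <- pi > pi_threshold
  ifelse(hi_z & hi_p, "network hub",
         ifelse(hi_z, "module hub",
                ifelse(hi_p, "connector", "peripheral")))
}

#' Per-module taxonomic composition
#'
#' Counts member OTUs per phylum in every module, lists member plants, and
#' flags phyla exclusive to a single module.
#'
#' @param net an `iden_network`.
#' @param partition an `iden_partition` (or named module vector).
#' @param lineage named lineage vector for the network's OTUs
#'   (semicolon-delimited ranks; the rank starting `p__` — or the second
#'   field — is taken as phylum).
#' @return list with `phylum_counts` (data.frame module, phylum, n_otus,
#'   exclusive), `plants` (data.frame module, plant), `n_otus_per_module`.
#' @export
module_composition <- function(net, partition, lineage) {
  module_of <- if (inherits(partition, "iden_partition"))
    partition$module_of else partition
  phyla <- extract_phylum(lineage[net$otu_ids])
  mod_otu <- module_of[net$otu_ids]
  tab <- as.data.frame(table(module = mod_otu, phylum = phyla),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3L] <- "n_otus"
  tab$module <- as.integer(tab$module)
  n_mod_with <- tapply(tab$module, tab$phylum, function(x)
    length(unique(x)))
  tab$exclusive <- unname(n_mod_with[tab$phylum] == 1)
  tab <- tab[order(tab$module, -tab$n_otus), ]
  rownames(tab) <- NULL
  plants <- data.frame(module = as.integer(module_of[net$plant_ids]),
                       plant = net$plant_ids, stringsAsFactors = FALSE)
  plants <- plants[order(plants$module, plants$plant), ]
  rownames(plants) <- NULL
  list(phylum_counts = tab, plants = plants,
       n_otus_per_module = table(mod_otu))
}

#' Extract the phylum rank from semicolon-delimited lineages
#'
#' @param lineage character vector of ranked lineages.
#' @return character vector of phylum names (`"unclassified"` when absent).
#' @export
extract_phylum <- function(lineage) {
  vapply(strsplit(lineage, ";"), function(ranks) {
    ranks <- trimws(ranks)
    hit <- grep("^p__", ranks, value = TRUE)
    if (length(hit)) return(sub("^p__", "", hit[1L]))
    if (length(ranks) >= 2L && nzchar(ranks[2L])) return(ranks[2L])
    "unclassified"
  }, character(1))
}

#' Normalized mutual information between two partitions
#'
#' NMI with arithmetic-mean normalization; 1 for identical partitions (up to
#' relabeling), 0 for independent ones.
#'
#' @param a,b vectors of module labels over the same nodes (matched by name
#'   when both are named).
#' @return NMI in `[0, 1]`.
#' @export
partition_nmi <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n; pk <- colSums(tab) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pjk <- tab / n
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / outer(pj, pk)[nz]))
  ha <- h(pj); hb <- h(pk)
  if (ha == 0 && hb == 0) return(1)
  mi / ((ha + hb) / 2)
}

#' Write node-role and module tables as TSV
#'
#' @param roles data.frame from [zi_pi()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_node_roles <- function(roles, path) {
  write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
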