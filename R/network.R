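# Threshold SparCC results into a bipartite plant-OTU incidence network:
# keep interdomain pairs with |rho| >= r_min and p < p_max, drop species
# left without any edge.

#' Construct the bipartite interdomain network
#'
#' @param corr a `sparcc_result` from [sparcc()] run on a stacked
#'   plants+bacteria table (feature domains must be available, either inside
#'   `corr` or via `domain`).
#' @param r_min minimum |rho| for an edge (default 0.3).
#' @param p_max maximum pseudo p-value, exclusive (default 0.05).
#' @param domain optional named domain vector overriding `corr$domain`.
#' @param site optional site label attached to the network.
#'
#' @return an `iden_network`: `plant_ids`, `otu_ids`, `incidence` (binary
#'   P x M matrix), `weights` (rho for retained edges, 0 elsewhere),
#'   `pvals` (retained edges' p, NA elsewhere), `site`. Species with no
#'   surviving edge are dropped (with a message listing the drop counts).
#' @export
build_network <- function(corr, r_min = 0.3, p_max = 0.05, domain = NULL,
                          site = NULL) {
  stopifnot(inherits(corr, "sparcc_result") || is.list(corr))
  if (is.null(domain)) domain <- corr$domain
  if (is.null(domain)) stop("feature domain tags are required")
  ids <- rownames(corr$rho)
  domain <- domain[ids]
  plants <- ids[domain == "plant"]
  otus <- ids[domain == "bacteria"]
  if (!length(plants) || !length(otus))
    stop("need features from both domains")
  rho <- corr$rho[plants, otus, drop = FALSE]
  pv <- corr$pvals[plants, otus, drop = FALSE]
  keep <- (abs(rho) >= r_min) & (pv < p_max)
  if (!any(keep)) stop("empty network under thresholds")
  prow <- rowSums(keep) > 0
  pcol <- colSums(keep) > 0
  if (any(!prow) || any(!pcol))
    message(sum(!prow), " plants and ", sum(!pcol),
            " OTUs dropped (no surviving edge)")
  inc <- keep[prow, pcol, drop = FALSE] * 1
  w <- rho[prow, pcol, drop = FALSE] * inc
  p <- pv[prow, pcol, drop = FALSE]
  p[inc == 0] <- NA_real_
  structure(list(plant_ids = plants[prow], otu_ids = otus[pcol],
                 incidence = inc, weights = w, pvals = p, site = site),
            class = "iden_network")
}

#' Build an `iden_network` directly from an incidence matrix
#'
#' Useful for constructed examples and null-model work.
#'
#' @param incidence binary plants x OTUs matrix (dimnames optional).
#' @param weights optional weight matrix of the same shape.
#' @param site optional site label.
#' @return an `iden_network`.
#' @export
as_iden_network <- function(incidence, weights = NULL, site = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)))
    rownames(incidence) <- sprintf("plant_%02d", seq_len(nrow(incidence)))
  if (is.null(colnames(incidence)))
    colnames(incidence) <- sprintf("OTU_%04d", seq_len(ncol(incidence)))
  if (is.null(weights)) weights <- incidence * 1
  structure(list(plant_ids = rownames(incidence),
                 otu_ids = colnames(incidence),
                 incidence = (incidence > 0) * 1, weights = weights,
                 pvals = NULL, site = site),
            class = "iden_network")
}

#' @export
print.iden_network <- function(x, ...) {
  cat("iden_network", if (!is.null(x$site)) paste0(" [", x$site, "]"), ": ",
      length(x$plant_ids), " plants x ", length(x$otu_ids), " OTUs, ",
      sum(x$incidence), " links\n", sep = "")
  invisible(x)
}

#' Convert an `iden_network` to an igraph bipartite graph
#'
#' @param net an `iden_network`.
#' @param partition optional partition from [anneal_modules()]; adds a
#'   `module` vertex attribute.
#' @param roles optional node-role table from [zi_pi()]; adds `zi`, `pi`,
#'   `role` attributes.
#' @return an igraph graph with vertex attributes `type` (TRUE for OTUs),
#'   `domain`, `degree`, plus optional module/role attributes, and edge
#'   attributes `rho` and `sign`.
#' @export
as_igraph <- function(net, partition = NULL, roles = NULL) {
  idx <- which(net$incidence == 1, arr.ind = TRUE)
  edges <- cbind(net$plant_ids[idx[, 1L]], net$otu_ids[idx[, 2L]])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(c(net$plant_ids, net$otu_ids),
                      igraph::V(g)$name)),
    name = setdiff(c(net$plant_ids, net$otu_ids), igraph::V(g)$name))
  nm <- igraph::V(g)$name
  igraph::V(g)$type <- nm %in% net$otu_ids
  igraph::V(g)$domain <- ifelse(nm %in% net$otu_ids, "bacteria", "plant")
  igraph::V(g)$degree <- igraph::degree(g)
  rho <- net$weights[cbind(match(edges[, 1L], net$plant_ids),
                           match(edges[, 2L], net$otu_ids))]
  igraph::E(g)$rho <- rho
  igraph::E(g)$sign <- ifelse(rho >= 0, "positive", "negative")
  if (!is.null(partition))
    igraph::V(g)$module <- unname(partition$module_of[nm])
  if (!is.null(roles)) {
    m <- match(nm, roles$id)
    igraph::V(g)$zi <- roles$zi[m]
    igraph::V(g)$pi <- roles$pi[m]
    igraph::V(g)$role <- roles$role[m]
  }
  g
}

#' Export a network for external graph tools
#'
#' @param net an `iden_network`.
#' @param path output file.
#' @param format `"edgelist"` (TSV: plant, otu, rho, p), `"graphml"` (via
#'   igraph) or `"gexf"`.
#' @param partition,roles optional annotations forwarded to [as_igraph()].
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path,
                           format = c("edgelist", "graphml", "gexf"),
                           partition = NULL, roles = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    idx <- which(net$incidence == 1, arr.ind = TRUE)
    df <- data.frame(plant_id = net$plant_ids[idx[, 1L]],
                     otu_id = net$otu_ids[idx[, 2L]],
                     rho = net$weights[idx],
                     p = if (is.null(net$pvals)) NA_real_ else net$pvals[idx])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  g <- as_igraph(net, partition = partition, roles = roles)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  .write_gexf(g, path)
  invisible(path)
}

# Minimal static GEXF 1.3 writer (no installed package emits GEXF).
.write_gexf <- function(g, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  nm <- igraph::V(g)$name
  has_module <- "module" %in% igraph::vertex_attr_names(g)
  has_role <- "role" %in% igraph::vertex_attr_names(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="domain" type="string"/>',
    '      <attribute id="1" title="degree" type="integer"/>',
    if (has_module) '      <attribute id="2" title="module" type="integer"/>',
    if (has_role) '      <attribute id="3" title="role" type="string"/>',
    '    </attributes>',
    '    <nodes>'), con)
  for (i in seq_along(nm)) {
    attrs <- c(sprintf('<attvalue for="0" value="%s"/>',
                       igraph::V(g)$domain[i]),
               sprintf('<attvalue for="1" value="%d"/>',
                       igraph::V(g)$degree[i]),
               if (has_module) sprintf('<attvalue for="2" value="%d"/>',
                                       igraph::V(g)$module[i]),
               if (has_role) sprintf('<attvalue for="3" value="%s"/>',
                                     esc(igraph::V(g)$role[i])))
    writeLines(sprintf('      <node id="%s" label="%s"><attvalues>%s</attvalues></node>',
                       esc(nm[i]), esc(nm[i]), paste(attrs, collapse = "")),
               con)
  }
  writeLines('    </nodes>', con)
  writeLines('    <edges>', con)
  el <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(el)))
    writeLines(sprintf('      <edge id="%d" source="%s" target="%s" weight="%.6f"/>',
                       k - 1L, esc(el[k, 1L]), esc(el[k, 2L]),
                       abs(igraph::E(g)$rho[k])), con)
  writeLines(c('    </edges>', '  </graph>', '</gexf>'), con)
}
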