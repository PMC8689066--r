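# Cross-site comparison of networks: shared/unique OTU accounting (Venn
# regions), plant incidence across sites, and per-site phylum composition.

#' Collect per-site networks and their node sets
#'
#' @param networks named list of `iden_network` objects (names are site
#'   labels; unnamed lists use the networks' own `site` fields).
#' @param lineage named lineage vector covering every network OTU.
#' @return a `site_collection` list: `networks`, `otu_sets`, `plant_sets`,
#'   `lineage`.
#' @export
site_collection <- function(networks, lineage = NULL) {
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    names(networks) <- vapply(networks, function(n)
      if (is.null(n$site)) stop("unnamed network without site label") else
        n$site, character(1))
  if (anyDuplicated(names(networks))) stop("duplicate site labels")
  if (!is.null(lineage)) {
    all_otus <- unique(unlist(lapply(networks, `[[`, "otu_ids")))
    missing <- setdiff(all_otus, names(lineage))
    if (length(missing))
      stop("network OTUs missing from lineage: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(networks = networks,
                 otu_sets = lapply(networks, `[[`, "otu_ids"),
                 plant_sets = lapply(networks, `[[`, "plant_ids"),
                 lineage = lineage),
            class = "site_collection")
}

#' Venn-region counts and shared/unique percentages for 2-4 sets
#'
#' Every intersection region is counted. Conventions: a site's unique
#' percentage is its exclusive count over its own set size; a pairwise
#' shared percentage is `100 * |A n B| / |A u B|`; the all-site shared
#' percentage is the common count over the union of all sets.
#'
#' @param sets named list of 2-4 character vectors.
#' @return list with `regions` (data.frame membership signature / count),
#'   `unique` (data.frame site, n_unique, pct_unique), `pairwise`
#'   (data.frame site_a, site_b, shared, union, pct_shared), `all_shared`,
#'   `pct_all_shared`, `n_union`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_counts supports 2-4 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L,
                                         dimnames = list(NULL, names(sets)))
  sig <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- as.data.frame(table(signature = sig), stringsAsFactors = FALSE)
  names(regions)[2L] <- "count"
  sizes <- vapply(sets, length, integer(1))
  uniq <- vapply(names(sets), function(nm) {
    sum(rowSums(memb) == 1 & memb[, nm])
  }, numeric(1))
  unique_df <- data.frame(site = names(sets), n_unique = uniq,
                          pct_unique = round(100 * uniq / sizes, 2),
                          stringsAsFactors = FALSE)
  pairs <- combn(names(sets), 2)
  pairwise <- do.call(rbind, apply(pairs, 2L, function(ab) {
    shared <- length(intersect(sets[[ab[1]]], sets[[ab[2]]]))
    un <- length(union(sets[[ab[1]]], sets[[ab[2]]]))
    data.frame(site_a = ab[1], site_b = ab[2], shared = shared,
               union = un, pct_shared = round(100 * shared / un, 2),
               stringsAsFactors = FALSE)
  }))
  all_shared <- length(Reduce(intersect, sets))
  list(regions = regions, unique = unique_df, pairwise = pairwise,
       all_shared = all_shared,
       pct_all_shared = round(100 * all_shared / length(univ), 2),
       n_union = length(univ))
}

#' Pairwise shared percentage under the shared-over-union convention
#'
#' `100 * |A n B| / (|A| + |B| - |A n B|)`, the convention consistent with
#' the printed cross-site OTU percentages.
#'
#' @param size_a,size_b set sizes. @param shared intersection size.
#' @param digits rounding (default 2).
#' @return percentage.
#' @export
shared_percentage <- function(size_a, size_b, shared, digits = 2) {
  stopifnot(shared <= size_a, shared <= size_b)
  round(100 * shared / (size_a + size_b - shared), digits)
}

#' Plant incidence and abundance across sites
#'
#' @param collection a [site_collection()].
#' @param plant_abundance optional named list (per site) of named plant
#'   abundance vectors; when given, the table holds abundances, else 0/1
#'   incidence.
#' @return list with `table` (plants x sites), `n_total_plants` (distinct
#'   network plants across sites).
#' @export
plant_site_incidence <- function(collection, plant_abundance = NULL) {
  sites <- names(collection$networks)
  plants <- sort(unique(unlist(collection$plant_sets)))
  tab <- matrix(0, length(plants), length(sites),
                dimnames = list(plants, sites))
  for (s in sites) {
    present <- collection$plant_sets[[s]]
    tab[present, s] <- if (is.null(plant_abundance)) 1 else
      plant_abundance[[s]][present]
  }
  list(table = tab, n_total_plants = length(plants))
}

#' Per-site phylum composition of network OTUs
#'
#' @param collection a [site_collection()] with lineage.
#' @param weights `"otus"` (fraction of network OTUs per phylum, default) or
#'   a named list of per-site named OTU abundance vectors.
#' @return list with `fractions` (sites x phyla, rows summing to 1) and
#'   `exclusive` (data.frame phylum, site for phyla found at one site only).
#' @export
site_phylum_composition <- function(collection, weights = "otus") {
  if (is.null(collection$lineage))
    stop("site_collection built without lineage")
  sites <- names(collection$networks)
  per_site <- lapply(sites, function(s) {
    otus <- collection$otu_sets[[s]]
    ph <- extract_phylum(collection$lineage[otus])
    w <- if (identical(weights, "otus")) rep(1, length(otus)) else
      weights[[s]][otus]
    tapply(w, ph, sum)
  })
  phyla <- sort(unique(unlist(lapply(per_site, names))))
  frac <- matrix(0, length(sites), length(phyla),
                 dimnames = list(sites, phyla))
  for (i in seq_along(sites))
    frac[i, names(per_site[[i]])] <- per_site[[i]]
  frac <- frac / rowSums(frac)
  n_sites_with <- colSums(frac > 0)
  excl <- which(n_sites_with == 1)
  exclusive <- data.frame(
    phylum = names(excl),
    site = vapply(names(excl), function(p) sites[which(frac[, p] > 0)],
                  character(1)),
    stringsAsFactors = FALSE)
  rownames(exclusive) <- NULL
  list(fractions = frac, exclusive = exclusive)
}
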