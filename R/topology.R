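# Network-level topology panel for bipartite plant-OTU networks:
# connectance, web asymmetry, links per species, one-mode clustering, NODF
# nestedness (binary and weighted), d' specialization asymmetry and
# checkerboard C-scores.

#' Connectance of a bipartite network
#'
#' Realized fraction of possible interdomain links, `L / (P * M)`.
#'
#' @param p number of plants. @param m number of microbes.
#' @param l number of links.
#' @param digits rounding for the report (default 3).
#' @return connectance in `[0, 1]`.
#' @export
connectance <- function(p, m, l, digits = 3) {
  stopifnot(p >= 1, m >= 1, l >= 0)
  if (l > p * m) stop("more links than possible pairs")
  round(l / (p * m), digits)
}

#' Web asymmetry of a bipartite network
#'
#' `(P - M) / (P + M)`; negative when the microbial level is larger.
#'
#' @inheritParams connectance
#' @return value in `[-1, 1]`.
#' @export
web_asymmetry <- function(p, m, digits = 3) {
  stopifnot(p + m > 0)
  round((p - m) / (p + m), digits)
}

#' Links per species
#'
#' `L / (P + M)`.
#'
#' @inheritParams connectance
#' @return positive scalar.
#' @export
links_per_species <- function(p, m, l, digits = 3) {
  stopifnot(p + m > 0, l >= 0)
  round(l / (p + m), digits)
}

# paired NODF term for two margins and a shared count, on one level
.nodf_pair <- function(fill_hi, fill_lo, shared) {
  if (fill_hi <= fill_lo || fill_lo == 0) return(0)
  100 * shared / fill_lo
}

#' NODF nestedness (0-100)
#'
#' Nestedness metric based on Overlap and Decreasing Fill. For every ordered
#' pair of rows with strictly decreasing marginal totals the paired term is
#' `100 * |shared partners| / (smaller marginal)`; pairs with tied marginals
#' contribute 0; likewise for columns. NODF is the mean over all row pairs
#' and column pairs. 100 = perfectly nested staircase, 0 = no overlap.
#'
#' @param a binary incidence matrix (coerced with `> 0`).
#' @return NODF in `[0, 100]`.
#' @export
nodf <- function(a) {
  a <- (as.matrix(a) > 0) * 1
  if (nrow(a) < 2 && ncol(a) < 2) {
    warning("degenerate matrix; NODF defined as 0")
    return(0)
  }
  level <- function(m) {
    n <- nrow(m)
    if (n < 2) return(numeric(0))
    fill <- rowSums(m)
    sh <- m %*% t(m)
    out <- numeric(n * (n - 1) / 2)
    k <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      k <- k + 1L
      hi <- max(fill[i], fill[j]); lo <- min(fill[i], fill[j])
      if (fill[i] != fill[j])
        out[k] <- .nodf_pair(hi, lo, sh[i, j])
    }
    out
  }
  vals <- c(level(a), level(t(a)))
  if (!length(vals)) {
    warning("degenerate matrix; NODF defined as 0")
    return(0)
  }
  mean(vals)
}

#' Weighted NODF, reported on a 0-1 scale
#'
#' Weighted variant of NODF: for each pair of rows, the row with strictly
#' more occupied cells is the richer one; the paired term counts cells where
#' the sparser row's weight is positive and strictly smaller than the
#' richer row's, divided by the sparser row's number of occupied cells.
#' Pairs with tied occupancy contribute 0; likewise for columns.
#'
#' @param w non-negative weight matrix.
#' @return weighted NODF in `[0, 1]`.
#' @export
weighted_nodf <- function(w) {
  w <- as.matrix(w)
  level <- function(m) {
    n <- nrow(m)
    if (n < 2) return(numeric(0))
    fill <- rowSums(m > 0)
    out <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (fill[i] == fill[j] || min(fill[i], fill[j]) == 0) {
        out <- c(out, 0); next
      }
      hi <- if (fill[i] > fill[j]) m[i, ] else m[j, ]
      lo <- if (fill[i] > fill[j]) m[j, ] else m[i, ]
      out <- c(out, 100 * sum(lo > 0 & lo < hi) / sum(lo > 0))
    }
    out
  }
  vals <- c(level(w), level(t(w)))
  if (!length(vals)) {
    warning("degenerate matrix; weighted NODF defined as 0")
    return(0)
  }
  mean(vals) / 100
}

#' Kullback-Leibler specialization d' per node and specialization asymmetry
#'
#' For node `i` with interaction weights `a_ij`, `d_i = sum_j p_ij *
#' ln(p_ij / q_j)` where `p_ij = a_ij / A_i.` is its partner-use profile and
#' `q_j = A_.j / A_..` is partner availability. `d'` rescales to `[0, 1]`
#' with minimum 0 (use proportional to availability) and maximum
#' `ln(A_.. / A_i.)` (all use concentrated on an otherwise unused partner).
#' Specialization asymmetry contrasts level means:
#' `SA = (<d'>_otus - <d'>_plants) / (<d'>_otus + <d'>_plants)`.
#'
#' @param w non-negative plants x OTUs weight matrix (binary allowed).
#' @return list with `d_plants`, `d_otus` (named vectors of d'), `sa`
#'   (signed, OTU level minus plant level) and `sa_abs`.
#' @export
dprime_specialization <- function(w) {
  w <- abs(as.matrix(w))
  total <- sum(w)
  if (total == 0) stop("empty interaction matrix")
  dprime_level <- function(m) {
    # rows of m are the focal level, columns the partners
    q <- colSums(m) / sum(m)
    out <- rep(NA_real_, nrow(m))
    for (i in seq_len(nrow(m))) {
      ai <- sum(m[i, ])
      if (ai == 0) next
      p <- m[i, ] / ai
      nz <- p > 0
      d <- sum(p[nz] * log(p[nz] / q[nz]))
      dmax <- log(sum(m) / ai)
      out[i] <- if (dmax <= 0) 0 else min(1, max(0, d / dmax))
    }
    names(out) <- rownames(m)
    out
  }
  dp <- dprime_level(w)
  do <- dprime_level(t(w))
  mp <- mean(dp, na.rm = TRUE); mo <- mean(do, na.rm = TRUE)
  sa <- if (mp + mo == 0) 0 else (mo - mp) / (mo + mp)
  list(d_plants = dp, d_otus = do, sa = sa, sa_abs = abs(sa))
}

#' Checkerboard score (C-score) for one level of a bipartite network
#'
#' For every unordered species pair in the level, the checkerboard unit is
#' `CU_ij = (r_i - S_ij) * (r_j - S_ij)` with `r` the species' partner counts
#' and `S_ij` their shared partners; the C-score is the mean CU over pairs.
#' The normalized variant divides each CU by `r_i * r_j`.
#'
#' @param a binary incidence matrix (plants x OTUs).
#' @param level `"plants"` (rows) or `"otus"` (columns).
#' @param normalize divide each unit by `r_i * r_j` (default FALSE).
#' @return mean checkerboard score.
#' @export
cscore <- function(a, level = c("plants", "otus"), normalize = FALSE) {
  level <- match.arg(level)
  a <- (as.matrix(a) > 0) * 1
  m <- if (level == "plants") a else t(a)
  if (nrow(m) < 2) stop("need at least 2 species at level ", level)
  r <- rowSums(m)
  sh <- m %*% t(m)
  pairs <- combn(nrow(m), 2)
  cu <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    u <- (r[i] - sh[i, j]) * (r[j] - sh[i, j])
    if (normalize) {
      if (r[i] * r[j] == 0) return(0)
      u <- u / (r[i] * r[j])
    }
    u
  })
  mean(cu)
}

#' Mean one-mode clustering coefficient of a bipartite network
#'
#' Projects the network onto each level (two species connected when they
#' share at least one partner) and averages the Watts-Strogatz local
#' clustering coefficient over all nodes of both projections; nodes with
#' fewer than two projection neighbours are skipped.
#'
#' @param a binary incidence matrix.
#' @return mean local clustering in `[0, 1]` (`NaN` if undefined for all
#'   nodes).
#' @export
cluster_coefficient <- function(a) {
  a <- (as.matrix(a) > 0) * 1
  local_cc <- function(adj) {
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
    igraph::transitivity(g, type = "local", isolates = "NaN")
  }
  cc <- c(local_cc(a %*% t(a)), local_cc(t(a) %*% a))
  cc <- cc[is.finite(cc)]
  if (!length(cc)) return(NaN)
  mean(cc)
}

#' Full topology report for one network
#'
#' Computes the whole network-level metric panel: node and link counts,
#' connectance, web asymmetry, links per species, clustering, NODF (0-100),
#' weighted NODF (0-1), specialization asymmetry and per-level C-scores.
#'
#' @param net an `iden_network`.
#' @param digits rounding applied to real-valued metrics (default 3).
#' @return a one-row data.frame of class `topology_report`.
#' @export
topology_report <- function(net, digits = 3) {
  a <- net$incidence
  p <- nrow(a); m <- ncol(a); l <- sum(a)
  sp <- dprime_specialization(abs(net$weights))
  out <- data.frame(
    site = if (is.null(net$site)) NA_character_ else net$site,
    n_plants = p, n_microbes = m, links = l,
    connectance = connectance(p, m, l, digits),
    web_asymmetry = web_asymmetry(p, m, digits),
    links_per_species = links_per_species(p, m, l, digits),
    cluster_coefficient = round(cluster_coefficient(a), digits),
    nestedness_nodf = round(nodf(a), digits),
    weighted_nestedness = round(weighted_nodf(abs(net$weights)), digits),
    specialization_asymmetry = round(sp$sa, digits),
    cscore_plants = round(cscore(a, "plants"), digits),
    cscore_otus = round(cscore(a, "otus"), digits),
    stringsAsFactors = FALSE)
  class(out) <- c("topology_report", "data.frame")
  out
}

#' Write a topology report as a one-row TSV
#'
#' @param report a `topology_report` (or several rbind-ed together).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_topology_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
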