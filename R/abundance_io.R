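# Input tables are plain TSV: an OTU count table (rows OTU id, columns sample
# ids, integer cells), an RDP-style taxonomy map, a long-format plant survey
# (plot, species, count) and a plot -> site map.

#' Read an OTU count table and its taxonomy
#'
#' @param path TSV file; first column OTU ids, header row sample ids, integer
#'   counts.
#' @param taxonomy_path TSV file with two columns: OTU id and a
#'   semicolon-delimited ranked lineage. Every OTU in `path` must appear.
#'
#' @return a [sample_matrix()] with all features tagged `bacteria`, column
#'   order preserved.
#' @export
read_otu_table <- function(path, taxonomy_path) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate OTU id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  rownames(mat) <- ids
  sample_matrix(mat, domain = "bacteria", lineage = read_taxonomy(taxonomy_path))
}

#' Read an RDP-style taxonomy table
#'
#' @param path TSV with columns OTU id and semicolon-delimited lineage.
#' @return named character vector of lineages.
#' @export
read_taxonomy <- function(path) {
  tax <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  setNames(as.character(tax[[2L]]), as.character(tax[[1L]]))
}

#' Read site metadata
#'
#' @param path TSV with columns plot id and site label.
#' @return named character vector mapping plot -> site.
#' @export
read_site_metadata <- function(path) {
  md <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  setNames(as.character(md[[2L]]), as.character(md[[1L]]))
}

#' Read a long-format plant survey and pivot to a plant x plot matrix
#'
#' Rows are (plot, species, stem count) records. Duplicate (plot, species)
#' rows are summed with a warning; absent pairs become zero.
#'
#' @param path TSV with columns plot, species, count.
#' @param site_of_sample optional named vector (see [read_site_metadata()]);
#'   when given, every surveyed plot must be present in it.
#'
#' @return a [sample_matrix()] with all features tagged `plant`. Species rows
#'   are ordered by first appearance in the file; plots likewise.
#' @export
read_plant_survey <- function(path, site_of_sample = NULL) {
  sv <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(sv) < 3L) stop("plant survey needs columns plot, species, count")
  plot <- as.character(sv[[1L]]); species <- as.character(sv[[2L]])
  count <- sv[[3L]]
  if (any(!is.finite(count) | count < 0))
    stop("negative or non-finite plant count in ", path)
  if (!is.null(site_of_sample)) {
    absent <- setdiff(unique(plot), names(site_of_sample))
    if (length(absent))
      stop("plots absent from site metadata: ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(paste(plot, species, sep = "\r")))
    warning("duplicate (plot, species) rows summed")
  sp <- unique(species); pl <- unique(plot)
  mat <- matrix(0, length(sp), length(pl), dimnames = list(sp, pl))
  for (k in seq_along(count))
    mat[species[k], plot[k]] <- mat[species[k], plot[k]] + count[k]
  sample_matrix(mat, domain = "plant",
                site_of_sample = if (is.null(site_of_sample)) NULL else
                  site_of_sample[pl])
}

#' Rarefy bacterial counts to a common depth
#'
#' Each sample's bacterial reads are subsampled without replacement to
#' exactly `depth` reads (one draw, seeded). Samples whose total is below
#' `depth` are dropped with a warning when `drop_shallow_samples`, otherwise
#' the call fails.
#'
#' @param x a [sample_matrix()] of bacterial counts.
#' @param depth target reads per sample (default 20000).
#' @param seed integer seed for the subsampling draw.
#' @param drop_shallow_samples drop under-depth samples (default TRUE).
#'
#' @return a rarefied [sample_matrix()]; every retained column sums exactly
#'   to `depth`.
#' @export
rarefy <- function(x, depth = 20000, seed = 1, drop_shallow_samples = TRUE) {
  stopifnot(inherits(x, "sample_matrix"), depth >= 1)
  if (any(x$domain != "bacteria"))
    stop("rarefy applies to bacterial count tables only")
  totals <- colSums(x$counts)
  shallow <- totals < depth
  if (all(shallow)) stop("no samples survive rarefaction")
  if (any(shallow)) {
    if (!drop_shallow_samples)
      stop("samples below rarefaction depth: ",
           paste(colnames(x$counts)[shallow], collapse = ", "))
    warning("dropping samples below depth ", depth, ": ",
            paste(colnames(x$counts)[shallow], collapse = ", "))
  }
  keep <- x$counts[, !shallow, drop = FALSE]
  set.seed(seed)
  # vegan::rrarefy subsamples rows of a sample x species matrix without
  # replacement, which is exactly the single-draw rarefaction used here.
  rar <- t(vegan::rrarefy(t(keep), depth))
  dimnames(rar) <- dimnames(keep)
  sample_matrix(rar, domain = "bacteria", lineage = x$lineage,
                site_of_sample = if (is.null(x$site_of_sample)) NULL else
                  x$site_of_sample[colnames(rar)])
}

#' Stack plant and bacterial tables into one joint composition
#'
#' Aligns the two tables on their shared plot ids (one pooled soil sample per
#' plot), applies the prevalence filter to bacterial features, and returns a
#' single plants-first feature stack — the table the SparCC stage consumes.
#'
#' @param plants a plant [sample_matrix()].
#' @param bacteria a bacterial [sample_matrix()] (normally rarefied).
#' @param policy a [filter_policy()].
#' @param plant_transform `"none"` (raw stem counts, default) or
#'   `"relative"` (plant counts rescaled to proportions within each plot and
#'   re-expressed as integers out of 1000).
#'
#' @return a joint [sample_matrix()]; plants first, then surviving OTUs, over
#'   the plot intersection.
#' @export
stack_domains <- function(plants, bacteria, policy = filter_policy(),
                          plant_transform = c("none", "relative")) {
  stopifnot(inherits(plants, "sample_matrix"),
            inherits(bacteria, "sample_matrix"))
  plant_transform <- match.arg(plant_transform)
  shared <- intersect(colnames(plants$counts), colnames(bacteria$counts))
  if (!length(shared)) stop("no shared plot ids between plants and bacteria")
  p <- plants$counts[, shared, drop = FALSE]
  b <- bacteria$counts[, shared, drop = FALSE]
  if (policy$min_prevalence > 0) {
    occ <- rowMeans(b > 0)
    b <- b[occ >= policy$min_prevalence, , drop = FALSE]
  }
  if (plant_transform == "relative") {
    cs <- colSums(p)
    cs[cs == 0] <- 1
    p <- round(sweep(p, 2, cs, "/") * 1000)
  }
  counts <- rbind(p, b)
  sample_matrix(counts,
                domain = c(rep("plant", nrow(p)), rep("bacteria", nrow(b))),
                lineage = bacteria$lineage[rownames(b)],
                site_of_sample = if (!is.null(plants$site_of_sample))
                  plants$site_of_sample[shared] else
                    if (!is.null(bacteria$site_of_sample))
                      bacteria$site_of_sample[shared] else NULL)
}

#' Write a count table (and optional taxonomy) in the dialect read back in
#'
#' @param x a [sample_matrix()].
#' @param path output TSV for the counts.
#' @param taxonomy_path optional output TSV for the lineage map.
#' @param id_column header for the id column.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(x, path, taxonomy_path = NULL,
                              id_column = "feature_id") {
  df <- data.frame(id = rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$lineage))
    write.table(data.frame(otu_id = names(x$lineage), lineage = x$lineage),
                taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a plant matrix as a long-format survey file
#'
#' Zero cells are omitted, mirroring a field survey that records only
#' observed species.
#'
#' @param x a plant [sample_matrix()].
#' @param path output TSV (plot, species, count).
#' @return invisibly, `path`.
#' @export
write_plant_survey <- function(x, path) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  df <- data.frame(plot = colnames(x$counts)[idx[, 2L]],
                   species = rownames(x$counts)[idx[, 1L]],
                   count = x$counts[idx])
  df <- df[order(df$plot, df$species), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
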