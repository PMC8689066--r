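#' Feature-by-sample count container for interdomain analyses
#'
#' A `sample_matrix` stacks abundance observations from one or both domains
#' (plants, soil bacteria) over a common set of samples (plots). Bacterial
#' features carry a ranked taxonomic lineage; samples may carry a site label.
#'
#' @param counts non-negative integer matrix, features in rows, samples in
#'   columns; both dimensions must be named with unique identifiers.
#' @param domain character vector, one of `"plant"` or `"bacteria"` per
#'   feature (recycled if length 1).
#' @param lineage named character vector mapping every bacterial feature id to
#'   a semicolon-delimited ranked lineage (RDP style). May be `NULL` when the
#'   matrix holds no bacteria.
#' @param site_of_sample optional named character vector mapping sample id to
#'   a site label.
#'
#' @return an object of class `sample_matrix` with elements `counts`,
#'   `domain`, `lineage`, `site_of_sample`.
#' @export
sample_matrix <- function(counts, domain, lineage = NULL,
                          site_of_sample = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  domain <- rep_len(as.character(domain), nrow(counts))
  if (!all(domain %in% c("plant", "bacteria")))
    stop("domain must be 'plant' or 'bacteria'")
  names(domain) <- rownames(counts)
  bact <- rownames(counts)[domain == "bacteria"]
  if (length(bact)) {
    if (is.null(lineage)) stop("bacterial features require a lineage map")
    missing <- setdiff(bact, names(lineage))
    if (length(missing))
      stop("OTUs missing from taxonomy: ", paste(missing, collapse = ", "))
    lineage <- lineage[bact]
  }
  if (!is.null(site_of_sample)) {
    absent <- setdiff(colnames(counts), names(site_of_sample))
    if (length(absent))
      stop("samples missing from site metadata: ",
           paste(absent, collapse = ", "))
    site_of_sample <- site_of_sample[colnames(counts)]
  }
  structure(list(counts = counts, domain = domain, lineage = lineage,
                 site_of_sample = site_of_sample),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  d <- table(factor(x$domain, levels = c("plant", "bacteria")))
  cat("sample_matrix: ", nrow(x$counts), " features (",
      d[["plant"]], " plants, ", d[["bacteria"]], " bacteria) x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.sample_matrix <- function(x) dim(x$counts)

#' Filtering policy applied before network construction
#'
#' @param rarefaction_depth reads retained per sample when rarefying the
#'   bacterial table (default 20000).
#' @param min_prevalence fraction of samples in which a bacterial feature must
#'   be present (count > 0) to be retained (default 0.5; 0 disables).
#' @param drop_shallow_samples drop samples whose total count is below
#'   `rarefaction_depth` instead of failing (default TRUE).
#'
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(rarefaction_depth = 20000, min_prevalence = 0.5,
                          drop_shallow_samples = TRUE) {
  stopifnot(rarefaction_depth >= 1,
            min_prevalence >= 0, min_prevalence <= 1,
            is.logical(drop_shallow_samples))
  structure(list(rarefaction_depth = rarefaction_depth,
                 min_prevalence = min_prevalence,
                 drop_shallow_samples = drop_shallow_samples),
            class = "filter_policy")
}
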