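# Fixed-fixed null model: checkerboard (2x2 submatrix) swaps preserve every
# row and column sum exactly; ensembles of rewired networks give the null
# distribution for each topology metric, compared by a one-sample t test.

#' Degree-preserving rewiring by checkerboard swaps
#'
#' Picks random 2x2 submatrices of the form `[[1,0],[0,1]]` (or its mirror)
#' and flips them, preserving both degree sequences exactly. After a
#' 1,000-attempt burn-in, `n_swaps` accepted swaps are performed (default
#' `10 * L`).
#'
#' @param a binary incidence matrix.
#' @param n_swaps accepted swaps after burn-in (default `10 * sum(a)`).
#' @param seed integer seed.
#' @param burn_in attempted swaps before counting (default 1000).
#' @param max_stale consecutive failed attempts before concluding the matrix
#'   has no swappable submatrix (default 50000).
#' @return a rewired binary matrix with identical row and column sums; the
#'   input (with a warning) when no checkerboard exists.
#' @export
rewire_incidence <- function(a, n_swaps = NULL, seed = 1, burn_in = 1000,
                             max_stale = 50000) {
  a <- (as.matrix(a) > 0) * 1
  nr <- nrow(a); nc <- ncol(a)
  if (nr < 2 || nc < 2 || sum(a) < 2 || all(a == 1)) {
    warning("no swappable 2x2 submatrix; returning input unchanged")
    return(a)
  }
  if (is.null(n_swaps)) n_swaps <- 10 * sum(a)
  set.seed(seed)
  accepted <- 0L; attempts <- 0L; stale <- 0L
  total_accept_target <- n_swaps
  while (accepted < total_accept_target) {
    i <- sample.int(nr, 2L); j <- sample.int(nc, 2L)
    attempts <- attempts + 1L
    sub <- a[i, j]
    ok <- (sub[1, 1] == 1 && sub[2, 2] == 1 && sub[1, 2] == 0 && sub[2, 1] == 0) ||
          (sub[1, 1] == 0 && sub[2, 2] == 0 && sub[1, 2] == 1 && sub[2, 1] == 1)
    if (ok) {
      a[i, j] <- 1 - sub
      stale <- 0L
      if (attempts > burn_in) accepted <- accepted + 1L
    } else {
      stale <- stale + 1L
      if (stale >= max_stale) {
        warning("no swappable 2x2 submatrix found after ", max_stale,
                " attempts; returning current matrix")
        break
      }
    }
  }
  a
}

#' Null-model significance of topology metrics
#'
#' Generates `n_rewires` degree-preserving null networks and, for every
#' metric, tests the null sample against the observed value with a
#' one-sample t test: `t = (mean(null) - observed) / (sd(null) / sqrt(n))`,
#' `df = n - 1`, two-sided p. A z-score
#' `(observed - mean(null)) / sd(null)` is reported alongside. Metrics that
#' are constant under margin-preserving rewiring (e.g. connectance) come out
#' degenerate: `p = 1` when the observed value equals the null constant,
#' else `p = 0`, flagged in the `degenerate` column.
#'
#' @param net an `iden_network`.
#' @param metrics named list of functions taking a binary incidence matrix;
#'   default panel: nodf, cscore (both levels), clustering, connectance.
#' @param n_rewires ensemble size (default 100).
#' @param seed integer seed (each null uses `seed + k`).
#' @return a data.frame of class `null_significance` with one row per
#'   metric (observed, null mean/sd, t, df, p, z, degenerate) and the null
#'   value matrix as attribute `"null_values"`.
#' @export
null_significance <- function(net, metrics = NULL, n_rewires = 100,
                              seed = 1) {
  a <- net$incidence
  if (is.null(metrics))
    metrics <- list(
      nestedness_nodf = nodf,
      cscore_plants = function(m) cscore(m, "plants"),
      cscore_otus = function(m) cscore(m, "otus"),
      cluster_coefficient = cluster_coefficient,
      connectance = function(m) connectance(nrow(m), ncol(m), sum(m),
                                            digits = 10))
  observed <- vapply(metrics, function(f) f(a), numeric(1))
  nulls <- matrix(NA_real_, n_rewires, length(metrics),
                  dimnames = list(NULL, names(metrics)))
  for (k in seq_len(n_rewires)) {
    ak <- rewire_incidence(a, seed = seed + k)
    nulls[k, ] <- vapply(metrics, function(f) f(ak), numeric(1))
  }
  rows <- lapply(names(metrics), function(nm)
    cbind(data.frame(metric = nm, observed = observed[[nm]],
                     stringsAsFactors = FALSE),
          one_sample_t(nulls[, nm], observed[[nm]])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "null_values") <- nulls
  class(out) <- c("null_significance", "data.frame")
  out
}

#' One-sample t test of a null sample against an observed reference value
#'
#' @param null_values numeric vector of null metric values.
#' @param observed observed metric value (the reference constant).
#' @return one-row data.frame: null_mean, null_sd, t, df, p, z, degenerate.
#' @export
one_sample_t <- function(null_values, observed) {
  n <- length(null_values)
  mu <- mean(null_values); s <- sd(null_values)
  if (is.na(s) || s == 0) {
    eq <- isTRUE(all.equal(mu, observed))
    return(data.frame(null_mean = mu, null_sd = 0,
                      t = if (eq) 0 else sign(mu - observed) * Inf,
                      df = n - 1, p = if (eq) 1 else 0,
                      z = NA_real_, degenerate = TRUE))
  }
  t <- (mu - observed) / (s / sqrt(n))
  data.frame(null_mean = mu, null_sd = s, t = t, df = n - 1,
             p = 2 * pt(-abs(t), df = n - 1),
             z = (observed - mu) / s, degenerate = FALSE)
}

#' Write a null-significance report as TSV
#'
#' @param x a `null_significance` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_null_report <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
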