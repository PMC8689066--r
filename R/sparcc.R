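# SparCC: correlation inference for compositional count data. Counts are
# never treated as absolute abundances; correlations between latent (basis)
# abundances are approximated from log-ratio variances under a sparsity
# assumption, with Dirichlet resampling of fractions and permutation pseudo
# p-values.

#' Parameters for the SparCC estimator
#'
#' @param n_inner_draws Dirichlet fraction draws averaged (element-wise
#'   median) per estimate (default 20).
#' @param exclusion_threshold |rho| above which the currently strongest pair
#'   is excluded from the basis-variance system, one pair per round (default
#'   0.1).
#' @param max_exclusion_rounds cap on exclusion rounds (default 10).
#' @param n_permutations row-permutation datasets for pseudo p-values
#'   (default 100).
#' @param pseudocount added to every cell before forming Dirichlet
#'   posteriors (default 1).
#' @param seed integer seed.
#'
#' @return a `sparcc_params` list.
#' @export
sparcc_params <- function(n_inner_draws = 20, exclusion_threshold = 0.1,
                          max_exclusion_rounds = 10, n_permutations = 100,
                          pseudocount = 1, seed = 1) {
  stopifnot(n_inner_draws >= 1, exclusion_threshold > 0,
            exclusion_threshold < 1, max_exclusion_rounds >= 1,
            n_permutations >= 1, pseudocount > 0)
  structure(as.list(environment()), class = "sparcc_params")
}

#' Log-ratio variation matrix
#'
#' `t[i, j] = Var_samples(log(x_i / x_j))` for a strictly positive fraction
#' matrix. This is the compositionally invariant summary SparCC starts from:
#' renormalizing any sample by a constant cancels in the ratio.
#'
#' @param fractions strictly positive features x samples matrix (columns need
#'   not sum to one; only ratios matter).
#' @return symmetric matrix with zero diagonal and non-negative entries.
#' @export
variation_matrix <- function(fractions) {
  if (any(fractions <= 0))
    stop("fractions must be strictly positive; apply a pseudocount upstream")
  lg <- log(fractions)
  cv <- cov(t(lg))              # feature x feature covariance of log fractions
  v <- diag(cv)
  tmat <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * cv
  tmat[tmat < 0] <- 0           # numerical floor
  diag(tmat) <- 0
  dimnames(tmat) <- list(rownames(fractions), rownames(fractions))
  tmat
}

# Solve the SparCC basis-variance system for a given inclusion pattern.
# include: logical D x D symmetric matrix of pairs still in the system.
.solve_basis <- function(tmat, include) {
  d <- rowSums(include)
  a <- include * 1
  diag(a) <- d
  b <- rowSums(tmat * include)
  omega <- tryCatch(solve(a, b), error = function(e)
    stop("basis-variance system is singular: ", conditionMessage(e)))
  if (any(omega <= 0)) {
    pos <- omega[omega > 0]
    if (!length(pos)) stop("all basis variances non-positive")
    warning("non-positive basis variance replaced by smallest positive value")
    omega[omega <= 0] <- min(pos)
  }
  omega
}

.rho_from_omega <- function(tmat, omega) {
  rho <- (outer(omega, omega, "+") - tmat) /
    (2 * sqrt(outer(omega, omega)))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

#' Approximate basis correlations from a variation matrix
#'
#' Solves `t_i. = (D - 2) * w_i + sum_j w_j` for the basis variances `w`
#' (sparsity approximation), converts to correlations
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` clipped to `[-1, 1]`,
#' then iteratively excludes the strongest correlated pair above
#' `exclusion_threshold` from the system and re-solves, up to
#' `max_exclusion_rounds` times.
#'
#' @param tmat variation matrix from [variation_matrix()].
#' @param exclusion_threshold,max_exclusion_rounds see [sparcc_params()].
#' @return list with `rho` (clipped symmetric correlation matrix), `omega`
#'   (basis variances) and `excluded` (two-column matrix of excluded pairs).
#' @export
basis_correlations <- function(tmat, exclusion_threshold = 0.1,
                               max_exclusion_rounds = 10) {
  d <- nrow(tmat)
  if (d < 4) stop("too few features for SparCC basis solution (need >= 4)")
  include <- matrix(TRUE, d, d)
  diag(include) <- FALSE
  excluded <- matrix(integer(0), 0, 2)
  rho <- NULL
  for (round in seq_len(max_exclusion_rounds + 1L)) {
    omega <- .solve_basis(tmat, include)
    rho <- .rho_from_omega(tmat, omega)
    if (round > max_exclusion_rounds) break
    cand <- abs(rho) * include
    # never disconnect a feature from the system entirely
    cand[rowSums(include) <= 2, ] <- 0
    cand[, colSums(include) <= 2] <- 0
    m <- which.max(cand)
    if (cand[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(cand))
    include[ij[1], ij[2]] <- include[ij[2], ij[1]] <- FALSE
    excluded <- rbind(excluded, sort(ij))
  }
  dimnames(rho) <- dimnames(tmat)
  list(rho = rho, omega = omega, excluded = excluded)
}

# One full SparCC point estimate: median over Dirichlet fraction draws.
.sparcc_rho <- function(counts, params) {
  d <- nrow(counts); n <- ncol(counts)
  alpha <- counts + params$pseudocount
  draws <- array(NA_real_, c(d, d, params$n_inner_draws))
  excluded <- matrix(integer(0), 0, 2)
  for (k in seq_len(params$n_inner_draws)) {
    g <- matrix(rgamma(d * n, shape = alpha), d, n)
    frac <- sweep(g, 2, colSums(g), "/")
    bc <- basis_correlations(variation_matrix(frac),
                             params$exclusion_threshold,
                             params$max_exclusion_rounds)
    draws[, , k] <- bc$rho
    excluded <- rbind(excluded, bc$excluded)
  }
  rho <- apply(draws, c(1, 2), median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  list(rho = rho, excluded = unique(excluded))
}

#' SparCC correlations with permutation pseudo p-values
#'
#' For each inner draw, per-sample fractions are drawn from a pseudocounted
#' Dirichlet posterior, converted to a variation matrix and solved for basis
#' correlations with iterative strongest-pair exclusion; the point estimate
#' is the element-wise median over draws. Pseudo p-values come from
#' `n_permutations` datasets in which every feature row is independently
#' permuted across samples; two-sided
#' `p_ij = (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_permutations + 1)`.
#'
#' @param x a [sample_matrix()] (stacked plants + bacteria) or a bare count
#'   matrix.
#' @param params a [sparcc_params()].
#'
#' @return a `sparcc_result` list: `rho` (symmetric, unit diagonal), `pvals`
#'   (symmetric, diagonal 1), `excluded_pairs`, `domain` (feature tags when
#'   the input was a `sample_matrix`), and `params`.
#' @export
sparcc <- function(x, params = sparcc_params()) {
  counts <- if (inherits(x, "sample_matrix")) x$counts else as.matrix(x)
  domain <- if (inherits(x, "sample_matrix")) x$domain else NULL
  set.seed(params$seed)
  obs <- .sparcc_rho(counts, params)
  n <- ncol(counts)
  exceed <- matrix(0, nrow(counts), nrow(counts))
  for (p in seq_len(params$n_permutations)) {
    perm <- counts
    for (i in seq_len(nrow(perm))) perm[i, ] <- perm[i, sample.int(n)]
    rho_p <- .sparcc_rho(perm, params)$rho
    exceed <- exceed + (abs(rho_p) >= abs(obs$rho))
  }
  pvals <- (1 + exceed) / (params$n_permutations + 1)
  pvals <- (pvals + t(pvals)) / 2
  diag(pvals) <- 1
  dimnames(pvals) <- dimnames(obs$rho)
  structure(list(rho = obs$rho, pvals = pvals,
                 excluded_pairs = obs$excluded, domain = domain,
                 params = params),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat("sparcc_result: ", nrow(x$rho), " features, ",
      x$params$n_inner_draws, " inner draws, ",
      x$params$n_permutations, " permutations\n", sep = "")
  invisible(x)
}

#' Write SparCC correlation and p-value matrices as TSV
#'
#' @param result a `sparcc_result`.
#' @param rho_path,pvals_path output paths (either may be `NULL` to skip).
#' @return invisibly, `result`.
#' @export
write_sparcc <- function(result, rho_path = NULL, pvals_path = NULL) {
  dump1 <- function(m, path) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rho_path)) dump1(result$rho, rho_path)
  if (!is.null(pvals_path)) dump1(result$pvals, pvals_path)
  invisible(result)
}
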