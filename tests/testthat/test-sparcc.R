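# SparCC core: variation matrix, basis solution, exclusion, permutation p.

test_that("variation matrix equals the per-pair log-ratio variance", {
  set.seed(11)
  frac <- matrix(rgamma(12, 2), 3, 4)
  frac <- sweep(frac, 2, colSums(frac), "/")
  tm <- variation_matrix(frac)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(tm[i, j], var(log(frac[i, ] / frac[j, ])),
                 tolerance = 1e-12)
  }
  expect_equal(diag(tm), rep(0, 3), ignore_attr = TRUE)

  # invariance to per-sample renormalization (ratios cancel)
  rescaled <- sweep(frac, 2, runif(4, 0.1, 10), "*")
  expect_equal(variation_matrix(rescaled), tm, tolerance = 1e-12)

  # proportional features have zero log-ratio variance
  frac2 <- rbind(frac, 0.5 * frac[1, ])
  expect_equal(variation_matrix(frac2)[1, 4], 0, tolerance = 1e-12)

  expect_error(variation_matrix(matrix(c(0.5, 0, 0.5, 1), 2, 2)),
               "strictly positive")
})

test_that("basis correlations recover known structure", {
  expect_error(basis_correlations(matrix(0, 3, 3)), "too few features")

  # independent log-normals: off-diagonal correlations near zero
  set.seed(21)
  x <- matrix(rlnorm(50 * 500), 50, 500)
  frac <- sweep(x, 2, colSums(x), "/")
  bc <- basis_correlations(variation_matrix(frac))
  expect_lt(mean(abs(bc$rho[upper.tri(bc$rho)])), 0.05)
  expect_equal(diag(bc$rho), rep(1, 50), ignore_attr = TRUE)
  expect_true(all(abs(bc$rho) <= 1))
  expect_equal(bc$rho, t(bc$rho))

  # planted basis correlation 0.8 between two of 50 features
  set.seed(22)
  sigma <- diag(50); sigma[1, 2] <- sigma[2, 1] <- 0.8
  z <- t(matrix(rnorm(500 * 50), 500, 50) %*% chol(sigma))
  y <- exp(z)
  bc2 <- basis_correlations(variation_matrix(sweep(y, 2, colSums(y), "/")))
  expect_lt(abs(bc2$rho[1, 2] - 0.8), 0.1)

  # perfectly proportional pair pushes rho to 1 after clipping
  y2 <- x; y2[2, ] <- 3 * y2[1, ]
  bc3 <- basis_correlations(variation_matrix(sweep(y2, 2, colSums(y2), "/")))
  expect_equal(bc3$rho[1, 2], 1)
})

test_that("exclusion removes at most max_exclusion_rounds pairs", {
  set.seed(23)
  sigma <- diag(10)
  sigma[1, 2] <- sigma[2, 1] <- 0.9
  sigma[3, 4] <- sigma[4, 3] <- 0.85
  z <- t(matrix(rnorm(300 * 10), 300, 10) %*% chol(sigma))
  y <- exp(z)
  frac <- sweep(y, 2, colSums(y), "/")
  bc <- basis_correlations(variation_matrix(frac),
                           exclusion_threshold = 0.1,
                           max_exclusion_rounds = 3)
  expect_lte(nrow(bc$excluded), 3)
  # a high threshold excludes nothing
  bc2 <- basis_correlations(variation_matrix(frac),
                            exclusion_threshold = 0.99)
  expect_equal(nrow(bc2$excluded), 0)
})

test_that("sparcc is seeded, symmetric and honors the +1 p correction", {
  sim <- simulate_iden(synthetic_config(n_otus = 16, n_plants = 4,
                                        n_plots = 12,
                                        sequencing_depth = 2000, seed = 6))
  st <- stack_domains(sim$plants, sim$bacteria,
                      filter_policy(min_prevalence = 0))
  pr <- fast_sparcc_params(seed = 10)
  r1 <- sparcc(st, pr)
  r2 <- sparcc(st, pr)
  expect_identical(r1$rho, r2$rho)
  expect_identical(r1$pvals, r2$pvals)
  expect_equal(r1$rho, t(r1$rho))
  expect_equal(r1$pvals, t(r1$pvals))
  expect_true(all(abs(r1$rho) <= 1))
  off <- r1$pvals[upper.tri(r1$pvals)]
  expect_gte(min(off), 1 / (pr$n_permutations + 1))
  expect_lte(max(off), 1)
})

test_that("estimates are compositionally stable when a sample is rescaled", {
  sim <- simulate_iden(synthetic_config(n_otus = 16, n_plants = 4,
                                        n_plots = 12,
                                        sequencing_depth = 2000, seed = 9))
  st <- stack_domains(sim$plants, sim$bacteria,
                      filter_policy(min_prevalence = 0))
  pr <- sparcc_params(n_inner_draws = 40, n_permutations = 1, seed = 3)
  base <- sparcc(st, pr)$rho
  scaled_counts <- st$counts
  scaled_counts[, 1] <- scaled_counts[, 1] * 10
  scaled <- sample_matrix(scaled_counts, st$domain, lineage = st$lineage)
  resc <- sparcc(scaled, pr)$rho
  # identical up to Dirichlet posterior noise at the rescaled counts
  expect_lt(max(abs(base - resc)), 0.25)
  expect_lt(mean(abs(base - resc)), 0.05)
})
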