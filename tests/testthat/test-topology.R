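# Topology panel: closed forms, NODF, C-score, d', clustering, all checked
# against independent brute-force oracles.

test_that("closed-form size metrics behave at the boundaries", {
  expect_equal(connectance(2, 2, 4), 1)
  expect_equal(web_asymmetry(5, 5), 0)
  expect_equal(links_per_species(1, 1, 1), 0.5)
  expect_error(connectance(2, 2, 5), "more links")
})

test_that("NODF is exact on staircases, identity and random matrices", {
  expect_equal(nodf(staircase_matrix(4)), 100)
  expect_equal(nodf(staircase_matrix(7)), 100)
  expect_equal(nodf(diag(5)), 0)

  # brute-force pairwise-overlap oracle on random matrices, plus the
  # independently implemented reference estimator
  nodf_oracle <- function(a) {
    vals <- c()
    for (m in list(a, t(a))) {
      n <- nrow(m)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        fi <- sum(m[i, ]); fj <- sum(m[j, ])
        if (fi == fj || min(fi, fj) == 0) { vals <- c(vals, 0); next }
        lo <- if (fi > fj) m[j, ] else m[i, ]
        hi <- if (fi > fj) m[i, ] else m[j, ]
        vals <- c(vals, 100 * sum(lo == 1 & hi == 1) / sum(lo))
      }
    }
    mean(vals)
  }
  for (s in 1:5) {
    a <- random_incidence(6, 8, 0.45, seed = s)
    expect_equal(nodf(a), nodf_oracle(a), tolerance = 1e-12)
    expect_equal(nodf(a),
                 unname(vegan::nestednodf(a)$statistic["NODF"]),
                 tolerance = 1e-9)
    # invariance to row/column permutation
    set.seed(s)
    expect_equal(nodf(a[sample(6), sample(8)]), nodf(a), tolerance = 1e-12)
  }
})

test_that("weighted NODF matches the reference estimator on random webs", {
  for (s in 1:5) {
    set.seed(100 + s)
    w <- matrix(rpois(48, 2), 6, 8)
    expect_equal(weighted_nodf(w) * 100,
                 unname(vegan::nestednodf(w, weighted = TRUE)$statistic["NODF"]),
                 tolerance = 1e-9)
  }
})

test_that("filling in a subset relation never decreases NODF", {
  a <- staircase_matrix(5)
  a[2, 4] <- 0  # row 2 now a proper subset of row 1 with a gap
  base <- nodf(a)
  a2 <- a; a2[2, 4] <- 1
  expect_gte(nodf(a2), base)
})

test_that("C-score equals the exhaustive pair oracle", {
  # identical partner sets: zero checkerboarding
  a <- rbind(c(1, 1, 0), c(1, 1, 0))
  expect_equal(cscore(a, "plants"), 0)
  # perfect checkerboard pair
  b <- rbind(c(1, 0), c(0, 1))
  expect_equal(cscore(b, "plants"), 1)

  cscore_oracle <- function(m) {
    pairs <- combn(nrow(m), 2)
    mean(apply(pairs, 2, function(ij) {
      s <- sum(m[ij[1], ] == 1 & m[ij[2], ] == 1)
      (sum(m[ij[1], ]) - s) * (sum(m[ij[2], ]) - s)
    }))
  }
  for (s in 1:5) {
    a <- random_incidence(5, 9, 0.4, seed = 10 + s)
    expect_equal(cscore(a, "plants"), cscore_oracle(a), tolerance = 1e-12)
    expect_equal(cscore(a, "otus"), cscore_oracle(t(a)), tolerance = 1e-12)
  }
  expect_error(cscore(matrix(1, 1, 3), "plants"), "at least 2")

  # fully nested matrix with shared minima: generalists cover specialists
  nested <- staircase_matrix(4)
  expect_equal(cscore(nested, "plants"), 0)
})

test_that("d' follows the Kullback-Leibler oracle and its limits", {
  # partner use proportional to availability: d' = 0
  w <- rbind(c(4, 2, 2), c(8, 4, 4))
  sp <- dprime_specialization(w)
  expect_equal(unname(sp$d_plants), c(0, 0), tolerance = 1e-12)

  # single exclusive partner in a large web: d' = 1
  w2 <- rbind(c(10, 0, 0, 0), c(0, 5, 5, 5), c(0, 5, 5, 5))
  expect_equal(unname(dprime_specialization(w2)$d_plants[1]), 1,
               tolerance = 1e-12)

  # hand-computed KL oracle on a 3 x 4 web
  set.seed(51)
  w3 <- matrix(rpois(12, 3) + 1, 3, 4)
  sp3 <- dprime_specialization(w3)
  q <- colSums(w3) / sum(w3)
  for (i in 1:3) {
    p <- w3[i, ] / sum(w3[i, ])
    d <- sum(p * log(p / q))
    dmax <- log(sum(w3) / sum(w3[i, ]))
    expect_equal(unname(sp3$d_plants[i]), min(1, max(0, d / dmax)),
                 tolerance = 1e-12)
  }
  # asymmetry sign convention: OTU level minus plant level
  expect_equal(sp3$sa,
               (mean(sp3$d_otus) - mean(sp3$d_plants)) /
                 (mean(sp3$d_otus) + mean(sp3$d_plants)),
               tolerance = 1e-12)
})

test_that("clustering matches a triangle-counting oracle on projections", {
  # complete bipartite: both projections complete
  expect_equal(cluster_coefficient(matrix(1, 3, 4)), 1)
  # star: single plant, OTU projection complete, plant side undefined
  expect_equal(cluster_coefficient(matrix(1, 1, 5)), 1)

  cc_oracle <- function(a) {
    vals <- c()
    for (adj in list(a %*% t(a), t(a) %*% a)) {
      adj <- (adj > 0) * 1; diag(adj) <- 0
      for (i in seq_len(nrow(adj))) {
        nb <- which(adj[i, ] == 1)
        if (length(nb) < 2) next
        links <- sum(adj[nb, nb]) / 2
        vals <- c(vals, links / choose(length(nb), 2))
      }
    }
    if (!length(vals)) NaN else mean(vals)
  }
  for (s in 1:5) {
    a <- random_incidence(4, 6, 0.45, seed = 20 + s)
    expect_equal(cluster_coefficient(a), cc_oracle(a), tolerance = 1e-12)
  }
})

test_that("the topology report assembles the full panel coherently", {
  net <- as_iden_network(random_incidence(5, 12, 0.35, seed = 9))
  rep <- topology_report(net)
  expect_equal(rep$links, sum(net$incidence))
  expect_equal(rep$connectance,
               connectance(rep$n_plants, rep$n_microbes, rep$links))
  expect_true(rep$connectance >= 0 && rep$connectance <= 1)
  expect_true(rep$web_asymmetry >= -1 && rep$web_asymmetry <= 1)
  expect_true(rep$nestedness_nodf >= 0 && rep$nestedness_nodf <= 100)
  expect_true(rep$weighted_nestedness >= 0 && rep$weighted_nestedness <= 1)
  expect_gt(rep$links_per_species, 0)
})
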