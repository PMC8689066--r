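# Barber modularity, simulated annealing, Zi-Pi roles, module composition.

test_that("Barber modularity matches closed forms and a direct oracle", {
  blocks <- block_network(2, 5, 2)
  expect_equal(barber_modularity(blocks$a, blocks$row_modules,
                                 blocks$col_modules), 0.5)

  q_oracle <- function(a, gr, gc) {
    l <- sum(a); k <- rowSums(a); d <- colSums(a)
    tot <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
      if (gr[i] == gc[j]) tot <- tot + a[i, j] - k[i] * d[j] / l
    tot / l
  }
  for (s in 1:3) {
    a <- random_incidence(4, 7, 0.4, seed = 30 + s)
    gr <- sample(1:3, 4, replace = TRUE)
    gc <- sample(1:3, 7, replace = TRUE)
    expect_equal(barber_modularity(a, gr, gc), q_oracle(a, gr, gc),
                 tolerance = 1e-12)
    # trivial one-module partition scores its configuration expectation
    expect_equal(barber_modularity(a, rep(1, 4), rep(1, 7)),
                 q_oracle(a, rep(1, 4), rep(1, 7)), tolerance = 1e-12)
  }
  expect_error(barber_modularity(matrix(0, 2, 2), 1:2, 1:2), "empty")
})

test_that("a planted partition scores above a random one", {
  blocks <- block_network(2, 10, 4)
  set.seed(61)
  q_planted <- barber_modularity(blocks$a, blocks$row_modules,
                                 blocks$col_modules)
  q_random <- barber_modularity(blocks$a,
                                sample(blocks$row_modules),
                                sample(4, 40, replace = TRUE))
  expect_gt(q_planted, q_random)
})

test_that("annealing recovers planted blocks exactly and deterministically", {
  blocks <- block_network(2, 10, 4)  # 8 plants, 40 OTUs, 4 disjoint blocks
  p1 <- anneal_modules(blocks$a, seed = 5)
  expect_equal(p1$n_modules, 4)
  expect_equal(partition_nmi(p1$module_of, blocks$truth), 1)
  q_planted <- barber_modularity(blocks$a, blocks$row_modules,
                                 blocks$col_modules)
  expect_gte(p1$Q, q_planted - 1e-9)
  # never below the single-module baseline
  expect_gte(p1$Q, barber_modularity(blocks$a, rep(1, 8), rep(1, 40)))

  p2 <- anneal_modules(blocks$a, seed = 5)
  expect_identical(p1$module_of, p2$module_of)
  expect_equal(p1$Q, p2$Q)
})

test_that("Zi is standardized within module-level groups and Pi bounded", {
  blocks <- block_network(3, 8, 3)
  a <- blocks$a
  a[1, 9:10] <- 1  # give one plant cross-module links
  net <- as_iden_network(a)
  part <- anneal_modules(net, seed = 7)
  roles <- zi_pi(net, part)
  expect_true(all(roles$pi >= 0 & roles$pi < 1))
  grp <- paste(roles$module, roles$domain)
  for (g in unique(grp)) {
    zi <- roles$zi[grp == g]
    if (length(zi) > 1 && sd(zi) > 0) {
      expect_equal(mean(zi), 0, tolerance = 1e-9)
      expect_equal(sd(zi), 1, tolerance = 1e-9)
    }
  }
  # all links inside the own module means Pi = 0
  pure <- zi_pi(as_iden_network(blocks$a),
                anneal_modules(blocks$a, seed = 1))
  expect_true(all(pure$pi == 0))
})

test_that("role thresholds tile the (Zi, Pi) plane and match printed calls", {
  expect_equal(classify_role(12.89, 0.67), "network hub")
  expect_equal(classify_role(1.63, 0.42), "peripheral")
  grid <- expand.grid(zi = seq(-2, 6, by = 0.5), pi = seq(0, 0.99, by = 0.06))
  roles <- classify_role(grid$zi, grid$pi)
  expect_true(all(roles %in% c("peripheral", "connector", "module hub",
                               "network hub")))
  expect_identical(roles == "network hub",
                   grid$zi > 2.5 & grid$pi > 0.62)
  expect_identical(roles == "module hub",
                   grid$zi > 2.5 & grid$pi <= 0.62)
  expect_identical(roles == "connector",
                   grid$zi <= 2.5 & grid$pi > 0.62)
})

test_that("module composition books phyla, plants and exclusivity", {
  blocks <- block_network(1, 3, 2)
  net <- as_iden_network(blocks$a)
  lineage <- setNames(paste0("k__B;p__", c("X", "X", "Y", "Y", "Z", "Z")),
                      colnames(blocks$a))
  part <- list(module_of = blocks$truth)
  comp <- module_composition(net, blocks$truth, lineage)
  m1 <- comp$phylum_counts[comp$phylum_counts$module == 1, ]
  expect_equal(sort(m1$phylum), c("X", "Y"))
  expect_equal(m1$n_otus[m1$phylum == "X"], 2)
  expect_equal(m1$n_otus[m1$phylum == "Y"], 1)
  # X occurs only in module 1, Z only in module 2
  expect_true(all(comp$phylum_counts$exclusive[
    comp$phylum_counts$phylum %in% c("X", "Z")]))
  expect_false(any(comp$phylum_counts$exclusive[
    comp$phylum_counts$phylum == "Y"]))
  # plants per module sum to P
  expect_equal(nrow(comp$plants), nrow(blocks$a))
})

test_that("NMI is 1 for relabelings and low for unrelated partitions", {
  truth <- rep(1:4, each = 10)
  relab <- c(4, 3, 2, 1)[truth]
  expect_equal(partition_nmi(truth, relab), 1)
  set.seed(77)
  indep <- sample(1:4, 40, replace = TRUE)
  expect_lt(partition_nmi(truth, indep), 0.5)
})
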