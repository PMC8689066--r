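# Reading, validation, rarefaction and domain stacking.

write_otu_fixture <- function(counts, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  otu <- file.path(dir, "otu.tsv")
  tax <- file.path(dir, "tax.tsv")
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, otu, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(otu_id = rownames(counts),
                         lineage = paste0("k__B;p__P", seq_len(nrow(counts)))),
              tax, sep = "\t", quote = FALSE, row.names = FALSE)
  list(otu = otu, tax = tax)
}

test_that("OTU tables read back exactly with lineages attached", {
  counts <- matrix(c(5, 0, 1, 2, 0, 7), 3, 2, byrow = TRUE,
                   dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
  f <- write_otu_fixture(counts)
  sm <- read_otu_table(f$otu, f$tax)
  expect_equal(unname(sm$counts), unname(counts))
  expect_equal(colnames(sm$counts), c("s1", "s2"))
  expect_length(sm$lineage, 3)
  expect_true(all(sm$domain == "bacteria"))

  # round trip of a larger synthetic table
  big <- simulate_iden(synthetic_config(n_otus = 50, n_plots = 17,
                                        sequencing_depth = 500,
                                        seed = 3))$bacteria
  dir <- withr::local_tempdir()
  write_count_table(big, file.path(dir, "o.tsv"),
                    taxonomy_path = file.path(dir, "t.tsv"),
                    id_column = "otu_id")
  back <- read_otu_table(file.path(dir, "o.tsv"), file.path(dir, "t.tsv"))
  expect_equal(back$counts, big$counts)
  expect_equal(back$lineage, big$lineage)
})

test_that("malformed OTU input is rejected with a located error", {
  dir <- withr::local_tempdir()
  writeLines(c("otu_id\ts1\ts2", "OTU_1\t5\t0", "OTU_1\t1\t2"),
             file.path(dir, "dup.tsv"))
  writeLines(c("otu_id\tlineage", "OTU_1\tk__B;p__P"),
             file.path(dir, "tax.tsv"))
  expect_error(read_otu_table(file.path(dir, "dup.tsv"),
                              file.path(dir, "tax.tsv")),
               "OTU_1")
  writeLines(c("otu_id\ts1\ts2", "OTU_1\t5\t0", "OTU_2\t1\t2.5"),
             file.path(dir, "frac.tsv"))
  writeLines(c("otu_id\tlineage", "OTU_1\tk__B", "OTU_2\tk__B"),
             file.path(dir, "tax2.tsv"))
  expect_error(read_otu_table(file.path(dir, "frac.tsv"),
                              file.path(dir, "tax2.tsv")),
               "OTU_2.*s2")
  # OTU missing from taxonomy names the offender
  writeLines(c("otu_id\ts1\ts2", "OTU_1\t5\t0", "OTU_2\t1\t2"),
             file.path(dir, "ok.tsv"))
  expect_error(read_otu_table(file.path(dir, "ok.tsv"),
                              file.path(dir, "tax.tsv")),
               "OTU_2")
})

test_that("plant surveys pivot to species x plot matrices", {
  dir <- withr::local_tempdir()
  writeLines(c("plot\tspecies\tcount", "p1\tA\t3", "p1\tB\t1", "p2\tA\t0"),
             file.path(dir, "sv.tsv"))
  sm <- read_plant_survey(file.path(dir, "sv.tsv"))
  expect_equal(unname(sm$counts),
               matrix(c(3, 1, 0, 0), 2, 2), ignore_attr = TRUE)
  expect_equal(rownames(sm$counts), c("A", "B"))
  expect_equal(colnames(sm$counts), c("p1", "p2"))
  expect_true(all(sm$domain == "plant"))

  # duplicates are summed with a warning
  writeLines(c("plot\tspecies\tcount", "p1\tA\t3", "p1\tA\t2"),
             file.path(dir, "dup.tsv"))
  expect_warning(sm2 <- read_plant_survey(file.path(dir, "dup.tsv")),
                 "summed")
  expect_equal(unname(sm2$counts[1, 1]), 5)

  # negative counts and unknown plots are hard errors
  writeLines(c("plot\tspecies\tcount", "p1\tA\t-3"),
             file.path(dir, "neg.tsv"))
  expect_error(read_plant_survey(file.path(dir, "neg.tsv")), "negative")
  writeLines(c("plot\tspecies\tcount", "p9\tA\t3"),
             file.path(dir, "orphan.tsv"))
  expect_error(read_plant_survey(file.path(dir, "orphan.tsv"),
                                 site_of_sample = c(p1 = "KNS")),
               "p9")
})

test_that("rarefaction hits the target depth exactly and reproducibly", {
  b <- toy_bacteria(n_otus = 10, n_plots = 4, depth = 4000, seed = 5)
  r <- rarefy(b, depth = 1000, seed = 9)
  expect_true(all(colSums(r$counts) == 1000))
  expect_true(all(r$counts <= b$counts))
  r2 <- rarefy(b, depth = 1000, seed = 9)
  expect_identical(r$counts, r2$counts)

  # depth equal to a column total returns that column unchanged
  tot <- colSums(b$counts)[1]
  r3 <- rarefy(b, depth = tot, seed = 1)
  expect_equal(r3$counts[, 1], b$counts[, 1])

  # shallow samples are dropped with a warning; all-shallow is an error
  shallow <- b
  shallow$counts[, 2] <- 0
  shallow <- sample_matrix(shallow$counts, "bacteria", lineage = b$lineage)
  expect_warning(r4 <- rarefy(shallow, depth = 1000, seed = 1), "plot_02")
  expect_equal(ncol(r4$counts), 3)
  expect_error(rarefy(b, depth = 1e7, seed = 1), "no samples survive")
})

test_that("stacking intersects plots and applies the prevalence filter", {
  set.seed(31)
  n_otus <- 40; n_plots <- 17
  counts <- matrix(rbinom(n_otus * n_plots, 1, 0.5) *
                     rpois(n_otus * n_plots, 50),
                   n_otus, n_plots,
                   dimnames = list(sprintf("OTU_%04d", 1:n_otus),
                                   sprintf("plot_%02d", 1:n_plots)))
  b <- sample_matrix(counts, "bacteria",
                     lineage = setNames(rep("k__B;p__P", n_otus),
                                        rownames(counts)))
  p <- toy_plants(n_plants = 4, n_plots = n_plots)
  colnames(p$counts) <- colnames(counts)

  st <- stack_domains(p, b, filter_policy(min_prevalence = 0.5))
  survivors <- sum(rowMeans(counts > 0) >= 0.5)  # brute-force occupancy
  expect_equal(nrow(st$counts), 4 + survivors)
  expect_equal(st$domain[1:4], setNames(rep("plant", 4), rownames(p$counts)))
  expect_equal(rownames(st$counts)[1:4], rownames(p$counts))

  # prevalence 0 keeps everything
  st0 <- stack_domains(p, b, filter_policy(min_prevalence = 0))
  expect_equal(nrow(st0$counts), 4 + n_otus)

  # disjoint plot ids fail
  p2 <- p
  colnames(p2$counts) <- paste0("x", seq_len(n_plots))
  p2 <- sample_matrix(p2$counts, "plant")
  expect_error(stack_domains(p2, b, filter_policy()), "no shared plot ids")
})
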