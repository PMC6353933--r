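test_that("reading a long-format table assembles one dataset per pair", {
  set.seed(101)
  pairs <- list(make_random_pair(39, pair_id = "A"),
                make_random_pair(39, pair_id = "B", level = "phylum"))
  paths <- write_fixture_tables(pairs)
  coll <- read_abundance_table(paths$table, paths$manifest)
  expect_length(coll, 2)
  expect_equal(names(coll), c("A", "B"))
  expect_equal(coll$A$n_sites, 39)
  expect_equal(coll$B$level, "phylum")
  expect_identical(coll$A$host_abundance, pairs[[1]]$host_abundance)
  expect_identical(coll$B$virus_abundance, pairs[[2]]$virus_abundance)
})

test_that("malformed tables are rejected with informative errors", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_tables(list(make_random_pair(5, pair_id = "A")),
                                dir)
  # missing column
  tab <- read.delim(paths$table)
  write.table(tab[-3], file.path(dir, "bad.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_abundance_table(file.path(dir, "bad.tsv"),
                                    paths$manifest),
               "missing column.*host_abundance")
  # negative abundance, reported with its row number
  tab2 <- tab
  tab2$host_abundance[3] <- -0.1
  write.table(tab2, file.path(dir, "neg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_abundance_table(file.path(dir, "neg.tsv"),
                                    paths$manifest),
               "negative host_abundance at row 3")
  # pair missing from manifest
  man <- read.delim(paths$manifest)
  man$pair_id <- "other"
  write.table(man, file.path(dir, "man2.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_abundance_table(paths$table, file.path(dir, "man2.tsv")),
               "absent from manifest: A")
  # unknown level is a closed-enum violation
  man$pair_id <- "A"
  man$level <- "order"
  write.table(man, file.path(dir, "man3.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_abundance_table(paths$table, file.path(dir, "man3.tsv")),
               "unknown level")
  # an empty table is a valid empty collection
  write.table(tab[0, ], file.path(dir, "empty.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_length(read_abundance_table(file.path(dir, "empty.tsv"),
                                     paths$manifest), 0)
})

test_that("zero-site filtering drops exactly the sites with a zero in either vector", {
  host <- c(rep(1, 32), rep(0, 2), rep(1, 5))
  virus <- c(rep(2, 32), rep(1, 2), rep(0, 5))
  d <- abundance_pair("mix", host, virus)
  res <- filter_zero_sites(d)
  expect_equal(res$dataset$n_sites, 32)
  expect_equal(res$report$n_sites_raw, 39)
  expect_equal(res$report$n_sites_zero_dropped, 7)
  expect_true(res$report$retained)

  # all-positive input is untouched; all-zero-virus input empties out
  set.seed(7)
  clean <- make_random_pair(10)
  res2 <- filter_zero_sites(clean)
  expect_identical(res2$dataset, clean)
  expect_equal(res2$report$n_sites_zero_dropped, 0)
  gone <- abundance_pair("gone", rep(1, 6), rep(0, 6))
  res3 <- filter_zero_sites(gone)
  expect_equal(res3$dataset$n_sites, 0)
  expect_false(res3$report$retained)
})

test_that("filtering is idempotent, order-preserving and count-consistent", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    d <- make_random_pair(n, pair_id = paste0("p", i))
    mask_h <- runif(n) < 0.2
    mask_v <- runif(n) < 0.2
    d$host_abundance[mask_h] <- 0
    d$virus_abundance[mask_v] <- 0
    once <- filter_zero_sites(d)
    twice <- filter_zero_sites(once$dataset)
    expect_identical(twice$dataset, once$dataset)
    expect_equal(twice$report$n_sites_zero_dropped, 0)
    # retained values are bitwise-identical to the kept originals
    keep <- !mask_h & !mask_v
    expect_identical(once$dataset$host_abundance, d$host_abundance[keep])
    expect_identical(once$dataset$virus_abundance, d$virus_abundance[keep])
    expect_equal(once$report$n_sites_kept + once$report$n_sites_zero_dropped,
                 once$report$n_sites_raw)
  }
})

test_that("minimum-site rule retains at 5 and excludes at 4, floor is 2", {
  pos5 <- make_random_pair(5)
  pos4 <- make_random_pair(4)
  pos39 <- make_random_pair(39)
  expect_true(apply_min_sites(pos5, 5)$retained)
  expect_false(apply_min_sites(pos4, 5)$retained)
  expect_true(apply_min_sites(pos39, 5)$retained)
  expect_error(apply_min_sites(pos5, 1), "min_sites")
  # dirty input must be zero-filtered first
  dirty <- abundance_pair("z", c(1, 0, 2), c(1, 1, 1))
  expect_error(apply_min_sites(dirty), "filter_zero_sites")
})

test_that("partition by level is a disjoint cover and rejects unknown levels", {
  set.seed(11)
  coll <- c(lapply(1:6, function(i)
              make_random_pair(6, pair_id = paste0("g", i))),
            lapply(1:3, function(i)
              make_random_pair(6, pair_id = paste0("f", i),
                               level = "phylum")))
  parts <- partition_by_level(coll)
  expect_length(parts$genus, 6)
  expect_length(parts$phylum, 3)
  bad <- coll[[1]]
  bad$level <- "order"
  expect_error(partition_by_level(c(coll, list(bad))), "unknown level")
})

test_that("write/read round-trip reproduces abundances to full precision", {
  set.seed(202)
  coll <- lapply(1:3, function(i)
    make_random_pair(12, pair_id = paste0("p", i)))
  names(coll) <- paste0("p", 1:3)
  dir <- withr::local_tempdir()
  write_abundance_table(coll, file.path(dir, "t.tsv"),
                        file.path(dir, "m.tsv"))
  back <- read_abundance_table(file.path(dir, "t.tsv"),
                               file.path(dir, "m.tsv"))
  for (id in names(coll)) {
    expect_identical(back[[id]]$host_abundance, coll[[id]]$host_abundance)
    expect_identical(back[[id]]$virus_abundance, coll[[id]]$virus_abundance)
  }
})
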