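test_that("count table TSV round-trips exactly and writes are byte-stable", {
  tab <- make_table(matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3),
                    phylum = c("Firmicutes", "Bacteroidetes", "unclassified"),
                    genus = c("Blautia", "Prevotella", "unclassified"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, f1)
  back <- read_count_table(f1)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$lineage, tab$lineage)
  write_count_table(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # 500-taxon random table round-trip (property over a generated fixture)
  big <- random_table(500, 7, seed = 42)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(big, f3)
  big2 <- read_count_table(f3)
  expect_identical(big2$counts, big$counts)
  expect_identical(big2$lineage, big$lineage)
})

test_that("reader rejects malformed input, naming the offender", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tlineage\tS1\tS2",
               "t1\tp__X\t5\t2",
               "t2\tp__X\t-1\t3"), f)
  expect_error(read_count_table(f), "t2.*S1")

  writeLines(c("taxon_id\tlineage\tS1\tS1",
               "t1\tp__X\t5\t2"), f)
  expect_error(read_count_table(f), "duplicate sample id")

  writeLines(c("taxon_id\tlineage\tS1",
               "t1\tp__X\t1.5"), f)
  expect_error(read_count_table(f), "non-integer")
})

test_that("reader tolerates CRLF, parses lineage dialect, handles empty taxa", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tlineage\tS1\r",
               "t1\tp__Firmicutes;g__Blautia\t4\r",
               "t2\tbadformat\t1\r"), f, sep = "\n")
  tab <- read_count_table(f)
  expect_equal(tab$lineage$phylum, c("Firmicutes", "unclassified"))
  expect_equal(tab$lineage$family, c("unclassified", "unclassified"))
  expect_equal(tab$lineage$genus, c("Blautia", "unclassified"))

  empty <- count_table(matrix(integer(0), nrow = 0, ncol = 2,
                              dimnames = list(NULL, c("S1", "S2"))))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(empty, f2)
  expect_equal(n_taxa(read_count_table(f2)), 0)
  expect_equal(sample_ids(read_count_table(f2)), c("S1", "S2"))
})

test_that("read-count filter applies a strict 'under' rule at the boundary", {
  m <- matrix(0L, nrow = 1, ncol = 5,
              dimnames = list("t1", paste0("S", 1:5)))
  m[1, ] <- c(5000L, 10000L, 15000L, 9999L, 1000000L)
  tab <- make_table(m)
  out <- filter_min_reads(tab)
  expect_equal(sample_ids(out), c("S2", "S3", "S5"))
  expect_equal(attr(out, "dropped_samples"), c("S1", "S4"))
  expect_equal(n_taxa(out), 1)
})

test_that("rarity filter uses a strict dataset-wide threshold", {
  # grand total 1,000,000; threshold 1e-5 corresponds to 10 reads
  m <- matrix(c(999900L, 50L, 40L, 10L), ncol = 1,
              dimnames = list(paste0("t", 1:4), "S1"))
  tab <- make_table(m)
  out <- filter_min_relative_abundance(tab)
  expect_equal(taxon_ids(out), paste0("t", 1:4))  # the 10-read taxon sits at the boundary
  m[4, 1] <- 9L
  out2 <- filter_min_relative_abundance(make_table(m))
  expect_equal(attr(out2, "dropped_taxa"), "t4")

  single <- make_table(matrix(3L, dimnames = list("only", "S1")))
  expect_equal(n_taxa(filter_min_relative_abundance(single)), 1)
  zero <- make_table(matrix(0L, dimnames = list("t", "S1")))
  expect_error(filter_min_relative_abundance(zero), "grand total")
})

test_that("filter order matters and the default is rarity-then-depth", {
  # one sample is pushed below 10k only after the rare taxon is removed
  m <- matrix(c(9995L, 3000000L,
                6L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("common", "rare"), c("S1", "S2")))
  tab <- make_table(m)
  # rare taxon total 6 / grand 3010001 < 1e-5 -> dropped first, S1 falls to 9995
  a <- filter_min_reads(filter_min_relative_abundance(tab))
  expect_equal(sample_ids(a), "S2")
  # opposite order keeps S1 (10001 reads) before the taxon filter
  b <- filter_min_relative_abundance(filter_min_reads(tab))
  expect_equal(sample_ids(b), c("S1", "S2"))
})

test_that("aggregation sums within rank labels and conserves column totals", {
  m <- matrix(c(3L, 1L, 4L, 1L, 5L, 9L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  tab <- make_table(m, genus = c("g1", "g1", "g2"))
  agg <- aggregate_taxa(tab, "genus")
  expect_equal(taxon_ids(agg), c("g1", "g2"))
  expect_equal(unname(agg$counts["g1", ]), c(3L + 1L, 1L + 5L))
  expect_identical(colSums(agg$counts), colSums(tab$counts))

  # conservation over random tables
  for (seed in 1:5) {
    rt <- random_table(60, 8, seed = seed)
    for (rank in c("phylum", "family", "genus")) {
      expect_identical(colSums(aggregate_taxa(rt, rank)$counts),
                       colSums(rt$counts))
    }
  }

  # degenerate: all genera unclassified -> one bucket
  allu <- make_table(m)
  expect_equal(n_taxa(aggregate_taxa(allu, "genus")), 1)
  expect_error(aggregate_taxa(tab, "species"))
})

test_that("to_relative normalizes every column to 1 and names zero columns", {
  tab <- make_table(matrix(c(6L, 2L, 2L), ncol = 1,
                           dimnames = list(paste0("t", 1:3), "S1")))
  expect_equal(unname(to_relative(tab)[, 1]), c(0.6, 0.2, 0.2))
  rt <- random_table(40, 6, seed = 3)
  expect_true(all(abs(colSums(to_relative(rt)) - 1) < 1e-12))
  zero <- make_table(matrix(c(1L, 0L), nrow = 1,
                            dimnames = list("t", c("A", "B"))))
  expect_error(to_relative(zero), "B")
})

test_that("metadata validation enforces enums and donor invariants", {
  tab <- random_table(5, 2, seed = 1)
  meta <- simple_meta(tab)
  expect_silent(validate_metadata(meta))
  bad <- meta; bad$arm[1] <- "treatment"
  expect_error(validate_metadata(bad), "invalid arm")
  bad2 <- meta; bad2$arm[1] <- "donor"; bad2$relapse_week[1] <- 4L
  expect_error(validate_metadata(bad2), "donor")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, f)
  back <- read_sample_metadata(f)
  expect_equal(back$sample_id, meta$sample_id)
  expect_true(all(is.na(back$relapse_week)))
  expect_error(check_table_metadata(tab, meta[-1, ]), "no metadata row")
})
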