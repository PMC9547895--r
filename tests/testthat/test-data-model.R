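test_that("lineage strings parse in both dialects and resolve ranks", {
  tx <- parse_taxon_labels(c(
    "p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__fragilis",
    "k__Bacteria|p__Firmicutes|g__Blautia|s__unclassified",
    "p__Firmicutes;f__Clostridiaceae;g__unclassified"))
  expect_equal(tx$resolution_rank, c("species", "genus", "family"))
  expect_equal(tx$species[1], "fragilis")
  expect_equal(tx$genus[2], "Blautia")
  expect_true(is.na(tx$species[2]))
  expect_error(parse_taxon_labels("Bacteroides"), "prefix")
})

test_that("TSV round trip preserves counts, sample order and lineages", {
  tbl <- make_table(matrix(c(5L, 0L, 2L, 7L, 1L, 9L), 3, 2),
                    labels = c("p__Bacteroidetes;g__Bacteroides;s__dorei",
                               "p__Firmicutes;g__Blautia;s__unclassified"))
  expect_equal(dim(tbl), c(3L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tbl, path)
  back <- read_abundance_table(path)
  expect_identical(back$counts, tbl$counts)
  expect_identical(back$taxa$label, tbl$taxa$label)
  expect_identical(back$taxa$resolution_rank, tbl$taxa$resolution_rank)
})

test_that("malformed tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2", "p__F;g__G1\t1.5\t2", "p__F;g__G2\t3\t4"), path)
  expect_error(read_abundance_table(path), "integer")
  writeLines(c("lineage\ts1", "p__F;g__G1\t1"), path)
  expect_error(read_abundance_table(path), "taxon")
  writeLines(c("taxon\ts1\ts1", "p__F;g__G1\t1\t2"), path)
  expect_error(read_abundance_table(path), "duplicate")
  expect_error(abundance_table(matrix(-1L, 1, 1,
                                      dimnames = list("a", NULL)),
                               "p__F;g__G1"),
               "non-negative")
})

test_that("BIOM tables read back with identical counts", {
  tbl <- make_table(matrix(c(5L, 0L, 2L, 7L, 1L, 9L), 3, 2))
  b <- biomformat::make_biom(t(tbl$counts))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  back <- read_abundance_table(path, format = "biom")
  expect_equal(unname(back$counts), unname(tbl$counts))
})

test_that("depth filter uses a strict threshold and preserves counts", {
  tbl <- make_table(rbind(c(1500L, 1500L), c(1501L, 1500L)))
  kept <- filter_samples_by_depth(tbl, 3000)
  expect_equal(sample_ids(kept), "s2")   # sum 3001 kept, 3000 dropped
  expect_identical(kept$counts[1, ], tbl$counts[2, ])

  tbl2 <- make_table(rbind(c(5L, 5L), c(15L, 5L), c(20L, 10L)))
  expect_equal(nrow(filter_samples_by_depth(tbl2, 15)$counts), 2L)
  expect_identical(filter_samples_by_depth(tbl2, 0)$counts, tbl2$counts)
  expect_error(filter_samples_by_depth(tbl2, 1e6), "removed all")
})

test_that("rare-taxa filter honours the >20-reads-in-<20-samples rule", {
  # taxon 1: 21 reads in 20 samples (retained); taxon 2: 21 reads in 19
  # samples (removed); taxon 3: all zero except depth padding (removed)
  n <- 22
  counts <- cbind(c(rep(21L, 20), 0L, 0L),
                  c(rep(21L, 19), 0L, 0L, 0L),
                  rep(0L, n))
  counts <- cbind(counts, rep(100L, n))  # anchor taxon keeps rows non-empty
  tbl <- make_table(counts)
  kept <- filter_rare_taxa(tbl, count_thr = 20, sample_thr = 20)
  expect_equal(ncol(kept$counts), 2L)
  expect_true(tbl$taxa$label[1] %in% kept$taxa$label)
  expect_false(tbl$taxa$label[2] %in% kept$taxa$label)
  expect_false(tbl$taxa$label[3] %in% kept$taxa$label)
})

test_that("rare-taxa filter is idempotent", {
  set.seed(42)
  tbl <- make_table(matrix(rpois(200, 15), 20, 10))
  once <- filter_rare_taxa(tbl, count_thr = 10, sample_thr = 5)
  twice <- filter_rare_taxa(once, count_thr = 10, sample_thr = 5)
  expect_identical(once$counts, twice$counts)
})

test_that("study design invariants are enforced", {
  expect_error(study_design("a1", "sub1", "HFD", "after"),
               "no baseline")
  expect_error(study_design(c("a1", "a2"), c("sub1", "sub1"), "HFD",
                            c("baseline", "baseline")),
               "duplicate")
  d <- study_design(c("a1", "a2"), c("sub1", "sub1"), "HFD",
                    c("baseline", "after"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study_design(d, path)
  expect_equal(read_study_design(path)$timepoint, d$timepoint)
})

test_that("gene reference validates rank and positivity", {
  expect_error(gene_reference("family", "x", 2000), "rank")
  expect_error(gene_reference("genus", "x", -5))
  ref <- gene_reference(c("species", "genus"), c("fragilis", "Blautia"),
                        c(4300, 3100))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_reference(ref, path)
  expect_equal(read_gene_reference(path)$mean_gene_count, c(4300, 3100))
})
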