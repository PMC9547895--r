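test_that("a one-component mixture reduces to a single DM fit", {
  cfg <- generator_config(n_subjects = 40, n_taxa = 30, n_enterotypes = 1,
                          seed = 61)
  genus <- aggregate_taxa(generate_baseline(cfg)$table, "genus")
  m <- fit_dmm(genus, K = 1, seed = 62)
  expect_equal(m$weights, 1)
  expect_true(all(m$assignments == 1L))
  expect_true(all(abs(rowSums(m$responsibilities) - 1) < 1e-12))
})

test_that("EM log-likelihood is non-decreasing", {
  cfg <- generator_config(n_subjects = 120, n_taxa = 40, seed = 63)
  genus <- aggregate_taxa(rarefy(generate_baseline(cfg)$table, seed = 64),
                          "genus")
  m <- fit_dmm(genus, K = 3, seed = 65)
  expect_true(all(diff(m$loglik) > -1e-6 * abs(m$loglik[1])))
  expect_true(all(abs(rowSums(m$responsibilities) - 1) < 1e-10))
  expect_true(all(m$medoids %in% sample_ids(genus)))
  for (k in seq_len(m$K)) {
    expect_equal(m$assignments[match(m$medoids[k], m$sample_ids)], k)
  }
})

test_that("well-separated components are recovered with high ARI", {
  cfg <- generator_config(n_subjects = 150, n_taxa = 60, seed = 66)
  bl <- generate_baseline(cfg)
  genus <- aggregate_taxa(rarefy(bl$table, seed = 67), "genus")
  m <- fit_dmm(genus, K = 4, seed = 68)
  expect_gt(ari(m$assignments, bl$truth$subjects$enterotype), 0.9)
})

test_that("medoids classify to their own component; ties go to the lowest index", {
  cfg <- generator_config(n_subjects = 80, n_taxa = 40, seed = 69)
  genus <- aggregate_taxa(rarefy(generate_baseline(cfg)$table, seed = 70),
                          "genus")
  m <- fit_dmm(genus, K = 3, seed = 71)
  med_tbl <- subset_table(genus, samples = m$medoids)
  expect_equal(unname(classify_by_medoid(med_tbl, m)), seq_len(3))
  # an equidistant tie resolves to the lowest component index
  fake <- m
  fake$medoid_profiles <- rbind(m$medoid_profiles[1, ],
                                m$medoid_profiles[1, ])
  fake$medoid_components <- c(1L, 2L)
  expect_message(
    lab <- classify_by_medoid(genus$counts[1, ], fake), "lowest")
  expect_equal(unname(lab), 1L)
  expect_error(classify_by_medoid(numeric(ncol(genus$counts)), m), "empty")
})

test_that("AGN is the read-weighted mean gene count over included taxa", {
  taxa <- parse_taxon_labels(c(
    "p__Bacteroidetes;g__Bacteroides;s__dorei",       # species-resolved
    "p__Firmicutes;g__Blautia;s__unclassified",       # genus-resolved
    "p__Firmicutes;f__Clostridiaceae;g__unclassified" # family: excluded
  ))
  ref <- gene_reference(c("species", "genus"), c("dorei", "Blautia"),
                        c(2000, 4000))
  res <- compute_agn(c(10, 30, 0), taxa, ref)
  expect_equal(res$agn, (10 * 2000 + 30 * 4000) / 40)  # 3500
  expect_equal(res$fraction_used, 1)
  # adding family-level reads changes fraction_used but AGN still averages
  # over included reads only
  res2 <- compute_agn(c(10, 30, 60), taxa, ref)
  expect_equal(res2$agn, 3500)
  expect_equal(res2$fraction_used, 0.4)
  # single matched taxon: AGN equals its reference value
  res3 <- compute_agn(c(25, 0, 0), taxa, ref)
  expect_equal(res3$agn, 2000)
  # scale invariance
  res4 <- compute_agn(c(100, 300, 600), taxa, ref)
  expect_equal(res4$agn, res2$agn)
  expect_error(compute_agn(c(0, 0, 10), taxa, ref), "no taxon matched")
})

test_that("B:F ratio handles both phyla, absences and the zero denominator", {
  taxa <- parse_taxon_labels(c("p__Bacteroidetes;g__A", "p__Firmicutes;g__B",
                               "p__Actinobacteria;g__C"))
  expect_equal(compute_bf_ratio(c(100, 100, 50), taxa), 1)
  expect_equal(compute_bf_ratio(c(0, 100, 0), taxa), 0)
  expect_equal(compute_bf_ratio(c(300, 200, 0), taxa), 1.5)
  expect_error(compute_bf_ratio(c(10, 0, 5), taxa), "Firmicutes")
  expect_equal(compute_bf_ratio(c(10, 0, 5), taxa, zero_firmicutes = "inf"),
               Inf)
})

test_that("community stats tabulate alpha, AGN and B:F per sample", {
  cfg <- generator_config(n_subjects = 15, n_taxa = 50, seed = 72)
  bl <- generate_baseline(cfg)
  stats <- community_stats(bl$table, bl$reference, zero_firmicutes = "inf")
  expect_equal(nrow(stats), 15L)
  expect_true(all(stats$agn >= 1500 & stats$agn <= 8000))
  expect_true(all(stats$fraction_used > 0 & stats$fraction_used <= 1))
  expect_true(all(stats$alpha_shannon > 0))
})
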