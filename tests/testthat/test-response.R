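test_that("partial correlations recover the precision-matrix closed form", {
  sigma <- matrix(c(1, 0.5, 0.3,
                    0.5, 1, 0.4,
                    0.3, 0.4, 1), 3, 3)
  prec <- solve(sigma)
  expected <- function(i, j) -prec[i, j] / sqrt(prec[i, i] * prec[j, j])
  d <- simulate_mvn_records(3000, sigma, seed = 81)
  net <- partial_correlation_network(
    d, c("response", "alpha_baseline", "agn_baseline"), random_effect = NULL)
  for (e in seq_len(nrow(net))) {
    i <- match(net$node_i[e], names(d))
    j <- match(net$node_j[e], names(d))
    expect_lt(abs(net$partial_r[e] - expected(i, j)), 0.07)
  }
})

test_that("network edges are BH-adjusted monotonically and flagged", {
  d <- simulate_mvn_records(200, diag(4), seed = 82,
                            names = c("response", "a", "b", "c"))
  net <- partial_correlation_network(d, c("response", "a", "b", "c"),
                                     random_effect = NULL)
  expect_equal(nrow(net), 6L)  # all unordered pairs
  expect_true(all(net$q_value >= net$p_value))
  expect_true(all(diff(net$q_value[order(net$p_value)]) >= 0))
  expect_identical(net$significant, net$q_value < 0.05)
})

test_that("mixed and simple paths agree when there is one intervention", {
  d <- simulate_mvn_records(150, diag(3), seed = 83)
  d$intervention <- "ONLY"
  n1 <- partial_correlation_network(
    d, c("response", "alpha_baseline", "agn_baseline"),
    random_effect = "intervention")
  n2 <- partial_correlation_network(
    d, c("response", "alpha_baseline", "agn_baseline"),
    random_effect = NULL)
  expect_equal(n1$partial_r, n2$partial_r, tolerance = 1e-10)
})

test_that("degenerate networks are rejected with informative errors", {
  d <- simulate_mvn_records(50, diag(3), seed = 84)
  expect_error(partial_correlation_network(d, c("response", "missing_one",
                                                "alpha_baseline")),
               "missing")
  d$dup <- d$response
  expect_error(partial_correlation_network(
    d, c("response", "dup", "alpha_baseline"), random_effect = NULL),
    "collinear|singular")
  d$flat <- 1
  expect_error(partial_correlation_network(
    d, c("response", "flat", "alpha_baseline"), random_effect = NULL),
    "constant")
})

test_that("response potential hits endpoints for identical and disjoint panels", {
  x <- drop(rmultinom(1, 2000, rep(1, 20)))
  panel_same <- matrix(rep(x, 5), 5, 20, byrow = TRUE)
  ctx <- make_table(rbind(x, panel_same))
  cfg <- null_model_config(ctx, n_reps = 99, seed = 85)
  ids <- sample_ids(ctx)
  expect_warning(pot <- response_potential(ids[1], ids[-1], cfg), "noisy")
  expect_equal(as.numeric(pot), -1)

  y <- c(drop(rmultinom(1, 2000, rep(1, 10))), rep(0L, 10))
  panel_disj <- t(vapply(1:5, function(i) {
    c(rep(0L, 10), drop(rmultinom(1, 2000, rep(1, 10))))
  }, numeric(20)))
  ctx2 <- make_table(rbind(y, panel_disj))
  cfg2 <- null_model_config(ctx2, n_reps = 99, seed = 86)
  ids2 <- sample_ids(ctx2)
  expect_warning(pot2 <- response_potential(ids2[1], ids2[-1], cfg2))
  expect_equal(as.numeric(pot2), 1)
  expect_error(response_potential(ids2[1], ids2[1], cfg2), "empty")
})

test_that("a planted taxon effect is detected with the right sign", {
  cfg <- generator_config(n_subjects = 150, n_taxa = 40, seed = 87)
  bl <- generate_baseline(cfg)
  clr <- clr_transform(bl$table)
  target <- which.max(apply(clr, 2, sd))
  set.seed(88)
  response <- 0.5 * clr[, target] + rnorm(150, 0, 0.5)
  records <- data.frame(
    subject_id = bl$design$subject_id,
    intervention = rep(c("A", "B"), length.out = 150),
    baseline_sample = bl$design$sample_id,
    response = response,
    alpha_baseline = apply(bl$table$counts, 1, shannon),
    stringsAsFactors = FALSE)
  tab <- taxa_response_association(bl$table, records, mode = "mixed_over_all")
  top <- tab[which.min(tab$p_value), ]
  expect_equal(top$taxon, colnames(clr)[target])
  expect_gt(top$coefficient, 0)
  expect_true(top$significant)
})

test_that("null taxa associations produce roughly uniform p-values", {
  cfg <- generator_config(n_subjects = 100, n_taxa = 30, seed = 89)
  bl <- generate_baseline(cfg)
  set.seed(90)
  records <- data.frame(
    subject_id = bl$design$subject_id,
    intervention = "ONLY",
    baseline_sample = bl$design$sample_id,
    response = rnorm(100),
    alpha_baseline = apply(bl$table$counts, 1, shannon),
    stringsAsFactors = FALSE)
  tab <- taxa_response_association(bl$table, records,
                                   mode = "per_intervention")
  ks <- suppressWarnings(stats::ks.test(tab$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("metadata associations route between mixed and simple models", {
  d <- simulate_mvn_records(120, diag(3), seed = 91)
  set.seed(92)
  f <- 0.8 * d$response + rnorm(120)
  res <- metadata_association(d, f)
  expect_equal(res$method, "mixed")
  expect_gt(res$coefficient, 0)
  expect_lt(res$p_value, 0.01)
  d1 <- d
  d1$intervention <- "ONLY"
  expect_message(res1 <- metadata_association(d1, f), "single intervention")
  expect_equal(res1$method, "simple")
  expect_error(metadata_association(d, rep(1, 120)), "constant")
  expect_error(metadata_association(d, sample(letters[1:3], 120, TRUE)),
               "2 levels")
})
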