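# Gradient-boosted-tree test of response predictability from baseline
# composition, and the response-potential substitution protocol: in each
# cross-validation iteration a main model predicts the response from
# arcsine-square-root abundances; its test-set quality is also evaluated
# against the response-potential values, and compared with a label-shuffled
# random model.

#' Configuration of the boosted-tree response model
#'
#' Defaults follow the standard protocol: depth-15 trees, 1000 boosting
#' rounds at learning rate 0.3 for the main model; predictor selection by 10
#' auxiliary 300-round models whose gain importances are averaged, keeping
#' the top 30 features after removing taxa with zero abundance in more than
#' 30% of the training samples; 50 cross-validation iterations with 2:1
#' train:test subject splits.
#'
#' @param tree_depth,n_trees,learning_rate main-model parameters.
#' @param selection_trees,selection_models auxiliary selection models.
#' @param n_selected number of predictors retained.
#' @param zero_fraction_thr maximum tolerated fraction of zero-abundance
#'   training samples per taxon.
#' @param n_cv number of cross-validation iterations.
#' @param test_fraction fraction of subjects in the test split (1/3 gives
#'   the 2:1 ratio).
#' @param seed integer seed.
#' @return an `ml_config` list.
#' @export
ml_config <- function(tree_depth = 15, n_trees = 1000, learning_rate = 0.3,
                      selection_trees = 300, selection_models = 10,
                      n_selected = 30, zero_fraction_thr = 0.3,
                      n_cv = 50, test_fraction = 1 / 3, seed = 1L) {
  stopifnot(tree_depth > 0, n_trees > 0, learning_rate > 0,
            selection_trees > 0, selection_models > 0, n_selected > 0,
            zero_fraction_thr >= 0, n_cv > 0,
            test_fraction > 0, test_fraction < 1)
  structure(as.list(environment()), class = "ml_config")
}

#' Arcsine-square-root transform of baseline relative abundances
#'
#' \eqn{\mathrm{asin}(\sqrt p)} per entry; the variance-stabilising
#' transform used for proportion predictors.
#'
#' @param tbl an `abundance_table` (converted to relative abundances) or a
#'   numeric matrix of proportions in \[0, 1\].
#' @return numeric matrix of transformed predictors, samples x taxa.
#' @export
transform_predictors <- function(tbl) {
  p <- if (inherits(tbl, "abundance_table")) relative_abundance(tbl)
       else as.matrix(tbl)
  if (any(p < 0 | p > 1)) stop("proportions outside [0, 1]")
  asin(sqrt(p))
}

xgb_params <- function(cfg) {
  list(max_depth = cfg$tree_depth, eta = cfg$learning_rate,
       objective = "reg:squarederror", nthread = 1,
       tree_method = "hist", max_bin = 64)
}

fit_xgb <- function(X, y, cfg, nrounds, seed) {
  with_seed(seed, {
    xgboost::xgb.train(params = c(xgb_params(cfg), list(seed = seed)),
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = nrounds, verbose = 0)
  })
}

#' Select predictors on the training set
#'
#' Removes taxa with zero abundance in more than `zero_fraction_thr` of the
#' training samples, trains `selection_models` boosted-tree models
#' (`selection_trees` rounds each, distinct seeds) on the survivors,
#' averages per-feature gain importance across the models and returns the
#' `n_selected` top-ranked feature names.  Only training data enter this
#' procedure.
#'
#' @param X numeric predictor matrix (training samples x taxa, named
#'   columns); zero-abundance screening interprets exact zeros.
#' @param y training response vector.
#' @param cfg an [ml_config()].
#' @return character vector of selected feature names (all survivors, with a
#'   message, when fewer than `n_selected` remain).
#' @export
select_predictors <- function(X, y, cfg = ml_config()) {
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  zero_frac <- colMeans(X == 0)
  survivors <- colnames(X)[zero_frac <= cfg$zero_fraction_thr]
  if (!length(survivors)) stop("zero-abundance filter removed all taxa")
  Xs <- X[, survivors, drop = FALSE]
  gain <- setNames(numeric(length(survivors)), survivors)
  for (m in seq_len(cfg$selection_models)) {
    fit <- fit_xgb(Xs, y, cfg, cfg$selection_trees, cfg$seed * 1000L + m)
    imp <- xgboost::xgb.importance(model = fit)
    if (nrow(imp)) gain[imp$Feature] <- gain[imp$Feature] + imp$Gain
  }
  gain <- gain / cfg$selection_models
  if (length(survivors) <= cfg$n_selected) {
    message("only ", length(survivors),
            " taxa survive filtering; keeping all")
    return(survivors)
  }
  names(sort(gain, decreasing = TRUE))[seq_len(cfg$n_selected)]
}

#' Squared Pearson correlation between truth and prediction
#'
#' The cross-validation quality measure: \eqn{r^2} of observed vs predicted
#' test values.  Constant predictions are defined to score 0 (with a
#' message) since the correlation is undefined.  Note the measure is
#' sign-blind: perfectly anti-correlated predictions also score 1.
#'
#' @param truth,predicted numeric vectors of equal length (>= 3).
#' @return squared Pearson correlation in \[0, 1\].
#' @export
caret_r2 <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 3)
  if (sd(predicted) == 0 || sd(truth) == 0) {
    message("constant values in caret_r2; returning 0")
    return(0)
  }
  cor(truth, predicted)^2
}

#' Cross-validated response prediction and potential substitution
#'
#' Per iteration: subjects are split 2:1 into train and test; predictors are
#' filtered and selected on the training set only; the main boosted-tree
#' model is fitted and its test predictions scored three ways - against the
#' held-out responses (`r2_initial`), against a label-shuffled rerun of the
#' whole procedure (`r2_random`, shuffling repeated per iteration), and
#' against the held-out response-potential values (`r2_potential`).  A mean
#' `r2_potential` comparable to `r2_initial` (and well above `r2_random`)
#' indicates the response-potential estimate captures the
#' baseline-predictable component of the response.
#'
#' @param X predictor matrix (subjects x taxa, from
#'   [transform_predictors()]), rows named by subject.
#' @param responses numeric response vector aligned with rows of `X`.
#' @param potentials numeric response-potential vector aligned with rows of
#'   `X` (or `NULL` to skip the substitution arm).
#' @param cfg an [ml_config()].
#' @return a `cv_result` list: `iterations` data frame (per-iteration
#'   r2_initial, r2_random, r2_potential) and `summary` (mean and sd per
#'   column).
#' @export
cv_predict_response <- function(X, responses, potentials = NULL,
                                cfg = ml_config()) {
  n <- nrow(X)
  stopifnot(length(responses) == n,
            is.null(potentials) || length(potentials) == n)
  n_test <- round(n * cfg$test_fraction)
  if (n_test < 5) stop("too few subjects for a 2:1 split with >= 5 test subjects")
  rows <- lapply(seq_len(cfg$n_cv), function(it) {
    it_seed <- cfg$seed + 17L * it
    test <- with_seed(it_seed, sample.int(n, n_test))
    train <- setdiff(seq_len(n), test)
    sel_cfg <- cfg
    sel_cfg$seed <- it_seed
    feats <- suppressMessages(
      select_predictors(X[train, , drop = FALSE], responses[train], sel_cfg))
    fit <- fit_xgb(X[train, feats, drop = FALSE], responses[train], cfg,
                   cfg$n_trees, it_seed + 1L)
    pred <- predict(fit, xgboost::xgb.DMatrix(X[test, feats, drop = FALSE]))
    r2_initial <- suppressMessages(caret_r2(responses[test], pred))
    r2_potential <- if (!is.null(potentials)) {
      suppressMessages(caret_r2(potentials[test], pred))
    } else NA_real_
    # random model: responses shuffled relative to predictors, full rerun
    y_perm <- with_seed(it_seed + 2L, responses[sample.int(n)])
    feats_r <- suppressMessages(
      select_predictors(X[train, , drop = FALSE], y_perm[train], sel_cfg))
    fit_r <- fit_xgb(X[train, feats_r, drop = FALSE], y_perm[train], cfg,
                     cfg$n_trees, it_seed + 3L)
    pred_r <- predict(fit_r,
                      xgboost::xgb.DMatrix(X[test, feats_r, drop = FALSE]))
    r2_random <- suppressMessages(caret_r2(y_perm[test], pred_r))
    data.frame(iteration = it, r2_initial = r2_initial,
               r2_random = r2_random, r2_potential = r2_potential)
  })
  iters <- do.call(rbind, rows)
  summ <- data.frame(
    measure = c("r2_initial", "r2_random", "r2_potential"),
    mean = c(mean(iters$r2_initial), mean(iters$r2_random),
             mean(iters$r2_potential)),
    sd = c(sd(iters$r2_initial), sd(iters$r2_random),
           sd(iters$r2_potential)))
  structure(list(iterations = iters, summary = summ, config = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("boosted-tree response prediction,", nrow(x$iterations),
      "CV iterations (2:1 split):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-13s mean R2 = %.3f (sd %.3f)\n",
                s$measure[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
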