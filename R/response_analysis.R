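# Per-subject response records, the response-potential estimator,
# partial-correlation networks with an intervention random effect, per-taxon
# response associations on clr abundances, and metadata associations.

#' Assemble per-subject response records
#'
#' Joins the RC_bray response of each baseline/after pair with the subject's
#' baseline covariates (Shannon alpha diversity, AGN, B:F ratio) and, when
#' supplied, an enterotype label and a response-potential estimate.
#'
#' @param pairs output of [rc_bray_pairs()] (or any data frame with
#'   subject_id, intervention, baseline_sample and a response column).
#' @param stats output of [community_stats()] on baseline samples.
#' @param enterotypes optional named vector of enterotype labels indexed by
#'   baseline sample id.
#' @param potential optional named vector of response-potential values
#'   indexed by baseline sample id.
#' @param response_col name of the response column in `pairs`.
#' @return a `response_records` data frame: subject_id, intervention,
#'   response, alpha_baseline, agn_baseline, bf_baseline, plus enterotype /
#'   response_potential when given.
#' @export
build_response_records <- function(pairs, stats, enterotypes = NULL,
                                   potential = NULL,
                                   response_col = "rc_bray") {
  m <- match(pairs$baseline_sample, stats$sample_id)
  if (anyNA(m)) stop("baseline samples missing from community stats")
  out <- data.frame(subject_id = pairs$subject_id,
                    intervention = pairs$intervention,
                    baseline_sample = pairs$baseline_sample,
                    response = pairs[[response_col]],
                    alpha_baseline = stats$alpha_shannon[m],
                    agn_baseline = stats$agn[m],
                    bf_baseline = stats$bf_ratio[m],
                    stringsAsFactors = FALSE)
  if (!is.null(enterotypes)) {
    out$enterotype <- unname(enterotypes[pairs$baseline_sample])
  }
  if (!is.null(potential)) {
    out$response_potential <- unname(potential[pairs$baseline_sample])
  }
  if (any(!is.finite(out$response)) ||
      any(!is.finite(out$alpha_baseline)) ||
      any(!is.finite(out$agn_baseline)) || any(!is.finite(out$bf_baseline))) {
    stop("non-finite response or covariates in records")
  }
  class(out) <- c("response_records", "data.frame")
  out
}

#' Response potential of a baseline sample
#'
#' The intervention-independent component of the response is estimated as
#' the mean RC_bray between the query sample and a large reference panel of
#' same-enterotype samples from other individuals, computed inside the
#' context of query plus reference.  Panels of fewer than 300 samples
#' trigger a warning (the estimate gets noisy).
#'
#' @param sample_id id of the query sample (present in `context`).
#' @param reference_ids ids of the reference panel (same enterotype, other
#'   subjects; must not include the query subject's own samples).
#' @param cfg a [null_model_config()] whose context contains query and
#'   reference.
#' @return mean RC_bray to the reference panel, with per-reference values in
#'   attribute `per_reference`.
#' @export
response_potential <- function(sample_id, reference_ids, cfg) {
  reference_ids <- setdiff(reference_ids, sample_id)
  if (!length(reference_ids)) stop("empty reference panel")
  if (length(reference_ids) < 300) {
    warning("reference panel has ", length(reference_ids),
            " samples (< 300); response potential will be noisy")
  }
  vals <- vapply(reference_ids, function(r) {
    as.numeric(rc_bray(sample_id, r, cfg))
  }, numeric(1))
  out <- mean(vals)
  attr(out, "per_reference") <- vals
  out
}

# Residuals of `target ~ predictors` with an optional random intercept per
# intervention.  Conditional residuals (observed minus fixed + predicted
# random intercept) are used for the mixed path.
component_residuals <- function(data, target, predictors, random_effect) {
  if (!is.null(random_effect) &&
      length(unique(data[[random_effect]])) > 1) {
    rhs <- c(if (length(predictors)) predictors else "1",
             sprintf("(1 | %s)", random_effect))
    f <- as.formula(paste(target, "~", paste(rhs, collapse = " + ")))
    fit <- lme4::lmer(f, data = data, REML = FALSE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    residuals(fit)
  } else {
    f <- reformulate(if (length(predictors)) predictors else "1",
                     response = target)
    residuals(lm(f, data = data))
  }
}

#' Partial-correlation network of response and community components
#'
#' For every unordered pair of components (i, j), two linear models are
#' fitted - component i and component j each regressed on all remaining
#' components - and the edge weight is the Pearson correlation of their
#' residuals.  With `random_effect = "intervention"`, both models carry a
#' random intercept per intervention (the mixed path reduces to the simple
#' one when only a single intervention is present).  Edge p-values come from
#' the Pearson test on the residual pairs; q-values are Benjamini-Hochberg
#' over all edges of the network.
#'
#' Components are standardised internally; partial correlations are
#' scale-invariant so results are unchanged.
#'
#' @param records a `response_records` data frame (or any data frame holding
#'   the component columns and the random-effect column).
#' @param components character vector of >= 3 component column names,
#'   e.g. `c("response", "alpha_baseline", "agn_baseline", "bf_baseline")`.
#' @param random_effect optional grouping column name
#'   (`"intervention"`), or `NULL` for simple linear models.
#' @param fdr_alpha FDR threshold for the `significant` flag (default 0.05).
#' @return a `pcor_network` data frame of edges: node_i, node_j, partial_r,
#'   p_value, q_value, significant.
#' @export
partial_correlation_network <- function(records, components,
                                        random_effect = NULL,
                                        fdr_alpha = 0.05) {
  stopifnot(length(components) >= 3, nrow(records) >= 10)
  if (!all(components %in% names(records))) {
    stop("missing component columns: ",
         paste(setdiff(components, names(records)), collapse = ", "))
  }
  dat <- records[, c(components, random_effect), drop = FALSE]
  if (any(!complete.cases(dat))) stop("missing values in components")
  for (cc in components) {
    if (sd(dat[[cc]]) == 0) stop("constant component: ", cc)
    dat[[cc]] <- as.numeric(scale(dat[[cc]]))
  }
  qr_rank <- qr(as.matrix(dat[, components]))$rank
  if (qr_rank < length(components)) {
    stop("collinear components; design is singular")
  }
  pairs <- utils::combn(components, 2)
  edges <- lapply(seq_len(ncol(pairs)), function(e) {
    i <- pairs[1, e]; j <- pairs[2, e]
    others <- setdiff(components, c(i, j))
    ri <- component_residuals(dat, i, others, random_effect)
    rj <- component_residuals(dat, j, others, random_effect)
    ct <- suppressWarnings(cor.test(ri, rj))
    data.frame(node_i = i, node_j = j, partial_r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, edges)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < fdr_alpha
  class(out) <- c("pcor_network", "data.frame")
  out
}

#' Per-taxon association of baseline abundance with response
#'
#' Fits, per taxon, a linear model of the response on the taxon's
#' clr-transformed baseline abundance (pseudocount 0.5), optionally adjusted
#' for baseline alpha diversity.  Three stratification modes mirror the
#' standard analysis variants: one mixed-effect model over all interventions
#' (random intercept per intervention), separate mixed models per enterotype,
#' or separate simple models per intervention.  Benjamini-Hochberg correction
#' is applied within each (mode, stratum) family.
#'
#' @param baseline_tbl an `abundance_table` of baseline samples.
#' @param records a `response_records` data frame whose `baseline_sample`
#'   column indexes rows of `baseline_tbl`.
#' @param mode `"mixed_over_all"`, `"per_enterotype"` or
#'   `"per_intervention"`.
#' @param adjust_alpha add baseline alpha diversity as a covariate.
#' @param pseudocount zero replacement for the clr transform (default 0.5).
#' @param fdr_alpha FDR threshold for the `significant` flag.
#' @return data frame: stratum, taxon, coefficient, p_value, q_value,
#'   significant.
#' @export
taxa_response_association <- function(baseline_tbl, records,
                                      mode = c("mixed_over_all",
                                               "per_enterotype",
                                               "per_intervention"),
                                      adjust_alpha = FALSE,
                                      pseudocount = 0.5, fdr_alpha = 0.05) {
  mode <- match.arg(mode)
  idx <- match(records$baseline_sample, rownames(baseline_tbl$counts))
  if (anyNA(idx)) stop("records reference samples absent from the table")
  clr <- clr_transform(subset_table(baseline_tbl, samples = idx),
                       pseudocount = pseudocount)
  strata <- switch(mode,
                   mixed_over_all = list(all = seq_len(nrow(records))),
                   per_enterotype = split(seq_len(nrow(records)),
                                          records$enterotype),
                   per_intervention = split(seq_len(nrow(records)),
                                            records$intervention))
  mixed <- mode != "per_intervention"
  res <- lapply(names(strata), function(s) {
    rows <- strata[[s]]
    if (length(rows) < 10) return(NULL)
    d0 <- data.frame(response = records$response[rows],
                     alpha = records$alpha_baseline[rows],
                     intervention = records$intervention[rows],
                     stringsAsFactors = FALSE)
    use_mixed <- mixed && length(unique(d0$intervention)) > 1
    per_taxon <- lapply(seq_len(ncol(clr)), function(tx) {
      d <- d0
      d$abund <- clr[rows, tx]
      if (sd(d$abund) == 0) return(NULL)
      if (use_mixed) {
        f <- as.formula(paste("response ~ abund",
                              if (adjust_alpha) "+ alpha" else "",
                              "+ (1 | intervention)"))
        fit <- suppressMessages(suppressWarnings(
          lmerTest::lmer(f, data = d, REML = FALSE,
                         control = lme4::lmerControl(
                           check.conv.singular = "ignore"))))
        cf <- summary(fit)$coefficients
        data.frame(stratum = s, taxon = colnames(clr)[tx],
                   coefficient = cf["abund", "Estimate"],
                   p_value = cf["abund", "Pr(>|t|)"],
                   stringsAsFactors = FALSE)
      } else {
        f <- as.formula(paste("response ~ abund",
                              if (adjust_alpha) "+ alpha" else ""))
        cf <- summary(lm(f, data = d))$coefficients
        data.frame(stratum = s, taxon = colnames(clr)[tx],
                   coefficient = cf["abund", "Estimate"],
                   p_value = cf["abund", "Pr(>|t|)"],
                   stringsAsFactors = FALSE)
      }
    })
    tab <- do.call(rbind, per_taxon)
    if (is.null(tab)) return(NULL)
    tab$q_value <- p.adjust(tab$p_value, method = "BH")
    tab
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no stratum had enough samples to fit models")
  out$significant <- out$q_value < fdr_alpha
  rownames(out) <- NULL
  out
}

#' Association of the response with one metadata factor
#'
#' Numeric or two-level factors are supported.  When the factor was observed
#' in more than one intervention a mixed-effect model with a random
#' intercept per intervention is used; a factor confined to a single
#' intervention routes to a simple linear regression (reported in `method`).
#'
#' @param records a `response_records` data frame.
#' @param factor_values vector aligned with `records` rows (numeric, or a
#'   2-level factor/character).
#' @return list: `coefficient`, `p_value`, `method` (`"mixed"` or
#'   `"simple"`), `n`.
#' @export
metadata_association <- function(records, factor_values) {
  stopifnot(length(factor_values) == nrow(records))
  keep <- !is.na(factor_values)
  d <- data.frame(response = records$response[keep],
                  intervention = records$intervention[keep],
                  stringsAsFactors = FALSE)
  fv <- factor_values[keep]
  if (!is.numeric(fv)) {
    lev <- unique(fv)
    if (length(lev) != 2) stop("categorical factor must have 2 levels")
    fv <- as.numeric(fv == lev[2])
  }
  if (sd(fv) == 0) stop("constant factor")
  d$f <- fv
  if (length(unique(d$intervention)) > 1) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(response ~ f + (1 | intervention), data = d,
                     REML = FALSE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))))
    cf <- summary(fit)$coefficients
    list(coefficient = cf["f", "Estimate"], p_value = cf["f", "Pr(>|t|)"],
         method = "mixed", n = nrow(d))
  } else {
    message("factor observed in a single intervention; using simple ",
            "linear regression")
    cf <- summary(lm(response ~ f, data = d))$coefficients
    list(coefficient = cf["f", "Estimate"], p_value = cf["f", "Pr(>|t|)"],
         method = "simple", n = nrow(d))
  }
}
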