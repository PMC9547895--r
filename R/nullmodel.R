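# Raup-Crick null-model beta diversity on Bray-Curtis dissimilarities
# (RC_bray), and the two table randomisations used to expose the purely
# computational dependence of beta diversity on alpha diversity.
#
# RC_bray locates the observed Bray-Curtis dissimilarity of a sample pair
# within a null distribution of dissimilarities between communities
# re-assembled at fixed richness and depth from the species pool of a
# declared context table.  The statistic is scaled to [-1, 1]: -1 means the
# pair is far more similar than the null expects (identical communities), +1
# far more distinct.

#' Configuration for the RC_bray null model
#'
#' The context table defines the species pool: per-taxon occurrence
#' frequency (prevalence) weights the null occupancy draw and mean relative
#' abundance weights the null count draw.  Because RC values depend on this
#' pool, the context in use (global, per-intervention, per-enterotype) should
#' be declared once per analysis; `label` is carried into results for
#' provenance.
#'
#' @param context an `abundance_table` containing every sample the model will
#'   be asked about (ideally rarefied to a common depth).
#' @param n_reps number of null assemblies per pair (>= 99; default 999).
#' @param seed integer master seed; each pair derives its own stream from
#'   (seed, sorted pair ids) so `rc_bray(x, y)` equals `rc_bray(y, x)`.
#' @param label optional context name recorded in outputs.
#' @return a `null_model_config` list.
#' @export
null_model_config <- function(context, n_reps = 999, seed = 1L,
                              label = "global") {
  stopifnot(inherits(context, "abundance_table"), n_reps >= 99)
  prevalence <- colMeans(context$counts > 0)
  mean_abund <- colMeans(relative_abundance(context))
  structure(list(context = context, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), label = label,
                 prevalence = prevalence, mean_abundance = mean_abund),
            class = "null_model_config")
}

# One null community: `richness` taxa drawn without replacement with
# probability proportional to pool prevalence; each receives one read, the
# remaining depth - richness reads are drawn with replacement with
# probability proportional to pool mean abundance (Stegen-style two-step
# assembly, preserving observed richness and depth exactly).
null_assembly <- function(richness, depth, prevalence, mean_abundance) {
  n_taxa <- length(prevalence)
  if (richness > sum(prevalence > 0)) {
    stop("sample richness exceeds the context species pool")
  }
  chosen <- sample.int(n_taxa, richness, prob = prevalence)
  out <- numeric(n_taxa)
  out[chosen] <- 1
  extra <- depth - richness
  if (extra > 0) {
    w <- mean_abundance[chosen]
    if (sum(w) <= 0) w <- rep(1, richness)
    out[chosen] <- out[chosen] + drop(rmultinom(1, extra, w))
  }
  out
}

#' RC_bray between two samples of a context
#'
#' Computes the observed Bray-Curtis dissimilarity of the pair, re-assembles
#' both communities `n_reps` times under the null model, and returns
#' \deqn{RC = 2\,\frac{\#\{null < obs\} + 0.5\,\#\{null = obs\}}{n_{reps}} - 1,}
#' in \[-1, 1\]; ties are split so both endpoints are attainable.  -1 is
#' produced by identical communities, +1 by maximally distinct ones.
#'
#' @param x_id,y_id sample ids present in `cfg$context`.
#' @param cfg a [null_model_config()].
#' @return RC_bray value in \[-1, 1\], with the null Bray-Curtis draws in
#'   attribute `null`.
#' @export
rc_bray <- function(x_id, y_id, cfg) {
  stopifnot(inherits(cfg, "null_model_config"))
  ids <- rownames(cfg$context$counts)
  if (!all(c(x_id, y_id) %in% ids)) {
    stop("sample(s) not in null-model context: ",
         paste(setdiff(c(x_id, y_id), ids), collapse = ", "))
  }
  x <- cfg$context$counts[x_id, ]
  y <- cfg$context$counts[y_id, ]
  obs <- bray_curtis(x, y)
  rx <- sum(x > 0); dx <- sum(x)
  ry <- sum(y > 0); dy <- sum(y)
  nulls <- with_seed(pair_seed(cfg$seed, x_id, y_id), {
    vapply(seq_len(cfg$n_reps), function(i) {
      nx <- null_assembly(rx, dx, cfg$prevalence, cfg$mean_abundance)
      ny <- null_assembly(ry, dy, cfg$prevalence, cfg$mean_abundance)
      bray_curtis(nx, ny)
    }, numeric(1))
  })
  tol <- 1e-10
  below <- sum(nulls < obs - tol)
  ties <- sum(abs(nulls - obs) <= tol)
  rc <- 2 * (below + 0.5 * ties) / cfg$n_reps - 1
  attr(rc, "null") <- nulls
  attr(rc, "obs") <- obs
  rc
}

#' Per-subject RC_bray response over baseline/after pairs
#'
#' For every subject in the design with both timepoints, computes RC_bray
#' between its baseline and after samples inside the configured context.
#' Subjects with a missing pair member are skipped with a warning.
#'
#' @param design a `study_design`.
#' @param cfg a [null_model_config()] whose context contains the paired
#'   samples.
#' @return data frame: subject_id, intervention, baseline/after sample ids,
#'   observed Bray-Curtis, `rc_bray`, and the context label.
#' @export
rc_bray_pairs <- function(design, cfg) {
  stopifnot(inherits(design, "data.frame"))
  base <- design[design$timepoint == "baseline", ]
  aft <- design[design$timepoint == "after", ]
  key <- paste(aft$intervention, aft$subject_id)
  m <- match(paste(base$intervention, base$subject_id), key)
  ids <- rownames(cfg$context$counts)
  rows <- lapply(seq_len(nrow(base)), function(i) {
    if (is.na(m[i])) return(NULL)
    s_b <- base$sample_id[i]
    s_a <- aft$sample_id[m[i]]
    if (!all(c(s_b, s_a) %in% ids)) {
      warning("pair for subject ", base$subject_id[i],
              " not in context; skipped")
      return(NULL)
    }
    rc <- rc_bray(s_b, s_a, cfg)
    data.frame(subject_id = base$subject_id[i],
               intervention = base$intervention[i],
               baseline_sample = s_b, after_sample = s_a,
               obs_bray = attr(rc, "obs"), rc_bray = as.numeric(rc),
               context = cfg$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no complete baseline/after pairs found in context")
  rownames(out) <- NULL
  out
}

#' Rescale RC_bray from \[-1, 1\] to \[0, 1\]
#'
#' `(rc + 1) / 2`; used where an analysis needs a non-negative response
#' (e.g. as a dissimilarity-like quantity).
#'
#' @param rc numeric vector in \[-1, 1\].
#' @return rescaled values in \[0, 1\].
#' @export
rescale_rc_to_unit <- function(rc) {
  if (any(rc < -1 - 1e-12 | rc > 1 + 1e-12)) stop("rc outside [-1, 1]")
  (rc + 1) / 2
}

#' Randomisation 1: permute taxon identities within each sample
#'
#' Each sample's count values are randomly permuted across taxon columns,
#' independently per sample.  The count multiset, read total and therefore
#' the Shannon index of every sample are preserved bit-exactly, while any
#' biological taxon structure is destroyed; pairwise beta diversity rises on
#' average.
#'
#' @param tbl an `abundance_table`.
#' @param seed integer seed.
#' @return a randomised `abundance_table`.
#' @export
randomise_1 <- function(tbl, seed = 1L) {
  stopifnot(inherits(tbl, "abundance_table"))
  counts <- with_seed(seed, {
    t(apply(tbl$counts, 1, function(r) r[sample.int(length(r))]))
  })
  rownames(counts) <- rownames(tbl$counts)
  abundance_table(counts, tbl$taxa)
}

#' Randomisation 2: re-assemble each sample from the pool
#'
#' Mirrors the null model inside the RC_bray calculation: mean taxa
#' abundances and prevalences are computed from the whole table; each sample
#' is rebuilt at its observed richness (taxa drawn without replacement,
#' prevalence-weighted) and read total (counts drawn with replacement among
#' the chosen taxa, abundance-weighted, after seeding each chosen taxon with
#' one read so the drawn taxon list is fully represented).  Per-sample
#' richness and depth are preserved exactly; Shannon changes slightly;
#' pairwise beta diversity falls on average.
#'
#' @param tbl an `abundance_table` with at least 2 samples.
#' @param seed integer seed.
#' @return a randomised `abundance_table`.
#' @export
randomise_2 <- function(tbl, seed = 1L) {
  stopifnot(inherits(tbl, "abundance_table"), nrow(tbl$counts) >= 2)
  prevalence <- colMeans(tbl$counts > 0)
  mean_abund <- colMeans(relative_abundance(tbl))
  counts <- with_seed(seed, {
    t(apply(tbl$counts, 1, function(r) {
      null_assembly(sum(r > 0), sum(r), prevalence, mean_abund)
    }))
  })
  rownames(counts) <- rownames(tbl$counts)
  abundance_table(counts, tbl$taxa)
}

#' Regression of pairwise beta diversity on pair-mean alpha diversity
#'
#' Draws `n_pairs` random sample pairs, computes the chosen beta-diversity
#' metric for each pair and the mean Shannon index of its two members, and
#' fits a simple linear regression of beta on alpha.  Run on original and
#' randomised tables this exposes the computational alpha-beta dependence:
#' Bray-Curtis and Aitchison retain a significant slope on randomised data
#' while RC_bray does not.
#'
#' @param tbl an `abundance_table` (rarefied for count-based metrics).
#' @param metric `"bray_curtis"`, `"aitchison"`, `"jaccard"`,
#'   `"inverse_pearson"` or `"rc_bray"`.
#' @param randomisation `"none"`, `"1"` or `"2"` - randomisation applied to
#'   the table before measuring.
#' @param n_pairs number of random pairs (default 500).
#' @param n_reps null replicates per pair when `metric = "rc_bray"`.
#' @param seed integer seed governing randomisation, pair draws and null
#'   streams.
#' @return an `alpha_beta_fit` list: `slope`, `p_value`, the fitted `lm`, and
#'   a data frame `data` with one row per pair (alpha, beta).
#' @export
alpha_beta_dependence <- function(tbl, metric = "bray_curtis",
                                  randomisation = c("none", "1", "2"),
                                  n_pairs = 500, n_reps = 999, seed = 1L) {
  randomisation <- match.arg(as.character(randomisation),
                             c("none", "1", "2"))
  metrics <- c("bray_curtis", "aitchison", "jaccard", "inverse_pearson",
               "rc_bray")
  metric <- match.arg(metric, metrics)
  tbl <- switch(randomisation,
                none = tbl,
                "1" = randomise_1(tbl, seed = seed + 11L),
                "2" = randomise_2(tbl, seed = seed + 22L))
  n <- nrow(tbl$counts)
  if (n < 2) stop("need at least two samples")
  if (n < 2 * n_pairs) {
    message("fewer than 2*n_pairs samples; pairs drawn with replacement")
  }
  pairs <- with_seed(seed + 33L, {
    t(replicate(n_pairs, sample.int(n, 2)))
  })
  alpha <- apply(tbl$counts, 1, shannon)
  cfg <- if (metric == "rc_bray") {
    null_model_config(tbl, n_reps = n_reps, seed = seed)
  } else NULL
  ids <- rownames(tbl$counts)
  beta <- vapply(seq_len(n_pairs), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    switch(metric,
           bray_curtis = bray_curtis(tbl$counts[i, ], tbl$counts[j, ]),
           aitchison = aitchison(tbl$counts[i, ], tbl$counts[j, ]),
           jaccard = jaccard(tbl$counts[i, ], tbl$counts[j, ]),
           inverse_pearson = inverse_pearson(tbl$counts[i, ],
                                             tbl$counts[j, ]),
           rc_bray = as.numeric(rc_bray(ids[i], ids[j], cfg)))
  }, numeric(1))
  mean_alpha <- (alpha[pairs[, 1]] + alpha[pairs[, 2]]) / 2
  if (sd(beta) == 0) {
    return(structure(list(slope = 0, p_value = NA_real_, fit = NULL,
                          metric = metric, randomisation = randomisation,
                          data = data.frame(alpha = mean_alpha, beta = beta)),
                     class = "alpha_beta_fit"))
  }
  if (sd(mean_alpha) == 0) stop("constant alpha diversity across pairs")
  fit <- lm(beta ~ alpha, data = data.frame(alpha = mean_alpha, beta = beta))
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 p_value = sm$coefficients[2, 4],
                 fit = fit, metric = metric, randomisation = randomisation,
                 data = data.frame(alpha = mean_alpha, beta = beta)),
            class = "alpha_beta_fit")
}

#' @export
print.alpha_beta_fit <- function(x, ...) {
  cat("alpha-beta regression (", x$metric, ", randomisation ",
      x$randomisation, "): slope = ", signif(x$slope, 4),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}
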