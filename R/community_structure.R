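# Enterotyping by Dirichlet-multinomial mixtures with nearest-medoid
# classification, and baseline community statistics: average gene number per
# organism (AGN) and the Bacteroidetes:Firmicutes ratio.

# Log-density of counts x (rows of X) under Dirichlet-multinomial(alpha),
# including the multinomial coefficient so values are comparable across
# components and usable for BIC.
dm_logdensity <- function(X, alpha) {
  N <- rowSums(X)
  A <- sum(alpha)
  const <- lgamma(N + 1) - rowSums(lgamma(X + 1))
  const + lgamma(A) - lgamma(N + A) +
    rowSums(lgamma(sweep(X, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# One Minka-style fixed-point update of a DM parameter vector under sample
# weights w (responsibilities).  Each update does not decrease the weighted
# log-likelihood.
dm_fixed_point <- function(X, w, alpha, n_inner = 10, floor = 1e-6) {
  N <- rowSums(X)
  for (it in seq_len(n_inner)) {
    A <- sum(alpha)
    num <- colSums(w * (digamma(sweep(X, 2, alpha, "+")) -
                          rep(digamma(alpha), each = nrow(X))))
    den <- sum(w * (digamma(N + A) - digamma(A)))
    alpha_new <- alpha * num / den
    alpha_new[!is.finite(alpha_new) | alpha_new < floor] <- floor
    if (max(abs(alpha_new - alpha)) < 1e-8 * max(alpha)) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  alpha
}

#' Fit a Dirichlet-multinomial mixture (enterotyping)
#'
#' EM fit of a K-component Dirichlet-multinomial mixture to a genus-level
#' count table.  Hard assignments are the argmax posterior responsibility;
#' each component's medoid is the member sample minimising summed
#' Bray-Curtis dissimilarity (on relative abundances) to the other members.
#' Initialisation is k-means on relative abundances under the given seed.
#'
#' @param tbl a genus-level `abundance_table` (see [aggregate_taxa()]).
#' @param K number of components (default 4, the canonical enterotype count).
#' @param seed integer seed for initialisation.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a `dmm_model`: `K`, `weights`, `alphas` (K x taxa), per-sample
#'   `responsibilities` and `assignments`, `medoids` (sample ids),
#'   `medoid_profiles` (relative abundances), `loglik` trace, `logLik` final
#'   value, `fit_score` (BIC; lower is better) and `converged`.
#' @export
fit_dmm <- function(tbl, K = 4, seed = 1L, max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(tbl, "abundance_table"), K >= 1)
  X <- tbl$counts
  storage.mode(X) <- "double"
  n <- nrow(X); tt <- ncol(X)
  props <- X / rowSums(X)
  init <- with_seed(seed, {
    if (K == 1) rep(1L, n) else {
      km <- suppressWarnings(kmeans(props, centers = K, nstart = 5,
                                    iter.max = 50))
      km$cluster
    }
  })
  # init alphas from cluster mean compositions at moderate concentration
  alphas <- t(vapply(seq_len(K), function(k) {
    m <- colMeans(props[init == k, , drop = FALSE])
    pmax(m, 1e-4) * 50
  }, numeric(tt)))
  weights <- tabulate(init, K) / n
  loglik <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    logdens <- vapply(seq_len(K), function(k) {
      log(weights[k]) + dm_logdensity(X, alphas[k, ])
    }, numeric(n))
    if (K == 1) logdens <- matrix(logdens, ncol = 1)
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    loglik <- c(loglik, sum(lse))
    resp <- exp(logdens - lse)
    if (iter > 1 &&
        abs(loglik[iter] - loglik[iter - 1]) <
          tol * (abs(loglik[iter - 1]) + 1)) {
      converged <- TRUE
      break
    }
    weights <- pmax(colMeans(resp), 1e-12)
    weights <- weights / sum(weights)
    for (k in seq_len(K)) {
      alphas[k, ] <- dm_fixed_point(X, resp[, k], alphas[k, ])
    }
  }
  if (!converged) {
    warning("DMM EM did not converge in ", max_iter,
            " iterations; returning best-so-far model")
  }
  assignments <- max.col(resp, ties.method = "first")
  bc <- as.matrix(vegan::vegdist(props, method = "bray"))
  medoids <- vapply(seq_len(K), function(k) {
    members <- which(assignments == k)
    if (!length(members)) return(NA_character_)
    sums <- rowSums(bc[members, members, drop = FALSE])
    rownames(X)[members[which.min(sums)]]
  }, character(1))
  npar <- K * tt + (K - 1)
  occupied <- which(!is.na(medoids))
  structure(list(K = K, weights = weights, alphas = alphas,
                 taxa = tbl$taxa$label,
                 responsibilities = resp, assignments = assignments,
                 sample_ids = rownames(X),
                 medoids = medoids,
                 medoid_components = occupied,
                 medoid_profiles = props[medoids[occupied], , drop = FALSE],
                 loglik = loglik, logLik = loglik[length(loglik)],
                 fit_score = -2 * loglik[length(loglik)] + npar * log(n),
                 converged = converged),
            class = "dmm_model")
}

#' @export
print.dmm_model <- function(x, ...) {
  cat("Dirichlet-multinomial mixture: K =", x$K, "| n =",
      length(x$assignments), "| logLik =", round(x$logLik, 1),
      "| BIC =", round(x$fit_score, 1), "\n")
  cat("component sizes:", paste(tabulate(x$assignments, x$K),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Classify samples into enterotypes by nearest medoid
#'
#' Assigns each sample the enterotype whose medoid has the lowest
#' Bray-Curtis dissimilarity (computed on relative abundances) to it.  Exact
#' ties are broken towards the lowest component index, with a message.
#'
#' @param samples an `abundance_table` of genus-level samples to classify, or
#'   a single count vector aligned to the model's taxa.
#' @param model a fitted `dmm_model`.
#' @return integer vector of component labels, named by sample id when
#'   available.
#' @export
classify_by_medoid <- function(samples, model) {
  stopifnot(inherits(model, "dmm_model"))
  m <- if (inherits(samples, "abundance_table")) {
    if (!identical(samples$taxa$label, model$taxa)) {
      idx <- match(model$taxa, samples$taxa$label)
      if (anyNA(idx)) stop("sample taxa do not cover the model's taxa")
      samples$counts[, idx, drop = FALSE]
    } else samples$counts
  } else matrix(samples, nrow = 1)
  if (any(rowSums(m) == 0)) stop("cannot classify an empty sample")
  props <- m / rowSums(m)
  med <- model$medoid_profiles
  labels <- apply(props, 1, function(p) {
    d <- apply(med, 1, function(q) sum(abs(p - q)) / sum(p + q))
    hits <- which(abs(d - min(d)) < 1e-12)
    if (length(hits) > 1) {
      message("medoid tie broken towards lowest component index")
    }
    model$medoid_components[hits[1]]
  })
  if (!is.null(rownames(m))) names(labels) <- rownames(m)
  labels
}

#' Average gene number per organism (AGN) of a sample
#'
#' Matches species-resolved taxa to species-rank reference entries and
#' genus-resolved taxa to genus-rank entries; taxa resolved only to family or
#' higher, and taxa without a reference match, are excluded.  AGN is the
#' read-weighted mean gene count over included taxa,
#' \eqn{\sum_i c_i g_i / \sum_i c_i}, where the denominator counts only reads
#' belonging to included taxa.
#'
#' @param counts count vector of one sample (aligned to `taxa`).
#' @param taxa rank-resolved taxa data frame ([parse_taxon_labels()]).
#' @param ref a `gene_reference`.
#' @return list with `agn` (genes/organism) and `fraction_used` (included
#'   reads / total reads).
#' @examples
#' # two species with 2000 and 4000 genes at counts 10 and 30 -> AGN 3500
#' @export
compute_agn <- function(counts, taxa, ref) {
  stopifnot(length(counts) == nrow(taxa), nrow(ref) > 0)
  genes <- rep(NA_real_, nrow(taxa))
  sp <- !is.na(taxa$resolution_rank) & taxa$resolution_rank == "species"
  ge <- !is.na(taxa$resolution_rank) & taxa$resolution_rank == "genus"
  sp_ref <- ref[ref$rank == "species", ]
  ge_ref <- ref[ref$rank == "genus", ]
  genes[sp] <- sp_ref$mean_gene_count[match(taxa$species[sp], sp_ref$name)]
  genes[ge] <- ge_ref$mean_gene_count[match(taxa$genus[ge], ge_ref$name)]
  inc <- !is.na(genes) & counts > 0
  if (!any(inc)) {
    stop("no taxon matched the gene reference; unmatched labels: ",
         paste(head(taxa$label[counts > 0], 5), collapse = ", "))
  }
  agn <- sum(counts[inc] * genes[inc]) / sum(counts[inc])
  list(agn = agn, fraction_used = sum(counts[inc]) / sum(counts))
}

#' Bacteroidetes:Firmicutes ratio of a sample
#'
#' @param counts count vector of one sample.
#' @param taxa taxa data frame with a `phylum` column.
#' @param zero_firmicutes `"error"` (default) or `"inf"`: behaviour when the
#'   sample has no Firmicutes reads.
#' @return total Bacteroidetes reads / total Firmicutes reads.
#' @export
compute_bf_ratio <- function(counts, taxa,
                             zero_firmicutes = c("error", "inf")) {
  zero_firmicutes <- match.arg(zero_firmicutes)
  b <- sum(counts[!is.na(taxa$phylum) & taxa$phylum == "Bacteroidetes"])
  f <- sum(counts[!is.na(taxa$phylum) & taxa$phylum == "Firmicutes"])
  if (f == 0) {
    if (zero_firmicutes == "error") stop("no Firmicutes reads in sample")
    return(Inf)
  }
  b / f
}

#' Per-sample community statistics
#'
#' Computes Shannon alpha diversity, AGN (with the fraction of reads used)
#' and the B:F ratio for every sample of a table.
#'
#' @param tbl an `abundance_table` (rarefied for comparability of alpha).
#' @param ref a `gene_reference`.
#' @param zero_firmicutes passed to [compute_bf_ratio()].
#' @return data frame: sample_id, alpha_shannon, agn, fraction_used,
#'   bf_ratio.
#' @export
community_stats <- function(tbl, ref, zero_firmicutes = "error") {
  rows <- lapply(seq_len(nrow(tbl$counts)), function(i) {
    cts <- tbl$counts[i, ]
    a <- compute_agn(cts, tbl$taxa, ref)
    data.frame(sample_id = rownames(tbl$counts)[i],
               alpha_shannon = shannon(cts),
               agn = a$agn, fraction_used = a$fraction_used,
               bf_ratio = compute_bf_ratio(cts, tbl$taxa, zero_firmicutes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialise a fitted DMM model as JSON
#' @param model a `dmm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmm_model <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, weights = model$weights,
         taxa = model$taxa, alphas = model$alphas,
         medoids = model$medoids, fit_score = model$fit_score),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
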