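# Rarefaction, alpha diversity, compositional transforms and the
# non-phylogenetic beta-diversity metrics.

#' Rarefy an abundance table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (a single draw; the seed is recorded in the result).  Samples with
#' fewer than `depth` reads are dropped with a warning and listed in the
#' `dropped` attribute.
#'
#' @param tbl an `abundance_table`.
#' @param depth target depth; defaults to the minimum sample read total.
#' @param seed integer seed for the subsampling draw.
#' @return a rarefied `abundance_table` with attributes `depth`, `seed` and
#'   `dropped`.
#' @export
rarefy <- function(tbl, depth = NULL, seed = 1L) {
  stopifnot(inherits(tbl, "abundance_table"))
  totals <- rowSums(tbl$counts)
  depth <- depth %||% min(totals)
  if (depth <= 0) stop("rarefaction depth must be positive")
  dropped <- rownames(tbl$counts)[totals < depth]
  if (length(dropped)) {
    warning(length(dropped), " sample(s) below depth ", depth, " dropped")
    tbl <- subset_table(tbl, samples = which(totals >= depth))
  }
  # rrarefy warns whenever the smallest count exceeds 1; integrality is
  # already enforced by the abundance_table contract
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(tbl$counts, depth)))
  res <- abundance_table(out, tbl$taxa)
  attr(res, "depth") <- depth
  attr(res, "seed") <- seed
  attr(res, "dropped") <- dropped
  res
}

#' Shannon index of one count vector
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats over taxa with positive counts.
#'
#' @param counts non-negative numeric vector with positive total.
#' @return Shannon entropy in nats.
#' @examples
#' shannon(c(1, 1, 2))  # ~1.0397
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero sample has no Shannon index")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, in \[0, 1\].
#'
#' @param x,y equal-length non-negative vectors (typically rarefied counts).
#' @return dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 0, 6), c(1, 3, 4))  # 0.375
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples are empty")
  sum(abs(x - y)) / tot
}

#' Centred log-ratio transform of an abundance table
#'
#' Zeros are replaced by `pseudocount` before taking logs; each sample's log
#' abundances are centred by their mean, so rows of the result sum to zero
#' and the transform is invariant to per-sample scaling.
#'
#' @param tbl an `abundance_table` (or a count matrix, samples in rows).
#' @param pseudocount positive value substituted for zero counts (default 0.5).
#' @return numeric matrix of clr values, samples x taxa.
#' @export
clr_transform <- function(tbl, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  m <- if (inherits(tbl, "abundance_table")) tbl$counts else as.matrix(tbl)
  storage.mode(m) <- "double"
  m[m == 0] <- pseudocount
  lg <- log(m)
  sweep(lg, 1, rowMeans(lg))
}

#' Aitchison distance between two samples
#'
#' Euclidean distance between clr-transformed compositions (zeros replaced by
#' `pseudocount`).
#'
#' @param x,y equal-length non-negative count vectors.
#' @param pseudocount zero replacement (default 0.5).
#' @return non-negative distance.
#' @export
aitchison <- function(x, y, pseudocount = 0.5) {
  z <- clr_transform(rbind(x, y), pseudocount)
  sqrt(sum((z[1, ] - z[2, ])^2))
}

#' Jaccard distance between two samples (presence/absence)
#'
#' \eqn{1 - |A \cap B| / |A \cup B|} on the supports of `x` and `y`; intended
#' for rarefied counts.
#'
#' @param x,y equal-length non-negative count vectors.
#' @return distance in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  a <- x > 0
  b <- y > 0
  u <- sum(a | b)
  if (u == 0) stop("both samples are empty")
  1 - sum(a & b) / u
}

#' Inverse Pearson correlation distance
#'
#' \eqn{1 - r(x, y)}; ranges over \[0, 2\].
#'
#' @param x,y equal-length numeric vectors, neither constant.
#' @return distance in \[0, 2\].
#' @export
inverse_pearson <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector has no correlation")
  1 - cor(x, y)
}

#' Pairwise distance matrix under a named metric
#'
#' Bray-Curtis and Jaccard are delegated to [vegan::vegdist()] (Jaccard on
#' presence/absence); Aitchison is the Euclidean distance on clr values;
#' inverse Pearson is `1 - cor`.
#'
#' @param tbl an `abundance_table`.
#' @param metric one of `"bray_curtis"`, `"aitchison"`, `"jaccard"`,
#'   `"inverse_pearson"`.
#' @param pseudocount zero replacement for the Aitchison metric.
#' @return symmetric numeric matrix with sample ids as dimnames and zero
#'   diagonal.
#' @export
pairwise_distances <- function(tbl, metric = c("bray_curtis", "aitchison",
                                               "jaccard", "inverse_pearson"),
                               pseudocount = 0.5) {
  metric <- match.arg(metric)
  m <- tbl$counts
  d <- switch(metric,
    bray_curtis = as.matrix(vegan::vegdist(m, method = "bray")),
    jaccard = as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE)),
    aitchison = as.matrix(stats::dist(clr_transform(tbl, pseudocount))),
    inverse_pearson = 1 - stats::cor(t(m))
  )
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Write a distance matrix as square TSV
#' @param d symmetric labelled matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
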