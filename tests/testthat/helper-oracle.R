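# Independent oracles used to pin expected values.

# Exact probability of every ordered selection of `r` items without
# replacement with weights w, aggregated to subset probabilities.
subset_probs <- function(w, r) {
  n <- length(w)
  subsets <- utils::combn(n, r)
  probs <- apply(subsets, 2, function(s) {
    perms <- all_perms(s)
    sum(vapply(perms, function(ord) {
      rem <- sum(w)
      p <- 1
      for (i in ord) {
        p <- p * w[i] / rem
        rem <- rem - w[i]
      }
      p
    }, numeric(1)))
  })
  list(subsets = subsets, probs = probs)
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# All compositions of m into k non-negative parts.
compositions <- function(m, k) {
  if (k == 1) return(matrix(m, 1, 1))
  out <- NULL
  for (first in 0:m) {
    rest <- compositions(m - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Exact distribution of one null community assembly: richness taxa chosen
# without replacement (prevalence weights), one read each, remaining reads
# multinomial with mean-abundance weights.  Returns count matrix (rows are
# outcomes over the full taxon set) and outcome probabilities.
null_assembly_distribution <- function(richness, depth, prevalence,
                                       mean_abundance) {
  sel <- subset_probs(prevalence, richness)
  rows <- list(); probs <- numeric(0)
  for (sidx in seq_along(sel$probs)) {
    s <- sel$subsets[, sidx]
    w <- mean_abundance[s] / sum(mean_abundance[s])
    comps <- compositions(depth - richness, richness)
    for (ci in seq_len(nrow(comps))) {
      cts <- numeric(length(prevalence))
      cts[s] <- 1 + comps[ci, ]
      p <- sel$probs[sidx] * stats::dmultinom(comps[ci, ], prob = w)
      rows <- c(rows, list(cts))
      probs <- c(probs, p)
    }
  }
  list(counts = do.call(rbind, rows), probs = probs)
}

# Exact RC value for a pair inside a context table, by full enumeration of
# the null distribution of Bray-Curtis values.
exact_rc <- function(x, y, context_counts, tol = 1e-10) {
  prevalence <- colMeans(context_counts > 0)
  mean_abund <- colMeans(context_counts / rowSums(context_counts))
  obs <- sum(abs(x - y)) / sum(x + y)
  dx <- null_assembly_distribution(sum(x > 0), sum(x), prevalence, mean_abund)
  dy <- null_assembly_distribution(sum(y > 0), sum(y), prevalence, mean_abund)
  p_below <- 0; p_tie <- 0
  for (i in seq_along(dx$probs)) {
    for (j in seq_along(dy$probs)) {
      bc <- sum(abs(dx$counts[i, ] - dy$counts[j, ])) /
        sum(dx$counts[i, ] + dy$counts[j, ])
      pij <- dx$probs[i] * dy$probs[j]
      if (bc < obs - tol) p_below <- p_below + pij
      else if (abs(bc - obs) <= tol) p_tie <- p_tie + pij
    }
  }
  list(rc = 2 * (p_below + 0.5 * p_tie) - 1,
       p = p_below + 0.5 * p_tie)
}

# Adjusted Rand index between two labelings (closed-form from the
# contingency table; independent of any clustering code under test).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (mx - expected)
}
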