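# Small in-code fixtures shared across test files.

# Abundance table from a bare count matrix; taxa get auto-generated
# species-resolved lineages unless labels are supplied.
make_table <- function(counts, labels = NULL, sample_prefix = "s") {
  counts <- as.matrix(counts)
  rn <- rownames(counts)
  if (is.null(rn) || any(!nzchar(rn)) || anyDuplicated(rn)) {
    rownames(counts) <- paste0(sample_prefix, seq_len(nrow(counts)))
  }
  if (is.null(labels)) {
    labels <- sprintf("p__Firmicutes;g__G%02d;s__sp%02d",
                      seq_len(ncol(counts)), seq_len(ncol(counts)))
  }
  abundance_table(counts, labels)
}

# Records drawn from a multivariate normal with covariance `sigma`, with a
# random 3-level intervention column.
simulate_mvn_records <- function(n, sigma, seed,
                                 names = c("response", "alpha_baseline",
                                           "agn_baseline")) {
  set.seed(seed)
  L <- chol(sigma)
  z <- matrix(rnorm(n * ncol(sigma)), n) %*% L
  d <- as.data.frame(z)
  names(d) <- names
  d$intervention <- sample(c("A", "B", "C"), n, replace = TRUE)
  d
}

# Paired design for n subjects whose samples are named <subj>_T0 / <subj>_T1.
make_paired_design <- function(subjects, intervention = "A") {
  study_design(sample_id = c(paste0(subjects, "_T0"), paste0(subjects, "_T1")),
               subject_id = rep(subjects, 2),
               intervention = intervention,
               timepoint = rep(c("baseline", "after"), each = length(subjects)))
}
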