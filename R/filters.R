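# Sample- and taxon-level filters applied before diversity analysis.

#' Drop shallow samples
#'
#' Keeps samples whose read total is strictly greater than `min_reads`
#' (the conventional post-denoising depth cut-off is 3000 reads, i.e. samples
#' with >3000 reads are retained).
#'
#' @param tbl an `abundance_table`.
#' @param min_reads non-negative integer depth threshold (strict).
#' @return the filtered `abundance_table`.
#' @export
filter_samples_by_depth <- function(tbl, min_reads = 3000) {
  stopifnot(inherits(tbl, "abundance_table"), min_reads >= 0)
  keep <- rowSums(tbl$counts) > min_reads
  if (!any(keep)) stop("depth filter removed all samples (min_reads = ",
                       min_reads, ")")
  subset_table(tbl, samples = which(keep))
}

#' Drop rare taxa
#'
#' A taxon is retained iff its count exceeds `count_thr` reads in at least
#' `sample_thr` samples; equivalently, taxa with abundance > `count_thr` reads
#' in fewer than `sample_thr` samples are excluded.  Both comparisons are
#' strict, so a taxon with 21 reads in exactly 20 samples survives the default
#' 20/20 rule.
#'
#' @param tbl an `abundance_table`.
#' @param count_thr per-sample read count a taxon must exceed (default 20).
#' @param sample_thr minimum number of qualifying samples (default 20).
#' @return the filtered `abundance_table`.
#' @export
filter_rare_taxa <- function(tbl, count_thr = 20, sample_thr = 20) {
  stopifnot(inherits(tbl, "abundance_table"),
            count_thr >= 0, sample_thr >= 0)
  qualifying <- colSums(tbl$counts > count_thr)
  keep <- qualifying >= sample_thr
  if (!any(keep)) stop("taxa filter removed all taxa")
  subset_table(tbl, taxa = which(keep))
}
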