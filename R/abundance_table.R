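# The abundance table: an integer count matrix (samples x taxa) plus the
# parsed taxa table.  Counts are always stored raw; relative abundances are
# derived on demand (rarefaction and the null model need integer reads).

#' Construct an abundance table
#'
#' @param counts non-negative integer matrix, samples in rows (rownames are
#'   sample ids), taxa in columns.
#' @param taxa data frame as returned by [parse_taxon_labels()], one row per
#'   column of `counts`; alternatively a character vector of lineage strings.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix with sample ids as rownames and canonical taxon
#'   labels as colnames) and `taxa` (the rank-resolved taxa data frame).
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), NULL))
#' abundance_table(m, c("p__Bacteroidetes;g__Bacteroides", "p__Firmicutes;g__Blautia"))
#' @export
abundance_table <- function(counts, taxa) {
  if (is.character(taxa)) taxa <- parse_taxon_labels(taxa)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is_wholenumber(counts) || any(counts < 0)) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- taxa$label
  obj <- structure(list(counts = counts, taxa = taxa),
                   class = "abundance_table")
  validate_abundance_table(obj)
}

#' Validate an abundance table's invariants
#'
#' Checks integrality and non-negativity of counts, uniqueness of sample ids
#' and taxon labels, strictly positive sample read totals, and agreement
#' between the count matrix and the taxa table.
#'
#' @param tbl an `abundance_table`.
#' @return `tbl`, invisibly usable, after passing all checks.
#' @export
validate_abundance_table <- function(tbl) {
  stopifnot(inherits(tbl, "abundance_table"))
  counts <- tbl$counts
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("sample ids must be present and unique")
  }
  if (anyDuplicated(tbl$taxa$label)) stop("duplicate taxon labels")
  if (ncol(counts) != nrow(tbl$taxa)) stop("counts/taxa dimension mismatch")
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) <= 0)) {
    stop("samples with zero total reads: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  }
  tbl
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa;", "read depth", min(rowSums(x$counts)), "-",
      max(rowSums(x$counts)), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Sample ids of an abundance table
#' @param tbl an `abundance_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(tbl) rownames(tbl$counts)

#' Subset an abundance table by samples and/or taxa
#' @param tbl an `abundance_table`.
#' @param samples sample ids or indices to keep (default all).
#' @param taxa taxon labels or column indices to keep (default all).
#' @return the subsetted `abundance_table`.
#' @export
subset_table <- function(tbl, samples = NULL, taxa = NULL) {
  counts <- tbl$counts
  tx <- tbl$taxa
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) {
    idx <- if (is.character(taxa)) match(taxa, tx$label) else taxa
    counts <- counts[, idx, drop = FALSE]
    tx <- tx[idx, , drop = FALSE]
    rownames(tx) <- NULL
  }
  abundance_table(counts, tx)
}

#' Relative abundances of an abundance table
#' @param tbl an `abundance_table`.
#' @return numeric matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(tbl) {
  tbl$counts / rowSums(tbl$counts)
}

#' Aggregate counts to a higher taxonomic rank
#'
#' Sums counts over taxa sharing the same lineage down to `rank` (enterotyping
#' operates on genus-level tables while most analyses stay at species level).
#' Taxa unresolved at `rank` are pooled per deepest resolved lineage.
#'
#' @param tbl an `abundance_table`.
#' @param rank target rank, one of phylum...genus.
#' @return an `abundance_table` at the requested rank.
#' @export
aggregate_taxa <- function(tbl, rank = "genus") {
  rank <- match.arg(rank, TAXON_RANKS)
  depth <- match(rank, TAXON_RANKS)
  tx <- tbl$taxa
  key_df <- tx[, TAXON_RANKS[seq_len(depth)], drop = FALSE]
  key <- canonical_taxon_label(
    cbind(key_df,
          matrix(NA_character_, nrow(tx), length(TAXON_RANKS) - depth,
                 dimnames = list(NULL, TAXON_RANKS[-seq_len(depth)]))))
  groups <- split(seq_len(nrow(tx)), key)
  counts <- vapply(groups, function(ix) {
    as.integer(rowSums(tbl$counts[, ix, drop = FALSE]))
  }, integer(nrow(tbl$counts)))
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  rownames(counts) <- rownames(tbl$counts)
  abundance_table(counts, parse_taxon_labels(names(groups)))
}

# ---- readers / writers -----------------------------------------------------

#' Read an abundance table from TSV or BIOM
#'
#' The TSV layout is the conventional taxa-by-samples export: first column
#' `taxon` holding lineage strings, remaining columns one per sample, integer
#' cells.  BIOM files (JSON or HDF5) are read through the biomformat package
#' when it is installed.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return an `abundance_table`.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    counts <- t(m)
    return(abundance_table(counts, rownames(m)))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "taxon") {
    stop("malformed abundance table header: first column must be 'taxon'")
  }
  ids <- names(df)[-1]
  if (anyDuplicated(ids)) stop("duplicate sample ids in header")
  body <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric cells in abundance table body")
  if (!is_wholenumber(body)) stop("non-integer counts in abundance table")
  counts <- t(body)
  rownames(counts) <- ids
  abundance_table(counts, df$taxon)
}

#' Write an abundance table as TSV
#' @param tbl an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tbl, path) {
  df <- data.frame(taxon = tbl$taxa$label, t(tbl$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a study design table
#'
#' Binds per-sample metadata: subject, intervention, timepoint and an
#' optional enterotype label.  Enforces that every subject observed after an
#' intervention also has a baseline sample and that (subject, timepoint) is
#' unique within an intervention.
#'
#' @param sample_id,subject_id,intervention character vectors.
#' @param timepoint character vector with values `"baseline"` or `"after"`.
#' @param enterotype optional character vector.
#' @return a `study_design` data frame.
#' @export
study_design <- function(sample_id, subject_id, intervention, timepoint,
                         enterotype = NULL) {
  d <- data.frame(sample_id = as.character(sample_id),
                  subject_id = as.character(subject_id),
                  intervention = as.character(intervention),
                  timepoint = as.character(timepoint),
                  stringsAsFactors = FALSE)
  if (!is.null(enterotype)) d$enterotype <- as.character(enterotype)
  validate_study_design(d)
}

#' Validate a study design's invariants
#' @param d a `study_design` data frame.
#' @return `d` after passing checks.
#' @export
validate_study_design <- function(d) {
  stopifnot(all(c("sample_id", "subject_id", "intervention", "timepoint")
                %in% names(d)))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in design")
  if (!all(d$timepoint %in% c("baseline", "after"))) {
    stop("timepoint must be 'baseline' or 'after'")
  }
  key <- paste(d$intervention, d$subject_id, d$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (intervention, subject, timepoint) rows")
  }
  aft <- d[d$timepoint == "after", ]
  base_key <- paste(d$intervention, d$subject_id)[d$timepoint == "baseline"]
  missing <- !(paste(aft$intervention, aft$subject_id) %in% base_key)
  if (any(missing)) {
    stop("subjects with an 'after' sample but no baseline: ",
         paste(unique(aft$subject_id[missing]), collapse = ", "))
  }
  class(d) <- c("study_design", "data.frame")
  d
}

#' Read a study design from TSV
#' @param path TSV with columns sample_id, subject_id, intervention, timepoint
#'   and optionally enterotype.
#' @return a `study_design` data frame.
#' @export
read_study_design <- function(path) {
  validate_study_design(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a study design as TSV
#' @param d a `study_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_design <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a taxon-to-gene-count reference
#'
#' Maps species- or genus-rank taxon names to the mean number of genes in the
#' corresponding genome assemblies; used by [compute_agn()].
#'
#' @param rank character vector, `"species"` or `"genus"`.
#' @param name taxon name at that rank.
#' @param mean_gene_count positive numeric vector.
#' @return a `gene_reference` data frame.
#' @export
gene_reference <- function(rank, name, mean_gene_count) {
  stopifnot(all(rank %in% c("species", "genus")),
            all(is.finite(mean_gene_count)), all(mean_gene_count > 0))
  d <- data.frame(rank = rank, name = as.character(name),
                  mean_gene_count = as.numeric(mean_gene_count),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d[, c("rank", "name")])) stop("duplicate reference entries")
  class(d) <- c("gene_reference", "data.frame")
  d
}

#' Read a gene-count reference from TSV
#' @param path TSV with columns rank, name, mean_gene_count.
#' @return a `gene_reference` data frame.
#' @export
read_gene_reference <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gene_reference(df$rank, df$name, df$mean_gene_count)
}

#' Write a gene-count reference as TSV
#' @param ref a `gene_reference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_reference <- function(ref, path) {
  write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
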