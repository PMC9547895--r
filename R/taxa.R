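# Rank-resolved taxon labels.
#
# Amplicon tables label taxa with lineage strings in one of two common
# dialects: semicolon- or pipe-delimited, rank-prefixed fields
# ("p__Firmicutes;c__Clostridia;...;g__Blautia;s__unclassified").  Labels are
# parsed once into a taxa data frame and stored canonically (semicolon
# delimited, rank prefixed).

TAXON_RANKS <- c("phylum", "class", "order", "family", "genus", "species")
RANK_PREFIX <- c(phylum = "p", class = "c", order = "o", family = "f",
                 genus = "g", species = "s")

#' Parse lineage strings into a rank-resolved taxa table
#'
#' Accepts semicolon- or pipe-delimited lineage strings with single-letter
#' rank prefixes (`p__`, `c__`, `o__`, `f__`, `g__`, `s__`; a leading `k__`
#' kingdom field is tolerated and dropped).  Fields that are empty or read
#' "unclassified" are treated as unresolved.
#'
#' @param labels character vector of lineage strings.
#' @return A data frame with one row per label: the canonical `label`, one
#'   column per rank from phylum to species (NA when unresolved), and
#'   `resolution_rank`, the deepest resolved rank.
#' @examples
#' parse_taxon_labels("p__Bacteroidetes;g__Bacteroides;s__fragilis")
#' @export
parse_taxon_labels <- function(labels) {
  stopifnot(is.character(labels), length(labels) > 0)
  if (any(!nzchar(labels))) stop("empty taxon label")
  parts <- strsplit(labels, "[;|]")
  out <- matrix(NA_character_, length(labels), length(TAXON_RANKS),
                dimnames = list(NULL, TAXON_RANKS))
  for (i in seq_along(parts)) {
    for (field in trimws(parts[[i]])) {
      if (!nzchar(field)) next
      if (!grepl("^[a-z]__", field)) {
        stop("taxon label field without rank prefix: '", field, "'")
      }
      pre <- substr(field, 1, 1)
      if (pre == "k") next
      rank <- names(RANK_PREFIX)[match(pre, RANK_PREFIX)]
      if (is.na(rank)) stop("unknown rank prefix '", pre, "__' in '", field, "'")
      value <- substr(field, 4, nchar(field))
      if (nzchar(value) && tolower(value) != "unclassified") {
        out[i, rank] <- value
      }
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df$resolution_rank <- apply(out, 1, function(r) {
    res <- which(!is.na(r))
    if (length(res)) TAXON_RANKS[max(res)] else NA_character_
  })
  df$label <- canonical_taxon_label(df)
  df[, c("label", TAXON_RANKS, "resolution_rank")]
}

# Canonical label: rank-prefixed resolved fields joined by ";", unresolved
# trailing ranks dropped, internal gaps written as "<prefix>__unclassified".
canonical_taxon_label <- function(taxa) {
  apply(as.matrix(taxa[, TAXON_RANKS]), 1, function(r) {
    deepest <- max(c(0, which(!is.na(r))))
    if (deepest == 0) return("p__unclassified")
    fields <- vapply(seq_len(deepest), function(k) {
      v <- if (is.na(r[k])) "unclassified" else r[k]
      paste0(RANK_PREFIX[[TAXON_RANKS[k]]], "__", v)
    }, character(1))
    paste(fields, collapse = ";")
  })
}
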