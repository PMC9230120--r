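# Confidence labels from precomputed homology-search evidence. The search
# itself (BLAST/DIAMOND against a large protein database) is run offline;
# this module only consumes its standard 12-column tabular output.

#' Parse a tabular homology-hit file (BLAST/DIAMOND outfmt-6 dialect)
#'
#' Expects tab-separated rows with at least 12 columns and the e-value in
#' column 11 (1-based). Malformed rows (too few columns, non-numeric
#' e-value) are skipped with a warning reporting the count.
#'
#' @param path Path to the TSV.
#' @param taxon_column Optional 1-based index of an extra column carrying
#'   the subject taxon name (e.g. outfmt "6 std staxids sscinames").
#' @return Data.frame with columns `query_id`, `subject_id`,
#'   `subject_taxon`, `evalue`.
#' @export
parse_homology_table <- function(path, taxon_column = NULL) {
  if (!file.exists(path)) stop("homology table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("homology table is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 12L
  evalue <- rep(NA_real_, length(fields))
  evalue[ok] <- suppressWarnings(
    as.numeric(vapply(fields[ok], `[[`, character(1), 11L)))
  ok <- ok & !is.na(evalue) & evalue >= 0
  if (!any(ok)) stop("no parseable rows in ", path)
  if (any(!ok)) warning(sum(!ok), " malformed row(s) skipped in ", path)
  fields <- fields[ok]
  taxon <- if (is.null(taxon_column)) rep("", length(fields)) else
    vapply(fields, function(f) if (length(f) >= taxon_column) f[[taxon_column]] else "",
           character(1))
  data.frame(query_id = vapply(fields, `[[`, character(1), 1L),
             subject_id = vapply(fields, `[[`, character(1), 2L),
             subject_taxon = taxon,
             evalue = evalue[which(ok)],
             stringsAsFactors = FALSE)
}

#' Assign high/low-confidence labels from homology hits
#'
#' A gene is labelled 1 (high confidence, conserved) iff it has at least
#' one hit with e-value strictly below `evalue_max` whose subject taxon is
#' not excluded; genes with no qualifying hit (including genes with no
#' hits at all) are labelled 0. Taxon exclusion is an exact,
#' case-insensitive match on `subject_taxon`; for hits without a taxon
#' annotation the excluded names are matched (case-insensitively) against
#' the subject id/description instead, so self-hits can still be removed.
#'
#' @param gene_ids Character vector of gene ids to label (must be unique).
#' @param hits Data.frame from [parse_homology_table()].
#' @param evalue_max Strict e-value threshold (hits at exactly this value
#'   do not count).
#' @param excluded_taxa Character vector of taxon names to ignore
#'   (typically the annotated species itself).
#' @return Data.frame with columns `gene_id`, `label`, `supporting_hits`.
#' @export
assign_labels <- function(gene_ids, hits, evalue_max = 0.01,
                          excluded_taxa = character()) {
  stopifnot(evalue_max > 0)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: '", gene_ids[duplicated(gene_ids)][1L], "'")
  qualifying <- hits$evalue < evalue_max
  if (length(excluded_taxa)) {
    excl_lc <- tolower(excluded_taxa)
    has_taxon <- nzchar(hits$subject_taxon)
    excluded <- logical(nrow(hits))
    excluded[has_taxon] <- tolower(hits$subject_taxon[has_taxon]) %in% excl_lc
    if (any(!has_taxon)) {
      pat <- paste(excl_lc, collapse = "|")
      excluded[!has_taxon] <- grepl(pat, tolower(hits$subject_id[!has_taxon]),
                                    fixed = FALSE)
    }
    qualifying <- qualifying & !excluded
  }
  counts <- table(factor(hits$query_id[qualifying], levels = gene_ids))
  data.frame(gene_id = gene_ids,
             label = as.integer(counts > 0L),
             supporting_hits = as.integer(counts),
             stringsAsFactors = FALSE)
}
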