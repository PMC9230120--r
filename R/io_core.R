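#' Read a FASTA file into a record table
#'
#' Reads a CDS or protein FASTA and validates the sequences against the
#' requested alphabet. DNA accepts the four bases plus IUPAC ambiguity
#' codes; protein accepts the 20 standard residues plus `X` and `*`.
#' Sequences are uppercased; record order is preserved; any description
#' after the first whitespace in the header is kept.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A data.frame with columns `id`, `seq`, `desc`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "acgt"), f)
#' read_fasta(f, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id in ", path, ": '", dup, "'")
  }
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "dna") DNA_ALPHABET else c(AA_STANDARD, "X", "*")
  pattern <- paste0("[^", paste(gsub("\\*", "\\\\*", allowed), collapse = ""), "]")
  bad <- regexpr(pattern, seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid ", alphabet, " character '",
         substr(seqs[i], bad[i], bad[i]), "' in record '", ids[i],
         "' at position ", bad[i])
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1L]], "'")
  }
  data.frame(id = ids, seq = unname(seqs), desc = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data.frame with columns `id` and `seq` (and optional
#'   `desc`), as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Pair CDS and protein records by gene id
#'
#' Inner-joins the two collections on `id` and reports how many ids were
#' present on one side only. Where a CDS/protein pair has inconsistent
#' lengths (protein length outside `floor(len(cds)/3)` minus 0 or 1,
#' allowing for a dropped trailing stop) a warning names the gene.
#'
#' @param cds Data.frame from `read_fasta(..., "dna")`.
#' @param proteins Data.frame from `read_fasta(..., "protein")`.
#' @return Data.frame with columns `gene_id`, `cds`, `protein`.
#' @export
pair_records <- function(cds, proteins) {
  if (missing(proteins) || is.null(proteins) || missing(cds) || is.null(cds)) {
    stop("both a CDS and a protein collection are required")
  }
  common <- intersect(cds$id, proteins$id)
  if (length(common) == 0L) stop("no gene ids shared between CDS and protein files")
  only_cds <- setdiff(cds$id, common)
  only_prot <- setdiff(proteins$id, common)
  if (length(only_cds))
    warning(length(only_cds), " CDS record(s) without a protein partner (e.g. '",
            only_cds[1L], "')")
  if (length(only_prot))
    warning(length(only_prot), " protein record(s) without a CDS partner (e.g. '",
            only_prot[1L], "')")
  ci <- match(common, cds$id)
  pi <- match(common, proteins$id)
  out <- data.frame(gene_id = common,
                    cds = cds$seq[ci],
                    protein = sub("\\*$", "", proteins$seq[pi]),
                    stringsAsFactors = FALSE)
  expected <- nchar(out$cds) %/% 3L
  plen <- nchar(out$protein)
  off <- !(plen == expected | plen == expected - 1L)
  if (any(off))
    warning(sum(off), " pair(s) with inconsistent CDS/protein lengths (e.g. '",
            out$gene_id[which(off)[1L]], "')")
  out
}

#' Run configuration
#'
#' Bundles the tunable knobs shared across the pipeline. All randomness in
#' the package flows from `random_seed` (stochastic operations also accept
#' an explicit seed argument that defaults to it).
#'
#' @param train_fraction Fraction of rows assigned to the training split.
#' @param random_seed Integer master seed.
#' @param entropy_k k-mer size for the Shannon entropy feature (codons by
#'   default).
#' @param skew_window Window width in bp for the GC/AT skew profiles.
#' @param evalue_max Strict e-value threshold for homology labeling.
#' @param excluded_taxa Taxa whose hits never count as evidence (the
#'   annotated species itself, typically).
#' @param cai_reference `"auto"` (codon usage computed from the
#'   high-confidence partition) or a path to a codon-usage TSV.
#' @param tune_iterations Bayesian-search iterations.
#' @param inner_cv_folds Folds of the inner cross-validation used during
#'   tuning.
#' @return A list of class `run_config`.
#' @export
run_config <- function(train_fraction = 0.80, random_seed = 42L,
                       entropy_k = 3L, skew_window = 100L,
                       evalue_max = 0.01, excluded_taxa = character(),
                       cai_reference = "auto",
                       tune_iterations = 50L, inner_cv_folds = 5L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            evalue_max > 0, skew_window >= 1, entropy_k >= 1,
            tune_iterations >= 1, inner_cv_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 random_seed = as.integer(random_seed),
                 entropy_k = as.integer(entropy_k),
                 skew_window = as.integer(skew_window),
                 evalue_max = evalue_max,
                 excluded_taxa = as.character(excluded_taxa),
                 cai_reference = cai_reference,
                 tune_iterations = as.integer(tune_iterations),
                 inner_cv_folds = as.integer(inner_cv_folds)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a JSON file whose keys match [run_config()]
#'   arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown configuration key(s): ",
                          paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a feature table as TSV
#'
#' One row per gene: `gene_id`, the feature columns in a fixed order, and
#' (if present) `label`. Numeric values are written with 7 significant
#' digits — the least precision that still round-trips through
#' [read_feature_table()] within a 1e-6 relative tolerance.
#'
#' @param rows Data.frame of features (plus `gene_id` and optionally
#'   `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "label"
  out[num] <- lapply(out[num], function(x) formatC(signif(x, 7), format = "g",
                                                   digits = 7))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the TSV.
#' @return Data.frame with the original column order.
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
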