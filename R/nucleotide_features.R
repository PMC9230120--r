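# 14 per-gene nucleotide features. Conventions shared by all operations:
# IUPAC ambiguity codes are accepted, excluded from compositional numerators
# and denominators, and counted in sequence length; codon-based features
# drop a trailing partial codon.

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

check_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("expected a single non-empty DNA string")
  invisible(seq)
}

#' GC content (percent)
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes are excluded from
#' both counts.
#'
#' @param seq DNA string.
#' @return GC percentage in `[0, 100]`.
#' @examples gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  check_dna(seq)
  ch <- seq_chars(seq)
  unamb <- sum(ch %in% c("A", "C", "G", "T"))
  if (unamb == 0L) stop("no unambiguous bases in sequence")
  100 * sum(ch %in% c("G", "C")) / unamb
}

#' GC content at the three codon positions
#'
#' GC percentage restricted to bases at 1-based positions k, k+3, k+6, ...
#' for k = 1, 2, 3. Bases of a trailing partial codon still count at their
#' position.
#'
#' @param seq DNA string of length >= 3.
#' @return Numeric vector `c(gc_pos1, gc_pos2, gc_pos3)`.
#' @export
gc_by_codon_position <- function(seq) {
  check_dna(seq)
  ch <- seq_chars(seq)
  if (length(ch) < 3L) stop("sequence shorter than one codon")
  pos <- (seq_along(ch) - 1L) %% 3L
  out <- vapply(0:2, function(k) {
    sub <- ch[pos == k]
    den <- sum(sub %in% c("A", "C", "G", "T"))
    if (den == 0L) 0 else 100 * sum(sub %in% c("G", "C")) / den
  }, numeric(1))
  names(out) <- c("gc_pos1", "gc_pos2", "gc_pos3")
  out
}

skew_window_bounds <- function(n, window) {
  k <- n %/% window
  rem <- n - k * window
  if (k == 0L) return(cbind(start = 1L, end = n))
  starts <- seq(1L, by = window, length.out = k)
  ends <- starts + window - 1L
  if (rem >= window / 2) {
    starts <- c(starts, k * window + 1L)
    ends <- c(ends, n)
  } else {
    ends[k] <- n
  }
  cbind(start = starts, end = ends)
}

#' Windowed GC or AT skew heterogeneity
#'
#' Splits the sequence into consecutive non-overlapping windows (a final
#' partial window is kept when at least half a window long, otherwise
#' merged into the previous one), computes the per-window skew
#' `(G - C) / (G + C)` (or `(A - T) / (A + T)`), scoring 0 when the
#' denominator is zero, and returns the population standard deviation of
#' the window skews. A single window gives 0.
#'
#' @param seq DNA string.
#' @param window Window width in bp.
#' @param pair `"GC"` or `"AT"`.
#' @return Non-negative skew standard deviation.
#' @export
skew_stdev <- function(seq, window = 100L, pair = c("GC", "AT")) {
  check_dna(seq)
  pair <- match.arg(pair)
  stopifnot(window >= 1)
  ch <- seq_chars(seq)
  bounds <- skew_window_bounds(length(ch), as.integer(window))
  b1 <- if (pair == "GC") "G" else "A"
  b2 <- if (pair == "GC") "C" else "T"
  skews <- apply(bounds, 1L, function(b) {
    w <- ch[b[1L]:b[2L]]
    x <- sum(w == b1); y <- sum(w == b2)
    if (x + y == 0L) 0 else (x - y) / (x + y)
  })
  sqrt(mean((skews - mean(skews))^2))
}

#' GC-based DNA melting temperature (deg C)
#'
#' `Tm = 81.5 + 0.41 * GC% + 16.6 * log10([Na+]) - 600 / N` with
#' `[Na+] = 0.05 M` and `N` the sequence length. A GC-only estimate is
#' used deliberately: nearest-neighbour models are length-dependent and
#' parameter-heavy, while this form keeps Tm a smooth function of
#' composition.
#'
#' @param seq DNA string.
#' @param na_molar Monovalent salt concentration (M).
#' @return Estimated melting temperature in degrees Celsius.
#' @examples melting_temperature(strrep("AGCT", 150))  # 79.40
#' @export
melting_temperature <- function(seq, na_molar = 0.05) {
  check_dna(seq)
  81.5 + 0.41 * gc_content(seq) + 16.6 * log10(na_molar) - 600 / nchar(seq)
}

#' Shannon entropy over non-overlapping k-mers (bits)
#'
#' Tokenizes into non-overlapping k-mers (default k = 3, i.e. codons;
#' trailing partial token dropped) and returns
#' `H = -sum p_i log2 p_i` over the token frequencies.
#'
#' @param seq DNA string of length >= k.
#' @param k Token size.
#' @return Entropy in bits, in `[0, 2k]` for unambiguous DNA.
#' @export
shannon_entropy <- function(seq, k = 3L) {
  check_dna(seq)
  stopifnot(k >= 1)
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than one ", k, "-mer")
  starts <- seq(1L, n - k + 1L, by = k)
  tokens <- substring(seq, starts, starts + k - 1L)
  p <- table(tokens) / length(tokens)
  -sum(p * log2(p))
}

#' DEFLATE compression ratio
#'
#' Ratio of compressed to raw byte size of the sequence under zlib DEFLATE
#' at the default level (6). Lower values indicate more repetitive
#' sequence; a ratio near 1 means incompressible.
#'
#' @param seq DNA string.
#' @return Compression ratio in `(0, ~1.1]`.
#' @export
compression_ratio <- function(seq) {
  check_dna(seq)
  length(memCompress(charToRaw(seq), type = "gzip")) / nchar(seq)
}

sense_codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  code[!code %in% "*"]
}

#' Codon usage counts from a set of coding sequences
#'
#' Counts complete, unambiguous codons across the input sequences.
#'
#' @param seqs Character vector of CDS strings.
#' @return Data.frame with columns `codon` (64 rows) and `count`.
#' @export
codon_usage <- function(seqs) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  counts <- stats::setNames(numeric(64), all_codons)
  for (s in seqs) {
    n3 <- (nchar(s) %/% 3L) * 3L
    if (n3 < 3L) next
    starts <- seq(1L, n3 - 2L, by = 3L)
    cod <- substring(s, starts, starts + 2L)
    cod <- cod[cod %in% all_codons]
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  data.frame(codon = all_codons, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Relative adaptiveness weights from a codon-usage reference
#'
#' Sharp-Li relative adaptiveness: within each synonymous family,
#' `w_c = f_c / max(f)`. Sense codons with zero reference count receive a
#' pseudo-count of 0.5 so weights stay positive.
#'
#' @param usage Codon-usage data.frame (`codon`, `count`), e.g. from
#'   [codon_usage()].
#' @return Named numeric vector of weights over the 61 sense codons.
#' @export
cai_weights <- function(usage) {
  stopifnot(all(c("codon", "count") %in% names(usage)))
  code <- sense_codon_table()
  f <- stats::setNames(usage$count, usage$codon)[names(code)]
  if (anyNA(f)) stop("codon-usage reference must cover all 61 sense codons")
  f[f == 0] <- 0.5
  w <- f
  for (aa in unique(code)) {
    fam <- names(code)[code == aa]
    w[fam] <- f[fam] / max(f[fam])
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness of the gene's sense codons
#' (stop codons, ambiguous codons and a trailing partial codon are
#' excluded).
#'
#' @param seq CDS string.
#' @param reference Either a codon-usage data.frame or a precomputed
#'   weight vector from [cai_weights()].
#' @return CAI in `(0, 1]`.
#' @export
codon_adaptation_index <- function(seq, reference) {
  check_dna(seq)
  w <- if (is.data.frame(reference)) cai_weights(reference) else reference
  n3 <- (nchar(seq) %/% 3L) * 3L
  if (n3 < 3L) stop("sequence shorter than one codon")
  starts <- seq(1L, n3 - 2L, by = 3L)
  cod <- substring(seq, starts, starts + 2L)
  cod <- cod[cod %in% names(w)]
  if (length(cod) == 0L) stop("no sense codons in sequence")
  exp(mean(log(w[cod])))
}

#' Nucleotide chain molecular weight (Da)
#'
#' Sum of monophosphate residue masses minus one water per phosphodiester
#' bond. Ambiguity codes contribute the mean mass of their expansion set.
#'
#' @param seq DNA string.
#' @return Molecular weight in Daltons.
#' @export
nucleotide_molecular_weight <- function(seq) {
  check_dna(seq)
  ch <- seq_chars(seq)
  mass <- vapply(ch, function(b) mean(DNA_RESIDUE_MASS[IUPAC_EXPANSION[[b]]]),
                 numeric(1))
  sum(mass) - (length(ch) - 1L) * WATER_MASS
}

#' Canonical start/stop codon flags
#'
#' `has_start` is 1 iff the sequence begins with ATG (only methionine is
#' treated as a start; non-AUG initiation such as CUG scores 0, a known
#' limitation). `has_stop` is 1 iff the final complete codon is TAA, TAG
#' or TGA.
#'
#' @param seq DNA string of length >= 3.
#' @return Integer vector `c(has_start, has_stop)`.
#' @export
start_stop_flags <- function(seq) {
  check_dna(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  n3 <- (n %/% 3L) * 3L
  c(has_start = as.integer(substr(seq, 1L, 3L) == "ATG"),
    has_stop = as.integer(substr(seq, n3 - 2L, n3) %in% STOP_CODONS))
}

nucleotide_feature_row <- function(seq, config, weights) {
  gcp <- gc_by_codon_position(seq)
  flags <- start_stop_flags(seq)
  c(length = nchar(seq),
    molecular_weight = nucleotide_molecular_weight(seq),
    gc_content = gc_content(seq),
    gcp,
    gc_skew_stdev = skew_stdev(seq, config$skew_window, "GC"),
    at_skew_stdev = skew_stdev(seq, config$skew_window, "AT"),
    melting_temperature = melting_temperature(seq),
    shannon_entropy = shannon_entropy(seq, config$entropy_k),
    compression_ratio = compression_ratio(seq),
    cai = codon_adaptation_index(seq, weights),
    has_start_codon = unname(flags["has_start"]),
    has_stop_codon = unname(flags["has_stop"]))
}

#' Extract the 14-feature nucleotide table
#'
#' Computes all nucleotide features for each record. Records whose CDS
#' length is not a multiple of 3 are kept (codon-based features drop the
#' trailing partial codon) with a warning; records that fail a component
#' computation are skipped with a warning naming the gene and the run
#' continues.
#'
#' @param records Data.frame with columns `gene_id` and `cds` (e.g. from
#'   [pair_records()] or [generate_corpus()]).
#' @param config A [run_config()].
#' @param reference Codon-usage reference: a data.frame (`codon`,
#'   `count`), a weight vector from [cai_weights()], or `"auto"` to
#'   compute usage from `records` themselves.
#' @return Data.frame: `gene_id` plus the 14 canonical feature columns.
#' @export
extract_nucleotide_features <- function(records, config = run_config(),
                                        reference = config$cai_reference) {
  stopifnot(all(c("gene_id", "cds") %in% names(records)))
  if (identical(reference, "auto")) reference <- codon_usage(records$cds)
  weights <- if (is.data.frame(reference)) cai_weights(reference) else reference
  partial <- nchar(records$cds) %% 3L != 0L
  if (any(partial))
    warning(sum(partial), " CDS length(s) not divisible by 3 (e.g. '",
            records$gene_id[which(partial)[1L]],
            "'); trailing partial codons are dropped for codon-based features")
  rows <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    rows[[i]] <- tryCatch({
      keep[i] <- TRUE
      nucleotide_feature_row(records$cds[i], config, weights)
    }, error = function(e) {
      keep[i] <<- FALSE
      warning("skipping gene '", records$gene_id[i], "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  out <- as.data.frame(do.call(rbind, rows[keep]))
  names(out) <- NUCLEOTIDE_FEATURE_NAMES
  cbind(gene_id = records$gene_id[keep], out)
}
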