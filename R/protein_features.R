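# 41 per-protein physicochemical features. `X` contributes to length only
# and is excluded from every scale-based mean and composition; a trailing
# `*` (stop) is stripped before any computation.

check_protein <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("expected a single non-empty protein string")
  invisible(seq)
}

protein_chars <- function(seq) {
  ch <- strsplit(sub("\\*$", "", seq), "", fixed = TRUE)[[1L]]
  if (length(ch) == 0L) stop("protein is empty after stripping trailing stop")
  ch
}

standard_chars <- function(ch) {
  std <- ch[ch %in% AA_STANDARD]
  if (length(std) == 0L) stop("protein contains no standard residues")
  std
}

#' Residue composition (20 percentages)
#'
#' `100 * count(aa) / count(standard residues)`; `X` is excluded from both
#' numerator and denominator.
#'
#' @param seq Protein string.
#' @return Named vector `pct_A` ... `pct_Y` summing to 100.
#' @export
residue_percentages <- function(seq) {
  check_protein(seq)
  std <- standard_chars(protein_chars(seq))
  counts <- vapply(AA_STANDARD, function(a) sum(std == a), numeric(1))
  stats::setNames(100 * counts / length(std), paste0("pct_", AA_STANDARD))
}

#' Amino-acid class composition (9 percentages)
#'
#' Class membership follows the pepstats conventions (tiny, small,
#' aliphatic, aromatic, nonpolar, polar, charged, basic, acidic).
#'
#' @param seq Protein string.
#' @return Named vector `pct_tiny` ... `pct_acidic`.
#' @export
class_percentages <- function(seq) {
  check_protein(seq)
  std <- standard_chars(protein_chars(seq))
  out <- vapply(AA_CLASSES, function(cls) 100 * sum(std %in% cls) / length(std),
                numeric(1))
  stats::setNames(out, paste0("pct_", names(AA_CLASSES)))
}

#' Protein molecular weight (Da)
#'
#' Sum of average-isotopic residue masses plus one water. `X` contributes
#' the mean residue mass.
#'
#' @param seq Protein string.
#' @return Molecular weight in Daltons.
#' @examples protein_molecular_weight("G")  # 75.07
#' @export
protein_molecular_weight <- function(seq) {
  check_protein(seq)
  ch <- protein_chars(seq)
  mass <- ifelse(ch %in% AA_STANDARD, AA_RESIDUE_MASS[ch],
                 mean(AA_RESIDUE_MASS))
  sum(mass) + WATER_MASS
}

#' GRAVY (grand average of hydropathy)
#'
#' Mean Kyte-Doolittle hydropathy over standard residues.
#'
#' @param seq Protein string.
#' @return GRAVY value (positive = hydrophobic).
#' @export
gravy <- function(seq) {
  check_protein(seq)
  mean(KYTE_DOOLITTLE[standard_chars(protein_chars(seq))])
}

#' Aromaticity
#'
#' Fraction of F, W and Y among standard residues.
#'
#' @param seq Protein string.
#' @return Fraction in `[0, 1]`.
#' @export
aromaticity <- function(seq) {
  check_protein(seq)
  std <- standard_chars(protein_chars(seq))
  sum(std %in% c("F", "W", "Y")) / length(std)
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum` of dipeptide instability weights (DIWV) over
#' consecutive residue pairs; pairs involving `X` or unlisted residues
#' weight 1.
#'
#' @param seq Protein string of length >= 2.
#' @return Instability index (> 40 suggests an unstable protein).
#' @export
instability_index <- function(seq) {
  check_protein(seq)
  ch <- protein_chars(seq)
  L <- length(ch)
  if (L < 2L) stop("instability index needs at least 2 residues")
  a <- ch[-L]; b <- ch[-1L]
  ok <- a %in% AA_STANDARD & b %in% AA_STANDARD
  w <- rep(1, L - 1L)
  w[ok] <- DIWV[cbind(a[ok], b[ok])]
  10 / L * sum(w)
}

#' Windowed flexibility (sum over windows)
#'
#' Vihinen window-9 flexibility profile: each of the `L - 8` windows is
#' scored by the weighted mean of the normalized flexibility scale with
#' symmetric weights (0.25, 0.4375, 0.625, 0.8125, 1, mirrored) / 5.25.
#' The feature is the SUM of window scores, making it extensive in length
#' (a per-window mean would be nearly length-invariant). Windows
#' containing `X` renormalize the weights over their standard residues.
#'
#' @param seq Protein string.
#' @return Sum of window scores; 0 (with a warning) for proteins shorter
#'   than 9 residues.
#' @export
flexibility <- function(seq) {
  check_protein(seq)
  ch <- protein_chars(seq)
  L <- length(ch)
  if (L < 9L) {
    warning("protein shorter than 9 residues; flexibility set to 0")
    return(0)
  }
  scores <- vapply(seq_len(L - 8L), function(i) {
    win <- ch[i:(i + 8L)]
    ok <- win %in% AA_STANDARD
    if (!any(ok)) return(0)
    sum(FLEX_WINDOW_WEIGHTS[ok] * VIHINEN_FLEX[win[ok]]) /
      sum(FLEX_WINDOW_WEIGHTS[ok])
  }, numeric(1))
  sum(scores)
}

#' Molar extinction coefficients at 280 nm
#'
#' Gill-von Hippel: `reduced = 5500 * W + 1490 * Y`;
#' `oxidised = reduced + 125 * floor(C / 2)` (cystine bridges).
#'
#' @param seq Protein string.
#' @return Named vector `c(reduced, oxidised)` in 1/(M cm).
#' @export
molar_extinction <- function(seq) {
  check_protein(seq)
  ch <- protein_chars(seq)
  reduced <- EXTINCTION[["W"]] * sum(ch == "W") + EXTINCTION[["Y"]] * sum(ch == "Y")
  c(reduced = reduced,
    oxidised = reduced + EXTINCTION[["cystine"]] * (sum(ch == "C") %/% 2L))
}

#' Ikai aliphatic index
#'
#' `molpct(A) + 2.9 * molpct(V) + 3.9 * (molpct(I) + molpct(L))` over
#' standard residues.
#'
#' @param seq Protein string.
#' @return Aliphatic index (thermostability proxy).
#' @export
aliphatic_index <- function(seq) {
  check_protein(seq)
  std <- standard_chars(protein_chars(seq))
  mp <- function(a) 100 * sum(std == a) / length(std)
  mp("A") + 2.9 * mp("V") + 3.9 * (mp("I") + mp("L"))
}

#' Aliphatic residue percentage
#'
#' `100 * (A + I + L + V) / standard residues`.
#'
#' @param seq Protein string.
#' @return Percentage in `[0, 100]`.
#' @export
aliphaticity <- function(seq) {
  check_protein(seq)
  std <- standard_chars(protein_chars(seq))
  100 * sum(std %in% c("A", "I", "L", "V")) / length(std)
}

protein_net_charge <- function(counts, n_pos_term, pH, pka) {
  pos <- sum(c(nterm = n_pos_term, counts[names(pka$positive)]) /
               (1 + 10^(pH - c(pka$nterm, pka$positive))))
  neg <- sum(c(cterm = 1, counts[names(pka$negative)]) /
               (1 + 10^(c(pka$cterm, pka$negative) - pH)))
  pos - neg
}

#' Isoelectric point
#'
#' pH of zero net charge under the Henderson-Hasselbalch model with the
#' Bjellqvist pKa set (N-terminus, C-terminus, D, E, C, Y, H, K, R),
#' solved by bisection on `[0, 14]`. Net charge is monotone decreasing in
#' pH, so the root is unique.
#'
#' @param seq Protein string.
#' @param pka pKa set; a list with elements `nterm`, `cterm`, `positive`,
#'   `negative` (see `PKA_BJELLQVIST` for the default structure).
#' @param tol Convergence tolerance on |net charge|.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = PKA_BJELLQVIST, tol = 1e-4) {
  check_protein(seq)
  ch <- protein_chars(seq)
  groups <- unique(c(names(pka$positive), names(pka$negative)))
  counts <- vapply(groups, function(a) sum(ch == a), numeric(1))
  lo <- 0; hi <- 14
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(counts, 1, mid, pka)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

protein_feature_row <- function(seq) {
  pct <- residue_percentages(seq)
  ext <- molar_extinction(seq)
  ch <- protein_chars(seq)
  c(pct,
    length = length(ch),
    molecular_weight = protein_molecular_weight(seq),
    isoelectric_point = isoelectric_point(seq),
    gravy = gravy(seq),
    aromaticity = aromaticity(seq),
    instability_index = instability_index(seq),
    flexibility = suppressWarnings(flexibility(seq)),
    molar_ext_reduced = unname(ext["reduced"]),
    molar_ext_oxidised = unname(ext["oxidised"]),
    aliphatic_index = aliphatic_index(seq),
    aliphaticity = aliphaticity(seq),
    starts_with_met = as.integer(ch[1L] == "M"),
    class_percentages(seq))
}

#' Extract the 41-feature protein table
#'
#' Computes all protein features for each record; a trailing `*` is
#' stripped first. Records that fail a component computation are skipped
#' with a warning naming the gene and the run continues.
#'
#' @param records Data.frame with columns `gene_id` and `protein`.
#' @param config A [run_config()] (reserved for scale selection).
#' @return Data.frame: `gene_id` plus the 41 canonical feature columns.
#' @export
extract_protein_features <- function(records, config = run_config()) {
  stopifnot(all(c("gene_id", "protein") %in% names(records)))
  rows <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    rows[[i]] <- tryCatch({
      keep[i] <- TRUE
      protein_feature_row(records$protein[i])
    }, error = function(e) {
      keep[i] <<- FALSE
      warning("skipping gene '", records$gene_id[i], "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  out <- as.data.frame(do.call(rbind, rows[keep]))
  names(out) <- PROTEIN_FEATURE_NAMES
  cbind(gene_id = records$gene_id[keep], out)
}
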