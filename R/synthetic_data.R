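# Synthetic paired CDS/protein corpora with planted class structure. The
# generator emulates the contrasts reported between conserved and
# non-conserved plant gene models: high-confidence genes are longer,
# slightly GC-poorer, almost always start with ATG and carry few repeats;
# low-confidence genes are shorter, GC-richer, often lack a canonical
# start and are repeat-enriched.

#' Simulation configuration
#'
#' Class 1 is the high-confidence (conserved) class. Lengths are
#' log-normal per class (in bp, rounded to a multiple of 3, floored at 21
#' bp); per-gene GC targets are Beta-distributed around the class mean;
#' `start_prob` is the probability the first codon is ATG;
#' `repeat_rate` is the probability a gene receives a planted tandem
#' repeat of `repeat_unit_codons` codons duplicated `repeat_copies`
#' times.
#'
#' @param n_per_class Named or ordered pair `c(class1, class0)`.
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @param length_mean Mean CDS length in bp per class `c(class1, class0)`.
#' @param length_sdlog Log-scale sd of the length distribution.
#' @param gc_mean Mean per-gene GC target (percent) per class.
#' @param gc_concentration Beta concentration of the per-gene GC target.
#' @param start_prob ATG probability per class.
#' @param repeat_rate Tandem-repeat planting probability per class.
#' @param repeat_unit_codons Repeat unit length in codons.
#' @param repeat_copies Extra tandem copies inserted when planted.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = c(2000L, 2000L), seed = 42L,
                              length_mean = c(1500, 600),
                              length_sdlog = c(0.45, 0.45),
                              gc_mean = c(42.12, 43.25),
                              gc_concentration = c(80, 80),
                              start_prob = c(0.95, 0.70),
                              repeat_rate = c(0.05, 0.15),
                              repeat_unit_codons = 10L,
                              repeat_copies = 3L) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 0),
            all(start_prob >= 0 & start_prob <= 1),
            all(repeat_rate >= 0 & repeat_rate <= 1),
            all(gc_mean > 0 & gc_mean < 100),
            all(length_mean >= 21), repeat_unit_codons >= 1, repeat_copies >= 1)
  structure(list(n_per_class = as.integer(n_per_class), seed = as.integer(seed),
                 length_mean = length_mean, length_sdlog = length_sdlog,
                 gc_mean = gc_mean, gc_concentration = gc_concentration,
                 start_prob = start_prob, repeat_rate = repeat_rate,
                 repeat_unit_codons = as.integer(repeat_unit_codons),
                 repeat_copies = as.integer(repeat_copies)),
            class = "simulation_config")
}

#' Named simulation presets
#'
#' `paper_like`: the default moderate class contrasts (GC 42.12 vs
#' 43.25%, mean length 1500 vs 600 bp, start probability 0.95 vs 0.70,
#' 3x repeat enrichment in class 0). `separable`: exaggerated contrasts
#' for planted-signal recovery checks. `null`: identical class
#' distributions, so any end-to-end AUC above chance is overfitting.
#'
#' @param n_per_class Pair of per-class counts applied to every preset.
#' @param seed Seed applied to every preset.
#' @return Named list of `simulation_config` objects.
#' @export
default_scenarios <- function(n_per_class = c(2000L, 2000L), seed = 42L) {
  list(
    paper_like = simulation_config(n_per_class, seed),
    separable = simulation_config(n_per_class, seed,
                                  length_mean = c(1400, 800),
                                  gc_mean = c(36, 50),
                                  gc_concentration = c(150, 150),
                                  start_prob = c(0.98, 0.30),
                                  repeat_rate = c(0.02, 0.30)),
    null = simulation_config(n_per_class, seed,
                             length_mean = c(1000, 1000),
                             gc_mean = c(42.5, 42.5),
                             start_prob = c(0.85, 0.85),
                             repeat_rate = c(0.10, 0.10))
  )
}

# Rejecting stop codons (AT-rich) raises realized GC above the sampling
# probability. For base GC probability p, the expected GC fraction of a
# non-stop codon is
#   E(p) = (p - (1-p)^2 p / 12) / (1 - (1-p)^2 (1+p) / 8),
# (the stop-codon terms of the unconditional expectation removed), which
# is monotone in p; inverting it makes realized per-gene GC hit the
# target.
gc_sampling_prob <- function(target) {
  expected <- function(p)
    (p - (1 - p)^2 * p / 12) / (1 - (1 - p)^2 * (1 + p) / 8)
  if (target <= 0 || target >= 1) return(target)
  stats::uniroot(function(p) expected(p) - target, c(1e-9, 1 - 1e-9),
                 tol = 1e-10)$root
}

sample_codons <- function(n, gc_frac, exclude_stops = TRUE) {
  probs <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2,
             G = gc_frac / 2, T = (1 - gc_frac) / 2)
  draw <- function(m) {
    b <- matrix(sample(names(probs), 3L * m, replace = TRUE, prob = probs),
                ncol = 3L)
    paste0(b[, 1L], b[, 2L], b[, 3L])
  }
  cod <- draw(n)
  if (exclude_stops) {
    bad <- cod %in% STOP_CODONS
    while (any(bad)) {
      cod[bad] <- draw(sum(bad))
      bad <- cod %in% STOP_CODONS
    }
  }
  cod
}

translate_cds <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    n3 <- (nchar(s) %/% 3L) * 3L
    starts <- seq(1L, n3 - 2L, by = 3L)
    aa <- code[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    sub("\\*$", "", paste(aa, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

generate_one_cds <- function(length_bp, gc_frac, has_start, repeat_planted,
                             unit_codons, copies) {
  n_codons <- max(7L, round(length_bp / 3))
  gc_frac <- gc_sampling_prob(gc_frac)
  first <- if (has_start) "ATG" else {
    cod <- sample_codons(1L, gc_frac)
    while (cod == "ATG") cod <- sample_codons(1L, gc_frac)
    cod
  }
  body <- sample_codons(n_codons - 2L, gc_frac)
  stop_codon <- sample(STOP_CODONS, 1L)
  codons <- c(first, body, stop_codon)
  inserted <- 0L
  if (repeat_planted && length(body) > unit_codons) {
    at <- sample.int(length(body) - unit_codons + 1L, 1L)
    unit <- body[at:(at + unit_codons - 1L)]
    body <- append(body, rep(unit, copies), after = at + unit_codons - 1L)
    codons <- c(first, body, stop_codon)
    inserted <- copies * unit_codons * 3L
  }
  list(seq = paste(codons, collapse = ""), inserted = inserted)
}

#' Generate a paired CDS/protein corpus with planted class structure
#'
#' For each gene: draws the class, a length and a per-gene GC target,
#' emits codons at that composition with internal stop codons rejected,
#' sets the first codon to ATG with the class's start probability,
#' appends a stop codon, optionally plants an in-frame tandem repeat, and
#' translates with the standard genetic code (trailing stop dropped).
#' Byte-identical output for a fixed config and seed.
#'
#' @param config A [simulation_config()].
#' @return List with `cds` and `protein` record data.frames (`id`,
#'   `seq`), and `truth` (gene_id, class, length, gc, has_start,
#'   repeat_fraction).
#' @export
generate_corpus <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  min_len <- (config$repeat_unit_codons + 3L) * 3L
  if (any(config$length_mean < min_len))
    stop("repeat unit longer than the configured gene length")
  n <- sum(config$n_per_class)
  with_seed(config$seed, {
    cls <- rep(c(1L, 0L), config$n_per_class)
    ci <- ifelse(cls == 1L, 1L, 2L) # column index into per-class parameters
    meanlog <- log(config$length_mean[ci]) - config$length_sdlog[ci]^2 / 2
    len <- pmax(21, round(stats::rlnorm(n, meanlog, config$length_sdlog[ci]) / 3) * 3)
    gc_m <- config$gc_mean[ci] / 100
    conc <- config$gc_concentration[ci]
    gc <- stats::rbeta(n, gc_m * conc, (1 - gc_m) * conc)
    has_start <- stats::runif(n) < config$start_prob[ci]
    planted <- stats::runif(n) < config$repeat_rate[ci]
    ids <- sprintf("gene%05d", seq_len(n))
    seqs <- character(n); inserted <- integer(n)
    for (i in seq_len(n)) {
      g <- generate_one_cds(len[i], gc[i], has_start[i], planted[i],
                            config$repeat_unit_codons, config$repeat_copies)
      seqs[i] <- g$seq
      inserted[i] <- g$inserted
    }
    list(cds = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
         protein = data.frame(id = ids, seq = translate_cds(seqs),
                              stringsAsFactors = FALSE),
         truth = data.frame(gene_id = ids, class = cls,
                            length = nchar(seqs),
                            gc = vapply(seqs, gc_content, numeric(1),
                                        USE.NAMES = FALSE),
                            has_start = as.integer(has_start),
                            repeat_fraction = inserted / nchar(seqs),
                            stringsAsFactors = FALSE))
  })
}

#' Build a labelled nucleotide feature table from a simulated corpus
#'
#' Convenience wrapper: extracts the 14 nucleotide features and attaches
#' the simulation truth as the label.
#'
#' @param corpus Result of [generate_corpus()].
#' @param config A [run_config()].
#' @return Labelled feature table (gene_id, 14 features, label).
#' @export
corpus_feature_table <- function(corpus, config = run_config()) {
  records <- data.frame(gene_id = corpus$cds$id, cds = corpus$cds$seq,
                        stringsAsFactors = FALSE)
  feats <- extract_nucleotide_features(records, config)
  feats$label <- corpus$truth$class[match(feats$gene_id, corpus$truth$gene_id)]
  feats
}
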