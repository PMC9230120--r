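# Brute-force oracle implementations, coded independently of the package
# internals (explicit per-character loops, no shared helper code). The
# published scale tables (masses, hydropathy, DIWV, pKa) are data, not
# algorithm, and are taken from the package constants; their values are
# pinned separately by literature spot checks in the unit tests.

o_chars <- function(s) strsplit(s, "")[[1]]

o_gc_content <- function(seq) {
  g <- 0; c_ <- 0; atgc <- 0
  for (b in o_chars(seq)) {
    if (b %in% c("A", "C", "G", "T")) atgc <- atgc + 1
    if (b == "G") g <- g + 1
    if (b == "C") c_ <- c_ + 1
  }
  100 * (g + c_) / atgc
}

o_gc_pos <- function(seq) {
  ch <- o_chars(seq)
  out <- numeric(3)
  for (k in 1:3) {
    idx <- seq(k, length(ch), by = 3)
    gc <- 0; den <- 0
    for (i in idx) {
      if (ch[i] %in% c("A", "C", "G", "T")) den <- den + 1
      if (ch[i] %in% c("G", "C")) gc <- gc + 1
    }
    out[k] <- if (den == 0) 0 else 100 * gc / den
  }
  out
}

o_skew_sd <- function(seq, window, pair) {
  ch <- o_chars(seq)
  n <- length(ch)
  k <- n %/% window
  rem <- n %% window
  if (k == 0) {
    bounds <- list(c(1, n))
  } else {
    bounds <- lapply(seq_len(k), function(i) c((i - 1) * window + 1, i * window))
    if (rem >= window / 2) {
      bounds <- c(bounds, list(c(k * window + 1, n)))
    } else if (rem > 0) {
      bounds[[k]][2] <- n
    }
  }
  pos_b <- if (pair == "GC") "G" else "A"
  neg_b <- if (pair == "GC") "C" else "T"
  skews <- sapply(bounds, function(b) {
    w <- ch[b[1]:b[2]]
    p <- sum(w == pos_b); q <- sum(w == neg_b)
    if (p + q == 0) 0 else (p - q) / (p + q)
  })
  sqrt(sum((skews - mean(skews))^2) / length(skews))
}

o_tm <- function(seq) 81.5 + 0.41 * o_gc_content(seq) +
  16.6 * log10(0.05) - 600 / nchar(seq)

o_entropy <- function(seq, k = 3) {
  n_tok <- nchar(seq) %/% k
  toks <- character(n_tok)
  for (i in seq_len(n_tok)) toks[i] <- substr(seq, (i - 1) * k + 1, i * k)
  h <- 0
  for (t in unique(toks)) {
    p <- sum(toks == t) / n_tok
    h <- h - p * log(p, base = 2)
  }
  h
}

o_mw_nt <- function(seq) {
  masses <- geneconf:::DNA_RESIDUE_MASS
  exp_set <- geneconf:::IUPAC_EXPANSION
  total <- 0
  for (b in o_chars(seq)) total <- total + mean(masses[exp_set[[b]]])
  total - (nchar(seq) - 1) * 18.0153
}

o_cai <- function(seq, usage) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  f <- setNames(usage$count, usage$codon)[sense]
  f[f == 0] <- 0.5
  logw_sum <- 0; m <- 0
  for (i in seq_len(nchar(seq) %/% 3)) {
    cod <- substr(seq, 3 * i - 2, 3 * i)
    if (!cod %in% sense) next
    aa <- code[[cod]]
    fam <- sense[code[sense] == aa]
    logw_sum <- logw_sum + log(f[[cod]] / max(f[fam]))
    m <- m + 1
  }
  exp(logw_sum / m)
}

o_compression <- function(seq) {
  # independent route: python zlib at default level on the same bytes
  out <- system2("python", c("-c", shQuote(paste0(
    "import zlib,sys; s=sys.stdin.read().strip().encode(); ",
    "print(len(zlib.compress(s))/len(s))"))),
    input = seq, stdout = TRUE)
  as.numeric(out)
}

# --- protein oracles -------------------------------------------------------

o_std <- function(seq) {
  ch <- o_chars(sub("\\*$", "", seq))
  ch[ch %in% AA20]
}

o_pct <- function(seq) {
  std <- o_std(seq)
  sapply(AA20, function(a) 100 * sum(std == a) / length(std))
}

o_class_pct <- function(seq) {
  std <- o_std(seq)
  cls <- geneconf:::AA_CLASSES
  sapply(cls, function(members) 100 * sum(std %in% members) / length(std))
}

o_mw_aa <- function(seq) {
  masses <- geneconf:::AA_RESIDUE_MASS
  ch <- o_chars(sub("\\*$", "", seq))
  total <- 18.0153
  for (a in ch) total <- total + (if (a %in% AA20) masses[[a]] else mean(masses))
  total
}

o_gravy <- function(seq) {
  kd <- geneconf:::KYTE_DOOLITTLE
  std <- o_std(seq)
  sum(sapply(std, function(a) kd[[a]])) / length(std)
}

o_aromaticity <- function(seq) {
  std <- o_std(seq)
  sum(std %in% c("F", "W", "Y")) / length(std)
}

o_instability <- function(seq) {
  diwv <- geneconf:::DIWV
  ch <- o_chars(sub("\\*$", "", seq))
  total <- 0
  for (i in seq_len(length(ch) - 1)) {
    a <- ch[i]; b <- ch[i + 1]
    total <- total + (if (a %in% AA20 && b %in% AA20) diwv[a, b] else 1)
  }
  10 / length(ch) * total
}

o_flexibility <- function(seq) {
  scale <- geneconf:::VIHINEN_FLEX
  wts <- c(0.25, 0.4375, 0.625, 0.8125, 1, 0.8125, 0.625, 0.4375, 0.25)
  ch <- o_chars(sub("\\*$", "", seq))
  if (length(ch) < 9) return(0)
  total <- 0
  for (i in seq_len(length(ch) - 8)) {
    num <- 0; den <- 0
    for (j in 0:8) {
      a <- ch[i + j]
      if (a %in% AA20) {
        num <- num + wts[j + 1] * scale[[a]]
        den <- den + wts[j + 1]
      }
    }
    if (den > 0) total <- total + num / den
  }
  total
}

o_extinction <- function(seq) {
  ch <- o_chars(sub("\\*$", "", seq))
  red <- 5500 * sum(ch == "W") + 1490 * sum(ch == "Y")
  c(red, red + 125 * (sum(ch == "C") %/% 2))
}

o_aliphatic_index <- function(seq) {
  std <- o_std(seq)
  mp <- function(a) 100 * sum(std == a) / length(std)
  mp("A") + 2.9 * mp("V") + 3.9 * (mp("I") + mp("L"))
}

o_aliphaticity <- function(seq) {
  std <- o_std(seq)
  100 * sum(std %in% c("A", "I", "L", "V")) / length(std)
}

o_charge_at <- function(seq, pH) {
  pka <- geneconf:::PKA_BJELLQVIST
  ch <- o_chars(sub("\\*$", "", seq))
  q <- 1 / (1 + 10^(pH - pka$nterm)) - 1 / (1 + 10^(pka$cterm - pH))
  for (a in names(pka$positive))
    q <- q + sum(ch == a) / (1 + 10^(pH - pka$positive[[a]]))
  for (a in names(pka$negative))
    q <- q - sum(ch == a) / (1 + 10^(pka$negative[[a]] - pH))
  q
}

o_pi_grid <- function(seq, step = 1e-4) {
  # fine-grid scan: pH of minimal |net charge|
  grid <- seq(0, 14, by = 0.01)
  q <- abs(sapply(grid, function(p) o_charge_at(seq, p)))
  centre <- grid[which.min(q)]
  fine <- seq(max(0, centre - 0.02), min(14, centre + 0.02), by = step)
  qf <- abs(sapply(fine, function(p) o_charge_at(seq, p)))
  fine[which.min(qf)]
}
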