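test_that("gc_content counts unambiguous bases only", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGGCCCATAT"), 60)
  expect_equal(gc_content("GCNN"), 100)  # ambiguity out of both counts
  expect_error(gc_content("NNN"), "unambiguous")
})

test_that("codon-position GC averages back to overall GC", {
  expect_equal(unname(gc_by_codon_position("ATGGCATGA")),
               c(100 / 3, 200 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(unname(gc_by_codon_position("GGGGGG")), c(100, 100, 100))
  expect_error(gc_by_codon_position("AT"))
  set.seed(5)
  for (i in 1:20) {
    s <- rand_dna(3 * sample(40:200, 1), gc = runif(1, 0.3, 0.6))
    expect_equal(mean(gc_by_codon_position(s)), gc_content(s), tolerance = 1e-9)
  }
})

test_that("skew stdev handles windows, zero denominators and single windows", {
  expect_equal(skew_stdev(paste0(strrep("G", 100), strrep("C", 100)), 100, "GC"), 1)
  expect_equal(skew_stdev(strrep("AT", 100), 100, "GC"), 0)
  expect_equal(skew_stdev("GGGCC", 100, "GC"), 0)  # single window
  expect_error(skew_stdev("", 100, "GC"))
})

test_that("melting temperature matches the salt-corrected GC formula", {
  expect_equal(melting_temperature(strrep("AGCT", 150)), 79.40, tolerance = 1e-3)
  expect_equal(melting_temperature(strrep("AT", 300000)), 59.90, tolerance = 1e-3)
  # a typical plant gene sits near 80 degrees
  set.seed(2)
  expect_gt(melting_temperature(rand_dna(2000, gc = 0.43)), 75)
  expect_lt(melting_temperature(rand_dna(2000, gc = 0.43)), 85)
})

test_that("entropy over non-overlapping k-mers hits closed-form cases", {
  expect_equal(shannon_entropy("AAAAAA", 3), 0)
  expect_equal(shannon_entropy("AAACCC", 3), 1)
  expect_equal(shannon_entropy("ACGT", 1), 2)
  expect_error(shannon_entropy("AC", 3))
})

test_that("entropy is invariant under codon permutation and bounded", {
  set.seed(31)
  for (i in 1:15) {
    s <- rand_dna(3 * sample(30:120, 1))
    n_cod <- nchar(s) / 3
    codons <- substring(s, 3 * (1:n_cod) - 2, 3 * (1:n_cod))
    perm <- paste(sample(codons), collapse = "")
    expect_equal(shannon_entropy(s, 3), shannon_entropy(perm, 3))
    expect_gte(shannon_entropy(s, 3), 0)
    expect_lte(shannon_entropy(s, 3), 6)
  }
})

test_that("compression ratio reflects repetitiveness", {
  expect_lt(compression_ratio(strrep("A", 10000)), 0.01)
  set.seed(8)
  r <- compression_ratio(rand_dna(10000))
  expect_gt(r, 0.25); expect_lt(r, 0.45)
  # tandem repeat compresses better than its shuffle
  for (i in 1:5) {
    unit <- rand_dna(50)
    tandem <- strrep(unit, 30)
    shuffled <- paste(sample(strsplit(tandem, "")[[1]]), collapse = "")
    expect_lt(compression_ratio(tandem), compression_ratio(shuffled))
  }
})

test_that("planting more tandem repeat never increases the ratio", {
  set.seed(12)
  unit <- rand_dna(60)
  base <- rand_dna(2400)
  ratios <- sapply(c(0, 6, 12, 20, 30), function(copies) {
    planted <- paste0(strrep(unit, copies), substr(base, 1, 2400 - 60 * copies))
    compression_ratio(planted)
  })
  expect_true(all(diff(ratios) <= 1e-4))
})

test_that("CAI matches closed-form cases and the log-average oracle", {
  usage <- uneven_usage()
  w <- cai_weights(usage)
  # gene built entirely from reference-optimal codons scores 1
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  optimal <- vapply(unique(code[sense]), function(aa) {
    fam <- sense[code[sense] == aa]
    names(which.max(w[fam]))
  }, character(1))
  gene <- paste(optimal, collapse = "")
  expect_equal(codon_adaptation_index(gene, usage), 1.0)
  # two-codon gene with w = {1, 0.25} scores sqrt(0.25)
  u2 <- codon_usage(character())
  u2$count <- rep(100, 64)
  u2$count[u2$codon == "CTT"] <- 25
  expect_equal(codon_adaptation_index("CTGCTT", u2), 0.5)
  # brute-force log-average oracle on random genes
  set.seed(41)
  for (i in 1:20) {
    s <- rand_dna(3 * sample(20:100, 1))
    expect_equal(codon_adaptation_index(s, usage), o_cai(s, usage),
                 tolerance = 1e-9)
  }
  # invariant to codon order (same weight multiset), bounded by (0, 1]
  s <- rand_dna(300)
  codons <- substring(s, 3 * (1:100) - 2, 3 * (1:100))
  perm <- paste(sample(codons), collapse = "")
  expect_equal(codon_adaptation_index(s, usage),
               codon_adaptation_index(perm, usage))
  expect_gt(codon_adaptation_index(s, usage), 0)
  expect_lte(codon_adaptation_index(s, usage), 1)
})

test_that("nucleotide molecular weight matches residue-mass arithmetic", {
  expect_equal(nucleotide_molecular_weight("A"), 331.2218)
  expect_equal(nucleotide_molecular_weight("AT"), 635.4150)
  s <- rand_dna(50)
  expect_gt(nucleotide_molecular_weight(paste0(s, "G")),
            nucleotide_molecular_weight(s))
})

test_that("start/stop flags use ATG and the final complete codon", {
  expect_equal(unname(start_stop_flags("ATGAAATAA")), c(1, 1))
  expect_equal(unname(start_stop_flags("CTGAAATAA")), c(0, 1))  # CUG scores 0
  expect_equal(unname(start_stop_flags("ATGAAA")), c(1, 0))
  # partial tail ignored: the final complete codon decides
  expect_equal(unname(start_stop_flags("ATGAAATAAC")), c(1, 1))
  expect_equal(unname(start_stop_flags("ATGAAATGAC")), c(1, 1))
  expect_error(start_stop_flags("AT"))
})

test_that("extract_nucleotide_features assembles 14 deterministic columns", {
  recs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     cds = c("ATGGCATGA", "ATGCCCAAATAA", "ATGGGGTGA"))
  ft <- extract_nucleotide_features(recs, run_config())
  expect_equal(dim(ft), c(3, 15))
  expect_equal(names(ft)[-1], geneconf:::NUCLEOTIDE_FEATURE_NAMES)
  expect_equal(ft$length[1], 9)
  expect_equal(ft$gc_content[1], 400 / 9, tolerance = 1e-4)
  expect_equal(ft$has_start_codon, c(1, 1, 1))
  expect_equal(ft$has_stop_codon, c(1, 1, 1))
  ft2 <- extract_nucleotide_features(recs, run_config())
  expect_identical(ft, ft2)
  # a failing record is skipped with a warning, the run continues
  bad <- rbind(recs, data.frame(gene_id = "gN", cds = "NNNNNNNNN"))
  expect_warning(ftb <- extract_nucleotide_features(bad, run_config()),
                 "gN")
  expect_equal(nrow(ftb), 3)
  # non-multiple-of-3 lengths are kept with a warning
  odd <- data.frame(gene_id = "godd", cds = "ATGAAATAAC")
  expect_warning(fto <- extract_nucleotide_features(odd, run_config(),
                                                    reference = uneven_usage()),
                 "divisible by 3")
  expect_equal(fto$length, 10)
})
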