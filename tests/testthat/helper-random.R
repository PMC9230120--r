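rand_dna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# A codon-usage reference with uneven synonymous counts, for CAI tests.
uneven_usage <- function() {
  usage <- codon_usage(character())
  set.seed(99)
  usage$count <- sample(5:100, 64, replace = TRUE)
  usage
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
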