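# Independent oracles, kept deliberately separate from the implementation
# paths they check.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

.all_codons <- local({
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1], 1,
        paste, collapse = "")
})

# brute-force enumeration of all codons at exact Hamming distance d from a
# source codon: scan all 64 codons and filter by distance
oracle_mutants <- function(codon, d) {
  src <- strsplit(codon, "")[[1]]
  hd <- vapply(.all_codons, function(x) {
    sum(strsplit(x, "")[[1]] != src)
  }, integer(1))
  muts <- sort(.all_codons[hd == d])
  code <- Biostrings::GENETIC_CODE
  aa <- as.character(code[muts])
  src_aa <- as.character(code[codon])
  cls <- ifelse(aa == "*", "nonsense", ifelse(aa == src_aa, "silent", "missense"))
  list(codons = muts,
       counts = c(silent = sum(cls == "silent"),
                  missense = sum(cls == "missense"),
                  nonsense = sum(cls == "nonsense")))
}

# character-by-character translation oracle via Biostrings
oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     no.init.codon = TRUE))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# exact per-generation survival of one codon against stop gain, via the
# 64-state Markov chain of independent per-site mutation (stops absorbing)
oracle_codon_survival <- function(codon, mu, generations) {
  P <- matrix(0, 64, 64, dimnames = list(.all_codons, .all_codons))
  for (a in .all_codons) {
    ca <- strsplit(a, "")[[1]]
    for (b in .all_codons) {
      d <- ca != strsplit(b, "")[[1]]
      P[a, b] <- prod(ifelse(d, mu / 3, 1 - mu))
    }
  }
  P[ORACLE_STOPS, ] <- 0
  for (s in ORACLE_STOPS) P[s, s] <- 1
  v <- stats::setNames(rep(0, 64), .all_codons)
  v[codon] <- 1
  vapply(seq_len(generations), function(t) {
    v <<- stats::setNames(as.vector(v %*% P), .all_codons)
    1 - sum(v[ORACLE_STOPS])
  }, numeric(1))
}
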