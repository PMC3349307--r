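# independent brute-force oracles, deliberately naive: position-by-position
# scans and double loops, sharing no code with the package internals

oracle_pair_counts <- function(s, d) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- setNames(integer(16), dinucleotides())
  for (i in seq_len(n - d)) {
    p <- paste0(ch[i], ch[i + d])
    out[p] <- out[p] + 1L
  }
  out
}

oracle_city_block <- function(a, b) {
  total <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      total <- total + abs(a[i, j] - b[i, j])
  total
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_profile <- function(d0 = 2) {
  m <- matrix(stats::runif(16 * d0), d0, 16)
  sweep(m, 1, rowSums(m), "/")
}

tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
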