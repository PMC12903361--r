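# Fixture builders and independent brute-force oracles used across tests.

rnd_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# brute-force all-pairs Hamming oracle for nucleotide diversity,
# independent of the package implementation
pi_oracle <- function(units) {
  n <- length(units)
  mats <- strsplit(units, "", fixed = TRUE)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    x <- mats[[i]]; y <- mats[[j]]
    ok <- x != "N" & y != "N"
    tot <- tot + sum(x[ok] != y[ok]) / sum(ok)
    np <- np + 1
  }
  tot / np
}

# brute-force all-substring matcher: every diagonal carrying an exact
# ungapped match of at least min_len bases between a and b
diag_oracle <- function(a, b, min_len = 14L) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(x); lb <- length(y)
  found <- integer(0)
  for (d in seq(-(la - min_len), lb - min_len)) {
    i <- max(1L, 1L - d); j <- i + d
    len <- min(la - i, lb - j) + 1L
    if (len < min_len) next
    eq <- x[i:(i + len - 1L)] == y[j:(j + len - 1L)]
    r <- rle(eq)
    if (any(r$values & r$lengths >= min_len)) found <- c(found, d)
  }
  found
}

# exact tandem-array pair with clean unique flanks, via the simulator
exact_pair <- function(unit_len, copies_a, copies_b, seed,
                       divergence = 0, flank = 1000L) {
  gen_vntr_pair(unit_len, copies_a, copies_b, divergence = divergence,
                flank_len = flank, seed = seed)
}

write_sim_genomes <- function(g, dir) {
  paths <- list(
    ref_fa = file.path(dir, "ref.fa"), ref_gff = file.path(dir, "ref.gff3"),
    strain_fa = file.path(dir, "strain.fa"),
    strain_gff = file.path(dir, "strain.gff3"))
  write_fasta(g$ref$genome, paths$ref_fa)
  write_fasta(g$strain$genome, paths$strain_fa)
  write_gff3(g$ref$gff, paths$ref_gff)
  write_gff3(g$strain$gff, paths$strain_gff)
  paths
}
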