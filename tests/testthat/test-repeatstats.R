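test_that("decompose_units partitions exact arrays and locks phase", {
  d <- decompose_units("ACGACGACG", c(0, 9), 3)
  expect_equal(d$units, rep("ACG", 3))
  expect_equal(d$copies, 3)
  expect_equal(d$overhang_bp, 0L)

  # off-phase block: the ACG frame is found, 2 bp overhang split across ends
  d <- decompose_units("TACGACGACGA", c(0, 11), 3)
  expect_equal(d$units, rep("ACG", 3))
  expect_equal(d$n_units, 3)
  expect_equal(d$overhang_bp, 2L)

  expect_error(decompose_units("ACGT", c(0, 4), 5), "shorter")
})

test_that("decompose_units is rotation-invariant on exact arrays", {
  set.seed(8)
  u <- rnd_dna(20)
  arr <- strrep(u, 6)
  ref <- sort(decompose_units(arr, c(0, nchar(arr)), 20)$units)
  for (rot in c(1, 7, 19)) {
    shifted <- paste0(substring(arr, rot + 1), substring(arr, 1, rot))
    got <- decompose_units(shifted, c(0, nchar(arr)), 20)
    expect_equal(sort(got$units), ref, info = paste("rot", rot))
  }
})

test_that("nucleotide diversity matches hand-enumerated pairs", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT", "ACGT")), 0)
  expect_equal(nucleotide_diversity(c("ACGT", "ACGA", "ACGT")), 1 / 6)
  expect_equal(nucleotide_diversity(c("ACGT", "TGCA")), 1)
  # N positions drop out of both numerator and denominator
  expect_equal(nucleotide_diversity(c("ACGN", "ACTT")), 1 / 3)
  expect_warning(pi1 <- nucleotide_diversity("ACGT"), "undefined")
  expect_true(is.na(pi1))
})

test_that("nucleotide diversity equals the brute-force Hamming oracle", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    len <- sample(5:40, 1)
    anc <- rnd_dna(len)
    units <- vapply(seq_len(n), function(j) mutate_seq(anc, runif(1, 0, 0.3)),
                    character(1))
    expect_equal(nucleotide_diversity(units), pi_oracle(units),
                 info = paste("case", i))
  }
})

test_that("pi concentrates near expectation for i.i.d. mutated units", {
  set.seed(10)
  q <- 0.02
  anc <- rnd_dna(300)
  units <- vapply(1:40, function(i) mutate_seq(anc, q), character(1))
  # two units differ where exactly one of two i.i.d. mutations hit and
  # changed to different bases; expectation ~ 2q(1-q) + q^2 * 2/3
  expected <- 2 * q * (1 - q) + q^2 * 2 / 3
  expect_equal(nucleotide_diversity(units), expected, tolerance = 0.25)
})

test_that("alignment-based pi handles unequal unit lengths", {
  units <- c("ACGTACGTAC", "ACGTACGTC", "ACGTACGTAC")  # one 1 bp deletion
  pi <- nucleotide_diversity(units)
  expect_true(attr(pi, "aligned"))
  expect_gt(as.numeric(pi), 0)
  expect_lt(as.numeric(pi), 0.3)
})

test_that("gc_content counts G+C over unambiguous bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTNNNN"), 0.5)
  expect_warning(g <- gc_content("NNN"), "undefined")
  expect_true(is.na(g))
})

test_that("GC enrichment uses a two-sided Welch test", {
  x <- c(0.5, 0.5, 0.5)
  expect_equal(gc_enrichment_test(x, x)$p_value, 1)
  expect_equal(gc_enrichment_test(x, x)$statistic, 0)

  set.seed(3)
  vntr <- rnorm(50, 0.60, 0.03)
  bg <- rnorm(50, 0.516, 0.03)
  res <- gc_enrichment_test(vntr, bg)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$direction, "higher")
  # agrees with stats::t.test called directly
  expect_equal(res$p_value, t.test(vntr, bg)$p.value)

  expect_error(gc_enrichment_test(0.5, c(0.4, 0.5)), "at least 2")
})

test_that("summarize_gene spans copies and units across strains", {
  blk <- function(g, u, ca, cb, r) data.frame(
    gene_id = g, a_start = 0L, a_end = as.integer(u * ca),
    b_start = 0L, b_end = as.integer(u * cb), unit_len = u, copies_a = ca,
    copies_b = cb, r = r, confidence = 1, n_diagonals = 5L)
  calls <- list(
    list(gene_id = "Ifi207", strain = "s1", flagged = TRUE,
         reason = "ratio_high", blocks = blk("Ifi207", 42, 25, 11, 0.44)),
    list(gene_id = "Ubc", strain = "s1", flagged = TRUE,
         reason = "ratio_high", blocks = blk("Ubc", 228, 8, 23, 2.9)),
    list(gene_id = "Ubc", strain = "s2", flagged = FALSE, reason = "none",
         blocks = blk("Ubc", 228, 8, 8, 1)),
    list(gene_id = "empty", strain = "s1", flagged = FALSE, reason = "none",
         blocks = blk("x", 1, 1, 1, 1)[0, ]))
  s <- summarize_gene(calls)
  expect_setequal(s$gene_id, c("Ifi207", "Ubc"))  # blockless gene absent
  ifi <- s[s$gene_id == "Ifi207", ]
  expect_equal(c(ifi$copy_min, ifi$copy_max), c(11, 25))
  expect_equal(c(ifi$unit_len_min, ifi$unit_len_max), c(42, 42))
  ubc <- s[s$gene_id == "Ubc", ]
  expect_equal(c(ubc$copy_min, ubc$copy_max), c(8, 23))
  expect_equal(ubc$strains_flagged, "s1")
})
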