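test_that("slice_haplotype tiles with tail handling", {
  s <- slice_haplotype(strrep("A", 250000))
  expect_equal(s$offset, c(0L, 100000L, 200000L))
  expect_equal(nchar(s$fragment), c(100000L, 100000L, 50000L))

  s <- slice_haplotype(strrep("A", 100000))
  expect_equal(nrow(s), 1)

  # sub-window tail folds into the previous fragment
  s <- slice_haplotype(strrep("A", 205000))
  expect_equal(nchar(s$fragment), c(100000L, 105000L))

  expect_error(slice_haplotype(strrep("A", 5000)), "shorter")
})

test_that("window_snp_counts recovers planted substitution counts", {
  set.seed(12)
  donor <- rnd_dna(40000)
  frag <- donor
  # plant 2 SNPs in window 2 (positions 10000-19999)
  ch <- strsplit(frag, "")[[1]]
  for (p in c(12345, 17890)) ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
  frag <- paste(ch, collapse = "")
  counts <- window_snp_counts(frag, donor)
  expect_equal(counts, c(0, 2, 0, 0))

  # identical fragment: all zero
  expect_equal(window_snp_counts(donor, donor), rep(0, 4))

  # no homology: all windows unaligned
  expect_true(all(is.infinite(window_snp_counts(rnd_dna(20000), donor))))
})

test_that("the hierarchy rule labels windows as in the H2 example", {
  cfg <- paint_config()
  # a z window with 2 SNPs to k and 1 SNP to b is marked b (highest wins)
  seg <- paint_windows(list(k = 2, b = 1), cfg, query_label = "z")
  expect_equal(seg$assigned, "b")
  # "less than 3 SNPs" is strict: 3 SNPs everywhere keeps the own label
  seg <- paint_windows(list(b = 3, k = 3, d = 3), cfg, query_label = "z")
  expect_equal(seg$assigned, "z")
  # 0 SNPs to two donors: higher hierarchy wins
  seg <- paint_windows(list(d = 0, k = 0), cfg, query_label = "z")
  expect_equal(seg$assigned, "k")
  # only lower-hierarchy donors available: self-labeled
  seg <- paint_windows(list(z = 0), cfg, query_label = "b")
  expect_equal(seg$assigned, "b")
  # unknown donor label is a config error
  expect_error(paint_windows(list(nope = 0), cfg), "hierarchy")
})

test_that("segments partition the window grid", {
  cfg <- paint_config()
  counts <- list(b = c(0, 5, 5, 0, 2), k = c(9, 1, 9, 9, 1))
  seg <- paint_windows(counts, cfg, query_label = "z")
  expect_equal(seg$start, c(0, 10000, 20000, 30000))
  expect_equal(seg$end, c(10000, 20000, 30000, 50000))
  expect_equal(seg$assigned, c("b", "k", "z", "b"))
  expect_equal(sum(seg$n_windows), 5)
  # disjoint, sorted, covering
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
})

test_that("raising max_snps_per_window never shrinks non-self windows", {
  set.seed(13)
  counts <- list(b = sample(0:6, 30, TRUE), k = sample(0:6, 30, TRUE))
  n_nonself <- vapply(1:7, function(m) {
    cfg <- paint_config(max_snps_per_window = m)
    seg <- paint_windows(counts, cfg, query_label = "z")
    sum(seg$n_windows[seg$assigned != "z"])
  }, numeric(1))
  expect_true(all(diff(n_nonself) >= 0))
})

test_that("planted two-donor mosaics are painted exactly", {
  set.seed(14)
  base <- rnd_dna(120000)
  donors <- c(b = base, k = mutate_seq(base, 0.002))  # ~20 SNPs / 10 kb
  mz <- gen_mosaic_haplotype(
    donors, data.frame(label = c("b", "k"), length = c(50000, 50000)),
    noise_snps_per_10kb = 0, seed = 3)
  cfg <- paint_config(hierarchy = c("b", "k", "z"))
  seg <- paint_haplotype(mz$query, donors, cfg, query_label = "z")
  expect_equal(seg$assigned, c("b", "k"))
  expect_equal(seg$start, c(0, 50000))
  expect_equal(seg$end, c(50000, 100000))

  # heavy noise (5 SNPs per 10 kb) exceeds the strict <3 bound: all self
  mz5 <- gen_mosaic_haplotype(
    donors, data.frame(label = c("b", "k"), length = c(50000, 50000)),
    noise_snps_per_10kb = 5, seed = 4)
  seg5 <- paint_haplotype(mz5$query, donors, cfg, query_label = "z")
  expect_true(all(seg5$assigned == "z"))
})

test_that("mosaic recovery tolerates sparse noise and finds breakpoints", {
  set.seed(15)
  base <- rnd_dna(200000)
  donors <- c(b = base, k = mutate_seq(base, 0.002),
              d = mutate_seq(base, 0.002))
  plan <- data.frame(label = c("k", "d", "k"),
                     length = c(60000, 30000, 40000))
  mz <- gen_mosaic_haplotype(donors, plan, noise_snps_per_10kb = 1,
                             seed = 5)
  cfg <- paint_config(hierarchy = c("b", "k", "d", "z"))
  seg <- paint_haplotype(mz$query, donors["k" == names(donors) |
                                            names(donors) == "d"],
                         cfg, query_label = "z")
  # windows: planted labels per 10 kb window
  win_label <- rep(plan$label, plan$length / 10000)
  got <- rep(seg$assigned, seg$n_windows)
  expect_gte(mean(got == win_label), 0.95)
  # breakpoints within one window
  bp_true <- cumsum(plan$length)[1:2]
  bp_got <- seg$end[seg$assigned != c(seg$assigned[-1], "")][1:2]
  expect_true(all(abs(bp_got - bp_true) <= 10000))
})
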