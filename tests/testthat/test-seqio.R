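test_that("read_fasta folds case, takes first header token, validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgt"), f)
  expect_equal(read_fasta(f), c(x = "ACGT"))

  writeLines(c(">x", "ACGT", ">x", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*x")

  writeLines(c(">bad", "ACRT"), f)
  expect_error(read_fasta(f), "bad")

  writeLines(character(0), f)
  expect_length(read_fasta(f), 0)
})

test_that("extract_cds recovers plus-strand single-exon CDS by substring", {
  f <- withr::local_tempfile(fileext = ".gff3")
  genome <- c(chr = "AAAAAAAAAACGTCGAAGGGGGGGG")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tmRNA\t11\t16\t.\t+\t.\tID=t1;Parent=g1",
               "chr\tsrc\tCDS\t11\t16\t.\t+\t0\tID=c1;Parent=t1"), f)
  recs <- extract_cds(genome, f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$seq, "CGTCGA")
  expect_equal(recs[[1]]$gene_id, "g1")
  expect_equal(recs[[1]]$exon_intervals[, "start"], 10L,
               ignore_attr = TRUE)
})

test_that("extract_cds reverse-complements two-exon minus-strand CDS", {
  # genome 1-based: exon1 [3,8] = ACGTAC, exon2 [11,16] = GGCTTA
  genome <- c(chr = paste0("TT", "ACGTAC", "TT", "GGCTTA", "TT"))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tmRNA\t3\t16\t.\t-\t.\tID=t1;Parent=g1",
               "chr\tsrc\tCDS\t3\t8\t.\t-\t0\tID=c1;Parent=t1",
               "chr\tsrc\tCDS\t11\t16\t.\t-\t0\tID=c2;Parent=t1"), f)
  recs <- extract_cds(genome, f)
  # hand-computed: revcomp("ACGTACGGCTTA") = "TAAGCCGTACGT"
  expect_equal(recs[[1]]$seq, "TAAGCCGTACGT")
  expect_equal(recs[[1]]$strand, "-")
})

test_that("extract_cds rejects missing chromosomes and mixed strands", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrX\tsrc\tCDS\t1\t6\t.\t+\t0\tID=c1;Parent=t1"), f)
  expect_error(extract_cds(c(chr = "ACGTACGT"), f), "missing chromosome")

  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t1\t4\t.\t+\t0\tID=c1;Parent=t1",
               "chr\tsrc\tCDS\t6\t8\t.\t-\t0\tID=c2;Parent=t1"), f)
  expect_error(extract_cds(c(chr = "ACGTACGT"), f), "mixed")
})

test_that("pair_orthologs intersects genes and reports skips", {
  mk <- function(gene, tx, seq, strain = "x")
    cds_record(gene, tx, strain, "chr", cbind(0L, nchar(seq)), "+", seq)
  ref <- list(mk("g1", "g1.t1", "ACGTACGT"), mk("g2", "g2.t1", "ACGTAC"))
  strain <- list(mk("g2", "g2.t1", "ACGTAC"), mk("g3", "g3.t1", "ACGT"))
  res <- pair_orthologs(ref, strain)
  expect_length(res$pairs, 1)
  expect_equal(res$pairs[[1]]$gene_id, "g2")
  expect_setequal(res$skipped$gene_id, c("g1", "g3"))

  # paired + skipped partitions the union of gene ids
  all_ids <- union(c("g1", "g2"), c("g2", "g3"))
  expect_setequal(c(res$pairs[[1]]$gene_id, res$skipped$gene_id), all_ids)

  # empty strain side: all ref genes skipped
  res0 <- pair_orthologs(ref, list())
  expect_length(res0$pairs, 0)
  expect_equal(nrow(res0$skipped), 2)
})

test_that("canonical transcript is the longest CDS, ties lexicographic", {
  mk <- function(gene, tx, seq)
    cds_record(gene, tx, "x", "chr", cbind(0L, nchar(seq)), "+", seq)
  ref <- list(mk("g1", "g1.t2", "ACGTACGTAC"), mk("g1", "g1.t1", "ACGTAC"))
  strain <- list(mk("g1", "g1.tB", "ACGTAC"), mk("g1", "g1.tA", "ACGTAC"))
  res <- pair_orthologs(ref, strain)
  expect_equal(res$pairs[[1]]$ref_cds$transcript_id, "g1.t2")   # longest
  expect_equal(res$pairs[[1]]$strain_cds$transcript_id, "g1.tA") # tie: lex
})

test_that("write_outputs writes BEDs that round-trip coordinates", {
  d <- withr::local_tempdir()
  blocks <- data.frame(gene_id = "g1", a_start = 1000L, a_end = 1462L,
                       b_start = 1000L, b_end = 2050L, unit_len = 42,
                       copies_a = 11, copies_b = 25, r = 1050 / 462,
                       confidence = 1, n_diagonals = 35L)
  calls <- data.frame(gene_id = "g1", strain = "s", unit_len = 42,
                      copies_ref = 11, copies_strain = 25, r = 1050 / 462,
                      confidence = 1, flagged = TRUE, reason = "ratio_high")
  paths <- write_outputs(calls, blocks, out_dir = d)
  expect_true(all(file.exists(paths)))
  back <- rtracklayer::import(paths[["blocks_ref"]])
  expect_equal(GenomicRanges::start(back) - 1L, 1000L)  # BED is 0-based
  expect_equal(GenomicRanges::end(back), 1462L)
  tab <- read.delim(paths[["calls"]])
  expect_equal(tab$gene_id, "g1")
  expect_true(tab$flagged)

  # empty inputs: headers-only TSV, empty BEDs
  d2 <- withr::local_tempdir()
  p2 <- write_outputs(NULL, NULL, out_dir = d2)
  expect_equal(nrow(read.delim(p2[["calls"]])), 0)
})
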