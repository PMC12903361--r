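# Seeded generation uses R's Mersenne-Twister with every RNG kind pinned
# explicitly, and restores the caller's RNG state afterwards, so fixtures
# are byte-stable across platforms and sessions.
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection"))
  expr
}

.random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random unit with an exact GC base count (round(gc * len))
.random_unit <- function(unit_len, gc) {
  n_gc <- round(gc * unit_len)
  if (n_gc < 0 || n_gc > unit_len)
    stop("impossible GC fraction ", gc, " for unit length ", unit_len)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), unit_len - n_gc, replace = TRUE))
  paste(bases[sample.int(unit_len)], collapse = "")
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate & chars != "N")
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# flank with no repeated seed_len-mer internally nor shared with the unit:
# guarantees negative controls are truly negative
.clean_flank <- function(len, unit, seed_len = 12L, max_tries = 50L) {
  unit_kmers <- if (nchar(unit) >= seed_len)
    substring(unit, seq_len(nchar(unit) - seed_len + 1L),
              seq_len(nchar(unit) - seed_len + 1L) + seed_len - 1L)
  else character(0)
  # the unit is circular in the array: include wrap-around k-mers
  if (nchar(unit) >= seed_len) {
    wrap <- paste0(unit, substring(unit, 1L, seed_len - 1L))
    unit_kmers <- unique(substring(
      wrap, seq_len(nchar(unit)), seq_len(nchar(unit)) + seed_len - 1L))
  }
  for (try in seq_len(max_tries)) {
    fl <- .random_dna(len)
    if (len < seed_len) return(fl)
    km <- substring(fl, seq_len(len - seed_len + 1L),
                    seq_len(len - seed_len + 1L) + seed_len - 1L)
    if (!anyDuplicated(km) && !any(km %in% unit_kmers)) return(fl)
  }
  stop("could not generate a repeat-free flank of length ", len)
}

#' Generate a synthetic ortholog pair with a planted tandem array
#'
#' One ancestral unit of the requested GC content is tandemly repeated,
#' with independent per-site substitutions at the divergence rate applied
#' to every copy, and embedded in unique flanks shared by both alleles.
#' Flanks are rejection-sampled to contain no repeated seed-length k-mer,
#' so they contribute no dot-plot signal of their own.
#'
#' @param unit_len Unit length in bp.
#' @param copies_a,copies_b Copy numbers of the two alleles.
#' @param divergence Per-site substitution rate applied to each copy.
#' @param flank_len Flank length in bp on each side (default 1000).
#' @param gc_bias Target unit GC fraction (default 0.5).
#' @param seed Integer seed.
#' @param gene_id Gene label recorded in the truth.
#' @return List with `seq_a`, `seq_b` and `truth` (gene_id, unit_seq,
#'   unit_len, copies, divergence, flank_len, array spans on both alleles
#'   as 0-based half-open `c(start, end)`, seed).
#' @export
gen_vntr_pair <- function(unit_len, copies_a, copies_b, divergence = 0,
                          flank_len = 1000L, gc_bias = 0.5, seed = 1L,
                          gene_id = "gene1") {
  stopifnot(unit_len >= 1, copies_a >= 1, copies_b >= 1,
            divergence >= 0, divergence < 0.5)
  with_sim_seed(seed, {
    unit <- .random_unit(unit_len, gc_bias)
    left <- .clean_flank(flank_len, unit)
    right <- .clean_flank(flank_len, unit)
    array_of <- function(k) paste(
      vapply(seq_len(k), function(i) .mutate(unit, divergence),
             character(1)), collapse = "")
    arr_a <- array_of(copies_a)
    arr_b <- array_of(copies_b)
    list(seq_a = paste0(left, arr_a, right),
         seq_b = paste0(left, arr_b, right),
         truth = list(gene_id = gene_id, unit_seq = unit,
                      unit_len = unit_len,
                      copies_a = copies_a, copies_b = copies_b,
                      divergence = divergence, flank_len = flank_len,
                      span_a = c(flank_len, flank_len + copies_a * unit_len),
                      span_b = c(flank_len, flank_len + copies_b * unit_len),
                      seed = seed))
  })
}

#' Generate an annotated toy genome pair (reference + strain)
#'
#' Builds a single-chromosome genome pair with single- and multi-exon CDS
#' on both strands; `round(n_genes * vntr_fraction)` genes carry a planted
#' VNTR whose copy number differs between reference and strain by more
#' than the polymorphism ratio band, the rest are identical between the
#' two genomes. Written annotation is standard GFF3 (gene/mRNA/CDS).
#'
#' @param n_genes Number of genes.
#' @param vntr_fraction Fraction of genes with planted polymorphism.
#' @param seed Integer seed.
#' @param unit_range,copy_range Sampling ranges for planted arrays.
#' @param divergence Per-copy per-site substitution rate of planted arrays.
#' @return List with `ref` and `strain` (each: `genome` named character
#'   vector, `gff` data.frame of gene/mRNA/CDS rows) and `truth` (per-gene
#'   list with vntr flag, unit, copies).
#' @export
gen_annotated_genome <- function(n_genes, vntr_fraction, seed = 1L,
                                 unit_range = c(20L, 80L),
                                 copy_range = c(7L, 18L),
                                 divergence = 0.005) {
  stopifnot(n_genes >= 1, vntr_fraction >= 0, vntr_fraction <= 1)
  n_vntr <- round(n_genes * vntr_fraction)
  with_sim_seed(seed, {
    vntr_genes <- sort(sample.int(n_genes, n_vntr))
    build <- list(ref = character(0), strain = character(0))
    gff <- list(ref = list(), strain = list())
    pos <- c(ref = 0L, strain = 0L)
    truth <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      strand <- sample(c("+", "-"), 1)
      n_exon <- sample(1:3, 1)
      exon_seqs <- vapply(seq_len(n_exon),
                          function(i) .random_dna(sample(300:800, 1)),
                          character(1))
      is_vntr <- g %in% vntr_genes
      info <- list(gene_id = gid, vntr = is_vntr, strand = strand)
      exon_seqs_strain <- exon_seqs
      if (is_vntr) {
        unit_len <- sample(unit_range[1]:unit_range[2], 1)
        unit <- .random_unit(unit_len, 0.5)
        repeat {  # planted polymorphism: copy ratio outside [0.9, 1.1]
          cc <- sample(copy_range[1]:copy_range[2], 2, replace = TRUE)
          if (min(cc) / max(cc) < 0.85) break
        }
        arr <- function(k) paste(
          vapply(seq_len(k), function(i) .mutate(unit, divergence),
                 character(1)), collapse = "")
        host <- sample(n_exon, 1)
        exon_seqs[host] <- paste0(exon_seqs[host], arr(cc[1]),
                                  .random_dna(100))
        exon_seqs_strain[host] <- paste0(exon_seqs_strain[host], arr(cc[2]),
                                         .random_dna(100))
        info <- c(info, list(unit_seq = unit, unit_len = unit_len,
                             copies_ref = cc[1], copies_strain = cc[2]))
      }
      info$cds_ref <- paste(exon_seqs, collapse = "")
      info$cds_strain <- paste(exon_seqs_strain, collapse = "")
      truth[[gid]] <- info
      for (side in c("ref", "strain")) {
        exs <- if (side == "ref") exon_seqs else exon_seqs_strain
        spacer <- .random_dna(sample(500:1500, 1))
        build[[side]] <- c(build[[side]], spacer)
        pos[side] <- pos[side] + nchar(spacer)
        starts <- integer(n_exon); ends <- integer(n_exon)
        for (i in seq_len(n_exon)) {
          if (i > 1) {
            intron <- .random_dna(sample(100:400, 1))
            build[[side]] <- c(build[[side]], intron)
            pos[side] <- pos[side] + nchar(intron)
          }
          # on minus strand the genome carries the reverse complement,
          # exons in genome order are the spliced sequence reversed
          k <- if (strand == "+") i else n_exon - i + 1L
          piece <- if (strand == "+") exs[k] else
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(exs[k])))
          build[[side]] <- c(build[[side]], piece)
          starts[i] <- pos[side]
          pos[side] <- pos[side] + nchar(piece)
          ends[i] <- pos[side]
        }
        gff[[side]][[gid]] <- data.frame(
          seqid = "chr1", start0 = starts, end0 = ends, strand = strand,
          gene_id = gid, tx_id = paste0(gid, ".t1"),
          stringsAsFactors = FALSE)
      }
    }
    out <- lapply(c(ref = "ref", strain = "strain"), function(side) {
      genome <- c(chr1 = paste(build[[side]], collapse = ""))
      rows <- do.call(rbind, gff[[side]])
      list(genome = genome, gff = rows)
    })
    list(ref = out$ref, strain = out$strain, truth = truth)
  })
}

#' Write a simulated annotation as a GFF3 file
#'
#' Emits gene, mRNA and CDS rows (1-based inclusive coordinates) from the
#' exon table produced by [gen_annotated_genome()].
#'
#' @param gff Exon table (`$ref$gff` / `$strain$gff` component).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(gff, path) {
  lines <- "##gff-version 3"
  for (tx in unique(gff$tx_id)) {
    sub <- gff[gff$tx_id == tx, , drop = FALSE]
    gid <- sub$gene_id[1]
    g_start <- min(sub$start0) + 1L; g_end <- max(sub$end0)
    lines <- c(lines,
      sprintf("%s\tdotvntr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              sub$seqid[1], g_start, g_end, sub$strand[1], gid),
      sprintf("%s\tdotvntr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              sub$seqid[1], g_start, g_end, sub$strand[1], tx, gid),
      sprintf("%s\tdotvntr\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s;Parent=%s",
              sub$seqid, sub$start0 + 1L, sub$end0, sub$strand, tx, tx))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a mosaic query haplotype from donor segments
#'
#' The query is a concatenation of donor segments per `plan`, with exactly
#' `noise_snps_per_10kb` substitutions planted in every 10 kb window (at
#' seeded random positions), so planted densities are exact, not expected.
#'
#' @param donors Named character vector of donor sequences.
#' @param plan data.frame or list of `(label, length)` pairs; lengths must
#'   be multiples of 10 kb and fit within the donors.
#' @param noise_snps_per_10kb Planted substitutions per 10 kb window
#'   (integer).
#' @param seed Integer seed.
#' @return List with `query` and `truth` (data.frame of segments: label,
#'   start, end on the query, donor_start, n_snps planted).
#' @export
gen_mosaic_haplotype <- function(donors, plan, noise_snps_per_10kb = 0,
                                 seed = 1L) {
  if (is.data.frame(plan))
    plan <- lapply(seq_len(nrow(plan)),
                   function(i) list(label = plan$label[i],
                                    length = plan$length[i]))
  labs <- vapply(plan, function(p) as.character(p$label), character(1))
  lens <- vapply(plan, function(p) as.integer(p$length), integer(1))
  if (any(!labs %in% names(donors)))
    stop("unknown donor label(s): ",
         paste(setdiff(labs, names(donors)), collapse = ", "))
  stopifnot(all(lens %% 10000L == 0L), all(lens >= 10000L))
  with_sim_seed(seed, {
    pieces <- character(length(plan))
    truth <- list()
    qpos <- 0L
    used <- stats::setNames(integer(length(donors)), names(donors))
    for (i in seq_along(plan)) {
      lab <- labs[i]; len <- lens[i]
      d_start <- used[[lab]]
      if (d_start + len > nchar(donors[[lab]]))
        stop("donor ", lab, " too short for plan")
      piece <- substring(donors[[lab]], d_start + 1L, d_start + len)
      used[[lab]] <- used[[lab]] + len  # consecutive draws from each donor
      n_snps <- 0L
      if (noise_snps_per_10kb > 0) {
        ch <- strsplit(piece, "", fixed = TRUE)[[1]]
        for (w in seq_len(len %/% 10000L)) {
          at <- (w - 1L) * 10000L + sample.int(10000L,
                                               noise_snps_per_10kb)
          for (j in at)
            ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
          n_snps <- n_snps + as.integer(noise_snps_per_10kb)
        }
        piece <- paste(ch, collapse = "")
      }
      pieces[i] <- piece
      truth[[i]] <- data.frame(label = lab, start = qpos, end = qpos + len,
                               donor_start = d_start, n_snps = n_snps,
                               stringsAsFactors = FALSE)
      qpos <- qpos + len
    }
    list(query = paste(pieces, collapse = ""),
         truth = do.call(rbind, truth))
  })
}
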