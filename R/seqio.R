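#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences, keeps the first whitespace-delimited token of each header as
#' the record ID, and validates the alphabet.
#'
#' @param path Path to a FASTA file (plain or line-wrapped).
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate sequence ID(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "),
         " (IUPAC ambiguity codes other than N are not supported)")
  names(seqs) <- ids
  seqs
}

#' Construct a CDS record
#'
#' A spliced, strand-resolved coding sequence with provenance coordinates.
#' Exon intervals are 0-based half-open genome coordinates sorted by genome
#' position; `seq` is already reverse-complemented for minus-strand records.
#'
#' @param gene_id,transcript_id,strain,chrom Identifiers.
#' @param exon_intervals Two-column matrix of 0-based half-open intervals.
#' @param strand `"+"` or `"-"`.
#' @param seq Spliced DNA sequence.
#' @return An object of class `cds_record`.
#' @export
cds_record <- function(gene_id, transcript_id, strain, chrom,
                       exon_intervals, strand, seq) {
  exon_intervals <- matrix(as.integer(exon_intervals), ncol = 2,
                           dimnames = list(NULL, c("start", "end")))
  stopifnot(strand %in% c("+", "-"),
            all(exon_intervals[, 2] > exon_intervals[, 1]))
  if (is.unsorted(exon_intervals[, 1], strictly = TRUE) &&
      nrow(exon_intervals) > 1)
    stop("exon intervals must be sorted by genome position")
  if (nrow(exon_intervals) > 1 &&
      any(exon_intervals[-1, 1] < exon_intervals[-nrow(exon_intervals), 2]))
    stop("exon intervals overlap")
  if (nchar(seq) != sum(exon_intervals[, 2] - exon_intervals[, 1]))
    stop("sequence length does not match exon intervals for ", transcript_id)
  if (grepl("[^ACGTN]", seq)) stop("non-ACGTN characters in CDS ", transcript_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 strain = strain, chrom = chrom,
                 exon_intervals = exon_intervals, strand = strand, seq = seq),
            class = "cds_record")
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s/%s %s:%s %d bp (%d exon%s, %s)\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand, nchar(x$seq),
              nrow(x$exon_intervals),
              if (nrow(x$exon_intervals) == 1) "" else "s", x$strain))
  invisible(x)
}

#' Extract spliced CDS from a genome and GFF3 annotation
#'
#' CDS segments of each transcript are concatenated in translation order and
#' minus-strand records reverse-complemented. GFF3 coordinates (1-based
#' inclusive) are converted to the package's 0-based half-open convention.
#'
#' @param genome Named character vector of chromosome sequences (as from
#'   [read_fasta()]).
#' @param gff_path Path to a GFF3 file with CDS features carrying
#'   `Parent` attributes.
#' @param strain Strain label stored on each record.
#' @return List of [cds_record()] objects, one per transcript.
#' @export
extract_cds <- function(genome, gff_path, strain = "ref") {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_cds <- !is.na(mc$type) & as.character(mc$type) == "CDS"
  if (!any(is_cds)) return(list())

  # transcript -> gene map from mRNA/transcript rows
  tx_rows <- as.character(mc$type) %in% c("mRNA", "transcript")
  tx2gene <- character(0)
  if (any(tx_rows)) {
    tid <- as.character(mc$ID[tx_rows])
    par <- vapply(mc$Parent[tx_rows], function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    tx2gene <- stats::setNames(ifelse(is.na(par), tid, par), tid)
  }

  cds <- gr[is_cds]
  parents <- S4Vectors::mcols(cds)$Parent
  pvec <- vapply(seq_along(cds), function(i) {
    p <- parents[[i]]
    if (length(p) == 0) stop("CDS feature without Parent attribute")
    as.character(p[[1]])
  }, character(1))

  out <- list()
  for (tx in unique(pvec)) {
    rows <- which(pvec == tx)
    sub <- cds[rows]
    chrom <- unique(as.character(GenomicRanges::seqnames(sub)))
    if (length(chrom) != 1)
      stop("CDS of transcript ", tx, " spans multiple chromosomes")
    if (!chrom %in% names(genome))
      stop("CDS of transcript ", tx, " references missing chromosome '",
           chrom, "'")
    strand_ <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(strand_) != 1 || !strand_ %in% c("+", "-"))
      stop("transcript ", tx, " has mixed or missing strand")
    ord <- order(GenomicRanges::start(sub))
    starts0 <- GenomicRanges::start(sub)[ord] - 1L  # to 0-based half-open
    ends0 <- GenomicRanges::end(sub)[ord]
    seq <- paste(substring(genome[[chrom]], starts0 + 1L, ends0),
                 collapse = "")
    if (nchar(seq) == 0) stop("zero-length CDS for transcript ", tx)
    if (strand_ == "-")
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    gene <- if (tx %in% names(tx2gene)) tx2gene[[tx]] else tx
    out[[tx]] <- cds_record(gene_id = gene, transcript_id = tx,
                            strain = strain, chrom = chrom,
                            exon_intervals = cbind(starts0, ends0),
                            strand = strand_, seq = seq)
  }
  unname(out)
}

#' Pair orthologous CDS records between a reference and a strain
#'
#' Genes are matched 1-to-1 by shared `gene_id`; one canonical transcript
#' (the longest CDS, ties broken lexicographically by `transcript_id`) is
#' kept per gene per side. Genes absent on either side go to the skip list.
#'
#' @param ref,strain Lists of [cds_record()] objects.
#' @return List with `pairs` (list of `gene_id`, `ref_cds`, `strain_cds`)
#'   and `skipped` (data.frame of gene_id, reason).
#' @export
pair_orthologs <- function(ref, strain) {
  canonical <- function(records) {
    if (length(records) == 0) return(list())
    genes <- vapply(records, `[[`, character(1), "gene_id")
    out <- list()
    for (g in unique(genes)) {
      cand <- records[genes == g]
      len <- vapply(cand, function(r) nchar(r$seq), integer(1))
      tid <- vapply(cand, `[[`, character(1), "transcript_id")
      out[[g]] <- cand[[order(-len, tid)[1]]]
    }
    out
  }
  r <- canonical(ref)
  s <- canonical(strain)
  shared <- sort(as.character(intersect(names(r), names(s))))
  only_r <- setdiff(names(r), names(s))
  only_s <- setdiff(names(s), names(r))
  skipped <- data.frame(
    gene_id = c(only_r, only_s),
    reason = c(rep("absent_in_strain", length(only_r)),
               rep("absent_in_ref", length(only_s))),
    stringsAsFactors = FALSE)
  pairs <- lapply(shared, function(g)
    structure(list(gene_id = g, ref_cds = r[[g]], strain_cds = s[[g]]),
              class = "ortholog_pair"))
  list(pairs = pairs,
       skipped = skipped[order(skipped$gene_id), , drop = FALSE])
}

block_granges <- function(blocks, which = c("a", "b")) {
  which <- match.arg(which)
  if (is.null(blocks) || nrow(blocks) == 0)
    return(GenomicRanges::GRanges())
  st <- blocks[[paste0(which, "_start")]]
  en <- blocks[[paste0(which, "_end")]]
  GenomicRanges::GRanges(
    seqnames = blocks$gene_id,
    ranges = IRanges::IRanges(start = st + 1L, end = en),  # to 1-based
    strand = "+",
    name = sprintf("%s_unit%d", blocks$gene_id, as.integer(blocks$unit_len)),
    score = round(pmin(1, blocks$confidence) * 1000))
}

#' Write scan outputs: call table (TSV) and interval files (BED6)
#'
#' Calls are written one row per gene x strain; blocks and painted segments
#' as BED6 (0-based half-open, name/score columns populated).
#'
#' @param calls data.frame of VNTR calls (as from [run_scan()]).
#' @param blocks data.frame of repeat blocks (as from [detect_blocks()],
#'   with a `gene_id` column).
#' @param paint data.frame of painted haplotype segments (may be `NULL`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_outputs <- function(calls, blocks, paint = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calls = file.path(out_dir, "vntr_calls.tsv"),
             blocks_ref = file.path(out_dir, "blocks_ref.bed"),
             blocks_strain = file.path(out_dir, "blocks_strain.bed"))
  call_cols <- c("gene_id", "strain", "unit_len", "copies_ref",
                 "copies_strain", "r", "confidence", "flagged", "reason")
  if (is.null(calls) || nrow(calls) == 0)
    calls <- stats::setNames(
      as.data.frame(lapply(call_cols, function(x) character(0))), call_cols)
  write.table(calls[, call_cols, drop = FALSE], paths[["calls"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  rtracklayer::export(block_granges(blocks, "a"), paths[["blocks_ref"]],
                      format = "BED")
  rtracklayer::export(block_granges(blocks, "b"), paths[["blocks_strain"]],
                      format = "BED")
  if (!is.null(paint) && nrow(paint) > 0) {
    paths <- c(paths, paint = file.path(out_dir, "painted_segments.bed"))
    gr <- GenomicRanges::GRanges(
      seqnames = paint$query_label,
      ranges = IRanges::IRanges(start = paint$start + 1L, end = paint$end),
      strand = "+", name = paint$assigned,
      score = pmin(1000, ifelse(is.finite(paint$max_snps), paint$max_snps, 1000)))
    rtracklayer::export(gr, paths[["paint"]], format = "BED")
  }
  invisible(paths)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, format = "fasta")
  invisible(path)
}
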