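#' Scan configuration
#'
#' Flat key/value configuration aggregating every stage's constants; unknown
#' keys are rejected. Defaults equal the procedure-defining constants:
#' 10 kb chunk window, 750 px plot area, more-than-5-copies block filter,
#' 0.80 confidence gate, (0.9, 1.1) ratio band, 100 kb slices, 10 kb
#' windows, fewer-than-3-SNPs painting threshold.
#'
#' @param ... Overrides as `key = value` pairs, e.g.
#'   `scan_config(detector.min_copies = 4)`.
#' @return Named list of class `scan_config`.
#' @export
scan_config <- function(...) {
  defaults <- list(
    chunk.window = 10000L, chunk.min_tail = 100L,
    anchors.seed_len = 12L, anchors.match = 5L, anchors.mismatch = -4L,
    anchors.xdrop = 30L, anchors.min_score = 70L, anchors.min_identity = 0.7,
    raster.width = 750L, raster.height = 750L, raster.margin = 40L,
    detector.min_copies = 5, detector.gap_split_factor = 2,
    detector.period_tolerance = 2, detector.min_confidence = 0.80,
    detector.r_low = 0.9, detector.r_high = 1.1,
    paint.slice_len = 100000L, paint.window_len = 10000L,
    paint.max_snps = 3L,
    paint.hierarchy = c("b", "k", "d", "a", "q", "c", "g", "z"))
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) > 0 || is.null(names(over)) || any(names(over) == ""))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "scan_config")
}

.anchor_params_from <- function(cfg) {
  anchor_params(seed_len = cfg$anchors.seed_len,
                match_score = cfg$anchors.match,
                mismatch_score = cfg$anchors.mismatch,
                xdrop = cfg$anchors.xdrop,
                min_anchor_score = cfg$anchors.min_score,
                min_identity = cfg$anchors.min_identity)
}

.detector_config_from <- function(cfg) {
  detector_config(min_copies = cfg$detector.min_copies,
                  gap_split_factor = cfg$detector.gap_split_factor,
                  period_tolerance = cfg$detector.period_tolerance,
                  min_confidence = cfg$detector.min_confidence,
                  r_low = cfg$detector.r_low, r_high = cfg$detector.r_high)
}

#' Scan one ortholog pair for tandem-repeat polymorphism
#'
#' Finds anchors between the two alleles (reference = A axis, strain = B
#' axis) over the full coding sequences — the exact sequence-space union of
#' the per-chunk dot plots — detects repeat blocks, scores confidence and
#' applies the ratio flagging rule.
#'
#' @param ref_seq,strain_seq Allele DNA sequences.
#' @param gene_id,strain Labels for the call.
#' @param cfg A [scan_config()].
#' @return A call: list with `gene_id`, `strain`, `blocks` (data.frame),
#'   `flagged`, `reason`, `n_anchors`.
#' @export
scan_pair <- function(ref_seq, strain_seq, gene_id = NA_character_,
                      strain = "strain", cfg = scan_config()) {
  ap <- .anchor_params_from(cfg)
  dc <- .detector_config_from(cfg)
  anchors <- find_anchors(ref_seq, strain_seq, ap)
  blocks <- detect_blocks(anchors, nchar(ref_seq), nchar(strain_seq),
                          dc, gene_id = gene_id)
  call <- list(gene_id = gene_id, strain = strain, blocks = blocks,
               flagged = FALSE, reason = "none",
               n_anchors = nrow(anchors))
  flag_polymorphic(list(call), dc)[[1]]
}

.calls_table <- function(calls) {
  if (length(calls) == 0)
    return(data.frame(gene_id = character(0), strain = character(0),
                      unit_len = numeric(0), copies_ref = numeric(0),
                      copies_strain = numeric(0), r = numeric(0),
                      confidence = numeric(0), flagged = logical(0),
                      reason = character(0)))
  rows <- lapply(calls, function(call) {
    b <- call$blocks
    if (nrow(b) == 0)
      return(data.frame(gene_id = call$gene_id, strain = call$strain,
                        unit_len = NA_real_, copies_ref = NA_real_,
                        copies_strain = NA_real_, r = NA_real_,
                        confidence = NA_real_, flagged = call$flagged,
                        reason = call$reason, stringsAsFactors = FALSE))
    top <- b[which.max(b$confidence), ]
    data.frame(gene_id = call$gene_id, strain = call$strain,
               unit_len = top$unit_len, copies_ref = top$copies_a,
               copies_strain = top$copies_b, r = top$r,
               confidence = top$confidence, flagged = call$flagged,
               reason = call$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the end-to-end VNTR scan
#'
#' Extracts CDS from both annotated genomes, pairs orthologs by gene ID,
#' scans every pair and writes the call table (TSV) and block BEDs, ranked
#' by confidence descending (ties by gene ID).
#'
#' @param ref_fasta,ref_gff,strain_fasta,strain_gff Input paths.
#' @param out_dir Output directory (created). `NULL` skips writing.
#' @param strain Strain label.
#' @param cfg A [scan_config()].
#' @param verbose Log per-stage counts to standard error.
#' @return List with `calls` (list of call objects, ranked), `table`
#'   (data.frame, one row per gene), `blocks` (data.frame of all retained
#'   blocks), `skipped` (gene skip list), `paths` (written files, if any).
#' @export
run_scan <- function(ref_fasta, ref_gff, strain_fasta, strain_gff,
                     out_dir = NULL, strain = "strain",
                     cfg = scan_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  for (p in c(ref_fasta, ref_gff, strain_fasta, strain_gff))
    if (!file.exists(p)) stop("input file not found: ", p)
  ref_genome <- read_fasta(ref_fasta)
  strain_genome <- read_fasta(strain_fasta)
  ref_cds <- extract_cds(ref_genome, ref_gff, strain = "ref")
  strain_cds <- extract_cds(strain_genome, strain_gff, strain = strain)
  say("extracted CDS: %d ref, %d strain", length(ref_cds),
      length(strain_cds))
  paired <- pair_orthologs(ref_cds, strain_cds)
  say("ortholog pairs: %d (skipped %d)", length(paired$pairs),
      nrow(paired$skipped))

  calls <- lapply(paired$pairs, function(pr) {
    call <- scan_pair(pr$ref_cds$seq, pr$strain_cds$seq,
                      gene_id = pr$gene_id, strain = strain, cfg = cfg)
    say("  %s: %d anchors, %d block(s), flagged=%s", pr$gene_id,
        call$n_anchors, nrow(call$blocks), call$flagged)
    call
  })
  # rank by confidence descending, ties by gene_id
  conf <- vapply(calls, function(c)
    if (nrow(c$blocks) > 0) max(c$blocks$confidence) else -Inf, numeric(1))
  gid <- vapply(calls, `[[`, character(1), "gene_id")
  calls <- calls[order(-conf, gid)]

  blocks <- do.call(rbind, c(lapply(calls, `[[`, "blocks"),
                             list(make.row.names = FALSE)))
  tab <- .calls_table(calls)
  paths <- NULL
  if (!is.null(out_dir))
    paths <- write_outputs(tab, blocks, paint = NULL, out_dir = out_dir)
  say("flagged calls: %d / %d", sum(tab$flagged), nrow(tab))
  list(calls = calls, table = tab, blocks = blocks,
       skipped = paired$skipped, paths = paths)
}
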