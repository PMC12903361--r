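#' Detector configuration
#'
#' The procedure-defining constants sit here: blocks are kept only when the
#' estimated copy number exceeds `min_copies` (strictly more than 5 repeats),
#' the confidence gate is 0.80, and the height/width ratio band is
#' (0.9, 1.1) — calls outside it are flagged as length-polymorphism
#' candidates.
#'
#' @param min_copies Keep blocks only if estimated copies strictly exceed
#'   this (default 5).
#' @param gap_split_factor Split a block where the projected inter-anchor
#'   gap exceeds `max(gap_split_factor * unit, 500)` bp (default 2).
#' @param period_tolerance Diagonal clustering tolerance in bp (default 2).
#' @param min_confidence Confidence gate for flagging; blocks at or below it
#'   are ignored (default 0.80).
#' @param r_low,r_high Ratio band boundaries (defaults 0.9 and 1.1).
#' @param min_period_support Minimum weighted fraction of off-diagonal
#'   offsets a fundamental period must explain (default 0.9).
#' @return List of class `detector_config`.
#' @export
detector_config <- function(min_copies = 5, gap_split_factor = 2,
                            period_tolerance = 2, min_confidence = 0.80,
                            r_low = 0.9, r_high = 1.1,
                            min_period_support = 0.9) {
  stopifnot(r_low > 0, r_low < 1, r_high > 1,
            min_confidence >= 0, min_confidence <= 1,
            period_tolerance >= 0, min_copies >= 0)
  structure(list(min_copies = min_copies,
                 gap_split_factor = gap_split_factor,
                 period_tolerance = period_tolerance,
                 min_confidence = min_confidence,
                 r_low = r_low, r_high = r_high,
                 min_period_support = min_period_support),
            class = "detector_config")
}

#' Estimate the fundamental repeat period from off-diagonal offsets
#'
#' Returns the smallest positive candidate offset `d` such that the observed
#' off-diagonal offsets cluster, within `tolerance`, at integer multiples of
#' `d`; candidates are the observed offset values themselves, weighted by
#' anchor length, and ties break toward smaller `d`.
#'
#' @param offsets Positive off-diagonal offsets in bp (absolute values of
#'   diagonal differences from the block backbone).
#' @param weights Optional weights (anchor lengths); default all 1.
#' @param tolerance Absorption tolerance in bp (default 2).
#' @param min_support Minimum weighted fraction of offsets a period must
#'   explain to be accepted outright (default 0.9).
#' @return The period in bp (numeric, with attribute `support` giving the
#'   explained weight fraction), or `NA` if no off-diagonal offsets.
#' @export
estimate_period <- function(offsets, weights = NULL, tolerance = 2,
                            min_support = 0.9) {
  offsets <- abs(as.numeric(offsets))
  keep <- is.finite(offsets) & offsets > 0
  offsets <- offsets[keep]
  if (length(offsets) == 0) return(NA_real_)
  if (is.null(weights)) weights <- rep(1, length(offsets))
  else weights <- as.numeric(weights)[keep]
  total <- sum(weights)
  cand <- sort(unique(offsets))
  best_d <- NA_real_; best_frac <- -1
  for (d in cand) {
    m <- pmax(1, round(offsets / d))
    ok <- abs(offsets - m * d) <= tolerance
    frac <- sum(weights[ok]) / total
    if (frac >= min_support) {
      return(structure(d, support = frac))
    }
    if (frac > best_frac) { best_frac <- frac; best_d <- d }
  }
  structure(best_d, support = best_frac)
}

# union length and gap positions of a set of 0-based half-open intervals
.interval_union <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  merged_s <- integer(0); merged_e <- integer(0)
  cur_s <- starts[1]; cur_e <- ends[1]
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (starts[i] <= cur_e) cur_e <- max(cur_e, ends[i])
      else { merged_s <- c(merged_s, cur_s); merged_e <- c(merged_e, cur_e)
             cur_s <- starts[i]; cur_e <- ends[i] }
    }
  }
  list(starts = c(merged_s, cur_s), ends = c(merged_e, cur_e))
}

# merge per-diagonal overlapping anchor intervals on the a-axis
.merge_by_diag <- function(anchors) {
  pieces <- lapply(split(anchors, anchors$diag), function(sub) {
    u <- .interval_union(sub$a_start, sub$a_end)
    data.frame(diag = sub$diag[1], a_start = u$starts, a_end = u$ends)
  })
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

# maximal runs of the a-axis covered by >= 2 distinct diagonals
.repeat_mask_runs <- function(merged, join_gap = 500) {
  ev <- data.frame(pos = c(merged$a_start, merged$a_end),
                   delta = rep(c(1L, -1L), each = nrow(merged)))
  ev <- stats::aggregate(delta ~ pos, ev, sum)
  ev <- ev[order(ev$pos), ]
  cov <- cumsum(ev$delta)
  hi <- cov >= 2
  if (!any(hi)) return(data.frame(start = integer(0), end = integer(0)))
  idx <- which(hi)
  runs <- data.frame(start = ev$pos[idx], end = ev$pos[idx + 1L])
  runs <- runs[runs$end > runs$start, , drop = FALSE]
  if (nrow(runs) > 1) {  # join runs separated by small gaps
    joined_s <- runs$start[1]; joined_e <- runs$end[1]
    out_s <- integer(0); out_e <- integer(0)
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - joined_e <= join_gap) joined_e <- runs$end[i]
      else { out_s <- c(out_s, joined_s); out_e <- c(out_e, joined_e)
             joined_s <- runs$start[i]; joined_e <- runs$end[i] }
    }
    runs <- data.frame(start = c(out_s, joined_s), end = c(out_e, joined_e))
  }
  runs
}

# clip anchors to an a-axis window; b coordinates follow the diagonal
.clip_anchors <- function(anchors, s, e) {
  cs <- pmax(anchors$a_start, s)
  ce <- pmin(anchors$a_end, e)
  keep <- ce - cs >= 1L
  a <- anchors[keep, , drop = FALSE]
  cs <- cs[keep]; ce <- ce[keep]
  data.frame(a_start = cs, a_end = ce,
             b_start = a$b_start + (cs - a$a_start),
             b_end = a$b_end - (a$a_end - ce),
             diag = a$diag, score = a$score, len = ce - cs)
}

# cluster diagonal values within tolerance; representative = weighted median
.diag_clusters <- function(diags, weights, tolerance) {
  o <- order(diags)
  d <- diags[o]; w <- weights[o]
  grp <- cumsum(c(1L, as.integer(diff(d) > tolerance)))
  reps <- vapply(split(seq_along(d), grp), function(ii) {
    dd <- d[ii]; ww <- w[ii]
    oo <- order(dd)
    cw <- cumsum(ww[oo]) / sum(ww)
    dd[oo][which(cw >= 0.5)[1]]
  }, numeric(1))
  wts <- vapply(split(w, grp), sum, numeric(1))
  data.frame(diag = reps, weight = wts)
}

# pick the b-side subcluster of one a-run, guided by the colinear backbone
.pick_b_cluster <- function(clip, anchors, run_s, run_e) {
  o <- order(clip$b_start, clip$b_end)
  clip <- clip[o, , drop = FALSE]
  hi <- cummax(clip$b_end)
  new_grp <- c(FALSE, clip$b_start[-1] > hi[-nrow(clip)] + 500)
  grp <- cumsum(c(1L, as.integer(new_grp[-1])))
  if (max(grp) == 1) return(clip)
  # expected b position at the run edge, from the nearest flanking anchor
  # that reaches well outside the run (the colinear backbone)
  expected <- NA_real_
  left <- anchors[anchors$a_start <= run_s - 100, , drop = FALSE]
  if (nrow(left) > 0) {
    bb <- left[order(-left$a_end, -left$score)[1], ]
    expected <- run_s + bb$diag
  } else {
    right <- anchors[anchors$a_end >= run_e + 100, , drop = FALSE]
    if (nrow(right) > 0) {
      bb <- right[order(right$a_start, -right$score)[1], ]
      expected <- run_e + bb$diag
    }
  }
  groups <- split(clip, grp)
  if (is.na(expected)) {
    wts <- vapply(groups, function(g) sum(g$len), numeric(1))
    return(groups[[which.max(wts)]])
  }
  dist <- vapply(groups, function(g) {
    lo <- min(g$b_start); hi <- max(g$b_end)
    if (expected >= lo && expected <= hi) 0 else min(abs(expected - lo),
                                                     abs(expected - hi))
  }, numeric(1))
  groups[[which.min(dist)]]
}

# build one candidate block from the anchors of one a-run (may recurse on
# criterion-2 gap splits); returns a list of row data.frames
.build_blocks_from_run <- function(anchors, run_s, run_e, cfg, depth = 0) {
  clip <- .clip_anchors(anchors, run_s, run_e)
  if (nrow(clip) == 0) return(list())
  clip <- .pick_b_cluster(clip, anchors, run_s, run_e)
  cl <- .diag_clusters(clip$diag, clip$len, cfg$period_tolerance)
  if (nrow(cl) < 2) return(list())  # no parallel off-diagonal family
  base <- cl$diag[which.max(cl$weight)]
  off <- abs(cl$diag - base)
  unit <- estimate_period(off[off > 0], cl$weight[off > 0],
                          tolerance = cfg$period_tolerance,
                          min_support = cfg$min_period_support)
  if (is.na(unit)) return(list())
  unit <- as.numeric(unit)

  # criterion 2: split at projected gaps wider than the gap rule
  a0 <- min(clip$a_start); a1 <- max(clip$a_end)
  u <- .interval_union(clip$a_start, clip$a_end)
  gap_lim <- max(cfg$gap_split_factor * unit, 500)
  if (length(u$starts) > 1 && depth < 8) {
    gaps <- u$starts[-1] - u$ends[-length(u$ends)]
    big <- which(gaps > gap_lim)
    if (length(big) > 0) {
      bounds <- c(a0, u$ends[big], a1)
      starts <- c(a0, u$starts[big + 1L])
      out <- list()
      for (i in seq_along(starts))
        out <- c(out, .build_blocks_from_run(anchors, starts[i],
                                             bounds[i + 1L], cfg, depth + 1))
      return(out)
    }
  }

  # edge consensus: the parallel family starts/ends exactly at the array
  # boundary, while X-drop extensions overshoot into the flank by random
  # small amounts; the modal coordinate within one unit of the extreme is
  # the boundary
  refine_edge <- function(vals, extreme, inner) {
    cand <- vals[abs(vals - extreme) <= unit]
    tb <- table(cand)
    if (max(tb) < 2) return(extreme)
    modal <- as.numeric(names(tb)[tb == max(tb)])
    if (inner) max(modal) else min(modal)
  }
  a0 <- refine_edge(clip$a_start, a0, inner = TRUE)
  a1 <- refine_edge(clip$a_end, a1, inner = FALSE)
  b0 <- refine_edge(clip$b_start, min(clip$b_start), inner = TRUE)
  b1 <- refine_edge(clip$b_end, max(clip$b_end), inner = FALSE)
  cov <- sum(pmax(0, pmin(u$ends, a1) - pmax(u$starts, a0))) / (a1 - a0)
  list(data.frame(
    a_start = a0, a_end = a1, b_start = b0, b_end = b1,
    unit_len = unit,
    copies_a = (a1 - a0) / unit, copies_b = (b1 - b0) / unit,
    r = (b1 - b0) / (a1 - a0),
    n_diagonals = nrow(cl),
    mean_anchor_len = mean(clip$len),
    coverage = cov))
}

#' Detect tandem-repeat signal blocks from dot-plot anchors
#'
#' Off-diagonal anchors are clustered into candidate blocks (regions of the
#' reference axis covered by two or more distinct diagonals), split where
#' projected gaps exceed the gap rule, and filtered by the annotation
#' criteria: blocks must exceed `min_copies` estimated repeat copies, and
#' blocks made of ultra-short scattered matches (mean anchor length below
#' half a unit covering under 30% of the bounding box) are rejected. The
#' repeat unit length is the fundamental period of the parallel-diagonal
#' family; per-allele copy numbers are span / unit; `r` is the strain span
#' over the reference span. Blocks abutting within one unit length on both
#' axes are merged before filtering, so windowed (chunked) anchor sets do
#' not split real arrays.
#'
#' @param anchors data.frame from [find_anchors()] for one ortholog pair, in
#'   full-CDS coordinates (sequence A = reference, B = strain).
#' @param len_a,len_b Allele lengths in bp.
#' @param cfg A [detector_config()].
#' @param gene_id Optional gene label carried into the output.
#' @return data.frame with one row per retained block: `gene_id`, `a_start`,
#'   `a_end`, `b_start`, `b_end`, `unit_len`, `copies_a`, `copies_b`, `r`,
#'   `confidence`, `n_diagonals`.
#' @export
detect_blocks <- function(anchors, len_a, len_b, cfg = detector_config(),
                          gene_id = NA_character_) {
  empty <- data.frame(gene_id = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), unit_len = numeric(0),
                      copies_a = numeric(0), copies_b = numeric(0),
                      r = numeric(0), confidence = numeric(0),
                      n_diagonals = integer(0))
  if (is.null(anchors) || nrow(anchors) == 0) return(empty)

  merged <- .merge_by_diag(anchors)
  runs <- .repeat_mask_runs(merged, join_gap = 500)
  if (nrow(runs) == 0) return(empty)

  cand <- list()
  for (i in seq_len(nrow(runs)))
    cand <- c(cand, .build_blocks_from_run(anchors, runs$start[i],
                                           runs$end[i], cfg))
  if (length(cand) == 0) return(empty)
  blocks <- do.call(rbind, cand)

  # merge blocks that abut within one unit length on both axes (cross-chunk)
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  i <- 1L
  while (i < nrow(blocks)) {
    cur <- blocks[i, ]; nxt <- blocks[i + 1L, ]
    close_unit <- abs(cur$unit_len - nxt$unit_len) <= cfg$period_tolerance
    if (close_unit &&
        nxt$a_start - cur$a_end <= cur$unit_len &&
        nxt$b_start - cur$b_end <= cur$unit_len) {
      unit <- cur$unit_len
      m <- cur
      m$a_end <- max(cur$a_end, nxt$a_end)
      m$b_end <- max(cur$b_end, nxt$b_end)
      m$b_start <- min(cur$b_start, nxt$b_start)
      m$copies_a <- (m$a_end - m$a_start) / unit
      m$copies_b <- (m$b_end - m$b_start) / unit
      m$r <- (m$b_end - m$b_start) / (m$a_end - m$a_start)
      m$n_diagonals <- max(cur$n_diagonals, nxt$n_diagonals)
      m$mean_anchor_len <- (cur$mean_anchor_len + nxt$mean_anchor_len) / 2
      m$coverage <- min(cur$coverage, nxt$coverage)
      blocks <- rbind(if (i > 1) blocks[seq_len(i - 1L), ], m,
                      if (i + 1L < nrow(blocks))
                        blocks[seq(i + 2L, nrow(blocks)), ])
    } else i <- i + 1L
  }

  # criterion 1: strictly more than min_copies repeats on at least one
  # allele, assessed at 0.1-copy resolution (block edges are localized to
  # a few bp, so raw copies carry sub-decimal jitter)
  keep <- round(pmax(blocks$copies_a, blocks$copies_b), 1) >
    cfg$min_copies + 0.05
  # criterion 3: ultra-short lines and points with poor coverage
  keep <- keep & !(blocks$mean_anchor_len < blocks$unit_len / 2 &
                   blocks$coverage < 0.3)
  blocks <- blocks[keep, , drop = FALSE]
  if (nrow(blocks) == 0) return(empty)

  blocks$gene_id <- gene_id
  blocks$confidence <- vapply(seq_len(nrow(blocks)), function(i)
    score_confidence(blocks[i, ], anchors, cfg), numeric(1))
  rownames(blocks) <- NULL
  blocks[, c("gene_id", "a_start", "a_end", "b_start", "b_end", "unit_len",
             "copies_a", "copies_b", "r", "confidence", "n_diagonals")]
}

#' Deterministic confidence score of a repeat block
#'
#' Confidence is the fraction of expected parallel diagonals that carry an
#' anchor, multiplied by the anchor coverage of the block bounding box on
#' the reference axis, clamped to \[0, 1\]. A noiseless exact array scores
#' 1.0. The expected diagonal count for spans `(wa, wb)` and unit `u` is
#' `floor((wa + wb)/u) - 1` (i.e. `copies_a + copies_b - 1` for exact
#' arrays).
#'
#' @param block One-row data.frame as produced by [detect_blocks()].
#' @param anchors The anchor set of the pair.
#' @param cfg A [detector_config()].
#' @return Numeric confidence in \[0, 1\].
#' @export
score_confidence <- function(block, anchors, cfg = detector_config()) {
  clip <- .clip_anchors(anchors, block$a_start, block$a_end)
  if (nrow(clip) == 0)
    stop("contract violation: block has no supporting anchors")
  cl <- .diag_clusters(clip$diag, clip$len, cfg$period_tolerance)
  wa <- block$a_end - block$a_start
  wb <- block$b_end - block$b_start
  n_exp <- max(1, floor((wa + wb) / block$unit_len) - 1)
  u <- .interval_union(clip$a_start, clip$a_end)
  cov <- sum(u$ends - u$starts) / wa
  max(0, min(1, nrow(cl) / n_exp) * min(1, cov))
}

#' Flag copy-number polymorphism candidates via the height/width ratio
#'
#' Blocks at or below the confidence gate are ignored; a call is flagged
#' when a remaining block has `r < r_low` (reason `ratio_low`) or
#' `r > r_high` (reason `ratio_high`).
#'
#' @param calls List of calls, each a list with at least `blocks` (a
#'   data.frame carrying `r` and `confidence`).
#' @param cfg A [detector_config()].
#' @return The calls, each with `flagged` (logical) and `reason`
#'   (`"ratio_low"`, `"ratio_high"` or `"none"`) filled in.
#' @export
flag_polymorphic <- function(calls, cfg = detector_config()) {
  lapply(calls, function(call) {
    b <- call$blocks
    b <- b[b$confidence > cfg$min_confidence, , drop = FALSE]
    low <- b$r < cfg$r_low
    high <- b$r > cfg$r_high
    call$flagged <- any(low) || any(high)
    call$reason <- if (!call$flagged) "none" else {
      off <- which(low | high)
      worst <- off[which.max(b$confidence[off])]
      if (b$r[worst] < cfg$r_low) "ratio_low" else "ratio_high"
    }
    call
  })
}
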