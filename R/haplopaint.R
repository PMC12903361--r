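#' Haplotype-painting configuration
#'
#' Defaults follow the MHC (H2) procedure: the query is sliced into 100 kb
#' fragments, substitution density is assessed per non-overlapping 10 kb
#' window, a window qualifies for a donor when it carries strictly fewer
#' than 3 SNPs against it (0.3 per mille), and qualifying donors compete
#' under the fixed hierarchy b > k > d > a > q > c > g > z.
#'
#' @param slice_len Fragment length in bp (default 100000; must be a
#'   multiple of `window_len`).
#' @param window_len Density window in bp (default 10000).
#' @param max_snps_per_window Strict upper bound: a window qualifies iff its
#'   SNP count is strictly below this (default 3).
#' @param hierarchy Ordered donor labels, highest precedence first.
#' @param min_window_coverage Windows with anchored coverage below this
#'   fraction are treated as unaligned to that donor (default 0.5).
#' @return List of class `paint_config`.
#' @export
paint_config <- function(slice_len = 100000L, window_len = 10000L,
                         max_snps_per_window = 3L,
                         hierarchy = c("b", "k", "d", "a", "q", "c", "g", "z"),
                         min_window_coverage = 0.5) {
  stopifnot(slice_len %% window_len == 0, window_len >= 1,
            !anyDuplicated(hierarchy))
  structure(list(slice_len = as.integer(slice_len),
                 window_len = as.integer(window_len),
                 max_snps_per_window = as.integer(max_snps_per_window),
                 hierarchy = hierarchy,
                 min_window_coverage = min_window_coverage),
            class = "paint_config")
}

#' Slice a query haplotype into fragments
#'
#' Consecutive non-overlapping `slice_len` fragments; a final short
#' fragment is kept on its own if at least one window long, otherwise it is
#' appended to the previous fragment.
#'
#' @param seq Query DNA sequence.
#' @param cfg A [paint_config()].
#' @return data.frame with `offset` (0-based) and `fragment` (sequence).
#' @export
slice_haplotype <- function(seq, cfg = paint_config()) {
  n <- nchar(seq)
  if (n < cfg$window_len)
    stop("sequence shorter than one window (", cfg$window_len, " bp)")
  offsets <- seq.int(0L, max(0L, n - 1L), by = cfg$slice_len)
  ends <- pmin(offsets + cfg$slice_len, n)
  if (length(offsets) > 1) {
    tail_len <- ends[length(ends)] - offsets[length(offsets)]
    if (tail_len < cfg$window_len) {  # fold short tail into previous slice
      ends[length(ends) - 1L] <- n
      offsets <- offsets[-length(offsets)]
      ends <- ends[-length(ends)]
    }
  }
  data.frame(offset = offsets,
             fragment = substring(seq, offsets + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Per-window substitution counts of a fragment against one donor
#'
#' The fragment is anchored to the donor with [find_anchors()]. A fragment
#' position counts as a substitution when it is covered by at least one
#' anchor and matches the donor in none of them (overlapping anchors vote;
#' a match anywhere wins, which keeps segment-boundary overshoot of a
#' neighboring anchor from inflating the count). Counts are per
#' non-overlapping window; a window with anchored coverage below
#' `min_window_coverage` is reported unaligned (`Inf`).
#'
#' @param fragment Query fragment DNA.
#' @param donor Donor haplotype DNA.
#' @param cfg A [paint_config()].
#' @param params [anchor_params()] used for the alignment.
#' @return Numeric vector of per-window SNP counts (`Inf` = unaligned); the
#'   last window absorbs any sub-window remainder of the fragment.
#' @export
window_snp_counts <- function(fragment, donor, cfg = paint_config(),
                              params = anchor_params()) {
  stopifnot(nchar(donor) > 0)
  flen <- nchar(fragment)
  n_win <- max(1L, flen %/% cfg$window_len)
  win_of <- function(pos0) pmin(n_win - 1L, pos0 %/% cfg$window_len)

  anchors <- find_anchors(fragment, donor, params)
  covered <- rep(FALSE, flen)
  any_match <- rep(FALSE, flen)
  for (i in seq_len(nrow(anchors))) {
    s <- anchors$a_start[i]; e <- anchors$a_end[i]
    idx <- (s + 1L):e
    mm <- .segment_mismatches_cpp(fragment, donor, s, anchors$b_start[i],
                                  e - s)
    covered[idx] <- TRUE
    is_mm <- rep(FALSE, e - s)
    is_mm[mm - s + 1L] <- TRUE
    any_match[idx[!is_mm]] <- TRUE
  }
  snp_pos <- which(covered & !any_match) - 1L
  cov_per_win <- tabulate(win_of(which(covered) - 1L) + 1L, nbins = n_win)
  win_len <- rep(cfg$window_len, n_win)
  win_len[n_win] <- flen - (n_win - 1L) * cfg$window_len
  snps <- tabulate(win_of(snp_pos) + 1L, nbins = n_win)
  counts <- as.numeric(snps)
  counts[cov_per_win / win_len < cfg$min_window_coverage] <- Inf
  counts
}

#' Label query windows by donor under the hierarchy rule
#'
#' Per window, donors with a SNP count strictly below
#' `max_snps_per_window` qualify; the window takes the highest-hierarchy
#' qualifying donor, or the query's own label if none qualifies. Only
#' donors ranked above `query_label` in the hierarchy compete (all donors
#' when the query label is not in the hierarchy). Adjacent same-label
#' windows are merged into segments.
#'
#' @param counts Named list: per donor, the per-window SNP count vector
#'   (all donors on the same window grid).
#' @param cfg A [paint_config()].
#' @param query_label Label of the query haplotype (default `"self"`).
#' @param offset Query offset in bp of window 0 (for multi-fragment use).
#' @return data.frame of segments: `query_label`, `start`, `end` (0-based
#'   half-open), `assigned`, `n_windows`, `max_snps`.
#' @export
paint_windows <- function(counts, cfg = paint_config(),
                          query_label = "self", offset = 0L) {
  donors <- names(counts)
  if (is.null(donors) || any(!donors %in% cfg$hierarchy))
    stop("donor label(s) absent from hierarchy: ",
         paste(setdiff(donors, cfg$hierarchy), collapse = ", "))
  rank <- match(donors, cfg$hierarchy)
  qrank <- match(query_label, cfg$hierarchy)
  eligible <- if (is.na(qrank)) rep(TRUE, length(donors)) else rank < qrank
  n_win <- length(counts[[1]])
  stopifnot(all(vapply(counts, length, integer(1)) == n_win))

  assigned <- character(n_win)
  max_snps <- numeric(n_win)
  ord <- order(rank)  # highest hierarchy first
  for (w in seq_len(n_win)) {
    lab <- query_label; snp <- NA_real_
    for (i in ord) {
      if (!eligible[i]) next
      cnt <- counts[[i]][w]
      if (is.finite(cnt) && cnt < cfg$max_snps_per_window) {
        lab <- donors[i]; snp <- cnt; break
      }
    }
    assigned[w] <- lab; max_snps[w] <- snp
  }

  grp <- cumsum(c(1L, as.integer(assigned[-1] != assigned[-n_win])))
  segs <- lapply(split(seq_len(n_win), grp), function(ii) {
    data.frame(query_label = query_label,
               start = offset + (ii[1] - 1L) * cfg$window_len,
               end = offset + ii[length(ii)] * cfg$window_len,
               assigned = assigned[ii[1]],
               n_windows = length(ii),
               max_snps = if (all(is.na(max_snps[ii]))) NA_real_
                          else max(max_snps[ii], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Paint a full query haplotype against a set of donors
#'
#' Slices the query ([slice_haplotype()]), counts per-window substitutions
#' against every donor ([window_snp_counts()]) and labels windows under the
#' hierarchy ([paint_windows()]), merging segments across fragment
#' boundaries.
#'
#' @param query Query DNA sequence.
#' @param donors Named character vector of donor sequences; names are
#'   hierarchy labels.
#' @param cfg A [paint_config()].
#' @param query_label Query's own label.
#' @param params [anchor_params()] for the alignment step.
#' @return data.frame of painted segments (see [paint_windows()]); the last
#'   window of each fragment absorbs any sub-window remainder, so segment
#'   ends may exceed the window grid by up to one window.
#' @export
paint_haplotype <- function(query, donors, cfg = paint_config(),
                            query_label = "self",
                            params = anchor_params()) {
  slices <- slice_haplotype(query, cfg)
  segs <- list()
  for (i in seq_len(nrow(slices))) {
    counts <- lapply(donors, function(d)
      window_snp_counts(slices$fragment[i], d, cfg, params))
    seg <- paint_windows(counts, cfg, query_label = query_label,
                         offset = slices$offset[i])
    # last window absorbed the fragment remainder; extend to true end
    seg$end[nrow(seg)] <- slices$offset[i] + nchar(slices$fragment[i])
    segs[[i]] <- seg
  }
  out <- do.call(rbind, segs)
  # merge same-label segments across fragment boundaries
  if (nrow(out) > 1) {
    keep <- c(TRUE, out$assigned[-1] != out$assigned[-nrow(out)] |
                    out$start[-1] != out$end[-nrow(out)])
    grp <- cumsum(keep)
    out <- do.call(rbind, lapply(split(out, grp), function(g)
      data.frame(query_label = g$query_label[1], start = min(g$start),
                 end = max(g$end), assigned = g$assigned[1],
                 n_windows = sum(g$n_windows),
                 max_snps = if (all(is.na(g$max_snps))) NA_real_
                            else max(g$max_snps, na.rm = TRUE),
                 stringsAsFactors = FALSE)))
  }
  rownames(out) <- NULL
  out
}
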