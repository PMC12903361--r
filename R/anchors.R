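#' Anchor-finding parameters
#'
#' Scoring follows the classic +5/-4 ungapped scheme with an X-drop of 30
#' and minimum anchor score 70; transitions are not privileged (a uniform
#' mismatch penalty replaces 4-way substitution scoring). N never seeds and
#' always scores as a mismatch.
#'
#' @param seed_len Exact-seed length in bp (default 12, minimum 4).
#' @param match_score,mismatch_score Per-base scores (defaults +5 / -4).
#' @param xdrop Stop extension when the running score falls this far below
#'   its maximum (default 30).
#' @param min_anchor_score Minimum score of a reported segment (default 70).
#' @param min_identity Minimum fraction of matching bases (default 0.7).
#' @param max_diag Only report segments with |diagonal| at or below this
#'   (default `Inf`, i.e. the full plot).
#' @return List of class `anchor_params`.
#' @export
anchor_params <- function(seed_len = 12L, match_score = 5L,
                          mismatch_score = -4L, xdrop = 30L,
                          min_anchor_score = 70L, min_identity = 0.7,
                          max_diag = Inf) {
  stopifnot(seed_len >= 4, min_anchor_score > 0, match_score > 0,
            mismatch_score < 0, xdrop > 0,
            min_identity > 0, min_identity <= 1)
  structure(list(seed_len = as.integer(seed_len),
                 match_score = as.integer(match_score),
                 mismatch_score = as.integer(mismatch_score),
                 xdrop = as.integer(xdrop),
                 min_anchor_score = as.integer(min_anchor_score),
                 min_identity = min_identity, max_diag = max_diag),
            class = "anchor_params")
}

#' Find ungapped local match segments (dot-plot anchors)
#'
#' Exact seeds of `seed_len` bases are extended without gaps in both
#' directions under an X-drop rule and trimmed to their maximal-scoring
#' extent. Segments below the score or identity cutoffs are discarded, and
#' segments contained in a higher-scoring segment on the same diagonal are
#' removed. Forward strand only. Coordinates are 0-based half-open; the
#' `diag` column is `b_start - a_start`.
#'
#' @param seq_a,seq_b DNA sequences (character scalars).
#' @param params An [anchor_params()] object.
#' @return data.frame with columns `a_start`, `a_end`, `b_start`, `b_end`,
#'   `identity`, `score`, `diag`, sorted by `a_start` then `diag`.
#' @export
find_anchors <- function(seq_a, seq_b, params = anchor_params()) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            nchar(seq_a) > 0, nchar(seq_b) > 0)
  df <- .find_anchors_cpp(seq_a, seq_b, params$seed_len, params$match_score,
                          params$mismatch_score, params$xdrop,
                          params$min_anchor_score, params$min_identity,
                          as.numeric(params$max_diag))
  if (nrow(df) > 0) {
    # drop segments contained in a higher-scoring segment on the same diagonal
    keep <- rep(TRUE, nrow(df))
    for (d in unique(df$diag)) {
      idx <- which(df$diag == d)
      if (length(idx) < 2) next
      sub <- df[idx, ]
      ord <- idx[order(-sub$score, sub$a_start)]
      best_lo <- integer(0); best_hi <- integer(0)
      for (i in ord) {
        if (any(df$a_start[i] >= best_lo & df$a_end[i] <= best_hi)) {
          keep[i] <- FALSE
        } else {
          best_lo <- c(best_lo, df$a_start[i])
          best_hi <- c(best_hi, df$a_end[i])
        }
      }
    }
    df <- df[keep, , drop = FALSE]
    df <- df[order(df$a_start, df$diag), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
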