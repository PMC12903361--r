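#' Split or pad a CDS into fixed-length comparison windows
#'
#' Coding sequences shorter than the window are centre-padded with N on both
#' ends up to the window length (an odd remainder adds the extra N on the
#' right). Longer sequences are cut into consecutive full windows; a
#' trailing fragment of at least `min_tail` bases becomes a final
#' centre-padded chunk, while shorter tails are dropped (and reported in the
#' `dropped_tail` attribute).
#'
#' @param seq DNA sequence (character scalar).
#' @param window Window length in bp (default 10000).
#' @param min_tail Minimum retained tail length in bp (default 100).
#' @param source_gene Gene label stored on each chunk.
#' @return List of chunks, each a list with `source_gene`, `index`,
#'   `core_start`, `core_end` (offsets into the original CDS, 0-based
#'   half-open), `seq` (length exactly `window`), `left_pad`, `right_pad`.
#'   Attribute `dropped_tail` gives the number of trailing bases dropped.
#' @export
chunk_cds <- function(seq, window = 10000L, min_tail = 100L,
                      source_gene = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  if (n == 0) stop("empty sequence cannot be chunked")
  window <- as.integer(window); min_tail <- as.integer(min_tail)
  if (!(window >= min_tail && min_tail >= 1))
    stop("require window >= min_tail >= 1")

  pad_chunk <- function(core, core_start, core_end, index) {
    deficit <- window - nchar(core)
    lp <- deficit %/% 2L
    rp <- deficit - lp  # odd remainder goes right
    list(source_gene = source_gene, index = index,
         core_start = core_start, core_end = core_end,
         seq = paste0(strrep("N", lp), core, strrep("N", rp)),
         left_pad = lp, right_pad = rp)
  }

  chunks <- list()
  dropped <- 0L
  if (n < window) {
    chunks[[1]] <- pad_chunk(seq, 0L, n, 0L)
  } else {
    n_full <- n %/% window
    for (i in seq_len(n_full) - 1L) {
      s <- i * window
      chunks[[i + 1L]] <- list(
        source_gene = source_gene, index = i,
        core_start = s, core_end = s + window,
        seq = substring(seq, s + 1L, s + window),
        left_pad = 0L, right_pad = 0L)
    }
    tail_len <- n - n_full * window
    if (tail_len >= min_tail) {
      s <- n_full * window
      chunks[[n_full + 1L]] <-
        pad_chunk(substring(seq, s + 1L, n), s, n, n_full)
    } else {
      dropped <- tail_len
    }
  }
  attr(chunks, "dropped_tail") <- dropped
  chunks
}
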