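#' Rasterize anchors to a fixed-size dot-plot grid
#'
#' Each anchor is drawn as a line in pixel space on a fixed `width` x
#' `height` plot area (750 x 750 by default, independent of sequence
#' length); cells accumulate occupancy counts.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param len_a,len_b Sequence lengths in bp (the axis extents).
#' @param width,height Plot area in pixels (defaults 750 x 750).
#' @return List of class `raster_grid` with `cells` (integer matrix, rows =
#'   x/pixels along sequence A, columns = y/pixels along B), `width`,
#'   `height`, `scale_a`, `scale_b` (bases per pixel).
#' @export
rasterize <- function(anchors, len_a, len_b, width = 750L, height = 750L) {
  if (len_a < 1 || len_b < 1) stop("zero-length axis")
  width <- as.integer(width); height <- as.integer(height)
  scale_a <- len_a / width
  scale_b <- len_b / height
  cells <- matrix(0L, nrow = width, ncol = height)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    for (i in seq_len(nrow(anchors))) {
      len <- anchors$a_end[i] - anchors$a_start[i]
      t <- seq.int(0L, len - 1L)
      px <- pmin(width - 1L, as.integer((anchors$a_start[i] + t) / scale_a))
      py <- pmin(height - 1L, as.integer((anchors$b_start[i] + t) / scale_b))
      idx <- unique(px + width * py) + 1L
      cells[idx] <- cells[idx] + 1L
    }
  }
  structure(list(cells = cells, width = width, height = height,
                 scale_a = scale_a, scale_b = scale_b),
            class = "raster_grid")
}

#' Export a raster grid as a portable graymap (PGM) image
#'
#' Occupied cells are drawn black on white. With `axes = TRUE` a margin of
#' `margin` pixels is added on every side (40 px by default, giving an
#' 830 x 830 canvas for the default 750 x 750 plot area) and tick marks are
#' drawn along the two axes.
#'
#' @param grid A `raster_grid` from [rasterize()].
#' @param path Output path (plain-text PGM, magic "P2").
#' @param axes Add the axis margin and ticks?
#' @param margin Margin width in pixels per side.
#' @return Invisibly, an integer matrix of gray levels (0-255) of the full
#'   canvas, `width + 2*margin` squared when `axes` is on.
#' @export
export_pgm <- function(grid, path = NULL, axes = TRUE, margin = 40L) {
  stopifnot(inherits(grid, "raster_grid"))
  img <- matrix(255L, grid$width, grid$height)
  img[grid$cells > 0] <- 0L
  if (axes) {
    m <- as.integer(margin)
    w <- grid$width + 2L * m
    h <- grid$height + 2L * m
    canvas <- matrix(255L, w, h)
    canvas[(m + 1):(m + grid$width), (m + 1):(m + grid$height)] <- img
    canvas[(m + 1):(m + grid$width), m] <- 0L       # x axis
    canvas[m, (m + 1):(m + grid$height)] <- 0L      # y axis
    ticks <- as.integer(seq(0, grid$width - 1, length.out = 11)) + m + 1L
    canvas[ticks, pmax(1L, m - 4L):m] <- 0L
    canvas[pmax(1L, m - 4L):m, ticks] <- 0L
    img <- canvas
  }
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(nrow(img), ncol(img)), "255"), con)
    write(t(img), con, ncolumns = nrow(img))
  }
  invisible(img)
}
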