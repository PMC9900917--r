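#' Plan the resolution levels of a tiled image pyramid
#'
#' Level 0 is the full-resolution image; each subsequent level halves both
#' dimensions with ceiling division. Planning stops at the first level whose
#' larger dimension fits within a single tile, so the coarsest level can
#' always be shown from one tile fetch.
#'
#' @param width,height Level-0 image dimensions in pixels.
#' @param tile_size Tile edge length in pixels (>= 16).
#' @return An object of class `srt_level_plan` with a `levels` matrix
#'   (columns `width`, `height`, one row per level, row 1 = level 0).
#' @examples
#' plan_levels(20000, 20000, 512)  # 7 levels: 20000 ... 313
#' @export
plan_levels <- function(width, height, tile_size = 512L) {
  if (width < 1 || height < 1) stop("image dimensions must be positive")
  if (tile_size < 16) stop("tile_size must be >= 16")
  w <- as.integer(width); h <- as.integer(height)
  dims <- matrix(c(w, h), ncol = 2)
  while (max(w, h) > tile_size) {
    w <- ceiling(w / 2); h <- ceiling(h / 2)
    dims <- rbind(dims, c(w, h))
  }
  colnames(dims) <- c("width", "height")
  structure(list(levels = dims, tile_size = as.integer(tile_size)),
            class = "srt_level_plan")
}

#' @export
print.srt_level_plan <- function(x, ...) {
  cat("<level plan> tile", x$tile_size, "px;", nrow(x$levels), "level(s)\n")
  for (i in seq_len(nrow(x$levels)))
    cat(sprintf("  level %d: %d x %d\n", i - 1L, x$levels[i, 1], x$levels[i, 2]))
  invisible(x)
}

#' Downsample one pyramid level by a factor of two
#'
#' Each output pixel is the arithmetic mean of its source block (2x2 in the
#' interior; 2x1, 1x2 or 1x1 at odd edges), rounded half-up back to the
#' integer range. Output dimensions are the ceiling half of the input.
#'
#' @param parent A numeric matrix (one channel of the finer level).
#' @return An integer matrix of dimensions `ceiling(dim(parent) / 2)`.
#' @export
downsample_level <- function(parent) {
  if (!is.matrix(parent) || any(dim(parent) < 1)) stop("parent must be a non-empty matrix")
  h <- nrow(parent); w <- ncol(parent)
  hc <- ceiling(h / 2); wc <- ceiling(w / 2)
  r1 <- seq(1L, h, by = 2L); c1 <- seq(1L, w, by = 2L)
  r2 <- pmin(r1 + 1L, h); c2 <- pmin(c1 + 1L, w)
  rv <- as.numeric(r1 + 1L <= h); cv <- as.numeric(c1 + 1L <= w) # second row/col exists?
  cm <- matrix(cv, hc, wc, byrow = TRUE)
  s <- parent[r1, c1, drop = FALSE] +
    parent[r2, c1, drop = FALSE] * rv +
    parent[r1, c2, drop = FALSE] * cm +
    parent[r2, c2, drop = FALSE] * rv * cm
  cnt <- outer(1 + rv, 1 + cv)
  out <- floor(s / cnt + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Gaussian-filter an image
#'
#' Per-channel 2-D Gaussian convolution with standard deviation `radius`
#' pixels, separable kernel truncated at four standard deviations, reflected
#' boundary. Used to soften compression and scanner artifacts before pyramid
#' construction. `radius = 0` is the identity.
#'
#' @param image A matrix (single channel) or a channels x height x width array.
#' @param radius Gaussian standard deviation in pixels (>= 0).
#' @return Filtered image with the same shape; integer inputs are rounded
#'   half-up back to integers.
#' @export
gaussian_filter_image <- function(image, radius) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(image)
  was_int <- is.integer(image)
  filt1 <- function(m) {
    r <- ceiling(4 * radius)
    k <- stats::dnorm(seq(-r, r), sd = radius)
    k <- k / sum(k)
    reflect <- function(i, n) {
      j <- (i - 1L) %% (2L * n)
      ifelse(j < n, j + 1L, 2L * n - j)
    }
    conv_rows <- function(a) {
      n <- nrow(a)
      ap <- a[reflect((1L - r):(n + r), n), , drop = FALSE]
      out <- matrix(0, n, ncol(a))
      for (kk in 0:(2L * r)) out <- out + k[kk + 1L] * ap[(1L + kk):(n + kk), , drop = FALSE]
      out
    }
    t(conv_rows(t(conv_rows(m))))
  }
  if (is.matrix(image)) {
    out <- filt1(image)
  } else {
    out <- array(0, dim(image))
    for (ch in seq_len(dim(image)[1]))
      out[ch, , ] <- filt1(matrix(image[ch, , ], dim(image)[2], dim(image)[3]))
  }
  if (was_int) {
    out <- floor(out + 0.5)
    storage.mode(out) <- "integer"
  }
  out
}

#' Build a tiled multi-resolution image pyramid
#'
#' Writes the image as a tiled TIFF in a cloud-optimized layout: level 0 plus
#' reduced-resolution overview levels per [plan_levels()], every channel a
#' separate planar sample, and all tile byte offsets serialized in a header
#' region at the start of the file so one initial range read suffices to
#' address any tile. Lossless mode (deflate tiles) reconstructs level 0
#' exactly; JPEG mode stores one baseline JPEG stream per tile at the given
#' quality (8-bit images only).
#'
#' @param image A channels x height x width integer array (or a plain matrix
#'   for a single channel) of non-negative values; values above 255 switch
#'   storage to 16-bit.
#' @param channels Character vector of channel names (defaults to
#'   `"channel1"`, ...).
#' @param tile_size Tile edge length; a multiple of 16.
#' @param compression `"lossless"` (deflate) or `"jpeg"`.
#' @param jpeg_quality JPEG quality 1-100, used when `compression = "jpeg"`.
#' @param out Output file path.
#' @return An image spec (see [image_spec()]) describing the written file.
#' @export
build_pyramid <- function(image, channels = NULL, tile_size = 512L,
                          compression = c("lossless", "jpeg"),
                          jpeg_quality = 90L, out) {
  compression <- match.arg(compression)
  if (is.matrix(image)) image <- array(image, c(1L, nrow(image), ncol(image)))
  if (length(dim(image)) != 3L || any(dim(image) < 1))
    stop("image must be a non-empty channels x height x width array")
  nch <- dim(image)[1]
  if (is.null(channels)) channels <- paste0("channel", seq_len(nch))
  if (length(channels) != nch)
    stop("channel name count (", length(channels), ") does not match image (", nch, ")")
  if (tile_size < 16 || tile_size %% 16 != 0)
    stop("tile_size must be a positive multiple of 16")
  if (min(image) < 0) stop("image values must be non-negative")
  bits <- if (max(image) > 255) 16L else 8L
  if (compression == "jpeg" && bits == 16L)
    stop("jpeg compression supports 8-bit images only")
  if (compression == "jpeg" && (jpeg_quality < 1 || jpeg_quality > 100))
    stop("jpeg_quality must be in 1..100")
  storage.mode(image) <- "integer"
  plan <- plan_levels(dim(image)[3], dim(image)[2], tile_size)
  levels <- vector("list", nrow(plan$levels))
  levels[[1]] <- image
  for (li in seq_len(nrow(plan$levels) - 1L)) {
    prev <- levels[[li]]
    nxt <- array(0L, c(nch, plan$levels[li + 1L, "height"], plan$levels[li + 1L, "width"]))
    for (ch in seq_len(nch))
      nxt[ch, , ] <- downsample_level(matrix(prev[ch, , ], dim(prev)[2], dim(prev)[3]))
    levels[[li + 1L]] <- nxt
  }
  desc <- list(channels = as.list(channels))
  if (compression == "jpeg") desc$jpeg_quality <- as.integer(jpeg_quality)
  comp_code <- if (compression == "lossless") TIFF_DEFLATE else TIFF_JPEG
  tiff_write_pyramid(levels, as.integer(tile_size), comp_code,
                     as.integer(jpeg_quality), bits,
                     canonical_json(desc), out)
  image_spec(path = basename(out), channels = channels,
             width = dim(image)[3], height = dim(image)[2],
             tile_size = as.integer(tile_size), n_levels = nrow(plan$levels),
             compression = compression,
             jpeg_quality = if (compression == "jpeg") as.integer(jpeg_quality) else NULL)
}

#' Open a tiled pyramid through a range reader
#'
#' Parses the header region (IFD chain and tile index) through the reader;
#' only those header bytes are fetched. Subsequent [read_tile()] calls fetch
#' exactly the requested tile's byte span.
#'
#' @param src Path to a pyramid file, or a `srt_range_reader`.
#' @return An object of class `srt_pyramid`.
#' @export
open_pyramid <- function(src) {
  reader <- if (inherits(src, "srt_range_reader")) src else range_reader(src)
  info <- tiff_parse(reader)
  desc <- if (nzchar(info$description))
    jsonlite::fromJSON(info$description, simplifyVector = FALSE) else list()
  lv <- lapply(info$levels, function(l) {
    l$tiles_down <- ceiling(l$height / l$tile_h)
    l$tiles_across <- ceiling(l$width / l$tile_w)
    l
  })
  structure(list(reader = reader, levels = lv,
                 header_bytes = info$header_bytes,
                 channels = unlist(desc$channels),
                 jpeg_quality = desc$jpeg_quality),
            class = "srt_pyramid")
}

#' @export
print.srt_pyramid <- function(x, ...) {
  l0 <- x$levels[[1]]
  cat("<tiled pyramid>", l0$width, "x", l0$height, "px,",
      l0$spp, "channel(s),", length(x$levels), "level(s), tile",
      l0$tile_w, "px\n")
  invisible(x)
}

#' Read one tile of a pyramid level
#'
#' Fetches and decodes a single tile; only that tile's byte ranges (one per
#' planar channel) pass through the range reader. Edge tiles are cropped to
#' the image extent.
#'
#' @param store An open `srt_pyramid`.
#' @param level Pyramid level, 0-based; level 0 is full resolution.
#' @param row,col Tile grid position, 1-based.
#' @return A channels x tile_height x tile_width integer array.
#' @export
read_tile <- function(store, level, row, col) {
  l <- .pyr_level(store, level)
  if (row < 1 || row > l$tiles_down || col < 1 || col > l$tiles_across)
    stop("tile (", row, ", ", col, ") outside the ", l$tiles_down, " x ",
         l$tiles_across, " grid of level ", level)
  nch <- l$spp
  th <- min(l$tile_h, l$height - (row - 1L) * l$tile_h)
  tw <- min(l$tile_w, l$width - (col - 1L) * l$tile_w)
  out <- array(0L, c(nch, th, tw))
  for (ch in seq_len(nch)) {
    k <- (ch - 1L) * l$tiles_down * l$tiles_across +
      (row - 1L) * l$tiles_across + col
    bytes <- store$reader$read(l$offsets[k], l$lengths[k])
    full <- .decode_tile(bytes, l$tile_w, l$tile_h, l$compression, l$bits)
    out[ch, , ] <- full[seq_len(th), seq_len(tw)]
  }
  out
}

.pyr_level <- function(store, level) {
  if (level < 0 || level >= length(store$levels))
    stop("level ", level, " outside 0..", length(store$levels) - 1L)
  store$levels[[level + 1L]]
}

#' Plan which tiles a viewport needs
#'
#' Returns exactly the tiles of `level` whose pixel footprint, scaled to
#' level-0 coordinates, intersects the viewport; row-major order, no
#' duplicates.
#'
#' @param viewport Numeric `c(x0, y0, x1, y1)`: a half-open rectangle in
#'   level-0 pixel coordinates (origin top-left, x rightward, y downward).
#' @param level Pyramid level, 0-based.
#' @param plan A `srt_level_plan` for the image.
#' @param tile_size Tile edge length in pixels.
#' @return An integer matrix with columns `row`, `col` (1-based), possibly
#'   with zero rows.
#' @export
plan_viewport <- function(viewport, level, plan, tile_size = plan$tile_size) {
  stopifnot(length(viewport) == 4, viewport[3] >= viewport[1], viewport[4] >= viewport[2])
  dims <- plan$levels[level + 1L, ]
  scale <- 2^level
  foot <- tile_size * scale # level-0 extent of one tile
  tr <- ceiling(dims["height"] / tile_size); tc <- ceiling(dims["width"] / tile_size)
  cols <- which(vapply(seq_len(tc), function(cl)
    (cl - 1) * foot < viewport[3] && cl * foot > viewport[1], NA))
  rows <- which(vapply(seq_len(tr), function(r)
    (r - 1) * foot < viewport[4] && r * foot > viewport[2], NA))
  if (length(rows) == 0 || length(cols) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  out <- cbind(row = rep(rows, each = length(cols)),
               col = rep(cols, times = length(rows)))
  storage.mode(out) <- "integer"
  out
}

#' Read a rectangular region of a pyramid level
#'
#' Plans the covering tiles with [plan_viewport()], fetches each through the
#' range reader, and stitches the pixels that fall inside the viewport.
#'
#' @inheritParams read_tile
#' @inheritParams plan_viewport
#' @return A list with `region` (channels x height x width integer array at
#'   the requested level) and `bytes_fetched` (bytes that passed through the
#'   reader during this call).
#' @export
read_region <- function(store, viewport, level) {
  l <- .pyr_level(store, level)
  plan <- structure(list(levels = do.call(rbind, lapply(store$levels, function(x)
    c(width = x$width, height = x$height))), tile_size = l$tile_w),
    class = "srt_level_plan")
  tiles <- plan_viewport(viewport, level, plan, l$tile_w)
  scale <- 2^level
  px0 <- max(0L, floor(viewport[1] / scale))
  py0 <- max(0L, floor(viewport[2] / scale))
  px1 <- min(l$width, ceiling(viewport[3] / scale))
  py1 <- min(l$height, ceiling(viewport[4] / scale))
  if (px1 <= px0 || py1 <= py0 || nrow(tiles) == 0)
    return(list(region = array(0L, c(l$spp, 0L, 0L)), bytes_fetched = 0))
  before <- store$reader$bytes_fetched()
  region <- array(0L, c(l$spp, py1 - py0, px1 - px0))
  for (i in seq_len(nrow(tiles))) {
    r <- tiles[i, "row"]; cl <- tiles[i, "col"]
    tile <- read_tile(store, level, r, cl)
    ty0 <- (r - 1L) * l$tile_h; tx0 <- (cl - 1L) * l$tile_w # level px origin of tile
    ys <- max(py0, ty0):(min(py1, ty0 + dim(tile)[2]) - 1L)
    xs <- max(px0, tx0):(min(px1, tx0 + dim(tile)[3]) - 1L)
    if (length(ys) < 1 || length(xs) < 1 || ys[1] > rev(ys)[1] || xs[1] > rev(xs)[1]) next
    region[, ys - py0 + 1L, xs - px0 + 1L] <- tile[, ys - ty0 + 1L, xs - tx0 + 1L]
  }
  list(region = region,
       bytes_fetched = store$reader$bytes_fetched() - before)
}
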