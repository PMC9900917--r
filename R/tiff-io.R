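# Internal tiled-TIFF container layer.
#
# Writes classic little-endian TIFF with one IFD per pyramid level
# (NewSubfileType = 1 marks reduced-resolution overviews), tiled layout
# (tags 322-325), planar channel storage, and all IFDs + tag value arrays
# packed into one contiguous header region at the start of the file so a
# single initial range read is enough to learn every tile's byte span.
# Tile codecs: deflate (zlib, Compression = 8) via memCompress, or
# per-tile baseline JPEG streams (Compression = 7) via the jpeg package.
#
# No installed R package writes this layout, hence the hand-rolled
# container; codecs and the independent read checks are not hand-rolled.

.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
.rd16 <- function(r) readBin(r, "integer", n = length(r) / 2L, size = 2L,
                             endian = "little", signed = FALSE)
.rd32 <- function(r) {
  # read unsigned 32-bit as double (file offsets may exceed .Machine$integer.max)
  lo <- .rd16(r[c(TRUE, TRUE, FALSE, FALSE)])
  hi <- .rd16(r[c(FALSE, FALSE, TRUE, TRUE)])
  hi * 65536 + lo
}

TIFF_DEFLATE <- 8L
TIFF_JPEG <- 7L

# pack one tile (matrix th x tw, integer) into compressed bytes
.encode_tile <- function(tile, compression, jpeg_quality, bits) {
  if (compression == TIFF_DEFLATE) {
    pix <- as.integer(t(tile)) # row-major
    rawpix <- if (bits == 8L) as.raw(pix) else
      writeBin(pix, raw(), size = 2L, endian = "little")
    memCompress(rawpix, type = "gzip")
  } else {
    jpeg::writeJPEG(tile / 255, raw(), quality = jpeg_quality / 100)
  }
}

.decode_tile <- function(bytes, tw, th, compression, bits) {
  if (compression == TIFF_DEFLATE) {
    rawpix <- memDecompress(bytes, type = "gzip")
    pix <- if (bits == 8L) as.integer(rawpix) else
      readBin(rawpix, "integer", n = length(rawpix) / 2L, size = 2L,
              endian = "little", signed = FALSE)
    matrix(pix, nrow = th, ncol = tw, byrow = TRUE)
  } else {
    img <- jpeg::readJPEG(bytes)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    matrix(as.integer(round(img * 255)), nrow = th, ncol = tw)
  }
}

# pad a sub-block up to tile_size x tile_size; zeros for deflate (cheap),
# edge replication for jpeg (avoids ringing at image borders)
.pad_tile <- function(block, ts, replicate_edge) {
  h <- nrow(block); w <- ncol(block)
  if (h == ts && w == ts) return(block)
  if (replicate_edge) {
    block[c(seq_len(h), rep(h, ts - h)), c(seq_len(w), rep(w, ts - w))]
  } else {
    out <- matrix(0L, ts, ts)
    out[seq_len(h), seq_len(w)] <- block
    out
  }
}

.ifd_entry <- function(tag, type, values) {
  list(tag = as.integer(tag), type = as.integer(type), values = values)
}

.entry_bytes <- function(e) {
  switch(as.character(e$type),
         "2" = c(charToRaw(e$values), as.raw(0L)), # NUL-terminated ASCII
         "3" = .le16(e$values),
         "4" = .le32(e$values),
         stop("unsupported TIFF type ", e$type))
}

.entry_count <- function(e) {
  if (e$type == 2L) nchar(e$values, type = "bytes") + 1L else length(e$values)
}

.serialize_ifd <- function(entries, ifd_offset, next_ifd) {
  entries <- entries[order(vapply(entries, function(e) e$tag, 0L))]
  n <- length(entries)
  voff <- ifd_offset + 2L + 12L * n + 4L
  body <- .le16(n)
  extra <- raw(0)
  for (e in entries) {
    vb <- .entry_bytes(e)
    body <- c(body, .le16(e$tag), .le16(e$type), .le32(.entry_count(e)))
    if (length(vb) <= 4L) {
      body <- c(body, vb, raw(4L - length(vb)))
    } else {
      body <- c(body, .le32(voff + length(extra)))
      extra <- c(extra, vb)
    }
  }
  c(body, .le32(next_ifd), extra)
}

# levels: list of c x h x w integer arrays; returns header byte count
tiff_write_pyramid <- function(levels, tile_size, compression, jpeg_quality,
                               bits, description, out) {
  nch <- dim(levels[[1]])[1]
  replicate_edge <- compression == TIFF_JPEG
  meta <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    a <- levels[[li]]
    h <- dim(a)[2]; w <- dim(a)[3]
    tr <- ceiling(h / tile_size); tc <- ceiling(w / tile_size)
    tiles <- vector("list", nch * tr * tc)
    k <- 0L
    for (ch in seq_len(nch)) for (r in seq_len(tr)) for (cl in seq_len(tc)) {
      y0 <- (r - 1L) * tile_size + 1L; x0 <- (cl - 1L) * tile_size + 1L
      ys <- y0:min(y0 + tile_size - 1L, h)
      xs <- x0:min(x0 + tile_size - 1L, w)
      block <- matrix(a[ch, ys, xs], length(ys), length(xs))
      tile <- .pad_tile(block, tile_size, replicate_edge)
      k <- k + 1L
      tiles[[k]] <- .encode_tile(tile, compression, jpeg_quality, bits)
    }
    meta[[li]] <- list(h = h, w = w, tiles = tiles)
  }
  build_entries <- function(li, offs, cnts) {
    m <- meta[[li]]
    es <- list(
      .ifd_entry(254L, 4L, if (li == 1L) 0L else 1L),
      .ifd_entry(256L, 4L, m$w),
      .ifd_entry(257L, 4L, m$h),
      .ifd_entry(258L, 3L, rep(bits, nch)),
      .ifd_entry(259L, 3L, compression),
      .ifd_entry(262L, 3L, 1L), # BlackIsZero
      .ifd_entry(277L, 3L, nch),
      .ifd_entry(284L, 3L, if (nch > 1L) 2L else 1L),
      .ifd_entry(322L, 3L, tile_size),
      .ifd_entry(323L, 3L, tile_size),
      .ifd_entry(324L, 4L, offs),
      .ifd_entry(325L, 4L, cnts),
      .ifd_entry(339L, 3L, rep(1L, nch))
    )
    if (nch > 1L) es <- c(es, list(.ifd_entry(338L, 3L, rep(0L, nch - 1L))))
    if (li == 1L && nzchar(description))
      es <- c(es, list(.ifd_entry(270L, 2L, description)))
    es
  }
  # first pass with dummy offsets fixes every IFD's size and position
  pos <- 8L
  ifd_pos <- integer(length(levels))
  for (li in seq_along(levels)) {
    ifd_pos[li] <- pos
    nt <- length(meta[[li]]$tiles)
    pos <- pos + length(.serialize_ifd(build_entries(li, integer(nt), integer(nt)),
                                       pos, 0L))
  }
  data_start <- pos
  cur <- data_start
  for (li in seq_along(levels)) {
    lens <- vapply(meta[[li]]$tiles, length, 0L)
    meta[[li]]$offsets <- as.integer(cur + c(0, cumsum(lens))[seq_along(lens)])
    meta[[li]]$lengths <- lens
    cur <- cur + sum(lens)
  }
  con <- file(out, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49L, 0x49L, 0x2aL, 0x00L)), .le32(8L)), con)
  for (li in seq_along(levels)) {
    nxt <- if (li < length(levels)) ifd_pos[li + 1L] else 0L
    writeBin(.serialize_ifd(build_entries(li, meta[[li]]$offsets, meta[[li]]$lengths),
                            ifd_pos[li], nxt), con)
  }
  for (li in seq_along(levels)) for (tl in meta[[li]]$tiles) writeBin(tl, con)
  data_start
}

# walk the IFD chain through a range reader; every byte fetched is counted
tiff_parse <- function(reader) {
  hdr <- reader$read(0, 8)
  if (!identical(hdr[1:4], as.raw(c(0x49L, 0x49L, 0x2aL, 0x00L))))
    stop("not a little-endian TIFF file")
  ifd_off <- .rd32(hdr[5:8])
  levels <- list()
  description <- ""
  while (ifd_off != 0) {
    n <- .rd16(reader$read(ifd_off, 2))
    block <- reader$read(ifd_off + 2, 12 * n + 4)
    tags <- list()
    for (i in seq_len(n)) {
      e <- block[((i - 1L) * 12L + 1L):(i * 12L)]
      tag <- .rd16(e[1:2]); type <- .rd16(e[3:4]); cnt <- .rd32(e[5:8])
      unit <- c(`2` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
      nbytes <- unit * cnt
      vb <- if (nbytes <= 4) e[9:(8 + nbytes)] else reader$read(.rd32(e[9:12]), nbytes)
      val <- switch(as.character(type),
                    `2` = rawToChar(vb[vb != as.raw(0)]),
                    `3` = .rd16(vb),
                    `4` = .rd32(vb))
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!is.null(g(270)) && !nzchar(description)) description <- g(270)
    levels[[length(levels) + 1L]] <- list(
      width = g(256), height = g(257),
      bits = g(258)[1], compression = g(259), spp = g(277, 1L),
      planar = g(284, 1L), tile_w = g(322), tile_h = g(323),
      offsets = g(324), lengths = g(325))
    ifd_off <- .rd32(block[(12L * n + 1L):(12L * n + 4L)])
  }
  list(levels = levels, description = description,
       header_bytes = reader$bytes_fetched())
}
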