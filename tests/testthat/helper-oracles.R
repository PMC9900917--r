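# Independent oracles and random-case generators shared across tests.
# These deliberately re-derive expected results by a different route than
# the implementation under test.

# winding-number point-in-polygon (signed angle accumulation); independent
# of the even-odd ray-crossing implementation in the package
wn_inside <- function(px, py, x, y) {
  n <- length(x)
  wn <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (y[i] <= py) {
      if (y[j] > py &&
          (x[j] - x[i]) * (py - y[i]) - (px - x[i]) * (y[j] - y[i]) > 0)
        wn <- wn + 1L
    } else {
      if (y[j] <= py &&
          (x[j] - x[i]) * (py - y[i]) - (px - x[i]) * (y[j] - y[i]) < 0)
        wn <- wn - 1L
    }
  }
  wn != 0L
}

# star-shaped simple polygon around a random center
random_simple_polygon <- function(n_vertices = sample(3:9, 1),
                                  cx = runif(1, 100, 400),
                                  cy = runif(1, 100, 400)) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 20, 90)
  ann_polygon(cx + rad * cos(ang), cy + rad * sin(ang))
}

# brute-force tile selection: test every tile's level-0 footprint rectangle
# against the viewport
viewport_tiles_bruteforce <- function(viewport, level, plan, tile_size) {
  dims <- plan$levels[level + 1, ]
  scale <- 2^level
  tr <- ceiling(dims[["height"]] / tile_size)
  tc <- ceiling(dims[["width"]] / tile_size)
  hits <- NULL
  for (r in seq_len(tr)) for (cl in seq_len(tc)) {
    x0 <- (cl - 1) * tile_size * scale; x1 <- cl * tile_size * scale
    y0 <- (r - 1) * tile_size * scale; y1 <- r * tile_size * scale
    if (x0 < viewport[3] && x1 > viewport[1] &&
        y0 < viewport[4] && y1 > viewport[2])
      hits <- rbind(hits, c(row = r, col = cl))
  }
  if (is.null(hits)) matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  else hits
}

# decode level-0 of a TIFF with Python tifffile (a reader that shares no
# code with this package); returns a channels x height x width array
tifffile_level0 <- function(path) {
  out <- tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread('%s')\n",
    "if a.ndim == 2: a = a[None, :, :]\n",
    "with open('%s', 'w') as f:\n",
    "    f.write(' '.join(map(str, a.shape)) + '\\n')\n",
    "    np.savetxt(f, a.reshape(a.shape[0] * a.shape[1], a.shape[2]), fmt='%%d')\n"),
    path, out)
  res <- system2("python", c("-c", shQuote(script)))
  stopifnot(res == 0)
  lines <- readLines(out)
  shp <- as.integer(strsplit(lines[1], " ")[[1]])
  vals <- as.integer(unlist(strsplit(lines[-1], " ")))
  arr <- array(0L, shp)
  flat <- matrix(vals, nrow = shp[1] * shp[2], byrow = TRUE)
  for (ch in seq_len(shp[1]))
    arr[ch, , ] <- flat[((ch - 1) * shp[2] + 1):(ch * shp[2]), ]
  arr
}

random_sample_meta <- function() {
  n_im <- sample(0:2, 1); n_ov <- sample(0:2, 1)
  ovs <- lapply(seq_len(n_ov), function(i) {
    circ <- runif(1) < 0.5
    overlay_spec(paste0("ov", i), paste0("ov", i, ".csv"),
                 sample(0:500, 1), if (circ) "circle" else "point",
                 if (circ) signif(runif(1, 1, 100), 6) else NULL)
  })
  fgs <- if (n_ov > 0 && runif(1) < 0.7) {
    lapply(seq_len(sample(1:2, 1)), function(i)
      feature_group_spec(paste0("fg", i), paste0("ov", sample(n_ov, 1)),
                         paste0("fg", i, ".bin"),
                         paste0("feat", seq_len(sample(1:5, 1))),
                         sample(c("quantitative", "categorical"), 1)))
  } else list()
  ims <- lapply(seq_len(n_im), function(i) {
    jp <- runif(1) < 0.5
    image_spec(paste0("im", i, ".tif"), paste0("c", seq_len(sample(1:4, 1))),
               sample(16:4096, 1), sample(16:4096, 1),
               tile_size = sample(c(256L, 512L), 1),
               n_levels = sample(1:6, 1),
               compression = if (jp) "jpeg" else "lossless",
               jpeg_quality = if (jp) sample(1:100, 1) else NULL)
  })
  sample_meta(paste0("sample", sample(1e4, 1)), ims, ovs, fgs,
              microns_per_pixel = signif(runif(1, 0.1, 10), 6))
}

random_annotation_set <- function(n = sample(1:8, 1)) {
  recs <- lapply(seq_len(n), function(i) {
    type <- sample(c("point", "circle", "polygon"), 1)
    g <- switch(type,
                point = ann_point(signif(runif(1, 0, 500), 6),
                                  signif(runif(1, 0, 500), 6)),
                circle = ann_circle(signif(runif(1, 0, 500), 6),
                                    signif(runif(1, 0, 500), 6),
                                    signif(runif(1, 10, 100), 6)),
                polygon = {
                  p <- random_simple_polygon()
                  ann_polygon(signif(p$x, 6), signif(p$y, 6))
                })
    list(label = paste0("label", sample(100, 1)), geometry = g)
  })
  annotation_set(recs, coord_frame = "image")
}

random_uint8_image <- function(nch, h, w) {
  array(sample(0:255, nch * h * w, replace = TRUE), c(nch, h, w))
}
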