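# Deterministic synthetic fixtures: every input format the converters
# consume can be generated offline from a seed. Geometry and format
# fidelity are the point; no biological expression structure is simulated.

# run code under a fixed seed without disturbing the session RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.blob_channel <- function(width, height, n_blobs = 5L) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  img <- matrix(0, height, width)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
    s <- stats::runif(1, min(width, height) / 20, min(width, height) / 5)
    amp <- stats::runif(1, 60, 200)
    img <- img + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  img <- img + stats::rnorm(length(img), sd = 8)
  img <- pmin(pmax(round(img), 0), 255)
  storage.mode(img) <- "integer"
  img
}

#' Generate a reproducible synthetic multi-channel TIFF
#'
#' Smooth Gaussian blobs plus mild noise, quantized to 8 bits. The same
#' seed always produces a byte-identical file. Multi-channel images are
#' written as one grayscale page per channel.
#'
#' @param path Output TIFF path.
#' @param width,height Image dimensions in pixels.
#' @param n_channels Number of channels (pages).
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
make_synthetic_image <- function(path, width = 512L, height = 512L,
                                 n_channels = 1L, seed = 1L) {
  stopifnot(width >= 1, height >= 1, n_channels >= 1)
  with_seed(seed, {
    pages <- lapply(seq_len(n_channels), function(i)
      .blob_channel(width, height) / 255)
    if (n_channels == 1L) tiff::writeTIFF(pages[[1]], path, bits.per.sample = 8L)
    else tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  })
  invisible(path)
}

.hex_lattice <- function(n, width, height, spacing, margin) {
  pts <- NULL
  r <- 0L
  repeat {
    y <- margin + r * spacing * sqrt(3) / 2
    if (y > height - margin) break
    xoff <- margin + (r %% 2L) * spacing / 2
    x <- seq(xoff, height * 0 + width - margin, by = spacing)
    if (length(x))
      pts <- rbind(pts, cbind(array_row = r, array_col = seq_along(x) - 1L,
                              x = x, y = y))
    r <- r + 1L
  }
  if (is.null(pts) || nrow(pts) < n)
    stop("hex lattice overflow: only ", if (is.null(pts)) 0L else nrow(pts),
         " spots fit in ", width, " x ", height, " at spacing ",
         round(spacing, 1), "; requested ", n)
  pts[seq_len(n), , drop = FALSE]
}

.sim_counts <- function(n_points, n_genes, density) {
  # per-gene rates log-uniform; a Bernoulli(density) mask thins the matrix
  # to the target fraction of nonzero cells, each nonzero >= 1
  rates <- exp(stats::runif(n_genes, log(0.5), log(50)))
  counts <- matrix(0L, n_points, n_genes)
  for (g in seq_len(n_genes)) {
    mask <- stats::rbinom(n_points, 1L, density)
    counts[, g] <- mask * (1L + stats::rpois(n_points, rates[g]))
  }
  counts
}

.write_maybe_gz <- function(lines, path, gzip) {
  if (gzip) {
    con <- gzfile(paste0(path, ".gz"), "wb")
    writeLines(lines, con)
    close(con)
    paste0(path, ".gz")
  } else {
    writeLines(lines, path)
    path
  }
}

#' Generate a synthetic Space Ranger-style Visium fixture
#'
#' Writes a directory that parses through every Visium converter input
#' path: a tissue positions CSV (headerless or headered dialect) with
#' spots on a hexagonal lattice plus some `in_tissue = 0` rows, a
#' scalefactors JSON, a MatrixMarket feature-barcode matrix (optionally
#' gzipped) restricted to in-tissue barcodes, an optional synthetic
#' full-resolution image, and a plain-text ground-truth count table
#' (`truth_counts.csv`) for oracle tests.
#'
#' Lattice spacing is `spot_diameter_fullres * 100 / 55`, mimicking the
#' packing of 55 um spots at 100 um centers.
#'
#' @param out_dir Output directory (created).
#' @param n_spots In-tissue spot count.
#' @param n_genes Gene count.
#' @param density Target fraction of nonzero count cells, in (0, 1].
#' @param seed RNG seed.
#' @param spot_diameter_fullres Spot diameter in full-resolution pixels.
#' @param image_size `c(width, height)` of the synthetic image.
#' @param dialect Tissue positions dialect to write.
#' @param gzip Gzip the matrix files?
#' @param n_out_tissue Number of `in_tissue = 0` rows to include.
#' @param write_image Write the synthetic TIFF?
#' @return List with `dir`, `image_path`, `positions` (all rows, both
#'   tissue states), `barcodes`, `genes`, and the dense ground-truth
#'   `counts` (in-tissue barcodes x genes).
#' @export
make_visium_fixture <- function(out_dir, n_spots = 50L, n_genes = 20L,
                                density = 0.05, seed = 1L,
                                spot_diameter_fullres = 55,
                                image_size = c(1000L, 1000L),
                                dialect = c("headerless", "headered"),
                                gzip = FALSE, n_out_tissue = 5L,
                                write_image = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(density > 0, density <= 1, n_spots >= 1, n_genes >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    n_total <- n_spots + n_out_tissue
    spacing <- spot_diameter_fullres * 100 / 55
    pts <- .hex_lattice(n_total, image_size[1], image_size[2], spacing,
                        margin = spot_diameter_fullres)
    in_tissue <- c(rep(1L, n_spots), rep(0L, n_out_tissue))
    ord <- sample(n_total) # interleave tissue states in file order
    barcodes_all <- sprintf("BC%04d-1", seq_len(n_total))
    pos <- data.frame(barcode = barcodes_all,
                      in_tissue = in_tissue,
                      array_row = pts[, "array_row"],
                      array_col = pts[, "array_col"],
                      pxl_row_in_fullres = pts[, "y"],
                      pxl_col_in_fullres = pts[, "x"])[ord, ]
    pos_lines <- sprintf("%s,%d,%d,%d,%.17g,%.17g", pos$barcode, pos$in_tissue,
                         pos$array_row, pos$array_col,
                         pos$pxl_row_in_fullres, pos$pxl_col_in_fullres)
    if (dialect == "headered")
      pos_lines <- c(paste(.tissue_cols, collapse = ","), pos_lines)
    writeLines(pos_lines, file.path(out_dir, "tissue_positions_list.csv"))

    writeBin(charToRaw(canonical_json(list(
      spot_diameter_fullres = spot_diameter_fullres,
      tissue_hires_scalef = 0.1))),
      file.path(out_dir, "scalefactors_json.json"))

    bc_tissue <- pos$barcode[pos$in_tissue == 1L] # file order
    counts <- .sim_counts(length(bc_tissue), n_genes, density)
    rownames(counts) <- bc_tissue
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    colnames(counts) <- genes

    m <- Matrix::Matrix(t(counts), sparse = TRUE) # genes x barcodes
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(m, tmp)
    .write_maybe_gz(readLines(tmp), file.path(out_dir, "matrix.mtx"), gzip)
    unlink(tmp)
    .write_maybe_gz(bc_tissue, file.path(out_dir, "barcodes.tsv"), gzip)
    .write_maybe_gz(sprintf("%s\t%s\tGene Expression", genes, genes),
                    file.path(out_dir, "features.tsv"), gzip)
    utils::write.csv(as.data.frame(counts),
                     file.path(out_dir, "truth_counts.csv"))

    image_path <- NULL
    if (write_image) {
      image_path <- file.path(out_dir, "image.tif")
      make_synthetic_image(image_path, image_size[1], image_size[2],
                           n_channels = 1L, seed = seed + 1L)
    }
    list(dir = out_dir, image_path = image_path, positions = pos,
         barcodes = bc_tissue, genes = genes, counts = counts)
  })
}

#' Generate a synthetic Vizgen-style MERFISH fixture
#'
#' Writes a cell-by-gene count table, a cell metadata table with micron
#' centroids, and a 3 x 3 micron-to-mosaic-pixel affine CSV; the
#' ground-truth pixel centroids (`apply_affine` of the micron centroids)
#' are returned and written to `truth_pixels.csv` for oracle tests.
#'
#' @param out_dir Output directory (created).
#' @param n_cells,n_genes Table dimensions.
#' @param density Target fraction of nonzero count cells.
#' @param seed RNG seed.
#' @param affine 3 x 3 micron-to-mosaic-pixel matrix (bottom row 0,0,1).
#' @param extent_um Width/height of the micron coordinate range.
#' @param write_image Also write a synthetic background TIFF?
#' @param image_size `c(width, height)` for the background image.
#' @return List with `dir`, the file paths, `cells`, `genes`, dense
#'   `counts`, micron `centroids`, the `affine`, and ground-truth
#'   `truth_pixels`.
#' @export
make_merfish_fixture <- function(out_dir, n_cells = 100L, n_genes = 30L,
                                 density = 0.2, seed = 1L,
                                 affine = matrix(c(2.1, 0, 1234.5,
                                                   0, 2.1, 987.6,
                                                   0, 0, 1), 3, 3, byrow = TRUE),
                                 extent_um = 200, write_image = FALSE,
                                 image_size = c(512L, 512L)) {
  stopifnot(nrow(affine) == 3, ncol(affine) == 3)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    cells <- sprintf("cell%04d", seq_len(n_cells))
    centroids <- cbind(x = stats::runif(n_cells, 0, extent_um),
                       y = stats::runif(n_cells, 0, extent_um))
    truth <- apply_affine(centroids, affine)
    counts <- .sim_counts(n_cells, n_genes, density)
    genes <- sprintf("gene%03d", seq_len(n_genes))
    colnames(counts) <- genes

    cbg_path <- file.path(out_dir, "cell_by_gene.csv")
    writeLines(c(paste(c("cell", genes), collapse = ","),
                 paste(cells, apply(counts, 1, paste, collapse = ","),
                       sep = ",")), cbg_path)
    md_path <- file.path(out_dir, "cell_metadata.csv")
    writeLines(c("EntityID,center_x,center_y",
                 sprintf("%s,%.17g,%.17g", cells, centroids[, "x"],
                         centroids[, "y"])), md_path)
    aff_path <- file.path(out_dir, "micron_to_mosaic_pixel_transform.csv")
    writeLines(apply(affine, 1, function(r) paste(sprintf("%.17g", r),
                                                  collapse = ",")), aff_path)
    writeLines(c("cell,x,y",
                 sprintf("%s,%.17g,%.17g", cells, truth[, "x"], truth[, "y"])),
               file.path(out_dir, "truth_pixels.csv"))
    image_path <- NULL
    if (write_image) {
      image_path <- file.path(out_dir, "mosaic.tif")
      make_synthetic_image(image_path, image_size[1], image_size[2],
                           n_channels = 1L, seed = seed + 1L)
    }
    list(dir = out_dir, cell_by_gene_path = cbg_path,
         cell_metadata_path = md_path, affine_path = aff_path,
         image_path = image_path, cells = cells, genes = genes,
         counts = counts, centroids = centroids, affine = affine,
         truth_pixels = truth)
  })
}
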