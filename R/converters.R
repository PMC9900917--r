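# Converters from platform outputs to sample folders.
#
# Visium: Space Ranger-style folder (tissue positions CSV in either
# dialect, scalefactors JSON, MatrixMarket feature-barcode matrix) plus a
# full-resolution image -> circle overlay (55 um spots), log1p feature
# group, Gaussian-filtered pyramid.
#
# MERFISH: Vizgen-style tables (cell-by-gene CSV, cell metadata CSV with
# micron centroids, 3x3 micron-to-mosaic-pixel affine CSV) -> point
# overlay at affine-transformed centroids, raw-count feature group.

VISIUM_SPOT_DIAMETER_UM <- 55

.tissue_cols <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row_in_fullres", "pxl_col_in_fullres")

#' Parse a Space Ranger tissue positions file
#'
#' Accepts both dialects: the headerless six-column CSV
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`)
#' and the same columns with a header line. Only spots with
#' `in_tissue = 1` are kept, in input order. The file stores pixel row
#' before pixel column, so x = `pxl_col_in_fullres` and
#' y = `pxl_row_in_fullres`.
#'
#' @param path Path to `tissue_positions_list.csv` (or equivalent).
#' @param name Overlay name for the result.
#' @return An [overlay()] of in-tissue spots in full-resolution pixels.
#' @export
parse_tissue_positions <- function(path, name = "spots") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  df <- utils::read.csv(path, header = has_header, colClasses = "character")
  if (ncol(df) != 6L)
    stop("tissue positions file has ", ncol(df), " columns; expected the ",
         "6-column Space Ranger layout (", paste(.tissue_cols, collapse = ","),
         "), with or without a header line")
  names(df) <- .tissue_cols
  for (col in .tissue_cols[-1]) df[[col]] <- as.numeric(df[[col]])
  df <- df[df$in_tissue == 1, ]
  overlay(name, df$barcode, x = df$pxl_col_in_fullres, y = df$pxl_row_in_fullres)
}

#' Parse a Space Ranger scalefactors file
#'
#' Derives the physical scale from the full-resolution spot diameter:
#' Visium spots are 55 um across, so
#' `microns_per_pixel = 55 / spot_diameter_fullres`.
#'
#' @param path Path to `scalefactors_json.json`.
#' @return List with `spot_diameter_fullres` (px) and `microns_per_pixel`
#'   (um/px).
#' @export
parse_scalefactors <- function(path) {
  doc <- jsonlite::fromJSON(path)
  d <- doc$spot_diameter_fullres
  if (is.null(d)) stop("scalefactors JSON lacks key 'spot_diameter_fullres'")
  d <- as.numeric(d)
  if (!is.finite(d) || d <= 0) stop("spot_diameter_fullres must be a positive real")
  list(spot_diameter_fullres = d,
       microns_per_pixel = VISIUM_SPOT_DIAMETER_UM / d)
}

.find_mtx_file <- function(dir, stem) {
  for (f in c(paste0(stem, ".gz"), stem)) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("no ", stem, "[.gz] in ", dir)
}

.read_tsv_col <- function(path, col = 1L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  vapply(strsplit(lines, "\t", fixed = TRUE), function(p)
    p[[min(col, length(p))]], "")
}

#' Read a MatrixMarket feature-barcode matrix directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (each optionally
#' gzipped) from a Space Ranger-style matrix directory. The MatrixMarket
#' file stores features (genes) as rows and barcodes as columns; the result
#' is transposed to barcodes-by-genes, the orientation used by overlays and
#' feature groups.
#'
#' @param dir Directory containing the three files.
#' @return List with `counts` (sparse `dgCMatrix`, barcodes x genes),
#'   `barcodes`, and `genes` (gene symbols: second TSV column when present).
#' @export
parse_mtx_counts <- function(dir) {
  mtx <- .find_mtx_file(dir, "matrix.mtx")
  bpath <- .find_mtx_file(dir, "barcodes.tsv")
  fpath <- .find_mtx_file(dir, "features.tsv")
  m <- if (grepl("\\.gz$", mtx)) {
    con <- gzfile(mtx)
    Matrix::readMM(con)
  } else Matrix::readMM(mtx)
  barcodes <- .read_tsv_col(bpath, 1L)
  genes <- .read_tsv_col(fpath, 2L)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop("matrix is ", nrow(m), " x ", ncol(m), " but features.tsv lists ",
         length(genes), " genes and barcodes.tsv lists ", length(barcodes),
         " barcodes")
  counts <- Matrix::t(m)
  dimnames(counts) <- list(barcodes, genes)
  list(counts = methods::as(counts, "CsparseMatrix"),
       barcodes = barcodes, genes = genes)
}

.read_image_array <- function(path) {
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(pages) > 1L) {
    # multi-page: one grayscale page per channel
    arr <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  } else {
    p <- pages[[1]]
    if (length(dim(p)) == 3L) arr <- aperm(p, c(3L, 1L, 2L))
    else arr <- array(p, c(1L, nrow(p), ncol(p)))
  }
  storage.mode(arr) <- "integer"
  arr
}

#' Convert a Visium (Space Ranger-style) output folder to a sample folder
#'
#' Builds a complete sample folder: a pyramid from the Gaussian-filtered
#' full-resolution image, a circle-geometry spot overlay (55 um diameter)
#' restricted to barcodes present both in the count matrix and among
#' in-tissue positions (in count-matrix order), and one feature group of
#' log-transformed (natural `log1p`) gene vectors.
#'
#' @param spaceranger_dir Folder with `tissue_positions*.csv`,
#'   `scalefactors_json.json`, and a matrix directory (or the three matrix
#'   files at top level).
#' @param image_path Full-resolution TIFF; `NULL` to skip the image.
#' @param out_dir Output sample folder (created if missing).
#' @param gaussian_radius Standard deviation (px) of the pre-pyramid
#'   Gaussian filter; the conventional value 4 softens scanner artifacts.
#' @param compression,jpeg_quality,tile_size Pyramid options, see
#'   [build_pyramid()].
#' @param name Sample name.
#' @return The written [sample_meta()], invisibly.
#' @export
convert_visium <- function(spaceranger_dir, image_path, out_dir,
                           gaussian_radius = 4, compression = "jpeg",
                           jpeg_quality = 90L, tile_size = 512L,
                           name = basename(out_dir)) {
  pos_file <- list.files(spaceranger_dir, "^tissue_positions.*\\.csv$",
                         full.names = TRUE)
  if (length(pos_file) != 1L)
    stop("expected one tissue_positions*.csv in ", spaceranger_dir)
  positions <- parse_tissue_positions(pos_file)
  sf <- parse_scalefactors(file.path(spaceranger_dir, "scalefactors_json.json"))
  mtx_dir <- if (file.exists(file.path(spaceranger_dir, "matrix.mtx")) ||
                 file.exists(file.path(spaceranger_dir, "matrix.mtx.gz")))
    spaceranger_dir else file.path(spaceranger_dir, "filtered_feature_bc_matrix")
  cm <- parse_mtx_counts(mtx_dir)

  # counts barcodes must exist among positions (any tissue state)
  all_bc <- .all_position_barcodes(pos_file)
  missing <- setdiff(cm$barcodes, all_bc)
  if (length(missing))
    stop("count matrix barcodes absent from tissue positions, e.g.: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  keep <- cm$barcodes[cm$barcodes %in% positions$ids] # counts order
  sel <- match(keep, positions$ids)
  spots <- overlay("spots", keep, positions$x[sel], positions$y[sel])

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- as.matrix(cm$counts[match(keep, cm$barcodes), , drop = FALSE])
  feats <- sparsify(log_transform_counts(counts), cm$genes)
  fg <- write_feature_group(spots, feats, out_dir, "genes")
  write_overlay(spots, file.path(out_dir, "spots.csv"))
  ov_spec <- overlay_spec("spots", "spots.csv", length(spots$ids),
                          geometry = "circle",
                          diameter_um = VISIUM_SPOT_DIAMETER_UM)
  images <- list()
  if (!is.null(image_path)) {
    img <- .read_image_array(image_path)
    if (gaussian_radius > 0) img <- gaussian_filter_image(img, gaussian_radius)
    img[img < 0L] <- 0L
    images <- list(build_pyramid(img, tile_size = tile_size,
                                 compression = compression,
                                 jpeg_quality = jpeg_quality,
                                 out = file.path(out_dir, "image.tif")))
  }
  meta <- sample_meta(name, images = images, overlays = list(ov_spec),
                      feature_groups = list(fg),
                      microns_per_pixel = sf$microns_per_pixel)
  write_sample_meta(meta, out_dir)
  invisible(meta)
}

.all_position_barcodes <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, header = grepl("barcode", first, fixed = TRUE),
                        colClasses = "character")
  df[[1]]
}

#' Apply a micron-to-pixel affine transformation
#'
#' Maps homogeneous micron coordinates to mosaic pixel coordinates:
#' row i of the result is the first two components of `M %*% c(x_i, y_i, 1)`.
#'
#' @param points n x 2 numeric matrix of micron coordinates.
#' @param M 3 x 3 affine matrix with bottom row `(0, 0, 1)`; must be
#'   invertible.
#' @return n x 2 matrix of pixel coordinates.
#' @export
apply_affine <- function(points, M) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  if (!is.matrix(M) || any(dim(M) != c(3L, 3L)))
    stop("M must be a 3 x 3 matrix")
  if (any(M[3, ] != c(0, 0, 1)))
    stop("affine bottom row must be exactly (0, 0, 1)")
  if (abs(det(M)) < .Machine$double.eps)
    stop("affine matrix is not invertible")
  hom <- cbind(points, 1)
  out <- hom %*% t(M[1:2, , drop = FALSE])
  colnames(out) <- c("x", "y")
  out
}

#' Read a Vizgen-style affine CSV
#'
#' Three rows of three comma-separated numbers (micron-to-mosaic-pixel
#' convention); a 2 x 3 file is accepted and promoted with bottom row
#' `(0, 0, 1)`.
#'
#' @param path Affine CSV path.
#' @return 3 x 3 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "numeric"
  if (nrow(m) == 2L && ncol(m) == 3L) m <- rbind(m, c(0, 0, 1))
  if (any(dim(m) != c(3L, 3L)) || anyNA(m))
    stop("affine file must be 3 (or 2) rows of 3 comma-separated numbers")
  dimnames(m) <- NULL
  m
}

#' Convert MERFISH (Vizgen-style) tables to a sample folder
#'
#' The overlay is the affine-transformed position of each cell (micron
#' centroids mapped to mosaic pixels); features are the raw per-cell
#' transcript counts — unlike Visium spot counts they are stored without a
#' log transform. An optional background image becomes a pyramid.
#'
#' @param cell_by_gene_path CSV with header `cell,<gene...>`, one row per
#'   cell.
#' @param cell_metadata_path CSV whose header includes a cell id column
#'   (`EntityID` or `cell`) plus `center_x`, `center_y` in microns.
#' @param affine_path Micron-to-mosaic-pixel affine CSV (see
#'   [read_affine()]).
#' @param image_path Optional background TIFF.
#' @param out_dir Output sample folder.
#' @param tile_size,compression,jpeg_quality Pyramid options.
#' @param name Sample name.
#' @return The written [sample_meta()], invisibly.
#' @export
convert_merfish <- function(cell_by_gene_path, cell_metadata_path, affine_path,
                            image_path = NULL, out_dir,
                            tile_size = 512L, compression = "jpeg",
                            jpeg_quality = 90L, name = basename(out_dir)) {
  cbg <- utils::read.csv(cell_by_gene_path, check.names = FALSE)
  genes <- names(cbg)[-1]
  counts <- data.matrix(cbg[, -1, drop = FALSE])
  cells <- as.character(cbg[[1]])
  md <- utils::read.csv(cell_metadata_path, check.names = FALSE)
  id_col <- intersect(c("EntityID", "cell"), names(md))[1]
  if (is.na(id_col)) stop("cell metadata needs an 'EntityID' or 'cell' column")
  if (!all(c("center_x", "center_y") %in% names(md)))
    stop("cell metadata needs 'center_x' and 'center_y' columns")
  md_ids <- as.character(md[[id_col]])
  only_counts <- setdiff(cells, md_ids)
  only_md <- setdiff(md_ids, cells)
  if (length(only_counts) || length(only_md))
    stop("cell id mismatch between tables: ", length(only_counts),
         " ids only in counts, ", length(only_md), " only in metadata")
  M <- read_affine(affine_path)
  sel <- match(cells, md_ids)
  px <- apply_affine(cbind(md$center_x[sel], md$center_y[sel]), M)
  cells_ov <- overlay("cells", cells, px[, "x"], px[, "y"])

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- sparsify(counts, genes)
  fg <- write_feature_group(cells_ov, feats, out_dir, "genes")
  write_overlay(cells_ov, file.path(out_dir, "cells.csv"))
  ov_spec <- overlay_spec("cells", "cells.csv", length(cells), geometry = "point")
  images <- list()
  if (!is.null(image_path)) {
    img <- .read_image_array(image_path)
    images <- list(build_pyramid(img, tile_size = tile_size,
                                 compression = compression,
                                 jpeg_quality = jpeg_quality,
                                 out = file.path(out_dir, "image.tif")))
  }
  # pixel pitch implied by the affine's linear part (px per um)
  px_per_um <- sqrt(abs(det(M[1:2, 1:2])))
  meta <- sample_meta(name, images = images, overlays = list(ov_spec),
                      feature_groups = list(fg),
                      microns_per_pixel = 1 / px_per_um)
  write_sample_meta(meta, out_dir)
  invisible(meta)
}

#' Convert a bare TIFF into an image-only sample folder
#'
#' @param tiff_path Input TIFF (2-D, channel-stacked, or multi-page).
#' @param out_dir Output sample folder.
#' @param channels Channel names; defaults per [build_pyramid()].
#' @param compression,jpeg_quality,tile_size Pyramid options; JPEG at
#'   quality 90 is the conventional default for brightfield images.
#' @param gaussian_radius Optional pre-pyramid Gaussian filter (px).
#' @param microns_per_pixel Physical scale recorded in the manifest.
#' @param name Sample name.
#' @return The written [sample_meta()], invisibly.
#' @export
preprocess_image <- function(tiff_path, out_dir, channels = NULL,
                             compression = "jpeg", jpeg_quality = 90L,
                             tile_size = 512L, gaussian_radius = 0,
                             microns_per_pixel = 1,
                             name = basename(out_dir)) {
  img <- tryCatch(.read_image_array(tiff_path),
                  error = function(e) stop("cannot read TIFF ", tiff_path,
                                           ": ", conditionMessage(e)))
  if (gaussian_radius > 0) {
    img <- gaussian_filter_image(img, gaussian_radius)
    img[img < 0L] <- 0L
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- build_pyramid(img, channels = channels, tile_size = tile_size,
                        compression = compression, jpeg_quality = jpeg_quality,
                        out = file.path(out_dir, "image.tif"))
  meta <- sample_meta(name, images = list(spec),
                      microns_per_pixel = microns_per_pixel)
  write_sample_meta(meta, out_dir)
  invisible(meta)
}
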