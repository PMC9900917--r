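# Visium and MERFISH converters.

write_positions <- function(path, rows, header = FALSE) {
  lines <- vapply(rows, function(r) paste(r, collapse = ","), "")
  if (header)
    lines <- c("barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
               lines)
  writeLines(lines, path)
}

test_that("tissue positions parse with row/col -> y/x swap and tissue filter", {
  f <- tempfile(fileext = ".csv")
  rows <- list(c("AAA-1", 1, 0, 0, 100.5, 200.5),
               c("BBB-1", 0, 0, 1, 110, 210),
               c("CCC-1", 1, 1, 0, 120, 220))
  write_positions(f, rows)
  ov <- parse_tissue_positions(f)
  expect_identical(ov$ids, c("AAA-1", "CCC-1")) # in_tissue = 0 dropped
  expect_equal(ov$x, c(200.5, 220)) # x = pxl_col
  expect_equal(ov$y, c(100.5, 120)) # y = pxl_row
  # headered dialect parses identically
  f2 <- tempfile(fileext = ".csv")
  write_positions(f2, rows, header = TRUE)
  expect_identical(parse_tissue_positions(f2), ov)
  # wrong column count names both dialects
  writeLines("a,b,c", f)
  expect_error(parse_tissue_positions(f), "with or without a header")
})

test_that("scalefactors anchor microns per pixel at the 55 um spot diameter", {
  f <- tempfile(fileext = ".json")
  writeLines('{"spot_diameter_fullres": 55.0, "tissue_hires_scalef": 0.08}', f)
  expect_equal(parse_scalefactors(f)$microns_per_pixel, 1.0)
  writeLines('{"spot_diameter_fullres": 110.0}', f)
  expect_equal(parse_scalefactors(f)$microns_per_pixel, 0.5)
  writeLines('{"spot_diameter_fullres": -3}', f)
  expect_error(parse_scalefactors(f), "positive")
  writeLines('{"other": 1}', f)
  expect_error(parse_scalefactors(f), "spot_diameter_fullres")
})

test_that("MatrixMarket directories parse with alignment to the TSV lists", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 7"), file.path(d, "matrix.mtx"))
  writeLines(c("BC1", "BC2"), file.path(d, "barcodes.tsv"))
  writeLines(c("ID1\tG1\tGene Expression", "ID2\tG2\tGene Expression",
               "ID3\tG3\tGene Expression"), file.path(d, "features.tsv"))
  got <- parse_mtx_counts(d)
  expect_equal(dim(got$counts), c(2, 3)) # barcodes x genes
  want <- matrix(0, 2, 3, dimnames = list(c("BC1", "BC2"), c("G1", "G2", "G3")))
  want["BC1", "G1"] <- 5; want["BC2", "G3"] <- 7
  expect_equal(as.matrix(got$counts), want)
  # empty triplet section -> all zeros
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(d, "matrix.mtx"))
  expect_equal(sum(parse_mtx_counts(d)$counts), 0)
  # dimension mismatch with the lists
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 2 0"), file.path(d, "matrix.mtx"))
  expect_error(parse_mtx_counts(d), "features.tsv lists 3")
})

test_that("gzipped and plain matrix fixtures parse identically", {
  withr::local_seed(41)
  td <- withr::local_tempdir()
  plain <- make_visium_fixture(file.path(td, "p"), n_spots = 15, n_genes = 6,
                               seed = 9, image_size = c(700, 700),
                               write_image = FALSE, gzip = FALSE)
  gz <- make_visium_fixture(file.path(td, "g"), n_spots = 15, n_genes = 6,
                            seed = 9, image_size = c(700, 700),
                            write_image = FALSE, gzip = TRUE)
  a <- parse_mtx_counts(file.path(td, "p"))
  b <- parse_mtx_counts(file.path(td, "g"))
  expect_equal(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$barcodes, b$barcodes)
})

test_that("visium conversion produces a valid folder with exact log1p features", {
  withr::local_seed(42)
  td <- withr::local_tempdir()
  fx <- make_visium_fixture(file.path(td, "fx"), n_spots = 50, n_genes = 20,
                            seed = 3)
  out <- file.path(td, "sample")
  meta <- convert_visium(file.path(td, "fx"), fx$image_path, out,
                         compression = "lossless")
  expect_identical(validate_sample(out), character(0))
  ovs <- meta$overlays[[1]]
  expect_equal(ovs$diameter_um, 55)
  expect_identical(ovs$geometry, "circle")
  ov <- read_overlay(file.path(out, "spots.csv"))
  expect_identical(ov$ids, fx$barcodes) # count-matrix barcode order
  # no in_tissue = 0 barcode leaks into the overlay
  out_bc <- fx$positions$barcode[fx$positions$in_tissue == 0]
  expect_length(intersect(ov$ids, out_bc), 0)
  grp <- open_feature_group(file.path(out, "genes.index.json"))
  on.exit(grp$reader$close())
  for (g in fx$genes) {
    got <- read_feature(grp, g)
    expect_equal(got, unname(log1p(fx$counts[, g])), tolerance = 1e-5)
  }
})

test_that("visium conversion rejects count barcodes missing from positions", {
  withr::local_seed(43)
  td <- withr::local_tempdir()
  fx <- make_visium_fixture(file.path(td, "fx"), n_spots = 10, n_genes = 4,
                            seed = 4, image_size = c(700, 700),
                            write_image = FALSE)
  bc <- readLines(file.path(td, "fx", "barcodes.tsv"))
  bc[1] <- "GHOST-1"
  writeLines(bc, file.path(td, "fx", "barcodes.tsv"))
  expect_error(convert_visium(file.path(td, "fx"), NULL, file.path(td, "s")),
               "GHOST-1")
})

test_that("apply_affine matches hand-computed products and rejects bad input", {
  p <- matrix(c(3, 4), 1, 2)
  expect_equal(apply_affine(p, diag(3)), p, ignore_attr = TRUE)
  expect_equal(apply_affine(p, diag(c(2, 2, 1))),
               matrix(c(6, 8), 1, 2), ignore_attr = TRUE)
  M <- matrix(c(2, 0, 10, 0, 3, -5, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(apply_affine(matrix(c(1, 1), 1, 2), M),
               matrix(c(12, -2), 1, 2), ignore_attr = TRUE)
  Mbad <- M; Mbad[3, ] <- c(0, 1, 1)
  expect_error(apply_affine(p, Mbad), "bottom row")
  Msing <- diag(c(1, 0, 1)); Msing[3, 3] <- 1
  expect_error(apply_affine(p, Msing), "invertible")
})

test_that("merfish conversion recovers the affine ground truth", {
  withr::local_seed(44)
  td <- withr::local_tempdir()
  fx <- make_merfish_fixture(file.path(td, "fx"), n_cells = 100, n_genes = 30,
                             seed = 6)
  out <- file.path(td, "sample")
  meta <- convert_merfish(fx$cell_by_gene_path, fx$cell_metadata_path,
                          fx$affine_path, out_dir = out)
  expect_identical(validate_sample(out), character(0))
  ov <- read_overlay(file.path(out, "cells.csv"))
  expect_lt(max(abs(ov$x - fx$truth_pixels[, "x"])), 1e-9)
  expect_lt(max(abs(ov$y - fx$truth_pixels[, "y"])), 1e-9)
  expect_identical(meta$overlays[[1]]$geometry, "point")
  # features are raw counts, not log-transformed
  grp <- open_feature_group(file.path(out, "genes.index.json"))
  on.exit(grp$reader$close())
  for (g in sample(fx$genes, 5))
    expect_equal(read_feature(grp, g), unname(fx$counts[, g]))
})

test_that("identity affine leaves centroids unchanged; scale 2 doubles them", {
  withr::local_seed(45)
  td <- withr::local_tempdir()
  fx <- make_merfish_fixture(file.path(td, "fx"), n_cells = 20, n_genes = 5,
                             seed = 7, affine = diag(3))
  out <- file.path(td, "s1")
  convert_merfish(fx$cell_by_gene_path, fx$cell_metadata_path,
                  fx$affine_path, out_dir = out)
  ov <- read_overlay(file.path(out, "cells.csv"))
  expect_equal(ov$x, unname(fx$centroids[, "x"]))
  expect_equal(ov$y, unname(fx$centroids[, "y"]))
  fx2 <- make_merfish_fixture(file.path(td, "fx2"), n_cells = 20, n_genes = 5,
                              seed = 7, affine = diag(c(2, 2, 1)))
  out2 <- file.path(td, "s2")
  convert_merfish(fx2$cell_by_gene_path, fx2$cell_metadata_path,
                  fx2$affine_path, out_dir = out2)
  ov2 <- read_overlay(file.path(out2, "cells.csv"))
  expect_equal(ov2$x, 2 * unname(fx2$centroids[, "x"]))
})

test_that("merfish conversion reports cell id mismatches by set difference", {
  withr::local_seed(46)
  td <- withr::local_tempdir()
  fx <- make_merfish_fixture(file.path(td, "fx"), n_cells = 10, n_genes = 3,
                             seed = 8)
  md <- readLines(fx$cell_metadata_path)
  writeLines(md[-2], fx$cell_metadata_path)
  expect_error(convert_merfish(fx$cell_by_gene_path, fx$cell_metadata_path,
                               fx$affine_path, out_dir = file.path(td, "s")),
               "1 ids only in counts")
})

test_that("2x3 affine files are promoted with a (0,0,1) bottom row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("2,0,10", "0,3,-5"), f)
  M <- read_affine(f)
  expect_equal(M[3, ], c(0, 0, 1))
  expect_equal(M[1:2, ], matrix(c(2, 0, 10, 0, 3, -5), 2, 3, byrow = TRUE))
  writeLines(c("1,2", "3,4"), f)
  expect_error(read_affine(f), "3")
})

test_that("preprocess_image defaults record jpeg quality 90 in the manifest", {
  withr::local_seed(47)
  td <- withr::local_tempdir()
  img_path <- file.path(td, "in.tif")
  make_synthetic_image(img_path, 200, 150, seed = 2)
  out <- file.path(td, "s")
  meta <- preprocess_image(img_path, out)
  expect_identical(meta$images[[1]]$compression, "jpeg")
  expect_equal(meta$images[[1]]$jpeg_quality, 90L)
  expect_identical(validate_sample(out), character(0))
  # lossless round trip through the written pyramid
  out2 <- file.path(td, "s2")
  meta2 <- preprocess_image(img_path, out2, compression = "lossless")
  pyr <- open_pyramid(file.path(out2, "image.tif"))
  on.exit(pyr$reader$close())
  orig <- tiff::readTIFF(img_path, as.is = TRUE)
  reg <- read_region(pyr, c(0, 0, 200, 150), 0)$region
  expect_identical(reg[1, , ], orig + 0L)
  expect_error(preprocess_image(file.path(td, "absent.tif"), out2), "cannot read")
})
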