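# Tiled pyramid construction and lazy reads.

test_that("plan_levels halves dimensions by ceiling until one tile suffices", {
  # independent oracle: repeated ceiling halving
  halving <- function(w, h, ts) {
    out <- matrix(c(w, h), ncol = 2)
    while (max(w, h) > ts) {
      w <- ceiling(w / 2); h <- ceiling(h / 2)
      out <- rbind(out, c(w, h))
    }
    out
  }
  expect_equal(nrow(plan_levels(512, 512, 512)$levels), 1)
  p <- plan_levels(20000, 20000, 512)
  expect_equal(p$levels[, "width"],
               c(20000, 10000, 5000, 2500, 1250, 625, 313))
  expect_equal(unname(p$levels), unname(halving(20000, 20000, 512)))
  p2 <- plan_levels(513, 100, 512)
  expect_equal(unname(p2$levels), matrix(c(513, 257, 100, 50), ncol = 2))
  for (i in 1:20) {
    w <- sample(1:5000, 1); h <- sample(1:5000, 1)
    ts <- sample(c(16, 256, 512), 1)
    expect_equal(unname(plan_levels(w, h, ts)$levels),
                 unname(halving(w, h, ts)))
  }
  expect_error(plan_levels(0, 10, 512), "positive")
  expect_error(plan_levels(10, 10, 8), "tile_size")
})

test_that("downsample_level is the block mean with half-up rounding", {
  expect_identical(downsample_level(matrix(0, 2, 2)), matrix(0L, 1, 1))
  expect_identical(downsample_level(matrix(c(1, 5, 3, 7), 2, 2)),
                   matrix(4L, 1, 1))
  # brute-force block-average oracle on random odd/even sizes
  oracle <- function(m) {
    hc <- ceiling(nrow(m) / 2); wc <- ceiling(ncol(m) / 2)
    out <- matrix(0L, hc, wc)
    for (i in seq_len(hc)) for (j in seq_len(wc)) {
      rs <- (2 * i - 1):min(2 * i, nrow(m))
      cs <- (2 * j - 1):min(2 * j, ncol(m))
      out[i, j] <- as.integer(floor(mean(m[rs, cs]) + 0.5))
    }
    out
  }
  for (d in list(c(3, 3), c(5, 4), c(7, 7), c(1, 6), c(8, 1))) {
    m <- matrix(sample(0:255, d[1] * d[2], replace = TRUE), d[1], d[2])
    expect_identical(downsample_level(m), oracle(m))
  }
  m3 <- matrix(sample(0:255, 9), 3, 3)
  expect_equal(downsample_level(m3)[2, 2], m3[3, 3]) # lone corner pixel
})

test_that("lossless pyramids round-trip bit-exactly across sizes and channels", {
  withr::local_seed(11)
  cases <- list(c(1, 17, 33), c(2, 257, 129), c(3, 100, 300), c(4, 64, 1025))
  for (cs in cases) {
    img <- random_uint8_image(cs[1], cs[2], cs[3])
    out <- tempfile(fileext = ".tif")
    spec <- build_pyramid(img, tile_size = 128, compression = "lossless", out = out)
    expect_equal(spec$n_levels, nrow(plan_levels(cs[3], cs[2], 128)$levels))
    pyr <- open_pyramid(out)
    reg <- read_region(pyr, c(0, 0, cs[3], cs[2]), 0)
    expect_identical(reg$region, img + 0L)
    pyr$reader$close()
  }
})

test_that("every overview pixel equals downsample_level of the finer level", {
  withr::local_seed(12)
  img <- random_uint8_image(2, 300, 520)
  out <- tempfile(fileext = ".tif")
  build_pyramid(img, tile_size = 128, compression = "lossless", out = out)
  pyr <- open_pyramid(out)
  on.exit(pyr$reader$close())
  expect_length(pyr$levels, 4) # 520 -> 260 -> 130 -> 65
  prev <- read_region(pyr, c(0, 0, 520, 300), 0)$region
  for (lv in 1:3) {
    cur <- read_region(pyr, c(0, 0, 520, 300), lv)$region
    for (ch in 1:2) {
      expected <- downsample_level(matrix(prev[ch, , ], dim(prev)[2], dim(prev)[3]))
      expect_identical(matrix(cur[ch, , ], dim(cur)[2], dim(cur)[3]), expected)
    }
    prev <- cur
  }
})

test_that("an independent TIFF reader decodes level 0 identically", {
  withr::local_seed(13)
  # tifffile shares no code with this package
  img1 <- random_uint8_image(1, 150, 220)
  f1 <- tempfile(fileext = ".tif")
  build_pyramid(img1, tile_size = 64, compression = "lossless", out = f1)
  expect_identical(tifffile_level0(f1), img1 + 0L)
  # planar multi-channel
  img3 <- random_uint8_image(3, 100, 130)
  f3 <- tempfile(fileext = ".tif")
  build_pyramid(img3, tile_size = 64, compression = "lossless", out = f3)
  expect_identical(tifffile_level0(f3), img3 + 0L)
})

test_that("jpeg pyramids store the quality tag and decode close to the input", {
  # smooth image: jpeg error should stay small at quality 90
  h <- 260; w <- 310
  img <- array(as.integer(round(127 + 100 * sin(outer(1:h, 1:w, "+") / 20))),
               c(1, h, w))
  out <- tempfile(fileext = ".tif")
  spec <- build_pyramid(img, tile_size = 128, compression = "jpeg",
                        jpeg_quality = 90, out = out)
  expect_equal(spec$jpeg_quality, 90L)
  pyr <- open_pyramid(out)
  on.exit(pyr$reader$close())
  expect_equal(pyr$jpeg_quality, 90L)
  reg <- read_region(pyr, c(0, 0, w, h), 0)$region
  expect_lt(mean(abs(reg - img)), 5)
  # the independent reader agrees with the package's own decoder
  expect_equal(tifffile_level0(out), reg)
})

test_that("argument errors: jpeg 16-bit, bad tile size, channel mismatch", {
  img16 <- array(sample(0:60000, 64 * 64, replace = TRUE), c(1, 64, 64))
  expect_error(build_pyramid(img16, compression = "jpeg", out = tempfile()),
               "8-bit")
  img <- random_uint8_image(1, 64, 64)
  expect_error(build_pyramid(img, tile_size = 100, out = tempfile()),
               "multiple of 16")
  expect_error(build_pyramid(img, channels = c("a", "b"), out = tempfile()),
               "channel name count")
})

test_that("16-bit lossless pyramids round-trip exactly", {
  withr::local_seed(15)
  img <- array(sample(0:65535, 90 * 140, replace = TRUE), c(1, 90, 140))
  out <- tempfile(fileext = ".tif")
  build_pyramid(img, tile_size = 64, compression = "lossless", out = out)
  pyr <- open_pyramid(out)
  on.exit(pyr$reader$close())
  expect_identical(read_region(pyr, c(0, 0, 140, 90), 0)$region, img + 0L)
  expect_identical(tifffile_level0(out), img + 0L)
})

test_that("reading one tile fetches only the header and that tile's bytes", {
  withr::local_seed(16)
  img <- random_uint8_image(1, 1024, 1024) # 16 tiles at 256
  out <- tempfile(fileext = ".tif")
  build_pyramid(img, tile_size = 256, compression = "lossless", out = out)
  fsize <- file.size(out)
  rr <- range_reader(out)
  pyr <- open_pyramid(rr)
  header <- rr$bytes_fetched()
  tl <- read_tile(pyr, 0, 2, 3)
  one_tile <- rr$bytes_fetched() - header
  l0 <- pyr$levels[[1]]
  k <- (2 - 1) * l0$tiles_across + 3
  expect_equal(one_tile, l0$lengths[k])
  n_tiles <- l0$tiles_down * l0$tiles_across
  expect_lt(rr$bytes_fetched(), fsize / n_tiles + header)
  expect_identical(tl[1, , ], img[1, 257:512, 513:768] + 0L)
  # cached reader: second identical read costs nothing
  rr2 <- caching_range_reader(range_reader(out))
  pyr2 <- open_pyramid(rr2)
  read_tile(pyr2, 0, 1, 1)
  before <- rr2$bytes_fetched()
  read_tile(pyr2, 0, 1, 1)
  expect_equal(rr2$bytes_fetched(), before)
  expect_error(read_tile(pyr, 0, 5, 1), "outside")
  rr$close(); rr2$close()
})

test_that("plan_viewport matches a brute-force intersection oracle", {
  withr::local_seed(17)
  plan <- plan_levels(1024, 1024, 256)
  # hand cases
  expect_equal(nrow(plan_viewport(c(0, 0, 1024, 1024), 0, plan)), 16)
  expect_equal(plan_viewport(c(10, 10, 20, 20), 0, plan),
               matrix(c(1L, 1L), 1, dimnames = list(NULL, c("row", "col"))))
  corner <- plan_viewport(c(250, 250, 260, 260), 0, plan)
  expect_equal(nrow(corner), 4)
  # randomized agreement, all levels
  for (i in 1:500) {
    lv <- sample(0:(nrow(plan$levels) - 1), 1)
    x <- sort(runif(2, -50, 1100)); y <- sort(runif(2, -50, 1100))
    vp <- c(x[1], y[1], x[2], y[2])
    got <- plan_viewport(vp, lv, plan)
    want <- viewport_tiles_bruteforce(vp, lv, plan, 256)
    expect_equal(unname(got), unname(want), ignore_attr = TRUE)
  }
})

test_that("read_region byte accounting is additive over disjoint viewports", {
  withr::local_seed(18)
  img <- random_uint8_image(1, 512, 512)
  out <- tempfile(fileext = ".tif")
  build_pyramid(img, tile_size = 128, compression = "lossless", out = out)
  rr <- range_reader(out)
  pyr <- open_pyramid(rr)
  on.exit(rr$close())
  header <- rr$bytes_fetched()
  r1 <- read_region(pyr, c(0, 0, 100, 100), 0)
  r2 <- read_region(pyr, c(300, 300, 400, 400), 0)
  l0 <- pyr$levels[[1]]
  expect_equal(r1$bytes_fetched, l0$lengths[1])
  expect_equal(rr$bytes_fetched(), header + r1$bytes_fetched + r2$bytes_fetched)
  expect_identical(r1$region[1, , ], img[1, 1:100, 1:100] + 0L)
  expect_identical(r2$region[1, , ], img[1, 301:400, 301:400] + 0L)
})

test_that("gaussian filter: identity at radius 0, unit mass, symmetric impulse", {
  img <- matrix(runif(50 * 60, 0, 255), 50, 60)
  expect_identical(gaussian_filter_image(img, 0), img)
  expect_error(gaussian_filter_image(img, -1), "radius")
  const <- matrix(7, 40, 40)
  expect_equal(gaussian_filter_image(const, 3), const, tolerance = 1e-12)
  imp <- matrix(0, 129, 129); imp[65, 65] <- 1
  g <- gaussian_filter_image(imp, 4)
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_equal(g, t(g), tolerance = 1e-12)              # transpose symmetry
  expect_equal(g, g[129:1, 129:1], tolerance = 1e-12)   # 180-degree rotation
  expect_equal(g[65, 65], stats::dnorm(0, sd = 4)^2 / sum(stats::dnorm(-16:16, sd = 4))^2,
               tolerance = 1e-6)
})
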