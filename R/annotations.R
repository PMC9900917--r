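# Labeled annotations at three granularities: freestanding points
# (e.g. marked cells), circles (e.g. 55 um Visium spots), and polygons
# (spatial domains). Coordinates are level-0 pixels in the frame of an
# overlay or of the image itself.

.ann_geoms <- c("point", "circle", "polygon")

.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Annotation geometries
#'
#' Constructors for the three annotation geometry kinds. Coordinates are
#' level-0 pixels; circle diameters are physical (microns) so a spot
#' annotation keeps its meaning across magnifications.
#'
#' @param x,y Coordinates (scalars for point/circle, vectors of at least 3
#'   vertices for polygon).
#' @param diameter_um Circle diameter in microns.
#' @return A geometry list with a `type` field.
#' @export
ann_point <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  list(type = "point", x = as.numeric(x), y = as.numeric(y))
}

#' @rdname ann_point
#' @export
ann_circle <- function(x, y, diameter_um) {
  stopifnot(is.finite(x), is.finite(y))
  if (!is.finite(diameter_um) || diameter_um <= 0)
    stop("circle diameter_um must be positive")
  list(type = "circle", x = as.numeric(x), y = as.numeric(y),
       diameter_um = as.numeric(diameter_um))
}

#' @rdname ann_point
#' @export
ann_polygon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("polygon needs at least 3 vertices")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("polygon vertices must be finite")
  if (.polygon_area(x, y) <= 0) stop("polygon has zero area")
  list(type = "polygon", x = as.numeric(x), y = as.numeric(y))
}

#' A set of labeled annotations
#'
#' An ordered list of `(label, geometry)` records tied to a coordinate
#' frame (an overlay name, or `"image"` for the raster itself). Order is
#' meaningful: when annotations overlap, [assign_labels()] gives precedence
#' to the earliest record.
#'
#' @param records List of records, each a list with `label` (non-empty
#'   string) and `geometry` (from [ann_point()], [ann_circle()],
#'   [ann_polygon()]).
#' @param coord_frame Name of the coordinate frame.
#' @return A list of class `srt_annotation_set`.
#' @export
annotation_set <- function(records = list(), coord_frame = "image") {
  for (r in records) {
    if (is.null(r$label) || !nzchar(r$label)) stop("annotation label must be non-empty")
    if (is.null(r$geometry$type) || !r$geometry$type %in% .ann_geoms)
      stop("unknown geometry type: ", r$geometry$type)
  }
  structure(list(coord_frame = coord_frame, records = records),
            class = "srt_annotation_set")
}

#' @export
print.srt_annotation_set <- function(x, ...) {
  types <- vapply(x$records, function(r) r$geometry$type, "")
  cat("<annotations>", length(x$records), "record(s) in frame '",
      x$coord_frame, "' (", sum(types == "point"), "point,",
      sum(types == "circle"), "circle,", sum(types == "polygon"), "polygon )\n")
  invisible(x)
}

.fmt6 <- function(v) sprintf("%.6g", v)

.geom_data <- function(g) {
  switch(g$type,
         point = paste(.fmt6(g$x), .fmt6(g$y)),
         circle = paste(.fmt6(g$x), .fmt6(g$y), .fmt6(g$diameter_um)),
         polygon = paste(paste(.fmt6(g$x), .fmt6(g$y)), collapse = ";"))
}

.parse_geom_data <- function(type, data, line) {
  fail <- function(msg) stop("line ", line, ": ", msg)
  tryCatch(.parse_geom_data_impl(type, data, fail),
           error = function(e) {
             msg <- conditionMessage(e)
             if (grepl("^line ", msg)) stop(e) else fail(msg)
           })
}

.parse_geom_data_impl <- function(type, data, fail) {
  if (type == "polygon") {
    pairs <- strsplit(strsplit(data, ";", fixed = TRUE)[[1]], " ", fixed = TRUE)
    if (any(lengths(pairs) != 2L)) fail("malformed polygon coordinate string")
    x <- as.numeric(vapply(pairs, `[[`, "", 1L))
    y <- as.numeric(vapply(pairs, `[[`, "", 2L))
    if (anyNA(x) || anyNA(y)) fail("non-numeric polygon vertex")
    ann_polygon(x, y)
  } else {
    v <- as.numeric(strsplit(data, " ", fixed = TRUE)[[1]])
    if (anyNA(v)) fail("non-numeric coordinate")
    if (type == "point") {
      if (length(v) != 2L) fail("point needs 'x y'")
      ann_point(v[1], v[2])
    } else if (type == "circle") {
      if (length(v) != 3L) fail("circle needs 'x y diameter_um'")
      ann_circle(v[1], v[2], v[3])
    } else fail(paste0("unknown geometry '", type, "'"))
  }
}

#' Export annotations to CSV
#'
#' Writes the native annotation dialect: header `label,geometry,data`, one
#' record per row, with coordinates serialized at 6 significant digits
#' (polygons as `x1 y1;x2 y2;...`). [import_annotations()] inverts it.
#'
#' @param set An [annotation_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(set, path) {
  stopifnot(inherits(set, "srt_annotation_set"))
  rows <- vapply(set$records, function(r)
    paste0("\"", gsub("\"", "\"\"", r$label), "\",", r$geometry$type, ",\"",
           .geom_data(r$geometry), "\""), "")
  tryCatch(writeLines(c("label,geometry,data", rows), path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

.import_native <- function(path, coord_frame) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("label", "geometry", "data")))
    stop("native annotation CSV must have header label,geometry,data")
  records <- lapply(seq_len(nrow(df)), function(i)
    list(label = df$label[i],
         geometry = .parse_geom_data(df$geometry[i], df$data[i], i + 1L)))
  annotation_set(records, coord_frame)
}

.import_napari_points <- function(path, coord_frame) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("axis-0", "axis-1")
  if (!all(need %in% names(df)))
    stop("points table needs 'axis-0' and 'axis-1' columns")
  labels <- if ("label" %in% names(df)) as.character(df$label) else
    rep("points", nrow(df))
  records <- lapply(seq_len(nrow(df)), function(i)
    list(label = labels[i],
         # external tables are row-major: axis-0 = row = y, axis-1 = col = x
         geometry = ann_point(x = df[["axis-1"]][i], y = df[["axis-0"]][i])))
  annotation_set(records, coord_frame)
}

.import_napari_shapes <- function(path, coord_frame) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("index", "shape-type", "axis-0", "axis-1")
  if (!all(need %in% names(df)))
    stop("shapes table needs columns ", paste(need, collapse = ", "))
  records <- list()
  for (ix in unique(df$index)) {
    sub <- df[df$index == ix, ]
    type <- sub[["shape-type"]][1]
    label <- if ("label" %in% names(sub)) as.character(sub$label[1]) else
      paste0("shape-", ix)
    geom <- switch(type,
                   polygon = ,
                   rectangle = ann_polygon(x = sub[["axis-1"]], y = sub[["axis-0"]]),
                   path = ,
                   line = NULL, # unsupported open shapes are skipped
                   stop("unsupported shape-type '", type, "'"))
    if (!is.null(geom))
      records[[length(records) + 1L]] <- list(label = label, geometry = geom)
  }
  annotation_set(records, coord_frame)
}

#' Import annotations from CSV
#'
#' `"native"` inverts [export_annotations()]. `"napari_points"` reads a
#' point table with `axis-0`/`axis-1` columns (row-major axis order, so
#' axis-0 maps to y and axis-1 to x); `"napari_shapes"` reads a shape table
#' (`index`, `shape-type`, `vertex-index`, `axis-0`, `axis-1`) and converts
#' closed shapes to polygons.
#'
#' @param path CSV file.
#' @param dialect One of `"native"`, `"napari_points"`, `"napari_shapes"`.
#' @param coord_frame Coordinate frame to attach.
#' @return An [annotation_set()].
#' @export
import_annotations <- function(path,
                               dialect = c("native", "napari_points",
                                           "napari_shapes"),
                               coord_frame = "image") {
  dialect <- match.arg(dialect)
  switch(dialect,
         native = .import_native(path, coord_frame),
         napari_points = .import_napari_points(path, coord_frame),
         napari_shapes = .import_napari_shapes(path, coord_frame))
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Ray-crossing (even-odd) containment test, vectorized over points.
#' Points exactly on a polygon edge or vertex count as inside — a
#' deterministic convention so a spot centered on a domain boundary is
#' always labeled.
#'
#' @param px,py Point coordinates (vectors of equal length).
#' @param poly A polygon from [ann_polygon()], or a list with numeric `x`,
#'   `y` vertex vectors.
#' @return Logical vector, one entry per point.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (is.null(x) || n < 3L || .polygon_area(x, y) <= 0)
    stop("degenerate polygon")
  stopifnot(length(px) == length(py))
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    # boundary: point within the segment's bounding box and collinear
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    on_seg <- abs(cross) < 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Assign annotation labels to overlay points
#'
#' Labels each overlay point with the first annotation record (in set
#' order) that contains it: circles by Euclidean distance at most half the
#' diameter (microns converted to pixels via `microns_per_pixel`), polygons
#' by [point_in_polygon()]. Point annotations are freestanding marks and
#' never capture overlay rows. Unmatched points get the empty-string
#' sentinel.
#'
#' @param ov An [overlay()].
#' @param set An [annotation_set()] in the overlay's coordinate frame.
#' @param microns_per_pixel Physical scale; required when the set contains
#'   circle annotations.
#' @return A data frame with columns `id` and `label` (empty string =
#'   unlabeled), one row per overlay point, in overlay order.
#' @export
assign_labels <- function(ov, set, microns_per_pixel = NULL) {
  stopifnot(inherits(ov, "srt_overlay"), inherits(set, "srt_annotation_set"))
  has_circle <- any(vapply(set$records, function(r)
    r$geometry$type == "circle", NA))
  if (has_circle && (is.null(microns_per_pixel) || microns_per_pixel <= 0))
    stop("circle annotations need a positive microns_per_pixel to convert ",
         "diameters to pixels")
  labels <- rep("", length(ov$ids))
  unset <- rep(TRUE, length(ov$ids))
  for (r in set$records) {
    g <- r$geometry
    hit <- switch(g$type,
                  point = rep(FALSE, length(ov$x)),
                  circle = {
                    rad_px <- (g$diameter_um / microns_per_pixel) / 2
                    (ov$x - g$x)^2 + (ov$y - g$y)^2 <= rad_px^2
                  },
                  polygon = point_in_polygon(ov$x, ov$y, g))
    take <- hit & unset
    labels[take] <- r$label
    unset[take] <- FALSE
  }
  data.frame(id = ov$ids, label = labels, stringsAsFactors = FALSE)
}

#' Merge an assignment table into a sample as a categorical feature group
#'
#' Converts the output of [assign_labels()] into a one-feature categorical
#' group over the given overlay and registers it in the sample manifest.
#'
#' @param folder Sample folder.
#' @param overlay_name Overlay the labels refer to.
#' @param assignment Data frame from [assign_labels()].
#' @param group_name Name for the new feature group.
#' @return The updated [sample_meta()], invisibly.
#' @export
merge_annotation_feature <- function(folder, overlay_name, assignment,
                                     group_name = "annotation") {
  meta <- read_sample_meta(file.path(folder, "sample.json"))
  ov_specs <- vapply(meta$overlays, function(o) o$name, "")
  oi <- match(overlay_name, ov_specs)
  if (is.na(oi)) stop("no overlay '", overlay_name, "' in sample")
  ov <- read_overlay(file.path(folder, meta$overlays[[oi]]$path),
                     name = overlay_name)
  if (!identical(assignment$id, ov$ids))
    stop("assignment ids do not match overlay row order")
  lv <- sort(unique(assignment$label[nzchar(assignment$label)]))
  codes <- match(assignment$label, lv)
  keep <- which(!is.na(codes))
  sf <- sparse_feature("label", keep, codes[keep])
  fg <- write_feature_group(ov, list(sf), folder, group_name,
                            value_kind = "categorical", levels = lv)
  meta$feature_groups <- c(
    Filter(function(g) g$name != group_name, meta$feature_groups), list(fg))
  meta <- sample_meta(meta$name, meta$images, meta$overlays,
                      meta$feature_groups, meta$microns_per_pixel)
  write_sample_meta(meta, folder)
  invisible(meta)
}
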