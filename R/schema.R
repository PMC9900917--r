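# Sample folder layout:
#   sample.json                 manifest (this module)
#   <image>.tif                 tiled pyramid(s)
#   <overlay>.csv               point coordinates, header id,x,y
#   <group>.bin + .index.json   chunked feature store
#
# The manifest is written with sorted keys and fixed number formatting so
# two writes of the same metadata are byte-identical.

.json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  s <- gsub("\r", "\\\\r", s)
  s <- gsub("\t", "\\\\t", s)
  s
}

.json_num <- function(x) {
  if (is.infinite(x) || is.na(x)) stop("non-finite number in JSON document")
  if (x == round(x) && abs(x) < 1e15) sprintf("%.0f", x)
  else formatC(signif(x, 6), format = "g", digits = 6)
}

# deterministic JSON: object keys sorted, numbers at 6 significant digits
canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      parts <- vapply(sort(nm), function(k)
        paste0("\"", .json_escape(k), "\":", canonical_json(x[[k]])), "")
      paste0("{", paste(parts, collapse = ","), "}")
    } else {
      paste0("[", paste(vapply(x, canonical_json, ""), collapse = ","), "]")
    }
  } else if (length(x) != 1L) {
    paste0("[", paste(vapply(x, canonical_json, ""), collapse = ","), "]")
  } else if (is.character(x)) {
    paste0("\"", .json_escape(x), "\"")
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else {
    .json_num(x)
  }
}

.need <- function(x, keys, what) {
  miss <- setdiff(keys, names(x))
  if (length(miss))
    stop("invalid ", what, ": missing field(s) ", paste(miss, collapse = ", "))
}

#' Image specification within a sample manifest
#'
#' Describes one tiled pyramid file: its channels, level-0 dimensions, tile
#' size, level count and compression. `jpeg_quality` must be present exactly
#' when `compression = "jpeg"`.
#'
#' @param path File path relative to the sample folder.
#' @param channels Character vector of channel names (at least one).
#' @param width,height Level-0 dimensions in pixels.
#' @param tile_size Tile edge length (>= 16).
#' @param n_levels Number of pyramid levels (>= 1).
#' @param compression `"lossless"` or `"jpeg"`.
#' @param jpeg_quality Integer 1-100, or `NULL` for lossless.
#' @return A list of class `srt_image_spec`.
#' @export
image_spec <- function(path, channels, width, height, tile_size = 512L,
                       n_levels = 1L, compression = "lossless",
                       jpeg_quality = NULL) {
  if (!is.character(path) || !nzchar(path)) stop("invalid image spec: empty path")
  if (length(channels) < 1) stop("invalid image spec: channels must be non-empty")
  if (width < 1 || height < 1) stop("invalid image spec: width/height must be positive")
  if (tile_size < 16) stop("invalid image spec: tile_size must be >= 16")
  if (n_levels < 1) stop("invalid image spec: n_levels must be >= 1")
  if (!compression %in% c("lossless", "jpeg"))
    stop("invalid image spec: compression must be lossless or jpeg")
  if (compression == "jpeg" && is.null(jpeg_quality))
    stop("invalid image spec: jpeg compression requires jpeg_quality")
  if (compression == "lossless" && !is.null(jpeg_quality))
    stop("invalid image spec: jpeg_quality only valid with jpeg compression")
  if (!is.null(jpeg_quality) && (jpeg_quality < 1 || jpeg_quality > 100))
    stop("invalid image spec: jpeg_quality must be in 1..100")
  structure(list(path = path, channels = as.character(channels),
                 width = as.integer(width), height = as.integer(height),
                 tile_size = as.integer(tile_size), n_levels = as.integer(n_levels),
                 compression = compression,
                 jpeg_quality = if (is.null(jpeg_quality)) NULL else as.integer(jpeg_quality)),
            class = "srt_image_spec")
}

#' Overlay specification within a sample manifest
#'
#' An overlay is an ordered layer of points (spots or cells) in level-0
#' pixel coordinates, stored as a CSV with header `id,x,y`. Circle geometry
#' (e.g. Visium spots) carries a physical diameter in microns.
#'
#' @param name Overlay name (unique within a sample).
#' @param path Coordinate CSV path relative to the sample folder.
#' @param n_points Number of points (rows of the CSV).
#' @param geometry `"point"` or `"circle"`.
#' @param diameter_um Circle diameter in microns; required iff
#'   `geometry = "circle"`.
#' @return A list of class `srt_overlay_spec`.
#' @export
overlay_spec <- function(name, path, n_points, geometry = c("point", "circle"),
                         diameter_um = NULL) {
  geometry <- match.arg(geometry)
  if (!nzchar(name)) stop("invalid overlay spec: empty name")
  if (n_points < 0) stop("invalid overlay spec: negative n_points")
  if (geometry == "circle" && (is.null(diameter_um) || diameter_um <= 0))
    stop("invalid overlay spec: circle geometry requires a positive diameter_um")
  if (geometry == "point" && !is.null(diameter_um))
    stop("invalid overlay spec: diameter_um only valid for circle geometry")
  structure(list(name = name, path = path, n_points = as.integer(n_points),
                 geometry = geometry, diameter_um = diameter_um),
            class = "srt_overlay_spec")
}

#' Feature group specification within a sample manifest
#'
#' A feature group attaches a set of named quantitative or categorical
#' feature vectors (one value per overlay point) to an overlay, stored as a
#' chunked compressed payload plus a byte-offset index.
#'
#' @param name Group name.
#' @param overlay_name Name of the overlay the features refer to.
#' @param path Payload path (`<group>.bin`) relative to the sample folder;
#'   the index sidecar is `<group>.index.json`.
#' @param feature_names Unique, non-empty feature names.
#' @param value_kind `"quantitative"` or `"categorical"`.
#' @return A list of class `srt_feature_group_spec`.
#' @export
feature_group_spec <- function(name, overlay_name, path, feature_names,
                               value_kind = c("quantitative", "categorical")) {
  value_kind <- match.arg(value_kind)
  if (!nzchar(name)) stop("invalid feature group spec: empty name")
  if (anyDuplicated(feature_names))
    stop("invalid feature group spec: duplicate feature names")
  if (length(feature_names) && any(!nzchar(feature_names)))
    stop("invalid feature group spec: empty feature name")
  structure(list(name = name, overlay_name = overlay_name, path = path,
                 feature_names = as.character(feature_names),
                 value_kind = value_kind),
            class = "srt_feature_group_spec")
}

#' Sample metadata (the master manifest)
#'
#' The manifest ties a sample folder together: its images, overlays, feature
#' groups, and the physical scale of level-0 pixels. Every feature group
#' must reference exactly one declared overlay by name.
#'
#' @param name Sample name (non-empty).
#' @param images List of [image_spec()] objects.
#' @param overlays List of [overlay_spec()] objects.
#' @param feature_groups List of [feature_group_spec()] objects.
#' @param microns_per_pixel Physical scale of a level-0 pixel, in microns
#'   (> 0).
#' @return A list of class `srt_sample_meta`.
#' @export
sample_meta <- function(name, images = list(), overlays = list(),
                        feature_groups = list(), microns_per_pixel = 1) {
  if (!is.character(name) || !nzchar(name)) stop("invalid sample meta: empty name")
  if (!is.numeric(microns_per_pixel) || !is.finite(microns_per_pixel) ||
      microns_per_pixel <= 0)
    stop("invalid sample meta: microns_per_pixel must be a positive real")
  ov_names <- vapply(overlays, function(o) o$name, "")
  if (anyDuplicated(ov_names)) stop("invalid sample meta: duplicate overlay names")
  for (fg in feature_groups) {
    hits <- sum(ov_names == fg$overlay_name)
    if (hits != 1L)
      stop("invalid sample meta: feature group '", fg$name,
           "' references overlay '", fg$overlay_name, "' which matches ",
           hits, " overlays")
  }
  structure(list(name = name, images = images, overlays = overlays,
                 feature_groups = feature_groups,
                 microns_per_pixel = microns_per_pixel),
            class = "srt_sample_meta")
}

#' @export
print.srt_sample_meta <- function(x, ...) {
  cat("<sample>", x$name, "-", length(x$images), "image(s),",
      length(x$overlays), "overlay(s),", length(x$feature_groups),
      "feature group(s);", x$microns_per_pixel, "um/px\n")
  invisible(x)
}

.spec_to_list <- function(s) {
  out <- unclass(s)
  out[!vapply(out, is.null, NA)]
}

#' Write the sample manifest
#'
#' Serializes the metadata to `sample.json` at the folder root with sorted
#' keys and fixed number formatting, so repeated writes of equal metadata
#' are byte-identical.
#'
#' @param meta A [sample_meta()] object.
#' @param folder Existing, writable sample folder.
#' @return The path to the written `sample.json`, invisibly.
#' @export
write_sample_meta <- function(meta, folder) {
  if (!inherits(meta, "srt_sample_meta")) stop("meta must be a sample_meta object")
  if (!dir.exists(folder)) stop("folder does not exist: ", folder)
  doc <- list(
    name = meta$name,
    microns_per_pixel = meta$microns_per_pixel,
    images = lapply(meta$images, .spec_to_list),
    overlays = lapply(meta$overlays, .spec_to_list),
    feature_groups = lapply(meta$feature_groups, .spec_to_list)
  )
  path <- file.path(folder, "sample.json")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(canonical_json(doc), "\n")), con)
  invisible(path)
}

.as_chr <- function(x) vapply(x, as.character, "")

#' Read and validate a sample manifest
#'
#' Parses `sample.json` and rebuilds the metadata through the validating
#' constructors, so every schema invariant is re-checked on read.
#'
#' @param path Path to a manifest JSON file.
#' @return A [sample_meta()] object.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .need(doc, c("name", "microns_per_pixel", "images", "overlays", "feature_groups"),
        "sample manifest")
  images <- lapply(doc$images, function(i) {
    .need(i, c("path", "channels", "width", "height", "tile_size", "n_levels",
               "compression"), "image spec")
    image_spec(i$path, .as_chr(i$channels), i$width, i$height, i$tile_size,
               i$n_levels, i$compression, i$jpeg_quality)
  })
  overlays <- lapply(doc$overlays, function(o) {
    .need(o, c("name", "path", "n_points", "geometry"), "overlay spec")
    overlay_spec(o$name, o$path, o$n_points, o$geometry, o$diameter_um)
  })
  fgs <- lapply(doc$feature_groups, function(f) {
    .need(f, c("name", "overlay_name", "path", "feature_names", "value_kind"),
          "feature group spec")
    feature_group_spec(f$name, f$overlay_name, f$path, .as_chr(f$feature_names),
                       f$value_kind)
  })
  sample_meta(doc$name, images, overlays, fgs, doc$microns_per_pixel)
}

#' Validate a sample folder
#'
#' Checks that the manifest parses, every referenced file exists, overlay
#' CSV row counts match their declared `n_points`, image pyramids open and
#' match their declared geometry, and feature-store indexes are internally
#' consistent (ascending non-overlapping byte ranges that decompress to
#' well-formed records). Findings are data, not errors; an empty character
#' vector means the folder is valid.
#'
#' @param folder Path to a sample folder.
#' @return Character vector of findings (empty if valid).
#' @export
validate_sample <- function(folder) {
  findings <- character(0)
  note <- function(...) findings <<- c(findings, paste0(...))
  if (!dir.exists(folder)) return(paste0("sample folder does not exist: ", folder))
  mpath <- file.path(folder, "sample.json")
  if (!file.exists(mpath)) return(paste0("missing manifest: ", mpath))
  meta <- tryCatch(read_sample_meta(mpath), error = function(e)
    conditionMessage(e))
  if (is.character(meta)) return(paste0("manifest invalid: ", meta))

  for (im in meta$images) {
    p <- file.path(folder, im$path)
    if (!file.exists(p)) { note("missing image file: ", im$path); next }
    pyr <- tryCatch(open_pyramid(p), error = function(e) conditionMessage(e))
    if (is.character(pyr)) { note("unreadable pyramid ", im$path, ": ", pyr); next }
    l0 <- pyr$levels[[1]]
    if (l0$width != im$width || l0$height != im$height)
      note("image ", im$path, ": level-0 dims ", l0$width, "x", l0$height,
           " differ from manifest ", im$width, "x", im$height)
    if (length(pyr$levels) != im$n_levels)
      note("image ", im$path, ": ", length(pyr$levels),
           " levels in file, manifest says ", im$n_levels)
    pyr$reader$close()
  }
  for (ov in meta$overlays) {
    p <- file.path(folder, ov$path)
    if (!file.exists(p)) { note("missing overlay file: ", ov$path); next }
    o <- tryCatch(read_overlay(p), error = function(e) conditionMessage(e))
    if (is.character(o)) { note("unreadable overlay ", ov$path, ": ", o); next }
    if (length(o$ids) != ov$n_points)
      note("overlay ", ov$name, ": ", length(o$ids),
           " rows in ", ov$path, ", manifest says ", ov$n_points)
  }
  ov_n <- stats::setNames(
    vapply(meta$overlays, function(o) o$n_points, 0L),
    vapply(meta$overlays, function(o) o$name, ""))
  for (fg in meta$feature_groups) {
    p <- file.path(folder, fg$path)
    idx_path <- file.path(folder, sub("\\.bin$", ".index.json", fg$path))
    if (!file.exists(p)) { note("missing feature payload: ", fg$path); next }
    if (!file.exists(idx_path)) {
      note("missing feature index: ", basename(idx_path)); next
    }
    grp <- tryCatch(open_feature_group(idx_path), error = function(e)
      conditionMessage(e))
    if (is.character(grp)) { note("unreadable feature group ", fg$name, ": ", grp); next }
    res <- tryCatch({
      check_feature_group(grp, n_points = ov_n[[fg$overlay_name]])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note("feature group ", fg$name, ": ", res)
    if (!identical(list_features(grp), fg$feature_names))
      note("feature group ", fg$name, ": index names differ from manifest")
    grp$reader$close()
  }
  findings
}
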