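# Chunked, compressed per-feature store.
#
# The lazy unit is one feature (e.g. one gene): each feature's sparse
# vector is serialized as CSV text lines "row,value", deflate-compressed
# independently of its neighbours, and concatenated into <group>.bin. A
# JSON sidecar <group>.index.json records each record's byte offset and
# length, so reading one feature costs the (small) index plus exactly one
# record's bytes through a range reader.

#' Point overlay
#'
#' An ordered set of points (spots or cells) in level-0 pixel coordinates.
#' Feature vectors index into this order: feature row `i` always refers to
#' overlay point `i`.
#'
#' @param name Overlay name.
#' @param ids Unique point identifiers (barcodes, cell ids).
#' @param x,y Coordinates in level-0 pixels (origin top-left, x rightward,
#'   y downward).
#' @return A list of class `srt_overlay`.
#' @export
overlay <- function(name, ids, x, y) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("overlay ids must be unique")
  if (length(ids) != length(x) || length(ids) != length(y))
    stop("ids, x and y must have equal length")
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("overlay coordinates must be finite")
  structure(list(name = name, ids = ids, x = as.numeric(x), y = as.numeric(y)),
            class = "srt_overlay")
}

#' @export
print.srt_overlay <- function(x, ...) {
  cat("<overlay>", x$name, "-", length(x$ids), "point(s)\n")
  invisible(x)
}

#' Read / write overlay coordinate CSVs
#'
#' Overlay files are plain CSVs with header `id,x,y`; coordinates are
#' written at full double precision so geometric round trips are exact to
#' the last bit.
#'
#' @param ov An [overlay()] object.
#' @param path CSV file path.
#' @return `write_overlay` returns `path` invisibly; `read_overlay` returns
#'   an [overlay()].
#' @export
write_overlay <- function(ov, path) {
  stopifnot(inherits(ov, "srt_overlay"))
  lines <- c("id,x,y",
             if (length(ov$ids))
               sprintf("%s,%.17g,%.17g", ov$ids, ov$x, ov$y))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_overlay
#' @param name Overlay name to attach on read (defaults to the file stem).
#' @export
read_overlay <- function(path, name = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  if (!identical(names(df), c("id", "x", "y")))
    stop("overlay CSV must have header id,x,y; got: ", paste(names(df), collapse = ","))
  overlay(name, df$id, df$x, df$y)
}

#' Sparse feature vector
#'
#' One feature's nonzero (or labeled) entries: strictly increasing 1-based
#' row positions into an overlay, with one value per position.
#'
#' @param name Feature name.
#' @param indices Strictly increasing integer positions (1-based).
#' @param values Numeric values (quantitative) or integer category codes.
#' @return A list of class `srt_sparse_feature`.
#' @export
sparse_feature <- function(name, indices, values) {
  indices <- as.integer(indices)
  if (length(indices) != length(values)) stop("indices and values differ in length")
  if (length(indices) && (any(indices < 1) || any(diff(indices) <= 0)))
    stop("indices must be strictly increasing and >= 1")
  structure(list(name = name, indices = indices, values = as.numeric(values)),
            class = "srt_sparse_feature")
}

#' Sparsify a dense feature matrix
#'
#' Converts each column of a points-by-features matrix into a
#' [sparse_feature()], dropping exact zeros. Densifying the result
#' reproduces the column exactly.
#'
#' @param dense Numeric matrix, `n_points` rows by `n_features` columns.
#' @param feature_names One name per column.
#' @return List of [sparse_feature()] objects, one per column.
#' @export
sparsify <- function(dense, feature_names) {
  if (!is.matrix(dense) && !inherits(dense, "Matrix"))
    stop("dense must be a matrix")
  if (ncol(dense) != length(feature_names))
    stop("feature_names length (", length(feature_names),
         ") does not match column count (", ncol(dense), ")")
  if (anyNA(dense)) stop("NA/NaN values in feature matrix; impute or drop first")
  lapply(seq_len(ncol(dense)), function(j) {
    col <- as.numeric(dense[, j])
    nz <- which(col != 0)
    sparse_feature(feature_names[j], nz, col[nz])
  })
}

#' Densify a sparse feature
#'
#' @param sf A [sparse_feature()].
#' @param n_points Length of the dense result.
#' @param fill Value for absent positions (0 for quantitative features).
#' @return Numeric vector of length `n_points`.
#' @export
densify <- function(sf, n_points, fill = 0) {
  if (length(sf$indices) && max(sf$indices) > n_points)
    stop("feature '", sf$name, "' indexes beyond ", n_points, " points")
  out <- rep(fill, n_points)
  out[sf$indices] <- sf$values
  out
}

.fmt_value <- function(v, value_kind) {
  if (value_kind == "categorical") sprintf("%d", as.integer(v))
  else sprintf("%.6g", v)
}

.encode_record <- function(sf, value_kind) {
  if (!length(sf$indices)) return(memCompress(raw(0), type = "gzip"))
  txt <- paste0(sf$indices, ",", .fmt_value(sf$values, value_kind),
                collapse = "\n")
  memCompress(charToRaw(txt), type = "gzip")
}

.decode_record <- function(bytes, value_kind) {
  rawtxt <- memDecompress(bytes, type = "gzip")
  if (!length(rawtxt)) return(list(indices = integer(0), values = numeric(0)))
  parts <- strsplit(strsplit(rawToChar(rawtxt), "\n", fixed = TRUE)[[1]],
                    ",", fixed = TRUE)
  idx <- as.integer(vapply(parts, `[[`, "", 1L))
  val <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(idx) || anyNA(val)) stop("malformed sparse record")
  list(indices = idx, values = val)
}

#' Write a chunked feature group
#'
#' Compresses each feature independently, concatenates the records into
#' `<name>.bin`, and writes the byte-offset index to `<name>.index.json`.
#' The index alone is enough to open the group and locate any record.
#'
#' @param overlay The [overlay()] the features refer to.
#' @param features List of [sparse_feature()] objects with unique names and
#'   indices within the overlay.
#' @param out_dir Output directory.
#' @param name Group name (file stem).
#' @param value_kind `"quantitative"` or `"categorical"`.
#' @param levels For categorical groups, the code-to-label table: labels in
#'   code order (code `i` means `levels[i]`).
#' @return A [feature_group_spec()] for the written group.
#' @export
write_feature_group <- function(overlay, features, out_dir, name,
                                value_kind = c("quantitative", "categorical"),
                                levels = NULL) {
  value_kind <- match.arg(value_kind)
  stopifnot(inherits(overlay, "srt_overlay"))
  n_points <- length(overlay$ids)
  nms <- vapply(features, function(f) f$name, "")
  if (anyDuplicated(nms)) stop("duplicate feature names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  for (f in features)
    if (length(f$indices) && max(f$indices) > n_points)
      stop("feature '", f$name, "' indexes beyond the overlay's ",
           n_points, " points")
  if (value_kind == "categorical" && is.null(levels))
    stop("categorical groups need a code-to-label table (levels)")
  records <- lapply(features, .encode_record, value_kind = value_kind)
  lens <- vapply(records, length, 0L)
  offsets <- c(0, cumsum(lens))[seq_along(lens)]
  index <- list(
    version = 1L,
    overlay = overlay$name,
    n_points = n_points,
    value_kind = value_kind,
    codec = "deflate",
    features = lapply(seq_along(features), function(i)
      list(name = nms[i], offset = offsets[i], length = lens[i],
           n = length(features[[i]]$indices)))
  )
  if (!is.null(levels)) index$levels <- as.list(as.character(levels))
  bin <- file.path(out_dir, paste0(name, ".bin"))
  con <- file(bin, "wb")
  for (r in records) writeBin(r, con)
  close(con)
  writeBin(charToRaw(paste0(canonical_json(index), "\n")),
           file.path(out_dir, paste0(name, ".index.json")))
  feature_group_spec(name = name, overlay_name = overlay$name,
                     path = paste0(name, ".bin"), feature_names = nms,
                     value_kind = value_kind)
}

#' Open a chunked feature group for lazy reads
#'
#' Loads only the JSON index; record bytes are fetched through the range
#' reader on demand, one feature at a time.
#'
#' @param index_path Path to `<name>.index.json`.
#' @param reader Optional `srt_range_reader` over the payload; defaults to a
#'   local-file reader over the sibling `<name>.bin`.
#' @return An object of class `srt_feature_group`.
#' @export
open_feature_group <- function(index_path, reader = NULL) {
  if (!file.exists(index_path)) stop("no such index: ", index_path)
  idx <- jsonlite::fromJSON(index_path, simplifyVector = FALSE)
  .need(idx, c("version", "overlay", "n_points", "value_kind", "codec", "features"),
        "feature group index")
  if (idx$codec != "deflate") stop("unsupported codec: ", idx$codec)
  feats <- do.call(rbind, lapply(idx$features, function(f)
    data.frame(name = f$name, offset = f$offset, length = f$length, n = f$n,
               stringsAsFactors = FALSE)))
  if (is.null(feats))
    feats <- data.frame(name = character(0), offset = numeric(0),
                        length = numeric(0), n = integer(0))
  if (is.null(reader))
    reader <- range_reader(sub("\\.index\\.json$", ".bin", index_path))
  structure(list(features = feats, n_points = idx$n_points,
                 overlay = idx$overlay, value_kind = idx$value_kind,
                 levels = if (is.null(idx$levels)) NULL else unlist(idx$levels),
                 reader = reader,
                 index_bytes = file.size(index_path)),
            class = "srt_feature_group")
}

#' @export
print.srt_feature_group <- function(x, ...) {
  cat("<feature group>", nrow(x$features), x$value_kind, "feature(s) over",
      x$n_points, "point(s) of overlay '", x$overlay, "'\n")
  invisible(x)
}

#' List the features of a group in index order
#'
#' @param group An open `srt_feature_group`.
#' @return Character vector of feature names, in the order they were
#'   written.
#' @export
list_features <- function(group) {
  group$features$name
}

#' Lazily read one feature as a dense vector
#'
#' Fetches exactly the named feature's byte range through the group's range
#' reader and densifies it (zeros filled for quantitative features, `NA`
#' for unlabeled categorical points). Categorical groups return a factor
#' via the stored code-to-label table.
#'
#' @param group An open `srt_feature_group`.
#' @param name Feature name.
#' @return Numeric vector (or factor) of length `n_points`.
#' @export
read_feature <- function(group, name) {
  i <- match(name, group$features$name)
  if (is.na(i)) {
    near <- utils::head(agrep(name, group$features$name,
                              max.distance = 0.3, value = TRUE), 5L)
    stop("no feature '", name, "' in group",
         if (length(near)) paste0("; near matches: ", paste(near, collapse = ", ")))
  }
  bytes <- group$reader$read(group$features$offset[i], group$features$length[i])
  rec <- .decode_record(bytes, group$value_kind)
  if (length(rec$indices) && max(rec$indices) > group$n_points)
    stop("corrupt record for '", name, "': index beyond n_points")
  if (group$value_kind == "categorical") {
    codes <- rep(NA_integer_, group$n_points)
    codes[rec$indices] <- as.integer(rec$values)
    factor(group$levels[codes], levels = group$levels)
  } else {
    out <- numeric(group$n_points)
    out[rec$indices] <- rec$values
    out
  }
}

#' Total bytes fetched while reading a feature group
#'
#' Sum of the index size (loaded once at open) and every payload byte that
#' has passed through the group's range reader — the quantity bounded by
#' the lazy-read contract.
#'
#' @param group An open `srt_feature_group`.
#' @return Number of bytes.
#' @export
group_bytes_fetched <- function(group) {
  group$index_bytes + group$reader$bytes_fetched()
}

# integrity scan used by validate_sample: ranges ascending, non-overlapping,
# inside the payload; every record decodes; indices within n_points
check_feature_group <- function(group, n_points = group$n_points) {
  f <- group$features
  if (nrow(f) == 0) return(invisible(TRUE))
  if (any(diff(f$offset) < 0)) stop("index offsets not ascending")
  ends <- f$offset + f$length
  if (any(f$offset[-1] < ends[-nrow(f)])) stop("overlapping byte ranges")
  if (ends[nrow(f)] > group$reader$size()) stop("byte range beyond payload size")
  if (!is.na(n_points) && !is.null(n_points) && n_points != group$n_points)
    stop("index n_points (", group$n_points, ") differs from overlay (", n_points, ")")
  for (i in seq_len(nrow(f))) {
    rec <- .decode_record(group$reader$read(f$offset[i], f$length[i]),
                          group$value_kind)
    if (length(rec$indices) != f$n[i])
      stop("record '", f$name[i], "': ", length(rec$indices),
           " entries, index says ", f$n[i])
    if (length(rec$indices) && max(rec$indices) > group$n_points)
      stop("record '", f$name[i], "' indexes beyond n_points")
  }
  invisible(TRUE)
}

#' Log-transform a count matrix
#'
#' Elementwise natural log of one plus the count, the standard
#' variance-stabilizing transform applied to spot-level gene counts before
#' they are written as quantitative features.
#'
#' @param counts Non-negative numeric matrix or vector.
#' @return `log(1 + counts)`, same shape.
#' @export
log_transform_counts <- function(counts) {
  if (anyNA(counts)) stop("counts contain NA")
  if (min(counts) < 0) stop("counts must be non-negative")
  log1p(counts)
}
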