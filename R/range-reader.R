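#' Byte-range readers with fetch accounting
#'
#' A range reader is the access contract behind every lazy store in this
#' package: it retrieves an arbitrary byte span of a resource and counts
#' every byte it fetches, so tests and users can verify that a tiled
#' pyramid or a chunked feature group really is read piecewise rather
#' than downloaded whole.
#'
#' `range_reader()` wraps a local file (seek + read). `http_range_reader()`
#' provides the same semantics over HTTP byte-range requests (requires the
#' `curl` package). `caching_range_reader()` decorates any reader with a
#' memoising cache keyed on `(offset, length)`: repeated identical reads
#' fetch zero new bytes.
#'
#' Byte offsets are 0-based, as in the underlying file formats.
#'
#' @param path Path to a local file.
#' @return An object of class `srt_range_reader`: a list with functions
#'   `read(offset, length)` returning a raw vector of exactly `length`
#'   bytes, `size()`, `bytes_fetched()`, and `close()`.
#' @examples
#' f <- tempfile()
#' writeBin(as.raw(0:255), f)
#' rr <- range_reader(f)
#' rr$read(10, 4)        # bytes 10..13
#' rr$bytes_fetched()    # 4
#' rr$close()
#' @export
range_reader <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  total <- 0L
  fsize <- file.size(path)
  obj <- list(
    read = function(offset, length) {
      stopifnot(offset >= 0, length >= 0)
      if (offset + length > fsize)
        stop("range [", offset, ", ", offset + length, ") out of bounds (file size ", fsize, ")")
      seek(con, where = offset, origin = "start")
      out <- readBin(con, "raw", n = length)
      if (length(out) != length) stop("short read at offset ", offset)
      total <<- total + length
      out
    },
    size = function() fsize,
    bytes_fetched = function() total,
    close = function() close(con)
  )
  class(obj) <- "srt_range_reader"
  obj
}

#' @rdname range_reader
#' @param reader A `srt_range_reader` to decorate.
#' @export
caching_range_reader <- function(reader) {
  cache <- new.env(parent = emptyenv())
  obj <- list(
    read = function(offset, length) {
      key <- paste0(offset, ":", length)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      out <- reader$read(offset, length)
      cache[[key]] <- out
      out
    },
    size = reader$size,
    bytes_fetched = reader$bytes_fetched,
    close = reader$close
  )
  class(obj) <- "srt_range_reader"
  obj
}

#' @rdname range_reader
#' @param url URL of a remote resource whose server honours HTTP `Range`
#'   headers.
#' @export
http_range_reader <- function(url) {
  if (!requireNamespace("curl", quietly = TRUE))
    stop("http_range_reader requires the 'curl' package")
  total <- 0L
  head <- curl::curl_fetch_memory(url, handle = curl::new_handle(nobody = TRUE))
  fsize <- suppressWarnings(as.numeric(
    curl::parse_headers_list(head$headers)[["content-length"]]))
  obj <- list(
    read = function(offset, length) {
      stopifnot(offset >= 0, length >= 0)
      h <- curl::new_handle(range = sprintf("%d-%d", offset, offset + length - 1))
      res <- curl::curl_fetch_memory(url, handle = h)
      if (!res$status_code %in% c(200L, 206L))
        stop("HTTP ", res$status_code, " fetching range at offset ", offset)
      out <- res$content
      if (length(out) != length) stop("short HTTP range read at offset ", offset)
      total <<- total + length
      out
    },
    size = function() fsize,
    bytes_fetched = function() total,
    close = function() invisible(NULL)
  )
  class(obj) <- "srt_range_reader"
  obj
}

#' @export
print.srt_range_reader <- function(x, ...) {
  cat("<range reader> size:", x$size(), "bytes; fetched:", x$bytes_fetched(), "bytes\n")
  invisible(x)
}
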