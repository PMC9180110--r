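#' Streamline set container and MRtrix TCK I/O
#'
#' A `streamline_set` holds polylines in world coordinates (mm) together
#' with per-streamline labels: the LGN side the streamline originates from
#' and whether it decussates at the chiasm (`crossing`) or stays ipsilateral
#' (`noncrossing`). Streamlines run LGN to orbit.
#'
#' @param points list of n x 3 numeric matrices (mm), each with >= 2 rows.
#' @param lgn_side character vector, `"left"` or `"right"` per streamline.
#' @param kind character vector, `"crossing"` or `"noncrossing"`.
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(points,
                           lgn_side = rep("left", length(points)),
                           kind = rep("noncrossing", length(points))) {
  if (!is.list(points)) stop("`points` must be a list of matrices")
  ok <- vapply(points, function(p) is.matrix(p) && ncol(p) == 3 &&
                 nrow(p) >= 2 && all(is.finite(p)), logical(1))
  if (!all(ok)) stop("each streamline needs >= 2 finite 3-D points")
  n <- length(points)
  lgn_side <- rep_len(as.character(lgn_side), n)
  kind <- rep_len(as.character(kind), n)
  if (!all(lgn_side %in% c("left", "right"))) stop("lgn_side must be left/right")
  if (!all(kind %in% c("crossing", "noncrossing")))
    stop("kind must be crossing/noncrossing")
  structure(list(points = points, lgn_side = lgn_side, kind = kind),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline_set: %d streamlines (%d crossing, %d noncrossing)\n",
              length(x$points), sum(x$kind == "crossing"),
              sum(x$kind == "noncrossing")))
  invisible(x)
}

#' Subset a streamline set by label
#' @param x a [streamline_set].
#' @param lgn_side,kind optional label filters.
#' @return a `streamline_set`.
#' @export
filter_streamlines <- function(x, lgn_side = NULL, kind = NULL) {
  keep <- rep(TRUE, length(x$points))
  if (!is.null(lgn_side)) keep <- keep & x$lgn_side %in% lgn_side
  if (!is.null(kind)) keep <- keep & x$kind %in% kind
  streamline_set(x$points[keep], x$lgn_side[keep], x$kind[keep])
}

#' Write streamlines to an MRtrix .tck file
#'
#' Float32 little-endian triplets; streamlines are delimited by NaN
#' triplets and the stream is terminated by an Inf triplet, per the MRtrix
#' track-file format. Labels are recorded as free-form header fields
#' (`opticpath_lgn_side`, `opticpath_kind`) so a round-trip preserves them.
#'
#' @param x a [streamline_set].
#' @param path output `.tck` file name.
#' @return `path`, invisibly.
#' @export
write_tck <- function(x, path) {
  stopifnot(inherits(x, "streamline_set"))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(x$points)),
           sprintf("opticpath_lgn_side: %s", paste(x$lgn_side, collapse = ",")),
           sprintf("opticpath_kind: %s", paste(x$kind, collapse = ",")))
  # 'file: . N' names the absolute byte offset of the binary data, which
  # depends on its own digit count: take the smallest self-consistent width.
  base <- sum(nchar(hdr, type = "bytes")) + length(hdr) +   # header lines + \n
    nchar("file: . ") + 1L + nchar("END") + 1L
  nd <- 1L
  while (nchar(as.character(base + nd)) > nd) nd <- nd + 1L
  offset <- base + nd
  hdr <- c(hdr, sprintf("file: . %d", offset), "END")
  txt <- paste0(paste(hdr, collapse = "\n"), "\n")
  if (nchar(txt, type = "bytes") != offset)
    stop("internal error: tck header offset miscomputed")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  for (p in x$points) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @return `read_tck` returns a [streamline_set]; label header fields are
#'   restored when present, otherwise labels default to left/noncrossing.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks")) stop("not an MRtrix tck file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unterminated tck header in ", path)
    if (identical(ln, "END")) break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
  }
  if (!identical(fields[["datatype"]], "Float32LE"))
    stop("unsupported tck datatype: ", fields[["datatype"]])
  offset <- as.integer(sub("^\\.\\s+", "", fields[["file"]]))
  close(con); on.exit(NULL)
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", offset)
  sz <- file.info(path)$size
  vals <- readBin(con, "numeric", (sz - offset) / 4L, size = 4L, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  endrow <- which(is.infinite(m[, 1]))[1]
  if (!is.na(endrow)) m <- m[seq_len(endrow - 1L), , drop = FALSE]
  breaks <- which(is.nan(m[, 1]))
  starts <- c(1L, head(breaks, -1L) + 1L)
  pts <- mapply(function(s, e) m[s:e, , drop = FALSE], starts, breaks - 1L,
                SIMPLIFY = FALSE)
  side <- if (!is.null(fields[["opticpath_lgn_side"]]))
    strsplit(fields[["opticpath_lgn_side"]], ",")[[1]] else "left"
  kind <- if (!is.null(fields[["opticpath_kind"]]))
    strsplit(fields[["opticpath_kind"]], ",")[[1]] else "noncrossing"
  streamline_set(pts, side, kind)
}
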