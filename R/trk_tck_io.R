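# Streamline file I/O: TrackVis TRK (binary, voxel-mm corner-origin storage)
# and MRtrix TCK (ASCII header + Float32LE triplets, world mm).
#
# Internal convention everywhere else in the package: world millimetres, RAS,
# 0-based voxel indices, voxel (i,j,k) maps to world via affine %*% (i,j,k,1).
# TRK stores vertices in voxel-mm with the origin at the *corner* of voxel
# (0,0,0); on load they are converted to world mm via
#   world = vox_to_ras %*% (stored / voxel_size - 0.5)
# and the inverse on write. TCK vertices are already world mm.

TRK_HDR_SIZE <- 1000L

pad_chars <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

raw_to_string <- function(r) {
  nul <- which(r == as.raw(0))
  if (length(nul)) r <- r[seq_len(min(nul) - 1)]
  rawToChar(r)
}

#' Read a tractogram from TRK or TCK
#'
#' Streamlines are returned in world millimetre RAS coordinates. TRK's
#' corner-origin voxel-mm storage convention is converted through the header's
#' voxel-to-world transform; TCK coordinates are passed through unchanged.
#' Per-streamline IDs and scalars written by [write_tractogram()] are
#' recovered (TRK track properties; TCK sidecar table).
#'
#' @param path file path (`.trk` or `.tck`).
#' @param dialect `"auto"` (sniff magic bytes, then extension), `"trk"` or
#'   `"tck"`.
#' @param space space label to attach; for TCK a `fiberfilter_space` header
#'   key written by this package takes precedence when `space = NULL`.
#' @return a [tractogram()]. A file with zero streamlines yields an empty
#'   tractogram with a warning.
#' @export
read_tractogram <- function(path, dialect = c("auto", "trk", "tck"), space = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "auto") {
    con <- file(path, "rb")
    magic <- readBin(con, "raw", n = 13)
    close(con)
    dialect <- if (length(magic) >= 13 && identical(magic, charToRaw("mrtrix tracks"))) {
      "tck"
    } else if (length(magic) >= 5 && identical(magic[1:5], charToRaw("TRACK"))) {
      "trk"
    } else if (grepl("\\.tck$", path, ignore.case = TRUE)) "tck"
    else if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk"
    else stopf("cannot determine streamline dialect of %s", path)
  }
  if (dialect == "trk") read_trk(path, space %||% "unknown") else read_tck(path, space)
}

#' Write a tractogram to TRK or TCK
#'
#' Round-trips through [read_tractogram()]: count, order, IDs and coordinates
#' (within float32 precision, < 1e-4 mm for brain-scale coordinates) are
#' preserved. An optional per-streamline scalar is stored as a TRK track
#' property where the dialect supports it, or in a TSV sidecar
#' (`<path>.sidecar.tsv`) for TCK.
#'
#' @param x a [tractogram()].
#' @param path output file path.
#' @param dialect `"trk"` or `"tck"` (default: from the file extension).
#' @param per_fiber_scalar optional numeric vector, one value per streamline;
#'   overrides `x$fiber_scalar`.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(x, path, dialect = c("auto", "trk", "tck"),
                             per_fiber_scalar = NULL) {
  stopifnot(inherits(x, "tractogram"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk"
    else if (grepl("\\.tck$", path, ignore.case = TRUE)) "tck"
    else stopf("cannot infer dialect from extension of %s; pass dialect=", path)
  }
  scal <- per_fiber_scalar %||% x$fiber_scalar
  if (!is.null(scal) && length(scal) != length(x$streamlines)) {
    stopf("per_fiber_scalar has length %d but the tractogram has %d streamlines",
          length(scal), length(x$streamlines))
  }
  if (dialect == "trk") write_trk(x, path, scal) else write_tck(x, path, scal)
  invisible(path)
}

read_trk <- function(path, space) {
  con <- file(path, "rb")
  on.exit(close(con))
  id_string <- readBin(con, "raw", n = 6)
  if (raw_to_string(id_string) != "TRACK") {
    stopf("malformed TRK header in %s: id_string is not 'TRACK'", path)
  }
  readBin(con, "integer", n = 3, size = 2, endian = "little")          # dim
  voxel_size <- readBin(con, "double", n = 3, size = 4, endian = "little")
  readBin(con, "double", n = 3, size = 4, endian = "little")           # origin
  n_scalars <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)                                          # scalar names
  n_properties <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  prop_raw <- readBin(con, "raw", n = 200)
  m <- matrix(readBin(con, "double", n = 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444 + 4 + 4)                                  # reserved, voxel_order, pad2
  readBin(con, "raw", n = 24 + 2 + 6)                                   # IOP, pad1, flags
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!identical(hdr_size, TRK_HDR_SIZE)) {
    stopf("malformed TRK header in %s: hdr_size is %s, expected 1000", path, hdr_size)
  }
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stopf("malformed TRK header in %s: non-positive voxel_size", path)
  }
  if (version < 2 || m[4, 4] == 0 || !all(is.finite(m))) {
    # pre-v2 files carry no transform; fall back to identity (voxel mm == world)
    m <- diag(4)
  }
  prop_names <- vapply(seq_len(max(n_properties, 0)), function(i) {
    raw_to_string(prop_raw[((i - 1) * 20 + 1):(i * 20)])
  }, character(1))

  streamlines <- list()
  props <- list()
  repeat {
    npts <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(npts) == 0) break
    if (npts < 0) stopf("malformed TRK track in %s: negative point count", path)
    vals <- readBin(con, "double", n = npts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (length(vals) < npts * (3 + n_scalars)) stopf("truncated TRK track data in %s", path)
    p <- if (n_properties > 0) {
      readBin(con, "double", n = n_properties, size = 4, endian = "little")
    } else numeric(0)
    pm <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pm, 2, voxel_size, "/") - 0.5
    streamlines[[length(streamlines) + 1]] <- apply_affine(m, vox)
    props[[length(props) + 1]] <- p
  }
  if (n_count > 0 && length(streamlines) != n_count) {
    warnf("TRK header of %s declares %d tracks but %d were read",
          path, n_count, length(streamlines))
  }
  if (length(streamlines) == 0) {
    warnf("TRK file %s contains zero streamlines", path)
    return(tractogram(list(), ids = integer(0), space = space))
  }
  ids <- seq_along(streamlines)
  fiber_scalar <- NULL
  if (n_properties > 0) {
    pm <- do.call(rbind, props)
    id_col <- which(prop_names == "fiber_id")
    if (length(id_col) == 1) ids <- as.integer(round(pm[, id_col]))
    sc_col <- which(prop_names == "scalar")
    if (length(sc_col) == 1) fiber_scalar <- pm[, sc_col]
  }
  tractogram(streamlines, ids = ids, space = space, fiber_scalar = fiber_scalar)
}

write_trk <- function(x, path, scal) {
  voxel_size <- c(1, 1, 1)     # identity voxel frame: voxel mm == world mm
  m <- diag(4)
  prop_names <- "fiber_id"
  if (!is.null(scal)) prop_names <- c(prop_names, "scalar")
  n_properties <- length(prop_names)

  con <- tryCatch(file(path, "wb"), error = function(e) {
    stopf("cannot open %s for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  writeBin(pad_chars("TRACK", 6), con)
  writeBin(as.integer(c(1, 1, 1)), con, size = 2, endian = "little")     # dim
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")     # origin
  writeBin(0L, con, size = 2, endian = "little")                         # n_scalars
  writeBin(raw(200), con)
  writeBin(as.integer(n_properties), con, size = 2, endian = "little")
  prop_raw <- raw(200)
  for (i in seq_along(prop_names)) {
    prop_raw[((i - 1) * 20 + 1):(i * 20)] <- pad_chars(prop_names[i], 20)
  }
  writeBin(prop_raw, con)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")           # vox_to_ras, row-major
  writeBin(raw(444), con)
  writeBin(pad_chars("RAS", 4), con)
  writeBin(raw(4), con)
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2 + 6), con)
  writeBin(as.integer(length(x$streamlines)), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                         # version
  writeBin(TRK_HDR_SIZE, con, size = 4, endian = "little")

  minv <- solve(m)
  for (i in seq_along(x$streamlines)) {
    s <- x$streamlines[[i]]
    vox <- apply_affine(minv, s)
    stored <- sweep(vox + 0.5, 2, voxel_size, "*")
    writeBin(as.integer(nrow(stored)), con, size = 4, endian = "little")
    writeBin(as.numeric(t(stored)), con, size = 4, endian = "little")
    p <- as.numeric(x$ids[i])
    if (!is.null(scal)) p <- c(p, as.numeric(scal[i]))
    writeBin(p, con, size = 4, endian = "little")
  }
}

read_tck <- function(path, space) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw_all == charToRaw("\n"))
  if (length(nl) == 0 || rawToChar(raw_all[1:(nl[1] - 1)]) != "mrtrix tracks") {
    stopf("malformed TCK header in %s: missing 'mrtrix tracks' magic line", path)
  }
  keys <- list()
  end_seen <- FALSE
  prev <- nl[1]
  for (k in nl[-1]) {
    line <- rawToChar(raw_all[(prev + 1):(k - 1)])
    prev <- k
    if (line == "END") { end_seen <- TRUE; break }
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2) keys[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (!end_seen) stopf("malformed TCK header in %s: no END line", path)
  dt <- keys[["datatype"]] %||% "Float32LE"
  if (!dt %in% c("Float32LE", "Float32BE")) {
    stopf("malformed TCK header in %s: unsupported datatype '%s'", path, dt)
  }
  endian <- if (dt == "Float32LE") "little" else "big"
  fo <- keys[["file"]]
  if (is.null(fo)) stopf("malformed TCK header in %s: missing 'file' field", path)
  offset <- as.numeric(sub("^\\.\\s+", "", fo))
  if (!is.finite(offset) || offset > length(raw_all)) {
    stopf("malformed TCK header in %s: bad file offset '%s'", path, fo)
  }
  n_float <- floor((length(raw_all) - offset) / 4)
  vals <- readBin(raw_all[(offset + 1):length(raw_all)], "double", n = n_float,
                  size = 4, endian = endian)
  vals <- vals[seq_len(3 * (length(vals) %/% 3))]
  pts <- matrix(vals, ncol = 3, byrow = TRUE)

  streamlines <- list()
  start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (!all(is.finite(pts[r, ]))) {
      if (r > start) {
        streamlines[[length(streamlines) + 1]] <- pts[start:(r - 1), , drop = FALSE]
      }
      start <- r + 1L
      if (all(is.infinite(pts[r, ]))) break
    }
  }
  if (length(streamlines) == 0) warnf("TCK file %s contains zero streamlines", path)
  ids <- seq_along(streamlines)
  fiber_scalar <- NULL
  sidecar <- paste0(path, ".sidecar.tsv")
  if (file.exists(sidecar)) {
    sc <- utils::read.delim(sidecar, sep = "\t")
    if (nrow(sc) == length(streamlines)) {
      ids <- as.integer(sc$fiber_id)
      if ("scalar" %in% names(sc)) fiber_scalar <- as.numeric(sc$scalar)
    }
  }
  space <- space %||% keys[["fiberfilter_space"]] %||% "unknown"
  tractogram(streamlines, ids = ids, space = space, fiber_scalar = fiber_scalar)
}

write_tck <- function(x, path, scal) {
  body_lines <- c(
    "mrtrix tracks",
    "datatype: Float32LE",
    sprintf("count: %d", length(x$streamlines)),
    sprintf("fiberfilter_space: %s", x$space)
  )
  # 'file: . <offset>' refers to the header's own byte length; fix the width
  # of the offset field so the value is self-consistent
  fmt_header <- function(off) {
    paste0(paste(c(body_lines, sprintf("file: . %d", off), "END"), collapse = "\n"), "\n")
  }
  off <- nchar(fmt_header(0), type = "bytes")
  while (nchar(fmt_header(off), type = "bytes") != off) {
    off <- nchar(fmt_header(off), type = "bytes")
  }
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stopf("cannot open %s for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  writeBin(charToRaw(fmt_header(off)), con)
  for (s in x$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")

  sidecar <- paste0(path, ".sidecar.tsv")
  if (!is.null(scal) || !identical(x$ids, seq_along(x$streamlines))) {
    df <- data.frame(fiber_id = x$ids)
    if (!is.null(scal)) df$scalar <- as.numeric(scal)
    utils::write.table(df, sidecar, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
}
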