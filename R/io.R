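# Streamline file I/O: TrackVis TRK, MRtrix TCK and a JSON-lines dialect.
# All coordinates are mm world space inside the package; TRK's voxel-scaled
# convention is converted at this boundary.

#' Read streamlines from TRK, TCK or JSON-lines
#'
#' Tracts with fewer than two distinct points are dropped (with a message
#' reporting the count); consecutive duplicate points are collapsed. An
#' optional minimum-length preprocessing filter removes short tracts at load
#' time, mirroring the common tractography practice of discarding spurious
#' short streamlines; it is off by default and the threshold is a free
#' parameter.
#'
#' @param path Path to the streamline file.
#' @param format One of `"auto"`, `"trk"`, `"tck"`, `"jsonl"`. `"auto"` picks
#'   by file extension.
#' @param min_length_mm Optional minimum tract length in mm; shorter tracts
#'   are dropped after loading.
#' @return A [tract_dataset()] in mm world coordinates with dense ids 0..N-1.
#' @export
read_tracts <- function(path, format = c("auto", "trk", "tck", "jsonl"),
                        min_length_mm = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") format <- guess_format(path)
  pts <- switch(format,
    trk = read_trk_points(path),
    tck = read_tck_points(path),
    jsonl = read_jsonl_points(path),
    stop("unknown streamline format '", format, "'")
  )
  pts <- lapply(pts, collapse_duplicate_points)
  ok <- vapply(pts, nrow, integer(1)) >= 2L
  if (any(!ok)) {
    message(sum(!ok), " tract(s) with fewer than 2 distinct points dropped")
    pts <- pts[ok]
  }
  if (length(pts) == 0L) stop("no valid tracts in '", path, "'")
  ds <- tract_dataset(pts, provenance = list(path = path, format = format))
  if (!is.null(min_length_mm)) {
    keep <- tract_lengths(ds) >= min_length_mm
    if (any(!keep))
      message(sum(!keep), " tract(s) below ", min_length_mm, " mm dropped")
    if (!any(keep)) stop("min_length_mm filter removed every tract")
    ds <- subset_tracts(ds, which(keep) - 1L)
  }
  message("loaded ", n_tracts(ds), " tracts from '", path, "' (", format, ")")
  ds
}

#' Write streamlines to TRK, TCK or JSON-lines
#'
#' Writing then reading a dataset reproduces its coordinates within float32
#' precision (TRK/TCK store single-precision floats; JSON-lines keeps full
#' double precision).
#'
#' @param dataset A [tract_dataset()].
#' @param path Output path.
#' @param format One of `"auto"`, `"trk"`, `"tck"`, `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(dataset, path, format = c("auto", "trk", "tck", "jsonl")) {
  stopifnot(inherits(dataset, "tract_dataset"))
  if (n_tracts(dataset) == 0L) stop("cannot write an empty dataset")
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    trk = write_trk_points(dataset$tracts, path),
    tck = write_tck_points(dataset$tracts, path),
    jsonl = write_jsonl_points(dataset$tracts, path),
    stop("unknown streamline format '", format, "'")
  )
  message("wrote ", n_tracts(dataset), " tracts to '", path, "' (", format, ")")
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = "trk", tck = "tck", jsonl = "jsonl", json = "jsonl",
    stop("cannot guess streamline format from extension '.", ext, "'")
  )
}

# ---- JSON-lines: one {"id":int,"points":[[x,y,z],...]} object per line -----

read_jsonl_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    p <- rec$points
    if (is.list(p)) p <- do.call(rbind, p)
    matrix(as.double(p), ncol = 3)
  })
}

write_jsonl_points <- function(tracts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(tracts)) {
    writeLines(jsonlite::toJSON(
      list(id = i - 1L, points = unname(tracts[[i]])),
      auto_unbox = TRUE, digits = NA), con)
  }
}

# ---- TrackVis TRK (binary, 1000-byte header, float32 voxel-mm coords) ------

read_trk_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6))
  if (!startsWith(id, "TRACK")) stop("'", path, "' is not a TRK file")
  readBin(con, "integer", 3, size = 2, endian = "little")      # dim
  voxel_size <- readBin(con, "double", 3, size = 4, endian = "little")
  readBin(con, "double", 3, size = 4, endian = "little")       # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)                                     # scalar names
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)                                     # property names
  M <- matrix(readBin(con, "double", 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)                # reserved etc.
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L) stop("unsupported TRK header size ", hdr_size)
  if (any(voxel_size <= 0)) voxel_size <- c(1, 1, 1)
  use_affine <- version >= 2 && M[4, 4] != 0 &&
    !isTRUE(all.equal(M, diag(4), check.attributes = FALSE))
  out <- list()
  repeat {
    n_pts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(n_pts) == 0L) break
    vals <- readBin(con, "double", n_pts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0)
      readBin(con, "double", n_props, size = 4, endian = "little")
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (use_affine) {
      vox <- sweep(m, 2, voxel_size, "/")        # voxel-mm -> voxel indices
      m <- t(M[1:3, 1:3] %*% t(vox) + M[1:3, 4]) # -> world mm
    }
    out[[length(out) + 1L]] <- m
  }
  if (n_count > 0 && length(out) != n_count)
    warning("TRK header announced ", n_count, " tracts, read ", length(out))
  out
}

write_trk_points <- function(tracts, path) {
  # World coordinates are stored directly: unit voxel size and identity
  # affine make voxel-mm and world frames coincide.
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(as.raw(0), con)
  bbox <- apply(do.call(rbind, tracts), 2, range)
  dim3 <- as.integer(pmax(1, ceiling(bbox[2, ] - pmin(0, bbox[1, ])) + 1))
  writeBin(dim3, con, size = 2, endian = "little")
  writeBin(c(1, 1, 1), con, size = 4, endian = "little")       # voxel_size
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(200), con)
  writeBin(as.double(t(diag(4))), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(c(charToRaw("LPS"), as.raw(0)), con)                # voxel_order
  writeBin(raw(4), con)
  writeBin(rep(0, 6), con, size = 4, endian = "little")
  writeBin(raw(2 + 6), con)
  writeBin(length(tracts), con, size = 4, endian = "little")   # n_count
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  for (t in tracts) {
    writeBin(nrow(t), con, size = 4, endian = "little")
    writeBin(as.double(t(t)), con, size = 4, endian = "little")
  }
}

# ---- MRtrix TCK (text header + float32 triples, NaN/Inf delimited) ---------

read_tck_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^mrtrix tracks", magic)) stop("'", path, "' is not a TCK file")
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("TCK header ended before END")
    if (trimws(line) == "END") break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.integer(sub("^\\.\\s*", "", val))
    if (key == "datatype") datatype <- val
  }
  if (is.na(offset)) stop("TCK header lacks a file offset")
  if (!datatype %in% c("Float32LE", "Float32BE"))
    stop("unsupported TCK datatype '", datatype, "'")
  endian <- if (datatype == "Float32LE") "little" else "big"
  seek(con, offset)
  raw_n <- file.size(path) - offset
  vals <- readBin(con, "double", raw_n / 4, size = 4, endian = endian)
  m <- matrix(vals[seq_len(3 * (length(vals) %/% 3))], ncol = 3, byrow = TRUE)
  out <- list()
  start <- 1L
  for (i in seq_len(nrow(m))) {
    if (all(is.nan(m[i, ])) || all(is.infinite(m[i, ]))) {
      if (i > start) out[[length(out) + 1L]] <- m[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
      if (all(is.infinite(m[i, ]))) break
    }
  }
  out
}

write_tck_points <- function(tracts, path) {
  header_for <- function(offset) paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", length(tracts), "\n",
    "file: . ", offset, "\nEND\n")
  offset <- nchar(header_for(0))
  offset <- nchar(header_for(offset))  # stabilise offset digits
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header_for(offset)), con)
  for (t in tracts) {
    writeBin(as.double(t(t)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}
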