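#' Read a 3D volume from disk
#'
#' Supported formats: multi-page TIFF stacks (`.tif`/`.tiff`), NRRD (`.nrrd`,
#' attached raw encoding), MetaImage (`.mha` attached, `.mhd` with detached
#' `.raw`), and raw binary with a JSON sidecar (`.raw` + `.json`). Voxel size
#' is taken from the format metadata (NRRD `spacings`, MetaImage
#' `ElementSpacing`, JSON sidecar) or, for TIFF stacks, must be supplied via
#' `voxel_size_um`; it is never silently assumed.
#'
#' TIFF pages map to increasing z; within a page, matrix rows map to x and
#' columns to y (the package's own writing convention, so read/write
#' round-trips are exact).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tiff"`, `"nrrd"`, `"mha"`, `"raw"`;
#'   `"auto"` infers from the extension.
#' @param voxel_size_um voxel edge length in micrometres; required for TIFF,
#'   overrides metadata elsewhere if given.
#' @return A [volume3d].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nrrd", "mha", "raw"),
                        voxel_size_um = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    tiff = read_tiff_stack(path, voxel_size_um),
    nrrd = read_nrrd(path, voxel_size_um),
    mha  = read_mha(path, voxel_size_um),
    raw  = read_raw_json(path, voxel_size_um)
  )
}

#' Write a 3D volume to disk
#'
#' Round-trips through [read_volume()] are bit-exact for NRRD, MetaImage and
#' raw+JSON (IEEE doubles) and for TIFF stacks holding integer data in
#' 0..65535 (written as 16-bit). Non-integer TIFF data are written as 32-bit
#' float, which quantizes doubles to single precision.
#'
#' @param vol a [volume3d].
#' @param path output path; the format is inferred from the extension unless
#'   `format` is given.
#' @param format one of `"auto"`, `"tiff"`, `"nrrd"`, `"mha"`, `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         format = c("auto", "tiff", "nrrd", "mha", "raw")) {
  stopifnot(inherits(vol, "volume3d"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    tiff = write_tiff_stack(vol, path),
    nrrd = write_nrrd(vol, path),
    mha  = write_mha(vol, path),
    raw  = write_raw_json(vol, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    tif = , tiff = "tiff",
    nrrd = "nrrd",
    mha = , mhd = "mha",
    raw = "raw",
    stop("cannot infer volume format from extension: .", ext)
  )
}

# --- TIFF stacks -------------------------------------------------------------

read_tiff_stack <- function(path, voxel_size_um) {
  if (is.null(voxel_size_um))
    stop("TIFF carries no voxel size; pass `voxel_size_um` explicitly")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  ref <- shapes[, 1]
  bad <- which(shapes[1, ] != ref[1] | shapes[2, ] != ref[2])
  if (length(bad))
    stop(sprintf("slice %d has shape %dx%d, expected %dx%d",
                 bad[1], shapes[1, bad[1]], shapes[2, bad[1]], ref[1], ref[2]))
  data <- array(0, c(ref[1], ref[2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    data[, , k] <- p
  }
  volume3d(data, voxel_size_um)
}

write_tiff_stack <- function(vol, path) {
  d <- vol$data
  is_int <- all(d == round(d)) && min(d) >= 0 && max(d) <= 65535
  pages <- lapply(seq_len(dim(d)[3]), function(k) {
    m <- d[, , k, drop = TRUE]
    dim(m) <- dim(d)[1:2]
    if (is_int) m / 65535 else m
  })
  if (is_int) {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
}

# --- NRRD (attached, raw little-endian) -------------------------------------

write_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(vol$data)[1], dim(vol$data)[2], dim(vol$data)[3]),
    sprintf("spacings: %.17g %.17g %.17g", vol$voxel_size, vol$voxel_size, vol$voxel_size),
    sprintf("axis mins: %.17g %.17g %.17g", vol$origin[1], vol$origin[2], vol$origin[3]),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
}

read_nrrd <- function(path, voxel_size_um = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (startsWith(line, "#")) next
    kv <- strsplit(line, ": ?", perl = TRUE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1]])
  if (length(sizes) != 3) stop("only 3-dimensional NRRD volumes are supported")
  if (!identical(fields$encoding, "raw"))
    stop("only raw-encoded NRRD is supported, got: ", fields$encoding)
  spac <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, " +")[[1]]) else NULL
  vs <- voxel_size_um
  if (is.null(vs)) {
    if (is.null(spac)) stop("NRRD has no `spacings` and no `voxel_size_um` given")
    if (diff(range(spac)) > 1e-9 * max(spac))
      stop("anisotropic NRRD spacings are not supported")
    vs <- spac[1]
  }
  origin <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], " +")[[1]]) else c(0, 0, 0)
  n <- prod(sizes)
  type <- fields$type
  data <- switch(type,
    double = readBin(con, "numeric", n, size = 8, endian = "little"),
    float  = readBin(con, "numeric", n, size = 4, endian = "little"),
    int    = , `signed int` = , int32 = , `int32_t` =
      readBin(con, "integer", n, size = 4, endian = "little"),
    short  = , int16 = , `int16_t` =
      readBin(con, "integer", n, size = 2, endian = "little"),
    uchar  = , `unsigned char` = , uint8 = , `uint8_t` =
      as.integer(readBin(con, "integer", n, size = 1, signed = FALSE)),
    stop("unsupported NRRD type: ", type)
  )
  if (length(data) != n) stop("NRRD data truncated: ", path)
  volume3d(array(data, sizes), vs, origin)
}

# --- MetaImage ---------------------------------------------------------------

write_mha <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", dim(vol$data)[1], dim(vol$data)[2], dim(vol$data)[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            vol$voxel_size, vol$voxel_size, vol$voxel_size),
    sprintf("Offset = %.17g %.17g %.17g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL"
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
}

read_mha <- function(path, voxel_size_um = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("no ElementDataFile entry in ", path)
    kv <- strsplit(line, " *= *")[[1]]
    fields[[kv[1]]] <- paste(kv[-1], collapse = " = ")
    if (kv[1] == "ElementDataFile") break
  }
  sizes <- as.integer(strsplit(fields$DimSize, " +")[[1]])
  spac <- as.numeric(strsplit(fields$ElementSpacing, " +")[[1]])
  vs <- if (!is.null(voxel_size_um)) voxel_size_um else {
    if (is.null(spac)) stop("MetaImage has no ElementSpacing")
    spac[1]
  }
  origin <- if (!is.null(fields$Offset))
    as.numeric(strsplit(fields$Offset, " +")[[1]]) else c(0, 0, 0)
  n <- prod(sizes)
  read_elems <- function(con) switch(fields$ElementType,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_SHORT  = readBin(con, "integer", n, size = 2, endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_UCHAR  = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE)),
    stop("unsupported ElementType: ", fields$ElementType)
  )
  if (identical(fields$ElementDataFile, "LOCAL")) {
    data <- read_elems(con)
  } else {
    rawpath <- file.path(dirname(path), fields$ElementDataFile)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    data <- read_elems(con2)
  }
  if (length(data) != n) stop("MetaImage data truncated: ", path)
  volume3d(array(data, sizes), vs, origin)
}

# --- raw + JSON sidecar ------------------------------------------------------

write_raw_json <- function(vol, path) {
  sidecar <- paste0(sub("\\.raw$", "", path), ".json")
  meta <- list(shape = dim(vol$data), voxel_size_um = vol$voxel_size,
               origin_um = vol$origin, dtype = "float64", endian = "little")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
}

read_raw_json <- function(path, voxel_size_um = NULL) {
  sidecar <- paste0(sub("\\.raw$", "", path), ".json")
  if (!file.exists(sidecar))
    stop("raw volume needs a JSON sidecar at ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vs <- if (!is.null(voxel_size_um)) voxel_size_um else meta$voxel_size_um
  if (is.null(vs)) stop("no voxel size in sidecar and none given")
  sizes <- as.integer(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  data <- readBin(con, "numeric", prod(sizes), size = 8, endian = "little")
  if (length(data) != prod(sizes)) stop("raw data truncated: ", path)
  origin <- if (!is.null(meta$origin_um)) as.numeric(meta$origin_um) else c(0, 0, 0)
  volume3d(array(data, sizes), vs, origin)
}
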