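# GeoTIFF I/O.
#
# Rasters are stored as uncompressed, band-sequential (PlanarConfiguration 2)
# GeoTIFFs with 64-bit IEEE floating point samples, one strip per band.
# Georeferencing uses ModelPixelScale + ModelTiepoint; the CRS is encoded as a
# ProjectedCSType EPSG geokey where available. Band names, CRS id and the
# nodata sentinel are carried in an ImageDescription JSON tag (nodata also in
# the conventional GDAL_NODATA tag 42113), so a write/read round trip is exact
# to the bit for every finite value and preserves NA cells.

.tif_types <- list(
  # type id -> list(size bytes, reader what, signed)
  "1" = list(size = 1L, what = "integer", signed = FALSE),  # BYTE
  "2" = list(size = 1L, what = "character"),                # ASCII
  "3" = list(size = 2L, what = "integer", signed = FALSE),  # SHORT
  "4" = list(size = 4L, what = "integer", signed = FALSE),  # LONG
  "11" = list(size = 4L, what = "double"),                  # FLOAT
  "12" = list(size = 8L, what = "double")                   # DOUBLE
)

.epsg_code <- function(crs_id) {
  m <- regmatches(crs_id, regexpr("[0-9]+$", crs_id))
  if (length(m) == 1L && grepl("^EPSG:", toupper(crs_id)))
    as.integer(m) else NA_integer_
}

#' Write a multiband raster to GeoTIFF
#'
#' Writes an uncompressed float64 GeoTIFF. `NA` cells are written as the
#' grid's nodata sentinel; band names and the CRS identifier travel in the
#' file's metadata tags so that [read_raster()] reproduces the input exactly.
#'
#' @param raster A [ts_raster()].
#' @param path Output file path (conventionally `.tif`).
#' @return Invisibly, `path`.
#' @export
write_raster <- function(raster, path) {
  if (!inherits(raster, "ts_raster")) stop("raster must be a ts_raster")
  g <- raster$grid
  nb <- length(raster$bands)
  if (nb < 1L) stop("raster has no bands")
  for (b in raster$bands)
    if (nrow(b) != g$n_rows || ncol(b) != g$n_cols)
      stop("band dimensions do not match the grid")

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  # header
  writeBin(charToRaw("II"), con); w16(42L)
  strip_bytes <- g$n_rows * g$n_cols * 8
  data_off <- 8
  strip_offs <- data_off + (seq_len(nb) - 1L) * strip_bytes
  w32(NA)  # placeholder for IFD offset, patched below
  seek(con, data_off)
  for (b in raster$bands) {
    v <- t(b)                      # TIFF is row-major
    v[is.na(v)] <- g$nodata
    writeBin(as.vector(v), con, size = 8, endian = "little")
  }

  desc <- jsonlite::toJSON(list(band_names = names(raster$bands),
                                crs_id = g$crs_id, nodata = g$nodata),
                           auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  nod_raw <- c(charToRaw(format(g$nodata, scientific = FALSE)), as.raw(0L))
  epsg <- .epsg_code(g$crs_id)
  geokeys <- c(1L, 1L, 0L, 2L,                  # version header, 2 keys
               1024L, 0L, 1L, 1L,               # model type: projected
               1025L, 0L, 1L, 1L)               # raster type: pixel-is-area
  if (!is.na(epsg)) {
    geokeys[4] <- 3L
    geokeys <- c(geokeys, 3072L, 0L, 1L, epsg)  # projected CS EPSG code
  }

  # out-of-line tag payloads live after the pixel data
  aux_off <- data_off + nb * strip_bytes
  pos <- aux_off
  place <- function(nbytes) {
    off <- pos
    pos <<- pos + nbytes + (nbytes %% 2)        # keep offsets word-aligned
    off
  }
  off_bps  <- if (nb > 2) place(2L * nb) else NA
  off_sf   <- if (nb > 2) place(2L * nb) else NA
  off_so   <- if (nb > 1) place(4L * nb) else NA
  off_sbc  <- if (nb > 1) place(4L * nb) else NA
  off_desc <- if (length(desc_raw) > 4) place(length(desc_raw)) else NA
  off_scale <- place(8L * 3L)
  off_tie   <- place(8L * 6L)
  off_geo   <- place(2L * length(geokeys))
  off_nod  <- if (length(nod_raw) > 4) place(length(nod_raw)) else NA
  ifd_off <- pos

  seek(con, aux_off)
  pad <- function(raw_len) if (raw_len %% 2) writeBin(as.raw(0L), con)
  if (nb > 2) { w16(rep(64L, nb)); w16(rep(3L, nb)) }
  if (nb > 1) { w32(strip_offs); w32(rep(strip_bytes, nb)) }
  if (!is.na(off_desc)) { writeBin(desc_raw, con); pad(length(desc_raw)) }
  writeBin(c(g$cell_size, g$cell_size, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, g$origin_x, g$origin_y, 0), con, size = 8,
           endian = "little")
  w16(geokeys)
  if (!is.na(off_nod)) { writeBin(nod_raw, con); pad(length(nod_raw)) }

  # IFD
  entry <- function(tag, type, count, value, offset = NA) {
    w16(tag); w16(type); w32(count)
    if (!is.na(offset)) { w32(offset); return(invisible()) }
    if (type == 3L) {                       # SHORT values inline, padded
      w16(value); if (count == 1L) w16(0L)
    } else if (type == 2L) {                # short ASCII inline
      r <- c(value, rep(as.raw(0L), 4L - length(value)))
      writeBin(r[1:4], con)
    } else w32(value)
  }
  seek(con, ifd_off)
  tags <- list(
    list(256L, 4L, 1L, g$n_cols),
    list(257L, 4L, 1L, g$n_rows),
    if (nb > 2) list(258L, 3L, nb, NA, off_bps) else list(258L, 3L, nb, rep(64L, nb)),
    list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 1L),
    if (!is.na(off_desc)) list(270L, 2L, length(desc_raw), NA, off_desc)
      else list(270L, 2L, length(desc_raw), desc_raw),
    if (nb > 1) list(273L, 4L, nb, NA, off_so) else list(273L, 4L, 1L, strip_offs),
    list(277L, 3L, 1L, nb),
    list(278L, 4L, 1L, g$n_rows),
    if (nb > 1) list(279L, 4L, nb, NA, off_sbc) else list(279L, 4L, 1L, strip_bytes),
    list(284L, 3L, 1L, 2L),
    if (nb > 2) list(339L, 3L, nb, NA, off_sf) else list(339L, 3L, nb, rep(3L, nb)),
    list(33550L, 12L, 3L, NA, off_scale),
    list(33922L, 12L, 6L, NA, off_tie),
    list(34735L, 3L, length(geokeys), NA, off_geo),
    if (!is.na(off_nod)) list(42113L, 2L, length(nod_raw), NA, off_nod)
      else list(42113L, 2L, length(nod_raw), nod_raw)
  )
  w16(length(tags))
  for (tg in tags) do.call(entry, tg)
  w32(0L)  # no next IFD

  seek(con, 4); w32(ifd_off)  # patch header pointer
  invisible(path)
}

.read_ifd_value <- function(con, type, count, raw4, endian) {
  tt <- .tif_types[[as.character(type)]]
  if (is.null(tt)) return(NULL)
  nbytes <- tt$size * count
  if (nbytes > 4) {
    off <- readBin(raw4, "integer", size = 4, endian = endian)
    seek(con, off)
    raw <- readBin(con, "raw", nbytes)
  } else raw <- raw4[seq_len(nbytes)]
  if (type == 2L) {
    s <- rawToChar(raw[raw != as.raw(0L)])
    return(s)
  }
  readBin(raw, tt$what, n = count, size = tt$size, endian = endian,
          signed = if (tt$size < 4 && tt$what == "integer") FALSE else TRUE)
}

#' Read a multiband raster from GeoTIFF
#'
#' Reads uncompressed striped GeoTIFFs with integer or IEEE floating point
#' samples (the format [write_raster()] produces, plus common single-band
#' variants). Cells equal to the nodata sentinel become `NA`. A file without
#' any CRS information is read with a warning and `crs_id = "unknown"`.
#'
#' @param path File path.
#' @return A [ts_raster()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 2))
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  if (readBin(con, "integer", size = 2, endian = endian) != 42L)
    stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", size = 4, endian = endian)
  seek(con, ifd_off)
  n_tags <- readBin(con, "integer", size = 2, endian = endian, signed = FALSE)
  tags <- vector("list", n_tags)
  ids <- integer(n_tags)
  entries <- lapply(seq_len(n_tags), function(i) {
    tag <- readBin(con, "integer", size = 2, endian = endian, signed = FALSE)
    type <- readBin(con, "integer", size = 2, endian = endian, signed = FALSE)
    count <- readBin(con, "integer", size = 4, endian = endian)
    raw4 <- readBin(con, "raw", 4)
    list(tag = tag, type = type, count = count, raw4 = raw4)
  })
  for (e in entries) {
    v <- .read_ifd_value(con, e$type, e$count, e$raw4, endian)
    tags[[as.character(e$tag)]] <- v
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("unsupported TIFF: missing tag ", tag)
    v
  }
  n_cols <- need(256L); n_rows <- need(257L)
  bps <- need(258L)
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
  if (comp != 1L) stop("unsupported TIFF: compressed data")
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
  planar <- if (is.null(tags[["284"]])) 1L else tags[["284"]]
  sfmt <- if (is.null(tags[["339"]])) rep(1L, spp) else tags[["339"]]
  strip_offs <- need(273L)
  strip_cnts <- need(279L)
  if (length(unique(bps)) > 1L) stop("unsupported TIFF: mixed bit depths")
  bits <- bps[1]; fmt <- sfmt[1]

  raw <- unlist(lapply(seq_along(strip_offs), function(i) {
    seek(con, strip_offs[i])
    readBin(con, "raw", strip_cnts[i])
  }))
  size <- bits %/% 8L
  n_vals <- length(raw) %/% size
  vals <- if (fmt == 3L) {
    readBin(raw, "double", n = n_vals, size = size, endian = endian)
  } else {
    readBin(raw, "integer", n = n_vals, size = size, endian = endian,
            signed = fmt == 2L || size == 4L)
  }
  if (n_vals < n_rows * n_cols * spp) stop("truncated TIFF data")

  if (planar == 2L || spp == 1L) {
    bands <- lapply(seq_len(spp), function(i) {
      seg <- vals[((i - 1) * n_rows * n_cols + 1):(i * n_rows * n_cols)]
      matrix(seg, n_rows, n_cols, byrow = TRUE)
    })
  } else {  # chunky: samples interleaved per pixel
    bands <- lapply(seq_len(spp), function(i) {
      seg <- vals[seq(i, n_rows * n_cols * spp, by = spp)]
      matrix(seg, n_rows, n_cols, byrow = TRUE)
    })
  }

  meta <- NULL
  if (!is.null(tags[["270"]]))
    meta <- tryCatch(jsonlite::fromJSON(tags[["270"]]), error = function(e) NULL)
  nodata <- if (!is.null(meta$nodata)) meta$nodata else
    if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else NA
  crs_id <- if (!is.null(meta$crs_id)) meta$crs_id else {
    geo <- tags[["34735"]]
    code <- NA_integer_
    if (!is.null(geo) && length(geo) >= 4) {
      nk <- geo[4]
      for (k in seq_len(nk)) {
        key <- geo[4 * k + 1:4]
        if (key[1] == 3072L) code <- key[4]
      }
    }
    if (!is.na(code)) paste0("EPSG:", code) else NA_character_
  }
  if (is.na(crs_id)) {
    warning("raster has no CRS information; grid kept with crs_id 'unknown'")
    crs_id <- "unknown"
  }
  scale <- tags[["33550"]]; tie <- tags[["33922"]]
  if (is.null(scale) || is.null(tie)) {
    warning("raster has no georeferencing tags; using unit grid at (0, 0)")
    scale <- c(1, 1, 0); tie <- c(0, 0, 0, 0, as.numeric(n_rows), 0)
  }
  grid <- ts_grid(origin_x = tie[4] - tie[1] * scale[1],
                  origin_y = tie[5] + tie[2] * scale[2],
                  cell_size = scale[1], n_rows = n_rows, n_cols = n_cols,
                  crs_id = crs_id,
                  nodata = if (is.na(nodata)) -9999 else nodata)
  if (!is.na(nodata))
    bands <- lapply(bands, function(b) { b[b == nodata] <- NA; b })
  nm <- if (!is.null(meta$band_names) && length(meta$band_names) == spp)
    meta$band_names else paste0("band_", seq_len(spp))
  names(bands) <- nm
  ts_raster(grid, bands)
}
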