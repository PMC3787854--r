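#' Read a hyperspectral cube from disk
#'
#' Supported formats: multi-page TIFF (one page per band, ascending
#' wavelength), ENVI BSQ/BIL binary with a companion `.hdr` text header, and
#' RDS (R's lossless serialization, used for bit-identical round-trips).
#'
#' TIFF rarely carries wavelength metadata. A sidecar JSON written by
#' [write_cube()] is used when present; otherwise `wavelengths` must be given
#' or an evenly spaced default grid spanning 390-680 nm is assumed and the
#' assumption recorded in `meta$wavelengths_assumed`. ENVI headers carry a
#' `wavelength` field which is honoured when present.
#'
#' @param path Path to the cube file.
#' @param format One of `"auto"`, `"tiff"`, `"envi"`, `"rds"`. `"auto"`
#'   dispatches on the file extension.
#' @param wavelengths Optional numeric vector overriding/supplying band
#'   wavelengths (nm).
#' @return An [hsi_cube].
#' @export
read_cube <- function(path, format = c("auto", "tiff", "envi", "rds"),
                      wavelengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    rds  = read_cube_rds(path, wavelengths),
    tiff = read_cube_tiff(path, wavelengths),
    envi = read_cube_envi(path, wavelengths))
}

#' Write a hyperspectral cube to disk
#'
#' RDS and ENVI (64-bit float) round-trip values exactly; TIFF pages are
#' stored as 32-bit integers scaled to the cube maximum (relative
#' quantization error below 2^-32), with wavelengths and metadata in a
#' sidecar `<path>.json`.
#'
#' @param cube An [hsi_cube].
#' @param path Output path.
#' @param format One of `"auto"`, `"tiff"`, `"envi"`, `"rds"`.
#' @param interleave ENVI only: `"bsq"` (band-sequential) or `"bil"`
#'   (band-interleaved-by-line).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "tiff", "envi", "rds"),
                       interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hsi_cube"))
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    rds  = saveRDS(cube, path),
    tiff = write_cube_tiff(cube, path),
    envi = write_cube_envi(cube, path, interleave))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    rds = "rds",
    bsq = , bil = , envi = , raw = , dat = "envi",
    stop("cannot guess cube format from extension '.", ext,
         "'; pass `format` explicitly", call. = FALSE))
}

default_grid <- function(n_bands) {
  if (n_bands == 1L) 390 else seq(390, 680, length.out = n_bands)
}

resolve_wavelengths <- function(n_bands, wavelengths, meta) {
  if (is.null(wavelengths)) {
    wavelengths <- default_grid(n_bands)
    meta$wavelengths_assumed <- "even grid 390-680 nm (no metadata found)"
  } else if (length(wavelengths) != n_bands) {
    stop("band count (", n_bands, ") does not match wavelength count (",
         length(wavelengths), ")", call. = FALSE)
  }
  list(wavelengths = wavelengths, meta = meta)
}

read_cube_rds <- function(path, wavelengths) {
  cube <- readRDS(path)
  if (!inherits(cube, "hsi_cube"))
    stop("RDS file does not contain an hsi_cube: ", path, call. = FALSE)
  if (!is.null(wavelengths))
    cube <- hsi_cube(cube$values, wavelengths, cube$meta)
  cube
}

write_cube_tiff <- function(cube, path) {
  scale <- max(cube$values)
  if (scale == 0) scale <- 1
  d <- dim(cube$values)
  pages <- lapply(seq_len(d[3L]),
                  function(b) cube$values[, , b, drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(wavelengths = cube$wavelengths, scale = scale,
                  meta = cube$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_cube_tiff <- function(path, wavelengths) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("multi-page TIFF has pages of differing dimensions", call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1L))))
    stop("cube TIFF pages must be single-channel (grayscale)", call. = FALSE)
  meta <- list(source = path)
  scale <- 1
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    scale <- sc$scale %||% 1
    if (is.null(wavelengths)) wavelengths <- sc$wavelengths
    if (!is.null(sc$meta) && length(sc$meta)) meta <- utils::modifyList(meta, as.list(sc$meta))
  }
  vals <- array(unlist(pages, use.names = FALSE),
                c(dims[1L, 1L], dims[2L, 1L], length(pages))) * scale
  rw <- resolve_wavelengths(length(pages), wavelengths, meta)
  hsi_cube(vals, rw$wavelengths, rw$meta)
}

# --- ENVI binary + .hdr (data type 5 = 64-bit float, byte order 0) ---------

write_cube_envi <- function(cube, path, interleave = "bsq") {
  d <- dim(cube$values)
  # ENVI stores sample (column) fastest within a line
  if (interleave == "bsq") {
    v <- as.vector(aperm(cube$values, c(2L, 1L, 3L)))   # sample, line, band
  } else {
    v <- as.vector(aperm(cube$values, c(2L, 3L, 1L)))   # sample, band, line
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 8L, endian = "little")
  hdr <- c("ENVI",
           "description = {hybridhsi hyperspectral cube}",
           paste0("samples = ", d[2L]),
           paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength units = Nanometers"),
           paste0("wavelength = {",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # brace-delimited values may span lines; [^}]* matches across newlines
  pat <- gregexpr("(?m)^\\s*([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)
  m <- regmatches(txt, pat)[[1L]]
  for (line in m) {
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    val <- gsub("[{}]", "", val)
    fields[[key]] <- trimws(val)
  }
  fields
}

read_cube_envi <- function(path, wavelengths) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    alt <- paste0(tools::file_path_sans_ext(path), ".hdr")
    if (file.exists(alt)) hdr_path <- alt
    else stop("companion ENVI header not found for ", path, call. = FALSE)
  }
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h$interleave)
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1")
    "big" else "little"
  sz <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
               stop("unsupported ENVI data type ", dtype,
                    " (only 4 = float32, 5 = float64)", call. = FALSE))
  n <- samples * lines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n, size = sz, endian = endian)
  if (length(v) != n)
    stop("ENVI file truncated: expected ", n, " values, read ", length(v),
         call. = FALSE)
  vals <- switch(interleave,
    bsq = aperm(array(v, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3L, 1L, 2L)),
    stop("unsupported ENVI interleave '", interleave, "'", call. = FALSE))
  meta <- list(source = path)
  if (is.null(wavelengths) && !is.null(h$wavelength))
    wavelengths <- as.numeric(strsplit(h$wavelength, ",")[[1L]])
  rw <- resolve_wavelengths(bands, wavelengths, meta)
  hsi_cube(vals, rw$wavelengths, rw$meta)
}

# --- masks and label maps ---------------------------------------------------

#' Read a binary mask from a single-band PNG or TIFF
#'
#' Any nonzero pixel value is treated as 1. Multi-channel (RGB) images are
#' rejected: masks must be single-band.
#'
#' @param path PNG or TIFF file.
#' @param role `"reference"` (ground truth, the default) or `"decision"`.
#' @return A [binary_mask].
#' @export
read_mask <- function(path, role = c("reference", "decision")) {
  role <- match.arg(role)
  img <- read_single_band(path)
  binary_mask((img > 0) * 1L, role = role)
}

#' Write a binary mask as a single-band PNG or TIFF
#'
#' @param mask A [binary_mask].
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_single_band(mask$values * 1.0, path)
  invisible(path)
}

#' Write a label image as 16-bit TIFF with a JSON legend sidecar
#'
#' Labels (0..n_classes, 0 = unclassified) are stored exactly in a 16-bit
#' single-band TIFF; `n_classes` and the legend go to `<path>.json`.
#'
#' @param li A [label_image].
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(li, path) {
  stopifnot(inherits(li, "label_image"))
  if (max(li$labels) > 65535L)
    stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(li$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(n_classes = li$n_classes,
         legend = if (is.null(li$legend)) NULL else as.list(li$legend)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label image written by [write_label_image()]
#'
#' @param path TIFF path; the `<path>.json` sidecar supplies `n_classes` and
#'   the legend when present.
#' @return A [label_image].
#' @export
read_label_image <- function(path) {
  img <- read_single_band(path)
  labels <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  n_classes <- NULL; legend <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n_classes <- sc$n_classes
    if (!is.null(sc$legend) && length(sc$legend))
      legend <- unlist(sc$legend)
  }
  label_image(labels, n_classes = n_classes, legend = legend)
}

read_single_band <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (is.list(pages)) {
        if (length(pages) > 1L)
          stop("expected a single-band image, got ", length(pages),
               " pages: ", path, call. = FALSE)
        pages[[1L]]
      } else pages
    },
    stop("unsupported image extension '.", ext, "'", call. = FALSE))
  if (length(dim(img)) > 2L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop("expected a single-band image, got ", dim(img)[3L],
              " channels: ", path, call. = FALSE)
  }
  img
}

write_single_band <- function(values, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(values, path),
    tif = , tiff = tiff::writeTIFF(values, path, bits.per.sample = 8L,
                                   compression = "none"),
    stop("unsupported image extension '.", ext, "'", call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
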