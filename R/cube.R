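#' Construct a hyperspectral image cube
#'
#' A hyperspectral cube is a co-registered stack of narrow-band images of one
#' scene: a `rows x cols x bands` array of non-negative reflectance values
#' (arbitrary camera units) together with one wavelength per band. Each pixel
#' `(r, c)` is a length-`bands` reflectance spectrum.
#'
#' @param values Numeric 3-d array `rows x cols x bands`. All values must be
#'   finite and non-negative.
#' @param wavelengths Numeric vector of band-centre wavelengths in nanometres,
#'   strictly increasing, one per band.
#' @param meta Named list of free-form acquisition metadata (source id, crop
#'   offsets, ...).
#' @return An object of class `hsi_cube` with elements `values`,
#'   `wavelengths`, `meta`.
#' @examples
#' cube <- hsi_cube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(450, 550, 650))
#' dim(cube$values)
#' @export
hsi_cube <- function(values, wavelengths, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a rows x cols x bands array", call. = FALSE)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    stop("number of wavelengths (", length(wavelengths),
         ") must equal the band dimension (", dim(values)[3L], ")",
         call. = FALSE)
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(values)))
    stop("cube values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("cube values must be non-negative", call. = FALSE)
  structure(list(values = values, wavelengths = wavelengths,
                 meta = as.list(meta)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

n_bands <- function(cube) dim(cube$values)[3L]

#' Crop a hyperspectral cube
#'
#' All bands are cropped identically; the crop offsets are recorded in
#' `meta$crop_offset` so pixel coordinates can be mapped back to the source
#' frame. Ranges are 1-based and inclusive, following R matrix indexing.
#'
#' @param cube An [hsi_cube].
#' @param rows,cols Integer vectors `c(first, last)` of 1-based inclusive
#'   row/column bounds. `NULL` keeps the full extent.
#' @return The cropped [hsi_cube].
#' @examples
#' cube <- hsi_cube(array(1, c(10, 10, 3)), c(500, 600, 700))
#' dim(crop_cube(cube, rows = c(3, 5), cols = c(1, 4))$values)  # 3 x 4 x 3
#' @export
crop_cube <- function(cube, rows = NULL, cols = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$values)
  rows <- if (is.null(rows)) c(1L, d[1L]) else as.integer(rows)
  cols <- if (is.null(cols)) c(1L, d[2L]) else as.integer(cols)
  check_range <- function(rg, hi, what) {
    if (length(rg) != 2L || anyNA(rg) || rg[1L] > rg[2L])
      stop("empty or malformed ", what, " range", call. = FALSE)
    if (rg[1L] < 1L || rg[2L] > hi)
      stop(what, " range [", rg[1L], ", ", rg[2L],
           "] outside image bounds 1..", hi, call. = FALSE)
  }
  check_range(rows, d[1L], "row")
  check_range(cols, d[2L], "col")
  out <- cube$values[rows[1L]:rows[2L], cols[1L]:cols[2L], , drop = FALSE]
  meta <- cube$meta
  meta$crop_offset <- c(row = rows[1L], col = cols[1L])
  hsi_cube(out, cube$wavelengths, meta)
}

#' Construct a label image
#'
#' An integer per-pixel class map. Label 0 is reserved for "unclassified";
#' valid classes are `1..n_classes`.
#'
#' @param labels Integer matrix of per-pixel labels in `0..n_classes`.
#' @param n_classes Number of valid classes. Defaults to `max(labels)`.
#' @param legend Optional named character vector mapping label (as name) to a
#'   class name.
#' @return An object of class `label_image`.
#' @export
label_image <- function(labels, n_classes = NULL, legend = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(labels, 0L)
  n_classes <- as.integer(n_classes)
  if (any(labels > n_classes))
    stop("labels exceed n_classes = ", n_classes, call. = FALSE)
  structure(list(labels = labels, n_classes = n_classes, legend = legend),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d, %d classes (%d px unclassified)\n",
              nrow(x$labels), ncol(x$labels), x$n_classes,
              sum(x$labels == 0L)))
  invisible(x)
}

#' Construct a binary per-pixel mask
#'
#' @param values Matrix with entries 0/1 (logical matrices are coerced).
#' @param role Either `"decision"` (a classifier output) or `"reference"`
#'   (ground truth).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, role = c("decision", "reference")) {
  role <- match.arg(role)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (is.logical(values)) values <- values * 1L
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("mask values must be 0 or 1", call. = FALSE)
  structure(list(values = values, role = role), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask role=%s> %d x %d, %d positive px\n",
              x$role, nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

# Flatten a cube to a pixels x bands matrix in row-major pixel order
# (pixel p <-> row = (p - 1) %/% ncols + 1, col = (p - 1) %% ncols + 1), so
# that which.max over pixels breaks ties at the smallest (row, col).
cube_matrix <- function(cube) {
  d <- dim(cube$values)
  m <- matrix(aperm(cube$values, c(2L, 1L, 3L)), nrow = d[1L] * d[2L],
              ncol = d[3L])
  attr(m, "cube_dim") <- d
  m
}

# Inverse of cube_matrix for a per-pixel vector (row-major order) -> matrix.
pixel_matrix <- function(v, d) {
  matrix(v, nrow = d[1L], ncol = d[2L], byrow = TRUE)
}

# row-major pixel index -> (row, col)
pixel_rc <- function(p, d) {
  c(row = (p - 1L) %/% d[2L] + 1L, col = (p - 1L) %% d[2L] + 1L)
}
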