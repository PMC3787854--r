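#' Spectral angle between two spectra
#'
#' Treats the two spectra as vectors in band space and returns the angle
#' between them: `acos(<x, ref> / (||x|| ||ref||))`, with the cosine clipped
#' to \[-1, 1\] to absorb floating-point overshoot. The angle is invariant
#' under positive scaling of either argument, which is what makes
#' angle-based classification robust to illumination (light/shadow)
#' differences. For non-negative spectra the angle lies in \[0, pi/2\].
#'
#' @param x,ref Numeric vectors of equal length; neither may be all-zero.
#' @return Angle in radians.
#' @examples
#' spectral_angle(c(1, 0), c(1, 1))  # pi/4
#' @export
spectral_angle <- function(x, ref) {
  x <- as.numeric(x); ref <- as.numeric(ref)
  if (length(x) != length(ref))
    stop("spectra must have equal length", call. = FALSE)
  nx <- sqrt(sum(x^2)); nr <- sqrt(sum(ref^2))
  if (nx == 0 || nr == 0)
    stop("spectral angle undefined for the zero vector", call. = FALSE)
  acos(min(1, max(-1, sum(x * ref) / (nx * nr))))
}

#' Spectral angle mapper classification of a cube
#'
#' Assigns each pixel to the reference signature subtending the smallest
#' spectral angle (ties broken by the lowest reference label). If
#' `threshold` is given, pixels whose winning angle exceeds it are left
#' unclassified (label 0). Pixels with an all-zero spectrum have no defined
#' angle: they are labelled 0 and their angle is `NA`.
#'
#' @param cube An [hsi_cube].
#' @param refs A [signature_set] of reference endmembers; all must be
#'   nonzero and match the cube's band count.
#' @param threshold Optional maximum acceptable angle in radians.
#' @return An object of class `sam_result`: list with `labels` (a
#'   [label_image]), `angles` (per-pixel winning angle, radians), and
#'   `threshold`.
#' @export
sam_classify <- function(cube, refs, threshold = NULL) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(refs, "signature_set"))
  R <- refs$values
  if (nrow(R) < 1L) stop("reference set is empty", call. = FALSE)
  if (ncol(R) != n_bands(cube))
    stop("reference length does not match cube band count", call. = FALSE)
  refnorm <- sqrt(rowSums(R^2))
  if (any(refnorm == 0))
    stop("all-zero reference signature(s): ",
         paste(which(refnorm == 0), collapse = ", "), call. = FALSE)
  if (!is.null(threshold)) {
    threshold <- as.numeric(threshold)
    if (!is.finite(threshold) || threshold < 0)
      stop("threshold must be a non-negative angle in radians", call. = FALSE)
  }
  d <- dim(cube$values)
  m <- cube_matrix(cube)
  pixnorm <- sqrt(rowSums(m^2))
  cosines <- (m %*% t(R)) / outer(pmax(pixnorm, .Machine$double.xmin), refnorm)
  cosines[cosines > 1] <- 1
  cosines[cosines < -1] <- -1
  best <- max.col(cosines, ties.method = "first")   # max cos = min angle
  ang <- acos(cosines[cbind(seq_along(best), best)])
  zero_pix <- pixnorm == 0
  best[zero_pix] <- 0L
  ang[zero_pix] <- NA_real_
  if (!is.null(threshold)) {
    rejected <- !zero_pix & ang > threshold
    best[rejected] <- 0L
  }
  labels <- label_image(pixel_matrix(as.integer(best), d),
                        n_classes = nrow(R))
  structure(list(labels = labels, angles = pixel_matrix(ang, d),
                 threshold = threshold),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("<sam_result> %d x %d px, %d references%s\n",
              nrow(x$labels$labels), ncol(x$labels$labels),
              x$labels$n_classes,
              if (is.null(x$threshold)) ""
              else sprintf(", threshold %.3f rad", x$threshold)))
  invisible(x)
}

#' Reduce a label image to a binary decision map
#'
#' Reclassifies a multi-class label map to the two-group outcome
#' pathological (1) / normal (0): a pixel maps to 1 exactly when its label
#' belongs to the designated target ("pathological") classes. Unclassified
#' pixels (label 0) always map to 0.
#'
#' @param labels A [label_image] or a `sam_result`.
#' @param targets Integer vector of pathological class labels (nonempty,
#'   within the label range).
#' @return A decision-role [binary_mask].
#' @export
binarize <- function(labels, targets) {
  if (inherits(labels, "sam_result")) labels <- labels$labels
  stopifnot(inherits(labels, "label_image"))
  targets <- as.integer(targets)
  if (!length(targets)) stop("target label set is empty", call. = FALSE)
  if (any(targets < 1L) || any(targets > labels$n_classes))
    stop("target labels outside class range 1..", labels$n_classes,
         call. = FALSE)
  hit <- matrix(labels$labels %in% targets, nrow(labels$labels),
                ncol(labels$labels))
  binary_mask(hit * 1L, role = "decision")
}

#' Suggest target (pathological) class labels from a reference mask
#'
#' Mechanical stand-in for expert visual identification of pathological
#' clusters: selects every class whose pixel set has precision at least
#' `min_overlap` against the reference mask, i.e.
#' `|class intersect mask| / |class| >= min_overlap`. Deterministic.
#'
#' @param labels A [label_image].
#' @param reference A reference-role [binary_mask] of the same shape.
#' @param min_overlap Required precision, in `(0, 1]` (default 0.5).
#' @return Sorted integer vector of selected class labels.
#' @export
suggest_target_labels <- function(labels, reference, min_overlap = 0.5) {
  stopifnot(inherits(labels, "label_image"), inherits(reference, "binary_mask"))
  if (!all(dim(labels$labels) == dim(reference$values)))
    stop("label image and reference mask shapes differ", call. = FALSE)
  if (min_overlap <= 0 || min_overlap > 1)
    stop("min_overlap must be in (0, 1]", call. = FALSE)
  lab <- as.vector(labels$labels)
  ref <- as.vector(reference$values)
  present <- sort(unique(lab[lab > 0L]))
  prec <- vapply(present, function(l) {
    in_class <- lab == l
    sum(ref[in_class]) / sum(in_class)
  }, numeric(1L))
  sel <- present[prec >= min_overlap]
  if (!length(sel))
    stop("no class reaches precision ", min_overlap,
         " against the reference mask; specify target labels manually",
         call. = FALSE)
  sel
}
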