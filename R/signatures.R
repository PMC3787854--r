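#' Construct a signature set (ordered endmember library)
#'
#' A signature set is an ordered list of per-band spectral signatures
#' (endmembers). The order is the selection order: signature 1 is the first
#' ("strongest") endmember. Signatures must be pairwise distinct.
#'
#' @param values Numeric matrix, one row per signature, one column per band.
#' @param origin Data frame with one row per signature describing provenance:
#'   columns `kind` (`"pixel"`, `"cluster_mean"`, or `"external"`), `row`,
#'   `col` (source pixel, `NA` otherwise), `label` (source cluster, `NA`
#'   otherwise).
#' @param selection_rule Character record of how the ordering was produced
#'   (e.g. `"max_min"`).
#' @param wavelengths Optional band wavelengths (nm) carried for CSV export.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(values, origin = NULL, selection_rule = "external",
                          wavelengths = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("signatures must be finite", call. = FALSE)
  k <- nrow(values)
  if (k >= 2L) {
    d2 <- as.matrix(stats::dist(values))^2
    if (any(d2[upper.tri(d2)] == 0))
      stop("signatures must be pairwise distinct", call. = FALSE)
  }
  if (is.null(origin)) {
    origin <- data.frame(kind = rep("external", k), row = NA_integer_,
                         col = NA_integer_, label = NA_integer_)
  }
  stopifnot(nrow(origin) == k)
  structure(list(values = values, origin = origin,
                 selection_rule = selection_rule,
                 wavelengths = wavelengths),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d signatures x %d bands (rule: %s)\n",
              nrow(x$values), ncol(x$values), x$selection_rule))
  invisible(x)
}

#' @export
as.matrix.signature_set <- function(x, ...) x$values

n_signatures <- function(sigs) nrow(sigs$values)

#' Select endmember signatures by hierarchical farthest-point sampling
#'
#' Builds a hierarchy of the "strongest" spectral signatures in a scene. The
#' seed (signature 1) is the spectrum of the pixel whose sum of squared
#' reflection values over all bands is largest. Each subsequent signature is
#' the pixel spectrum most separable from the already-selected set:
#' under `rule = "max_min"` (the default, farthest-point sampling) it
#' maximizes the minimum squared Euclidean distance to signatures
#' `1..k-1`; under `"max_sum"` it maximizes the sum of squared distances.
#' Ties are broken by the smallest `(row, col)` in row-major order. Pixels
#' spectrally identical to an already-selected signature are never re-selected.
#'
#' @param cube An [hsi_cube].
#' @param n_signatures Number of signatures to select (default 20).
#' @param rule `"max_min"` or `"max_sum"`.
#' @return A [signature_set] with `origin$kind == "pixel"` recording the
#'   source pixel of each signature.
#' @export
select_signatures <- function(cube, n_signatures = 20L,
                              rule = c("max_min", "max_sum")) {
  stopifnot(inherits(cube, "hsi_cube"))
  rule <- match.arg(rule)
  n_signatures <- as.integer(n_signatures)
  d <- dim(cube$values)
  n_pix <- d[1L] * d[2L]
  if (n_signatures < 1L || n_signatures > n_pix)
    stop("n_signatures must be in 1..", n_pix, call. = FALSE)
  m <- cube_matrix(cube)
  norms2 <- rowSums(m^2)

  chosen <- integer(n_signatures)
  chosen[1L] <- which.max(norms2)             # first index = row-major tie-break
  # d2mat[p, j]: squared distance of pixel p to chosen signature j
  d2mat <- matrix(NA_real_, n_pix, n_signatures)
  d2_to <- function(idx) {
    s <- m[idx, ]
    d2 <- pmax(norms2 - 2 * drop(m %*% s) + sum(s^2), 0)
    d2[colSums(abs(t(m) - s)) == 0] <- 0   # exact duplicates, incl. self
    d2
  }
  d2mat[, 1L] <- d2_to(chosen[1L])
  if (n_signatures > 1L) {
    for (k in 2:n_signatures) {
      prev <- d2mat[, seq_len(k - 1L), drop = FALSE]
      mind2 <- do.call(pmin, as.data.frame(prev))
      eligible <- mind2 > 0                   # exclude exact duplicates
      if (!any(eligible))
        stop("cube has only ", k - 1L, " distinct spectra; cannot select ",
             n_signatures, " signatures", call. = FALSE)
      score <- if (rule == "max_min") mind2 else rowSums(prev)
      score[!eligible] <- -Inf
      chosen[k] <- which.max(score)
      d2mat[, k] <- d2_to(chosen[k])
    }
  }
  rc <- t(vapply(chosen, pixel_rc, integer(2L), d = d))
  signature_set(m[chosen, , drop = FALSE],
                origin = data.frame(kind = "pixel", row = rc[, 1L],
                                    col = rc[, 2L], label = NA_integer_),
                selection_rule = rule,
                wavelengths = cube$wavelengths)
}

#' Construct per-class affinity maps
#'
#' @param values Numeric `rows x cols x classes` array. In `"abundance"`
#'   mode values are non-negative mixture proportions; in `"posterior"` mode
#'   they are class probabilities summing to 1 at every pixel.
#' @param model `"abundance"` or `"posterior"`.
#' @param residual Optional per-pixel residual-norm matrix (abundance mode).
#' @return An object of class `affinity_maps`.
#' @export
affinity_maps <- function(values, model = c("abundance", "posterior"),
                          residual = NULL) {
  model <- match.arg(model)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (model == "abundance") {
    if (any(values < -1e-9))
      stop("abundance values must be non-negative", call. = FALSE)
  } else {
    sums <- apply(values, c(1L, 2L), sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("posteriors must sum to 1 at every pixel", call. = FALSE)
  }
  structure(list(values = values, model = model, residual = residual),
            class = "affinity_maps")
}

#' @export
print.affinity_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<affinity_maps model=%s> %d x %d px, %d classes\n",
              x$model, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Linear-mixture-model unmixing of a cube against a signature set
#'
#' Under the linear mixture model a pixel's spectrum R is a weighted
#' combination of the component signatures,
#' `R = f_1 mu_1 + ... + f_N mu_N`, the weights being the surface
#' proportions of each component. For each pixel the abundances `f`
#' minimizing `||R - sum_n f_n mu_n||^2` are estimated subject to the chosen
#' constraint:
#' \describe{
#'   \item{`nonneg`}{`f_n >= 0` (non-negative least squares, the default).}
#'   \item{`nonneg_sum_to_one`}{additionally `sum f_n = 1`, enforced by the
#'     standard row-augmentation of the NNLS system with a large weight.}
#'   \item{`unconstrained`}{ordinary least squares; a rank-deficient
#'     signature matrix is flagged and solved by the least-norm solution.}
#' }
#'
#' @param cube An [hsi_cube].
#' @param sigs A [signature_set]; signature length must equal the band count.
#' @param constraint See above.
#' @return Abundance-mode [affinity_maps] with a per-pixel residual-norm
#'   image in `$residual`.
#' @export
unmix_lmm <- function(cube, sigs,
                      constraint = c("nonneg", "nonneg_sum_to_one",
                                     "unconstrained")) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(sigs, "signature_set"))
  constraint <- match.arg(constraint)
  if (ncol(sigs$values) != n_bands(cube))
    stop("signature length does not match cube band count", call. = FALSE)
  S <- t(sigs$values)                       # bands x K
  K <- ncol(S)
  d <- dim(cube$values)
  m <- cube_matrix(cube)                    # pixels x bands
  n_pix <- nrow(m)

  if (constraint == "unconstrained") {
    qrS <- qr(S)
    if (qrS$rank < K) {
      warning("rank-deficient signature matrix (rank ", qrS$rank, " < ", K,
              "); using least-norm solution", call. = FALSE)
      sv <- svd(S)
      pos <- sv$d > max(sv$d) * 1e-12
      pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      FF <- t(pinv %*% t(m))
    } else {
      FF <- t(qr.coef(qrS, t(m)))
    }
  } else {
    A <- S
    if (constraint == "nonneg_sum_to_one") {
      delta <- 1e4 * max(abs(S))
      A <- rbind(S, rep(delta, K))
    }
    FF <- matrix(0, n_pix, K)
    for (p in seq_len(n_pix)) {
      b <- m[p, ]
      if (constraint == "nonneg_sum_to_one") b <- c(b, delta)
      FF[p, ] <- pracma::lsqnonneg(A, b)$x
    }
  }
  resid_norm <- sqrt(rowSums((m - FF %*% t(S))^2))
  aff <- array(0, c(d[1L], d[2L], K))
  for (k in seq_len(K)) aff[, , k] <- pixel_matrix(FF[, k], d)
  if (constraint != "unconstrained") aff[aff < 0] <- 0
  affinity_maps(aff, model = "abundance",
                residual = pixel_matrix(resid_norm, d))
}

#' Posterior class probabilities under an isotropic-Gaussian model
#'
#' Each class k is modelled as an isotropic Gaussian centred on its
#' signature with shared variance `sigma^2` and uniform prior, so the
#' posterior is `p_k proportional to exp(-||R - mu_k||^2 / (2 sigma^2))`,
#' normalized over classes. With `scale = "auto"` the bandwidth `sigma` is
#' the median over pixels of the Euclidean distance to the nearest
#' signature (falling back to 1 if that median is 0, which only happens
#' when at least half the pixels coincide exactly with a signature).
#'
#' Maximum-posterior assignment ([assign_clusters()]) is invariant to
#' `sigma`: it always reduces to nearest-signature-in-Euclidean-distance.
#'
#' @param cube An [hsi_cube].
#' @param sigs A [signature_set].
#' @param scale Positive bandwidth `sigma`, or `"auto"`.
#' @return Posterior-mode [affinity_maps].
#' @export
posterior_probabilities <- function(cube, sigs, scale = "auto") {
  stopifnot(inherits(cube, "hsi_cube"), inherits(sigs, "signature_set"))
  if (ncol(sigs$values) != n_bands(cube))
    stop("signature length does not match cube band count", call. = FALSE)
  d <- dim(cube$values)
  m <- cube_matrix(cube)
  D2 <- sq_dist_to_sigs(m, sigs$values)     # pixels x K
  if (identical(scale, "auto")) {
    sigma <- stats::median(sqrt(apply(D2, 1L, min)))
    if (sigma == 0) sigma <- 1
  } else {
    sigma <- as.numeric(scale)
    if (!is.finite(sigma) || sigma <= 0)
      stop("posterior bandwidth sigma must be positive", call. = FALSE)
  }
  logp <- -D2 / (2 * sigma^2)
  logp <- logp - apply(logp, 1L, max)       # stable softmax
  P <- exp(logp)
  P <- P / rowSums(P)
  K <- ncol(P)
  aff <- array(0, c(d[1L], d[2L], K))
  for (k in seq_len(K)) aff[, , k] <- pixel_matrix(P[, k], d)
  affinity_maps(aff, model = "posterior")
}

sq_dist_to_sigs <- function(m, sig_values) {
  norms2 <- rowSums(m^2)
  signorm2 <- rowSums(sig_values^2)
  D2 <- outer(norms2, signorm2, "+") - 2 * m %*% t(sig_values)
  pmax(D2, 0)
}

#' Assign each pixel to the class of maximum affinity
#'
#' A comparison of per-class affinities (posterior probabilities or
#' abundances) yields the maximum-likelihood class for each pixel. Ties are
#' broken by the lowest class label. Every pixel receives a label in
#' `1..K`; none remains unclassified.
#'
#' @param aff An [affinity_maps].
#' @return A [label_image] with `n_classes` equal to the number of affinity
#'   classes.
#' @export
assign_clusters <- function(aff) {
  stopifnot(inherits(aff, "affinity_maps"))
  d <- dim(aff$values)
  M <- matrix(aff$values, d[1L] * d[2L], d[3L])   # column-major pixels: fine,
  lab <- max.col(M, ties.method = "first")        # tie-break is per pixel
  label_image(matrix(lab, d[1L], d[2L]), n_classes = d[3L])
}

#' Mean spectral profile of each cluster
#'
#' Extracts one signature per nonempty label as the per-band arithmetic mean
#' over that label's pixels — the spectral profile of the cluster. Empty
#' labels are omitted (and reported via a message); `origin` records the
#' source cluster of each profile.
#'
#' @param cube An [hsi_cube].
#' @param labels A [label_image] of the same spatial shape. Label 0
#'   (unclassified) is ignored.
#' @return A [signature_set] with `origin$kind == "cluster_mean"`.
#' @export
cluster_mean_profiles <- function(cube, labels) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(labels, "label_image"))
  d <- dim(cube$values)
  if (!all(dim(labels$labels) == d[1:2]))
    stop("label image shape does not match cube", call. = FALSE)
  present <- sort(unique(as.vector(labels$labels)))
  present <- present[present > 0L]
  if (!length(present))
    stop("no nonempty labels to profile", call. = FALSE)
  all_labels <- seq_len(labels$n_classes)
  empty <- setdiff(all_labels, present)
  if (length(empty))
    message("omitting empty label(s): ", paste(empty, collapse = ", "))
  B <- d[3L]
  means <- matrix(0, length(present), B)
  lab_vec <- as.vector(labels$labels)              # column-major, matches slices
  for (b in seq_len(B)) {
    band <- as.vector(cube$values[, , b])
    means[, b] <- vapply(present,
                         function(l) mean(band[lab_vec == l]), numeric(1L))
  }
  signature_set(means,
                origin = data.frame(kind = "cluster_mean", row = NA_integer_,
                                    col = NA_integer_, label = present),
                selection_rule = "cluster_mean",
                wavelengths = cube$wavelengths)
}

# --- signature serialization ------------------------------------------------

#' Write a signature set to CSV or JSON
#'
#' CSV layout: one row per signature; wavelength-labelled band columns
#' (`wl_390`, ...) followed by the origin columns and the selection rule.
#'
#' @param sigs A [signature_set].
#' @param path Output path; format dispatched on `.csv` / `.json`.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  ext <- tolower(tools::file_ext(path))
  wl <- sigs$wavelengths %||% default_grid(ncol(sigs$values))
  if (ext == "csv") {
    df <- as.data.frame(sigs$values)
    names(df) <- paste0("wl_", format(wl, trim = TRUE))
    df <- cbind(df, sigs$origin,
                selection_rule = sigs$selection_rule)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(
      list(wavelengths = wl,
           signatures = unname(apply(sigs$values, 1L, identity,
                                     simplify = FALSE)),
           origin = sigs$origin, selection_rule = sigs$selection_rule),
      path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported signature format '.", ext, "'", call. = FALSE)
  invisible(path)
}

#' Read a signature set written by [write_signatures()]
#'
#' @param path `.csv` or `.json` file.
#' @return A [signature_set].
#' @export
read_signatures <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    band_cols <- grep("^wl_", names(df), value = TRUE)
    wl <- as.numeric(sub("^wl_", "", band_cols))
    ord <- order(wl)
    values <- as.matrix(df[, band_cols[ord], drop = FALSE])
    dimnames(values) <- NULL
    origin <- df[, c("kind", "row", "col", "label"), drop = FALSE]
    rule <- if ("selection_rule" %in% names(df)) df$selection_rule[1L]
            else "external"
    signature_set(values, origin = origin, selection_rule = rule,
                  wavelengths = wl[ord])
  } else if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    values <- if (is.matrix(x$signatures)) x$signatures
              else do.call(rbind, lapply(x$signatures, as.numeric))
    signature_set(values, origin = as.data.frame(x$origin),
                  selection_rule = x$selection_rule,
                  wavelengths = as.numeric(x$wavelengths))
  } else stop("unsupported signature format '.", ext, "'", call. = FALSE)
}
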