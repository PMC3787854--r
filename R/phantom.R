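#' Built-in synthetic tissue reflectance profiles
#'
#' Documented synthetic constants on the 30-band 390-680 nm grid (10 nm
#' steps), qualitatively shaped after the tissue classes of narrow-band
#' laryngeal endoscopy; they are not measured patient spectra.
#' \describe{
#'   \item{`mucosa_like`}{healthy mucosa background: smooth reflectance
#'     rising from 0.30 at 390 nm to 0.62 at 680 nm.}
#'   \item{`polyp_like`}{hemorrhagic-polyp-like lesion: constant 0.24 from
#'     390 to 580 nm, then a saturating (flattening) increase to 680 nm.}
#'   \item{`leukoplakia_like`}{white-plaque-like lesion: bright and nearly
#'     flat, 0.60 to 0.68 across the range.}
#' }
#' Pairwise spectral angles between the three profiles are 0.14-0.25 rad.
#'
#' @param name One of `"mucosa_like"`, `"polyp_like"`, `"leukoplakia_like"`.
#' @param wavelengths Band grid in nm; defaults to `seq(390, 680, by = 10)`.
#' @return Numeric reflectance vector, one value per band.
#' @export
builtin_profile <- function(name, wavelengths = seq(390, 680, by = 10)) {
  wl <- as.numeric(wavelengths)
  u <- (wl - 390) / 290
  switch(name,
    mucosa_like = 0.30 + 0.32 * pmax(u, 0)^1.3,
    polyp_like = ifelse(wl <= 580, 0.24,
                        0.24 + 0.30 * (1 - exp(-(wl - 580) / 60))),
    leukoplakia_like = 0.60 + 0.08 * u,
    stop("unknown profile '", name, "'; available: mucosa_like, ",
         "polyp_like, leukoplakia_like", call. = FALSE))
}

#' Specify a synthetic endoscopic hyperspectral phantom
#'
#' A phantom emulates the statistical structure of a narrow-band endoscopic
#' image stack: a dominant background tissue, one or more lesion regions
#' with distinct spectral profiles, a smooth multiplicative illumination
#' field (light/shadow contrast), and additive sensor noise.
#'
#' @param shape `c(rows, cols)`; default `c(128, 110)`.
#' @param wavelengths Band grid in nm; default `seq(390, 680, by = 10)`.
#' @param background Background profile: a name understood by
#'   [builtin_profile()] or a numeric per-band vector.
#' @param lesions List of lesion regions. Each is a list with `shape`
#'   (`"ellipse"` or `"blob"`), `center = c(row, col)`, `radii = c(a, b)`
#'   in pixels, optional `angle` (rotation, radians), optional `wobble` and
#'   `lobes` (blob boundary modulation), and `profile` (name or numeric
#'   vector).
#' @param illumination List: `type` (`"gradient"` or `"uniform"`),
#'   `direction` (radians), `strength` (peak relative deviation of the
#'   linear gradient, default 0.25), `vignette` (relative corner darkening,
#'   default 0.15).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the mean
#'   noise-free signal (default 0.02). Negative draws are truncated at zero.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise
#'   scaled so the SD at the mean signal matches `noise_sd`).
#' @param seed Integer random seed; identical specs with identical seeds
#'   generate bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 110L),
                         wavelengths = seq(390, 680, by = 10),
                         background = "mucosa_like",
                         lesions = list(list(shape = "ellipse",
                                             center = c(64, 55),
                                             radii = c(22, 16),
                                             angle = 0.5,
                                             profile = "polyp_like")),
                         illumination = list(type = "gradient",
                                             direction = pi / 6,
                                             strength = 0.25,
                                             vignette = 0.15),
                         noise_sd = 0.02,
                         noise_model = c("gaussian", "poisson"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  wavelengths <- as.numeric(wavelengths)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  resolve_profile <- function(p) {
    v <- if (is.character(p)) builtin_profile(p, wavelengths) else as.numeric(p)
    if (length(v) != length(wavelengths))
      stop("profile length does not match band count", call. = FALSE)
    if (any(v <= 0)) stop("profiles must be strictly positive", call. = FALSE)
    v
  }
  bg_name <- if (is.character(background)) background else "background"
  bg <- resolve_profile(background)
  lesions <- lapply(lesions, function(l) {
    l$shape <- match.arg(l$shape %||% "ellipse", c("ellipse", "blob"))
    l$angle <- l$angle %||% 0
    l$wobble <- l$wobble %||% if (l$shape == "blob") 0.25 else 0
    l$lobes <- l$lobes %||% 5L
    l$profile_name <- if (is.character(l$profile)) l$profile else "lesion"
    l$profile_values <- resolve_profile(l$profile)
    rmax <- max(l$radii) * (1 + l$wobble)
    if (l$center[1L] - rmax < 1 || l$center[1L] + rmax > shape[1L] ||
        l$center[2L] - rmax < 1 || l$center[2L] + rmax > shape[2L])
      stop("lesion region extends outside image bounds", call. = FALSE)
    l
  })
  structure(list(shape = shape, wavelengths = wavelengths,
                 background_name = bg_name, background = bg,
                 lesions = lesions, illumination = illumination,
                 noise_sd = noise_sd, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize one lesion region to a logical matrix.
rasterize_lesion <- function(l, shape) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dr <- r - l$center[1L]
  dc <- c_ - l$center[2L]
  ca <- cos(l$angle); sa <- sin(l$angle)
  x <- ca * dr + sa * dc
  y <- -sa * dr + ca * dc
  rho <- sqrt((x / l$radii[1L])^2 + (y / l$radii[2L])^2)
  if (l$wobble > 0) {
    theta <- atan2(y / l$radii[2L], x / l$radii[1L])
    rho <- rho / (1 + l$wobble * sin(l$lobes * theta))
  }
  rho <= 1
}

# Smooth multiplicative illumination field, strictly positive.
illumination_field <- function(illum, shape) {
  type <- illum$type %||% "gradient"
  if (type == "uniform") return(matrix(1, shape[1L], shape[2L]))
  strength <- illum$strength %||% 0.25
  vignette <- illum$vignette %||% 0.15
  if (strength >= 1 || vignette >= 1)
    stop("illumination strength and vignette must be < 1 to keep the field positive",
         call. = FALSE)
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dir <- illum$direction %||% 0
  # projection along `dir`, normalized to [-1, 1] across the frame
  proj <- cos(dir) * (r - (shape[1L] + 1) / 2) +
    sin(dir) * (c_ - (shape[2L] + 1) / 2)
  span <- max(abs(proj))
  if (span > 0) proj <- proj / span
  field <- 1 + strength * proj
  if (vignette > 0) {
    rr <- ((r - (shape[1L] + 1) / 2) / (shape[1L] / 2))^2 +
      ((c_ - (shape[2L] + 1) / 2) / (shape[2L] / 2))^2
    field <- field * (1 - vignette * rr / max(rr))
  }
  field
}

#' Generate a synthetic phantom from a specification
#'
#' Each pixel spectrum is `illumination(row, col) * profile(region)` plus
#' additive noise, truncated at zero. Identical spec and seed give
#' bit-identical output. Overlapping lesion regions with different profiles
#' are rejected (the ground truth would be ambiguous); overlaps sharing one
#' profile are merged into the earlier region.
#'
#' @param spec A [phantom_spec].
#' @return List with `cube` (an [hsi_cube]), `mask` (reference
#'   [binary_mask]; 1 = any lesion region), and `labels` (a [label_image]
#'   with background = 1, lesion i = i + 1, and a legend of profile names).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  B <- length(spec$wavelengths)
  region <- matrix(1L, shape[1L], shape[2L])
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    hit <- rasterize_lesion(l, shape)
    clash <- hit & region > 1L
    if (any(clash)) {
      other <- spec$lesions[[region[which(clash)[1L]] - 1L]]
      if (!identical(other$profile_values, l$profile_values))
        stop("overlapping lesion regions with different profiles: ",
             "ground truth would be ambiguous", call. = FALSE)
      hit <- hit & region == 1L
    }
    region[hit] <- i + 1L
  }
  profiles <- rbind(spec$background,
                    do.call(rbind, lapply(spec$lesions,
                                          function(l) l$profile_values)))
  illum <- illumination_field(spec$illumination, shape)
  vals <- array(0, c(shape, B))
  for (b in seq_len(B)) {
    vals[, , b] <- illum * matrix(profiles[region, b], shape[1L], shape[2L])
  }
  if (spec$noise_sd > 0) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(spec$seed)
    mean_signal <- mean(vals)
    if (spec$noise_model == "gaussian") {
      sd_abs <- spec$noise_sd * mean_signal
      vals <- vals + stats::rnorm(length(vals), sd = sd_abs)
    } else {
      gain <- spec$noise_sd^2 * mean_signal
      vals <- stats::rpois(length(vals), lambda = vals / gain) * gain
    }
    vals[vals < 0] <- 0
    vals <- array(vals, c(shape, B))
  }
  legend <- c("background" = 1L,
              stats::setNames(seq_along(spec$lesions) + 1L,
                              vapply(spec$lesions, function(l) l$profile_name,
                                     character(1L))))
  legend <- stats::setNames(names(legend), as.character(legend))
  list(cube = hsi_cube(vals, spec$wavelengths,
                       meta = list(source = "synthetic phantom",
                                   seed = spec$seed)),
       mask = binary_mask((region > 1L) * 1L, role = "reference"),
       labels = label_image(region, n_classes = length(spec$lesions) + 1L,
                            legend = legend))
}

#' Generate a phantom pair for signature-transfer experiments
#'
#' Produces two phantoms that share their spectral profiles (the band grid
#' and the background/lesion profile assignment must match) but have
#' independent lesion geometry, illumination fields, and noise draws —
#' the case-pair design in which endmembers learned on image A classify
#' image B.
#'
#' @param spec_a,spec_b [phantom_spec] objects sharing `wavelengths` and
#'   profile names.
#' @return List with elements `a` and `b`, each as returned by
#'   [generate_phantom()].
#' @export
generate_phantom_pair <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "phantom_spec"), inherits(spec_b, "phantom_spec"))
  if (!isTRUE(all.equal(spec_a$wavelengths, spec_b$wavelengths)))
    stop("phantom pair must share the same band grid", call. = FALSE)
  profs <- function(s) c(s$background_name,
                         sort(unique(vapply(s$lesions,
                                            function(l) l$profile_name,
                                            character(1L)))))
  if (!identical(profs(spec_a), profs(spec_b)))
    stop("phantom pair must share background and lesion profile names",
         call. = FALSE)
  list(a = generate_phantom(spec_a), b = generate_phantom(spec_b))
}
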