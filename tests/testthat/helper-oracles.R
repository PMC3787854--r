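# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use explicit per-pixel loops and none of the package's
# vectorized internals.

rand_cube <- function(rows, cols, bands, seed = NULL, max_val = 1) {
  if (!is.null(seed)) set.seed(seed)
  hsi_cube(array(runif(rows * cols * bands, 0.01, max_val),
                 c(rows, cols, bands)),
           wavelengths = seq(400, by = 10, length.out = bands))
}

# Exhaustive hierarchical selection: scan every pixel at every iteration.
oracle_select <- function(cube, n, rule = "max_min") {
  v <- cube$values
  d <- dim(v)
  pix <- vector("list", d[1L] * d[2L])
  rc <- matrix(0L, d[1L] * d[2L], 2L)
  i <- 0L
  for (r in seq_len(d[1L])) for (cc in seq_len(d[2L])) {
    i <- i + 1L
    pix[[i]] <- v[r, cc, ]
    rc[i, ] <- c(r, cc)
  }
  ss <- vapply(pix, function(s) sum(s^2), numeric(1L))
  chosen <- which.max(ss)
  while (length(chosen) < n) {
    best <- -Inf
    best_i <- NA_integer_
    for (i in seq_along(pix)) {
      d2 <- vapply(chosen, function(j) sum((pix[[i]] - pix[[j]])^2),
                   numeric(1L))
      if (min(d2) == 0) next
      sc <- if (rule == "max_min") min(d2) else sum(d2)
      if (sc > best) {
        best <- sc
        best_i <- i
      }
    }
    if (is.na(best_i)) stop("oracle: no distinct pixel left")
    chosen <- c(chosen, best_i)
  }
  list(rc = rc[chosen, , drop = FALSE],
       values = do.call(rbind, pix[chosen]))
}

# Per-pixel angle scan.
oracle_sam <- function(cube, ref_values) {
  d <- dim(cube$values)
  lab <- matrix(0L, d[1L], d[2L])
  ang <- matrix(NA_real_, d[1L], d[2L])
  for (r in seq_len(d[1L])) for (cc in seq_len(d[2L])) {
    x <- cube$values[r, cc, ]
    if (sum(x^2) == 0) next
    a <- apply(ref_values, 1L, function(s)
      acos(min(1, max(-1, sum(x * s) / sqrt(sum(x^2) * sum(s^2))))))
    lab[r, cc] <- which.min(a)
    ang[r, cc] <- min(a)
  }
  list(labels = lab, angles = ang)
}

# Per-pixel argmax scan with lowest-label ties.
oracle_assign <- function(aff_values) {
  d <- dim(aff_values)
  lab <- matrix(0L, d[1L], d[2L])
  for (r in seq_len(d[1L])) for (cc in seq_len(d[2L])) {
    v <- aff_values[r, cc, ]
    lab[r, cc] <- which(v == max(v))[1L]
  }
  lab
}

# Per-pixel confusion tally.
oracle_confusion <- function(dec, ref) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(dec)) {
    if (dec[i] == 1L && ref[i] == 1L) tp <- tp + 1L
    else if (dec[i] == 0L && ref[i] == 1L) fn <- fn + 1L
    else if (dec[i] == 1L && ref[i] == 0L) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Per-band accumulation of cluster means.
oracle_cluster_means <- function(cube, labels) {
  d <- dim(cube$values)
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0]
  out <- matrix(0, length(present), d[3L])
  for (li in seq_along(present)) {
    acc <- numeric(d[3L])
    cnt <- 0L
    for (r in seq_len(d[1L])) for (cc in seq_len(d[2L])) {
      if (labels[r, cc] == present[li]) {
        acc <- acc + cube$values[r, cc, ]
        cnt <- cnt + 1L
      }
    }
    out[li, ] <- acc / cnt
  }
  list(labels = present, means = out)
}

# Small phantom pair sharing profiles but differing in geometry,
# illumination, and noise draws; sized for seconds-scale tests.
small_pair_specs <- function(noise_sd = 0.02, seed_a = 11L, seed_b = 22L) {
  list(
    a = phantom_spec(shape = c(48L, 40L),
                     lesions = list(list(shape = "ellipse",
                                         center = c(24, 20),
                                         radii = c(9, 6), angle = 0.4,
                                         profile = "polyp_like")),
                     illumination = list(type = "gradient", direction = 0.5,
                                         strength = 0.25, vignette = 0.15),
                     noise_sd = noise_sd, seed = seed_a),
    b = phantom_spec(shape = c(48L, 40L),
                     lesions = list(list(shape = "ellipse",
                                         center = c(30, 24),
                                         radii = c(7, 10), angle = -0.9,
                                         profile = "polyp_like")),
                     illumination = list(type = "gradient", direction = 2.1,
                                         strength = 0.25, vignette = 0.15),
                     noise_sd = noise_sd, seed = seed_b))
}
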