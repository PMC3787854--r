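#' Configuration for one classification phase
#'
#' Collects the tunable choices of the pipeline: the number of endmember
#' signatures (default 20, the point past which additional clusters carry
#' increasingly little tissue information), the successor-selection rule,
#' the posterior bandwidth, the optional spectral-angle rejection threshold,
#' and how target (pathological) classes are resolved.
#'
#' @param cube Input cube: a path readable by [read_cube()] or an
#'   [hsi_cube].
#' @param reference Optional reference mask: a path readable by
#'   [read_mask()] or a [binary_mask].
#' @param out_dir Output directory for artifacts; created if missing.
#'   `NULL` keeps results in memory only.
#' @param n_signatures Number of endmembers to select (default 20).
#' @param rule Successor-selection rule, `"max_min"` or `"max_sum"`.
#' @param scale Posterior bandwidth sigma, or `"auto"`.
#' @param abundance Whether to compute linear-mixture abundance maps for
#'   inspection (default `TRUE`); cluster assignment always uses posteriors.
#' @param constraint Abundance constraint for [unmix_lmm()].
#' @param sam_threshold Optional maximum acceptable spectral angle
#'   (radians); `NULL` assigns every pixel.
#' @param targets Optional integer vector of pathological cluster labels;
#'   when `NULL` they are suggested from the reference mask via
#'   [suggest_target_labels()].
#' @param min_overlap Precision threshold for [suggest_target_labels()].
#' @param wavelengths Optional wavelengths for path inputs.
#' @param seed Seed recorded in the run manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cube, reference = NULL, out_dir = NULL,
                            n_signatures = 20L,
                            rule = c("max_min", "max_sum"),
                            scale = "auto", abundance = TRUE,
                            constraint = "nonneg",
                            sam_threshold = NULL, targets = NULL,
                            min_overlap = 0.5, wavelengths = NULL,
                            seed = 1L) {
  rule <- match.arg(rule)
  if (n_signatures < 1L) stop("n_signatures must be >= 1", call. = FALSE)
  if (min_overlap <= 0 || min_overlap > 1)
    stop("min_overlap must be in (0, 1]", call. = FALSE)
  structure(list(cube = cube, reference = reference, out_dir = out_dir,
                 n_signatures = as.integer(n_signatures), rule = rule,
                 scale = scale, abundance = abundance,
                 constraint = constraint, sam_threshold = sam_threshold,
                 targets = targets, min_overlap = min_overlap,
                 wavelengths = wavelengths, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Only path-based configurations round-trip (in-memory cubes and masks
#' have no file representation).
#'
#' @param config A [pipeline_config].
#' @param path YAML file path.
#' @return `read_config` returns a [pipeline_config]; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.character(config$cube %||% ""))
    stop("only path-based configs can be serialized to YAML", call. = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1L))])
}

resolve_cube <- function(x, wavelengths = NULL) {
  if (inherits(x, "hsi_cube")) x
  else read_cube(x, wavelengths = wavelengths)
}

resolve_mask <- function(x, role = "reference") {
  if (is.null(x)) NULL
  else if (inherits(x, "binary_mask")) x
  else read_mask(x, role = role)
}

#' Run the unsupervised phase: endmember selection and cluster mapping
#'
#' Selects `n_signatures` endmembers by hierarchical farthest-point
#' sampling, computes posterior class probabilities, assigns each pixel to
#' its maximum-posterior cluster, extracts cluster-mean spectral profiles,
#' and (optionally) computes linear-mixture abundance maps for inspection.
#' When `out_dir` is set, artifacts (cluster map, signature and profile
#' CSVs, affinity RDS) and a JSON run manifest with content hashes are
#' written.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with `cube`, `signatures`, `posterior`,
#'   `clusters`, `profiles`, `abundance` (or `NULL`), and `paths`.
#' @export
run_unsupervised <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cube <- resolve_cube(config$cube, config$wavelengths)
  sigs <- select_signatures(cube, config$n_signatures, config$rule)
  post <- posterior_probabilities(cube, sigs, config$scale)
  clusters <- assign_clusters(post)
  profiles <- suppressMessages(cluster_mean_profiles(cube, clusters))
  abund <- if (isTRUE(config$abundance))
    unmix_lmm(cube, sigs, config$constraint) else NULL
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_label_image(clusters, p("clusters.tif"))
    write_signatures(sigs, p("signatures.csv"))
    write_signatures(profiles, p("profiles.csv"))
    saveRDS(post, p("posterior.rds"))
    if (!is.null(abund)) saveRDS(abund, p("abundance.rds"))
    paths <- c(clusters = p("clusters.tif"), signatures = p("signatures.csv"),
               profiles = p("profiles.csv"), posterior = p("posterior.rds"),
               if (!is.null(abund)) c(abundance = p("abundance.rds")))
    write_manifest(config, inputs = character(0), outputs = paths,
                   path = p("manifest.json"))
    paths <- c(paths, manifest = p("manifest.json"))
  }
  invisible(list(cube = cube, signatures = sigs, posterior = post,
                 clusters = clusters, profiles = profiles,
                 abundance = abund, paths = paths))
}

#' Run the full hybrid workflow: cluster A, transfer, classify B, validate
#'
#' Phase A (unsupervised) clusters cube A and extracts its cluster-mean
#' endmembers. All endmembers transfer to cube B, which is classified with
#' the spectral angle mapper; the target ("pathological") classes —
#' supplied explicitly in `config_b$targets` as phase-A cluster labels, or
#' suggested from phase A's reference mask — are reduced to a binary
#' decision map. If a reference mask for B is available the decision map is
#' validated with confusion-matrix sensitivity, specificity, and bias;
#' otherwise validation is skipped with a warning and the decision map is
#' still produced.
#'
#' @param config_a [pipeline_config] for the training cube (phase A).
#' @param config_b [pipeline_config] for the target cube (phase B).
#' @return Invisibly, a list with `phase_a` (the [run_unsupervised()]
#'   result), `sam`, `decision`, `targets` (phase-A cluster labels),
#'   `metrics` (or `NULL`), and `paths`.
#' @export
run_hybrid <- function(config_a, config_b) {
  stopifnot(inherits(config_a, "pipeline_config"),
            inherits(config_b, "pipeline_config"))
  res_a <- run_unsupervised(config_a)
  targets <- config_b$targets %||% config_a$targets
  if (is.null(targets)) {
    ref_a <- resolve_mask(config_a$reference)
    if (is.null(ref_a))
      stop("no target labels given and phase A has no reference mask; ",
           "set `targets` or provide a reference for suggest_target_labels()",
           call. = FALSE)
    targets <- suggest_target_labels(res_a$clusters, ref_a,
                                     config_a$min_overlap)
  }
  targets <- as.integer(targets)
  refs <- res_a$profiles
  ref_idx <- which(refs$origin$label %in% targets)
  if (!length(ref_idx))
    stop("target labels ", paste(targets, collapse = ", "),
         " match no transferred cluster profile", call. = FALSE)
  cube_b <- resolve_cube(config_b$cube, config_b$wavelengths)
  sam <- sam_classify(cube_b, refs, threshold = config_b$sam_threshold)
  decision <- binarize(sam$labels, ref_idx)
  ref_b <- resolve_mask(config_b$reference)
  metrics <- NULL
  if (is.null(ref_b)) {
    warning("no reference mask for the target cube: validation skipped, ",
            "decision map still written", call. = FALSE)
  } else {
    metrics <- detection_metrics(confusion(decision, ref_b))
  }
  paths <- NULL
  if (!is.null(config_b$out_dir)) {
    dir.create(config_b$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config_b$out_dir, f)
    write_label_image(sam$labels, p("sam_labels.tif"))
    write_mask(decision, p("decision.png"))
    saveRDS(sam, p("sam.rds"))
    paths <- c(sam_labels = p("sam_labels.tif"), decision = p("decision.png"),
               sam = p("sam.rds"))
    if (!is.null(metrics)) {
      write_metrics(metrics, p("metrics.json"))
      paths <- c(paths, metrics = p("metrics.json"))
    }
    write_manifest(config_b, inputs = res_a$paths %||% character(0),
                   outputs = paths, path = p("manifest.json"),
                   extra = list(targets = targets))
    paths <- c(paths, manifest = p("manifest.json"))
  }
  invisible(list(phase_a = res_a, sam = sam, decision = decision,
                 targets = targets, metrics = metrics, paths = paths))
}

# JSON run manifest: configuration, package version, content hashes.
write_manifest <- function(config, inputs, outputs, path, extra = list()) {
  serializable <- unclass(config)
  serializable <- serializable[vapply(serializable, function(x)
    is.null(x) || is.atomic(x), logical(1L))]
  manifest <- c(list(
    package = "hybridhsi",
    version = as.character(utils::packageVersion("hybridhsi")),
    config = serializable,
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    output_md5 = as.list(tools::md5sum(unname(outputs)))), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
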